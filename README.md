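# sichml

Machine-learning prediction of **symptomatic intracranial haemorrhage
(SICH)** after stroke thrombolysis, from whole-brain CT intensity images
combined with clinical severity.

Intravenous tPA for acute ischemic stroke carries a ~6% risk of SICH.
Bedside risk scores (SEDAN, HAT) combine clinical variables with
radiologist CT readings, but their discrimination is modest and the
radiology inputs suffer substantial inter-rater variability. `sichml`
implements and evaluates the alternative of learning directly from the
image: a soft-margin support-vector classifier over the subject's entire
preprocessed CT voxel vector, with **per-sample box constraints
proportional to baseline NIHSS**,

    max_a  sum_i a_i - 1/2 sum_ij a_i a_j y_i y_j k(x_i, x_j)
    s.t.   0 <= a_i <= C * NIHSS_i / mean(NIHSS),   sum_i a_i y_i = 0,

so that clinically severe strokes contribute proportionately more to the
fitted margin (sign convention: negative decision distance = SICH-like).
Because cohorts of this kind are not publicly deposited, the package
includes a synthetic cohort generator with the statistical structure the
analysis assumes, making every stage testable end to end.

## What the package provides

- **Synthetic cohorts** — `generate_cohort()` (case–control sampling from a
  latent logistic risk model over NIHSS, ischemia extent and background
  hypoattenuation burden), `render_ct()` (two-section CT phantom volumes,
  NIfTI-1 I/O), `simulate_raters()` / `consensus_reading()` with
  `calibrate_rater_noise()` inverting the closed-form expected Cohen's
  kappa so simulated raters hit target agreement levels.
- **Preprocessing** — rigid template registration by coarse-to-fine
  normalized-cross-correlation search (`normalize_section()`), section
  joining with overlap averaging and unsampled-seam sentinels
  (`join_sections()`), brain masking, the anomalous-voxel deletion /
  mean-imputation rule (`clean_cohort()`, with a full audit trail), and
  multiplicative global intensity correction.
- **Prognostic scores** — `sedan_score()`, `hat_score()`, their adapted
  (NIHSS + radiology only) variants, and univariate logistic odds ratios
  (`univariate_or()`, `univariate_table()`).
- **SVM** — `nihss_to_caps()`, `train_svm()` (sequential minimal
  optimization with per-sample caps, C++ core), `decision_distance()`,
  the radiology-feature `train_manual_svm()`, and `ablate()`
  (no-NIHSS / no-base / single-hemisphere variants).
- **Evaluation** — repeated 1-case + 9-foil splits (`make_split_plan()`),
  deterministic distance ranking and modal-rank identification,
  ten-threshold ROC AUC, exact binomial chance probabilities, and a paired
  bootstrap model comparison (`compare_models()`).
- **Pipeline** — `run_pipeline()` executes simulate → preprocess → score →
  train → evaluate → report from one `run_config()`, deterministically per
  master seed, with a hash manifest; `inst/cli/sichml.R` is a thin shell
  wrapper.

## Worked example

```r
library(sichml)
cfg <- run_config(n_sich = 8, n_control = 40, foil_sets_per_case = 10,
                  grid = list(nx = 32L, ny = 32L, nz = 20L,
                              upper_slices = 14L, lower_slices = 8L),
                  signal_amplitude = 2.5, jitter = FALSE,
                  registration = "none", n_boot = 500)
res <- run_pipeline(cfg, seed = 7, out_dir = "sichml_demo")
res$report
#>           model   auc auc_lo auc_hi identified         modal_ranks p_vs_ref
#> 1 automated_svm 0.695  0.463  0.938          4     1 1 8 1 3 1 9 3       NA
#> 2    manual_svm 0.471  0.363  0.544          1   2 10 10 2 4 1 4 8    0.020
#> 3         sedan 0.567  0.405  0.735          0     3 2 4 9 3 3 9 9    0.340
#> 4           hat 0.518  0.322  0.720          3 1 1 10 7 10 1 10 10    0.000
#> 5 adapted_sedan 0.505  0.390  0.595          0    4 4 4 8 6 4 7 10    0.152
#> 6   adapted_hat 0.518  0.322  0.720          3 1 1 10 7 10 1 10 10    0.000
```

Each row is one prognostic model evaluated on the same case–foil split
plan. `auc` is the ten-threshold ROC area over all pooled test distances
(with a bootstrap 95% interval over SICH cases); `modal_ranks` is, per SICH
case, the commonest rank (1 = most SICH-like of the 10 test subjects) that
model assigned it across its foil sets; `identified` counts cases with
modal rank 1. Here the image-based SVM identifies 4 of 8 cases and attains
the highest AUC; with this strong synthetic image signal it outperforms
score-based prediction. The chance probability of identifying, say, 9 of 16
cases at a 10% hit rate is `binomial_chance_probability(16, 9, 0.1)` =
5.5e-06.

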