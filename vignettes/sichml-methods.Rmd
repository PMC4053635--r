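---
title: "Predicting post-thrombolysis haemorrhage from CT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting post-thrombolysis haemorrhage from CT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sichml)
```

## The problem

Intravenous thrombolysis (tPA) for acute ischemic stroke carries a roughly 6%
risk of symptomatic intracranial haemorrhage (SICH) — neurological
deterioration attributable to imaging-confirmed bleeding within a week of
treatment. Established bedside risk scores (SEDAN, HAT) combine a handful of
clinical variables with radiologist readings of the baseline CT, but their
discrimination is modest and the radiology inputs are noisy (inter-rater
kappa for acute ischemic change is only about 0.35). `sichml` implements an
alternative: a support-vector classifier that takes the *whole* preprocessed
CT intensity image as its feature vector, weights each training subject's
influence by clinical stroke severity (NIHSS), and is evaluated by a
repeated case–foil ranking design. Because clinical CT cohorts of this kind
are not publicly deposited, the package ships a synthetic cohort generator
with the statistical structure the analysis assumes, so every stage is
testable end to end.

## The synthetic cohort generator

`generate_cohort()` draws subjects from a latent risk model and fixes the
case–control composition by rejection, preserving the latent–outcome
dependence that a real case–control sample would show.

Latent state per subject: presence of acute ischemia (prevalence 0.29), the
involved fraction of the MCA territory given ischemia (Beta(1, 3)), a
diffuse background hypoattenuation burden (Gamma(2, 0.5); proxy for
small-vessel disease, old infarcts and atrophy), a hyperdense MCA sign
(probability 0.58 given ischemia, 0.04 otherwise), a Fazekas grade, and a
lesion side. NIHSS is coupled to ischemia extent
(`round(11 + 16 * fraction + N(0, 4.5))`, clamped to 0–42), reflecting that
clinical severity partly measures infarct volume.

SICH risk is logistic on standardized NIHSS, ischemia fraction and burden
with coefficients (0.5, 1.0, 1.0); the intercept (−3.55) sets the population
rate near 6%. The standardization constants are fixed in the configuration
(not re-estimated from data) so stored probabilities can be re-evaluated
exactly from stored latents, and were chosen, together with the marginals
above, so that a 16-case / 100-control sample reproduces the group contrasts
a cohort of this kind reports: NIHSS ≈ 15.5 vs 12.0, acute ischemia ≈ 57%
vs 27%, >1/3 MCA involvement ≈ 35% vs 7%, hyperdense MCA ≈ 35% vs 19%.
These defaults are the study conditions; they are deliberately not exposed
as tuning levers anywhere downstream.

What the generator does *not* emulate: real anatomy (the phantom is an
ellipsoid with schematic ventricles, skull, lesions), scanner artefacts
other than Gaussian noise and rigid jitter, asymptomatic haemorrhages, and
non-improving non-SICH controls. Passing tests therefore demonstrate that
the pipeline recovers the kind of signal it assumes, not that it would
perform comparably on clinical data.

### Rater simulation

Three independent raters read each scan. Binary features flip with a
symmetric per-feature error rate; `calibrate_rater_noise()` inverts the
closed-form expected kappa of two independent symmetric-noise raters,

$$\kappa(\varepsilon) = \frac{P_o - P_e}{1 - P_e},\quad
P_o = (1-\varepsilon)^2 + \varepsilon^2,\quad
q = p + \varepsilon(1 - 2p),\quad P_e = q^2 + (1-q)^2,$$

by bisection, so the default flip rates hit the reported agreement levels
(kappa 0.355 for acute ischemia at prevalence 0.27; 0.673 for the
hyperdense MCA sign at prevalence 0.17). Symmetric error is a modelling
choice: agreement statistics alone cannot identify asymmetric error rates,
so one parameter per feature is the most that is inferable. Fazekas grades
get discrete ±1 noise clamped to 0–3. Consensus is 2-of-3 majority for
binary features and the arithmetic mean for Fazekas; the consensus used by
the scores is the binary one, since score definitions are integer-pointed.

## CT phantom and preprocessing

Each subject's scan is rendered on a common grid (default 64 × 64 × 40
voxels; the full template-space size is a configuration option) and sampled
into two overlapping axial sections — upper cerebrum and brain base — as
clinical CT brains often are. Parenchyma sits near 35 HU, ventricles near
8 HU, skull at 800 HU, air at −1000 HU. Risk-bearing features are: a
hypoattenuating wedge in the lateral MCA sector whose angular size is the
ischemia fraction (−7 HU at unit amplitude), a low-spatial-frequency
texture scaled by background burden, and the hyperdense vessel dot. All
three scale with `signal_amplitude`, so amplitude 0 produces images that
carry *no* outcome information — the null condition used in testing. A
small per-section rigid jitter emulates imperfect spatial normalization.

Preprocessing follows the two-section design:

1. **Rigid registration** (`normalize_section()`): coarse-to-fine grid
   search over 3 translations and one in-plane rotation maximizing
   normalized cross-correlation against a featureless template rendering;
   the first two passes run on a 2× downsampled grid, the last at full
   resolution with a 0.1-voxel step. A best correlation under 0.5 raises a
   registration failure. This deliberately replaces nonlinear
   template normalization: the generator only ever applies rigid jitter,
   so a rigid correction is the matched inverse.
2. **Joining** (`join_sections()`): overlap voxels take the mean of the two
   sections, single-section voxels pass through, voxels sampled by neither
   carry an `NA` sentinel — never a fabricated value.
3. **Masking** (`apply_brain_mask()`): an inclusive brain mask without
   ventricles, eroded away from the skull; voxels are vectorized in fixed
   x-fastest, 0-based order so a column always addresses the same
   coordinate across subjects.
4. **Cleaning** (`clean_cohort()`): a cell is anomalous if < 0 HU,
   > 200 HU, or unsampled. Voxels anomalous in ≥ 5 subjects are deleted;
   remaining anomalous cells are imputed with the voxel's mean over
   non-anomalous subjects. Unsampled join voxels are handled under the same
   rule — one uniform policy. The retained-column count is data-dependent.
5. **Global intensity correction** (`global_intensity_correct()`):
   multiplicative rescaling of each subject to the pre-correction grand
   mean. Multiplication (rather than subtraction) preserves HU ratios and
   non-negativity. Note a consequence: a *uniform* hypoattenuation
   component is removed by this step, so diffuse-burden signal survives
   only through its spatial texture.

## Prognostic scores

`sedan_score()` and `hat_score()` implement the validated point systems
(SEDAN: glucose 8.1–12.0 mmol/L = 1, > 12.0 = 2; age > 75 = 1;
NIHSS ≥ 10 = 1; early ischemic change = 1; dense artery = 1. HAT:
glucose > 11.1 mmol/L = 1; NIHSS 15–20 = 1, > 20 = 2; hypodensity < 1/3
MCA = 1, ≥ 1/3 = 2). The *adapted* variants keep only the NIHSS and
radiological components at identical weights, giving ranges 0–3 (SEDAN) and
0–4 (HAT); an adapted HAT maximum of 4 follows arithmetically from removing
the single glucose point. `univariate_or()` is a single-predictor logistic
fit; for binary exposures it equals the 2×2 cross-product ratio, and
complete separation is flagged rather than reported as a finite estimate.

## The soft-margin SVM with per-sample caps

Training solves the usual dual

$$\max_\alpha \sum_i \alpha_i - \tfrac12 \sum_{ij} \alpha_i \alpha_j y_i y_j
k(x_i, x_j) \quad \text{s.t.}\quad 0 \le \alpha_i \le C_i,\ \ \textstyle\sum_i \alpha_i y_i = 0,$$

except that each subject has an individual box constraint
$C_i = C \cdot \mathrm{NIHSS}_i / \overline{\mathrm{NIHSS}}$
(`nihss_to_caps()`; a zero NIHSS is floored at 0.01 C). "Proportionate" is
read as mean-normalized linear — the simplest scale-free mapping. The
solver (`smo_solve`, C++) is sequential minimal optimization with
maximal-violating-pair working-set selection; ties resolve to the lowest
index, making the solution deterministic given the input order. The default
multilayer-perceptron kernel $k(u,v) = \tanh(\langle u,v\rangle - 1)$ is
indefinite, so pairwise curvatures are floored and convergence is reported
(with the KKT residual) rather than assumed; the linear kernel is the safe,
and practically preferable, choice for whole-image inputs, whose raw HU dot
products saturate the tanh. Sign convention throughout: **negative decision
distance = SICH-like** (cases are labelled −1).

Two regimes of the penalty scale deserve note. Raw whole-image features give
Gram diagonals of order $10^6$–$10^7$, so at the default $C = 1$ the
separable 106-subject training sets solve in the interior of the box and the
NIHSS weighting is effectively inactive; caps begin to bind when $C$ is of
the order of the reciprocal Gram scale. Both regimes are legitimate
soft-margin machines; the package keeps features raw (no per-voxel
standardization) and $C = 1$ as defaults and leaves the regime to the
configuration. The "manual" SVM, whose three features (NIHSS, ischemia
extent 0/1/2, hyperdense MCA 0/1) carry incommensurate units, standardizes
them — refit inside each training split so no test information leaks.

Ablations (`ablate()`): `NO_NIHSS` replaces the caps by uniform ones;
`NO_BASE` drops voxels below the upper section's first slice;
`SINGLE_HEMISPHERE` mirrors right-lesion subjects in x so every lesion maps
to one half-grid and keeps only columns whose mirror survived cleaning.

## Case-foil evaluation

`make_split_plan()` draws, for each SICH case, `foil_sets_per_case`
mutually distinct sets of 9 distinct controls (uniformly, without
within-set replacement) — the only reading of a fixed-size repeated design
consistent with "1 case + 9 foils, all combinations distinct". At the
default 16 + 100 and 110 sets per case this is 1760 splits of 106 training
and 10 test subjects, testing under an assumed 10% SICH frequency. Per
split, test subjects are ranked by decision distance (rank 1 = most
SICH-like; ties by subject id — deterministic). Per case, the modal rank
across its splits summarizes performance, ties resolving toward the smaller
rank; a case is *identified* if its modal rank is 1. The ROC uses ten
evenly spaced thresholds across the pooled distances of all splits
(pooled, so each model yields one curve), augmented with (0,0) and (1,1)
and integrated by trapezoid; a degenerate pooled range returns 0.5 with a
warning. `binomial_chance_probability()` gives the exact chance level of an
identification count. `compare_models()` is a *declared surrogate*: a
paired bootstrap over SICH cases (splits resampled with case multiplicity),
reported as such, because no named test is prescribed for this design.

## Numerical choices and problem sizes

- SMO stopping tolerance 1e-6 on the KKT gap, budget 2e5 iterations;
  curvature floor 1e-12; bias from free support vectors, else the midpoint
  of the violation bracket.
- Registration search: ±1.6 voxels, ±2° by default, three passes
  (coarse/fine/full-resolution); correlation floor 0.5.
- Cleaning bounds are inclusive at 0 and 200 HU (strictly outside is
  anomalous); the brain phantom floors parenchyma at 3 HU so noiseless
  renderings never produce anomalous brain voxels.
- Per-stage pipeline seeds derive from the master seed by a fixed counter
  scheme (`master %% 1e5 * 20011 + stage * 7919 mod 2^31 − 1`), so stages
  can be reproduced in isolation.
- The test suite exercises the pipeline at desk scale by choice: a
  32 × 32 × 20 grid for preprocessing/null checks and the default
  64 × 64 × 40 grid with 15 foil sets per case for the recovery check. The
  null condition (amplitude 0) is summarized as the mean held-out AUC over
  10 generator seeds; the recovery condition uses a strong image signal
  (amplitude 3 — a wedge depth near 21 HU, i.e. an established-infarct-like
  lesion rather than subtle early change), under which the automated SVM
  matches or beats both adapted scores' identified counts in at least 8 of
  10 seeds. At realistic amplitude 1 the adapted HAT score — which reads
  two of the three generative risk factors directly — rivals the automated
  SVM; that competitive regime is expected, not a defect.

## Limitations

The phantom is schematic; registration is rigid-only by design; the
generator's risk model is the same family the scores discretize, which
flatters the scores in a way real data need not; and the bootstrap model
comparison is a surrogate for an unspecified test. Real-data performance
claims are out of scope: the package demonstrates the machinery, its
determinism, and its statistical behaviour under a known generative truth.

## A minimal run

```{r example, eval = FALSE}
cfg <- run_config(n_sich = 4, n_control = 20, foil_sets_per_case = 5,
                  grid = list(nx = 32L, ny = 32L, nz = 20L,
                              upper_slices = 14L, lower_slices = 8L),
                  n_boot = 200)
res <- run_pipeline(cfg, seed = 1, out_dir = tempfile("sichml_run"))
res$report
```
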