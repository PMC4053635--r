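#' Default generative configuration for the synthetic stroke cohort
#'
#' Returns the parameter list that drives [generate_cohort()]. The defaults
#' describe a thrombolysed acute ischemic stroke population in which the risk
#' of symptomatic intracranial haemorrhage (SICH) loads on clinical severity
#' (NIHSS), on the extent of focal acute ischemia within the middle cerebral
#' artery (MCA) territory, and on diffuse background hypoattenuation burden
#' (small-vessel disease / atrophy). The SICH label is drawn from a logistic
#' model over those three factors; the intercept is set so the population
#' SICH rate is approximately 6%, the complication rate reported for
#' intravenous tPA.
#'
#' @details
#' Components:
#' \describe{
#'   \item{prev_ischemia}{probability that visible acute ischemic change is
#'     present on the baseline CT.}
#'   \item{frac_shape1, frac_shape2}{Beta shape parameters for the fraction of
#'     the MCA territory involved, given ischemia is present.}
#'   \item{burden_shape, burden_scale}{Gamma parameters for the unitless
#'     diffuse background hypoattenuation burden (mean 1 at defaults).}
#'   \item{nihss_base, nihss_slope, nihss_sd}{NIHSS is generated as
#'     \code{round(base + slope * ischemia_fraction + N(0, sd))} clamped to
#'     0..42, coupling clinical severity to ischemia extent.}
#'   \item{p_hyperdense_isch, p_hyperdense_no_isch}{probability of a
#'     hyperdense MCA sign given ischemia present / absent.}
#'   \item{fazekas_probs}{marginal distribution of the Fazekas white-matter
#'     score 0..3.}
#'   \item{logistic_coefs, logistic_intercept}{risk-model coefficients on
#'     standardized (NIHSS, ischemia fraction, background burden), and the
#'     intercept fixing the population SICH rate.}
#'   \item{standardize}{population means/sds used to standardize the three
#'     risk inputs (fixed constants, so stored probabilities can be
#'     re-evaluated exactly from the stored latents).}
#' }
#' Remaining entries are marginal distributions of the clinical variables
#' (age, treatment delay, systolic blood pressure, glucose, INR, platelets,
#' gender, prior anti-thrombotic therapy), which do not enter the risk model.
#'
#' @param ... named overrides of any default component.
#' @return A named list of class `cohort_params`.
#' @export
cohort_params <- function(...) {
  p <- list(
    prev_ischemia = 0.29,
    frac_shape1 = 1.0, frac_shape2 = 3.0,
    burden_shape = 2, burden_scale = 0.5,
    nihss_base = 11, nihss_slope = 16, nihss_sd = 4.5,
    p_hyperdense_isch = 0.58, p_hyperdense_no_isch = 0.04,
    fazekas_probs = c(0.35, 0.35, 0.20, 0.10),
    logistic_coefs = c(nihss = 0.5, ischemia_fraction = 1.0, burden = 1.0),
    logistic_intercept = -3.55,
    standardize = list(
      nihss = c(mean = 12.8, sd = 9.0),
      ischemia_fraction = c(mean = 0.073, sd = 0.25),
      burden = c(mean = 1.0, sd = 0.707)
    ),
    p_male = 0.51,
    p_antithrombotic = 0.64,
    age_mean = 73.5, age_sd = 11,
    delay_mean = 145, delay_sd = 35,
    sbp_mean = 161, sbp_sd = 24,
    glucose_meanlog = log(7.3), glucose_sdlog = 0.22,
    inr_mean = 1.1, inr_sd = 0.2,
    platelets_mean = 237, platelets_sd = 60,
    max_attempts = 500000L
  )
  dots <- list(...)
  stopifnot(all(names(dots) %in% names(p)))
  p[names(dots)] <- dots
  structure(p, class = "cohort_params")
}

# SICH probability from latent risk factors; exported so the label-latent
# consistency of a generated cohort can be re-checked from stored latents.
#' Evaluate the latent SICH risk model
#'
#' Computes P(SICH) from NIHSS, MCA ischemia fraction and background burden
#' under the logistic risk model of a [cohort_params()] configuration.
#'
#' @param nihss,ischemia_fraction,burden numeric vectors of latent risk inputs.
#' @param params a [cohort_params()] list.
#' @return Vector of probabilities in (0, 1).
#' @export
sich_risk <- function(nihss, ischemia_fraction, burden, params = cohort_params()) {
  s <- params$standardize
  z <- cbind(
    (nihss - s$nihss["mean"]) / s$nihss["sd"],
    (ischemia_fraction - s$ischemia_fraction["mean"]) / s$ischemia_fraction["sd"],
    (burden - s$burden["mean"]) / s$burden["sd"]
  )
  stats::plogis(params$logistic_intercept + drop(z %*% params$logistic_coefs))
}

draw_subjects <- function(n, params) {
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  ischemia_present <- stats::runif(n) < params$prev_ischemia
  frac <- ifelse(ischemia_present,
                 stats::rbeta(n, params$frac_shape1, params$frac_shape2), 0)
  burden <- stats::rgamma(n, shape = params$burden_shape, scale = params$burden_scale)
  nihss <- as.integer(clamp(round(params$nihss_base + params$nihss_slope * frac +
                                    stats::rnorm(n, 0, params$nihss_sd)), 0, 42))
  hyper <- stats::runif(n) < ifelse(ischemia_present,
                                    params$p_hyperdense_isch,
                                    params$p_hyperdense_no_isch)
  fazekas <- sample(0:3, n, replace = TRUE, prob = params$fazekas_probs)
  side <- sample(c("L", "R"), n, replace = TRUE)
  p_sich <- sich_risk(nihss, frac, burden, params)
  outcome <- stats::runif(n) < p_sich

  clinical <- data.frame(
    gender_male = stats::runif(n) < params$p_male,
    age = clamp(stats::rnorm(n, params$age_mean, params$age_sd), 30, 100),
    treatment_delay = clamp(stats::rnorm(n, params$delay_mean, params$delay_sd), 30, 270),
    nihss = nihss,
    sbp = clamp(stats::rnorm(n, params$sbp_mean, params$sbp_sd), 90, 240),
    glucose = stats::rlnorm(n, params$glucose_meanlog, params$glucose_sdlog),
    inr = clamp(stats::rnorm(n, params$inr_mean, params$inr_sd), 0.8, 4),
    platelets = clamp(stats::rnorm(n, params$platelets_mean, params$platelets_sd), 50, 600),
    antithrombotic = stats::runif(n) < params$p_antithrombotic,
    outcome = ifelse(outcome, "SICH", "NO_SICH"),
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    ischemia_present = ischemia_present,
    ischemia_fraction_mca = frac,
    hyperdense_mca = hyper,
    fazekas = fazekas,
    background_burden = burden,
    lesion_side = side,
    sich_probability = p_sich,
    stringsAsFactors = FALSE
  )
  list(clinical = clinical, truth = truth)
}

#' Generate a synthetic case-control stroke thrombolysis cohort
#'
#' Draws subjects from the generative risk model of [cohort_params()] and
#' retains, by rejection, exactly `n_sich` subjects whose SICH label came up
#' positive and `n_control` whose label came up negative — preserving the
#' dependence between the latent risk factors and the outcome (cases are
#' enriched in high NIHSS, large ischemic fractions and high background
#' burden, as in a real case-control design).
#'
#' @param n_sich number of SICH cases to retain (>= 1).
#' @param n_control number of non-SICH controls to retain (>= 1).
#' @param params generative configuration from [cohort_params()].
#' @param seed integer seed; the cohort is bitwise reproducible given it.
#' @return A list with elements `clinical` (one row per subject: `subject_id`,
#'   `gender_male`, `age`, `treatment_delay`, `nihss`, `sbp`, `glucose`,
#'   `inr`, `platelets`, `antithrombotic`, `outcome`) and `truth` (the latent
#'   generative state per subject: `ischemia_present`,
#'   `ischemia_fraction_mca`, `hyperdense_mca`, `fazekas`,
#'   `background_burden`, `lesion_side`, `sich_probability`). Rows align.
#' @export
generate_cohort <- function(n_sich, n_control, params = cohort_params(), seed = 1L) {
  stopifnot(n_sich >= 1, n_control >= 1, inherits(params, "cohort_params"))
  set.seed(as.integer(seed))
  got_case <- 0L; got_ctrl <- 0L; attempts <- 0L
  keep_clin <- list(); keep_truth <- list()
  batch <- max(64L, 4L * (n_sich + n_control))
  while (got_case < n_sich || got_ctrl < n_control) {
    if (attempts >= params$max_attempts) {
      stop("rejection sampling exceeded ", params$max_attempts,
           " attempts; generative params make the requested case-control ",
           "composition infeasible")
    }
    d <- draw_subjects(batch, params)
    attempts <- attempts + batch
    is_case <- d$clinical$outcome == "SICH"
    take_case <- which(is_case)[seq_len(min(sum(is_case), n_sich - got_case))]
    take_ctrl <- which(!is_case)[seq_len(min(sum(!is_case), n_control - got_ctrl))]
    take <- sort(c(take_case, take_ctrl))
    if (length(take)) {
      keep_clin[[length(keep_clin) + 1L]] <- d$clinical[take, , drop = FALSE]
      keep_truth[[length(keep_truth) + 1L]] <- d$truth[take, , drop = FALSE]
    }
    got_case <- got_case + length(take_case)
    got_ctrl <- got_ctrl + length(take_ctrl)
  }
  clinical <- do.call(rbind, keep_clin)
  truth <- do.call(rbind, keep_truth)
  rownames(clinical) <- rownames(truth) <- NULL
  clinical <- cbind(subject_id = sprintf("S%03d", seq_len(nrow(clinical))),
                    clinical, stringsAsFactors = FALSE)
  truth <- cbind(subject_id = clinical$subject_id, truth, stringsAsFactors = FALSE)
  list(clinical = clinical, truth = truth)
}
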