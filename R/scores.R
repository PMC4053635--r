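#' SEDAN score (0-6)
#'
#' Blood Sugar, Early infarct signs, Dense cerebral artery, Age, NIHSS.
#' Component points follow the original validated score: baseline glucose
#' 8.1-12.0 mmol/L scores 1 and > 12.0 scores 2; age > 75 years, baseline
#' NIHSS >= 10, early ischemic change on CT, and a hyperdense cerebral
#' artery sign score 1 each.
#'
#' @param record one-row data frame / list with `glucose` (mmol/L), `age`
#'   (years), `nihss`.
#' @param consensus one-row consensus reading with logical `acute_ischemia`
#'   and `hyperdense_mca`.
#' @return List: `score` (integer 0-6) and `breakdown` (named component
#'   points summing to the score).
#' @export
sedan_score <- function(record, consensus) {
  need(record, c("glucose", "age", "nihss"))
  need(consensus, c("acute_ischemia", "hyperdense_mca"))
  b <- c(
    glucose = if (record$glucose > 12) 2L else if (record$glucose >= 8.1) 1L else 0L,
    age = as.integer(record$age > 75),
    nihss = as.integer(record$nihss >= 10),
    acute_ischemia = as.integer(isTRUE(as.logical(consensus$acute_ischemia))),
    hyperdense_mca = as.integer(isTRUE(as.logical(consensus$hyperdense_mca)))
  )
  list(score = sum(b), breakdown = b)
}

#' HAT score (0-5)
#'
#' Hemorrhage After Thrombolysis score: baseline glucose > 11.1 mmol/L
#' (diabetes proxy) scores 1; baseline NIHSS 15-20 scores 1 and > 20 scores
#' 2; visible hypodensity under 1/3 of the MCA territory scores 1 and >= 1/3
#' scores 2.
#'
#' @inheritParams sedan_score
#' @param consensus consensus reading with logical `acute_ischemia` and
#'   `gt_third_mca`.
#' @return List: `score` (integer 0-5) and `breakdown`.
#' @export
hat_score <- function(record, consensus) {
  need(record, c("glucose", "nihss"))
  need(consensus, c("acute_ischemia", "gt_third_mca"))
  isch <- isTRUE(as.logical(consensus$acute_ischemia))
  gt3 <- isch && isTRUE(as.logical(consensus$gt_third_mca))
  b <- c(
    glucose = as.integer(record$glucose > 11.1),
    nihss = if (record$nihss > 20) 2L else if (record$nihss >= 15) 1L else 0L,
    hypodensity = if (gt3) 2L else if (isch) 1L else 0L
  )
  list(score = sum(b), breakdown = b)
}

#' Adapted SEDAN and HAT scores (radiology + NIHSS components only)
#'
#' The adapted variants drop the non-significant clinical components
#' (glucose from both; age from SEDAN) while keeping the remaining
#' component weights identical, giving an adapted SEDAN of 0-3 and an
#' adapted HAT of 0-4.
#'
#' @inheritParams sedan_score
#' @return List: `adapted_sedan`, `adapted_hat`, and their breakdowns.
#' @export
adapted_scores <- function(record, consensus) {
  s <- sedan_score(record, consensus)
  h <- hat_score(record, consensus)
  bs <- s$breakdown[c("nihss", "acute_ischemia", "hyperdense_mca")]
  bh <- h$breakdown[c("nihss", "hypodensity")]
  list(adapted_sedan = sum(bs), adapted_hat = sum(bh),
       sedan_breakdown = bs, hat_breakdown = bh)
}

need <- function(x, fields) {
  miss <- fields[!fields %in% names(x)]
  ok <- vapply(fields[fields %in% names(x)],
               function(f) !is.null(x[[f]]) && !is.na(x[[f]]), logical(1))
  if (length(miss) || !all(ok)) {
    stop("missing score component(s): ",
         paste(c(miss, fields[fields %in% names(x)][!ok]), collapse = ", "))
  }
  invisible(TRUE)
}

#' Score panel for a whole cohort
#'
#' @param clinical clinical table from [generate_cohort()].
#' @param consensus consensus readings from [consensus_reading()], same
#'   subjects.
#' @return Data frame with `subject_id`, `sedan`, `hat`, `adapted_sedan`,
#'   `adapted_hat`.
#' @export
score_panel <- function(clinical, consensus) {
  stopifnot(identical(clinical$subject_id, consensus$subject_id))
  rows <- lapply(seq_len(nrow(clinical)), function(i) {
    rec <- clinical[i, ]; con <- consensus[i, ]
    a <- adapted_scores(rec, con)
    data.frame(subject_id = rec$subject_id,
               sedan = sedan_score(rec, con)$score,
               hat = hat_score(rec, con)$score,
               adapted_sedan = a$adapted_sedan,
               adapted_hat = a$adapted_hat,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Univariate logistic odds ratio for one predictor of SICH
#'
#' Single-predictor logistic regression (iteratively reweighted least
#' squares via [stats::glm()]), returning the odds ratio per unit of the
#' exposure with its Wald 95% confidence interval and p-value. For a binary
#' exposure with all four 2x2 cells occupied this equals the cross-product
#' ratio. Complete separation is flagged instead of returning a spurious
#' finite estimate.
#'
#' @param exposure numeric or logical per-subject exposure.
#' @param outcome logical (or "SICH"/"NO_SICH") per-subject outcome.
#' @return List: `odds_ratio`, `ci95` (length 2), `p`, `separated` (logical).
#' @export
univariate_or <- function(exposure, outcome) {
  if (is.character(outcome)) outcome <- outcome == "SICH"
  y <- as.numeric(outcome)
  x <- as.numeric(exposure)
  stopifnot(length(x) == length(y), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2) stop("need both outcome classes")
  fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
  sm <- summary(fit)$coefficients
  beta <- sm["x", "Estimate"]; se <- sm["x", "Std. Error"]
  separated <- !fit$converged || abs(beta) > 15 || se > 100
  if (separated) {
    return(list(odds_ratio = NA_real_, ci95 = c(NA_real_, NA_real_),
                p = NA_real_, separated = TRUE))
  }
  list(odds_ratio = exp(beta),
       ci95 = exp(beta + c(-1, 1) * stats::qnorm(0.975) * se),
       p = sm["x", "Pr(>|z|)"],
       separated = FALSE)
}

#' Univariate odds-ratio table for a cohort
#'
#' Fits [univariate_or()] for each requested clinical/radiological variable
#' and reports group summaries, mirroring a baseline-characteristics table.
#'
#' @param clinical clinical table.
#' @param consensus consensus readings (may be `NULL` to skip CT variables).
#' @return Data frame: `variable`, `mean_sich`, `mean_no_sich`,
#'   `odds_ratio`, `ci_lo`, `ci_hi`, `p`.
#' @export
univariate_table <- function(clinical, consensus = NULL) {
  y <- clinical$outcome == "SICH"
  vars <- list(
    gender_male = as.numeric(clinical$gender_male),
    age = clinical$age,
    treatment_delay = clinical$treatment_delay,
    nihss = clinical$nihss,
    sbp = clinical$sbp,
    glucose = clinical$glucose,
    inr = clinical$inr,
    platelets = clinical$platelets,
    antithrombotic = as.numeric(clinical$antithrombotic)
  )
  if (!is.null(consensus)) {
    stopifnot(identical(clinical$subject_id, consensus$subject_id))
    vars$ct_acute_ischemia <- as.numeric(consensus$acute_ischemia)
    vars$ct_gt_third_mca <- as.numeric(consensus$gt_third_mca)
    vars$ct_hyperdense_mca <- as.numeric(consensus$hyperdense_mca)
    vars$ct_fazekas <- consensus$fazekas
  }
  rows <- lapply(names(vars), function(v) {
    x <- vars[[v]]
    u <- univariate_or(x, y)
    data.frame(variable = v, mean_sich = mean(x[y]), mean_no_sich = mean(x[!y]),
               odds_ratio = u$odds_ratio, ci_lo = u$ci95[1], ci_hi = u$ci95[2],
               p = u$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Odds ratio from 2x2 cell counts
#'
#' Convenience wrapper: expands (exposed cases, unexposed cases, exposed
#' controls, unexposed controls) into subject-level vectors and runs the
#' logistic fit of [univariate_or()].
#'
#' @param a,b,c_,d exposed-case, unexposed-case, exposed-control,
#'   unexposed-control counts.
#' @return As [univariate_or()].
#' @export
or_from_cells <- function(a, b, c_, d) {
  exposure <- c(rep(1, a), rep(0, b), rep(1, c_), rep(0, d))
  outcome <- c(rep(TRUE, a + b), rep(FALSE, c_ + d))
  univariate_or(exposure, outcome)
}
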