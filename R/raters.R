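#' Cohen's kappa for two binary readings
#'
#' Chance-corrected agreement between two vectors of binary judgements,
#' using the raters' empirical marginals for the chance term.
#'
#' @param a,b logical (or 0/1) vectors of equal length.
#' @return Kappa in \[-1, 1\]; exactly 1 for identical readings.
#' @export
cohen_kappa <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  stopifnot(length(a) == length(b), length(a) > 0)
  po <- mean(a == b)
  pa <- mean(a); pb <- mean(b)
  pe <- pa * pb + (1 - pa) * (1 - pb)
  if (abs(1 - pe) < 1e-12) return(if (po >= 1) 1 else 0)
  (po - pe) / (1 - pe)
}

# Expected kappa between two independent raters who each misread a binary
# truth of prevalence p with symmetric flip probability eps. Observed
# agreement (both correct or both flipped) is prevalence-free; the chance
# term uses the common marginal q = p + eps(1 - 2p).
expected_kappa <- function(eps, prevalence) {
  po <- (1 - eps)^2 + eps^2
  q <- prevalence + eps * (1 - 2 * prevalence)
  pe <- q^2 + (1 - q)^2
  (po - pe) / (1 - pe)
}

#' Calibrate the per-rater flip rate to a target inter-rater kappa
#'
#' Finds, by bisection on the closed-form expected-kappa function, the
#' symmetric misclassification rate such that two independent raters reading
#' the same binary truth (of the given prevalence) have expected Cohen's
#' kappa equal to `kappa_target`. Expected kappa falls monotonically from 1
#' at flip rate 0 to 0 at flip rate 1/2, so any target in (0, 1] is
#' attainable at any non-degenerate prevalence.
#'
#' @param kappa_target desired pairwise kappa, in (0, 1].
#' @param prevalence truth prevalence, in (0, 1).
#' @param tol bisection tolerance on the flip rate.
#' @return The flip probability in \[0, 0.5).
#' @export
calibrate_rater_noise <- function(kappa_target, prevalence, tol = 1e-10) {
  if (!(kappa_target > 0 && kappa_target <= 1)) {
    stop("kappa_target must lie in (0, 1]")
  }
  if (!(prevalence > 0 && prevalence < 1)) stop("prevalence must lie in (0, 1)")
  if (kappa_target == 1) return(0)
  lo <- 0; hi <- 0.5
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (expected_kappa(mid, prevalence) > kappa_target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Simulate three independent neuroradiologist readings per subject
#'
#' Each rater reports the binary CT features (acute ischemia, > 1/3 MCA
#' involvement, hyperdense MCA sign) equal to the latent truth with an
#' independent per-feature flip probability, and the Fazekas white-matter
#' grade with discrete +-1 noise clamped to 0..3. A rater who reads acute
#' ischemia as absent cannot report > 1/3 MCA involvement.
#'
#' @param truths `truth` data frame from [generate_cohort()].
#' @param flip_rates named list/vector of per-feature flip probabilities in
#'   \[0, 0.5): `acute_ischemia`, `gt_third_mca`, `hyperdense_mca`,
#'   `fazekas` (the latter is the probability of a +-1 mis-grade).
#' @param seed integer seed.
#' @param n_raters number of raters (3 in the study design).
#' @return Data frame with one row per subject x rater: `subject_id`,
#'   `rater_id`, `acute_ischemia`, `gt_third_mca`, `hyperdense_mca`,
#'   `fazekas`.
#' @export
simulate_raters <- function(truths, flip_rates = default_flip_rates(),
                            seed = 1L, n_raters = 3L) {
  fr <- unlist(flip_rates)[c("acute_ischemia", "gt_third_mca",
                             "hyperdense_mca", "fazekas")]
  if (any(is.na(fr)) || any(fr < 0) || any(fr >= 0.5)) {
    stop("flip rates must be named and lie in [0, 0.5)")
  }
  set.seed(as.integer(seed))
  n <- nrow(truths)
  truth_gt3 <- truths$ischemia_fraction_mca >= 1 / 3
  out <- vector("list", n_raters)
  for (r in seq_len(n_raters)) {
    flip <- function(x, rate) xor(x, stats::runif(n) < rate)
    ai <- flip(truths$ischemia_present, fr["acute_ischemia"])
    gt3 <- flip(truth_gt3, fr["gt_third_mca"]) & ai
    hd <- flip(truths$hyperdense_mca, fr["hyperdense_mca"])
    step <- sample(c(-1L, 0L, 1L), n, replace = TRUE,
                   prob = c(fr["fazekas"] / 2, 1 - fr["fazekas"], fr["fazekas"] / 2))
    fz <- pmin(pmax(truths$fazekas + step, 0L), 3L)
    out[[r]] <- data.frame(subject_id = truths$subject_id, rater_id = r,
                           acute_ischemia = ai, gt_third_mca = gt3,
                           hyperdense_mca = hd, fazekas = fz,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res[order(res$subject_id, res$rater_id), , drop = FALSE]
}

#' Default per-feature rater flip rates
#'
#' Acute-ischemia and hyperdense-MCA flip rates are calibrated so that
#' pairwise inter-rater kappa matches the reported agreement levels (0.355
#' for acute ischemic change at prevalence 0.27; 0.673 for the hyperdense
#' MCA sign at prevalence 0.17). The > 1/3 MCA grading reuses the
#' acute-ischemia noise level; Fazekas mis-grading is a nominal 20%.
#'
#' @return Named list of flip probabilities.
#' @export
default_flip_rates <- function() {
  ai <- calibrate_rater_noise(0.355, 0.27)
  list(acute_ischemia = ai,
       gt_third_mca = ai,
       hyperdense_mca = calibrate_rater_noise(0.673, 0.17),
       fazekas = 0.2)
}

#' Consensus reading across the three raters
#'
#' Binary features are combined by 2-of-3 majority; the Fazekas grade by the
#' arithmetic mean (real-valued). The implication that > 1/3 MCA involvement
#' requires acute ischemia is re-imposed on the consensus.
#'
#' @param readings data frame from [simulate_raters()] (exactly 3 raters per
#'   subject).
#' @return Data frame with one row per subject: consensus `acute_ischemia`,
#'   `gt_third_mca`, `hyperdense_mca` (logical) and `fazekas` (numeric mean).
#' @export
consensus_reading <- function(readings) {
  sp <- split(readings, readings$subject_id)
  rows <- lapply(sp, function(d) {
    if (nrow(d) != 3L) stop("need exactly 3 raters per subject, got ", nrow(d),
                            " for ", d$subject_id[1])
    maj <- function(x) sum(x) >= 2L
    ai <- maj(d$acute_ischemia)
    data.frame(subject_id = d$subject_id[1],
               acute_ischemia = ai,
               gt_third_mca = maj(d$gt_third_mca) && ai,
               hyperdense_mca = maj(d$hyperdense_mca),
               fazekas = mean(d$fazekas),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res[match(unique(readings$subject_id), res$subject_id), , drop = FALSE]
}

#' Mean pairwise kappa among the raters of one feature
#'
#' @param readings data frame from [simulate_raters()].
#' @param feature column name of the binary feature.
#' @return Mean of the three pairwise Cohen's kappas.
#' @export
mean_pairwise_kappa <- function(readings, feature = "acute_ischemia") {
  raters <- sort(unique(readings$rater_id))
  cols <- lapply(raters, function(r) {
    d <- readings[readings$rater_id == r, ]
    d[[feature]][order(d$subject_id)]
  })
  pairs <- utils::combn(length(raters), 2)
  mean(apply(pairs, 2, function(p) cohen_kappa(cols[[p[1]]], cols[[p[2]]])))
}
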