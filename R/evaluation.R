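#' Build the repeated case-foil split plan
#'
#' For every SICH case, draws `foil_sets_per_case` distinct sets of 9
#' different non-SICH subjects (uniformly, without replacement within a
#' set); each split tests the case against its 9 foils and trains on all
#' remaining subjects. With 16 cases, 100 controls and 110 foil sets per
#' case this yields the full 1760-split design (train 106 / test 10).
#'
#' @param labels logical per-subject SICH indicator (or "SICH"/"NO_SICH").
#' @param foil_sets_per_case number of distinct foil sets per case.
#' @param seed integer seed; the plan is bitwise reproducible.
#' @return Object of class `split_plan`: `splits` (list of
#'   `list(train, test, case)` with integer subject indices; `test` is
#'   sorted, 1 case + 9 foils), `per_case_index` (list mapping each case
#'   index to its split numbers), `n_subjects`.
#' @export
make_split_plan <- function(labels, foil_sets_per_case = 110L, seed = 1L) {
  if (is.character(labels)) labels <- labels == "SICH"
  labels <- as.logical(labels)
  n <- length(labels)
  cases <- which(labels); controls <- which(!labels)
  if (length(controls) < 10) stop("need at least 10 non-SICH subjects")
  capacity <- choose(length(controls), 9)
  if (foil_sets_per_case > capacity) {
    stop("foil_sets_per_case = ", foil_sets_per_case,
         " exceeds the number of distinct 9-subject foil sets (", capacity, ")")
  }
  set.seed(as.integer(seed))
  splits <- list(); per_case <- stats::setNames(vector("list", length(cases)),
                                               as.character(cases))
  for (cs in cases) {
    seen <- character(0); got <- 0L; attempts <- 0L
    idx <- integer(foil_sets_per_case)
    while (got < foil_sets_per_case) {
      attempts <- attempts + 1L
      if (attempts > 200L * foil_sets_per_case) {
        stop("could not draw enough distinct foil sets")
      }
      foils <- sort(sample(controls, 9))
      key <- paste(foils, collapse = ",")
      if (key %in% seen) next
      seen <- c(seen, key)
      got <- got + 1L
      test <- sort(c(cs, foils))
      splits[[length(splits) + 1L]] <- list(train = setdiff(seq_len(n), test),
                                            test = test, case = cs)
      idx[got] <- length(splits)
    }
    per_case[[as.character(cs)]] <- idx
  }
  structure(list(splits = splits, per_case_index = per_case, n_subjects = n),
            class = "split_plan")
}

#' Rank the test subjects of one split by SICH-likeness
#'
#' Rank 1 is the most SICH-like (most negative) hyperplane distance; ties
#' are broken by subject-id order, so the mapping is deterministic and
#' invariant to the order in which distances are supplied.
#'
#' @param distances signed decision values of the test subjects.
#' @param ids subject identifiers used for tie-breaking (defaults to
#'   positional order).
#' @return Integer ranks, a permutation of `1:length(distances)` aligned
#'   with the input.
#' @export
rank_test_set <- function(distances, ids = seq_along(distances)) {
  if (any(!is.finite(distances))) stop("non-finite decision distance")
  ord <- order(distances, ids)
  r <- integer(length(distances))
  r[ord] <- seq_along(distances)
  r
}

#' Modal rank of each SICH case across its splits
#'
#' @param plan a `split_plan`.
#' @param case_ranks integer vector, one entry per split: the rank the model
#'   gave the split's SICH case.
#' @return List: `modal` (data frame `case`, `modal_rank`) and `identified`
#'   (number of cases whose modal rank is 1; modal ties resolve toward the
#'   smaller rank).
#' @export
modal_rank_summary <- function(plan, case_ranks) {
  stopifnot(inherits(plan, "split_plan"),
            length(case_ranks) == length(plan$splits))
  rows <- lapply(names(plan$per_case_index), function(cs) {
    idx <- plan$per_case_index[[cs]]
    if (any(idx > length(case_ranks))) stop("missing splits for case ", cs)
    tb <- table(case_ranks[idx])
    best <- as.integer(names(tb)[tb == max(tb)])
    data.frame(case = as.integer(cs), modal_rank = min(best))
  })
  modal <- do.call(rbind, rows)
  list(modal = modal, identified = sum(modal$modal_rank == 1L))
}

#' Ten-threshold ROC area
#'
#' Classifies the pooled test-subject decision distances at ten evenly
#' spaced thresholds spanning their range (distance at or below a threshold
#' is called SICH), computes (FPR, TPR) at each, augments with (0,0) and
#' (1,1), and integrates by the trapezoid rule. A degenerate pooled range
#' (all distances equal) returns 0.5 with a warning.
#'
#' @param distances pooled signed decision values.
#' @param labels logical SICH indicator per value.
#' @return AUC in \[0, 1\].
#' @export
auc_ten_thresholds <- function(distances, labels) {
  labels <- as.logical(labels)
  stopifnot(length(distances) == length(labels))
  if (!any(labels) || all(labels)) stop("need both classes among pooled predictions")
  rng <- range(distances)
  if (diff(rng) < .Machine$double.eps) {
    warning("degenerate pooled distance range; AUC set to 0.5")
    return(0.5)
  }
  thr <- seq(rng[1], rng[2], length.out = 10)
  tpr <- vapply(thr, function(t) mean(distances[labels] <= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(distances[!labels] <= t), numeric(1))
  fpr <- c(0, fpr, 1); tpr <- c(0, tpr, 1)
  ord <- order(fpr, tpr)
  fpr <- fpr[ord]; tpr <- tpr[ord]
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Exact binomial probabilities for chance-level case identification
#'
#' Point mass `P(X = k) = C(n, k) p^k (1-p)^(n-k)` with the binomial
#' coefficient computed exactly, and the upper-tail variant `P(X >= k)`.
#' Used to quantify how unlikely it is to top-rank the SICH subject in `k`
#' of `n` case-foil tests when picking 1 of 10 at random (p = 0.1).
#'
#' @param n_tests number of independent tests.
#' @param n_hits number of successes.
#' @param p per-test success probability.
#' @param tail if `TRUE`, return `P(X >= n_hits)` instead of the point mass.
#' @return A probability.
#' @export
binomial_chance_probability <- function(n_tests, n_hits, p, tail = FALSE) {
  stopifnot(n_hits >= 0, n_hits <= n_tests, p >= 0, p <= 1)
  point <- function(k) choose(n_tests, k) * p^k * (1 - p)^(n_tests - k)
  if (tail) sum(vapply(n_hits:n_tests, point, numeric(1))) else point(n_hits)
}

#' Run a model over a split plan and summarise its performance
#'
#' `evaluate_svm` retrains the per-sample-cap SVM on each split's 106
#' training subjects (reusing one precomputed cohort Gram matrix) and
#' computes hyperplane distances for the 10 test subjects; `evaluate_score`
#' evaluates a fixed prognostic score (negated, so that higher risk means a
#' more negative, more SICH-like distance).
#'
#' @param features subjects x d matrix (ignored when `K` given).
#' @param labels logical per-subject SICH indicator.
#' @param caps per-sample soft-margin caps.
#' @param plan a `split_plan` over the same subjects.
#' @param kernel a [kernel_spec()].
#' @param K optional precomputed full-cohort Gram matrix.
#' @param ... passed to [train_svm()].
#' @return Object of class `evaluation_result`: `distances` and `ranks`
#'   (splits x 10 matrices), `test_ids`, `case_rank` per split, `modal`,
#'   `identified`, `auc` (ten-threshold, pooled over all splits), `pooled`
#'   (data frame of pooled distances/labels), `n_splits`.
#' @export
evaluate_svm <- function(features, labels, caps, plan,
                         kernel = kernel_spec("linear"), K = NULL, ...) {
  labels <- as.logical(labels)
  if (is.null(K)) K <- kernel_matrix(as.matrix(features), spec = kernel)
  y <- ifelse(labels, -1, 1)
  evaluate_with(plan, labels, function(train, test) {
    m <- train_svm(NULL, y[train], caps[train], kernel,
                   K = K[train, train, drop = FALSE], ...)
    decision_distance(m, K_test = K[test, train, drop = FALSE])
  })
}

#' @rdname evaluate_svm
#' @param score per-subject prognostic score (higher = riskier).
#' @export
evaluate_score <- function(score, labels, plan) {
  labels <- as.logical(labels)
  d <- -as.numeric(score)
  evaluate_with(plan, labels, function(train, test) d[test])
}

#' @rdname evaluate_svm
#' @param distance_fun `function(train_idx, test_idx)` returning the signed
#'   distances of the test subjects.
#' @export
evaluate_with <- function(plan, labels, distance_fun) {
  stopifnot(inherits(plan, "split_plan"), length(labels) == plan$n_subjects)
  ns <- length(plan$splits)
  distances <- matrix(NA_real_, ns, 10)
  ranks <- matrix(NA_integer_, ns, 10)
  test_ids <- matrix(NA_integer_, ns, 10)
  case_rank <- integer(ns)
  for (s in seq_len(ns)) {
    sp <- plan$splits[[s]]
    d <- distance_fun(sp$train, sp$test)
    r <- rank_test_set(d, sp$test)
    distances[s, ] <- d; ranks[s, ] <- r; test_ids[s, ] <- sp$test
    case_rank[s] <- r[match(sp$case, sp$test)]
  }
  pooled <- data.frame(distance = as.vector(t(distances)),
                       is_case = as.vector(t(test_ids)) %in%
                         which(as.logical(labels)),
                       split = rep(seq_len(ns), each = 10))
  ms <- modal_rank_summary(plan, case_rank)
  structure(list(distances = distances, ranks = ranks, test_ids = test_ids,
                 case_rank = case_rank, modal = ms$modal,
                 identified = ms$identified,
                 auc = auc_ten_thresholds(pooled$distance, pooled$is_case),
                 pooled = pooled, n_splits = ns),
            class = "evaluation_result")
}

#' Compare evaluated models by paired bootstrap over SICH cases
#'
#' Resamples the SICH cases with replacement; each bootstrap replicate
#' recomputes every model's pooled ten-threshold AUC over the splits of the
#' sampled cases (with multiplicity) on the shared split plan. Reports each
#' model's AUC with a percentile interval, identified count and per-case
#' modal ranks, plus a two-sided bootstrap p-value for the AUC difference
#' against the first (reference) model. The paired bootstrap is a declared
#' surrogate comparison procedure.
#'
#' @param results named list of `evaluation_result` objects from the same
#'   `split_plan`.
#' @param plan the shared `split_plan`.
#' @param n_boot bootstrap replicates.
#' @param seed integer seed.
#' @return Data frame: `model`, `auc`, `auc_lo`, `auc_hi`, `identified`,
#'   `modal_ranks`, `p_vs_ref`.
#' @export
compare_models <- function(results, plan, n_boot = 2000L, seed = 1L) {
  stopifnot(length(results) >= 2, !is.null(names(results)))
  ref <- results[[1]]
  for (r in results) {
    stopifnot(inherits(r, "evaluation_result"))
    if (!identical(r$test_ids, ref$test_ids)) stop("mismatched split plans")
  }
  set.seed(as.integer(seed))
  cases <- names(plan$per_case_index)
  boot_auc <- function(res, case_sample) {
    # splits of a case drawn k times contribute with multiplicity k
    mult <- table(unlist(plan$per_case_index[case_sample]))
    p <- res$pooled[res$pooled$split %in% as.integer(names(mult)), ]
    w <- as.integer(mult[as.character(p$split)])
    auc_ten_thresholds(rep(p$distance, w), rep(p$is_case, w))
  }
  draws <- replicate(n_boot, sample(cases, length(cases), replace = TRUE),
                     simplify = FALSE)
  aucs <- lapply(results, function(res)
    vapply(draws, function(cs) boot_auc(res, cs), numeric(1)))
  rows <- lapply(seq_along(results), function(i) {
    res <- results[[i]]
    ab <- aucs[[i]]
    if (i == 1) p <- NA_real_ else {
      diffs <- aucs[[1]] - ab
      p <- min(1, 2 * min(mean(diffs <= 0), mean(diffs >= 0)))
    }
    data.frame(model = names(results)[i],
               auc = res$auc,
               auc_lo = stats::quantile(ab, 0.025, names = FALSE),
               auc_hi = stats::quantile(ab, 0.975, names = FALSE),
               identified = res$identified,
               modal_ranks = paste(res$modal$modal_rank, collapse = " "),
               p_vs_ref = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
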