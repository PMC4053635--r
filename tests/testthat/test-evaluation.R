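test_that("split plans have the 1-case / 9-foil structure by construction", {
  labels <- rep(c(TRUE, FALSE), c(3, 20))
  plan <- make_split_plan(labels, foil_sets_per_case = 5, seed = 2)
  expect_equal(length(plan$splits), 15)
  keys <- character(0)
  for (sp in plan$splits) {
    expect_equal(length(sp$test), 10)
    expect_equal(sum(labels[sp$test]), 1)
    expect_equal(length(sp$train), 13)
    expect_equal(sort(c(sp$train, sp$test)), 1:23)
    keys <- c(keys, paste(sp$test, collapse = ","))
  }
  expect_equal(anyDuplicated(keys), 0L)
  # per-case index partitions the splits
  expect_equal(sort(unname(unlist(plan$per_case_index))), 1:15)
})

test_that("split plans are reproducible and respect capacity limits", {
  labels <- rep(c(TRUE, FALSE), c(2, 11))
  a <- make_split_plan(labels, 4, seed = 5)
  b <- make_split_plan(labels, 4, seed = 5)
  d <- make_split_plan(labels, 4, seed = 6)
  expect_identical(a, b)
  expect_false(identical(a$splits, d$splits))
  # 11 controls admit choose(11, 9) = 55 distinct foil sets
  expect_error(make_split_plan(labels, 56, seed = 1), "distinct")
  expect_silent(make_split_plan(labels, 55, seed = 1))
  expect_error(make_split_plan(rep(c(TRUE, FALSE), c(2, 8)), 1), "10 non-SICH")

  one <- make_split_plan(rep(c(TRUE, FALSE), c(1, 10)), 1, seed = 1)
  expect_equal(length(one$splits), 1)
  expect_equal(length(one$splits[[1]]$test), 10)
})

test_that("ranking is most-negative-first with id-order ties", {
  d <- c(-5, -1, 0, 1, 2, 3, 4, 5, 6, 8)
  expect_equal(rank_test_set(d)[1], 1L)
  expect_equal(rank_test_set(rep(0, 10), ids = 1:10), 1:10)
  # permutation invariance of the subject -> rank mapping
  ids <- sample(101:110)
  d2 <- rnorm(10)
  perm <- sample(10)
  r1 <- rank_test_set(d2, ids)
  r2 <- rank_test_set(d2[perm], ids[perm])
  expect_equal(r2[order(ids[perm])], r1[order(ids)])
  expect_error(rank_test_set(c(NA, rnorm(9))), "non-finite")
})

test_that("modal ranks take the commonest value, ties toward rank 1", {
  labels <- rep(c(TRUE, FALSE), c(2, 20))
  plan <- make_split_plan(labels, 10, seed = 3)
  ranks <- c(rep(c(1L, 2L), c(6, 4)),   # case 1: mode 1
             rep(c(1L, 2L), 5))         # case 2: 5/5 tie -> 1
  ms <- modal_rank_summary(plan, ranks)
  expect_equal(ms$modal$modal_rank, c(1L, 1L))
  expect_equal(ms$identified, 2L)
  ms2 <- modal_rank_summary(plan, c(rep(3L, 10), rep(c(2L, 7L), c(4, 6))))
  expect_equal(ms2$modal$modal_rank, c(3L, 7L))
  expect_equal(ms2$identified, 0L)
})

test_that("a perfectly separating score identifies every case", {
  labels <- rep(c(TRUE, FALSE), c(4, 30))
  score <- ifelse(labels, 10, 1)          # higher = riskier
  plan <- make_split_plan(labels, 8, seed = 9)
  ev <- evaluate_score(score, labels, plan)
  expect_equal(ev$identified, 4L)
  expect_equal(ev$auc, 1)
  expect_true(all(ev$case_rank == 1L))
})

test_that("ten-threshold AUC matches a hand-computed ROC table", {
  # cases at distances 1,2,3,5,7; controls at 4,6,8,9,10; thresholds 1..10.
  # TPR/FPR by hand give trapezoid area 0.88, equal to the exact
  # Mann-Whitney AUC because the distances align with the threshold grid.
  d <- 1:10
  lab <- c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE)
  expect_equal(auc_ten_thresholds(d, lab), 0.88, tolerance = 1e-12)

  expect_equal(auc_ten_thresholds(c(-5, -4, 5, 6), c(TRUE, TRUE, FALSE, FALSE)), 1)
  set.seed(2)
  dd <- rnorm(4000)
  ll <- rep(c(TRUE, FALSE), 2000)
  expect_lt(abs(auc_ten_thresholds(dd, ll) - 0.5), 0.05)
  expect_warning(a <- auc_ten_thresholds(rep(1, 10), rep(c(TRUE, FALSE), 5)),
                 "degenerate")
  expect_equal(a, 0.5)
  expect_error(auc_ten_thresholds(1:4, rep(TRUE, 4)), "both classes")
})

test_that("the coarse ten-threshold AUC tracks the exact rank AUC", {
  skip_if_not_installed("pROC")
  set.seed(8)
  for (i in 1:20) {
    n <- 200
    lab <- rep(c(TRUE, FALSE), c(40, 160))
    d <- rnorm(n) - 1.2 * lab
    coarse <- auc_ten_thresholds(d, lab)
    exact <- as.numeric(pROC::auc(pROC::roc(lab, -d, quiet = TRUE,
                                            direction = "<")))
    expect_lt(abs(coarse - exact), 0.1)
  }
})

test_that("exact binomial chance probabilities behave", {
  expect_equal(signif(binomial_chance_probability(16, 9, 0.1), 1), 5e-6)
  expect_equal(binomial_chance_probability(7, 0, 0), 1)
  expect_equal(binomial_chance_probability(2, 1, 0.5), 0.5)
  # point masses form a distribution (n = 30)
  total <- sum(vapply(0:30, function(k)
    binomial_chance_probability(30, k, 0.1), numeric(1)))
  expect_lt(abs(total - 1), 1e-12)
  # tail dominates the point mass
  expect_gte(binomial_chance_probability(16, 9, 0.1, tail = TRUE),
             binomial_chance_probability(16, 9, 0.1))
  expect_error(binomial_chance_probability(5, 7, 0.1), "n_hits")
})

test_that("model self-comparison is null and mismatched plans are refused", {
  labels <- rep(c(TRUE, FALSE), c(3, 25))
  plan <- make_split_plan(labels, 6, seed = 4)
  set.seed(4)
  score <- rnorm(28) + 2 * labels
  ev <- evaluate_score(score, labels, plan)
  rep_ <- compare_models(list(a = ev, b = ev), plan, n_boot = 200, seed = 1)
  expect_equal(nrow(rep_), 2)
  expect_equal(rep_$auc[1], rep_$auc[2])
  expect_equal(rep_$p_vs_ref[2], 1)
  expect_true(is.na(rep_$p_vs_ref[1]))

  other <- evaluate_score(score, labels, make_split_plan(labels, 6, seed = 5))
  expect_error(compare_models(list(a = ev, b = other), plan), "mismatched")
})

test_that("an informative model beats an uninformative one under bootstrap", {
  labels <- rep(c(TRUE, FALSE), c(6, 40))
  plan <- make_split_plan(labels, 20, seed = 7)
  set.seed(7)
  good <- evaluate_score(5 * labels + rnorm(46, 0, 0.5), labels, plan)
  noise <- evaluate_score(rnorm(46), labels, plan)
  rep_ <- compare_models(list(good = good, noise = noise), plan,
                         n_boot = 500, seed = 2)
  expect_gt(rep_$auc[1], rep_$auc[2])
  expect_lt(rep_$p_vs_ref[2], 0.05)
})
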