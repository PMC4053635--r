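toy_set <- function(n, seed, sd = 0.5) {
  set.seed(seed)
  X <- matrix(rnorm(n * 3), n)
  y <- ifelse(X[, 1] + sd * rnorm(n) > 0, 1, -1)
  if (length(unique(y)) < 2) y[1] <- -y[1]
  list(X = X, y = y)
}

test_that("NIHSS-to-cap mapping is mean-normalized with a zero floor", {
  expect_equal(nihss_to_caps(c(12, 12, 12), 2), c(2, 2, 2))
  expect_equal(nihss_to_caps(c(10, 20), 1), c(2 / 3, 4 / 3))
  expect_equal(nihss_to_caps(c(0, 15), 1), c(0.01, 2))
  expect_error(nihss_to_caps(c(0, 0)), "all-zero")
})

test_that("a symmetric pair yields a centred, unit-margin boundary", {
  m <- train_svm(matrix(c(-1, 1), 2), c(-1, 1), c(10, 10),
                 kernel_spec("linear"))
  d <- decision_distance(m, matrix(c(-1, 1), 2))
  expect_equal(d, c(-1, 1), tolerance = 1e-6)
  expect_equal(m$bias, 0, tolerance = 1e-9)
  expect_equal(decision_distance(m, matrix(0, 1, 1)), m$bias)
})

test_that("uniform-cap training matches the dense QP reference solver", {
  skip_if_not_installed("kernlab")
  for (seed in 1:20) {
    d <- toy_set(40, seed)
    C <- rep(1.5, 40)
    m <- train_svm(d$X, d$y, C, kernel_spec("linear"))
    expect_true(m$converged)
    f_ref <- qp_decision(d$X, d$y, C)
    expect_lt(max(abs(decision_distance(m, d$X) - f_ref)), 1e-4)
  }
})

test_that("per-sample caps also match the QP reference", {
  skip_if_not_installed("kernlab")
  for (seed in 1:10) {
    d <- toy_set(30, seed + 100)
    set.seed(seed)
    C <- runif(30, 0.3, 3)
    m <- train_svm(d$X, d$y, C, kernel_spec("linear"))
    f_ref <- qp_decision(d$X, d$y, C)
    expect_lt(max(abs(decision_distance(m, d$X) - f_ref)), 1e-4)
  }
})

test_that("converged solutions satisfy the KKT margin conditions", {
  for (seed in 1:5) {
    d <- toy_set(50, seed + 7, sd = 1)
    set.seed(seed)
    C <- runif(50, 0.5, 2)
    m <- train_svm(d$X, d$y, C, kernel_spec("linear"))
    expect_true(m$converged)
    expect_lt(abs(sum(m$alpha * m$labels)), 1e-6 * max(C))
    yf <- d$y * decision_distance(m, d$X)
    tol <- 1e-3
    expect_true(all(yf[m$alpha < 1e-9] >= 1 - tol))
    expect_true(all(yf[m$alpha > C - 1e-9] <= 1 + tol))
    free <- m$alpha > 1e-9 & m$alpha < C - 1e-9
    if (any(free)) expect_lt(max(abs(yf[free] - 1)), tol)
  }
})

test_that("raising one subject's cap never increases its margin violation", {
  d <- toy_set(40, 3, sd = 2)           # heavily overlapping classes
  C <- rep(0.5, 40)
  m1 <- train_svm(d$X, d$y, C, kernel_spec("linear"))
  slack <- pmax(0, 1 - d$y * decision_distance(m1, d$X))
  worst <- which.max(slack)
  C2 <- C; C2[worst] <- 2 * C2[worst]
  m2 <- train_svm(d$X, d$y, C2, kernel_spec("linear"))
  slack2 <- pmax(0, 1 - d$y * decision_distance(m2, d$X))
  expect_lte(slack2[worst], slack[worst] + 1e-6)
})

test_that("predictions are invariant to training-set subject order", {
  d <- toy_set(30, 11)
  set.seed(11)
  C <- runif(30, 0.5, 2)
  m1 <- train_svm(d$X, d$y, C, kernel_spec("linear"), seed = 1)
  perm <- sample(30)
  m2 <- train_svm(d$X[perm, ], d$y[perm], C[perm], kernel_spec("linear"),
                  seed = 1)
  probe <- matrix(rnorm(15), 5, 3)
  expect_equal(decision_distance(m1, probe), decision_distance(m2, probe),
               tolerance = 1e-5)
})

test_that("the sigmoid kernel trains deterministically within budget", {
  d <- toy_set(24, 5)
  Xs <- scale(d$X)
  m1 <- train_svm(Xs, d$y, rep(1, 24), kernel_spec("sigmoid", 0.05, -0.5))
  m2 <- train_svm(Xs, d$y, rep(1, 24), kernel_spec("sigmoid", 0.05, -0.5))
  f <- decision_distance(m1, Xs)
  expect_true(all(is.finite(f)))
  expect_identical(f, decision_distance(m2, Xs))
  expect_error(kernel_spec("sigmoid", scale = 0), "scale")
  expect_error(kernel_spec("rbf"), "gamma")
})

test_that("the manual SVM separates a clean radiology contrast", {
  co <- generate_cohort(12, 60, seed = 4)
  rd <- simulate_raters(co$truth, seed = 3)
  cons <- consensus_reading(rd)
  m <- train_manual_svm(co$clinical, cons)
  d <- decision_distance(m, manual_features(co$clinical, cons))
  # negative = SICH-like: cases should average lower than controls
  sich <- co$clinical$outcome == "SICH"
  expect_lt(mean(d[sich]), mean(d[!sich]))
  expect_equal(ncol(m$support_vectors), 3)
})

test_that("ablation variants restrict features as specified", {
  g <- tiny_grid()
  mask <- brain_mask_template(g)
  coords <- mask_coords(mask)
  set.seed(2)
  vecs <- matrix(runif(8 * nrow(coords), 20, 60), 8)
  cm <- clean_cohort(vecs, coords)

  nb <- ablate_features("NO_BASE", cm, g)
  expect_equal(nrow(nb$voxel_index), sum(coords$z >= g$upper_z0))
  expect_true(all(nb$voxel_index$z >= g$upper_z0))

  side <- rep(c("L", "R"), 4)
  sh <- ablate_features("SINGLE_HEMISPHERE", cm, g, side)
  expect_true(all(sh$voxel_index$x < (g$nx - 1) / 2))
  # the template mask is x-symmetric: exactly half the voxels survive
  expect_equal(nrow(sh$voxel_index), nrow(coords) / 2)
  # right-lesion subjects read mirrored columns
  mirror_col <- which(coords$x == g$nx - 1 - sh$voxel_index$x[1] &
                        coords$y == sh$voxel_index$y[1] &
                        coords$z == sh$voxel_index$z[1])
  expect_equal(sh$values[2, 1], vecs[2, mirror_col])
  expect_equal(sh$values[1, 1], vecs[1, which(coords$x == sh$voxel_index$x[1] &
                                                coords$y == sh$voxel_index$y[1] &
                                                coords$z == sh$voxel_index$z[1])])

  nn <- ablate_features("NO_NIHSS", cm, g)
  expect_identical(nn$values, cm$values)
})

test_that("NO_NIHSS ablation equals the cap pipeline on an equal-NIHSS cohort", {
  g <- tiny_grid()
  mask <- brain_mask_template(g)
  coords <- mask_coords(mask)
  set.seed(6)
  vecs <- matrix(runif(10 * nrow(coords), 20, 60), 10)
  cm <- clean_cohort(vecs, coords)
  labels <- rep(c(TRUE, FALSE), c(3, 7))
  nihss <- rep(14L, 10)
  m_ab <- ablate("NO_NIHSS", cm, nihss, labels, g, base_c = 1)
  m_full <- train_svm(cm$values, labels, nihss_to_caps(nihss, 1),
                      kernel_spec("linear"))
  expect_equal(m_ab$alpha, m_full$alpha, tolerance = 1e-8)
  expect_equal(m_ab$bias, m_full$bias, tolerance = 1e-8)
})

test_that("models survive JSON serialization", {
  d <- toy_set(20, 9)
  m <- train_svm(d$X, d$y, rep(1, 20), kernel_spec("linear"))
  path <- tempfile(fileext = ".json")
  write_svm_model(m, path)
  back <- read_svm_model(path)
  probe <- matrix(rnorm(9), 3, 3)
  expect_equal(decision_distance(back, probe), decision_distance(m, probe),
               tolerance = 1e-9)
  unlink(path)
})
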