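test_that("joining averages overlaps, keeps single samples, flags gaps", {
  g <- ct_grid(8, 8, 10, upper_slices = 6, lower_slices = 6)
  up <- flat_section(g, "UPPER", 30)
  lo <- flat_section(g, "LOWER", 34)
  j <- join_sections(up, lo, g)
  # slices 5-6 (1-based) are sampled by both sections
  expect_true(all(j$voxels[, , 5:6] == 32))
  expect_true(all(j$sample_count[, , 5:6] == 2L))
  expect_true(all(j$voxels[, , 1:4] == 34))
  expect_true(all(j$voxels[, , 7:10] == 30))

  # a truncated lower section leaves unsampled voxels at the seam
  g2 <- ct_grid(8, 8, 12, upper_slices = 6, lower_slices = 7)
  lo_short <- ct_section(array(41, dim = c(8, 8, 4)), g2$spacing, c(0, 0, 0),
                         "LOWER")
  up2 <- flat_section(g2, "UPPER", 41)
  j2 <- join_sections(up2, lo_short, g2)
  expect_true(all(is.na(j2$voxels[, , 5:6])))
  expect_true(all(j2$sample_count[, , 5:6] == 0L))
  expect_true(all(j2$voxels[, , 1:4] == 41))

  bad <- ct_section(array(0, dim = c(6, 8, 6)), g$spacing, c(0, 0, 4), "UPPER")
  expect_error(join_sections(bad, lo, g), "match")
})

test_that("masking preserves values and fixed voxel order", {
  g <- ct_grid(8, 8, 10, upper_slices = 6, lower_slices = 6)
  set.seed(1)
  # full-overlap identical-value pair reproduces the input exactly
  full <- ct_section(array(runif(640, 20, 50), dim = c(8, 8, 10)),
                     g$spacing, c(0, 0, 0), "UPPER")
  j <- join_sections(full, ct_section(full$voxels, g$spacing, c(0, 0, 0),
                                      "LOWER"), g)
  mask <- array(TRUE, dim = c(8, 8, 10))
  expect_identical(apply_brain_mask(j, mask), as.vector(full$voxels))

  single <- array(FALSE, dim = c(8, 8, 10)); single[3, 4, 5] <- TRUE
  expect_identical(apply_brain_mask(j, single), full$voxels[3, 4, 5])
  expect_equal(nrow(mask_coords(single)), 1)
  expect_equal(unlist(mask_coords(single)), c(x = 2, y = 3, z = 4))
  expect_error(apply_brain_mask(j, array(FALSE, dim = c(8, 8, 10))), "empty")
})

test_that("cleaning deletes voxels anomalous in >= 5 subjects and imputes the rest", {
  m <- matrix(50, nrow = 6, ncol = 3)
  m[1:5, 1] <- 250                      # anomalous in 5 of 6: delete
  m[1:2, 2] <- c(-10, NA); m[3:6, 2] <- c(10, 20, 30, 40)  # impute with 25
  cm <- clean_cohort(m, subject_threshold = 5L)
  expect_equal(ncol(cm$values), 2)
  expect_equal(cm$deleted_voxels$col, 1)
  expect_equal(cm$values[1:2, 1], c(25, 25))
  expect_equal(cm$values[3:6, 1], c(10, 20, 30, 40))
  expect_equal(nrow(cm$imputed_cells), 2)

  clean <- matrix(runif(30, 10, 150), 6, 5)
  out <- clean_cohort(clean)
  expect_identical(out$values, clean)
  expect_equal(nrow(out$deleted_voxels), 0)
  expect_equal(nrow(out$imputed_cells), 0)
  expect_error(clean_cohort(clean[1:3, ]), "subject_threshold")
})

test_that("cleaning matches the brute-force per-cell oracle on random matrices", {
  set.seed(42)
  for (rep in 1:20) {
    m <- matrix(runif(8 * 50, 10, 190), 8, 50)
    m[sample(length(m), 60)] <- sample(c(-5, 250, NA), 60, replace = TRUE)
    cm <- clean_cohort(m)
    oracle <- clean_oracle(m)
    expect_equal(cm$values, oracle$values, tolerance = 1e-12)
    expect_equal(cm$deleted_voxels$col, oracle$deleted)
    # audit partition covers every input column
    expect_equal(nrow(cm$voxel_index) + nrow(cm$deleted_voxels), ncol(m))
  }
})

test_that("the deleted-voxel set is invariant to subject permutation", {
  set.seed(7)
  m <- matrix(runif(8 * 40, 10, 190), 8, 40)
  m[sample(length(m), 80)] <- 300
  perm <- sample(8)
  expect_equal(clean_cohort(m)$deleted_voxels,
               clean_cohort(m[perm, ])$deleted_voxels)
})

test_that("cleaning an already-clean matrix is idempotent", {
  set.seed(9)
  m <- matrix(runif(8 * 30, 10, 190), 8, 30)
  m[sample(length(m), 30)] <- sample(c(-5, 250), 30, replace = TRUE)
  once <- clean_cohort(m)
  twice <- clean_cohort(once$values)
  expect_identical(twice$values, once$values)
  expect_equal(nrow(twice$deleted_voxels), 0)
  expect_equal(nrow(twice$imputed_cells), 0)
})

test_that("global intensity correction equalizes row means at the grand mean", {
  cm <- structure(list(values = matrix(c(30, 60), 2, 4),
                       voxel_index = data.frame(col = 1:4),
                       deleted_voxels = data.frame(col = integer(0)),
                       imputed_cells = data.frame(subject = integer(0),
                                                  voxel = integer(0))),
                  class = "cohort_matrix")
  out <- global_intensity_correct(cm)
  expect_equal(out$grand_mean, 45)
  expect_equal(out$values[1, ], rep(45, 4))
  expect_equal(out$values[2, ], rep(45, 4))
  expect_equal(out$values[1, ] / cm$values[1, ], rep(1.5, 4))

  single <- cm; single$values <- cm$values[1, , drop = FALSE]
  expect_equal(global_intensity_correct(single)$values, single$values)

  set.seed(3)
  big <- cm; big$values <- matrix(runif(200, 20, 60), 10, 20)
  corrected <- global_intensity_correct(big)$values
  expect_lt(diff(range(rowMeans(corrected))) / mean(corrected), 1e-9)
})

test_that("cohort matrices round-trip through the directory format", {
  set.seed(5)
  m <- matrix(runif(60, 10, 190), 6, 10)
  m[2, 3] <- 300
  cm <- global_intensity_correct(clean_cohort(m))
  dir <- tempfile()
  write_cohort_matrix(cm, dir)
  back <- read_cohort_matrix(dir)
  expect_equal(back$values, cm$values)
  expect_equal(back$imputed_cells, cm$imputed_cells)
  expect_equal(back$grand_mean, cm$grand_mean)
  unlink(dir, recursive = TRUE)
})

test_that("rigid registration recovers known jitter within half a voxel", {
  g <- tiny_grid()
  tr <- make_truth(background_burden = 0.5, fazekas = 1)
  # identity jitter: estimated transform is (near) zero
  secs0 <- render_ct(tr, g, noise_sd = 1, seed = 3, jitter = FALSE)
  n0 <- normalize_section(secs0$upper, g)
  expect_lt(max(abs(n0$jitter$translation)), 0.5)

  # known pure x-shift of 1.2 voxels
  jit <- list(upper = list(translation = c(1.2, 0, 0), rot_deg = 0),
              lower = list(translation = c(0, 0, 0), rot_deg = 0))
  secs <- render_ct(tr, g, noise_sd = 1, seed = 4, jitter = jit)
  n1 <- normalize_section(secs$upper, g)
  expect_lt(abs(n1$jitter$translation[1] - 1.2), 0.5)
  expect_lt(max(abs(n1$jitter$translation[2:3])), 0.5)

  # structureless input cannot be registered
  noise <- ct_section(array(rnorm(prod(c(g$nx, g$ny, g$upper_slices))),
                            dim = c(g$nx, g$ny, g$upper_slices)),
                      g$spacing, c(0, 0, g$upper_z0), "UPPER")
  expect_error(normalize_section(noise, g), "registration failure")
})
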