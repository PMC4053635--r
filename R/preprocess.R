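#' Rigidly align a CT section to the template
#'
#' Estimates a small rigid transform (3 translations and one in-plane
#' rotation) by maximizing normalized cross-correlation against the
#' template-space rendering of the same section, using a coarse-to-fine grid
#' search (coarse and intermediate passes on a 2x-downsampled grid, final
#' pass at full resolution), and resamples the section onto the common grid
#' by trilinear interpolation. This is a deliberately simple surrogate for
#' full nonlinear spatial normalization: the generator only ever applies
#' small rigid jitter, so a rigid correction suffices.
#'
#' @param section a [ct_section()] whose jitter lies within `max_shift`
#'   voxels / `max_rot` degrees.
#' @param grid the common [ct_grid()].
#' @param template fixed image; defaults to [template_section()] of the same
#'   kind.
#' @param max_shift,max_rot search half-ranges (voxels, degrees).
#' @param ncc_floor minimum acceptable correlation at the optimum; below it
#'   the input is judged unregistrable and an error is raised.
#' @return A list: `section` (the aligned [ct_section()], identity offset),
#'   `jitter` (the estimated acquisition transform, `translation` in voxels
#'   and `rot_deg`), `ncc` (correlation at the optimum).
#' @export
normalize_section <- function(section, grid = ct_grid(),
                              template = template_section(grid, section$section_kind),
                              max_shift = 1.6, max_rot = 2, ncc_floor = 0.5) {
  stopifnot(inherits(section, "ct_section"))
  dm <- dim(section$voxels)
  center <- phantom_geometry(grid)$center
  orig <- section$origin_offset

  co_full <- coord_grid(dm, orig)
  sub <- co_full[co_full[, 1] %% 2 == 0 & co_full[, 2] %% 2 == 0, , drop = FALSE]
  tvox_full <- as.vector(template$voxels)
  tvox_sub <- tvox_full[co_full[, 1] %% 2 == 0 & co_full[, 2] %% 2 == 0]

  ncc <- function(a, b) {
    sa <- stats::sd(a); sb <- stats::sd(b)
    if (sa < 1e-9 || sb < 1e-9) return(-1)
    mean((a - mean(a)) * (b - mean(b))) / (sa * sb)
  }
  score <- function(p, coords, tv) {
    src <- rigid_transform(coords, p[1:3], p[4], center)
    src[, 3] <- src[, 3] - orig[3]   # section-local z
    ncc(resample_trilinear(section$voxels, src), tv)
  }
  search_around <- function(p0, steps, rot_steps, coords, tv) {
    best <- p0; best_s <- score(p0, coords, tv)
    for (tx in p0[1] + steps) for (ty in p0[2] + steps)
      for (tz in p0[3] + steps) for (r in p0[4] + rot_steps) {
        s <- score(c(tx, ty, tz, r), coords, tv)
        if (s > best_s + 1e-12) { best <- c(tx, ty, tz, r); best_s <- s }
      }
    list(p = best, s = best_s)
  }

  st1 <- max_shift / 2
  r1 <- search_around(c(0, 0, 0, 0),
                      c(-2, -1, 0, 1, 2) * st1, c(-2, -1, 0, 1, 2) * (max_rot / 2),
                      sub, tvox_sub)
  r2 <- search_around(r1$p, c(-1, 0, 1) * (st1 / 3), c(-1, 0, 1) * (max_rot / 6),
                      sub, tvox_sub)
  r3 <- search_around(r2$p, c(-1, 0, 1) * (st1 / 9), c(-1, 0, 1) * (max_rot / 18),
                      co_full, tvox_full)
  if (r3$s < ncc_floor) {
    stop("registration failure: best normalized cross-correlation ",
         sprintf("%.3f", r3$s), " below floor ", ncc_floor)
  }

  p <- r3$p
  src <- rigid_transform(co_full, p[1:3], p[4], center)
  src[, 3] <- src[, 3] - orig[3]
  aligned <- ct_section(array(resample_trilinear(section$voxels, src), dim = dm),
                        section$spacing, orig, section$section_kind)
  # the estimated correction is R_p; the acquisition jitter is its inverse
  th <- -p[4] * pi / 180
  jt <- -c(cos(th) * p[1] - sin(th) * p[2], sin(th) * p[1] + cos(th) * p[2], p[3])
  list(section = aligned,
       jitter = list(translation = jt, rot_deg = -p[4]),
       ncc = r3$s)
}

#' Join the two CT sections on the common grid
#'
#' Places both sections into common space and combines them: voxels sampled
#' by both sections take the arithmetic mean of the two values, voxels
#' sampled by one take that value, and voxels sampled by neither carry an
#' `NA` sentinel (the dark "join" seam) — never a fabricated HU value.
#'
#' @param upper,lower [ct_section()] objects already on the common grid.
#' @param grid the common [ct_grid()].
#' @return An object of class `joined_volume`: `voxels` (3D HU array with
#'   `NA` where unsampled) and `sample_count` (integer 3D array, 0-2).
#' @export
join_sections <- function(upper, lower, grid = ct_grid()) {
  du <- dim(upper$voxels); dl <- dim(lower$voxels)
  if (!identical(du[1:2], dl[1:2]) ||
      du[1] != grid$nx || du[2] != grid$ny ||
      !isTRUE(all.equal(upper$spacing, lower$spacing))) {
    stop("section grids do not match the common grid")
  }
  dm <- c(grid$nx, grid$ny, grid$nz)
  acc <- array(0, dm); cnt <- array(0L, dm)
  add <- function(sec) {
    z <- sec$origin_offset[3] + seq_len(dim(sec$voxels)[3])
    if (max(z) > grid$nz) stop("section extends beyond the common grid")
    acc[, , z] <<- acc[, , z] + sec$voxels
    cnt[, , z] <<- cnt[, , z] + 1L
  }
  add(upper); add(lower)
  vox <- ifelse(cnt > 0L, acc / pmax(cnt, 1L), NA_real_)
  structure(list(voxels = array(vox, dm), sample_count = cnt),
            class = "joined_volume")
}

#' Extract the masked voxel vector of one subject
#'
#' Flattens the brain-mask voxels of a joined volume into a vector in fixed
#' x-fastest (column-major, 0-based) order, so a given vector position always
#' addresses the same common-grid coordinate across subjects. Unsampled
#' voxels are carried through as `NA`.
#'
#' @param volume a `joined_volume` from [join_sections()].
#' @param mask logical 3D array on the common grid (see
#'   [brain_mask_template()]).
#' @return Numeric vector of length `sum(mask)`.
#' @export
apply_brain_mask <- function(volume, mask) {
  stopifnot(inherits(volume, "joined_volume"))
  if (!identical(dim(volume$voxels), dim(mask))) stop("mask grid mismatch")
  if (!any(mask)) stop("empty brain mask")
  volume$voxels[mask]
}

#' Common-grid coordinates of the mask voxels, in vector order
#'
#' @param mask logical 3D array.
#' @return Data frame with 0-based `x`, `y`, `z`, one row per mask voxel in
#'   the same x-fastest order as [apply_brain_mask()].
#' @export
mask_coords <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  data.frame(x = w[, 1] - 1L, y = w[, 2] - 1L, z = w[, 3] - 1L)
}

#' Clean the cohort voxel matrix: delete or impute anomalous values
#'
#' A cell is anomalous if its value is below `hu_low`, above `hu_high`, or
#' unsampled (`NA`, the join seam). Voxels (columns) anomalous in
#' `subject_threshold` or more subjects are deleted outright; in the
#' remaining columns, anomalous cells are replaced by the mean of that
#' voxel's value over the non-anomalous subjects, so rare artefacts do not
#' silence a voxel for the whole sample.
#'
#' @param vectors subjects x voxels numeric matrix (rows from
#'   [apply_brain_mask()]).
#' @param coords optional data frame of per-column common-grid coordinates
#'   (from [mask_coords()]); carried into the audit trail.
#' @param hu_low,hu_high plausible brain HU range; values strictly outside
#'   are anomalous.
#' @param subject_threshold minimum number of anomalous subjects for a voxel
#'   to be deleted rather than imputed.
#' @return An object of class `cohort_matrix`: `values` (cleaned subjects x
#'   retained-voxels matrix), `voxel_index` (retained columns' coordinates,
#'   or original column numbers when `coords` is `NULL`), `deleted_voxels`,
#'   `imputed_cells` (data frame of subject row / retained-column pairs).
#' @export
clean_cohort <- function(vectors, coords = NULL, hu_low = 0, hu_high = 200,
                         subject_threshold = 5L) {
  stopifnot(is.matrix(vectors))
  n <- nrow(vectors)
  if (n < subject_threshold) {
    stop("need at least subject_threshold = ", subject_threshold, " subjects")
  }
  if (is.null(coords)) {
    coords <- data.frame(col = seq_len(ncol(vectors)))
  }
  stopifnot(nrow(coords) == ncol(vectors))

  anom <- is.na(vectors) | vectors < hu_low | vectors > hu_high
  n_anom <- colSums(anom)
  del <- n_anom >= subject_threshold
  keep <- !del

  values <- vectors[, keep, drop = FALSE]
  anom_k <- anom[, keep, drop = FALSE]
  imputed <- which(anom_k, arr.ind = TRUE)
  if (nrow(imputed)) {
    col_clean_sum <- colSums(ifelse(anom_k, 0, values), na.rm = TRUE)
    col_clean_n <- n - colSums(anom_k)
    stopifnot(all(col_clean_n[unique(imputed[, 2])] > 0))
    values[imputed] <- (col_clean_sum / col_clean_n)[imputed[, 2]]
  }
  structure(list(
    values = values,
    voxel_index = coords[keep, , drop = FALSE],
    deleted_voxels = coords[del, , drop = FALSE],
    imputed_cells = data.frame(subject = as.integer(imputed[, 1]),
                               voxel = as.integer(imputed[, 2]))
  ), class = "cohort_matrix")
}

#' Correct the cohort matrix for global mean intensity
#'
#' Rescales every subject's voxel vector multiplicatively so that each row
#' mean over the retained voxels equals the cohort grand mean computed
#' before correction. A multiplicative correction preserves HU ratios and
#' non-negativity.
#'
#' @param matrix a `cohort_matrix` from [clean_cohort()].
#' @return The corrected `cohort_matrix`, with the pre-correction grand mean
#'   stored as `grand_mean`.
#' @export
global_intensity_correct <- function(matrix) {
  stopifnot(inherits(matrix, "cohort_matrix"))
  rm_ <- rowMeans(matrix$values)
  if (any(rm_ == 0)) stop("subject with zero mean intensity")
  grand <- mean(matrix$values)
  matrix$values <- matrix$values * (grand / rm_)
  matrix$grand_mean <- grand
  matrix
}

#' Write / read a cohort voxel matrix directory
#'
#' The matrix is stored as a flat little-endian double binary file plus a
#' JSON sidecar holding dimensions, the voxel index, the deletion and
#' imputation audit trail, and the grand mean when present.
#'
#' @param matrix a `cohort_matrix`.
#' @param dir directory to create/write.
#' @return `write_cohort_matrix` returns `dir` invisibly;
#'   `read_cohort_matrix` returns the `cohort_matrix`.
#' @export
write_cohort_matrix <- function(matrix, dir) {
  stopifnot(inherits(matrix, "cohort_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  con <- file(file.path(dir, "values.bin"), "wb")
  writeBin(as.vector(matrix$values), con, size = 8, endian = "little")
  close(con)
  side <- list(n_subjects = nrow(matrix$values),
               n_voxels = ncol(matrix$values),
               voxel_order = "x-fastest, 0-based",
               voxel_index = matrix$voxel_index,
               deleted_voxels = matrix$deleted_voxels,
               imputed_cells = matrix$imputed_cells,
               grand_mean = matrix$grand_mean)
  jsonlite::write_json(side, file.path(dir, "sidecar.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' @rdname write_cohort_matrix
#' @export
read_cohort_matrix <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "sidecar.json"),
                              simplifyVector = TRUE)
  n <- side$n_subjects * side$n_voxels
  con <- file(file.path(dir, "values.bin"), "rb")
  v <- readBin(con, "double", n = n, size = 8, endian = "little")
  close(con)
  out <- structure(list(values = matrix(v, side$n_subjects, side$n_voxels),
                        voxel_index = as.data.frame(side$voxel_index),
                        deleted_voxels = as.data.frame(side$deleted_voxels),
                        imputed_cells = as.data.frame(side$imputed_cells)),
                   class = "cohort_matrix")
  if (!is.null(side$grand_mean)) out$grand_mean <- side$grand_mean
  out
}
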