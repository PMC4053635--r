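#' Kernel specification
#'
#' The default is the multilayer-perceptron (sigmoid) kernel
#' `k(u, v) = tanh(scale * <u, v> + offset)` with `scale = 1`,
#' `offset = -1`. The sigmoid kernel is indefinite, so dual convergence is
#' budget-bounded rather than guaranteed; the linear kernel is the
#' documented safe fallback and the practical choice for whole-image HU
#' inputs, whose large raw dot products saturate the tanh.
#'
#' @param kind `"sigmoid"`, `"linear"` or `"rbf"`.
#' @param scale,offset sigmoid parameters (`scale` must be positive).
#' @param gamma RBF bandwidth (required for `"rbf"`).
#' @return A list of class `kernel_spec`.
#' @export
kernel_spec <- function(kind = c("sigmoid", "linear", "rbf"),
                        scale = 1, offset = -1, gamma = NULL) {
  kind <- match.arg(kind)
  if (kind == "sigmoid" && scale <= 0) stop("sigmoid kernel needs scale > 0")
  if (kind == "rbf" && (is.null(gamma) || gamma <= 0)) {
    stop("rbf kernel needs gamma > 0")
  }
  structure(list(kind = kind, scale = scale, offset = offset, gamma = gamma),
            class = "kernel_spec")
}

#' Kernel matrix between two sets of feature vectors
#'
#' @param X,Y numeric matrices (rows = observations); `Y = NULL` gives the
#'   Gram matrix of `X`.
#' @param spec a [kernel_spec()].
#' @return `nrow(X)` x `nrow(Y)` kernel matrix.
#' @export
kernel_matrix <- function(X, Y = NULL, spec = kernel_spec()) {
  X <- as.matrix(X)
  Y <- if (is.null(Y)) X else as.matrix(Y)
  stopifnot(ncol(X) == ncol(Y))
  switch(spec$kind,
    linear = X %*% t(Y),
    sigmoid = tanh(spec$scale * (X %*% t(Y)) + spec$offset),
    rbf = {
      d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * (X %*% t(Y))
      exp(-spec$gamma * pmax(d2, 0))
    })
}

#' Per-sample soft-margin caps proportional to NIHSS
#'
#' Maps each subject's baseline NIHSS to the upper bound of its dual
#' variable, `C_i = base_c * nihss_i / mean(nihss)`, so that clinically
#' severe strokes contribute proportionately more to the fitted margin. A
#' zero NIHSS is floored at `0.01 * base_c` so every subject retains a
#' nonzero (if negligible) influence.
#'
#' @param nihss integer vector of baseline NIHSS values (>= 0, not all 0).
#' @param base_c overall penalty scale (> 0).
#' @return Vector of per-sample caps.
#' @export
nihss_to_caps <- function(nihss, base_c = 1) {
  stopifnot(all(nihss >= 0), base_c > 0)
  if (all(nihss == 0)) stop("all-zero NIHSS cannot define soft-margin caps")
  caps <- base_c * nihss / mean(nihss)
  caps[caps < 0.01 * base_c] <- 0.01 * base_c
  caps
}

#' Train the soft-margin SVM with per-sample penalty caps
#'
#' Solves the soft-margin dual with per-sample upper bounds by sequential
#' pairwise (minimal) optimization — working pairs chosen by maximal KKT
#' violation, ties toward the lowest index, so the solution is deterministic
#' given the input order. Sign convention: subjects labelled `-1` (SICH)
#' receive negative decision distances.
#'
#' @param features subjects x d numeric matrix (or `NULL` when
#'   `K` is supplied; the model then predicts only via precomputed kernels).
#' @param labels vector in \{-1, +1\} (or logical: `TRUE` = SICH = -1).
#' @param caps per-sample positive caps (see [nihss_to_caps()]).
#' @param kernel a [kernel_spec()].
#' @param seed accepted for interface uniformity; the solver itself is
#'   deterministic.
#' @param K optional precomputed training Gram matrix.
#' @param tol KKT stopping tolerance.
#' @param max_iter iteration budget; exceeding it yields a flagged
#'   (`converged = FALSE`) but usable model.
#' @return Object of class `svm_model`: `kernel`, `support_vectors`,
#'   `dual_coefs` (alpha_i * y_i over support vectors), `sv_index`, `bias`,
#'   `per_sample_cap`, `alpha`, `labels`, convergence diagnostics, and
#'   `sign_convention = "negative distance = SICH-like"`.
#' @export
train_svm <- function(features, labels, caps, kernel = kernel_spec(),
                      seed = 1L, K = NULL, tol = 1e-6, max_iter = 200000L) {
  if (is.logical(labels)) labels <- ifelse(labels, -1, 1)
  labels <- as.numeric(labels)
  stopifnot(all(labels %in% c(-1, 1)), all(caps > 0))
  if (length(unique(labels)) < 2) stop("both classes must be present")
  if (is.null(K)) {
    stopifnot(!is.null(features))
    features <- as.matrix(features)
    K <- kernel_matrix(features, spec = kernel)
  }
  stopifnot(nrow(K) == length(labels), length(caps) == length(labels))
  sol <- smo_solve(K, labels, as.numeric(caps), eps = tol,
                   max_iter = as.integer(max_iter))
  sv <- which(sol$alpha > 1e-12)
  structure(list(
    kernel = kernel,
    support_vectors = if (!is.null(features)) features[sv, , drop = FALSE],
    dual_coefs = sol$alpha[sv] * labels[sv],
    sv_index = sv,
    bias = sol$bias,
    per_sample_cap = caps,
    alpha = sol$alpha,
    labels = labels,
    converged = sol$converged,
    iterations = sol$iterations,
    kkt_violation = sol$kkt_violation,
    sign_convention = "negative distance = SICH-like"
  ), class = "svm_model")
}

#' Signed distance to the SVM hyperplane
#'
#' `f(x) = sum_i dual_coefs_i k(sv_i, x) + bias`; negative values are
#' SICH-like under the model's sign convention.
#'
#' @param model an `svm_model`.
#' @param x a feature vector, or a matrix with one row per test subject, of
#'   the model's dimensionality (same retained-voxel index); alternatively
#'   supply `K_test`.
#' @param K_test optional precomputed kernel block between test subjects
#'   (rows) and all training subjects (columns).
#' @return Numeric vector of signed decision values.
#' @export
decision_distance <- function(model, x = NULL, K_test = NULL) {
  stopifnot(inherits(model, "svm_model"))
  if (is.null(K_test)) {
    if (is.null(model$support_vectors)) stop("model trained on a precomputed kernel; supply K_test")
    x <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
    if (ncol(x) != ncol(model$support_vectors)) {
      stop("dimension mismatch: model expects ", ncol(model$support_vectors),
           " features (same retained-voxel index), got ", ncol(x))
    }
    if (!is.null(model$center)) {
      x <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
    }
    Ksv <- kernel_matrix(x, model$support_vectors, model$kernel)
  } else {
    Ksv <- as.matrix(K_test)[, model$sv_index, drop = FALSE]
  }
  drop(Ksv %*% model$dual_coefs) + model$bias
}

#' Train the "manual" SVM on radiologist-derived features
#'
#' Uses three features per subject — baseline NIHSS, consensus acute
#' ischemia extent coded 0 / 1 / 2 (none, under 1/3, at least 1/3 of the
#' MCA territory), and the consensus hyperdense MCA sign 0/1 — standardized
#' to zero mean and unit variance (they carry incommensurate units), then
#' fits [train_svm()].
#'
#' @param clinical clinical table from [generate_cohort()].
#' @param consensus consensus readings from [consensus_reading()].
#' @param caps per-sample caps; defaults to [nihss_to_caps()] of the cohort.
#' @param kernel a [kernel_spec()]; linear by default for the 3-feature
#'   space.
#' @param ... passed to [train_svm()].
#' @return An `svm_model` carrying the standardization (`center`, `scale`)
#'   applied to test features by [decision_distance()].
#' @export
train_manual_svm <- function(clinical, consensus,
                             caps = nihss_to_caps(clinical$nihss),
                             kernel = kernel_spec("linear"), ...) {
  stopifnot(identical(clinical$subject_id, consensus$subject_id))
  f <- manual_features(clinical, consensus)
  center <- colMeans(f)
  scale_ <- apply(f, 2, stats::sd)
  scale_[scale_ < 1e-12] <- 1
  fs <- sweep(sweep(f, 2, center), 2, scale_, "/")
  m <- train_svm(fs, clinical$outcome == "SICH", caps, kernel, ...)
  m$center <- center
  m$scale <- scale_
  m
}

#' @rdname train_manual_svm
#' @export
manual_features <- function(clinical, consensus) {
  extent <- ifelse(!consensus$acute_ischemia, 0,
                   ifelse(consensus$gt_third_mca, 2, 1))
  cbind(nihss = clinical$nihss,
        ischemia_extent = extent,
        hyperdense_mca = as.numeric(consensus$hyperdense_mca))
}

#' Feature-space restriction for the SVM ablation variants
#'
#' `NO_BASE` drops voxel columns lying only in the brain-base section
#' (common-grid `z` below the upper section's first slice).
#' `SINGLE_HEMISPHERE` keeps, for each subject, the hemisphere carrying the
#' clinically localized lesion: subjects with right-sided lesions have their
#' voxel vector mirrored in x first, so every subject's lesion hemisphere
#' maps onto one common half-grid; only columns whose mirror column was
#' also retained by cleaning can be kept. `NO_NIHSS` leaves features
#' untouched (the ablation is in the caps; see [ablate()]).
#'
#' @param variant `"NO_NIHSS"`, `"NO_BASE"` or `"SINGLE_HEMISPHERE"`.
#' @param matrix a `cohort_matrix` (cleaned, with `voxel_index` coordinates).
#' @param grid the common [ct_grid()].
#' @param lesion_side per-subject `"L"`/`"R"` (required for
#'   `SINGLE_HEMISPHERE`).
#' @return A list: `values` (restricted subjects x voxels matrix) and
#'   `voxel_index`.
#' @export
ablate_features <- function(variant = c("NO_NIHSS", "NO_BASE", "SINGLE_HEMISPHERE"),
                            matrix, grid = ct_grid(), lesion_side = NULL) {
  variant <- match.arg(variant)
  stopifnot(inherits(matrix, "cohort_matrix"))
  vi <- matrix$voxel_index
  if (variant == "NO_NIHSS") {
    return(list(values = matrix$values, voxel_index = vi))
  }
  if (variant == "NO_BASE") {
    keep <- vi$z >= grid$upper_z0
    if (!any(keep)) stop("empty feature set after masking")
    return(list(values = matrix$values[, keep, drop = FALSE],
                voxel_index = vi[keep, , drop = FALSE]))
  }
  # SINGLE_HEMISPHERE
  stopifnot(!is.null(lesion_side), length(lesion_side) == nrow(matrix$values))
  key <- function(x, y, z) paste(x, y, z, sep = ",")
  col_of <- stats::setNames(seq_len(nrow(vi)), key(vi$x, vi$y, vi$z))
  mirror <- col_of[key(grid$nx - 1L - vi$x, vi$y, vi$z)]
  left <- vi$x < (grid$nx - 1) / 2
  keep <- which(left & !is.na(mirror))
  if (!length(keep)) stop("empty feature set after masking")
  vals <- matrix$values[, keep, drop = FALSE]
  right_rows <- which(lesion_side == "R")
  if (length(right_rows)) {
    vals[right_rows, ] <- matrix$values[right_rows, mirror[keep], drop = FALSE]
  }
  list(values = vals, voxel_index = vi[keep, , drop = FALSE])
}

#' Train an SVM ablation variant
#'
#' `NO_NIHSS` replaces the NIHSS-proportional caps by uniform caps
#' (`base_c`); `NO_BASE` and `SINGLE_HEMISPHERE` restrict the voxel columns
#' via [ablate_features()] while keeping NIHSS-weighted caps.
#'
#' @inheritParams ablate_features
#' @param nihss per-subject baseline NIHSS.
#' @param labels outcome labels (logical SICH, or -1/+1).
#' @param base_c penalty scale.
#' @param kernel a [kernel_spec()].
#' @param ... passed to [train_svm()].
#' @return An `svm_model` with the restricted `voxel_index` attached.
#' @export
ablate <- function(variant, matrix, nihss, labels, grid = ct_grid(),
                   lesion_side = NULL, base_c = 1,
                   kernel = kernel_spec("linear"), ...) {
  af <- ablate_features(variant, matrix, grid, lesion_side)
  caps <- if (variant == "NO_NIHSS") rep(base_c, nrow(af$values))
          else nihss_to_caps(nihss, base_c)
  m <- train_svm(af$values, labels, caps, kernel, ...)
  m$voxel_index <- af$voxel_index
  m
}

#' Serialize / restore an SVM model
#'
#' JSON container holding the kernel spec, support vectors, dual
#' coefficients, bias, caps and a hash of the voxel index guarding against
#' applying the model to a differently-cleaned cohort.
#'
#' @param model an `svm_model`.
#' @param path file path (`.json`).
#' @param voxel_index optional voxel index data frame to fingerprint.
#' @return `write_svm_model` returns `path` invisibly; `read_svm_model` the
#'   restored `svm_model`.
#' @export
write_svm_model <- function(model, path, voxel_index = model$voxel_index) {
  stopifnot(inherits(model, "svm_model"))
  payload <- list(
    kernel = unclass(model$kernel),
    support_vectors = model$support_vectors,
    dual_coefs = model$dual_coefs,
    sv_index = model$sv_index,
    bias = model$bias,
    per_sample_cap = model$per_sample_cap,
    center = model$center, scale = model$scale,
    sign_convention = model$sign_convention,
    converged = model$converged,
    voxel_index_hash = if (!is.null(voxel_index)) {
      sum(as.numeric(unlist(voxel_index)) * seq_along(unlist(voxel_index))) %% 2^31
    }
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_svm_model
#' @export
read_svm_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  num_or_null <- function(x) if (is.numeric(x) && length(x)) x
  p$center <- num_or_null(p$center); p$scale <- num_or_null(p$scale)
  m <- structure(list(
    kernel = structure(p$kernel, class = "kernel_spec"),
    support_vectors = if (!is.null(p$support_vectors)) as.matrix(p$support_vectors),
    dual_coefs = p$dual_coefs, sv_index = p$sv_index, bias = p$bias,
    per_sample_cap = p$per_sample_cap,
    center = p$center, scale = p$scale,
    sign_convention = p$sign_convention, converged = p$converged
  ), class = "svm_model")
  m$voxel_index_hash <- p$voxel_index_hash
  m
}
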