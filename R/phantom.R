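#' Common-grid specification for the two-section CT geometry
#'
#' Describes the common template space and how the two acquisition sections
#' (upper cerebrum, brain base) tile it. Clinical CT brains are frequently
#' acquired in two overlapping sections; here the lower section covers the
#' first `lower_slices` axial slices of the common grid and the upper section
#' the last `upper_slices`, so they overlap in
#' `upper_slices + lower_slices - nz` slices.
#'
#' @param nx,ny,nz common-grid dimensions in voxels. The default 64 x 64 x 40
#'   is a desk-scale grid; pass e.g. `ct_grid(79, 95, 68, ...)` for a
#'   template-sized grid.
#' @param upper_slices,lower_slices axial extent of each section.
#' @param spacing voxel spacing in mm per axis.
#' @return A list of class `ct_grid` with the section slice ranges
#'   (`upper_z0`, 0-based first slice of the upper section) precomputed.
#' @export
ct_grid <- function(nx = 64L, ny = 64L, nz = 40L,
                    upper_slices = 28L, lower_slices = 16L,
                    spacing = c(3, 3, 3)) {
  overlap <- upper_slices + lower_slices - nz
  if (overlap < 1) stop("sections must overlap: upper_slices + lower_slices > nz")
  stopifnot(nx >= 8, ny >= 8, nz >= 8, all(spacing > 0))
  structure(list(nx = as.integer(nx), ny = as.integer(ny), nz = as.integer(nz),
                 upper_slices = as.integer(upper_slices),
                 lower_slices = as.integer(lower_slices),
                 overlap = as.integer(overlap),
                 upper_z0 = as.integer(nz - upper_slices),
                 spacing = as.numeric(spacing)),
            class = "ct_grid")
}

#' Construct a CT section object
#'
#' @param voxels 3D array of Hounsfield units.
#' @param spacing mm per axis.
#' @param origin_offset 0-based voxel coordinates of the section's first
#'   voxel within the common grid.
#' @param kind `"UPPER"` or `"LOWER"`.
#' @return An object of class `ct_section`.
#' @export
ct_section <- function(voxels, spacing, origin_offset, kind) {
  stopifnot(length(dim(voxels)) == 3, all(spacing > 0), all(is.finite(voxels)),
            kind %in% c("UPPER", "LOWER"))
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 origin_offset = as.numeric(origin_offset),
                 section_kind = kind),
            class = "ct_section")
}

# Trilinear interpolation of a 3D volume at fractional 1-based voxel
# coordinates; coordinates outside the volume return `fill`.
resample_trilinear <- function(vol, coords, fill = -1000) {
  d <- dim(vol)
  x <- coords[, 1]; y <- coords[, 2]; z <- coords[, 3]
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  inside <- x0 >= 1 & x0 <= d[1] - 1 & y0 >= 1 & y0 <= d[2] - 1 &
    z0 >= 1 & z0 <= d[3] - 1
  out <- rep(fill, nrow(coords))
  if (!any(inside)) return(out)
  x0 <- x0[inside]; y0 <- y0[inside]; z0 <- z0[inside]
  fx <- fx[inside]; fy <- fy[inside]; fz <- fz[inside]
  idx <- function(i, j, k) (k - 1) * d[1] * d[2] + (j - 1) * d[1] + i
  v <- vol[idx(x0,     y0,     z0)]     * (1 - fx) * (1 - fy) * (1 - fz) +
       vol[idx(x0 + 1, y0,     z0)]     * fx       * (1 - fy) * (1 - fz) +
       vol[idx(x0,     y0 + 1, z0)]     * (1 - fx) * fy       * (1 - fz) +
       vol[idx(x0 + 1, y0 + 1, z0)]     * fx       * fy       * (1 - fz) +
       vol[idx(x0,     y0,     z0 + 1)] * (1 - fx) * (1 - fy) * fz +
       vol[idx(x0 + 1, y0,     z0 + 1)] * fx       * (1 - fy) * fz +
       vol[idx(x0,     y0 + 1, z0 + 1)] * (1 - fx) * fy       * fz +
       vol[idx(x0 + 1, y0 + 1, z0 + 1)] * fx       * fy       * fz
  out[inside] <- v
  out
}

# 1-based voxel coordinate grid for a box of dims dm, offset by orig (0-based).
coord_grid <- function(dm, orig = c(0, 0, 0)) {
  cbind(rep(seq_len(dm[1]), times = dm[2] * dm[3]) + orig[1],
        rep(rep(seq_len(dm[2]), each = dm[1]), times = dm[3]) + orig[2],
        rep(seq_len(dm[3]), each = dm[1] * dm[2]) + orig[3])
}

# In-plane (xy) rotation about `center` followed by translation.
rigid_transform <- function(coords, translation, rot_deg, center) {
  th <- rot_deg * pi / 180
  cx <- coords[, 1] - center[1]; cy <- coords[, 2] - center[2]
  cbind(center[1] + cos(th) * cx - sin(th) * cy + translation[1],
        center[2] + sin(th) * cx + cos(th) * cy + translation[2],
        coords[, 3] + translation[3])
}

phantom_geometry <- function(grid) {
  c0 <- c((grid$nx + 1) / 2, (grid$ny + 1) / 2, (grid$nz + 1) / 2)
  list(center = c0,
       brain_r = c(0.40 * grid$nx, 0.44 * grid$ny, 0.44 * grid$nz),
       skull_outer = 1.13,
       vent_offset = 0.09 * grid$nx,
       vent_r = c(0.055 * grid$nx, 0.17 * grid$ny, 0.11 * grid$nz),
       mca_z_band = c(0.35, 0.78),
       vessel_pos_frac = 0.30,
       vessel_r = 1.6)
}

ellipsoid_dist2 <- function(coords, center, radii) {
  ((coords[, 1] - center[1]) / radii[1])^2 +
    ((coords[, 2] - center[2]) / radii[2])^2 +
    ((coords[, 3] - center[3]) / radii[3])^2
}

# Smooth unit-variance texture field: low-resolution Gaussian noise upsampled
# trilinearly onto the full grid. Deterministic for a fixed RNG state.
smooth_field <- function(grid, coarse = c(8, 8, 5)) {
  f <- array(stats::rnorm(prod(coarse)), dim = coarse)
  co <- coord_grid(c(grid$nx, grid$ny, grid$nz))
  sc <- (coarse - 1) / c(grid$nx - 1, grid$ny - 1, grid$nz - 1)
  cc <- cbind(1 + (co[, 1] - 1) * sc[1], 1 + (co[, 2] - 1) * sc[2],
              1 + (co[, 3] - 1) * sc[3])
  v <- resample_trilinear(f, cc, fill = 0)
  array(v / max(stats::sd(v), 1e-9), dim = c(grid$nx, grid$ny, grid$nz))
}

#' Render the noiseless common-grid CT phantom for one subject
#'
#' Builds an ellipsoidal brain (parenchyma about 35 HU) with lateral
#' ventricles (about 8 HU), a dense skull shell (> 200 HU), periventricular
#' hypodense caps scaled by the Fazekas grade, a diffuse low-spatial-frequency
#' hypoattenuation texture scaled by `background_burden`, a hypoattenuating
#' wedge in the MCA territory of relative angular size
#' `ischemia_fraction_mca` on `lesion_side`, and an optional hyperdense MCA
#' vessel dot. Air is -1000 HU.
#'
#' @param truth one row of the `truth` table from [generate_cohort()] (or any
#'   list with the same fields).
#' @param grid a [ct_grid()].
#' @param signal_amplitude multiplier on the SICH-risk-bearing image features
#'   (ischemic wedge depth and background-burden texture); 0 renders a
#'   cohort whose images carry no outcome information.
#' @param seed integer seed for the subject's texture field.
#' @return 3D array of HU on the common grid.
#' @export
render_phantom <- function(truth, grid = ct_grid(), signal_amplitude = 1, seed = 1L) {
  set.seed(as.integer(seed))
  g <- phantom_geometry(grid)
  dm <- c(grid$nx, grid$ny, grid$nz)
  co <- coord_grid(dm)
  vol <- rep(-1000, nrow(co))

  db <- ellipsoid_dist2(co, g$center, g$brain_r)
  skull <- db > 1 & db <= g$skull_outer^2
  brain <- db <= 1
  vol[skull] <- 800
  vol[brain] <- 35

  # ventricles and Fazekas periventricular caps
  for (s in c(-1, 1)) {
    vc <- g$center + c(s * g$vent_offset, 0, 0)
    dv <- ellipsoid_dist2(co, vc, g$vent_r)
    fz <- as.numeric(truth$fazekas)
    cap <- brain & dv > 1 & dv <= 1.6^2
    vol[cap] <- vol[cap] - 2.5 * fz
    vol[dv <= 1 & brain] <- 8
  }

  # diffuse background hypoattenuation, scaled by burden
  burden <- as.numeric(truth$background_burden)
  if (burden > 0 && signal_amplitude > 0) {
    fld <- as.vector(smooth_field(grid))
    vol[brain] <- vol[brain] -
      burden * signal_amplitude * (1.2 + 1.0 * pmax(fld[brain], 0))
  }

  # focal ischemic wedge: angular sub-sector of the lateral MCA territory
  frac <- as.numeric(truth$ischemia_fraction_mca)
  side_sign <- if (as.character(truth$lesion_side) == "R") 1 else -1
  if (isTRUE(truth$ischemia_present) && frac > 0) {
    zfrac <- (co[, 3] - 1) / (dm[3] - 1)
    lateral <- side_sign * (co[, 1] - g$center[1])
    ang <- atan2(co[, 2] - g$center[2], lateral)  # 0 = lateral axis
    half_sector <- pi / 3                          # MCA territory: +-60 deg
    wedge_half <- half_sector * frac
    in_wedge <- brain & lateral > 0 & abs(ang) <= wedge_half &
      zfrac >= g$mca_z_band[1] & zfrac <= g$mca_z_band[2]
    vol[in_wedge] <- vol[in_wedge] - 7 * signal_amplitude
  }

  # hyperdense MCA vessel dot near the sylvian fissure (amplitude-scaled:
  # it is an outcome-correlated image feature like the wedge and texture)
  if (isTRUE(truth$hyperdense_mca)) {
    vp <- g$center + c(side_sign * g$vessel_pos_frac * grid$nx, 0, 0)
    dvessel <- sqrt((co[, 1] - vp[1])^2 + (co[, 2] - vp[2])^2 +
                      (co[, 3] - vp[3])^2)
    vol[brain & dvessel <= g$vessel_r] <- 35 + 35 * signal_amplitude
  }

  # attenuation floor: stacked hypodense features never drive parenchyma
  # to or below 0 HU (keeps clean scans inside the plausible brain range)
  vol[brain] <- pmax(vol[brain], 3)

  array(vol, dim = dm)
}

#' Render a subject's two-section CT acquisition
#'
#' Samples the common-grid phantom of [render_phantom()] into the two
#' acquisition sections of the grid, optionally applying an independent small
#' random rigid jitter per section (emulating imperfect spatial
#' normalization) and additive Gaussian HU noise.
#'
#' @inheritParams render_phantom
#' @param noise_sd additive Gaussian noise, HU; must be >= 0.
#' @param jitter logical, or a list with `upper`/`lower` each
#'   `list(translation = c(tx, ty, tz), rot_deg = r)` to impose a known
#'   transform. `TRUE` draws translations uniformly in +-1.2 voxels and an
#'   in-plane rotation in +-1.5 degrees.
#' @return `list(upper =, lower =)` of [ct_section()] objects.
#' @export
render_ct <- function(truth, grid = ct_grid(), noise_sd = 2, seed = 1L,
                      signal_amplitude = 1, jitter = TRUE) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  vol <- render_phantom(truth, grid, signal_amplitude, seed)
  set.seed(as.integer(seed) + 1L)
  draw_jitter <- function() list(translation = stats::runif(3, -1.2, 1.2),
                                 rot_deg = stats::runif(1, -1.5, 1.5))
  jit <- if (isTRUE(jitter)) list(upper = draw_jitter(), lower = draw_jitter())
         else if (is.list(jitter)) jitter
         else list(upper = list(translation = c(0, 0, 0), rot_deg = 0),
                   lower = list(translation = c(0, 0, 0), rot_deg = 0))
  center <- phantom_geometry(grid)$center
  make_section <- function(kind) {
    if (kind == "UPPER") { z0 <- grid$upper_z0; ns <- grid$upper_slices }
    else { z0 <- 0L; ns <- grid$lower_slices }
    j <- jit[[tolower(kind)]]
    co <- coord_grid(c(grid$nx, grid$ny, ns), orig = c(0, 0, z0))
    src <- rigid_transform(co, j$translation, j$rot_deg, center)
    v <- resample_trilinear(vol, src)
    if (noise_sd > 0) v <- v + stats::rnorm(length(v), 0, noise_sd)
    ct_section(array(v, dim = c(grid$nx, grid$ny, ns)), grid$spacing,
               c(0, 0, z0), kind)
  }
  list(upper = make_section("UPPER"), lower = make_section("LOWER"))
}

#' Template brain mask on the common grid
#'
#' Inclusive brain mask excluding ventricles: the brain ellipsoid eroded away
#' from the skull (so small rigid jitter cannot drag bone into the mask on a
#' clean scan), minus a safety margin around both lateral ventricles.
#'
#' @param grid a [ct_grid()].
#' @return Logical 3D array on the common grid.
#' @export
brain_mask_template <- function(grid = ct_grid()) {
  g <- phantom_geometry(grid)
  co <- coord_grid(c(grid$nx, grid$ny, grid$nz))
  m <- ellipsoid_dist2(co, g$center, 0.88 * g$brain_r) <= 1
  for (s in c(-1, 1)) {
    vc <- g$center + c(s * g$vent_offset, 0, 0)
    m <- m & ellipsoid_dist2(co, vc, 1.25 * g$vent_r) > 1
  }
  array(m, dim = c(grid$nx, grid$ny, grid$nz))
}

#' Render the registration template for one section
#'
#' The template is the featureless mean-brain phantom (no ischemia, no
#' hyperdense vessel, zero Fazekas and background burden), rendered noiseless
#' and jitter-free into the requested section. Used as the fixed image by
#' [normalize_section()].
#'
#' @param grid a [ct_grid()].
#' @param kind `"UPPER"` or `"LOWER"`.
#' @return A [ct_section()].
#' @export
template_section <- function(grid = ct_grid(), kind = c("UPPER", "LOWER")) {
  kind <- match.arg(kind)
  blank <- list(ischemia_present = FALSE, ischemia_fraction_mca = 0,
                hyperdense_mca = FALSE, fazekas = 0, background_burden = 0,
                lesion_side = "L", sich_probability = 0)
  render_ct(blank, grid, noise_sd = 0, seed = 0L, jitter = FALSE)[[tolower(kind)]]
}

#' Write / read a CT section as NIfTI-1
#'
#' Sections are stored RAS-oriented with HU-valued voxels; the common-grid
#' origin offset is carried in the NIfTI qform translation (in mm).
#'
#' @param section a [ct_section()].
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `write_section` returns `path` invisibly; `read_section` returns a
#'   [ct_section()].
#' @export
write_section <- function(section, path) {
  img <- RNifti::asNifti(section$voxels)
  RNifti::pixdim(img) <- section$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_section
#' @param path file path to read.
#' @param origin_offset,kind section placement metadata (not all NIfTI writers
#'   round-trip the qform; these override what the header implies).
#' @export
read_section <- function(path, origin_offset, kind) {
  img <- RNifti::readNifti(path)
  ct_section(array(as.numeric(img), dim = dim(img)),
             RNifti::pixdim(img)[seq_len(3)], origin_offset, kind)
}
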