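# Shared fixtures: tiny grids and latent-truth rows used across test files.

tiny_grid <- function() ct_grid(32, 32, 20, upper_slices = 14, lower_slices = 8)

make_truth <- function(ischemia_present = FALSE, ischemia_fraction_mca = 0,
                       hyperdense_mca = FALSE, fazekas = 0,
                       background_burden = 0, lesion_side = "L",
                       sich_probability = 0.1, subject_id = "S001") {
  data.frame(subject_id = subject_id,
             ischemia_present = ischemia_present,
             ischemia_fraction_mca = ischemia_fraction_mca,
             hyperdense_mca = hyperdense_mca,
             fazekas = fazekas,
             background_burden = background_burden,
             lesion_side = lesion_side,
             sich_probability = sich_probability,
             stringsAsFactors = FALSE)
}

# A flat section filled with a constant, for join/mask arithmetic tests.
flat_section <- function(grid, kind, value) {
  ns <- if (kind == "UPPER") grid$upper_slices else grid$lower_slices
  z0 <- if (kind == "UPPER") grid$upper_z0 else 0L
  ct_section(array(value, dim = c(grid$nx, grid$ny, ns)),
             grid$spacing, c(0, 0, z0), kind)
}

# Brute-force per-cell reference for the cohort cleaning rule.
clean_oracle <- function(m, hu_low = 0, hu_high = 200, thr = 5L) {
  anom <- function(v) is.na(v) | v < hu_low | v > hu_high
  del <- logical(ncol(m))
  out <- m
  for (j in seq_len(ncol(m))) {
    bad <- anom(m[, j])
    if (sum(bad) >= thr) { del[j] <- TRUE; next }
    if (any(bad)) out[bad, j] <- mean(m[!bad, j])
  }
  list(values = out[, !del, drop = FALSE], deleted = which(del))
}
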