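# Independent reference implementations used as oracles.

# Dense-QP solution of the soft-margin dual (kernlab interior-point solver),
# independent of the SMO path.
qp_decision <- function(X, y, C, K = kernel_matrix(X, spec = kernel_spec("linear"))) {
  H <- (y %*% t(y)) * K
  sol <- kernlab::ipop(c = rep(-1, nrow(X)), H = H, A = matrix(y, 1), b = 0,
                       r = 0, l = rep(0, nrow(X)), u = C, sigf = 9)
  a <- kernlab::primal(sol)
  free <- which(a > 1e-6 & a < C - 1e-6)
  b <- mean(y[free] - (K %*% (a * y))[free])
  drop(K %*% (a * y)) + b
}

# One full synthetic-cohort evaluation: generate, render, preprocess, score,
# train and rank. Used by the end-to-end recovery and null checks.
e2e_run <- function(seed, amplitude, grid, foil_sets = 15) {
  co <- generate_cohort(16, 100, seed = seed)
  mask <- brain_mask_template(grid)
  coords <- mask_coords(mask)
  vecs <- t(vapply(seq_len(116), function(i) {
    s <- render_ct(co$truth[i, ], grid, noise_sd = 2, seed = seed * 1000 + i,
                   jitter = FALSE, signal_amplitude = amplitude)
    apply_brain_mask(join_sections(s$upper, s$lower, grid), mask)
  }, numeric(sum(mask))))
  cm <- global_intensity_correct(clean_cohort(vecs, coords))
  labels <- co$clinical$outcome == "SICH"
  caps <- nihss_to_caps(co$clinical$nihss)
  plan <- make_split_plan(labels, foil_sets, seed = seed)
  K <- kernel_matrix(cm$values, spec = kernel_spec("linear"))
  ev <- evaluate_svm(NULL, labels, caps, plan, kernel_spec("linear"), K = K)
  cons <- consensus_reading(simulate_raters(co$truth, seed = seed + 5))
  sc <- score_panel(co$clinical, cons)
  list(auc = ev$auc, identified = ev$identified,
       identified_adapted_sedan =
         evaluate_score(sc$adapted_sedan, labels, plan)$identified,
       identified_adapted_hat =
         evaluate_score(sc$adapted_hat, labels, plan)$identified)
}
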