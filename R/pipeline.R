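#' Pipeline run configuration
#'
#' One structured configuration object driving the full study pipeline
#' (simulate, preprocess, score, train, evaluate, report). Round-trips
#' losslessly through YAML via [write_run_config()] / [read_run_config()].
#'
#' @param n_sich,n_control case-control composition of the simulated cohort.
#' @param foil_sets_per_case case-foil test sets per SICH case (110 gives
#'   the full 1760-split design at 16 + 100).
#' @param grid named list of [ct_grid()] arguments.
#' @param noise_sd CT noise, HU.
#' @param signal_amplitude multiplier on the risk-bearing image features.
#' @param jitter whether acquisition jitter is simulated.
#' @param registration `"rigid"` to run [normalize_section()], `"none"` to
#'   take the sections as already template-space (only sensible with
#'   `jitter = FALSE`).
#' @param hu_low,hu_high,subject_threshold cleaning rule parameters.
#' @param kernel named list of [kernel_spec()] arguments for the automated
#'   SVM (linear by default: raw whole-image HU dot products saturate the
#'   sigmoid kernel).
#' @param base_c soft-margin scale for [nihss_to_caps()].
#' @param n_boot bootstrap replicates for [compare_models()].
#' @param write_volumes write per-subject NIfTI sections under the run
#'   directory.
#' @return A list of class `run_config`.
#' @export
run_config <- function(n_sich = 16L, n_control = 100L,
                       foil_sets_per_case = 110L,
                       grid = list(nx = 64L, ny = 64L, nz = 40L,
                                   upper_slices = 28L, lower_slices = 16L),
                       noise_sd = 2, signal_amplitude = 1,
                       jitter = TRUE, registration = "rigid",
                       hu_low = 0, hu_high = 200, subject_threshold = 5L,
                       kernel = list(kind = "linear"),
                       base_c = 1, n_boot = 1000L, write_volumes = FALSE) {
  structure(list(n_sich = as.integer(n_sich), n_control = as.integer(n_control),
                 foil_sets_per_case = as.integer(foil_sets_per_case),
                 grid = grid, noise_sd = noise_sd,
                 signal_amplitude = signal_amplitude, jitter = jitter,
                 registration = match.arg(registration, c("rigid", "none")),
                 hu_low = hu_low, hu_high = hu_high,
                 subject_threshold = as.integer(subject_threshold),
                 kernel = kernel, base_c = base_c, n_boot = as.integer(n_boot),
                 write_volumes = isTRUE(write_volumes)),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

# Per-stage seeds derived from the master seed by a fixed counter scheme,
# kept below 2^31 so they remain valid R integer seeds.
stage_seed <- function(master, stage) {
  as.integer((as.numeric(master) %% 100000) * 20011 + stage * 7919) %% 2147483647L
}

#' Run the full study pipeline
#'
#' Executes simulate -> preprocess -> score -> train -> evaluate -> report
#' from one configuration, deterministically for a given master seed
#' (per-stage seeds are derived by a documented counter scheme). Every
#' artefact is written under `out_dir`; a manifest records the per-stage
#' seeds and MD5 hashes of all written files, making silent input changes
#' detectable. Any stage failure aborts with the stage name.
#'
#' @param config a [run_config()].
#' @param seed master integer seed.
#' @param out_dir run directory (created).
#' @return Invisibly, a list with the run directory, the comparison report
#'   data frame, and the per-model `evaluation_result`s.
#' @export
run_pipeline <- function(config = run_config(), seed = 1L, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(master_seed = as.integer(seed), stages = list())
  written <- character(0)
  note <- function(stage, seed_used, files) {
    manifest$stages[[stage]] <<- list(seed = seed_used, files = files)
    written <<- c(written, files)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  grid <- do.call(ct_grid, config$grid)
  kernel <- do.call(kernel_spec, config$kernel)

  # 1. cohort ----------------------------------------------------------
  s1 <- stage_seed(seed, 1)
  cohort <- stage("simulate_cohort",
                  generate_cohort(config$n_sich, config$n_control, seed = s1))
  f_clin <- file.path(out_dir, "clinical.csv")
  f_truth <- file.path(out_dir, "truth.csv")
  utils::write.csv(cohort$clinical, f_clin, row.names = FALSE)
  utils::write.csv(cohort$truth, f_truth, row.names = FALSE)
  note("simulate_cohort", s1, c(f_clin, f_truth))

  # 2. raters ----------------------------------------------------------
  s2 <- stage_seed(seed, 2)
  readings <- stage("simulate_raters", simulate_raters(cohort$truth, seed = s2))
  consensus <- stage("consensus", consensus_reading(readings))
  f_read <- file.path(out_dir, "readings.csv")
  f_cons <- file.path(out_dir, "consensus.csv")
  utils::write.csv(readings, f_read, row.names = FALSE)
  utils::write.csv(consensus, f_cons, row.names = FALSE)
  note("simulate_raters", s2, c(f_read, f_cons))

  # 3. imaging + preprocessing -----------------------------------------
  s3 <- stage_seed(seed, 3)
  mask <- brain_mask_template(grid)
  coords <- mask_coords(mask)
  n <- nrow(cohort$clinical)
  vectors <- matrix(NA_real_, n, sum(mask))
  vol_dir <- file.path(out_dir, "volumes")
  if (config$write_volumes) dir.create(vol_dir, showWarnings = FALSE)
  stage("preprocess", {
    templates <- list(UPPER = template_section(grid, "UPPER"),
                      LOWER = template_section(grid, "LOWER"))
    for (i in seq_len(n)) {
      secs <- render_ct(cohort$truth[i, ], grid, noise_sd = config$noise_sd,
                        seed = s3 + i, signal_amplitude = config$signal_amplitude,
                        jitter = config$jitter)
      if (config$write_volumes) {
        write_section(secs$upper, file.path(vol_dir, sprintf("%s_upper.nii.gz",
                                                             cohort$clinical$subject_id[i])))
        write_section(secs$lower, file.path(vol_dir, sprintf("%s_lower.nii.gz",
                                                             cohort$clinical$subject_id[i])))
      }
      if (config$registration == "rigid") {
        secs$upper <- normalize_section(secs$upper, grid,
                                        templates$UPPER)$section
        secs$lower <- normalize_section(secs$lower, grid,
                                        templates$LOWER)$section
      }
      joined <- join_sections(secs$upper, secs$lower, grid)
      vectors[i, ] <- apply_brain_mask(joined, mask)
    }
  })
  matrix_clean <- stage("clean", clean_cohort(vectors, coords,
                                              hu_low = config$hu_low,
                                              hu_high = config$hu_high,
                                              subject_threshold = config$subject_threshold))
  matrix_clean <- stage("intensity_correct", global_intensity_correct(matrix_clean))
  f_mat <- file.path(out_dir, "cohort_matrix")
  write_cohort_matrix(matrix_clean, f_mat)
  note("preprocess", s3, file.path(f_mat, c("values.bin", "sidecar.json")))

  # 4. scores ----------------------------------------------------------
  scores <- stage("scores", score_panel(cohort$clinical, consensus))
  tab1 <- stage("univariate", univariate_table(cohort$clinical, consensus))
  f_sc <- file.path(out_dir, "scores.csv")
  f_t1 <- file.path(out_dir, "univariate_table.csv")
  utils::write.csv(scores, f_sc, row.names = FALSE)
  utils::write.csv(tab1, f_t1, row.names = FALSE)
  note("scores", NA, c(f_sc, f_t1))

  # 5. models + evaluation ---------------------------------------------
  s5 <- stage_seed(seed, 5)
  labels <- cohort$clinical$outcome == "SICH"
  plan <- stage("split_plan", make_split_plan(labels,
                                              config$foil_sets_per_case,
                                              seed = s5))
  caps <- nihss_to_caps(cohort$clinical$nihss, config$base_c)
  K <- kernel_matrix(matrix_clean$values, spec = kernel)
  results <- stage("evaluate", list(
    automated_svm = evaluate_svm(NULL, labels, caps, plan, kernel, K = K),
    manual_svm = evaluate_manual_svm(cohort$clinical, consensus, caps, plan),
    sedan = evaluate_score(scores$sedan, labels, plan),
    hat = evaluate_score(scores$hat, labels, plan),
    adapted_sedan = evaluate_score(scores$adapted_sedan, labels, plan),
    adapted_hat = evaluate_score(scores$adapted_hat, labels, plan)
  ))
  full_model <- stage("train_full", train_svm(NULL, labels, caps, kernel,
                                              K = K))
  full_model$voxel_index <- matrix_clean$voxel_index
  f_model <- file.path(out_dir, "automated_svm.json")
  write_svm_model(full_model, f_model)

  s6 <- stage_seed(seed, 6)
  report <- stage("compare", compare_models(results, plan,
                                            n_boot = config$n_boot, seed = s6))
  f_rep <- file.path(out_dir, "report.csv")
  utils::write.csv(report, f_rep, row.names = FALSE)
  f_md <- file.path(out_dir, "report.md")
  writeLines(report_markdown(report), f_md)
  note("evaluate", s5, c(f_model, f_rep, f_md))

  manifest$config <- unclass(config)
  manifest$hashes <- as.list(tools::md5sum(written))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(dir = out_dir, report = report, results = results,
                 plan = plan, matrix = matrix_clean, cohort = cohort))
}

#' Per-split evaluation of the "manual" radiology-feature SVM
#'
#' Standardization is refit within each training split so no test
#' information leaks into the feature scaling.
#'
#' @inheritParams evaluate_svm
#' @param clinical,consensus cohort tables.
#' @export
evaluate_manual_svm <- function(clinical, consensus, caps, plan,
                                kernel = kernel_spec("linear")) {
  labels <- clinical$outcome == "SICH"
  f <- manual_features(clinical, consensus)
  evaluate_with(plan, labels, function(train, test) {
    ctr <- colMeans(f[train, , drop = FALSE])
    sc <- apply(f[train, , drop = FALSE], 2, stats::sd)
    sc[sc < 1e-12] <- 1
    std <- function(m) sweep(sweep(m, 2, ctr), 2, sc, "/")
    m <- train_svm(std(f[train, , drop = FALSE]), labels[train], caps[train],
                   kernel)
    decision_distance(m, std(f[test, , drop = FALSE]))
  })
}

report_markdown <- function(report) {
  hdr <- c("| Model | AUC (95% CI) | SICHs identified | Per-case modal ranks | p vs reference |",
           "|---|---|---|---|---|")
  rows <- vapply(seq_len(nrow(report)), function(i) {
    r <- report[i, ]
    sprintf("| %s | %.3f (%.3f-%.3f) | %d | %s | %s |",
            r$model, r$auc, r$auc_lo, r$auc_hi, r$identified, r$modal_ranks,
            if (is.na(r$p_vs_ref)) "ref" else sprintf("%.3f", r$p_vs_ref))
  }, character(1))
  c("# Case-foil evaluation report", "",
    "Model comparison p-values are paired-bootstrap surrogates over SICH cases.",
    "", hdr, rows)
}
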