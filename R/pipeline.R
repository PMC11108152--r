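# End-to-end orchestration: simulate -> maps -> train/evaluate -> explain.
# The desk preset is a CPU-scale configuration of the full protocol: a
# synthetic cohort with one spherical AD lesion, combined 4-channel map
# stacks, a width-scaled GAP network and seeded repeated subject-level
# splits.

#' Desk-scale cohort configuration
#'
#' The default study conditions for CPU-scale experiments: 24x28x24 grid, 120
#' time points at TR 3 s, 20 subjects per class, one scan each, and one
#' spherical ROI (center (8, 14, 12), radius 4 voxels) carrying the AD-class
#' effects: band-limited amplitude scaling x1.5 and a coherence boost of 0.6.
#' Neutral cohorts (`null_effects = TRUE`) drop the ROI effects so both
#' classes are draws from the same distribution.
#'
#' @param seed Master seed.
#' @param n_subjects_per_class Subjects per class.
#' @param amplitude_scale,coherence_boost AD-effect magnitudes.
#' @param null_effects Generate a neutral-effect cohort.
#' @param ... Overrides passed to [simulation_config()].
#' @return A `simulation_config` with an attached `roi` attribute (the
#'   injected ROI mask).
#' @export
desk_cohort_config <- function(seed = 1, n_subjects_per_class = 20,
                               amplitude_scale = 1.5, coherence_boost = 0.6,
                               null_effects = FALSE, ...) {
  gs <- c(24, 28, 24)
  roi <- make_spherical_roi(c(8, 14, 12), 4, gs)
  effects <- if (null_effects) list() else list(
    roi_effect(roi, "amplitude_scale", amplitude_scale, "AD"),
    roi_effect(roi, "coherence_boost", coherence_boost, "AD"))
  cfg <- simulation_config(grid_shape = gs, n_timepoints = 120, tr = 3.0,
                           n_subjects_per_class = n_subjects_per_class,
                           scans_per_subject = 1, noise_sd = 1.0,
                           seed = seed, roi_effects = effects, ...)
  attr(cfg, "roi") <- roi
  cfg
}

#' Desk-scale training configuration
#'
#' Training hyperparameters used by the CPU-scale experiments: Adam with a
#' learning rate suited to the narrow desk network, the protocol's weight
#' decay 5e-4 and batch size 4.
#'
#' @param n_epochs Epoch budget.
#' @param seed Seed.
#' @return A [train_config()].
#' @export
desk_train_config <- function(n_epochs = 30, seed = 1)
  train_config(lr = 1e-3, weight_decay = 5e-4, batch_size = 4,
               n_epochs = n_epochs, seed = seed)

#' Per-class average Grad-CAM heatmaps of a run's test scans
#'
#' Computes a Grad-CAM heatmap for every test scan of a run, upsamples it to
#' input resolution (align-corners trilinear), unit-max normalizes it, and
#' averages within each true class.
#'
#' @param run A `run_result`.
#' @param stacks Named list of `map_stack`s.
#' @param class_mode `"predicted"` (explain the predicted class, default) or
#'   `"true"` (explain the true class).
#' @param include `"all"` test scans or only `"correct"`ly classified ones.
#' @return List with `AD`, `NC` (average `heatmap`s, possibly NULL) and
#'   `per_scan` (named list of full-resolution heatmaps).
#' @export
class_average_heatmaps <- function(run, stacks,
                                   class_mode = c("predicted", "true"),
                                   include = c("all", "correct")) {
  class_mode <- match.arg(class_mode)
  include <- match.arg(include)
  target <- run$model$spec$input_shape
  per_scan <- list()
  for (i in seq_along(run$test_scans)) {
    id <- run$test_scans[i]
    ci <- if (class_mode == "true") match(run$truths[i], c("AD", "NC")) else NULL
    hm <- gradcam(run$model, stacks[[id]], class_index = ci)
    per_scan[[id]] <- unit_max(upsample(hm, target))
  }
  avg <- lapply(c(AD = "AD", NC = "NC"), function(cl) {
    keep <- run$truths == cl
    if (include == "correct") keep <- keep & run$predictions == run$truths
    ids <- run$test_scans[keep]
    if (!length(ids)) return(NULL)
    average_heatmaps(per_scan[ids], "unit_max")
  })
  list(AD = avg$AD, NC = avg$NC, per_scan = per_scan)
}

#' Run the full desk-scale pipeline
#'
#' Simulate a cohort, compute combined activity-map stacks, run the repeated
#' subject-level-split experiment with a GAP-head network, explain the test
#' scans with Grad-CAM, and summarize per-class ROI concentration. All
#' randomness derives from `seed`.
#'
#' @param seed Master seed.
#' @param out_dir Optional output directory for CSV/JSON artifacts (and NIfTI
#'   scans when `write_nifti = TRUE`).
#' @param n_repeats Number of repeated splits (default 3).
#' @param sim_config Optional [simulation_config()] (defaults to
#'   [desk_cohort_config()] with this seed).
#' @param spec Optional [network_spec()] (defaults to the desk GAP network).
#' @param tconfig Optional [train_config()] (defaults to
#'   [desk_train_config()]).
#' @param roi Optional ROI mask for concentration reports (defaults to the
#'   injected ROI of the desk cohort).
#' @param write_nifti Write the simulated scans as NIfTI files.
#' @param verbose Print progress.
#' @return List: `cohort`, `result` (experiment), `table` (accuracy
#'   data.frame), `explain` (per-run class averages and concentrations),
#'   `concentration` (per-class mean concentration across runs).
#' @export
run_all <- function(seed = 1, out_dir = NULL, n_repeats = 3,
                    sim_config = NULL, spec = NULL, tconfig = NULL,
                    roi = NULL, write_nifti = FALSE, verbose = FALSE) {
  if (is.null(sim_config)) sim_config <- desk_cohort_config(seed = seed)
  if (is.null(roi)) roi <- attr(sim_config, "roi")
  if (is.null(spec))
    spec <- network_spec(input_shape = sim_config$grid_shape, in_channels = 4,
                         head = "gap", preset = "desk")
  if (is.null(tconfig)) tconfig <- desk_train_config(seed = seed)

  if (verbose) message("simulating cohort ...")
  cohort <- generate_cohort(sim_config,
                            out_dir = if (write_nifti) file.path(out_dir, "scans"))
  if (verbose) message("computing activity maps ...")
  stacks <- cohort_map_stacks(cohort, "combined", sim_config$band,
                              verbose = verbose)
  if (verbose) message("training ", n_repeats, " repeats ...")
  result <- run_experiment(stacks, cohort$manifest, spec, tconfig,
                           n_repeats = n_repeats, base_seed = seed,
                           verbose = verbose)

  brain <- cohort$scans[[1]]$brain_mask
  explain <- lapply(result$runs, function(run) {
    ch <- class_average_heatmaps(run, stacks)
    conc <- lapply(ch[c("AD", "NC")], function(h)
      if (is.null(h)) NULL else roi_concentration(h, roi, brain))
    mis <- misclassified_report(run, ch$per_scan, roi, brain)
    list(averages = ch[c("AD", "NC")], concentration = conc,
         misclassified = mis)
  })
  conc_mean <- vapply(c(AD = "AD", NC = "NC"), function(cl)
    mean(vapply(explain, function(e)
      if (is.null(e$concentration[[cl]])) NA_real_
      else e$concentration[[cl]]$concentration, numeric(1)), na.rm = TRUE),
    numeric(1))
  table <- accuracy_table(list(combined = result))

  out <- list(cohort = cohort, stacks = stacks, result = result,
              table = table, explain = explain, concentration = conc_mean,
              roi = roi, seed = seed)
  if (!is.null(out_dir)) write_run_artifacts(out, out_dir)
  out
}

write_run_artifacts <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(out$table, file.path(out_dir, "accuracy_table.csv"),
                   row.names = FALSE)
  for (r in seq_along(out$result$runs)) {
    run <- out$result$runs[[r]]
    utils::write.csv(as.data.frame(run$confusion),
                     file.path(out_dir, sprintf("confusion_run%d.csv", r)))
    pr <- pr_curve(run$probabilities[, 1], run$truths)
    utils::write.csv(pr$points,
                     file.path(out_dir, sprintf("pr_curve_run%d.csv", r)),
                     row.names = FALSE)
  }
  summary <- list(
    seed = out$seed,
    accuracy_mean = out$result$accuracy$mean,
    accuracy_sd = out$result$accuracy$sd,
    accuracy_per_run = out$result$accuracy$per_run,
    concentration_AD = unname(out$concentration["AD"]),
    concentration_NC = unname(out$concentration["NC"]))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Tiny fixture set for fast unit tests
#'
#' A miniature cohort (2 subjects per class on a 12^3 grid, 40 time points)
#' plus closed-form spectral test cases: sinusoidal series whose ALFF and
#' fALFF values are known analytically from their construction.
#'
#' @param seed Integer seed.
#' @return List: `cohort`, `config`, and `spectral_cases` (each with a
#'   series, tr, band and the expected ALFF/fALFF values).
#' @export
make_fixtures <- function(seed = 42) {
  cfg <- simulation_config(grid_shape = c(12, 12, 12), n_timepoints = 40,
                           tr = 3.0, n_subjects_per_class = 2,
                           scans_per_subject = 1, noise_sd = 0.5, seed = seed,
                           n_sinusoids = 3)
  cohort <- generate_cohort(cfg)
  tr <- 2.0; n <- 100
  tt <- (0:(n - 1)) * tr
  bins <- band_bin_indices(n, tr)                      # in-band DFT bins
  f_in <- bins[2] / (n * tr)
  f_out <- 45 / (n * tr)                               # above 0.1 Hz
  m <- length(bins)
  cases <- list(
    in_band = list(series = 3 * cos(2 * pi * f_in * tt), tr = tr,
                   alff = 3 / m, falff = 1),
    out_band = list(series = 2 * cos(2 * pi * f_out * tt), tr = tr,
                    alff = 0, falff = 0),
    mixed = list(series = 2 * cos(2 * pi * f_in * tt) +
                   2 * sin(2 * pi * f_out * tt), tr = tr,
                 alff = 2 / m, falff = 0.5))
  list(cohort = cohort, config = cfg, spectral_cases = cases)
}
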