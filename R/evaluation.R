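# Repeated-split evaluation: subject-level 80/20 splits, repeated training
# runs, accuracy tables (mean +/- sample sd), confusion matrices,
# precision-recall curves, and heatmap-based reports.

#' Subject-level stratified train/test split
#'
#' Shuffles subjects within each class with the given seed and assigns the
#' first `ceiling(fraction * n_class)` to the training set, so that all scans
#' of a subject fall on the same side (no leakage between train and test).
#'
#' @param manifest Data frame with columns `subject_id`, `scan_id`, `label`.
#' @param fraction Training fraction (default 0.8).
#' @param seed Integer seed.
#' @return A `split_plan`: list with `train_subjects`, `test_subjects`,
#'   `train_scans`, `test_scans`, `fraction`, `seed`.
#' @export
subject_split <- function(manifest, fraction = 0.8, seed = 1) {
  stopifnot(fraction > 0, fraction < 1)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  train <- character(); test <- character()
  for (cl in unique(manifest$label)) {
    subj <- unique(manifest$subject_id[manifest$label == cl])
    if (length(subj) < 2)
      stop("class ", cl, " has fewer than 2 subjects; cannot split")
    subj <- sample(subj)
    n_tr <- ceiling(fraction * length(subj))
    if (n_tr == length(subj)) n_tr <- length(subj) - 1L
    train <- c(train, subj[seq_len(n_tr)])
    test <- c(test, subj[(n_tr + 1):length(subj)])
  }
  stopifnot(length(intersect(train, test)) == 0)
  structure(list(train_subjects = train, test_subjects = test,
                 train_scans = manifest$scan_id[manifest$subject_id %in% train],
                 test_scans = manifest$scan_id[manifest$subject_id %in% test],
                 fraction = fraction, seed = seed),
            class = "split_plan")
}

#' Confusion matrix for binary AD/NC predictions
#'
#' @param predictions,truths Character vectors of `"AD"`/`"NC"`.
#' @return 2x2 integer matrix, rows = truth (AD, NC), columns = prediction.
#' @export
confusion_matrix <- function(predictions, truths) {
  stopifnot(length(predictions) == length(truths))
  lv <- c("AD", "NC")
  if (!all(c(predictions, truths) %in% lv))
    stop("labels must be 'AD' or 'NC'")
  m <- table(factor(truths, lv), factor(predictions, lv))
  mat <- matrix(as.integer(m), 2, 2, dimnames = list(truth = lv, predicted = lv))
  mat
}

#' Precision-recall curve for the AD class
#'
#' Precision and recall of the positive class at every unique score
#' threshold, plus the area under the curve (trapezoid over recall).
#'
#' @param probabilities Numeric vector of P(positive class) per scan.
#' @param truths Character vector of `"AD"`/`"NC"`.
#' @param positive_class Label treated as positive (default `"AD"`).
#' @return A `pr_curve` object: data.frame `points` (threshold, precision,
#'   recall) and scalar `auc`.
#' @export
pr_curve <- function(probabilities, truths, positive_class = "AD") {
  stopifnot(length(probabilities) == length(truths),
            all(probabilities >= 0 & probabilities <= 1))
  pos <- truths == positive_class
  if (all(pos) || !any(pos))
    stop("precision-recall curve needs both classes in the truth vector")
  th <- sort(unique(c(0, probabilities)))
  pts <- lapply(th, function(t) {
    called <- probabilities >= t
    tp <- sum(called & pos)
    prec <- if (any(called)) tp / sum(called) else 1
    data.frame(threshold = t, precision = prec, recall = tp / sum(pos))
  })
  pts <- do.call(rbind, pts)
  # integrate along descending threshold (recall nondecreasing), anchored at
  # (recall 0, precision 1); ties in recall contribute zero width
  o <- order(pts$threshold, decreasing = TRUE)
  r <- c(0, pts$recall[o]); p <- c(1, pts$precision[o])
  auc <- sum(diff(r) * (p[-1] + p[-length(p)]) / 2)
  structure(list(points = pts, auc = auc, positive_class = positive_class),
            class = "pr_curve")
}

# Build per-scan map stacks for a cohort. map_kinds "combined" = all four
# canonical channels; otherwise a subset of c("alff","falff","reho","vmhc").
#' Compute (optionally normalized) map stacks for every scan of a cohort
#'
#' @param cohort A `cohort`.
#' @param map_kinds `"combined"` or character subset of
#'   `c("alff", "falff", "reho", "vmhc")`.
#' @param band Frequency band in Hz.
#' @param normalize Per-channel normalization mode, see [normalize_map()].
#' @param verbose Print progress.
#' @return Named list (by scan_id) of `map_stack`s.
#' @export
cohort_map_stacks <- function(cohort, map_kinds = "combined",
                              band = c(0.01, 0.1),
                              normalize = "none",
                              verbose = FALSE) {
  kinds <- if (identical(map_kinds, "combined"))
    c("alff", "falff", "reho", "vmhc") else tolower(map_kinds)
  stacks <- list()
  for (sc in cohort$scans) {
    maps <- lapply(kinds, function(k)
      normalize_map(activity_map(sc, k, band), normalize))
    stacks[[sc$scan_id]] <- stack_maps(maps)
    if (verbose) message("maps: ", sc$scan_id)
  }
  stacks
}

#' Run the repeated-split classification experiment
#'
#' For each repeat: a fresh seeded subject-level split, a freshly initialized
#' network, training on the train scans and prediction on the held-out test
#' scans. Aggregates per-run accuracies into mean +/- sample sd.
#'
#' @param stacks Named list of `map_stack`s (see [cohort_map_stacks()]).
#' @param manifest Cohort manifest (subject_id, scan_id, label).
#' @param spec A [network_spec()]; `in_channels` must match the stacks.
#' @param config A [train_config()].
#' @param n_repeats Number of repeated splits/trainings (default 10).
#' @param base_seed Seed from which per-repeat split/init/train seeds derive.
#' @param fraction Training fraction for the subject split.
#' @param verbose Print per-run progress.
#' @return An `experiment_result`: list with `runs` (list of `run_result`)
#'   and `accuracy` (per-run percent accuracies, mean, sd).
#' @export
run_experiment <- function(stacks, manifest, spec, config = train_config(),
                           n_repeats = 10, base_seed = 1, fraction = 0.8,
                           verbose = FALSE) {
  stopifnot(length(unique(manifest$label)) == 2)
  runs <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    run_seed <- base_seed * 1000L + r
    plan <- subject_split(manifest, fraction, seed = run_seed)
    tr_ids <- plan$train_scans; te_ids <- plan$test_scans
    lab <- stats::setNames(manifest$label, manifest$scan_id)
    model <- build_network(spec, seed = run_seed + 1L)
    cfg <- config; cfg$seed <- run_seed + 2L
    model <- train_model(model, stacks[tr_ids], lab[tr_ids], cfg)
    probs <- t(vapply(te_ids, function(id) predict_stack(model, stacks[[id]]),
                      numeric(2)))
    pred <- c("AD", "NC")[max.col(probs)]
    cm <- confusion_matrix(pred, unname(lab[te_ids]))
    acc <- 100 * sum(diag(cm)) / sum(cm)
    runs[[r]] <- structure(
      list(run_index = r, seed = run_seed, plan = plan, model = model,
           test_scans = te_ids, probabilities = probs, predictions = pred,
           truths = unname(lab[te_ids]), confusion = cm, accuracy = acc),
      class = "run_result")
    if (verbose) message(sprintf("run %d/%d: accuracy %.1f%%",
                                 r, n_repeats, acc))
  }
  accs <- vapply(runs, `[[`, numeric(1), "accuracy")
  structure(list(runs = runs,
                 accuracy = list(per_run = accs, mean = mean(accs),
                                 sd = stats::sd(accs))),
            class = "experiment_result")
}

#' Accuracy table over map kinds
#'
#' Mirrors the per-map-kind accuracy table layout: one row per map kind with
#' the per-run accuracies and mean +/- sample sd.
#'
#' @param results Named list of `experiment_result`s (names = map kinds).
#' @return A data.frame with columns `map_kind`, `run_1..run_R`, `mean`, `sd`.
#' @export
accuracy_table <- function(results) {
  rows <- lapply(names(results), function(k) {
    accs <- results[[k]]$accuracy$per_run
    row <- as.data.frame(as.list(stats::setNames(accs,
                                                 paste0("run_", seq_along(accs)))))
    cbind(data.frame(map_kind = k), row,
          data.frame(mean = mean(accs), sd = stats::sd(accs)))
  })
  do.call(rbind, rows)
}

#' Heatmap report for misclassified test scans
#'
#' Lists each misclassified scan with its heatmap ROI-concentration next to
#' the class-average concentration, quantifying whether errors focused on
#' different regions than the class average.
#'
#' @param run A `run_result`.
#' @param heatmaps Named list (by scan_id) of full-resolution `heatmap`s for
#'   the run's test scans.
#' @param roi_mask,brain_mask Logical arrays at heatmap resolution.
#' @return A data.frame (possibly 0-row) with scan_id, truth, prediction,
#'   concentration and the true-class average concentration.
#' @export
misclassified_report <- function(run, heatmaps, roi_mask, brain_mask) {
  conc <- vapply(run$test_scans, function(id)
    roi_concentration(heatmaps[[id]], roi_mask, brain_mask)$concentration,
    numeric(1))
  class_avg <- vapply(c(AD = "AD", NC = "NC"), function(cl) {
    ids <- run$test_scans[run$truths == cl]
    if (!length(ids)) return(NA_real_)
    avg <- average_heatmaps(heatmaps[ids])
    roi_concentration(avg, roi_mask, brain_mask)$concentration
  }, numeric(1))
  bad <- which(run$predictions != run$truths)
  data.frame(scan_id = run$test_scans[bad],
             truth = run$truths[bad], prediction = run$predictions[bad],
             concentration = unname(conc[bad]),
             class_average_concentration = unname(class_avg[run$truths[bad]]),
             row.names = NULL, stringsAsFactors = FALSE)
}
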