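#' Configuration for an end-to-end pipeline run
#'
#' Exactly one of `simulation` / `input_data` must be supplied: either a
#' [sim_config()] describing a synthetic cohort (its seed drives every
#' random stage) or a list with `matrix_path` and `meta_path` pointing at a
#' dataset in the native delimited format.
#'
#' @param simulation a [sim_config()], or `NULL` when reading data.
#' @param input_data list with `matrix_path`, `meta_path`, or `NULL`.
#' @param exclusion,baseline_anchors,align_ref [regions()] for the
#'   preprocessing stages.
#' @param align_iters whole-spectrum alignment iterations.
#' @param align_intervals second-stage intervals as a [regions()] object,
#'   or `NULL` (default) for a whole-axis [regular_intervals()]
#'   segmentation with valley-snapped boundaries.
#' @param align_pretreatment pretreatment for interval lag estimation.
#' @param align_max_shift largest allowed rigid shift, grid points.
#' @param qc_rules outlier rules to apply, see [flag_outliers()].
#' @param scaling_method scaling ahead of OPLS-DA.
#' @param max_orth largest orthogonal-component count tried in CV.
#' @param n_folds CV folds.
#' @param n_permutations permutation-test iterations.
#' @param test_fraction fraction of subjects per class held out as the
#'   external test set.
#' @param selection_quantile,selection_tolerance marker-report settings,
#'   see [map_regions_to_metabolites()].
#' @param seed seed for fold shuffling, subject split and permutations.
#' @param output_dir directory for artifacts, or `NULL` to skip writing.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(simulation = sim_config(
                              n_subjects_per_class = c(25, 20)),
                            input_data = NULL,
                            exclusion = default_exclusion_regions(),
                            baseline_anchors = default_baseline_anchors(),
                            align_ref = default_alignment_reference(),
                            align_iters = 4,
                            align_intervals = NULL,
                            align_pretreatment = "none",
                            align_max_shift = 50,
                            qc_rules = c("moments", "pca", "snr"),
                            scaling_method = "class_centroid",
                            max_orth = 3, n_folds = 7,
                            n_permutations = 200, test_fraction = 0.3,
                            selection_quantile = 0.98,
                            selection_tolerance = 0.02,
                            seed = 1L, output_dir = NULL) {
  if (is.null(simulation) == is.null(input_data))
    stop("exactly one of simulation / input_data must be supplied")
  if (!is.null(simulation) && is.null(simulation$seed))
    stop("a seed is mandatory when simulating")
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full fingerprinting pipeline
#'
#' Executes simulate/read, region exclusion, baseline correction,
#' whole-spectrum then interval alignment, probabilistic quotient
#' normalisation, outlier screening, a subject-level train/test split,
#' replicate-preserving 7-fold CV for orthogonal-component selection, the
#' final OPLS-DA fit, Bayesian thresholds, the external-test confusion
#' matrix, a subject-level permutation test and selectivity-ratio marker
#' selection with library annotation. Every artifact can be written to
#' `output_dir` together with a manifest of parameters and seeds.
#'
#' @param config a [pipeline_config()].
#' @return a `pipeline_report` list: preprocessed dataset, QC report, fit
#'   metrics, threshold model, confusion matrix, permutation result,
#'   marker report and the final model.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$simulation)) {
    if (any(config$simulation$n_subjects_per_class < 1L))
      stop("validation error: zero subjects in a class")
    ds <- simulate_cohort(load_default_library(), config$simulation)
  } else {
    ds <- read_spectra(config$input_data$matrix_path,
                       config$input_data$meta_path)
  }
  lib <- load_default_library()

  ds <- exclude_regions(ds, config$exclusion)
  bc <- baseline_correct(ds, config$baseline_anchors)
  ds <- bc$dataset
  ga <- global_align(ds, config$align_ref, n_iter = config$align_iters,
                     max_shift = config$align_max_shift)
  ds <- ga$dataset
  intervals <- if (is.null(config$align_intervals))
    regular_intervals(ds) else config$align_intervals
  ia <- interval_align(ds, intervals,
                       pretreatment = config$align_pretreatment,
                       max_shift = config$align_max_shift)
  ds <- ia$dataset
  pq <- pqn_normalize(ds)
  ds <- pq$dataset

  qc <- flag_outliers(ds, rules = config$qc_rules)
  ds <- remove_flagged(ds, qc)

  split <- subject_split(ds$samples, config$test_fraction,
                         seed = config$seed + 1L)
  train <- subset_samples(ds, split$train)
  test <- subset_samples(ds, split$test)

  plan <- make_cv_plan(train$samples, n_folds = config$n_folds,
                       seed = config$seed)
  metrics <- cross_validate(train, plan,
                            scaling_method = config$scaling_method,
                            max_orth = config$max_orth)
  k <- metrics$chosen_components
  thr <- bayesian_thresholds(metrics$cv_predictions[, as.character(k)],
                             train$samples$class_label)

  cod <- class_coding(train$samples$class_label)
  scal <- fit_scaling(train$intensities, config$scaling_method,
                      labels = train$samples$class_label)
  Xs <- apply_scaling(scal, train$intensities)
  model <- opls_fit(Xs, cod$y, k)
  y_test <- opls_predict(model, apply_scaling(scal, test$intensities))
  confusion <- classify_and_score(y_test, thr, test$samples$class_label)

  perm <- permutation_test(train, plan,
                           scaling_method = config$scaling_method,
                           n_orth = k, n_iter = config$n_permutations,
                           seed = config$seed + 2L)

  sr <- selectivity_ratio(model, Xs)
  bsl <- backscale_loadings(model, scal, Xs)
  ppm_kept <- train$ppm[scal$keep]
  markers <- map_regions_to_metabolites(
    sr, ppm_kept, lib, quantile = config$selection_quantile,
    tolerance = config$selection_tolerance, loading = bsl$backscaled)

  report <- structure(list(dataset = ds, qc = qc, split = split,
                           cv_plan = plan, metrics = metrics,
                           thresholds = thr, confusion = confusion,
                           permutation = perm, model = model,
                           scaling = scal, selectivity = sr,
                           backscaled = bsl, markers = markers,
                           config = config),
                      class = "pipeline_report")
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  %d spectra after QC (%d subject(s) flagged)\n",
              n_samples(x$dataset), length(x$qc$flagged_subjects)))
  cat(sprintf("  chosen orthogonal components: %d (RMSECV %.4f)\n",
              x$metrics$chosen_components,
              min(x$metrics$rmsecv)))
  cat(sprintf("  thresholds: %s\n",
              paste(sprintf("%s %.4f", names(x$thresholds$threshold),
                            x$thresholds$threshold), collapse = ", ")))
  cat(sprintf("  test-set accuracy: %.4f; permutation p: %.4g\n",
              x$confusion$accuracy, x$permutation$p))
  cat(sprintf("  marker regions: %d\n", nrow(x$markers$regions)))
  invisible(x)
}

# stratified subject-level split into train/test subject id sets
subject_split <- function(samples, test_fraction, seed) {
  subj <- unique(samples$subject_id)
  cls <- samples$class_label[match(subj, samples$subject_id)]
  test <- with_seed(seed, unlist(lapply(unique(cls), function(cl) {
    s <- subj[cls == cl]
    sample(s, max(1L, round(length(s) * test_fraction)))
  })))
  list(train = setdiff(subj, test), test = test)
}

subset_samples <- function(ds, subjects) {
  keep <- ds$samples$subject_id %in% subjects
  ds$intensities <- ds$intensities[keep, , drop = FALSE]
  ds$samples <- ds$samples[keep, , drop = FALSE]
  rownames(ds$samples) <- NULL
  if (!is.null(ds$truth)) {
    ds$truth$dilution <- ds$truth$dilution[keep]
    ds$truth$shift_jitter <- ds$truth$shift_jitter[keep, , drop = FALSE]
  }
  ds
}

write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_spectra(report$dataset, file.path(dir, "preprocessed_matrix.tsv"),
                file.path(dir, "preprocessed_meta.tsv"))
  utils::write.table(
    data.frame(components = names(report$metrics$rmsecv),
               rmsec = report$metrics$rmsec,
               rmsecv = report$metrics$rmsecv),
    file.path(dir, "fit_metrics.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  utils::write.table(as.data.frame.matrix(report$confusion$counts),
                     file.path(dir, "confusion.tsv"), sep = "\t",
                     quote = FALSE)
  utils::write.table(report$markers$regions,
                     file.path(dir, "markers.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  cfg <- report$config
  manifest <- c(
    sprintf("seed: %d", cfg$seed),
    sprintf("scaling_method: %s", cfg$scaling_method),
    sprintf("n_folds: %d", cfg$n_folds),
    sprintf("chosen_components: %d", report$metrics$chosen_components),
    sprintf("thresholds: %s",
            paste(sprintf("%s=%.6f", names(report$thresholds$threshold),
                          report$thresholds$threshold), collapse = " ")),
    sprintf("accuracy: %.6f", report$confusion$accuracy),
    sprintf("permutation_p: %.6g", report$permutation$p),
    sprintf("flagged_subjects: %s",
            paste(report$qc$flagged_subjects, collapse = " ")))
  writeLines(manifest, file.path(dir, "manifest.txt"))
  invisible(report)
}
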