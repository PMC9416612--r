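#' Construct a spectra dataset
#'
#' The container every pipeline stage transforms: a strictly monotone ppm
#' axis, an `n x P` intensity matrix and a per-sample metadata table
#' carrying subject, replicate and class assignments. The axis is stored
#' ascending; display functions present it descending, following NMR
#' convention.
#'
#' @param ppm numeric vector of chemical shifts (ppm), strictly monotone.
#' @param intensities numeric matrix, one row per sample, `length(ppm)`
#'   columns.
#' @param samples data frame with columns `sample_id`, `subject_id`,
#'   `replicate_index`, `class_label`.
#' @param processing_log list of applied-step records (append-only).
#' @param truth optional record of simulation ground truth.
#' @return an object of class `spectra_dataset`.
#' @export
spectra_dataset <- function(ppm, intensities, samples,
                            processing_log = list(), truth = NULL) {
  ppm <- as.numeric(ppm)
  if (length(ppm) < 2L) stop("ppm axis needs at least two points")
  d <- diff(ppm)
  if (all(d < 0)) { # accept a descending axis, store ascending
    ppm <- rev(ppm)
    intensities <- intensities[, rev(seq_along(ppm)), drop = FALSE]
    d <- diff(ppm)
  }
  if (any(d <= 0)) stop("ppm axis must be strictly monotone")
  intensities <- as.matrix(intensities)
  if (ncol(intensities) != length(ppm))
    stop("intensity matrix must have one column per ppm point")
  required <- c("sample_id", "subject_id", "replicate_index", "class_label")
  if (!all(required %in% names(samples)))
    stop("samples table must have columns: ", paste(required, collapse = ", "))
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (nrow(samples) != nrow(intensities))
    stop("samples table and intensity matrix disagree on sample count")
  if (anyDuplicated(samples$sample_id)) stop("sample_id values must be unique")
  cls <- tapply(samples$class_label, samples$subject_id,
                function(z) length(unique(z)))
  if (any(cls > 1L))
    stop("every subject must have one class_label across its replicates")
  rownames(intensities) <- samples$sample_id
  structure(list(ppm = ppm, intensities = intensities, samples = samples,
                 processing_log = processing_log, truth = truth),
            class = "spectra_dataset")
}

#' @export
print.spectra_dataset <- function(x, ...) {
  cat("<spectra_dataset> ", nrow(x$intensities), " spectra x ",
      length(x$ppm), " points, ", sprintf("%.2f", max(x$ppm)), " to ",
      sprintf("%.2f", min(x$ppm)), " ppm\n", sep = "")
  cat("  classes: ",
      paste(sprintf("%s (%d)", names(table(x$samples$class_label)),
                    table(x$samples$class_label)), collapse = ", "), "\n",
      sep = "")
  if (length(x$processing_log))
    cat("  processing: ",
        paste(vapply(x$processing_log, `[[`, "", "step"), collapse = " -> "),
        "\n", sep = "")
  invisible(x)
}

#' Number of spectra / variables in a dataset
#' @param ds a [spectra_dataset()].
#' @return integer count.
#' @export
n_samples <- function(ds) nrow(ds$intensities)

#' @rdname n_samples
#' @export
n_variables <- function(ds) length(ds$ppm)

# Append one record to the processing log (append-only bookkeeping).
log_step <- function(ds, step, params = list()) {
  ds$processing_log <- c(ds$processing_log,
                         list(list(step = step, params = params)))
  ds
}

#' Write / read a dataset in the native delimited format
#'
#' The native on-disk pair is a tab-delimited matrix file whose first row is
#' the ppm axis (descending, the display convention) followed by one row of
#' intensities per sample, and a metadata table with columns `sample_id`,
#' `subject_id`, `replicate_index`, `class_label`. The processing log and
#' simulation truth are not persisted.
#'
#' @param ds a [spectra_dataset()].
#' @param matrix_path path of the intensity matrix file.
#' @param meta_path path of the sample metadata file.
#' @return `write_spectra` returns `ds` invisibly; `read_spectra` returns a
#'   [spectra_dataset()].
#' @export
write_spectra <- function(ds, matrix_path, meta_path) {
  ord <- rev(seq_along(ds$ppm)) # present descending
  m <- rbind(ds$ppm[ord], ds$intensities[, ord, drop = FALSE])
  utils::write.table(m, matrix_path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(ds$samples, meta_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(ds)
}

#' @rdname write_spectra
#' @export
read_spectra <- function(matrix_path, meta_path) {
  m <- as.matrix(utils::read.table(matrix_path, sep = "\t", header = FALSE))
  samples <- utils::read.table(meta_path, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
  spectra_dataset(ppm = m[1L, ], intensities = m[-1L, , drop = FALSE],
                  samples = samples)
}
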