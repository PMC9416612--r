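#' Default exclusion windows
#'
#' The residual-water zone 4.35-5.0 ppm plus the signal-free ends of the
#' spectrum (below 0.17 ppm and above 8 ppm).
#' @return a [regions()] object.
#' @export
default_exclusion_regions <- function()
  regions(c(4.35, 5.0), c(-Inf, 0.17), c(8.0, Inf))

#' Default baseline anchor windows (peak-free for the shipped library)
#' @return a [regions()] object.
#' @export
default_baseline_anchors <- function()
  regions(c(0.2, 0.4), c(6.6, 6.8), c(9.5, 10.0))

#' Default alignment reference windows
#'
#' The zone around the alpha-D-glucopyranose anomeric doublet at 5.23 ppm,
#' immediately right of the broad lipid olefinic resonance at 5.27 ppm.
#' @return a [regions()] object.
#' @export
default_alignment_reference <- function()
  regions(c(5.12, 5.19), c(5.20, 5.35))

#' Remove spectral regions from a dataset
#'
#' Drops every column whose ppm value falls inside any of the (closed)
#' intervals.
#'
#' @param ds a [spectra_dataset()].
#' @param rs a [regions()] object; defaults to
#'   [default_exclusion_regions()].
#' @return the trimmed [spectra_dataset()].
#' @export
exclude_regions <- function(ds, rs = default_exclusion_regions()) {
  drop <- ppm_in_regions(ds$ppm, rs)
  if (all(drop)) stop("exclusion regions would remove every variable")
  if (!any(drop)) return(log_step(ds, "exclude_regions", list(removed = 0L)))
  ds$ppm <- ds$ppm[!drop]
  ds$intensities <- ds$intensities[, !drop, drop = FALSE]
  log_step(ds, "exclude_regions", list(removed = sum(drop)))
}

#' First-order baseline correction
#'
#' Fits, per sample, a least-squares straight line to the intensities over
#' peak-free anchor regions and subtracts it from the whole spectrum.
#'
#' @param ds a [spectra_dataset()].
#' @param anchors a [regions()] of peak-free windows; defaults to
#'   [default_baseline_anchors()].
#' @return list with the corrected `dataset` and a `baseline` model
#'   (per-sample slope and intercept).
#' @export
baseline_correct <- function(ds, anchors = default_baseline_anchors()) {
  idx <- which(ppm_in_regions(ds$ppm, anchors))
  if (length(idx) < 3L) stop("anchor regions must contain at least 3 points")
  x <- ds$ppm[idx]
  if (length(unique(x)) < 2L) stop("degenerate anchor set")
  # closed-form simple linear regression, vectorised over samples
  mx <- mean(x); dx <- x - mx; sxx <- sum(dx^2)
  Y <- ds$intensities[, idx, drop = FALSE]
  my <- rowMeans(Y)
  slope <- as.numeric(Y %*% dx) / sxx
  intercept <- my - slope * mx
  ds$intensities <- ds$intensities -
    outer(slope, ds$ppm) - matrix(intercept, nrow = length(intercept),
                                  ncol = length(ds$ppm))
  model <- list(slope = stats::setNames(slope, ds$samples$sample_id),
                intercept = stats::setNames(intercept, ds$samples$sample_id),
                anchor_regions = anchors)
  class(model) <- "baseline_model"
  list(dataset = log_step(ds, "baseline_correct",
                          list(n_anchor_points = length(idx))),
       baseline = model)
}

#' Per-vector pretreatment for alignment
#'
#' `snv` standard normal variate: subtract the mean and divide by the
#' standard deviation. `derivative`: first-order derivative by central
#' differences with one-sided endpoints (unit spacing). `none`: identity.
#' Used to estimate alignment lags; intensities themselves are shifted
#' un-pretreated.
#'
#' @param x numeric vector.
#' @param mode one of `"none"`, `"snv"`, `"derivative"`.
#' @return transformed vector of the same length.
#' @export
pretreat_vector <- function(x, mode = c("none", "snv", "derivative")) {
  mode <- match.arg(mode)
  switch(mode,
    none = x,
    snv = {
      s <- stats::sd(x)
      if (!is.finite(s) || s == 0) stop("snv undefined for a constant vector")
      (x - mean(x)) / s
    },
    derivative = {
      n <- length(x)
      if (n < 3L) stop("derivative needs at least 3 points")
      c(x[2L] - x[1L],
        (x[3:n] - x[1:(n - 2L)]) / 2,
        x[n] - x[n - 1L])
    })
}

#' Whole-spectrum alignment against reference signals
#'
#' Iteratively shifts each spectrum rigidly by the integer lag maximising
#' its cross-correlation with a target spectrum restricted to the reference
#' regions. The target is recomputed each iteration from the current data
#' set (median or mean spectrum). Vacated edge points repeat the edge
#' value. Defaults: the two windows around the anomeric glucose doublet at
#' 5.23 ppm and 4 iterations.
#'
#' @param ds a [spectra_dataset()].
#' @param ref_regions [regions()] the correlation is evaluated over.
#' @param n_iter number of refinement iterations.
#' @param max_shift largest allowed |lag| in grid points.
#' @param target `"median"` or `"mean"` spectrum of the current data set.
#' @return list with the aligned `dataset` and an `alignment` record with
#'   cumulative per-sample shifts and iterations run.
#' @export
global_align <- function(ds, ref_regions = default_alignment_reference(),
                         n_iter = 4, max_shift = 50,
                         target = c("median", "mean")) {
  target <- match.arg(target)
  if (nrow(ref_regions) == 0L) stop("ref_regions must be non-empty")
  cols <- which(ppm_in_regions(ds$ppm, ref_regions))
  if (length(cols) == 0L) stop("no grid points inside ref_regions")
  if (max_shift >= length(cols))
    stop("max_shift must be smaller than the reference region width")
  X <- ds$intensities
  total <- integer(nrow(X))
  for (it in seq_len(n_iter)) {
    tgt <- if (target == "median") apply(X, 2L, stats::median) else colMeans(X)
    lag <- vapply(seq_len(nrow(X)),
                  function(i) best_lag(X[i, ], tgt, cols, max_shift),
                  integer(1))
    if (all(lag == 0L)) break
    for (i in which(lag != 0L)) X[i, ] <- shift_vector(X[i, ], lag[i])
    total <- total + lag
  }
  ds$intensities <- X
  res <- list(global_shifts = stats::setNames(total, ds$samples$sample_id),
              interval_shifts = NULL,
              target_spec = paste0(target, " spectrum of current data set"),
              iterations_run = it)
  class(res) <- "alignment_result"
  list(dataset = log_step(ds, "global_align",
                          list(n_iter = n_iter, max_shift = max_shift)),
       alignment = res)
}

#' Regular interval segmentation of a ppm axis
#'
#' Splits the dataset's axis into `n_intervals` contiguous runs of grid
#' points for use with [interval_align()] — the whole-axis segmentation
#' mode of interval-correlation alignment. By default every interior
#' boundary is snapped to the nearest local minimum of the median spectrum
#' (within a third of an interval width), so that boundaries fall between
#' peaks rather than through them — splitting a multiplet across two
#' independently shifted intervals would tear it apart.
#'
#' @param ds a [spectra_dataset()].
#' @param n_intervals number of intervals.
#' @param snap_to_minima move interior boundaries to valleys of the median
#'   spectrum.
#' @return a [regions()] object with disjoint intervals covering the axis.
#' @export
regular_intervals <- function(ds, n_intervals = 64, snap_to_minima = TRUE) {
  P <- length(ds$ppm)
  if (n_intervals < 1L || n_intervals > P)
    stop("n_intervals must be between 1 and the number of grid points")
  bounds <- floor(seq(0L, P, length.out = n_intervals + 1L))
  if (snap_to_minima && n_intervals > 1L) {
    med <- apply(ds$intensities, 2L, stats::median)
    w <- max(1L, floor(P / n_intervals / 3))
    for (k in seq(2L, n_intervals)) {
      lo <- max(bounds[k - 1L] + 1L, bounds[k] - w)
      hi <- min(bounds[k + 1L] - 1L, bounds[k] + w)
      if (lo < hi)
        bounds[k] <- lo + which.min(med[lo:hi]) - 1L
    }
  }
  iv <- lapply(seq_len(n_intervals), function(k)
    c(ds$ppm[bounds[k] + 1L], ds$ppm[bounds[k + 1L]]))
  do.call(regions, iv)
}

#' Interval-wise alignment of selected spectral areas
#'
#' Each interval is aligned independently with the same correlation
#' criterion as [global_align()]. Lags are estimated on pretreated interval
#' segments (SNV or first derivative, interchangeably) while the
#' intensities themselves are shifted un-pretreated; edge fill stays inside
#' the interval. Default intervals cover the zones that resist
#' whole-spectrum alignment, 1.16-1.22 and 3.62-3.69 ppm.
#'
#' @param ds a [spectra_dataset()].
#' @param intervals disjoint [regions()] to align separately.
#' @param pretreatment passed to [pretreat_vector()] for lag estimation.
#' @param max_shift largest allowed |lag| in grid points.
#' @param target `"median"` or `"mean"` segment of the current data set.
#' @return list with the aligned `dataset` and an `alignment` record with
#'   per-interval per-sample shifts.
#' @export
interval_align <- function(ds,
                           intervals = regions(c(1.16, 1.22), c(3.62, 3.69)),
                           pretreatment = c("none", "snv", "derivative"),
                           max_shift = 50, target = c("median", "mean")) {
  pretreatment <- match.arg(pretreatment)
  target <- match.arg(target)
  if (nrow(intervals) == 0L)
    return(list(dataset = log_step(ds, "interval_align", list(intervals = 0L)),
                alignment = structure(list(global_shifts = NULL,
                                           interval_shifts = list(),
                                           target_spec = target,
                                           iterations_run = 0L),
                                      class = "alignment_result")))
  ov <- intervals[order(intervals[, 1L]), , drop = FALSE]
  if (nrow(ov) > 1L && any(ov[-1L, 1L] <= ov[-nrow(ov), 2L]))
    stop("intervals must be disjoint")
  X <- ds$intensities
  shifts <- list()
  for (k in seq_len(nrow(intervals))) {
    cols <- which(ppm_in_regions(ds$ppm, intervals[k, , drop = FALSE]))
    if (length(cols) == 0L) next
    seg <- X[, cols, drop = FALSE]
    ms <- min(max_shift, length(cols) - 1L)
    pre <- t(apply(seg, 1L, pretreat_vector, mode = pretreatment))
    tgt <- if (target == "median") apply(pre, 2L, stats::median)
           else colMeans(pre)
    all_cols <- seq_len(ncol(pre))
    lag <- vapply(seq_len(nrow(pre)),
                  function(i) best_lag(pre[i, ], tgt, all_cols, ms),
                  integer(1))
    for (i in which(lag != 0L)) seg[i, ] <- shift_vector(seg[i, ], lag[i])
    X[, cols] <- seg
    shifts[[sprintf("%.4g_%.4g", intervals[k, 1L], intervals[k, 2L])]] <-
      stats::setNames(lag, ds$samples$sample_id)
  }
  ds$intensities <- X
  res <- list(global_shifts = NULL, interval_shifts = shifts,
              target_spec = paste0(target, " segment of current data set"),
              iterations_run = 1L)
  class(res) <- "alignment_result"
  list(dataset = log_step(ds, "interval_align",
                          list(intervals = nrow(intervals),
                               pretreatment = pretreatment)),
       alignment = res)
}

#' Probabilistic quotient normalisation
#'
#' Estimates a per-sample dilution factor and divides it out. Each spectrum
#' is first reduced to unit total area; the reference is the column-median
#' of the unit-area spectra (over all samples or over the `Control` class
#' only); the per-sample quotient is the median of the variable-wise ratios
#' sample/reference. The output is rescaled so its median total area equals
#' that of the input, which makes the operation an exact fixed point
#' (applying it twice changes nothing) and makes the stored divisor equal
#' the true relative dilution when one spectrum is a scaled copy of
#' another.
#'
#' @param ds a [spectra_dataset()].
#' @param reference `"median_all"` or `"median_control"`.
#' @return list with the normalised `dataset` and a `normalization` record
#'   whose `quotients` are the per-sample dilution estimates.
#' @export
pqn_normalize <- function(ds, reference = c("median_all", "median_control")) {
  reference <- match.arg(reference)
  X <- ds$intensities
  if (nrow(X) < 2L) stop("PQN needs at least 2 samples")
  area <- rowSums(X)
  if (any(area <= 0)) stop("non-positive spectrum area")
  U <- X / area
  ref_rows <- if (reference == "median_control")
    which(ds$samples$class_label == "Control") else seq_len(nrow(X))
  if (length(ref_rows) == 0L) stop("no samples available for the reference")
  refspec <- apply(U[ref_rows, , drop = FALSE], 2L, stats::median)
  use <- refspec > 0
  if (!any(use)) stop("reference spectrum has no positive variables")
  q <- apply(U[, use, drop = FALSE] /
               rep(refspec[use], each = nrow(U)), 1L, stats::median)
  if (any(q <= 0)) stop("non-positive median quotient")
  A <- stats::median(area)
  k <- A / stats::median(1 / q)
  ds$intensities <- (k * U) / q
  dil <- area * q / k # the factor each raw spectrum was divided by
  res <- list(quotients = stats::setNames(dil, ds$samples$sample_id),
              reference = reference)
  class(res) <- "normalization_result"
  list(dataset = log_step(ds, "pqn_normalize", list(reference = reference)),
       normalization = res)
}
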