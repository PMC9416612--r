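#' Column-wise skewness and kurtosis
#'
#' Sample skewness g1 and kurtosis in the non-excess convention (a normal
#' column sits near 3). Zero-variance columns are recorded as `NA` rather
#' than raising an error.
#'
#' @param ds a [spectra_dataset()] with at least 4 samples.
#' @return a `moment_profile`: list with numeric vectors `skewness` and
#'   `kurtosis`, one value per variable.
#' @export
column_moments <- function(ds) {
  X <- ds$intensities
  n <- nrow(X)
  if (n < 4L) stop("moments need at least 4 samples")
  mu <- colMeans(X)
  D <- X - rep(mu, each = n)
  m2 <- colSums(D^2) / n
  m3 <- colSums(D^3) / n
  m4 <- colSums(D^4) / n
  zero <- m2 <= 0
  g1 <- ifelse(zero, NA_real_, m3 / m2^1.5)
  b2 <- ifelse(zero, NA_real_, m4 / m2^2)
  structure(list(skewness = g1, kurtosis = b2, ppm = ds$ppm),
            class = "moment_profile")
}

#' Flag outlier samples before modelling
#'
#' Three independent screening rules, with flags always propagated from a
#' sample to all replicates of its subject:
#'
#' * moment-zone rule: in columns whose kurtosis is both above the
#'   empirical `kurtosis_quantile` and above `kurtosis_floor`, a sample is
#'   flagged when its intensity exceeds the column mean by more than
#'   `moment_zone_sd` standard deviations in at least `zone_min_columns`
#'   of those columns — genuine artifacts (failed water suppression,
#'   spurious resonances) span a region, while single-column excursions
#'   are ordinary heavy-tailed peak-flank behaviour;
#' * PCA rule: Hotelling T-squared (F approximation) or Q residual
#'   (weighted chi-square approximation) beyond the `limit_quantile`
#'   control limit of a mean-centered PCA;
#' * SNR rule: median intensity over the peak region divided by the noise
#'   standard deviation (estimated in `noise_region`) below `snr_floor`,
#'   catching heavily diluted spectra.
#'
#' @param ds a preprocessed [spectra_dataset()].
#' @param moment_zone_sd multiplier for the moment-zone rule (default 4).
#' @param kurtosis_quantile,kurtosis_floor define the high-kurtosis zone.
#' @param zone_min_columns offending zone columns required to flag a
#'   sample; `NULL` means 10 percent of the zone (at least 3 columns).
#' @param pca_components components of the screening PCA; `NULL` picks the
#'   smallest number capturing 90 percent of variance (at most 10).
#' @param limit_quantile confidence level of the T-squared and Q limits
#'   (0.99: automated removal warrants a tighter limit than exploratory
#'   inspection).
#' @param snr_floor minimum acceptable signal-to-noise ratio.
#' @param noise_region [regions()] treated as signal-free for the noise
#'   estimate.
#' @param rules subset of `c("moments", "pca", "snr")` to apply.
#' @return an `outlier_report`: flagged subjects, per-sample reason sets and
#'   the thresholds used.
#' @export
flag_outliers <- function(ds, moment_zone_sd = 4, kurtosis_quantile = 0.99,
                          kurtosis_floor = 5, zone_min_columns = NULL,
                          pca_components = NULL,
                          limit_quantile = 0.99, snr_floor = 5,
                          noise_region = regions(c(9.5, 10.0)),
                          rules = c("moments", "pca", "snr")) {
  X <- ds$intensities
  n <- nrow(X)
  reasons <- stats::setNames(vector("list", n), ds$samples$sample_id)

  if ("moments" %in% rules && n >= 4L) {
    mp <- column_moments(ds)
    kq <- stats::quantile(mp$kurtosis, kurtosis_quantile, na.rm = TRUE)
    zone <- which(!is.na(mp$kurtosis) & mp$kurtosis >= kq &
                    mp$kurtosis > kurtosis_floor)
    if (length(zone)) {
      if (is.null(zone_min_columns))
        zone_min_columns <- max(3L, ceiling(0.10 * length(zone)))
      Z <- X[, zone, drop = FALSE]
      mu <- colMeans(Z); sdv <- col_sds(Z)
      hit <- Z > rep(mu + moment_zone_sd * sdv, each = n)
      for (i in which(rowSums(hit) >= zone_min_columns))
        reasons[[i]] <- c(reasons[[i]], "moment_zone_contribution")
    }
  }

  if ("pca" %in% rules && n >= 4L) {
    Xc <- scale(X, center = TRUE, scale = FALSE)
    sv <- svd(Xc)
    ev <- sv$d^2 / (n - 1L)
    pos <- ev > max(ev) * 1e-12
    if (is.null(pca_components)) {
      cum <- cumsum(ev[pos]) / sum(ev[pos])
      pca_components <- min(which(cum >= 0.90), 10L, sum(pos))
    }
    k <- min(pca_components, sum(pos), n - 1L)
    Tsc <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
    t2 <- rowSums(Tsc^2 / rep(ev[seq_len(k)], each = n))
    t2_lim <- k * (n - 1) * (n + 1) / (n * (n - k)) *
      stats::qf(limit_quantile, k, n - k)
    E <- Xc - Tsc %*% t(sv$v[, seq_len(k), drop = FALSE])
    qres <- rowSums(E^2)
    rest <- ev[pos][-seq_len(min(k, sum(pos)))]
    if (length(rest)) { # Box weighted chi-square approximation
      th1 <- sum(rest); th2 <- sum(rest^2)
      g <- th2 / th1; h <- th1^2 / th2
      q_lim <- g * stats::qchisq(limit_quantile, df = h)
    } else q_lim <- Inf
    for (i in which(t2 > t2_lim)) reasons[[i]] <- c(reasons[[i]], "pca_T2")
    for (i in which(qres > q_lim)) reasons[[i]] <- c(reasons[[i]], "pca_Q")
  } else {
    t2_lim <- q_lim <- NA_real_
  }

  if ("snr" %in% rules) {
    noise_cols <- which(ppm_in_regions(ds$ppm, noise_region))
    if (length(noise_cols) >= 3L) {
      ref <- apply(X, 2L, stats::median)
      peak_cols <- which(ref >= stats::quantile(ref, 0.75))
      noise_sd <- apply(X[, noise_cols, drop = FALSE], 1L, stats::sd)
      signal <- apply(X[, peak_cols, drop = FALSE], 1L, stats::median)
      snr <- signal / noise_sd
      for (i in which(is.finite(snr) & snr < snr_floor))
        reasons[[i]] <- c(reasons[[i]], "low_snr")
    }
  }

  flagged_samples <- names(reasons)[lengths(reasons) > 0]
  flagged_subjects <- unique(
    ds$samples$subject_id[ds$samples$sample_id %in% flagged_samples])
  # subject-level atomicity: a flagged subject drags all its replicates
  for (i in which(ds$samples$subject_id %in% flagged_subjects))
    if (length(reasons[[i]]) == 0L) reasons[[i]] <- "replicate_of_flagged"
  structure(list(flagged_subjects = flagged_subjects,
                 reasons = reasons,
                 thresholds = list(moment_zone_sd = moment_zone_sd,
                                   zone_min_columns = zone_min_columns,
                                   kurtosis_quantile = kurtosis_quantile,
                                   kurtosis_floor = kurtosis_floor,
                                   limit_quantile = limit_quantile,
                                   t2_limit = t2_lim, q_limit = q_lim,
                                   snr_floor = snr_floor)),
            class = "outlier_report")
}

#' Drop flagged subjects from a dataset
#'
#' @param ds a [spectra_dataset()].
#' @param report an `outlier_report` from [flag_outliers()].
#' @return the reduced [spectra_dataset()].
#' @export
remove_flagged <- function(ds, report) {
  keep <- !ds$samples$subject_id %in% report$flagged_subjects
  if (all(keep)) return(log_step(ds, "remove_flagged", list(removed = 0L)))
  ds$intensities <- ds$intensities[keep, , drop = FALSE]
  ds$samples <- ds$samples[keep, , drop = FALSE]
  rownames(ds$samples) <- NULL
  if (!is.null(ds$truth)) {
    ds$truth$dilution <- ds$truth$dilution[keep]
    ds$truth$shift_jitter <- ds$truth$shift_jitter[keep, , drop = FALSE]
  }
  log_step(ds, "remove_flagged",
           list(removed = sum(!keep),
                subjects = report$flagged_subjects))
}
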