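#' Variable importance in projection
#'
#' Standard VIP over the predictive component(s):
#' `vip_i = sqrt(P * sum_a(w_ia^2 SSY_a) / sum_a(SSY_a))`, so that the mean
#' of `vip^2` is one. For the single-predictive-component OPLS-DA model the
#' formula collapses to `sqrt(P) |w_i|`.
#'
#' @param model an `opls_model`, or a list with a weight matrix `W`
#'   (P x A, columns unit norm) and `ssy` (explained Y sum of squares per
#'   component).
#' @return a `vip_profile`: numeric vector `vip` of length P.
#' @export
vip <- function(model) {
  if (inherits(model, "opls_model")) {
    W <- matrix(model$w, ncol = 1L)
    ssy <- model$q^2 * sum(model$t^2)
  } else {
    W <- as.matrix(model$W)
    ssy <- model$ssy
  }
  if (sum(ssy) <= 0) stop("zero total explained Y-variance")
  P <- nrow(W)
  v <- sqrt(P * as.numeric(W^2 %*% ssy) / sum(ssy))
  structure(list(vip = v), class = "vip_profile")
}

#' Selectivity ratio under the target projection
#'
#' Projects the scaled data on the normalised regression vector
#' (`t_TP = Xs b / |b|`), regresses every variable on that target score
#' (`p_TP = Xs' t_TP / (t_TP' t_TP)`) and reports, per variable, the ratio
#' of explained to residual variance. For centred data this equals
#' `r^2 / (1 - r^2)` with `r` the correlation between the variable and the
#' target score.
#'
#' @param model an `opls_model` fitted on `Xs`.
#' @param Xs the scaled training matrix.
#' @return a `selectivity_ratio_profile`: `sr` per variable and the
#'   `target_scores`.
#' @export
selectivity_ratio <- function(model, Xs) {
  Xs <- as.matrix(Xs)
  b <- model$b
  nb <- sqrt(sum(b^2))
  if (nb == 0) stop("zero regression vector")
  t_tp <- as.numeric(Xs %*% b) / nb
  p_tp <- as.numeric(crossprod(Xs, t_tp)) / sum(t_tp^2)
  expl <- p_tp^2 * sum(t_tp^2)
  resid <- colSums(Xs^2) - expl
  sr <- ifelse(resid > 1e-12 * max(colSums(Xs^2)), expl / resid,
               ifelse(expl > 0, Inf, 0))
  structure(list(sr = sr, target_scores = t_tp),
            class = "selectivity_ratio_profile")
}

#' Map high-ranking spectral regions to library metabolites
#'
#' Variables strictly above the profile's `quantile` threshold are merged
#' into contiguous regions (gaps of up to `gap` grid points allowed) and
#' each region is annotated with every library multiplet whose chemical
#' shift lies within the region extended by `tolerance`. When a back-scaled
#' loading is supplied, the sign of its region mean gives the direction of
#' class association (positive = associated with the positive class).
#'
#' @param profile a `selectivity_ratio_profile` or `vip_profile` aligned to
#'   `ppm`.
#' @param ppm the dataset's ppm axis.
#' @param library a [metabolite_library()].
#' @param quantile fraction of variables below the selection threshold.
#' @param tolerance ppm slack when matching library shifts to regions.
#' @param gap largest in-region gap, grid points.
#' @param loading optional back-scaled loading vector for direction calls.
#' @return a `marker_report`: data frame of regions (bounds in ppm,
#'   descending order, peak statistic, direction) and a list of matched
#'   metabolites per region.
#' @export
map_regions_to_metabolites <- function(profile, ppm, library,
                                       quantile = 0.98, tolerance = 0.02,
                                       gap = 3, loading = NULL) {
  stat <- if (!is.null(profile$sr)) profile$sr else profile$vip
  if (length(stat) != length(ppm)) stop("profile not aligned to the axis")
  thr <- stats::quantile(stat[is.finite(stat)], quantile)
  sel <- which(is.finite(stat) & stat > thr)
  if (length(sel) == 0L)
    stop("empty selection at quantile ", quantile)
  # merge runs separated by <= gap points
  brk <- c(0L, which(diff(sel) > gap + 1L), length(sel))
  out <- data.frame()
  matches <- list()
  ent <- library$entries
  for (g in seq_len(length(brk) - 1L)) {
    idx <- sel[(brk[g] + 1L):brk[g + 1L]]
    lo <- min(ppm[idx]); hi <- max(ppm[idx])
    hit <- ent$shift_ppm >= lo - tolerance & ent$shift_ppm <= hi + tolerance
    dir <- if (!is.null(loading)) sign(mean(loading[idx])) else NA_real_
    out <- rbind(out, data.frame(
      low_ppm = lo, high_ppm = hi, n_points = length(idx),
      peak_statistic = max(stat[idx]),
      direction = dir,
      metabolites = paste(unique(ent$metabolite[hit]), collapse = "; "),
      stringsAsFactors = FALSE))
    matches[[g]] <- ent[hit, c("metabolite", "group", "shift_ppm")]
  }
  ord <- order(out$high_ppm, decreasing = TRUE) # NMR display convention
  structure(list(regions = out[ord, , drop = FALSE],
                 matches = matches[ord],
                 quantile = quantile, tolerance = tolerance),
            class = "marker_report")
}

#' @export
print.marker_report <- function(x, ...) {
  cat("<marker_report> ", nrow(x$regions), " region(s) above the ",
      x$quantile, " quantile\n", sep = "")
  print(x$regions, row.names = FALSE)
  invisible(x)
}
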