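#' Plot spectra, scores and selection profiles
#'
#' Basic diagnostic graphics: overlaid spectra (ppm axis reversed, the NMR
#' display convention), OPLS score plots coloured by class, and a
#' selectivity-ratio profile.
#'
#' @param ds a [spectra_dataset()].
#' @param n number of spectra to overlay.
#' @param ... further arguments to [graphics::matplot()] / [graphics::plot()].
#' @return invisibly, the object plotted.
#' @export
plot_spectra <- function(ds, n = min(10L, n_samples(ds)), ...) {
  idx <- seq_len(n)
  graphics::matplot(ds$ppm, t(ds$intensities[idx, , drop = FALSE]),
                    type = "l", lty = 1, xlim = rev(range(ds$ppm)),
                    xlab = "ppm", ylab = "intensity", ...)
  invisible(ds)
}

#' @rdname plot_spectra
#' @param model an `opls_model`.
#' @param labels class labels for colouring.
#' @export
plot_scores <- function(model, labels, ...) {
  to <- if (model$n_orth > 0) model$T_o[, 1L] else rep(0, length(model$t))
  cl <- as.factor(labels)
  graphics::plot(model$t, to, col = as.integer(cl), pch = 19,
                 xlab = "predictive score t", ylab = "orthogonal score t_o",
                 ...)
  graphics::legend("topright", legend = levels(cl),
                   col = seq_along(levels(cl)), pch = 19, bty = "n")
  invisible(model)
}

#' @rdname plot_spectra
#' @param profile a `selectivity_ratio_profile` or `vip_profile`.
#' @param ppm ppm axis aligned with the profile.
#' @export
plot_selection_profile <- function(profile, ppm, ...) {
  stat <- if (!is.null(profile$sr)) profile$sr else profile$vip
  graphics::plot(ppm, stat, type = "h", xlim = rev(range(ppm)),
                 xlab = "ppm",
                 ylab = if (!is.null(profile$sr)) "selectivity ratio"
                        else "VIP", ...)
  invisible(profile)
}
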