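#' Fit an OPLS / OPLS-DA model
#'
#' Orthogonal projections to latent structures for a single response:
#' the systematic variation in X is split into a part linearly related to
#' y (one predictive component for a two-class response), a part orthogonal
#' to y (structured noise, `n_orth` components) and residual variance.
#'
#' Algorithm (X already centred/scaled, y coded 0/1 and centred
#' internally): the predictive weight is `w = X'y / |X'y|`; each orthogonal
#' round computes `t = Xw`, `p = X't/(t't)`, removes the y-predictive part
#' of the loading, `w_o = p - (w'p)w` (normalised), forms `t_o = X w_o`,
#' `p_o = X't_o/(t_o't_o)` and deflates `X <- X - t_o p_o'`. The final
#' predictive component is computed on the filtered X. Extraction stops
#' early when the orthogonal score norm falls below tolerance (nothing
#' orthogonal left to model); the actual count is recorded.
#'
#' @param Xs scaled matrix, samples in rows.
#' @param y numeric two-valued response (class coding 0/1, with the
#'   positive class at 1) or a centred version of it.
#' @param n_orth number of orthogonal components requested (>= 0).
#' @return an `opls_model`: predictive weights/scores/loading (`w`, `t`,
#'   `p`), orthogonal blocks (`W_o`, `T_o`, `P_o`), y-loading `q`,
#'   regression vector `b` for direct prediction, `y_mean`, per-block
#'   explained X-variance, and `n_orth` actually extracted.
#' @export
opls_fit <- function(Xs, y, n_orth = 1L) {
  Xs <- as.matrix(Xs)
  y <- as.numeric(y)
  if (length(unique(y)) != 2L)
    stop("y must take exactly two values before centering")
  if (n_orth < 0L) stop("n_orth must be >= 0")
  y_mean <- mean(y)
  yc <- y - y_mean
  ssx_total <- sum(Xs^2)
  tol <- 1e-12 * sqrt(ssx_total)
  w <- as.numeric(crossprod(Xs, yc))
  w <- w / sqrt(sum(w^2))
  E <- Xs
  W_o <- P_o <- matrix(numeric(0), nrow = ncol(Xs), ncol = 0L)
  T_o <- matrix(numeric(0), nrow = nrow(Xs), ncol = 0L)
  r2x_orth <- numeric(0)
  stopped_norm <- NA_real_
  for (j in seq_len(n_orth)) {
    tt <- as.numeric(E %*% w)
    p <- as.numeric(crossprod(E, tt)) / sum(tt^2)
    wo <- p - sum(w * p) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-12 * max(1, sqrt(sum(p^2)))) { stopped_norm <- nwo; break }
    wo <- wo / nwo
    to <- as.numeric(E %*% wo)
    if (sqrt(sum(to^2)) < tol) { stopped_norm <- sqrt(sum(to^2)); break }
    po <- as.numeric(crossprod(E, to)) / sum(to^2)
    E <- E - outer(to, po)
    W_o <- cbind(W_o, wo); T_o <- cbind(T_o, to); P_o <- cbind(P_o, po)
    r2x_orth <- c(r2x_orth, sum(to^2) * sum(po^2) / ssx_total)
  }
  tt <- as.numeric(E %*% w)
  p <- as.numeric(crossprod(E, tt)) / sum(tt^2)
  q <- sum(yc * tt) / sum(tt^2)
  # closed-form coefficient vector: b = (I - w_o1 p_o1') ... (I - w_ok p_ok') w q
  b <- w * q
  for (j in rev(seq_len(ncol(W_o))))
    b <- b - W_o[, j] * sum(P_o[, j] * b)
  r2x_pred <- sum(tt^2) * sum(p^2) / ssx_total
  structure(list(w = w, t = tt, p = p, q = q, b = b, y_mean = y_mean,
                 W_o = W_o, T_o = T_o, P_o = P_o,
                 n_orth = ncol(W_o), n_orth_requested = n_orth,
                 stopped_norm = stopped_norm,
                 explained_variance = list(
                   predictive = r2x_pred, orthogonal = r2x_orth,
                   total = r2x_pred + sum(r2x_orth)),
                 fitted = tt * q + y_mean),
            class = "opls_model")
}

#' @export
print.opls_model <- function(x, ...) {
  ev <- x$explained_variance
  cat("<opls_model> 1 predictive + ", x$n_orth, " orthogonal component(s)\n",
      sep = "")
  cat(sprintf("  X variance: predictive %.2f%%, orthogonal %s, total %.2f%%\n",
              100 * ev$predictive,
              if (length(ev$orthogonal))
                paste(sprintf("%.2f%%", 100 * ev$orthogonal), collapse = " + ")
              else "none",
              100 * ev$total))
  invisible(x)
}

#' Predict a response with a fitted OPLS model
#'
#' Removes the orthogonal variation from the new (already scaled) data with
#' the model's `W_o`/`P_o`, projects on the predictive weight and maps back
#' through the y-loading: `yhat = t_new q + y_mean`.
#'
#' @param model an `opls_model`.
#' @param Xnew_scaled matrix scaled with the training [fit_scaling()] model.
#' @return numeric vector of predicted responses (around the 0/1 class
#'   coding).
#' @export
opls_predict <- function(model, Xnew_scaled) {
  E <- as.matrix(Xnew_scaled)
  if (ncol(E) != length(model$w))
    stop("column count does not match the fitted model")
  for (j in seq_len(model$n_orth)) {
    to <- as.numeric(E %*% model$W_o[, j])
    E <- E - outer(to, model$P_o[, j])
  }
  as.numeric(E %*% model$w) * model$q + model$y_mean
}

#' Back-scaled predictive loading and correlation weights
#'
#' Multiplies the predictive loading by the per-variable scale so the
#' loading again resembles a spectrum, and computes for each variable the
#' absolute Pearson correlation between the scaled data column and the
#' predictive score — the colour-coding weight of the S-line plot.
#'
#' @param model an `opls_model` fitted on `Xs`.
#' @param scaling the `scaling_model` used to produce `Xs`.
#' @param Xs the scaled training matrix.
#' @return list with `backscaled` (loading x scale) and `weights`
#'   (absolute correlations in `[0, 1]`).
#' @export
backscale_loadings <- function(model, scaling, Xs) {
  Xs <- as.matrix(Xs)
  if (ncol(Xs) != length(model$p)) stop("shape mismatch")
  sc <- scaling$scales[scaling$keep]
  tt <- model$t
  tc <- tt - mean(tt)
  Xc <- Xs - rep(colMeans(Xs), each = nrow(Xs))
  denom <- sqrt(colSums(Xc^2) * sum(tc^2))
  w <- ifelse(denom > 0, abs(as.numeric(crossprod(Xc, tc))) / denom, 0)
  list(backscaled = model$p * sc, weights = pmin(w, 1))
}
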