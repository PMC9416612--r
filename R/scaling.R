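#' Fit a column scaling model
#'
#' Variants used ahead of PCA and OPLS-DA:
#'
#' * `center`: subtract the column mean;
#' * `pareto`: center, divide by the square root of the column standard
#'   deviation;
#' * `auto`: center, divide by the column standard deviation (unit
#'   variance);
#' * `class_centroid`: subtract the average of the two class-mean vectors,
#'   (x̄A + x̄B)/2, and divide by the pooled standard deviation — the
#'   unbalanced-class variant that keeps the centre of gravity midway
#'   between groups.
#'
#' Columns with zero variance cannot be scaled under `pareto`, `auto` or
#' `class_centroid`; they are dropped with a warning and recorded in the
#' model so it can be applied consistently to new data.
#'
#' @param X numeric matrix, samples in rows.
#' @param method one of `center`, `pareto`, `auto`, `class_centroid`.
#' @param labels class labels, required for `class_centroid` (exactly two
#'   classes, each with at least 2 samples).
#' @return a `scaling_model` with `offsets`, `scales`, a `keep` column
#'   mask and, for `class_centroid`, the class means and pooled sd.
#' @export
fit_scaling <- function(X, method = c("center", "pareto", "auto",
                                      "class_centroid"), labels = NULL) {
  method <- match.arg(method)
  X <- as.matrix(X)
  cm <- colMeans(X)
  sdv <- col_sds(X)
  extra <- list()
  if (method == "class_centroid") {
    if (is.null(labels)) stop("class_centroid scaling requires labels")
    lv <- unique(labels)
    if (length(lv) != 2L) stop("class_centroid needs exactly two classes")
    nA <- sum(labels == lv[1L]); nB <- sum(labels == lv[2L])
    if (nA < 1L || nB < 1L) stop("each class needs at least 1 sample")
    mA <- colMeans(X[labels == lv[1L], , drop = FALSE])
    mB <- colMeans(X[labels == lv[2L], , drop = FALSE])
    ssA <- if (nA > 1L) (nA - 1) * col_sds(X[labels == lv[1L], , drop = FALSE])^2
           else rep(0, ncol(X))
    ssB <- if (nB > 1L) (nB - 1) * col_sds(X[labels == lv[2L], , drop = FALSE])^2
           else rep(0, ncol(X))
    pooled <- sqrt((ssA + ssB) / max(nA + nB - 2L, 1L))
    offsets <- (mA + mB) / 2
    scales <- pooled
    extra <- list(class_means = stats::setNames(list(mA, mB), lv),
                  pooled_sd = pooled)
  } else {
    offsets <- cm
    scales <- switch(method, center = rep(1, ncol(X)),
                     pareto = sqrt(sdv), auto = sdv)
  }
  keep <- rep(TRUE, ncol(X))
  if (method != "center") {
    keep <- is.finite(scales) & scales > 0
    if (!all(keep))
      warning(sum(!keep), " zero-variance column(s) dropped by ", method,
              " scaling")
  }
  structure(c(list(method = method, offsets = offsets, scales = scales,
                   keep = keep), extra),
            class = "scaling_model")
}

#' Apply / invert a scaling model
#'
#' `apply_scaling` centres and scales new data with a fitted model (dropping
#' any columns the fit discarded); `invert_scaling` undoes it exactly.
#'
#' @param model a `scaling_model` from [fit_scaling()].
#' @param X matrix on the original scale (`apply_scaling`) or on the scaled
#'   scale (`invert_scaling`).
#' @return matrix of scaled (or restored) values.
#' @export
apply_scaling <- function(model, X) {
  X <- as.matrix(X)[, model$keep, drop = FALSE]
  off <- model$offsets[model$keep]
  sc <- model$scales[model$keep]
  (X - rep(off, each = nrow(X))) / rep(sc, each = nrow(X))
}

#' @rdname apply_scaling
#' @export
invert_scaling <- function(model, X) {
  X <- as.matrix(X)
  off <- model$offsets[model$keep]
  sc <- model$scales[model$keep]
  X * rep(sc, each = nrow(X)) + rep(off, each = nrow(X))
}

#' Principal component analysis by singular value decomposition
#'
#' Operates on an already centred/scaled matrix. Component k explains
#' `d_k^2 / sum(d^2)` of the total scaled variance. If `K` exceeds the
#' matrix rank the trailing zero-variance components are kept but flagged.
#'
#' @param Xs scaled matrix (samples in rows).
#' @param K number of components.
#' @return a `pca_model` with column-orthonormal `loadings` (P x K),
#'   `scores` (n x K), per-component and cumulative
#'   `explained_variance_fraction`, and a `zero_variance` flag vector.
#' @export
pca_fit <- function(Xs, K) {
  Xs <- as.matrix(Xs)
  if (K < 1L || K > min(nrow(Xs), ncol(Xs)))
    stop("K must be between 1 and min(n, P)")
  sv <- svd(Xs, nu = K, nv = K)
  tot <- sum(sv$d^2)
  frac <- sv$d[seq_len(K)]^2 / tot
  zero <- sv$d[seq_len(K)] <= sv$d[1L] * 1e-12
  structure(list(loadings = sv$v,
                 scores = Xs %*% sv$v,
                 singular_values = sv$d[seq_len(K)],
                 explained_variance_fraction = frac,
                 cumulative_variance_fraction = cumsum(frac),
                 zero_variance = zero),
            class = "pca_model")
}
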