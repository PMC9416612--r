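#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global random number generator seeded at `seed`,
#' restoring the caller's RNG state afterwards so library functions never
#' disturb user-level randomness.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  code
}

#' Construct a set of ppm intervals
#'
#' A region set is the package's representation of one or more closed ppm
#' intervals, used for exclusion windows, baseline anchors and alignment
#' reference zones. Infinite bounds are allowed.
#'
#' @param ... numeric length-2 vectors `c(low, high)` in ppm.
#' @return an object of class `region_set`: a two-column matrix with columns
#'   `low` and `high`.
#' @examples
#' regions(c(4.35, 5.0), c(-Inf, 0.17), c(8.0, Inf))
#' @export
regions <- function(...) {
  iv <- list(...)
  if (length(iv) == 1L && is.list(iv[[1L]])) iv <- iv[[1L]]
  if (length(iv) == 0L) {
    m <- matrix(numeric(0), ncol = 2L)
  } else {
    ok <- vapply(iv, function(v) is.numeric(v) && length(v) == 2L, logical(1))
    if (!all(ok)) stop("each region must be a numeric c(low, high) pair")
    m <- do.call(rbind, iv)
  }
  colnames(m) <- c("low", "high")
  if (nrow(m) > 0L && any(m[, 1L] >= m[, 2L]))
    stop("every region must satisfy low < high")
  structure(m, class = c("region_set", class(m)))
}

#' Test ppm values for membership in a region set
#'
#' Intervals are closed on both ends; membership is decided on the stored
#' axis values.
#'
#' @param ppm numeric vector of chemical shifts.
#' @param rs a [regions()] object.
#' @return logical vector, `TRUE` where `ppm` falls inside any interval.
#' @export
ppm_in_regions <- function(ppm, rs) {
  if (is.null(rs) || nrow(rs) == 0L) return(rep(FALSE, length(ppm)))
  inside <- rep(FALSE, length(ppm))
  for (i in seq_len(nrow(rs)))
    inside <- inside | (ppm >= rs[i, 1L] & ppm <= rs[i, 2L])
  inside
}

# Rigid integer shift of a vector; vacated positions repeat the edge value
# (zero-fill would create artificial baseline steps).
shift_vector <- function(x, lag) {
  n <- length(x)
  if (lag == 0L || n == 0L) return(x)
  if (abs(lag) >= n) return(rep(if (lag > 0) x[1L] else x[n], n))
  if (lag > 0L) c(rep(x[1L], lag), x[seq_len(n - lag)])
  else c(x[seq(1L - lag, n)], rep(x[n], -lag))
}

# Integer lag in [-max_shift, max_shift] maximizing the inner product of the
# shifted sample with the target over `cols`. Ties prefer the smallest |lag|.
# Evaluates shift_vector(x, l)[cols] by index arithmetic (edge repeat).
best_lag <- function(x, target, cols, max_shift) {
  n <- length(x)
  lags <- seq.int(-max_shift, max_shift)
  tc <- target[cols]
  score <- vapply(lags, function(l) {
    idx <- cols - l
    idx[idx < 1L] <- 1L
    idx[idx > n] <- n
    sum(tc * x[idx])
  }, numeric(1))
  best <- which(score == max(score))
  lags[best[which.min(abs(lags[best]))]]
}

# Sample standard deviation per column without the copying of apply().
col_sds <- function(X) {
  n <- nrow(X)
  if (n < 2L) return(rep(NA_real_, ncol(X)))
  mu <- colMeans(X)
  sqrt(colSums((X - rep(mu, each = n))^2) / (n - 1L))
}
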