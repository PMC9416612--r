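# class coding: positive class maps to 1, the other to 0
class_coding <- function(labels, positive = NULL) {
  lv <- unique(labels)
  if (length(lv) != 2L) stop("exactly two classes are required")
  if (is.null(positive))
    positive <- if ("Schizophrenia" %in% lv) "Schizophrenia" else lv[1L]
  if (!positive %in% lv) stop("positive class not present in labels")
  list(positive = positive, negative = setdiff(lv, positive),
       y = as.numeric(labels == positive))
}

#' Contiguous-block size for replicate-preserving cross-validation
#'
#' With `N` samples in complete replicate groups of size `r` and an
#' `n_folds`-fold contiguous-block CV, each block holds
#' `ceiling(N / (r * n_folds))` subjects, i.e. that many replicate groups.
#'
#' @param n_samples total sample count `N`.
#' @param replicates replicate count per subject `r`.
#' @param n_folds number of CV folds.
#' @return list with `subjects_per_block` and `block_size_samples`.
#' @examples
#' cv_block_size(265, 3, 7) # 13 subjects, 39 samples per block
#' @export
cv_block_size <- function(n_samples, replicates = 3, n_folds = 7) {
  spb <- ceiling(n_samples / (replicates * n_folds))
  list(subjects_per_block = spb, block_size_samples = spb * replicates)
}

#' Build a replicate-preserving cross-validation plan
#'
#' Subjects are shuffled by `seed` and assigned to contiguous blocks of
#' [cv_block_size()] subjects each, so that all replicates of a subject
#' always share one fold. The last block may be smaller.
#'
#' @param samples sample metadata table with `sample_id`, `subject_id`,
#'   `replicate_index` (every subject must have the same replicate count).
#' @param n_folds number of folds (at most the subject count).
#' @param seed integer shuffle seed.
#' @return a `cv_plan`: `fold_of_sample` (aligned with `samples`),
#'   `n_folds`, `subjects_per_block`, `block_size_samples`, `seed`.
#' @export
make_cv_plan <- function(samples, n_folds = 7, seed = 1L) {
  reps <- table(samples$subject_id)
  if (length(unique(as.integer(reps))) != 1L)
    stop("all subjects must have the same replicate count")
  r <- as.integer(reps[1L])
  subjects <- unique(samples$subject_id)
  if (n_folds > length(subjects))
    stop("n_folds cannot exceed the subject count")
  bs <- cv_block_size(nrow(samples), r, n_folds)
  shuffled <- with_seed(seed, sample(subjects))
  fold_of_subject <- rep(seq_len(n_folds),
                         each = bs$subjects_per_block)[seq_along(shuffled)]
  fold <- fold_of_subject[match(samples$subject_id, shuffled)]
  structure(list(fold_of_sample = fold, n_folds = n_folds,
                 subjects_per_block = bs$subjects_per_block,
                 block_size_samples = bs$block_size_samples,
                 seed = as.integer(seed)),
            class = "cv_plan")
}

# guard: no subject may sit in more than one fold
assert_no_leakage <- function(samples, plan) {
  split_count <- tapply(plan$fold_of_sample, samples$subject_id,
                        function(f) length(unique(f)))
  if (any(split_count > 1L))
    stop("leakage: subject(s) split across folds: ",
         paste(names(split_count)[split_count > 1L], collapse = ", "))
  invisible(TRUE)
}

# held-out predictions for one OPLS configuration over a CV plan
cv_predictions <- function(X, y, labels, plan, scaling_method, n_orth) {
  pred <- numeric(length(y))
  for (f in seq_len(plan$n_folds)) {
    te <- which(plan$fold_of_sample == f)
    if (!length(te)) next
    tr <- setdiff(seq_along(y), te)
    if (length(unique(labels[tr])) < 2L)
      stop("a training fold lacks one of the classes")
    scal <- fit_scaling(X[tr, , drop = FALSE], scaling_method,
                        labels = labels[tr])
    m <- opls_fit(apply_scaling(scal, X[tr, , drop = FALSE]), y[tr], n_orth)
    pred[te] <- opls_predict(m, apply_scaling(scal, X[te, , drop = FALSE]))
  }
  pred
}

#' Cross-validated OPLS-DA component selection
#'
#' For every orthogonal-component count `0..max_orth`, refits scaling and
#' OPLS-DA on each training fold and predicts the held-out fold, yielding
#' RMSECV per count; RMSEC comes from full-data fits. The chosen count is
#' the smallest one within 1 percent of the minimum RMSECV. A leakage guard
#' asserts on every run that no subject is split across folds.
#'
#' @param ds a [spectra_dataset()] with two classes.
#' @param plan a [make_cv_plan()] covering all samples.
#' @param scaling_method passed to [fit_scaling()].
#' @param max_orth largest orthogonal-component count to try.
#' @param positive positive-class label (default `"Schizophrenia"` when
#'   present).
#' @return a `fit_metrics` object: `rmsec`, `rmsecv` (named by component
#'   count), `chosen_components`, the held-out `cv_predictions` matrix
#'   (one column per count) and the 0/1 response `y`.
#' @export
cross_validate <- function(ds, plan, scaling_method = "auto", max_orth = 3,
                           positive = NULL) {
  if (length(plan$fold_of_sample) != n_samples(ds))
    stop("plan does not cover this dataset")
  assert_no_leakage(ds$samples, plan)
  cod <- class_coding(ds$samples$class_label, positive)
  X <- ds$intensities
  ks <- 0:max_orth
  rmsec <- rmsecv <- stats::setNames(numeric(length(ks)), ks)
  preds <- matrix(NA_real_, nrow = nrow(X), ncol = length(ks),
                  dimnames = list(ds$samples$sample_id, ks))
  for (k in ks) {
    scal <- fit_scaling(X, scaling_method, labels = ds$samples$class_label)
    full <- opls_fit(apply_scaling(scal, X), cod$y, k)
    rmsec[as.character(k)] <- sqrt(mean((full$fitted - cod$y)^2))
    pk <- cv_predictions(X, cod$y, ds$samples$class_label, plan,
                         scaling_method, k)
    preds[, as.character(k)] <- pk
    rmsecv[as.character(k)] <- sqrt(mean((pk - cod$y)^2))
  }
  best <- min(rmsecv)
  chosen <- ks[which(rmsecv <= best * 1.01)[1L]]
  structure(list(rmsec = rmsec, rmsecv = rmsecv,
                 chosen_components = chosen,
                 cv_predictions = preds, y = cod$y,
                 positive = cod$positive, negative = cod$negative),
            class = "fit_metrics")
}

# equal-posterior point of two Gaussians with priors; root between the means
solve_equal_posterior <- function(m0, s0, pi0, m1, s1, pi1) {
  A <- 1 / (2 * s0^2) - 1 / (2 * s1^2)
  B <- m1 / s1^2 - m0 / s0^2
  C <- m0^2 / (2 * s0^2) - m1^2 / (2 * s1^2) + log((pi1 * s0) / (pi0 * s1))
  lo <- min(m0, m1); hi <- max(m0, m1)
  if (abs(A) < 1e-12 * max(1, abs(B))) {
    x <- -C / B
    if (x >= lo && x <= hi) return(list(threshold = x, fallback = FALSE))
  } else {
    disc <- B^2 - 4 * A * C
    if (disc >= 0) {
      roots <- (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
      inside <- roots[roots >= lo & roots <= hi]
      if (length(inside))
        return(list(threshold = inside[1L], fallback = FALSE))
    }
  }
  list(threshold = (m0 + m1) / 2, fallback = TRUE)
}

#' Bayesian classification thresholds from calibration predictions
#'
#' Fits a Gaussian to each class's calibration predictions and places the
#' per-class threshold where the posterior probabilities of the two classes
#' are equal (the root of the resulting quadratic lying between the class
#' means; if the overlap is degenerate and no root lies between the means,
#' the midpoint is used and flagged). The threshold for the complementary
#' class model is computed on the mirrored predictions `1 - yhat`, so for
#' a two-class 0/1 coding the two thresholds sum to one.
#'
#' @param y_hat_cal calibration (or cross-validated) predictions.
#' @param labels class labels aligned with `y_hat_cal`.
#' @param prior `"proportions"` (class frequencies; the default, suited to
#'   unequal classes) or `"equal"`.
#' @param positive positive-class label.
#' @return a `threshold_model`: per-class Gaussian fits, priors, and a
#'   named `threshold` vector (one entry per class model).
#' @export
bayesian_thresholds <- function(y_hat_cal, labels,
                                prior = c("proportions", "equal"),
                                positive = NULL) {
  prior <- match.arg(prior)
  cod <- class_coding(labels, positive)
  pos <- y_hat_cal[labels == cod$positive]
  neg <- y_hat_cal[labels == cod$negative]
  if (length(pos) < 2L || length(neg) < 2L)
    stop("both classes need at least two calibration predictions")
  m1 <- mean(pos); s1 <- stats::sd(pos)
  m0 <- mean(neg); s0 <- stats::sd(neg)
  if (s0 <= 0 || s1 <= 0) stop("per-class sd must be positive")
  if (prior == "proportions") {
    pi1 <- length(pos) / length(y_hat_cal)
    pi0 <- 1 - pi1
  } else pi0 <- pi1 <- 0.5
  t_pos <- solve_equal_posterior(m0, s0, pi0, m1, s1, pi1)
  # mirrored problem: the complementary class model sees 1 - yhat
  t_neg <- solve_equal_posterior(1 - m1, s1, pi1, 1 - m0, s0, pi0)
  thr <- stats::setNames(c(t_pos$threshold, t_neg$threshold),
                         c(cod$positive, cod$negative))
  structure(list(classes = c(cod$positive, cod$negative),
                 positive = cod$positive,
                 means = stats::setNames(c(m1, m0),
                                         c(cod$positive, cod$negative)),
                 sds = stats::setNames(c(s1, s0),
                                       c(cod$positive, cod$negative)),
                 priors = stats::setNames(c(pi1, pi0),
                                          c(cod$positive, cod$negative)),
                 threshold = thr,
                 fallback = t_pos$fallback || t_neg$fallback),
            class = "threshold_model")
}

#' Classify predictions and build the confusion matrix
#'
#' A sample is assigned to the positive class when `yhat >=` its threshold
#' and to the negative class when `1 - yhat >=` the negative-class
#' threshold; samples satisfying neither or both rules are reported as
#' `Unassigned`. Accuracy is the fraction of correctly assigned samples
#' over all samples.
#'
#' @param y_hat predicted responses (0/1 class coding).
#' @param thresholds a `threshold_model` from [bayesian_thresholds()].
#' @param actual true class labels.
#' @return a `confusion_matrix`: `counts` (predicted x actual, including
#'   an `Unassigned` row) and `accuracy`.
#' @export
classify_and_score <- function(y_hat, thresholds, actual) {
  if (length(y_hat) != length(actual)) stop("length mismatch")
  pos <- thresholds$positive
  neg <- setdiff(thresholds$classes, pos)
  as_pos <- y_hat >= thresholds$threshold[pos]
  as_neg <- (1 - y_hat) >= thresholds$threshold[neg]
  predicted <- ifelse(as_pos & !as_neg, pos,
                      ifelse(as_neg & !as_pos, neg, "Unassigned"))
  counts <- table(factor(predicted, levels = c(pos, neg, "Unassigned")),
                  factor(actual, levels = c(pos, neg)),
                  dnn = c("Predicted", "Actual"))
  accuracy <- (counts[pos, pos] + counts[neg, neg]) / length(y_hat)
  structure(list(counts = counts, accuracy = accuracy),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  print(x$counts)
  cat(sprintf("accuracy: %.4f\n", x$accuracy))
  invisible(x)
}

#' Subject-level permutation test of an OPLS-DA model
#'
#' The observed statistic is computed from a replicate-preserving CV run at
#' the given orthogonal-component count; for each iteration the class
#' labels are permuted at the subject level (replicates move together), the
#' whole CV pipeline is re-run and the statistic recorded. The empirical p
#' value is `(1 + #(null >= observed)) / (n_iter + 1)` for CV accuracy
#' (larger is better) and the mirrored rule for RMSECV.
#'
#' @param ds a [spectra_dataset()].
#' @param plan a [make_cv_plan()].
#' @param scaling_method passed to [fit_scaling()].
#' @param n_orth orthogonal-component count of the model under test.
#' @param n_iter number of permutations (default 200).
#' @param seed integer seed for the permutations.
#' @param statistic `"accuracy"` (CV accuracy at the 0.5 midpoint) or
#'   `"rmsecv"`.
#' @param positive positive-class label.
#' @return a `permutation_result`: observed statistic, null statistics and
#'   empirical `p`.
#' @export
permutation_test <- function(ds, plan, scaling_method = "auto", n_orth = 1,
                             n_iter = 200, seed = 1L,
                             statistic = c("accuracy", "rmsecv"),
                             positive = NULL) {
  statistic <- match.arg(statistic)
  if (n_iter < 1L) stop("n_iter must be >= 1")
  assert_no_leakage(ds$samples, plan)
  cod <- class_coding(ds$samples$class_label, positive)
  X <- ds$intensities
  stat_of <- function(labels) {
    y <- as.numeric(labels == cod$positive)
    pred <- cv_predictions(X, y, labels, plan, scaling_method, n_orth)
    if (statistic == "accuracy") mean((pred >= 0.5) == (y == 1))
    else sqrt(mean((pred - y)^2))
  }
  observed <- stat_of(ds$samples$class_label)
  subjects <- unique(ds$samples$subject_id)
  subj_class <- ds$samples$class_label[match(subjects,
                                             ds$samples$subject_id)]
  null_stats <- with_seed(seed, vapply(seq_len(n_iter), function(i) {
    perm <- sample(subj_class)
    stat_of(perm[match(ds$samples$subject_id, subjects)])
  }, numeric(1)))
  p <- if (statistic == "accuracy")
    (1 + sum(null_stats >= observed)) / (n_iter + 1)
  else (1 + sum(null_stats <= observed)) / (n_iter + 1)
  structure(list(n_iterations = n_iter, statistic = statistic,
                 observed = observed, null = null_stats, p = p),
            class = "permutation_result")
}
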