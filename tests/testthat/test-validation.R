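triplicate_samples <- function(n_subj, classes = NULL) {
  if (is.null(classes))
    classes <- rep(c("Schizophrenia", "Control"), length.out = n_subj)
  data.frame(
    sample_id = paste0("s", seq_len(n_subj * 3)),
    subject_id = rep(paste0("u", seq_len(n_subj)), each = 3),
    replicate_index = rep(1:3, n_subj),
    class_label = rep(classes, each = 3),
    stringsAsFactors = FALSE)
}

test_that("contiguous-block size follows the replicate-aware formula", {
  bs <- cv_block_size(265, 3, 7)
  expect_equal(bs$subjects_per_block, 13L)
  expect_equal(bs$block_size_samples, 39L)
  expect_equal(cv_block_size(21, 3, 7)$block_size_samples, 3L)
})

test_that("seven subjects over seven folds give one subject per fold", {
  plan <- make_cv_plan(triplicate_samples(7), n_folds = 7, seed = 1)
  tab <- table(plan$fold_of_sample)
  expect_equal(length(tab), 7L)
  expect_true(all(tab == 3L))
})

test_that("no subject is ever split across folds", {
  samp <- triplicate_samples(23)
  for (seed in 1:100) {
    plan <- make_cv_plan(samp, n_folds = 7, seed = seed)
    splits <- tapply(plan$fold_of_sample, samp$subject_id,
                     function(f) length(unique(f)))
    expect_true(all(splits == 1L))
  }
  expect_error(make_cv_plan(rbind(triplicate_samples(4),
                                  data.frame(sample_id = "x",
                                             subject_id = "u9",
                                             replicate_index = 1,
                                             class_label = "Control")),
                            n_folds = 2), "same replicate count")
})

test_that("cross-validation matches a naive uncached fold loop", {
  ds <- standard_fixture(seed = 29, n_points = 512)
  plan <- make_cv_plan(ds$samples, n_folds = 5, seed = 3)
  fm <- cross_validate(ds, plan, scaling_method = "auto", max_orth = 2)
  y <- as.numeric(ds$samples$class_label == "Schizophrenia")
  for (k in 0:2) {
    pred <- numeric(length(y))
    for (f in 1:5) {
      te <- plan$fold_of_sample == f
      sm <- fit_scaling(ds$intensities[!te, ], "auto")
      m <- opls_fit(apply_scaling(sm, ds$intensities[!te, ]), y[!te], k)
      pred[te] <- opls_predict(m, apply_scaling(sm, ds$intensities[te, ]))
    }
    expect_equal(unname(fm$rmsecv[as.character(k)]),
                 sqrt(mean((pred - y)^2)), tolerance = 1e-10)
  }
  expect_true(all(diff(fm$rmsec) <= 1e-10))
})

test_that("a strongly separable cohort cross-validates nearly perfectly", {
  lib <- load_default_library()
  ds <- simulate_cohort(lib, sim_config(
    n_subjects_per_class = c(7, 7), noise_sd = 0, shift_jitter_sd = 0,
    dilution_log_sd = 0, baseline_slope_range = c(0, 0),
    baseline_offset_range = c(0, 0), concentration_cv = 0.05,
    marker_fold_changes = c("Alanine" = 3, "Glycine" = 3, "Lactate/lactic acid" = 3),
    include_water_hump = FALSE, include_lipid_humps = FALSE,
    grid = list(ppm_min = 0, ppm_max = 10, n_points = 512), seed = 37))
  plan <- make_cv_plan(ds$samples, n_folds = 7, seed = 5)
  fm <- cross_validate(ds, plan, scaling_method = "center", max_orth = 2)
  expect_lt(min(fm$rmsecv), 0.05)
})

test_that("Bayesian thresholds obey symmetry, a grid oracle and complementarity", {
  # symmetric case
  set.seed(9)
  yhat <- c(rnorm(50, 0.2, 0.1), rnorm(50, 0.8, 0.1))
  labels <- rep(c("Control", "Schizophrenia"), each = 50)
  tm <- bayesian_thresholds(yhat, labels, prior = "equal")
  m <- tm$means; s <- tm$sds
  # analytic symmetric threshold from the fitted Gaussians
  if (abs(s[1] - s[2]) < 0.02)
    expect_equal(unname(tm$threshold["Schizophrenia"]),
                 unname((m[1] + m[2]) / 2), tolerance = 0.02)
  expect_equal(unname(sum(tm$threshold)), 1, tolerance = 1e-6)

  # asymmetric case against a brute-force posterior grid search
  pos <- rnorm(60, 0.8, 0.15); neg <- rnorm(40, 0.2, 0.05)
  yhat <- c(pos, neg)
  labels <- rep(c("Schizophrenia", "Control"), c(60, 40))
  tm <- bayesian_thresholds(yhat, labels, prior = "proportions")
  m1 <- mean(pos); s1 <- sd(pos); m0 <- mean(neg); s0 <- sd(neg)
  pi1 <- 0.6; pi0 <- 0.4
  g <- seq(m0, m1, by = 1e-5)
  diff_post <- abs(pi1 * dnorm(g, m1, s1) - pi0 * dnorm(g, m0, s0))
  expect_equal(unname(tm$threshold["Schizophrenia"]),
               g[which.min(diff_post)], tolerance = 1e-4)
  expect_equal(unname(sum(tm$threshold)), 1, tolerance = 1e-6)

  # degenerate overlap falls back to the midpoint, flagged
  tm2 <- bayesian_thresholds(c(rnorm(20, 0.5, 0.3), rnorm(20, 0.5001, 0.0001)),
                             rep(c("Control", "Schizophrenia"), each = 20))
  expect_true(is.finite(tm2$threshold[1]))
})

test_that("threshold complementarity holds across seeded instances", {
  for (s in 1:10) {
    set.seed(s)
    yhat <- c(rnorm(30, runif(1, 0.6, 0.9), runif(1, 0.05, 0.2)),
              rnorm(20, runif(1, 0.1, 0.4), runif(1, 0.05, 0.2)))
    labels <- rep(c("Schizophrenia", "Control"), c(30, 20))
    tm <- bayesian_thresholds(yhat, labels)
    expect_equal(unname(sum(tm$threshold)), 1, tolerance = 1e-6)
  }
})

test_that("classification and accuracy match an explicit counting loop", {
  thr <- bayesian_thresholds(
    c(rnorm(20, 0.85, 0.05), rnorm(20, 0.15, 0.05)),
    rep(c("Schizophrenia", "Control"), each = 20))
  set.seed(10)
  yhat <- runif(20)
  actual <- sample(c("Schizophrenia", "Control"), 20, replace = TRUE)
  cm <- classify_and_score(yhat, thr, actual)
  t_pos <- thr$threshold[["Schizophrenia"]]
  t_neg <- thr$threshold[["Control"]]
  pred <- character(20)
  for (i in 1:20) {
    as_pos <- yhat[i] >= t_pos
    as_neg <- (1 - yhat[i]) >= t_neg
    pred[i] <- if (as_pos && !as_neg) "Schizophrenia"
               else if (as_neg && !as_pos) "Control" else "Unassigned"
  }
  expect_equal(sum(cm$counts), 20)
  for (p in c("Schizophrenia", "Control", "Unassigned"))
    for (a in c("Schizophrenia", "Control"))
      expect_equal(unname(cm$counts[p, a]), sum(pred == p & actual == a))
  expect_equal(cm$accuracy, mean(pred == actual))
  # all-correct case
  cm2 <- classify_and_score(c(0.9, 0.9, 0.1), thr,
                            c("Schizophrenia", "Schizophrenia", "Control"))
  expect_equal(cm2$accuracy, 1.0)
})

test_that("accuracy equals one minus the misclassified-plus-unassigned rate", {
  thr <- bayesian_thresholds(
    c(rnorm(20, 0.85, 0.05), rnorm(20, 0.15, 0.05)),
    rep(c("Schizophrenia", "Control"), each = 20))
  set.seed(11)
  yhat <- runif(40)
  actual <- sample(c("Schizophrenia", "Control"), 40, replace = TRUE)
  cm <- classify_and_score(yhat, thr, actual)
  wrong <- sum(cm$counts) - cm$counts["Schizophrenia", "Schizophrenia"] -
    cm$counts["Control", "Control"]
  expect_equal(cm$accuracy, 1 - wrong / 40)
})

test_that("the permutation observed statistic equals the plain CV accuracy", {
  ds <- standard_fixture(seed = 43, n_points = 512)
  plan <- make_cv_plan(ds$samples, n_folds = 5, seed = 7)
  fm <- cross_validate(ds, plan, scaling_method = "auto", max_orth = 1)
  pr <- permutation_test(ds, plan, scaling_method = "auto", n_orth = 1,
                         n_iter = 3, seed = 17)
  y <- as.numeric(ds$samples$class_label == "Schizophrenia")
  acc <- mean((fm$cv_predictions[, "1"] >= 0.5) == (y == 1))
  expect_equal(pr$observed, acc)
  expect_gte(pr$p, 1 / 4)
})
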