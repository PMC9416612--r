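make_flat_dataset <- function(n = 4, ppm = seq(0, 10, by = 0.01),
                              value = 1) {
  X <- matrix(value, nrow = n, ncol = length(ppm))
  spectra_dataset(ppm, X, data.frame(
    sample_id = paste0("s", seq_len(n)),
    subject_id = paste0("u", seq_len(n)),
    replicate_index = 1L,
    class_label = rep(c("Schizophrenia", "Control"), length.out = n)))
}

test_that("region exclusion matches a per-point membership oracle", {
  ds <- make_flat_dataset()
  expect_equal(exclude_regions(ds, regions())$ppm, ds$ppm)
  out <- exclude_regions(ds)
  keep_oracle <- vapply(ds$ppm, function(p) {
    !((p >= 4.35 && p <= 5.0) || p <= 0.17 || p >= 8.0)
  }, logical(1))
  expect_equal(length(out$ppm), sum(keep_oracle))
  expect_equal(out$ppm, ds$ppm[keep_oracle])
  expect_false(any(abs(out$ppm - 4.70) < 1e-9))
  expect_error(exclude_regions(ds, regions(c(-Inf, Inf))), "every variable")
})

test_that("baseline correction recovers a pure line exactly", {
  ds <- make_flat_dataset(n = 3, value = 0)
  res <- baseline_correct(ds)
  expect_equal(unname(res$baseline$slope), rep(0, 3))
  expect_equal(unname(res$baseline$intercept), rep(0, 3))
  expect_equal(res$dataset$intensities, ds$intensities)

  a <- c(2.5, -1.2, 0.4); b <- c(10, -3, 7)
  ds$intensities <- outer(a, ds$ppm) + matrix(b, 3, length(ds$ppm))
  res <- baseline_correct(ds)
  expect_equal(unname(res$baseline$slope), a, tolerance = 1e-9)
  expect_equal(unname(res$baseline$intercept), b, tolerance = 1e-9)
  anchors <- ppm_in_regions(ds$ppm, default_baseline_anchors())
  expect_lt(max(abs(res$dataset$intensities[, anchors])), 1e-9)
})

test_that("planted baselines are removed down to the noise level", {
  ds <- simulate_cohort(load_default_library(), sim_config(
    n_subjects_per_class = c(4, 3), noise_sd = 0.5,
    baseline_slope_range = c(-5, 5), baseline_offset_range = c(0, 10),
    grid = list(ppm_min = 0, ppm_max = 10, n_points = 2048), seed = 21))
  res <- baseline_correct(ds)
  anchors <- ppm_in_regions(ds$ppm, default_baseline_anchors())
  resid <- res$dataset$intensities[, anchors]
  expect_lte(abs(median(resid)), 0.5)
  # recovered coefficients track the planted ones
  expect_gt(cor(res$baseline$slope, ds$truth$baseline$slope), 0.99)
})

test_that("pretreatment modes satisfy their defining identities", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  s <- pretreat_vector(x, "snv")
  expect_equal(mean(s), 0, tolerance = 1e-12)
  expect_equal(sd(s), 1, tolerance = 1e-12)
  expect_error(pretreat_vector(rep(2, 5), "snv"), "constant")
  expect_equal(pretreat_vector(rep(2, 5), "derivative"), rep(0, 5))
  expect_equal(pretreat_vector(seq_len(10), "derivative"), rep(1, 10))
  expect_equal(pretreat_vector(x, "none"), x)
})

test_that("global alignment recovers a planted integer shift exactly", {
  lib <- load_default_library()
  ds <- simulate_cohort(lib, clean_config(
    n_subjects_per_class = c(3, 3), replicates_per_subject = 1,
    marker_fold_changes = c("Alanine" = 1), n_points = 4096, seed = 5))
  ga0 <- global_align(ds, max_shift = 20)
  expect_equal(unname(ga0$alignment$global_shifts), rep(0L, 6))

  n <- length(ds$ppm)
  x <- ds$intensities[2, ]
  ds$intensities[2, ] <- c(x[(n - 6):n], x[1:(n - 7)]) # circular +7 points
  ga <- global_align(ds, max_shift = 20, n_iter = 1)
  expect_equal(unname(ga$alignment$global_shifts[2]), -7L)
  # brute-force lag oracle over the reference window
  cols <- which(ppm_in_regions(ds$ppm, default_alignment_reference()))
  tgt <- apply(ds$intensities, 2, median)
  score <- vapply(-20:20, function(l) {
    shifted <- if (l > 0) c(rep(ds$intensities[2, 1], l),
                            ds$intensities[2, 1:(n - l)])
               else if (l < 0) c(ds$intensities[2, (1 - l):n],
                                 rep(ds$intensities[2, n], -l))
               else ds$intensities[2, ]
    sum(tgt[cols] * shifted[cols])
  }, numeric(1))
  expect_equal((-20:20)[which.max(score)], -7L)
})

test_that("alignment tightens peak positions on jittered cohorts", {
  ds <- simulate_cohort(load_default_library(), sim_config(
    n_subjects_per_class = c(6, 5), noise_sd = 0.5,
    shift_jitter_sd = 0.01, linewidth_hz = 1.2 * 16384 / 2048,
    baseline_slope_range = c(0, 0), baseline_offset_range = c(0, 0),
    grid = list(ppm_min = 0, ppm_max = 10, n_points = 2048), seed = 31))
  # track the strong isolated alanine doublet
  peak_pos <- function(X) {
    win <- which(ds$ppm >= 1.40 & ds$ppm <= 1.52)
    ds$ppm[win[apply(X[, win], 1, which.max)]]
  }
  before <- peak_pos(ds$intensities)
  a <- global_align(ds, max_shift = 30)$dataset
  a <- interval_align(a, regular_intervals(a), max_shift = 30)$dataset
  after <- peak_pos(a$intensities)
  expect_lt(mean(abs(after - median(after))),
            mean(abs(before - median(before))))
})

test_that("interval alignment reduces to global alignment on the whole axis", {
  ds <- simulate_cohort(load_default_library(), sim_config(
    n_subjects_per_class = c(3, 3), noise_sd = 0.5, shift_jitter_sd = 0.005,
    grid = list(ppm_min = 0, ppm_max = 10, n_points = 1024), seed = 41))
  whole <- regions(c(min(ds$ppm), max(ds$ppm)))
  ia <- interval_align(ds, whole, pretreatment = "none", max_shift = 15)
  ga <- global_align(ds, ref_regions = whole, n_iter = 1, max_shift = 15)
  expect_equal(ia$dataset$intensities, ga$dataset$intensities)
  expect_equal(unname(ia$alignment$interval_shifts[[1]]),
               as.integer(unname(ga$alignment$global_shifts)))
})

test_that("interval alignment is confined to its interval", {
  ds <- simulate_cohort(load_default_library(), clean_config(
    n_subjects_per_class = c(3, 2), replicates_per_subject = 1,
    marker_fold_changes = c("Alanine" = 1), n_points = 4096, seed = 51))
  cols <- which(ds$ppm >= 1.2 & ds$ppm <= 1.4)
  seg <- ds$intensities[1, cols]
  k <- length(seg)
  ds$intensities[1, cols] <- c(seg[(k - 2):k], seg[1:(k - 3)]) # +3 inside
  ia <- interval_align(ds, regions(c(1.2, 1.4), c(3.0, 3.2)),
                       max_shift = 10)
  expect_equal(unname(ia$alignment$interval_shifts[["1.2_1.4"]][1]), -3L)
  expect_equal(unname(ia$alignment$interval_shifts[["3_3.2"]]), rep(0L, 5))
  empty <- interval_align(ds, regions())
  expect_equal(empty$dataset$intensities, ds$intensities)
})

test_that("PQN leaves identical spectra alone and undoes a known scaling", {
  ds <- make_flat_dataset(n = 5)
  ds$intensities <- matrix(rep(abs(sin(ds$ppm)) + 0.5, each = 5), nrow = 5)
  res <- pqn_normalize(ds)
  expect_equal(unname(res$normalization$quotients), rep(1, 5))
  expect_equal(res$dataset$intensities, ds$intensities)

  ds$intensities[5, ] <- 3 * ds$intensities[1, ]
  res <- pqn_normalize(ds)
  expect_equal(unname(res$normalization$quotients[5]), 3, tolerance = 1e-10)
  expect_equal(as.numeric(res$dataset$intensities[5, ]),
               as.numeric(ds$intensities[1, ]), tolerance = 1e-10)
})

test_that("PQN recovers simulated dilution factors and is idempotent", {
  ds <- simulate_cohort(load_default_library(), sim_config(
    n_subjects_per_class = c(10, 10), dilution_log_sd = 0.3,
    linewidth_hz = 1.2 * 16384 / 1024, # keep lines resolvable on this grid
    grid = list(ppm_min = 0, ppm_max = 10, n_points = 1024), seed = 11))
  ds <- exclude_regions(ds)
  ds <- baseline_correct(ds)$dataset
  p1 <- pqn_normalize(ds)
  expect_gte(cor(p1$normalization$quotients, ds$truth$dilution), 0.95)
  p2 <- pqn_normalize(p1$dataset)
  num <- abs(p2$dataset$intensities - p1$dataset$intensities)
  den <- abs(p1$dataset$intensities)
  big <- den > 1e-6
  expect_lt(max(num[big] / den[big]), 1e-10)
})

test_that("preprocessing keeps the log append-only and sample order fixed", {
  ds <- simulate_cohort(load_default_library(), sim_config(
    n_subjects_per_class = c(3, 3),
    grid = list(ppm_min = 0, ppm_max = 10, n_points = 512), seed = 61))
  ids <- ds$samples$sample_id
  steps <- length(ds$processing_log)
  ds <- exclude_regions(ds)
  expect_length(ds$processing_log, steps + 1)
  ds <- baseline_correct(ds)$dataset
  expect_length(ds$processing_log, steps + 2)
  ds <- global_align(ds, max_shift = 10)$dataset
  expect_length(ds$processing_log, steps + 3)
  ds <- pqn_normalize(ds)$dataset
  expect_length(ds$processing_log, steps + 4)
  expect_identical(ds$samples$sample_id, ids)
})

test_that("alignment only permutes intensities apart from edge fill", {
  ds <- simulate_cohort(load_default_library(), sim_config(
    n_subjects_per_class = c(3, 3), shift_jitter_sd = 0.01, noise_sd = 0.2,
    baseline_slope_range = c(0, 0), baseline_offset_range = c(0, 0),
    grid = list(ppm_min = 0, ppm_max = 10, n_points = 1024), seed = 71))
  ga <- global_align(ds, max_shift = 20)
  for (i in seq_len(n_samples(ds))) {
    lag <- ga$alignment$global_shifts[i]
    n <- length(ds$ppm)
    core_old <- if (lag >= 0) ds$intensities[i, 1:(n - lag)]
                else ds$intensities[i, (1 - lag):n]
    core_new <- if (lag >= 0) ga$dataset$intensities[i, (1 + lag):n]
                else ga$dataset$intensities[i, 1:(n + lag)]
    expect_identical(unname(core_new), unname(core_old))
  }
})
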