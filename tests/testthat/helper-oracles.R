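# Independent oracles and small fixtures shared across tests.

# NIPALS PLS1, written independently of the package's OPLS implementation;
# used as the equivalence oracle for fitted values.
oracle_pls1_fitted <- function(X, y, ncomp) {
  X <- as.matrix(X)
  ymean <- mean(y)
  f <- y - ymean
  E <- X
  Tm <- matrix(0, nrow(X), ncomp)
  Q <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    w <- as.numeric(crossprod(E, f))
    w <- w / sqrt(sum(w^2))
    tt <- as.numeric(E %*% w)
    p <- as.numeric(crossprod(E, tt)) / sum(tt^2)
    q <- sum(f * tt) / sum(tt^2)
    E <- E - outer(tt, p)
    f <- f - q * tt
    Tm[, a] <- tt
    Q[a] <- q
  }
  ymean + as.numeric(Tm %*% Q)
}

# trapezoidal numerical integration
trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

# a library restricted to the named metabolites
sub_library <- function(metabolites, full = load_default_library()) {
  metabolite_library(
    full$entries[full$entries$metabolite %in% metabolites, , drop = FALSE],
    frequency = full$frequency)
}

# deterministic, artefact-free simulation settings for unit tests
clean_config <- function(..., n_points = 2048, seed = 42) {
  args <- list(...)
  base <- list(noise_sd = 0, shift_jitter_sd = 0, dilution_log_sd = 0,
               baseline_slope_range = c(0, 0),
               baseline_offset_range = c(0, 0),
               concentration_cv = 0,
               include_water_hump = FALSE, include_lipid_humps = FALSE,
               grid = list(ppm_min = 0, ppm_max = 10, n_points = n_points),
               seed = seed)
  base[names(args)] <- args
  do.call(sim_config, base)
}

# the standard planted-marker fixture: ten marker metabolites at fold 2,
# realistic noise/jitter/dilution. Tests run the generator at reduced
# spectral resolution, so the linewidth is broadened proportionally to
# keep lines resolvable (>= 2 grid points per FWHM), as a spectrometer
# matches digitization to linewidth.
# six marker metabolites whose library entries contribute exactly ten
# marker variables (multiplet positions), chosen among resonances that are
# resolvable from non-marker signals at the working resolution (a ranking
# at a heavily overlapped position measures the overlap, not the method),
# planted at fold 3 so they are decisively discriminatory relative to the
# between-subject concentration spread
ten_marker_folds <- c(
  "Alanine" = 3, "Gamma-aminobutyric acid" = 3,
  "3-Hydroxybutyric acid" = 3, "Asparagine" = 3,
  "Citrate/citric acid" = 3, "Lysine" = 3)

standard_fixture <- function(seed = 101, n_points = 2048) {
  lw <- 1.2 * 16384 / n_points
  simulate_cohort(load_default_library(), sim_config(
    n_subjects_per_class = c(10, 8),
    marker_fold_changes = ten_marker_folds,
    linewidth_hz = lw,
    grid = list(ppm_min = 0, ppm_max = 10, n_points = n_points),
    seed = seed))
}

# preprocess a dataset with the pipeline's default stages (no QC)
preprocess_default <- function(ds, align = FALSE) {
  ds <- exclude_regions(ds)
  ds <- baseline_correct(ds)$dataset
  if (align) {
    ds <- global_align(ds)$dataset
    ds <- interval_align(ds, regular_intervals(ds, 64), max_shift = 20)$dataset
  }
  pqn_normalize(ds)$dataset
}

# fully preprocessed, aligned, autoscaled OPLS analysis of the standard
# fixture at the generator's native resolution; cached per seed
.fixture_cache <- new.env(parent = emptyenv())
aligned_fixture_analysis <- function(seed = 59) {
  key <- as.character(seed)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  ds <- standard_fixture(seed = seed, n_points = 16384)
  ds <- preprocess_default(ds, align = TRUE)
  sm <- fit_scaling(ds$intensities, "auto")
  Xs <- apply_scaling(sm, ds$intensities)
  y <- as.numeric(ds$samples$class_label == "Schizophrenia")
  model <- opls_fit(Xs, y, 1)
  out <- list(ds = ds, sm = sm, Xs = Xs, y = y, model = model,
              ppm = ds$ppm[sm$keep])
  .fixture_cache[[key]] <- out
  out
}
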