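#' Render one multiplet onto a ppm grid
#'
#' Expands a splitting pattern into Lorentzian lines and evaluates their sum.
#' Patterns: `s` one line; `d` two equal lines split J/2 either side of the
#' center; `t` three lines 1:2:1 spaced J; `q` four lines 1:3:3:1 spaced J;
#' `dd` four equal lines from two couplings; `m` a single line broadened to
#' three times the nominal linewidth (no coupling tree is available for
#' unresolved multiplets). Couplings are converted to ppm as J / frequency.
#' Each line is a unit-area Lorentzian, so the integrated area of the
#' multiplet is proportional to `amplitude * protons`.
#'
#' @param center_ppm chemical shift of the multiplet center (ppm).
#' @param pattern one of `s`, `d`, `t`, `q`, `dd`, `m`.
#' @param couplings_hz numeric vector of scalar couplings in Hz (empty for
#'   `s` and `m`).
#' @param protons number of protons in the resonance group.
#' @param grid monotone ppm axis to evaluate on.
#' @param linewidth_hz full width at half maximum of a single line, Hz.
#' @param frequency spectrometer frequency, MHz.
#' @param amplitude concentration-like scale factor (>= 0).
#' @return numeric intensity vector, `length(grid)`.
#' @export
render_multiplet <- function(center_ppm, pattern, couplings_hz = numeric(0),
                             protons = 1, grid, linewidth_hz,
                             frequency = 500.26, amplitude = 1) {
  if (any(diff(grid) <= 0) && any(diff(grid) >= 0))
    stop("grid must be monotone")
  if (linewidth_hz <= 0) stop("linewidth must be positive")
  if (amplitude < 0) stop("amplitude must be non-negative")
  if (amplitude == 0) return(numeric(length(grid)))
  lw <- linewidth_hz
  j_ppm <- couplings_hz / frequency
  lines <- switch(pattern,
    s = list(offsets = 0, weights = 1),
    d = list(offsets = c(-1, 1) * j_ppm[1L] / 2, weights = c(1, 1) / 2),
    t = list(offsets = c(-1, 0, 1) * j_ppm[1L], weights = c(1, 2, 1) / 4),
    q = list(offsets = c(-1.5, -0.5, 0.5, 1.5) * j_ppm[1L],
             weights = c(1, 3, 3, 1) / 8),
    dd = {
      if (length(j_ppm) < 2L) stop("dd requires two couplings")
      list(offsets = c(-j_ppm[1L] - j_ppm[2L], -j_ppm[1L] + j_ppm[2L],
                       j_ppm[1L] - j_ppm[2L], j_ppm[1L] + j_ppm[2L]) / 2,
           weights = rep(0.25, 4L))
    },
    m = {
      lw <- 3 * linewidth_hz
      list(offsets = 0, weights = 1)
    },
    stop("unknown pattern: ", pattern))
  gamma <- (lw / 2) / frequency # half width at half maximum, ppm
  out <- numeric(length(grid))
  for (k in seq_along(lines$offsets)) {
    x0 <- center_ppm + lines$offsets[k]
    out <- out + lines$weights[k] * (gamma / pi) / ((grid - x0)^2 + gamma^2)
  }
  amplitude * protons * out
}

#' Simulation configuration for synthetic serum cohorts
#'
#' Defaults emulate the study conditions the pipeline is built for: two
#' classes of 51 and 39 subjects, three replicate spectra per subject, a
#' 0-10 ppm grid of 16384 points at 500.26 MHz, per-sample dilution
#' variation, per-metabolite chemical-shift jitter, linear baseline drift,
#' additive noise, a broad residual-water line near 4.70 ppm and broad
#' lipid lines near 0.88/1.28/5.27 ppm, and class-dependent concentration
#' shifts on a subset of library metabolites.
#'
#' @param n_subjects_per_class integer pair, sizes of the `Schizophrenia`
#'   and `Control` classes.
#' @param replicates_per_subject replicate spectra per subject.
#' @param grid list with `ppm_min`, `ppm_max`, `n_points` (>= 256).
#' @param linewidth_hz single-line full width at half maximum, Hz.
#' @param noise_sd additive Gaussian noise standard deviation, intensity
#'   units.
#' @param baseline_slope_range,baseline_offset_range uniform ranges for the
#'   per-sample linear baseline (intensity per ppm, intensity).
#' @param shift_jitter_sd per-metabolite chemical-shift jitter sd, ppm.
#' @param dilution_log_sd sd of the per-sample log-normal dilution factor.
#' @param marker_fold_changes named numeric vector, fold change applied to
#'   the named metabolites in the `Schizophrenia` class (> 0).
#' @param concentration_cv between-subject coefficient of variation of
#'   metabolite concentrations (log-normal).
#' @param include_water_hump,include_lipid_humps include the broad
#'   residual-water / lipid resonances.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_subjects_per_class = c(51, 39),
                       replicates_per_subject = 3,
                       grid = list(ppm_min = 0, ppm_max = 10,
                                   n_points = 16384),
                       linewidth_hz = 1.2,
                       noise_sd = 2,
                       baseline_slope_range = c(-5, 5),
                       baseline_offset_range = c(0, 10),
                       shift_jitter_sd = 0.002,
                       dilution_log_sd = 0.1,
                       marker_fold_changes = c(
                         "Lactate/lactic acid" = 1.5, "Glucose" = 1.5,
                         "Alanine" = 1.5, "Glycine" = 1.5, "Glutamine" = 1.5,
                         "Choline" = 1.5, "Valine" = 1.5,
                         "Gamma-aminobutyric acid" = 1.5),
                       concentration_cv = 0.2,
                       include_water_hump = TRUE,
                       include_lipid_humps = TRUE,
                       seed = 1L) {
  cfg <- list(n_subjects_per_class = as.integer(n_subjects_per_class),
              replicates_per_subject = as.integer(replicates_per_subject),
              grid = grid, linewidth_hz = linewidth_hz, noise_sd = noise_sd,
              baseline_slope_range = baseline_slope_range,
              baseline_offset_range = baseline_offset_range,
              shift_jitter_sd = shift_jitter_sd,
              dilution_log_sd = dilution_log_sd,
              marker_fold_changes = marker_fold_changes,
              concentration_cv = concentration_cv,
              include_water_hump = include_water_hump,
              include_lipid_humps = include_lipid_humps,
              seed = as.integer(seed))
  stopifnot(length(cfg$n_subjects_per_class) == 2L,
            cfg$replicates_per_subject >= 1L,
            cfg$grid$n_points >= 256L,
            cfg$linewidth_hz > 0,
            cfg$noise_sd >= 0, cfg$shift_jitter_sd >= 0,
            cfg$dilution_log_sd >= 0, cfg$concentration_cv >= 0)
  if (any(cfg$marker_fold_changes <= 0))
    stop("marker fold changes must be positive")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a synthetic serum NMR cohort
#'
#' Draws per-subject metabolite concentrations (log-normal around the
#' library default of 1, CV `concentration_cv`, multiplied by
#' `marker_fold_changes` in the `Schizophrenia` class), then renders each
#' replicate spectrum with its own dilution factor, per-metabolite shift
#' jitter, linear baseline and additive noise. Ground truth (dilution
#' factors, planted shifts, subject concentrations, marker variables) is
#' stored in the `truth` field.
#'
#' @param library a [metabolite_library()].
#' @param config a [sim_config()].
#' @return a [spectra_dataset()] with `truth` attached.
#' @examples
#' lib <- load_default_library()
#' ds <- simulate_cohort(lib, sim_config(n_subjects_per_class = c(3, 2),
#'   grid = list(ppm_min = 0, ppm_max = 10, n_points = 1024), seed = 7))
#' ds
#' @export
simulate_cohort <- function(library, config = sim_config()) {
  stopifnot(inherits(library, "metabolite_library"),
            inherits(config, "sim_config"))
  if (any(config$n_subjects_per_class < 1L))
    stop("both classes need at least one subject")
  unknown <- setdiff(names(config$marker_fold_changes),
                     library_metabolites(library))
  if (length(unknown))
    stop("marker metabolites not in library: ",
         paste(unknown, collapse = ", "))
  grid <- seq(config$grid$ppm_min, config$grid$ppm_max,
              length.out = config$grid$n_points)
  mets <- library_metabolites(library)
  nA <- config$n_subjects_per_class[1L] # Schizophrenia
  nB <- config$n_subjects_per_class[2L] # Control
  r <- config$replicates_per_subject
  subj <- c(sprintf("SCZ%03d", seq_len(nA)), sprintf("CTL%03d", seq_len(nB)))
  cls <- rep(c("Schizophrenia", "Control"), c(nA, nB))

  with_seed(config$seed, {
    conc <- matrix(stats::rlnorm(length(subj) * length(mets),
                                 meanlog = 0, sdlog = config$concentration_cv),
                   nrow = length(subj), ncol = length(mets),
                   dimnames = list(subj, mets))
    for (m in names(config$marker_fold_changes))
      conc[cls == "Schizophrenia", m] <-
        conc[cls == "Schizophrenia", m] * config$marker_fold_changes[[m]]

    n <- length(subj) * r
    samples <- data.frame(
      sample_id = sprintf("%s_r%d", rep(subj, each = r), rep(seq_len(r), length(subj))),
      subject_id = rep(subj, each = r),
      replicate_index = rep(seq_len(r), length(subj)),
      class_label = rep(cls, each = r),
      stringsAsFactors = FALSE)

    # broad-resonance amplitudes vary between subjects (serum lipid and
    # residual-water content are individual), log-normally around defaults
    water_amp <- 100 * stats::rlnorm(length(subj), 0, 0.2)
    lipid_base <- c(30, 60, 10) # 0.88, 1.28, 5.27 ppm
    lipid_amp <- matrix(stats::rlnorm(length(subj) * 3, 0, 0.3),
                        nrow = length(subj)) *
      rep(lipid_base, each = length(subj))

    dilution <- exp(stats::rnorm(n, 0, config$dilution_log_sd))
    slope <- stats::runif(n, config$baseline_slope_range[1L],
                          config$baseline_slope_range[2L])
    offset <- stats::runif(n, config$baseline_offset_range[1L],
                           config$baseline_offset_range[2L])
    jitter <- matrix(stats::rnorm(n * length(mets), 0, config$shift_jitter_sd),
                     nrow = n, dimnames = list(samples$sample_id, mets))

    X <- matrix(0, nrow = n, ncol = length(grid),
                dimnames = list(samples$sample_id, NULL))
    ent <- library$entries
    for (i in seq_len(n)) {
      sp <- numeric(length(grid))
      sid <- samples$subject_id[i]
      for (k in seq_len(nrow(ent))) {
        met <- ent$metabolite[k]
        sp <- sp + render_multiplet(
          center_ppm = ent$shift_ppm[k] + jitter[i, met],
          pattern = ent$pattern[k],
          couplings_hz = ent$couplings_hz[[k]],
          protons = ent$protons[k],
          grid = grid, linewidth_hz = config$linewidth_hz,
          frequency = library$frequency,
          amplitude = conc[sid, met])
      }
      si <- match(samples$subject_id[i], subj)
      if (config$include_water_hump)
        sp <- sp + render_multiplet(4.70, "s", protons = 1, grid = grid,
                                    linewidth_hz = 60,
                                    frequency = library$frequency,
                                    amplitude = water_amp[si])
      if (config$include_lipid_humps) {
        lip_ppm <- c(0.88, 1.28, 5.27)
        for (j in seq_along(lip_ppm))
          sp <- sp + render_multiplet(lip_ppm[j], "s", protons = 1,
                                      grid = grid, linewidth_hz = 20,
                                      frequency = library$frequency,
                                      amplitude = lipid_amp[si, j])
      }
      sp <- sp * dilution[i] + slope[i] * grid + offset[i]
      if (config$noise_sd > 0)
        sp <- sp + stats::rnorm(length(grid), 0, config$noise_sd)
      X[i, ] <- sp
    }

    marker_vars <- marker_truth(library, names(config$marker_fold_changes),
                                config$marker_fold_changes,
                                config$linewidth_hz)
    truth <- list(dilution = stats::setNames(dilution, samples$sample_id),
                  baseline = data.frame(sample_id = samples$sample_id,
                                        slope = slope, intercept = offset),
                  concentrations = conc,
                  water_amplitude = stats::setNames(water_amp, subj),
                  lipid_amplitudes = matrix(lipid_amp, ncol = 3,
                                            dimnames = list(subj,
                                                            c("0.88", "1.28",
                                                              "5.27"))),
                  shift_jitter = jitter,
                  marker_variables = marker_vars,
                  config = config)
    ds <- spectra_dataset(grid, X, samples, truth = truth)
    log_step(ds, "simulate",
             list(seed = config$seed, n = n, n_points = length(grid)))
  })
}

# ppm positions of every multiplet of the planted marker metabolites,
# together with the half-width of the multiplet's rendered footprint
# (outermost line offset plus three linewidths).
marker_truth <- function(library, marker_names, folds, linewidth_hz) {
  ent <- library$entries[library$entries$metabolite %in% marker_names, ]
  lw_ppm <- linewidth_hz / library$frequency
  span <- vapply(seq_len(nrow(ent)), function(k) {
    j <- ent$couplings_hz[[k]]
    off_hz <- switch(ent$pattern[k],
                     s = 0, m = 0,
                     d = j[1L] / 2, t = j[1L], q = 1.5 * j[1L],
                     dd = sum(j[1:2]) / 2)
    off_hz / library$frequency +
      3 * lw_ppm * if (ent$pattern[k] == "m") 3 else 1
  }, numeric(1))
  data.frame(metabolite = ent$metabolite, ppm = ent$shift_ppm,
             span_ppm = span,
             fold_change = as.numeric(folds[ent$metabolite]),
             stringsAsFactors = FALSE)
}
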