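---
title: "Serum 1H-NMR fingerprinting: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serum 1H-NMR fingerprinting: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

serumNMR implements a whole-spectrum ("fingerprinting") classification
workflow for one-dimensional 1H-NMR serum spectra: rather than quantifying
individual metabolites, it models every spectral variable jointly and asks
which coordinated intensity changes separate a patient class from a
control class. This vignette explains the statistical machinery, the
choices behind the defaults, what the synthetic cohort generator does and
does not emulate, and the package's known limitations.

## The data model

A `spectra_dataset` holds a strictly monotone ppm axis (stored ascending,
displayed descending per NMR convention), an `n x P` intensity matrix and
a sample table (`sample_id`, `subject_id`, `replicate_index`,
`class_label`). Subjects contribute replicate spectra (three by default),
and every operation in the package treats the subject — never the
individual spectrum — as the statistical unit wherever independence
matters: outlier flags, cross-validation folds, permutation draws and the
train/test split all move whole subjects.

## Preprocessing

**Region exclusion.** The residual-water zone (4.35–5.0 ppm) and the
signal-free ends of the spectrum (below 0.17 ppm, above 8 ppm) are
removed before any statistics are computed. Intervals are closed in ppm
and membership is decided on the stored axis values.

**Baseline.** A first-order polynomial is fitted per spectrum to
intensities over peak-free anchor windows (defaults 0.2–0.4, 6.6–6.8 and
9.5–10.0 ppm, chosen to be empty for the shipped metabolite library) and
subtracted from the whole spectrum. The fit is the closed-form simple
linear regression, vectorised over samples.

**Alignment.** Chemical shifts of serum resonances vary with pH, ionic
strength and temperature, so the same proton does not land on the same
column in every spectrum. Alignment proceeds in two stages of
interval-correlation-optimised shifting. First, each spectrum is rigidly
shifted by the integer lag maximising its cross-correlation with a target
spectrum over reference windows (defaults 5.12–5.19 and 5.20–5.35 ppm,
the zone of the anomeric glucose doublet at 5.23 ppm), iterated four
times with the target recomputed from the current data (the median
spectrum by default — the target must come from the data set itself, and
the median is robust to outlying spectra). Second, individual spectral
areas are aligned independently with the same criterion; lags may be
estimated on SNV- or derivative-pretreated segments while the intensities
themselves are shifted untreated. `regular_intervals()` supplies a
whole-axis segmentation (64 intervals by default) whose interior
boundaries snap to valleys of the median spectrum: a boundary through a
multiplet would let its two halves shift independently and tear it apart.
Vacated edge positions repeat the edge value rather than zero-filling, to
avoid creating artificial baseline steps; the largest allowed shift is
50 grid points by default. Shifting is integer-valued, so jitter smaller
than about half a grid spacing is irreducible — the reason digitization
should always resolve the linewidth (see the simulator section).

**Normalisation.** Probabilistic quotient normalisation estimates each
sample's dilution as the median of the variable-wise ratios between the
sample and a reference spectrum, then divides it out. The implementation
uses a median-area-preserving convention: spectra are reduced to unit
total area, the reference is the column-median of the unit-area spectra,
the per-sample quotient is the median ratio over positive reference
variables, and the output is rescaled once so that its median total area
equals the input's. Two useful properties follow exactly rather than
approximately: the operation is a fixed point (applying it twice changes
intensities only at floating-point level), and when one spectrum is a
scaled copy of the cohort consensus its stored divisor equals the true
scale factor. The `quotients` field of the result is the per-sample
dilution estimate (total area times median quotient over the rescale
constant).

## Outlier screening

Three independent rules flag samples, and any flag is propagated to all
replicates of the subject (replicates are never separated):

* **Moment-zone rule.** Columns whose non-excess kurtosis is both in the
  top percentile and above 5 define a "zone" of distributionally aberrant
  variables. A sample is flagged when it exceeds the column mean by more
  than 4 standard deviations in at least 10% of the zone (minimum 3
  columns). The multi-column requirement is essential: genuine artifacts
  — failed water suppression, spurious resonances — span a region of the
  spectrum, whereas single-column excursions are ordinary behaviour at
  peak flanks, where shift jitter makes intensity distributions heavy-
  tailed by nature. With a one-column rule, roughly half the subjects of
  a clean simulated cohort get flagged.
* **PCA rule.** Hotelling T-squared (F approximation) and Q residuals
  (Box weighted-chi-square approximation) on a mean-centered PCA, at the
  0.99 control limit. The conventional exploratory limit of 0.95 marks
  5% of samples by construction; combined with T-squared and Q and with
  subject-level propagation it would remove about one clean subject in
  seven, so automated removal uses the tighter limit.
* **SNR rule.** Median intensity over peak-region columns divided by the
  noise standard deviation (estimated in 9.5–10 ppm) below 5 flags
  heavily diluted spectra.

The number of screening components defaults to the smallest count
capturing 90% of variance (capped at 10).

## Scaling, PCA and OPLS-DA

Four column scalings are available: mean centering; Pareto (divide by the
square root of the standard deviation); autoscaling (unit variance); and
class-centroid centering and scaling, which subtracts the average of the
two class-mean vectors and divides by the pooled standard deviation.
Class-centroid scaling addresses unbalanced classes: overall mean
centering drags the centre of gravity toward the larger class and shifts
the decision boundary with it. Zero-variance columns cannot be
variance-scaled and are dropped with a warning, recorded in the model so
new data are treated consistently. PCA is the singular value
decomposition of the scaled matrix; component k explains
`d_k^2 / sum(d^2)` of the scaled variance.

OPLS-DA separates the systematic variation of X into a part linearly
related to the class response, a part orthogonal to it (structured
noise) and residual variance. With X scaled and y coded 0/1 (positive
class = 1, consistent with per-class thresholds that bracket 0.5), the
predictive weight is `w = X'y` normalised; each orthogonal round computes
the loading of the current predictive score, removes its y-predictive
part, normalises the remainder into an orthogonal weight, and deflates X
by the resulting orthogonal component; the predictive component is
computed on the filtered X. Orthogonal extraction stops early when the
orthogonal score norm falls below `1e-12` times the matrix norm — there
is nothing orthogonal left to model — and the achieved count is recorded.
A closed-form coefficient vector `b` is assembled so prediction is a
single matrix product; it agrees with sequential orthogonal removal to
floating-point accuracy, and fitted values agree with a PLS1 model using
one extra component (a known algebraic equivalence that the test suite
checks against an independent NIPALS implementation). Explained X
variance is reported per block against total scaled-X variance.

Back-scaled loadings multiply the predictive loading by the per-variable
scale so the loading again looks like a spectrum; each variable's
absolute correlation with the predictive score serves as its colour
weight (the S-line display).

## Validation

**Block cross-validation.** With N samples in complete replicate groups
of size r, each contiguous block holds `ceiling(N/(r * n_folds))`
subjects; subjects are shuffled by seed and assigned to blocks whole, so
no subject ever appears in both the training and the held-out part of a
fold (a guard asserts this on every run). RMSECV is computed per
orthogonal-component count by refitting scaling and OPLS-DA inside every
fold; the chosen count is the smallest within 1% of the minimum RMSECV —
when two models are statistically indistinguishable, the simpler one
wins.

**Bayesian thresholds.** A Gaussian is fitted to each class's
calibration (cross-validated) predictions; the class threshold is the
predicted value where the two posterior densities are equal — the root
of a quadratic, taken between the class means; if class overlap is so
degenerate that no root lies between the means, the midpoint is used and
flagged. Priors default to class proportions, which is what makes the
thresholds asymmetric for unequal classes. The complementary class model
is solved on the mirrored predictions `1 - yhat`, so the two thresholds
sum to one by construction. Classification applies both one-class rules;
samples accepted by neither or both are reported as `Unassigned`, and
accuracy counts correctly assigned samples over all samples.

**Permutation test.** Class labels are permuted at the subject level —
permuting individual replicates would leak a subject's identity across
the null and invalidate it — and the full CV pipeline is re-run per
iteration (200 by default). The statistic is CV accuracy at the 0.5
midpoint (RMSECV available by option), and the empirical p-value is
`(1 + #(null >= observed)) / (n_iter + 1)`.

## Variable selection

VIP is the standard formula over predictive components; for the
single-predictive-component OPLS-DA model it collapses to
`sqrt(P) |w|`, with mean square one. The selectivity ratio projects the
scaled data onto the normalised regression vector (target projection)
and reports, per variable, explained over residual variance; for centred
data this equals `r^2/(1 - r^2)` with r the correlation between variable
and target score, which makes it scale-equivariant under autoscaling.
Variables above a quantile threshold (strictly above, so a threshold of
1 selects nothing and raises the documented error) are merged into
regions, allowing gaps of up to 3 grid points, and each region is
annotated with every library multiplet within 0.02 ppm. The default
threshold is the 98th percentile; for cohorts with mild effects a looser
threshold (e.g. 0.95) is appropriate, since a 2% budget of columns is
quickly exhausted by the footprints of the strongest resonances.

## The synthetic cohort generator

The generator exists so that every stage of the pipeline can be tested
against known ground truth. It renders each metabolite of a 26-entry
serum library (one row per resonance group: shift, multiplet pattern,
couplings, proton count; 500.26 MHz) as a sum of unit-area Lorentzian
lines — singlet, doublet, triplet, quartet and doublet-of-doublets
patterns expand to the textbook line positions and intensity ratios;
unresolved multiplets ("m") are rendered as a single line at three times
the nominal linewidth, since no coupling tree is available for them.
Multiplet area is proportional to concentration times proton count.

Per subject, metabolite concentrations are drawn log-normally around 1
with a coefficient of variation of 0.2, and metabolites named in
`marker_fold_changes` are multiplied by their fold change in the
`Schizophrenia` class. Per sample (subject x replicate), the generator
applies a log-normal dilution factor, a per-metabolite chemical-shift
jitter (normal, sd 0.002 ppm — all multiplets of a metabolite move
together, as they do physically), a linear baseline, additive Gaussian
noise, a broad residual-water line at 4.70 ppm and broad lipid lines at
0.88, 1.28 and 5.27 ppm. Water and lipid amplitudes vary log-normally
between subjects (sd 0.2 and 0.3): serum lipid content is highly
individual, and holding these resonances fixed would make them spuriously
class-correlated after quotient normalisation whenever marker fold
changes alter total spectral area. Everything is reproducible from one
seed, ground truth (dilutions, jitters, concentrations, marker multiplet
positions and footprints) is stored with the dataset, and the default
configuration emulates the intended study scale: 51 + 39 subjects, three
replicates each, a 0–10 ppm grid of 16384 points, 1.2 Hz linewidth.

Two fixture rules matter when simulating at reduced size. First,
resolution and linewidth must be scaled together: at 16384 points the
grid spacing (0.00061 ppm) resolves a 1.2 Hz line, but a coarser grid
with the same linewidth undersamples the peaks, and sub-grid shift
jitter then produces large peak-top intensity noise that no integer
alignment can remove — an artefact of the fixture, not a property of the
method. Test fixtures therefore broaden the linewidth by `16384 /
n_points`, mimicking how a spectrometer matches digitization to
linewidth. Second, planted markers used to evaluate variable ranking
should sit at resonances resolvable from non-marker signals: a ranking
statistic evaluated at a column shared by a marker and a non-marker
(lactate's 1.31 doublet under threonine's 1.32, glycine's 3.54 singlet
inside the sugar envelope) measures the overlap, not the method.

What the generator does **not** emulate: second-order (strong-coupling)
multiplet distortion and roofing; free-induction-decay synthesis, phasing
errors or apodization effects; protein background and its CPMG
suppression; pH-dependent shift differences between metabolites beyond
random jitter; and realistic absolute concentration ratios — all
metabolites are drawn around a common scale, so, unlike real serum, the
glucose anomeric doublet is not prominent enough to serve as an
argmax-trackable landmark (position-recovery checks track the strong
isolated alanine doublet instead). Passing tests on synthetic cohorts
therefore demonstrate the correctness and calibration of the algorithms
under the stated noise model, not classifier performance on real serum.

## Numerical choices

* Alignment lag ties prefer the smallest absolute lag (no spurious
  drift); the correlation score is an inner product over the reference
  columns with edge-repeat semantics.
* OPLS component extraction stops at a score norm below `1e-12` times
  the matrix norm; PCA flags trailing components whose singular values
  fall below `1e-12` of the largest.
* The equal-posterior quadratic falls back to a linear solution when the
  class variances are effectively equal, and to the midpoint (flagged)
  when no root lies between the class means.
* Component-count ties in CV resolve to the smallest count within 1% of
  the minimum RMSECV.
* Degenerate inputs raise errors early: SNV of a constant vector,
  exclusion of every variable, non-positive spectrum areas or quotients,
  unequal replicate counts in a CV plan, folds whose training part lacks
  a class.

## Problem sizes used in tests

The test-suite and the acceptance script run the generator at 256–4096
points for algorithmic checks (with linewidth scaled as above) and at the
full 16384-point default for the variable-selection fixture and the
end-to-end pipeline run; cohorts range from 4 + 4 to 25 + 20 subjects
with triplicates. These sizes were chosen so that each check isolates
the property under test at the smallest scale at which it is
scientifically meaningful.

## Known limitations

* Alignment is integer-valued; sub-grid shift correction (interpolation)
  is not implemented.
* One predictive component only: multi-class OPLS-DA is out of scope.
* The selectivity-ratio and VIP rankings are reported without
  per-variable significance tests (no jackknifed F-tests).
* The presence/absence cohort table records detection, not direction or
  magnitude, of metabolite changes.
* Detection of dispersion-shaped (first-derivative-like) loading
  patterns, which indicate residual positional variation rather than
  concentration change, is not automated; inspect back-scaled loadings
  visually.
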