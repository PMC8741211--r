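---
title: "Microglomerular activity and connectivity analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microglomerular activity and connectivity analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgpipe)
```

## The scientific problem

In the input region of the *Drosophila* mushroom body -- the calyx --
olfactory projection neurons (PNs) hand their signal to Kenyon cells (KCs)
at large synaptic complexes called microglomeruli (MGs): one PN bouton
wrapped by the claw-like dendritic endings of many KCs. A single GABAergic
neuron, the anterior paired lateral (APL) neuron, innervates the whole
calyx and forms reciprocal synapses with both boutons and claws. The
question this package's pipeline addresses is what that inhibition does to
the odour code at the PN-to-KC handover: whether odour-specific differences
in input strength, clearly visible in PN boutons, are *normalized* away in
the postsynaptic KC claws, and whether the inhibition acts globally or
locally within the calyx volume.

The package implements the complete measurement chain for two-photon
calcium-imaging movies of the calyx -- motion correction, active-MG
detection, dF/F0 quantification, group statistics, and the volumetric
ratio-profile analysis -- together with a synthetic-data generator that
emulates the acquisition, so that every stage can be validated against
known ground truth without any imaging data. A separate module analyses
connectome synapse tables for the structural side of the question:
reciprocal APL synapse weights and their compartment localization.

## The forward model of the generator

A synthetic recording is assembled per pixel as

F(t, x) = B(x) * bleach(t) * (1 + sum_mg a_mg(odour) * G_mg(x) * k(t)) + noise

with the following components.

**Baseline image `B`.** A smooth heterogeneous field (15% fractional sd)
inside an elliptical "calyx" region, dropping to 25% of the interior level
outside. The interior mean is 1200 counts. The photon budget matters: the
detector normalizes to the pixelwise *minimum* image, which sits roughly
3 sigma below the baseline, so the normalized background pedestal scales
like 6.4 sigma/B. The default was chosen so this pedestal (~0.2) sits well
below typical MG response amplitudes; with a substantially poorer budget
the detection criterion starts to truncate the weak odour's amplitude
distribution more than the strong one's, which contradicts the observation
that the number of detected responding units is essentially odour
independent.

**MG footprints `G`.** MGs are ~5 um structures; each footprint is a
compact super-Gaussian `exp(-log(20) * (r/R)^4)` whose full width at 5% of
peak equals the 5-um diameter. A plain Gaussian parameterized the obvious
way (FWHM = diameter) has skirts that bridge adjacent MGs into merged
connected components at anatomical packing density; the merged blobs then
either fail the size gate or acquire centroids that belong to no real MG.
Real MG puncta are discrete, so the compact profile is the more faithful
choice, not merely the more convenient one. Centres are placed by rejection
sampling with a minimum spacing of one MG diameter (discrete MG cores
cannot interpenetrate).

**Transient kernel `k`.** A difference of exponentials (rise 0.2 s, decay
1.0 s) normalized to unit *continuous* peak and launched at each puff
onset. Amplitudes are therefore peak dF/F0 by construction; the residual
gap between the continuous peak and the sampled maximum on the frame grid
is known exactly (`ground_truth$kernel_peak`) and used by
`correct_peak_dilution()`.

**Amplitude law.** Per odour, an MG is active with probability
`active_fraction` (default 0.55) and its peak amplitude is log-normal --
positive and right-skewed, as measured peak histograms are. The
log-amplitude splits into a per-MG responsiveness factor shared across
odours plus an odour-specific residual (correlation 0.5 at unchanged
marginals): the same bouton is imaged under every odour, and its size,
indicator expression and synaptic strength are odour independent. The
preset layers encode the scientific contrast: the PN-bouton layer responds
to the strong odour with a 1.6-fold larger median; the KC-claw layer under
intact inhibition has that difference removed by a per-odour gain (the
normalization under study); the KC-claw layer with inhibition blocked
mirrors the PN contrast. Amplitudes below 5% dF/F0 count as inactive.

**Noise, bleaching, motion.** Gaussian noise with variance
`photon_gain * signal + read_noise^2` (shot-noise-limited at two-photon
count rates), exponential photobleaching at 1e-4 /s, and an integer-pixel
reflected random walk (max 2 px) starting at the reference position.
Bleaching interacts with the dF/F0 convention (F0 is the mean of the
*first 30 frames* of the whole recording, not a per-trial baseline): at
1e-4 /s the induced droop over a recording is ~1%, consistent with the
near-unity odour-pair ratios the volumetric analysis produces; an order of
magnitude more would visibly distort late trials.

**Stimulus protocol.** Two 5-s odour puffs per odour separated by 20 s of
clean air, ~9 Hz planar sampling, 30 baseline frames before the first
onset, odour order randomized per fly. Volumetric recordings acquire 5
z-slices per time point at a 16 Hz frame rate (3.2 volumes/s) and impose a
per-slice amplitude multiplier per odour (uniform, linear or logistic
gradient) to emulate the axial regionalization of PN terminals; the single
inhibitory neuron's response amplitude is deterministic per odour.

## The detection pipeline

`analyze_movie()` chains the stages exactly as a user would:

1. **Rigid registration** (`register_movie()`): integer-pixel translation
   per frame by FFT cross-correlation. Two passes: the baseline frames are
   first mutually aligned (a blurred template biases all estimates by a
   common offset, which cancels in relative alignment), a sharp template is
   rebuilt from them, and all frames are estimated against it; the first
   frame anchors zero. Estimation uses a central 64-px crop when that still
   covers most of the field (at least 80%); otherwise the field is used
   whole. The sharp boundary of the imaged region must stay inside the
   estimation window: during clean-air intervals the smooth interior alone
   gives too flat a correlation peak, and shift estimates then wander by a
   pixel or two. No subpixel interpolation: the detector thresholds a
   maximum image, and at 5-um ROI scale integer accuracy suffices while
   avoiding interpolation artefacts.
2. **Minimum-image normalization** (`min_image()`, `normalize_to_min()`):
   `N = (F - M) / (M + eps)` with `M` the pixelwise minimum over the whole
   recording. The divisive form makes detection invariant to illumination
   scale and puts responses on the dF/F-like relative scale.
3. **Response images**: per trial, the pixelwise maximum of `N` over the
   trial's analysis window (onset to next onset). A pixel "varies above
   threshold" exactly when its response-image value exceeds the threshold.
4. **Threshold**: Otsu's criterion on the response histogram. Three
   robustness choices, each documented here because the obvious variant
   fails in a specific, diagnosable way:
   - *Signal-region restriction.* Thresholding is restricted to the calyx
     signal mask (`calyx_mask()`: Otsu on the temporal mean image, the
     operator-independent stand-in for drawing a region around the
     GCaMP-expressing calyx), eroded by 2 px. Pixels outside the structure
     are dim, so their *relative* noise after minimum-image division is the
     largest in the field; residual integer-pixel motion additionally turns
     the sharp boundary into spuriously large normalized responses.
   - *One threshold per recording*, computed from the mean of the per-trial
     response images. A per-trial Otsu adapts to each odour's response
     strength, so the detection floor differs between the odours being
     compared and fluctuates fly by fly; that jitter both unbalances the
     paired design and inflates the pooled distribution comparison under
     the null. Averaging the trials weights each odour equally (taking
     their overall maximum would let the strongest odour set the
     criterion). The per-trial variant remains available in
     `detect_active_rois()`.
   - *Winsorized histogram and pre-stimulus floor.* The top 0.5% of
     response values are capped before Otsu -- a single hot pixel would
     otherwise stretch the histogram range and capture the between-class
     split, something a bounded integer-image histogram never allows -- and
     the threshold is floored at 1.3 times the 99.9th percentile of the
     baseline-window response: an accepted response must exceed anything
     the recording showed before stimulation. The floor is what sends a
     stimulus-free recording to the correct empty result.
5. **Components and size gate**: 8-connected components per z-slice;
   components are kept when their area lies within 0.25-4 times the disc
   area of the expected 5-um ROI diameter. The band is symmetric in area
   because "size matches the expected diameter" is qualitative; both
   rejection counts are reported.

`otsu_threshold()` itself is the textbook 256-bin histogram maximization of
between-class variance, with one stated convention: when the criterion ties
across an empty valley between well-separated classes, the centre of the
tied run is returned (a lowest-edge tie-break would sit at the foot of the
lower mode).

## Traces and summaries

Per-ROI traces are unweighted means over the ROI's pixels; `F0` is the mean
over the first 30 frames of the recording (the stated convention, kept
global rather than per-trial); `dff = 100 * (F - F0) / F0`; `dF/F0%MAX` is
the unsmoothed within-window maximum. `summarize_trial()` reports the
active-ROI count and the mean peak among active ROIs per odour exposure.
Because the ROI mean dilutes the centre amplitude by the baseline-weighted
footprint average, and the frame grid undersamples the kernel peak,
`correct_peak_dilution()` inverts both factors given the known footprint --
on noiseless data this recovers ground-truth amplitudes to numerical
precision, which is the package's end-to-end consistency check.

Pooled peak *distributions* take one exposure per odour (the first puff):
repeated puffs re-measure the same boutons, and double-counting them
pseudo-replicates the distribution comparison.

## Group statistics

- `paired_compare()`: within-pair differences are screened with the
  D'Agostino-Pearson omnibus test (skewness and kurtosis transformed to
  normal deviates, K2 ~ chi-squared(2); written out in full here and
  verified against an independent reference implementation) at alpha 0.05;
  pass means paired t, fail means Wilcoxon matched-pairs. Below n = 8,
  where the skewness transform is undefined, Shapiro-Wilk screens instead.
  Zero-variance differences are reported as degenerate rather than tested.
- `ks_compare()`: two-sample Kolmogorov-Smirnov on raw pooled values,
  never on binned histograms (binning is presentation-only and loses
  power).
- `response_distance()`: per-fly differences of mean peaks between odours,
  with a Welch t comparison across odour pairs or layers.
- `two_factor_compare()`: two-way ANOVA (condition x odour) with
  Tukey-adjusted within-condition contrasts, for the
  inhibition-intact/blocked design; an all-constant table is flagged
  degenerate with adjusted p = 1.
- `subtype_localization_compare()`: one-way ANOVA of per-neuron claw
  fractions across KC subtypes on a balanced, seeded subsample (default 70
  per subtype) with Tukey comparisons.

## Volumetric locality analysis

`zslice_peaks()` takes the per-slice signal-mask mean trace, computes
dF/F0% against the 30-volume baseline and one peak per odour and slice.
`ratio_profile()` averages across animals *first* and takes the odour-pair
ratio of means *second* (the stated order of operations; the per-fly ratios
are retained for dispersion and regression). `compare_slopes()` fits the
per-fly ratios by OLS on the slice index (unit: one z-step -- the analysis
compares curve shapes over sections, not physical depth) and tests slope
equality through the profile-by-slice interaction of the pooled model.
Because the same mask and the same activation foci underlie every odour of
a fly, footprint dilution cancels exactly in the ratio, which is why slope
recovery is accurate even though the absolute slice signals are diluted.

## Connectome module

Synapse tables are one row per annotated synaptic connection with
pre/post ids, 3D coordinates (nanometres when unitless, the convention of
dense-reconstruction exports), a region label and an optional compartment
tag. `filter_region()` keeps exact label matches (e.g. `"CA(R)"`, the
right calyx); `reciprocal_weights()` counts both directions per partner,
with "interacting" meaning made *and* received synapses (one-directional
partners are retained but flagged); `weight_correlation()` reports the
squared Pearson correlation -- identical to the OLS R-squared for a simple
regression -- over interacting neurons of one class;
`compartment_fractions()` gives per-neuron tag fractions with mean and SEM
across neurons, excluding uninformative (all-unknown) neurons. The manual
two-rater localization scoring used on real data is replaced by explicit
tags; for untagged tables the tags simply read "unknown" and the fractions
are undefined rather than guessed.

The synthetic table generator draws each neuron's weight onto the hub
uniformly from a range, sets the reciprocal weight by a linear model with
Gaussian noise (rounded, clipped at zero, clips counted), tags hub-to-PN
rows "bouton" and hub-to-KC rows "claw" according to per-neuron
truncated-normal fractions (KC means differ by subtype), and plants decoy
rows in other regions plus silent neurons so the filters have something to
reject. The default intercepts (25 for PNs, 12 for KCs) keep zero-clipping
rare; with a near-zero intercept roughly a third of the reciprocal weights
clip, which both distorts the emitted counts (a pile-up at zero that real
weight data do not show) and biases the recovered correlation. The noise
sds are calibrated so the realized correlations sit near the values
reported for calyx PN and KC populations (r2 ~ 0.63 and ~ 0.60); this
calibration fixes the generator's conditions and is not a tuning knob.

## Experiment recipes and problem sizes

`run_experiment()` wires the four experiment families end to end; all
seeds derive from one master seed and a manifest records them.

- `planar_contrast` and `apl_on_off` simulate 10 flies per layer on a
  ~65-um field holding 44 MGs (15-26 active per odour, comparable to a
  well-responding calyx section). The field size is a runtime-conscious
  package choice; the stimulus protocol, sampling rate and fly counts are
  the study conditions.
- `volumetric_locality` simulates 7 flies, three odours (one with a rising
  linear gradient, two uniform) on a ~48-um, 5-slice field with 40
  overlapping 4-um activation foci, so the slice signal is diffuse, as the
  calcium signal of a single wide-field inhibitory arbor is.
- `connectome_audit` runs the full synapse-table analysis at 126
  interacting PNs of 136, and 300 interacting KCs of 308 (the PN census
  matches the full-scale count; the KC population is scaled down for desk
  use).

## What the synthetic data do and do not establish

The generator reproduces the statistical structure the analysis relies on:
compact blobs on a heterogeneous baseline, Poisson-like noise, rigid
drift, log-normal odour-dependent amplitudes with cross-odour correlation,
slice-wise activation gradients, and linear reciprocal connectivity with
compartment tags. It deliberately omits optics (no PSF), neuropil
contamination, non-rigid deformation, indicator nonlinearity and
spike-to-calcium dynamics. Passing tests therefore demonstrate that the
measurement chain is correct and well calibrated under its stated
assumptions -- they do not certify performance on recordings whose
artefacts fall outside this model, and the detection stage in particular
should be expected to degrade under non-rigid motion or strong neuropil
background.

## Numerical conventions and degenerate inputs

Frame indices are 0-based with half-open trial windows `[onset, offset)`
in every exported artefact; internal R code converts at the boundary.
Movies round-trip through 16-bit TIFF with a recorded scale factor
(bit-exact for integer counts); volumetric pages are Z-fastest. Constant
images are a degeneracy error for `otsu_threshold()` but an *empty result*
(not an error) for detection; empty trials yield count 0 with an undefined
mean peak; flies missing an odour are excluded from paired analyses and
reported; zero denominator means mark ratio-profile slices undefined.
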