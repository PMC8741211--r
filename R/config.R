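#' Simulation configuration
#'
#' Parameters of the synthetic calyx recording. The defaults describe the
#' reference planar acquisition: a field large enough for one full calyx
#' z-section (~80 um at 0.65 um/px), 80 microglomeruli of 5 um diameter,
#' 5 s odour puffs separated by 20 s clean air, two puffs per odour, ~9 Hz
#' sampling, and a 30-frame baseline before the first puff. Noise is
#' shot-noise-limited (variance = gain * signal) plus Gaussian read noise;
#' motion is an integer-pixel random walk.
#'
#' @param field_px `c(ny, nx)` field size in pixels.
#' @param pixel_size_um micrometres per pixel.
#' @param frame_rate_hz frames per second (planar) -- for volumetric configs
#'   this is the per-frame rate; the volume rate is `frame_rate_hz / n_z`.
#' @param n_z number of z-slices (1 = planar).
#' @param z_step_um spacing between slices.
#' @param n_mg number of microglomeruli placed in the field.
#' @param mg_radius_um MG radius (default 2.5, i.e. the 5 um expected
#'   diameter used throughout the analysis).
#' @param min_spacing_um minimum centre-to-centre distance; default one MG
#'   diameter so that discrete MG cores never interpenetrate.
#' @param puff_s,gap_s,n_puffs,baseline_frames,tail_s stimulus protocol.
#' @param rise_s,decay_s transient kernel time constants (difference of
#'   exponentials, normalized to unit peak).
#' @param baseline_mean mean baseline fluorescence (counts) inside the calyx.
#' @param baseline_sd_frac fractional spatial heterogeneity of the baseline.
#' @param outside_frac baseline level outside the calyx, as a fraction of
#'   `baseline_mean`.
#' @param photon_gain noise variance per unit signal (Poisson-like scaling).
#' @param read_noise_sd additive Gaussian read noise (counts).
#' @param bleach_per_s exponential photobleaching rate (1/s).
#' @param motion_max_px maximum rigid drift (pixels); 0 disables motion.
#' @param motion_step_p probability of a +-1 px step per axis per frame.
#' @param amplitude_floor minimum peak dF/F0 (%) counted as an active MG.
#' @param randomize_order randomize odour block order.
#' @param seed RNG seed; the movie is reproducible from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(field_px = c(124L, 124L), pixel_size_um = 0.65,
                       frame_rate_hz = 9, n_z = 1L, z_step_um = 2,
                       n_mg = 80L, mg_radius_um = 2.5,
                       min_spacing_um = 2 * mg_radius_um,
                       puff_s = 5, gap_s = 20, n_puffs = 2L,
                       baseline_frames = 30L, tail_s = 10,
                       rise_s = 0.2, decay_s = 1.0,
                       baseline_mean = 1200, baseline_sd_frac = 0.15,
                       outside_frac = 0.25,
                       photon_gain = 1, read_noise_sd = 3,
                       bleach_per_s = 1e-4,
                       motion_max_px = 2L, motion_step_p = 0.1,
                       amplitude_floor = 5,
                       randomize_order = TRUE, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(rise_s > 0, decay_s > rise_s, frame_rate_hz > 0, pixel_size_um > 0,
            puff_s > 0, gap_s > 0, n_puffs >= 1, baseline_frames >= 1,
            mg_radius_um > 0, min_spacing_um > 0)
  class(cfg) <- "sim_config"
  cfg
}

#' Per-layer odour-response model
#'
#' Describes how the peak dF/F0 amplitudes of microglomeruli are distributed
#' for one imaged cell layer. Amplitudes are log-normal (positive and
#' right-skewed, as measured peak distributions are); each MG is active for a
#' given odour with probability `active_fraction`. `gain` is a per-odour
#' multiplicative factor modelling inhibitory normalization: the effective
#' log-mean is `log_mean + log(gain)`, and in the normalized KC layer the
#' gains equalize the across-odour log-means.
#'
#' @param layer one of `"PN_BOUTON"`, `"KC_CLAW_APL_ON"`,
#'   `"KC_CLAW_APL_OFF"`, `"APL_GLOBAL"`.
#' @param odours character vector of odour labels.
#' @param log_mean named numeric: log of the median peak amplitude (%) per
#'   odour, before normalization.
#' @param log_sd log-scale standard deviation (>= 0).
#' @param active_fraction probability that an MG responds to a given odour.
#' @param gain named numeric per-odour normalization gain.
#' @param cross_odour_cor log-scale correlation of one MG's amplitudes
#'   across odours. The same bouton is imaged under every odour, and its
#'   size, indicator level and synaptic strength are shared, so responses
#'   are correlated; the marginal per-odour distribution is unaffected.
#' @return list of class `layer_model`.
#' @export
layer_model <- function(layer, odours, log_mean, log_sd, active_fraction,
                        gain = stats::setNames(rep(1, length(odours)), odours),
                        cross_odour_cor = 0.5) {
  layer <- match.arg(layer, c("PN_BOUTON", "KC_CLAW_APL_ON",
                              "KC_CLAW_APL_OFF", "APL_GLOBAL"))
  log_mean <- log_mean[odours]; gain <- gain[odours]
  stopifnot(!anyNA(log_mean), !anyNA(gain), log_sd >= 0,
            active_fraction >= 0, active_fraction <= 1,
            cross_odour_cor >= 0, cross_odour_cor <= 1)
  eff <- log_mean + log(gain)
  if (layer == "KC_CLAW_APL_ON" &&
      max(eff) - min(eff) > sqrt(.Machine$double.eps))
    stop("layer_model: KC_CLAW_APL_ON requires equal per-odour log-means after gain")
  structure(list(layer = layer, odours = odours, log_mean = log_mean,
                 log_sd = log_sd, active_fraction = active_fraction,
                 gain = gain, cross_odour_cor = cross_odour_cor,
                 effective_log_mean = eff),
            class = "layer_model")
}

#' Default layer models for a two-odour contrast
#'
#' Presets encoding the contrast the analysis is designed to measure: the PN
#' bouton layer responds to `odours[2]` with 1.6-fold larger median peak
#' amplitude than to `odours[1]`; the KC claw layer under intact inhibition
#' (`APL_ON`) has that difference normalized away (gain 1/1.6 on the strong
#' odour); the KC claw layer without inhibition (`APL_OFF`) mirrors the PN
#' contrast. Median peaks are ~40-45% dF/F0 with log-sd 0.4-0.5.
#'
#' @param odours two odour labels, weak first (default `c("Mch", "Oct")`).
#' @param contrast fold-change of the strong odour at the input layer.
#' @return named list of `layer_model`s: `PN_BOUTON`, `KC_CLAW_APL_ON`,
#'   `KC_CLAW_APL_OFF`.
#' @export
layer_presets <- function(odours = c("Mch", "Oct"), contrast = 1.6) {
  stopifnot(length(odours) == 2)
  nm <- function(v) stats::setNames(v, odours)
  list(
    PN_BOUTON = layer_model("PN_BOUTON", odours,
                            log_mean = nm(c(log(45), log(45 * contrast))),
                            log_sd = 0.5, active_fraction = 0.55),
    KC_CLAW_APL_ON = layer_model("KC_CLAW_APL_ON", odours,
                                 log_mean = nm(c(log(40), log(40 * contrast))),
                                 log_sd = 0.4, active_fraction = 0.55,
                                 gain = nm(c(1, 1 / contrast))),
    KC_CLAW_APL_OFF = layer_model("KC_CLAW_APL_OFF", odours,
                                  log_mean = nm(c(log(40), log(40 * contrast))),
                                  log_sd = 0.5, active_fraction = 0.55)
  )
}

#' Axial activation gradient
#'
#' Per-slice amplitude multipliers modelling the regionalization of
#' projection-neuron terminals (and hence of local inhibitory activation)
#' along the anterior-posterior axis of the calyx. Multipliers are in
#' `(0, 1]`.
#'
#' @param type `"uniform"`, `"linear"` or `"logistic"`.
#' @param lo,hi multiplier range (linear/logistic).
#' @param midpoint,steepness logistic parameters (slice units).
#' @param direction `"up"` (increasing with slice index) or `"down"`.
#' @return function of `n_z` returning the multiplier vector.
#' @export
gradient_spec <- function(type = c("uniform", "linear", "logistic"),
                          lo = 0.4, hi = 1.0, midpoint = 3, steepness = 1.5,
                          direction = c("up", "down")) {
  type <- match.arg(type)
  direction <- match.arg(direction)
  stopifnot(lo > 0, hi <= 1, lo <= hi)
  f <- function(n_z) {
    m <- switch(type,
      uniform = rep(hi, n_z),
      linear = seq(lo, hi, length.out = n_z),
      logistic = lo + (hi - lo) * stats::plogis(steepness * (seq_len(n_z) - midpoint)))
    if (direction == "down") m <- rev(m)
    m
  }
  structure(f, class = c("gradient_spec", "function"),
            params = list(type = type, lo = lo, hi = hi, midpoint = midpoint,
                          steepness = steepness, direction = direction))
}
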