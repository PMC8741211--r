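## End-to-end orchestration: per-movie analysis and the four experiment
## recipes (simulate -> register -> detect -> traces -> statistics), with a
## reproducibility manifest.

#' Analyse one registered or raw recording end to end
#'
#' Runs registration, minimum-image normalization, per-trial ROI detection,
#' trace extraction and trial summaries for a single movie.
#'
#' @param movie a [MovieStack].
#' @param protocol its [StimulusProtocol].
#' @param fly fly identifier carried into the summaries.
#' @param register run motion correction first (default TRUE).
#' @param max_shift_px registration search bound.
#' @param expected_diameter_um,area_band,eps detection parameters, see
#'   [detect_active_rois()].
#' @param keep_roisets retain per-trial `RoiSet`s (memory-heavy).
#' @return list `summaries` (one row per trial), `peaks` (pooled per-ROI
#'   `dF/F0%MAX` with fly/odour/trial), `shifts`, `roisets` (optional).
#' @export
analyze_movie <- function(movie, protocol, fly = 1L, register = TRUE,
                          max_shift_px = 5L, expected_diameter_um = 5,
                          area_band = c(0.25, 4), eps = 1e-6,
                          keep_roisets = FALSE) {
  shifts <- NULL
  if (register) {
    reg <- register_movie(movie, protocol, max_shift_px)
    movie <- reg$movie
    shifts <- reg$shifts
  }
  ## per-z matrix views built once; everything downstream works on them
  d <- dim(movie$data)
  mats <- lapply(seq_len(d[3]), function(z) slice_matrix(movie$data, z))
  n_trials <- nrow(protocol$trials)
  mask <- array(FALSE, d[1:3])
  mask_eroded <- mask
  resp <- lapply(seq_len(n_trials), function(i) array(0, d[1:3]))
  nmats <- vector("list", d[3])
  for (z in seq_len(d[3])) {
    m <- mats[[z]][, 1]
    for (t in seq_len(d[4])[-1]) m <- pmin(m, mats[[z]][, t])
    nmats[[z]] <- (mats[[z]] - m) / (m + eps)
    mask[, , z] <- rowMeans(mats[[z]]) > otsu_threshold(rowMeans(mats[[z]]))
    mask_eroded[, , z] <- erode_mask(mask[, , z], 2L)
    for (i in seq_len(n_trials)) {
      frames <- trial_frames(protocol, i)
      r <- nmats[[z]][, frames[1]]
      for (t in frames[-1]) r <- pmax(r, nmats[[z]][, t])
      resp[[i]][, , z] <- r
    }
  }
  bframes <- baseline_frames_idx(protocol)
  bvals <- unlist(lapply(seq_len(d[3]), function(z) {
    r <- nmats[[z]][, bframes[1]]
    for (t in bframes[-1]) r <- pmax(r, nmats[[z]][, t])
    r[as.vector(mask_eroded[, , z])]
  }))
  thr <- max(
    otsu_threshold(winsorize_top(Reduce(`+`, resp)[mask_eroded] / n_trials)),
    1.3 * stats::quantile(bvals, 0.999, names = FALSE))
  summaries <- list(); peaks <- list(); roisets <- list()
  for (i in seq_len(n_trials)) {
    rs <- detect_active_rois(movie, protocol, i, expected_diameter_um,
                             area_band, eps, region_mask = mask,
                             threshold = thr, response = resp[[i]])
    ts <- extract_traces(movie, rs, protocol, mats = mats)
    summaries[[i]] <- summarize_trial(ts, fly = fly, trial = i,
                                      odour = protocol$trials$odour[i])
    pk <- ts$peaks[ts$peaks$trial == i, , drop = FALSE]
    if (nrow(pk)) peaks[[i]] <- cbind(fly = fly, pk)
    if (keep_roisets) roisets[[i]] <- rs
  }
  list(summaries = do.call(rbind, summaries),
       peaks = if (length(peaks)) do.call(rbind, peaks) else NULL,
       shifts = shifts,
       roisets = if (keep_roisets) roisets else NULL)
}

#' Compact per-fly configuration for the layer-contrast recipes
#'
#' A ~65 um field at 0.85 um/px holding 44 MGs, yielding 20-26 active MGs
#' per odour -- comparable to a well-responding calyx section -- while
#' keeping per-fly runtime reasonable.
#'
#' @param ... overrides passed to [sim_config()].
#' @return a `sim_config`.
#' @export
contrast_config <- function(...) {
  base <- list(field_px = c(76L, 76L), pixel_size_um = 0.85, n_mg = 44L)
  do.call(sim_config, utils::modifyList(base, list(...)))
}

#' Volumetric configuration for the locality recipe
#'
#' Five z-slices sampled at ~16 Hz frame rate (3.2 volumes/s) and a ~48 um
#' field at 1.2 um/px. The inhibitory neuron's calycal arbor is modelled as
#' 40 broad (4 um radius), overlapping activation foci so the slice signal
#' is diffuse, as calcium transients of a single wide-field neurite tree
#' are; the per-odour base amplitude is deterministic (one neuron, not a
#' population).
#'
#' @param ... overrides passed to [sim_config()].
#' @return a `sim_config`.
#' @export
volumetric_config <- function(...) {
  base <- list(field_px = c(32L, 32L), pixel_size_um = 1.5, frame_rate_hz = 16,
               n_z = 5L, n_mg = 40L, mg_radius_um = 4, min_spacing_um = 3)
  do.call(sim_config, utils::modifyList(base, list(...)))
}

## Default gradient set of the locality experiment: the segregated odour's
## activation rises along z while the two colocalized odours are uniform.
locality_gradients <- function() {
  list(PA = gradient_spec("linear", lo = 0.4, hi = 1.0),
       MP = gradient_spec("uniform"),
       FA = gradient_spec("uniform"))
}

#' Run a full experiment recipe
#'
#' Executes one of the study's experiment families over simulated data and
#' returns (optionally writes) all summaries and statistics:
#'
#' * `"planar_contrast"`: `n_flies` per cell layer (PN boutons, KC claws
#'   with intact inhibition, KC claws with blocked inhibition), two odours;
#'   per layer: normality-gated paired test on per-fly mean peaks, paired
#'   test on active-ROI counts, and two-sample KS on the pooled peak
#'   distributions.
#' * `"apl_on_off"`: the two KC-claw conditions analysed as a two-factor
#'   (condition x odour) design with Tukey contrasts.
#' * `"volumetric_locality"`: `n_flies` volumetric recordings with three
#'   odours; ratio profiles for the segregated and colocalized odour pairs
#'   and their slope comparison.
#' * `"connectome_audit"`: synthetic synapse table; region filtering,
#'   reciprocal weights, weight correlations (PN, KC), bouton-localization
#'   fractions and the KC-subtype comparison.
#'
#' @param recipe recipe name.
#' @param seed master seed; every per-fly simulation seed derives from it.
#' @param n_flies flies per group.
#' @param config a `sim_config` template for the per-fly simulations
#'   (defaults: [contrast_config()] / [volumetric_config()]).
#' @param odours odour labels.
#' @param out_dir if non-NULL, results (CSV/JSON + manifest) are written
#'   there.
#' @return recipe-specific result list (invisibly contains everything
#'   written).
#' @export
run_experiment <- function(recipe = c("planar_contrast", "apl_on_off",
                                      "volumetric_locality", "connectome_audit"),
                           seed = 1L, n_flies = 10L, config = NULL,
                           odours = NULL, out_dir = NULL) {
  recipe <- match.arg(recipe)
  res <- switch(recipe,
    planar_contrast = run_planar_contrast(seed, n_flies, config, odours),
    apl_on_off = run_apl_on_off(seed, n_flies, config, odours),
    volumetric_locality = run_volumetric_locality(seed, n_flies, config),
    connectome_audit = run_connectome_audit(seed))
  res$manifest <- list(recipe = recipe, seed = seed, n_flies = n_flies,
                       package_version = as.character(utils::packageVersion("mgpipe")),
                       r_version = R.version.string,
                       timestamp = format(Sys.time(), tz = "UTC"))
  if (!is.null(out_dir)) write_experiment(res, recipe, out_dir)
  invisible(res)
}

## One simulated fly through the full planar pipeline.
simulate_and_analyze_fly <- function(config, layer, fly, seed) {
  cfg <- config
  cfg$seed <- seed
  sim <- simulate_calyx_movie(cfg, layer)
  out <- analyze_movie(sim$movie, sim$protocol, fly = fly)
  out$ground_truth <- sim$ground_truth
  out
}

## Per-fly per-odour aggregates of the trial summaries.
per_fly_odour <- function(summaries, what = "mean_peak") {
  agg <- stats::aggregate(summaries[[what]],
                          by = list(fly = summaries$fly, odour = summaries$odour),
                          FUN = mean, na.rm = TRUE)
  names(agg)[3] <- "value"
  agg
}

layer_statistics <- function(summaries, peaks, odours) {
  pf_peak <- per_fly_odour(summaries, "mean_peak")
  pf_count <- per_fly_odour(summaries, "active_roi_count")
  wide <- function(pf) {
    a <- pf$value[pf$odour == odours[1]][order(pf$fly[pf$odour == odours[1]])]
    b <- pf$value[pf$odour == odours[2]][order(pf$fly[pf$odour == odours[2]])]
    list(a = a, b = b)
  }
  wp <- wide(pf_peak); wc <- wide(pf_count)
  ## pooled peak distributions use one exposure per odour: repeated puffs of
  ## the same odour re-measure the same boutons, and double-counting them
  ## would pseudo-replicate the distribution comparison
  first_trials <- stats::aggregate(trial ~ fly + odour, peaks, min)
  pk1 <- merge(peaks, first_trials, by = c("fly", "odour", "trial"))
  list(per_fly_peaks = pf_peak, per_fly_counts = pf_count,
       paired_peak = paired_compare(wp$a, wp$b),
       paired_count = paired_compare(wc$a, wc$b),
       ks_peaks = ks_compare(pk1$dff_max[pk1$odour == odours[1]],
                             pk1$dff_max[pk1$odour == odours[2]]),
       distance = response_distance(pf_peak, odours[1], odours[2]))
}

run_planar_contrast <- function(seed, n_flies, config, odours) {
  if (is.null(config)) config <- contrast_config()
  if (is.null(odours)) odours <- c("Mch", "Oct")
  layers <- layer_presets(odours)
  out <- list()
  for (li in seq_along(layers)) {
    lname <- names(layers)[li]
    summaries <- list(); peaks <- list()
    for (f in seq_len(n_flies)) {
      fl <- simulate_and_analyze_fly(config, layers[[li]], f,
                                     child_seed(seed, (li - 1L) * n_flies + f))
      summaries[[f]] <- fl$summaries
      peaks[[f]] <- fl$peaks
    }
    summaries <- do.call(rbind, summaries)
    peaks <- do.call(rbind, peaks)
    out[[lname]] <- c(list(summaries = summaries, peaks = peaks),
                      layer_statistics(summaries, peaks, odours))
  }
  ## distance contrast: normalized KC layer vs PN input layer
  out$distance_comparison <- compare_distances(out$KC_CLAW_APL_ON$distance,
                                               out$PN_BOUTON$distance)
  out$odours <- odours
  out
}

run_apl_on_off <- function(seed, n_flies, config, odours) {
  if (is.null(config)) config <- contrast_config()
  if (is.null(odours)) odours <- c("Mch", "Oct")
  layers <- layer_presets(odours)[c("KC_CLAW_APL_ON", "KC_CLAW_APL_OFF")]
  names(layers) <- c("APL_ON", "APL_OFF")
  rows_peak <- list(); rows_count <- list(); all_peaks <- list()
  for (li in seq_along(layers)) {
    cond <- names(layers)[li]
    for (f in seq_len(n_flies)) {
      fl <- simulate_and_analyze_fly(config, layers[[li]], f,
                                     child_seed(seed, 600L + (li - 1L) * n_flies + f))
      pf <- per_fly_odour(fl$summaries, "mean_peak")
      pc <- per_fly_odour(fl$summaries, "active_roi_count")
      rows_peak[[length(rows_peak) + 1L]] <-
        data.frame(fly = paste0(cond, "_", f), condition = cond,
                   odour = pf$odour, value = pf$value)
      rows_count[[length(rows_count) + 1L]] <-
        data.frame(fly = paste0(cond, "_", f), condition = cond,
                   odour = pc$odour, value = pc$value)
      if (!is.null(fl$peaks))
        all_peaks[[length(all_peaks) + 1L]] <- cbind(condition = cond, fl$peaks)
    }
  }
  cell_table <- do.call(rbind, rows_peak)
  count_table <- do.call(rbind, rows_count)
  peaks <- do.call(rbind, all_peaks)
  first_trials <- stats::aggregate(trial ~ condition + fly + odour, peaks, min)
  pk1 <- merge(peaks, first_trials, by = c("condition", "fly", "odour", "trial"))
  list(cell_table = cell_table, count_table = count_table, peaks = peaks,
       anova_peak = two_factor_compare(cell_table),
       anova_count = two_factor_compare(count_table),
       ks_on = ks_compare(
         pk1$dff_max[pk1$condition == "APL_ON" & pk1$odour == odours[1]],
         pk1$dff_max[pk1$condition == "APL_ON" & pk1$odour == odours[2]]),
       ks_off = ks_compare(
         pk1$dff_max[pk1$condition == "APL_OFF" & pk1$odour == odours[1]],
         pk1$dff_max[pk1$condition == "APL_OFF" & pk1$odour == odours[2]]),
       odours = odours)
}

run_volumetric_locality <- function(seed, n_flies, config) {
  if (is.null(config)) config <- volumetric_config()
  grads <- locality_gradients()
  peaks <- list()
  truth <- NULL
  for (f in seq_len(n_flies)) {
    cfg <- config
    cfg$seed <- child_seed(seed, 900L + f)
    sim <- simulate_volumetric_movie(cfg, grads)
    reg <- register_movie(sim$movie, sim$protocol)
    pk <- zslice_peaks(reg$movie, sim$protocol)
    peaks[[f]] <- cbind(fly = f, pk)
    truth <- sim$ground_truth
  }
  peaks <- do.call(rbind, peaks)
  prof_seg <- ratio_profile(peaks, "PA", "MP")
  prof_col <- ratio_profile(peaks, "FA", "MP")
  slopes <- compare_slopes(prof_seg, prof_col)
  true_ratio <- truth$slice_amplitude["PA", ] / truth$slice_amplitude["MP", ]
  list(peaks = peaks, profile_segregated = prof_seg,
       profile_colocalized = prof_col, slopes = slopes,
       true_ratio_profile = true_ratio,
       true_slope = profile_slope(true_ratio))
}

run_connectome_audit <- function(seed) {
  sim <- simulate_synapse_table(seed = seed)
  ca <- filter_region(sim$synapses, "CA(R)")
  w <- reciprocal_weights(ca, "APL", sim$neuron_meta)
  pn_ids <- w$neuron_id[w$class == "PN" & w$interacting]
  kc <- sim$neuron_meta[sim$neuron_meta$class == "KC", ]
  fr_pn <- compartment_fractions(ca, "APL", "from_hub", "bouton",
                                 neurons = w$neuron_id[w$class == "PN"])
  fr_kc <- compartment_fractions(ca, "APL", "from_hub", "claw",
                                 neurons = w$neuron_id[w$class == "KC"])
  kc_fr <- merge(fr_kc$per_neuron, kc[, c("neuron_id", "subtype")],
                 by = "neuron_id")
  list(table = sim, weights = w,
       correlation_pn = weight_correlation(w, "PN"),
       correlation_kc = weight_correlation(w, "KC"),
       bouton_fractions = fr_pn, claw_fractions = fr_kc,
       subtype_compare = subtype_localization_compare(kc_fr, n_per_group = 70L,
                                                      seed = seed),
       n_interacting_pn = length(pn_ids),
       n_pn_total = sum(sim$neuron_meta$class == "PN"),
       n_interacting_kc = sum(w$class == "KC" & w$interacting),
       n_kc_total = sum(sim$neuron_meta$class == "KC"))
}

## Serialize an experiment's tables and stats to out_dir.
write_experiment <- function(res, recipe, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  drop_heavy <- function(x) {
    if (is.list(x) && !is.data.frame(x))
      lapply(x[!vapply(x, function(e)
        inherits(e, c("MovieStack", "lm", "RoiSet", "TraceSet", "function")),
        logical(1))], drop_heavy)
    else x
  }
  for (nm in names(res)) {
    el <- res[[nm]]
    if (is.data.frame(el))
      utils::write.csv(el, file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
  }
  jsonlite::write_json(drop_heavy(res), file.path(out_dir, paste0(recipe, "_results.json")),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       na = "null")
  invisible(out_dir)
}
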