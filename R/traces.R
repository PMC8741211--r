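## Per-ROI trace extraction and dF/F0 statistics.

#' Extract per-ROI dF/F0 traces
#'
#' For every ROI in the set, the raw trace is the unweighted mean intensity
#' over the ROI's pixels per frame; `F0` is the mean of the trace over the
#' protocol's baseline window (the first 30 frames by default), and
#' `dff(t) = 100 * (F(t) - F0) / F0`. `dff_max` is the within-window maximum
#' of `dff` for each trial, with no smoothing.
#'
#' @param movie a registered [MovieStack].
#' @param roiset a `RoiSet` from [detect_active_rois()].
#' @param protocol the [StimulusProtocol].
#' @param mats optional precomputed per-z-slice pixel-by-frame matrices of
#'   `movie$data` (an internal fast path for repeated extraction).
#' @return object of class `TraceSet`: list with `F` (ROIs x T raw traces),
#'   `F0`, `dff` (ROIs x T, %), `peaks` (data.frame `roi`, `trial`, `odour`,
#'   `dff_max`), `trial` (the trial the mask came from) and `excluded`
#'   (ROI ids flagged for non-positive F0).
#' @export
extract_traces <- function(movie, roiset, protocol, mats = NULL) {
  d <- dim(movie$data)
  n_roi <- nrow(roiset$rois)
  if (n_roi == 0L) {
    return(structure(list(F = matrix(numeric(), 0, d[4]), F0 = numeric(),
                          dff = matrix(numeric(), 0, d[4]),
                          peaks = data.frame(roi = integer(), trial = integer(),
                                             odour = character(),
                                             dff_max = numeric()),
                          trial = roiset$trial, excluded = integer()),
                     class = "TraceSet"))
  }
  lab_vec <- as.vector(roiset$labels)
  sel <- which(lab_vec > 0L)
  grp <- lab_vec[sel]
  area <- tabulate(grp, n_roi)
  npx2d <- d[1] * d[2]
  Fm <- if (is.null(mats)) {
    matrix(movie$data, prod(d[1:3]), d[4])[sel, , drop = FALSE]
  } else {
    do.call(rbind, lapply(seq_len(d[3]), function(z) {
      j <- sel[(sel - 1L) %/% npx2d + 1L == z] - (z - 1L) * npx2d
      mats[[z]][j, , drop = FALSE]
    }))
  }
  Ftr <- rowsum(Fm, grp) / area
  dimnames(Ftr) <- NULL
  F0 <- rowMeans(Ftr[, baseline_frames_idx(protocol), drop = FALSE])
  excluded <- which(F0 <= 0)
  dff <- 100 * (Ftr - F0) / F0
  if (length(excluded)) {
    dff[excluded, ] <- NA_real_
    warning(length(excluded), " ROI(s) with non-positive F0 excluded")
  }
  keep <- setdiff(seq_len(n_roi), excluded)
  peaks <- do.call(rbind, lapply(seq_len(nrow(protocol$trials)), function(i) {
    w <- trial_frames(protocol, i)
    data.frame(roi = keep, trial = i, odour = protocol$trials$odour[i],
               dff_max = apply(dff[keep, w, drop = FALSE], 1, max))
  }))
  structure(list(F = Ftr, F0 = F0, dff = dff, peaks = peaks,
                 trial = roiset$trial, excluded = excluded),
            class = "TraceSet")
}

#' Summarize one odour-exposure trial
#'
#' The trial's activity summary: the number of active ROIs and the mean of
#' their peak responses (`mean_peak`), i.e. the average `dF/F0%MAX` among all
#' active ROIs of that odour exposure. With no active ROIs, `mean_peak` is
#' `NaN`.
#'
#' @param traceset a `TraceSet` (its own trial is summarized by default).
#' @param fly fly / animal identifier.
#' @param trial trial index (defaults to the trace set's own trial).
#' @param odour odour label of the trial; taken from the peaks table when
#'   `NULL` (empty trials then carry `NA`).
#' @return one-row data.frame: `fly`, `odour`, `trial`, `active_roi_count`,
#'   `mean_peak`.
#' @export
summarize_trial <- function(traceset, fly = NA, trial = traceset$trial,
                            odour = NULL) {
  pk <- traceset$peaks[traceset$peaks$trial == trial, , drop = FALSE]
  data.frame(fly = fly,
             odour = odour %||% (if (nrow(pk)) pk$odour[1] else NA_character_),
             trial = trial,
             active_roi_count = nrow(pk),
             mean_peak = if (nrow(pk)) mean(pk$dff_max) else NaN)
}

#' Correct a measured peak for footprint dilution and frame sampling
#'
#' The mean trace over an ROI's pixels dilutes the true centre amplitude by
#' the baseline-weighted mean of the MG footprint over those pixels, and the
#' sampled maximum of the transient kernel sits slightly below its continuous
#' unit peak. Given the known footprint (centre, radius) and kernel, both
#' factors are computable, so the ground-truth amplitude can be recovered
#' from `dff_max` on noiseless data.
#'
#' @param dff_max measured peak (%).
#' @param roi_pixels 2-column matrix of (y, x) pixel coordinates of the ROI.
#' @param centre true MG centre `(y, x)` in pixels.
#' @param radius_px MG radius in pixels.
#' @param weights per-pixel baseline weights (e.g. the minimum image values
#'   at `roi_pixels`); unweighted if `NULL`.
#' @param kernel_peak sampled kernel maximum (see
#'   `ground_truth$kernel_peak`), 1 for continuous sampling.
#' @return corrected amplitude estimate (%).
#' @export
correct_peak_dilution <- function(dff_max, roi_pixels, centre, radius_px,
                                  weights = NULL, kernel_peak = 1) {
  r <- sqrt((roi_pixels[, 1] - centre[1])^2 + (roi_pixels[, 2] - centre[2])^2)
  g <- mg_footprint_value(r, radius_px)
  if (is.null(weights)) weights <- rep(1, length(g))
  dilution <- sum(weights * g) / sum(weights)
  dff_max / (dilution * kernel_peak)
}
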