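#' Fluorescence movie container
#'
#' A `MovieStack` bundles a non-negative fluorescence array with its spatial
#' and temporal calibration. Planar recordings have a single z-slice;
#' volumetric recordings store the slices of each time point together, so the
#' array is indexed `[y, x, z, t]`.
#'
#' @param data numeric array `Y x X x Z x T` (a `Y x X x T` array or a list of
#'   frames is promoted to `Z = 1`).
#' @param pixel_size_um pixel size in micrometres per pixel (> 0).
#' @param frame_rate_hz frames (planar) or volumes (volumetric) per second.
#' @param z_step_um spacing between z-slices in micrometres.
#' @return object of class `MovieStack`.
#' @examples
#' m <- MovieStack(array(1, c(4, 4, 1, 10)), pixel_size_um = 0.5,
#'                 frame_rate_hz = 9)
#' dim(m$data)
#' @export
MovieStack <- function(data, pixel_size_um, frame_rate_hz, z_step_um = 1) {
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data)[1:2], 1L, dim(data)[3])
  stopifnot(length(dim(data)) == 4L)
  if (any(data < 0)) stop("MovieStack: fluorescence values must be >= 0")
  if (pixel_size_um <= 0 || frame_rate_hz <= 0 || z_step_um <= 0)
    stop("MovieStack: calibration fields must be > 0")
  structure(list(data = data, pixel_size_um = pixel_size_um,
                 frame_rate_hz = frame_rate_hz, z_step_um = z_step_um),
            class = "MovieStack")
}

#' @export
print.MovieStack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("MovieStack: %d x %d px, %d z-slice(s), %d frames @ %.2f Hz, %.3g um/px\n",
              d[1], d[2], d[3], d[4], x$frame_rate_hz, x$pixel_size_um))
  invisible(x)
}

n_frames <- function(movie) dim(movie$data)[4]
n_zslices <- function(movie) dim(movie$data)[3]

#' Stimulus protocol
#'
#' Ordered odour-puff trials with a baseline window. Frame indices are
#' 0-based and trial windows half-open `[onset, offset)`, the convention used
#' by every exported artefact; internal code converts where needed. The
#' baseline window (default: the first 30 frames of the recording) defines
#' F0 for all dF/F0 computations.
#'
#' @param trials data.frame with columns `odour`, `puff`, `onset`, `offset`,
#'   `window_end` (analysis window is `[onset, window_end)`).
#' @param baseline_frames number of baseline frames preceding the first puff.
#' @param frame_rate_hz sampling rate the frame indices refer to.
#' @param n_frames total recording length; trials must fit inside it.
#' @param randomized whether the odour order was randomized.
#' @return object of class `StimulusProtocol`.
#' @export
StimulusProtocol <- function(trials, baseline_frames = 30L, frame_rate_hz = 9,
                             n_frames = NULL, randomized = FALSE) {
  stopifnot(all(c("odour", "puff", "onset", "offset", "window_end") %in% names(trials)))
  trials <- trials[order(trials$onset), , drop = FALSE]
  if (baseline_frames <= 0 || baseline_frames > trials$onset[1])
    stop("StimulusProtocol: baseline frames must precede the first puff onset")
  if (any(trials$onset >= trials$offset))
    stop("StimulusProtocol: onset must precede offset")
  if (nrow(trials) > 1 && any(utils::head(trials$offset, -1) > utils::tail(trials$onset, -1)))
    stop("StimulusProtocol: trial windows overlap")
  if (!is.null(n_frames) && any(trials$window_end > n_frames))
    stop("StimulusProtocol: trials exceed recording length")
  structure(list(trials = trials, baseline_frames = as.integer(baseline_frames),
                 frame_rate_hz = frame_rate_hz, n_frames = n_frames,
                 randomized = randomized),
            class = "StimulusProtocol")
}

#' @export
print.StimulusProtocol <- function(x, ...) {
  cat(sprintf("StimulusProtocol: %d trials (%s), baseline %d frames\n",
              nrow(x$trials), paste(unique(x$trials$odour), collapse = ", "),
              x$baseline_frames))
  invisible(x)
}

#' Build an odour-puff protocol
#'
#' Baseline window, then for each odour `n_puffs` puffs of `puff_s` seconds
#' separated by `gap_s` of clean air, with a short recording tail after the
#' last puff. Each puff is one trial; a trial's analysis window runs to the
#' next onset (the clean-air interval belongs to the preceding puff).
#'
#' @param odours odour labels in presentation order.
#' @param frame_rate_hz sampling rate (frames or volumes per second).
#' @param baseline_frames frames before the first onset.
#' @param n_puffs puffs per odour.
#' @param puff_s,gap_s,tail_s puff length, clean-air gap and recording tail
#'   in seconds.
#' @param randomized whether `odours` was randomized (recorded as metadata).
#' @return a [StimulusProtocol] whose `n_frames` is the implied recording
#'   length.
#' @export
make_protocol <- function(odours, frame_rate_hz, baseline_frames = 30L,
                          n_puffs = 2L, puff_s = 5, gap_s = 20, tail_s = 10,
                          randomized = FALSE) {
  puff_f <- s_to_frames(puff_s, frame_rate_hz)
  gap_f <- s_to_frames(gap_s, frame_rate_hz)
  tail_f <- s_to_frames(tail_s, frame_rate_hz)
  onset <- as.integer(baseline_frames)
  rows <- list()
  for (od in odours) {
    for (p in seq_len(n_puffs)) {
      rows[[length(rows) + 1L]] <- data.frame(
        odour = od, puff = p, onset = onset, offset = onset + puff_f)
      onset <- onset + puff_f + gap_f
    }
  }
  tr <- do.call(rbind, rows)
  ## analysis window: up to the next onset (the clean-air interval belongs to
  ## the preceding puff), truncated for the final trial
  nf <- tr$offset[nrow(tr)] + tail_f
  tr$window_end <- c(utils::tail(tr$onset, -1), nf)
  StimulusProtocol(tr, baseline_frames, frame_rate_hz, n_frames = nf,
                   randomized = randomized)
}

## 1-based frame indices of the analysis window of trial i.
trial_frames <- function(protocol, i) {
  tr <- protocol$trials[i, ]
  seq.int(tr$onset + 1L, tr$window_end)
}

## 1-based baseline frame indices.
baseline_frames_idx <- function(protocol) seq_len(protocol$baseline_frames)
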