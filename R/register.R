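## Rigid translation-only motion correction.

## Integer-shift cross-correlation via FFT against a precomputed conjugate
## template spectrum. Returns the (dy, dx) that maximizes correlation of
## translate(frame, dy, dx) with the template, searched within +-max_shift.
estimate_shift <- function(frame, template_fft_conj, max_shift) {
  a <- frame - mean(frame)
  cc <- Re(stats::fft(Conj(stats::fft(a)) * Conj(template_fft_conj),
                      inverse = TRUE))
  ny <- nrow(frame); nx <- ncol(frame)
  sh <- -max_shift:max_shift
  iy <- ifelse(sh >= 0, sh + 1L, ny + sh + 1L)
  ix <- ifelse(sh >= 0, sh + 1L, nx + sh + 1L)
  sub <- cc[iy, ix, drop = FALSE]
  k <- arrayInd(which.max(sub), dim(sub))
  c(dy = sh[k[1]], dx = sh[k[2]])
}

#' Rigid motion correction of a movie
#'
#' Estimates an integer-pixel translation per frame by cross-correlation with
#' a reference template (the mean of the baseline frames, a lower-noise
#' template than any single frame) and translates each frame to align it.
#' Because residual drift within the baseline window blurs the template and
#' can bias every estimate by a common offset, the estimated shifts are
#' re-referenced so that the median baseline-frame shift is zero. Volumetric
#' movies share one shift per volume, estimated on the z-mean. Vacated
#' pixels are filled with the frame median. No subpixel interpolation is
#' performed: the downstream detector thresholds a maximum image, and at the
#' 5 um ROI scale integer shifts avoid interpolation artefacts.
#'
#' @param movie a [MovieStack].
#' @param protocol a [StimulusProtocol]; its baseline window defines the
#'   template. If `NULL`, the first 30 frames are used.
#' @param max_shift_px largest correction applied; larger estimates are
#'   clamped, flagged and warned about.
#' @return list with `movie` (registered [MovieStack]) and `shifts`
#'   (data.frame `frame` (0-based), `dy`, `dx`, `clamped`). The shifts are
#'   the applied corrections: a scene displaced by `(+3, -2)` px yields
#'   shifts `(-3, +2)`.
#' @export
register_movie <- function(movie, protocol = NULL, max_shift_px = 5L) {
  d <- dim(movie$data)
  ny <- d[1]; nx <- d[2]; nz <- d[3]; nt <- d[4]
  if (nt < 2) stop("register_movie: need at least two frames")
  nb <- if (is.null(protocol)) min(30L, nt) else protocol$baseline_frames
  ## z-mean view, one column per frame
  zm <- movie$data
  dim(zm) <- c(ny * nx, nz, nt)
  if (nz > 1L) {
    s <- zm[, 1L, ]
    for (z in 2:nz) s <- s + zm[, z, ]
    zm <- s / nz
  } else {
    dim(zm) <- c(ny * nx, nt)
  }
  search <- max_shift_px + 2L
  ## estimation uses a central 64 x 64 crop when that still covers most of
  ## the field: sharp structure (the boundary of the imaged region) must
  ## stay inside the window, because during clean-air intervals the smooth
  ## interior alone gives too flat a correlation peak to lock on
  md <- min(ny, nx)
  crop <- if (md > 64L && 64L >= 0.8 * md) 64L else md
  cy0 <- (ny - crop) %/% 2L; cx0 <- (nx - crop) %/% 2L
  crop_idx <- as.vector(outer((cy0 + 1L):(cy0 + crop),
                              (cx0 + (1L:crop) - 1L) * ny, "+"))
  frame_of <- function(t) matrix(zm[crop_idx, t], crop, crop)
  ## pass 1: mutually align the baseline frames against their raw mean (a
  ## blurred template biases all estimates by a common offset, which cancels
  ## in the relative alignment used here)
  template <- matrix(0, crop, crop)
  for (t in seq_len(nb)) template <- template + frame_of(t)
  template <- template / nb
  tf <- Conj(stats::fft(template - mean(template)))
  b_shift <- matrix(0L, nb, 2)
  for (t in seq_len(nb))
    b_shift[t, ] <- estimate_shift(frame_of(t), tf, search)
  ## pass 2: sharp template from the re-aligned baseline frames
  template2 <- matrix(0, crop, crop)
  for (t in seq_len(nb)) {
    fr <- frame_of(t)
    template2 <- template2 + shift_frame(fr, b_shift[t, 1], b_shift[t, 2],
                                         stats::median(fr))
  }
  template2 <- template2 / nb
  tf2 <- Conj(stats::fft(template2 - mean(template2)))
  shifts <- matrix(0L, nt, 2)
  for (t in seq_len(nt))
    shifts[t, ] <- estimate_shift(frame_of(t), tf2, search)
  ## anchor: the first frame is the reference (shift exactly zero)
  shifts <- sweep(shifts, 2, shifts[1, ])
  clamped <- abs(shifts[, 1]) > max_shift_px | abs(shifts[, 2]) > max_shift_px
  shifts <- pmax(pmin(shifts, max_shift_px), -max_shift_px)
  out <- movie$data
  for (t in seq_len(nt)) {
    if (shifts[t, 1] != 0L || shifts[t, 2] != 0L) {
      for (z in seq_len(nz)) {
        fr <- out[, , z, t]
        out[, , z, t] <- shift_frame(fr, shifts[t, 1], shifts[t, 2],
                                     stats::median(fr))
      }
    }
  }
  if (any(clamped))
    warning(sum(clamped), " frame(s) exceeded max_shift_px; shifts clamped")
  reg <- MovieStack(out, movie$pixel_size_um, movie$frame_rate_hz, movie$z_step_um)
  list(movie = reg,
       shifts = data.frame(frame = seq_len(nt) - 1L,
                           dy = shifts[, 1], dx = shifts[, 2],
                           clamped = clamped))
}
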