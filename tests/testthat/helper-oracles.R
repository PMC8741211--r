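## Independent brute-force oracles and small fixture builders shared across
## the test files. The oracles deliberately use different code paths than
## the implementation (apply/loops vs vectorized accumulation).

## Pixelwise minimum over frames via apply (per z-slice).
oracle_min_image <- function(movie) {
  d <- dim(movie$data)
  out <- array(0, d[1:3])
  for (z in seq_len(d[3]))
    out[, , z] <- apply(movie$data[, , z, , drop = FALSE], c(1, 2), min)
  out
}

## Elementwise (F - M) / (M + eps) via explicit loops.
oracle_normalize <- function(movie, min_img, eps) {
  d <- dim(movie$data)
  out <- array(NA_real_, d)
  for (t in seq_len(d[4])) for (z in seq_len(d[3]))
    out[, , z, t] <- (movie$data[, , z, t] - min_img[, , z]) /
      (min_img[, , z] + eps)
  out
}

## Otsu by exhaustive search over all 255 interior bin edges, recomputing
## class weights and means directly at each candidate; ties (flat criterion
## across an empty valley) resolved to the centre of the tied run, as in the
## implementation's contract.
oracle_otsu <- function(x, n_bins = 256L) {
  x <- as.vector(x)
  edges <- seq(min(x), max(x), length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1L), n_bins)
  mids <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  v <- mids[bin]
  bcv <- rep(-Inf, n_bins - 1L)
  for (k in 2:n_bins) {
    lo <- v[bin < k]; hi <- v[bin >= k]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(v); w1 <- 1 - w0
    bcv[k - 1L] <- w0 * w1 * (mean(lo) - mean(hi))^2
  }
  tied <- which(bcv >= max(bcv) * (1 - 1e-9))
  mean(edges[tied + 1L])
}

## Tiny fast simulation config (short protocol; not the study protocol --
## unit tests exercise code paths, not study conditions).
tiny_config <- function(...) {
  base <- list(field_px = c(32L, 32L), pixel_size_um = 0.85, n_mg = 4L,
               n_puffs = 1L, gap_s = 6, tail_s = 3, baseline_frames = 10L,
               motion_max_px = 0L)
  do.call(sim_config, utils::modifyList(base, list(...)))
}

## Noiseless variant of any config.
noiseless <- function(cfg) {
  cfg$photon_gain <- 0; cfg$read_noise_sd <- 0
  cfg$bleach_per_s <- 0; cfg$motion_max_px <- 0L
  cfg
}

## Two-odour layer with fixed (degenerate) amplitude for every MG.
fixed_layer <- function(amp = 50, odours = c("Mch", "Oct"), active = 1) {
  layer_model("PN_BOUTON", odours,
              log_mean = stats::setNames(rep(log(amp), 2), odours),
              log_sd = 0, active_fraction = active)
}

## Minimal two-trial protocol for hand-built movies.
tiny_protocol <- function(n_frames, baseline = 10L, rate = 9) {
  onset1 <- baseline
  width <- (n_frames - baseline) %/% 2L
  tr <- data.frame(odour = c("A", "B"), puff = 1L,
                   onset = c(onset1, onset1 + width),
                   offset = c(onset1 + 5L, onset1 + width + 5L),
                   window_end = c(onset1 + width, n_frames))
  StimulusProtocol(tr, baseline, rate, n_frames = n_frames)
}
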