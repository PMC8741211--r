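## Synthetic calcium-movie generator.
##
## Forward model per pixel:
##   F(t, x) = B(x) * bleach(t) * (1 + sum_mg a_mg(odour) * G_mg(x) * k(t)) + noise
## with B a heterogeneous baseline (bright inside the elliptical calyx field,
## dim outside), G_mg a compact isotropic footprint, k a
## difference-of-exponentials transient normalized to unit peak and launched
## at each puff onset, rigid random-walk motion, and Gaussian noise with
## variance = photon_gain * signal + read_noise^2.

## Unit-peak difference-of-exponentials transient, t in seconds from onset.
transient_kernel <- function(t, rise_s, decay_s) {
  tpk <- log(decay_s / rise_s) * rise_s * decay_s / (decay_s - rise_s)
  peak <- exp(-tpk / decay_s) - exp(-tpk / rise_s)
  k <- (exp(-t / decay_s) - exp(-t / rise_s)) / peak
  k[t < 0] <- 0
  k
}

## Maximum of the kernel on the sampled frame grid (onsets fall on frame
## boundaries, so this factor is shared by every trial).
kernel_sampled_peak <- function(config) {
  t <- seq(0, 5 * config$decay_s, by = 1 / config$frame_rate_hz)
  max(transient_kernel(t, config$rise_s, config$decay_s))
}

## MG centre placement: rejection sampling inside the elliptical field with
## minimum centre spacing. Errors out if the field cannot host n_mg centres.
place_mg_centres <- function(config) {
  ny <- config$field_px[1]; nx <- config$field_px[2]
  r_px <- config$mg_radius_um / config$pixel_size_um
  spacing_px <- config$min_spacing_um / config$pixel_size_um
  semi_y <- 0.475 * ny - r_px; semi_x <- 0.475 * nx - r_px
  if (semi_y <= 0 || semi_x <= 0)
    stop("field too small for the MG radius")
  cy <- (ny + 1) / 2; cx <- (nx + 1) / 2
  pts <- matrix(NA_real_, config$n_mg, 2)
  n_placed <- 0L
  for (attempt in seq_len(20000L * config$n_mg)) {
    y <- stats::runif(1, cy - semi_y, cy + semi_y)
    x <- stats::runif(1, cx - semi_x, cx + semi_x)
    if (((y - cy) / semi_y)^2 + ((x - cx) / semi_x)^2 > 1) next
    if (n_placed > 0L) {
      d2 <- (pts[seq_len(n_placed), 1] - y)^2 + (pts[seq_len(n_placed), 2] - x)^2
      if (min(d2) < spacing_px^2) next
    }
    n_placed <- n_placed + 1L
    pts[n_placed, ] <- c(y, x)
    if (n_placed == config$n_mg) return(pts)
  }
  stop("configuration error: field cannot accommodate ", config$n_mg,
       " MG centres at minimum spacing ", config$min_spacing_um, " um")
}

## Compact super-Gaussian footprint: G(r) = exp(-ln(20) * (r/R)^4), so the
## full width at 5% of peak equals the MG diameter 2R. The sharp fall-off
## keeps adjacent MGs from bridging above threshold into merged components.
## Returned as a dense npx x n_mg matrix (entries below 0.005 are zero).
mg_footprint_matrix <- function(centres, config) {
  ny <- config$field_px[1]; nx <- config$field_px[2]
  r_px <- config$mg_radius_um / config$pixel_size_um
  cutoff <- r_px * (log(200) / log(20))^0.25
  G <- matrix(0, ny * nx, nrow(centres))
  for (m in seq_len(nrow(centres))) {
    y0 <- centres[m, 1]; x0 <- centres[m, 2]
    ys <- max(1L, floor(y0 - cutoff)):min(ny, ceiling(y0 + cutoff))
    xs <- max(1L, floor(x0 - cutoff)):min(nx, ceiling(x0 + cutoff))
    r2 <- outer((ys - y0)^2, (xs - x0)^2, "+")
    g <- exp(-log(20) * (r2 / r_px^2)^2)
    g[g < 0.005] <- 0
    G[as.vector(outer(ys, (xs - 1L) * ny, "+")), m] <- as.vector(g)
  }
  G
}

## Footprint value at radius r (used for dilution correction downstream).
mg_footprint_value <- function(r_px, radius_px) {
  g <- exp(-log(20) * (r_px^2 / radius_px^2)^2)
  ifelse(g < 0.005, 0, g)
}

## Heterogeneous baseline image.
baseline_image <- function(config) {
  ny <- config$field_px[1]; nx <- config$field_px[2]
  mask <- ellipse_mask(ny, nx)
  B <- matrix(config$outside_frac * config$baseline_mean, ny, nx)
  het <- 1 + config$baseline_sd_frac * smooth_field(ny, nx)
  B[mask] <- config$baseline_mean * pmax(het[mask], 0.2)
  B
}

## Reflected random walk of integer shifts, one (dy, dx) row per frame.
motion_walk <- function(n, max_px, step_p) {
  if (max_px <= 0) return(matrix(0L, n, 2))
  step <- function() {
    s <- stats::rbinom(n, 1, step_p) * sample(c(-1L, 1L), n, replace = TRUE)
    w <- cumsum(c(0L, s[-n]))  # recording starts at the reference position
    ## reflect at +-max_px
    per <- 4L * max_px
    w <- w %% per
    w <- ifelse(w > 2L * max_px, w - per, w)
    as.integer(ifelse(w > max_px, 2L * max_px - w,
                      ifelse(w < -max_px, -2L * max_px - w, w)))
  }
  cbind(dy = step(), dx = step())
}

## Translate one frame (matrix) by integer (dy, dx); vacated pixels get fill.
shift_frame <- function(fr, dy, dx, fill) {
  if (dy == 0 && dx == 0) return(fr)
  ny <- nrow(fr); nx <- ncol(fr)
  out <- matrix(fill, ny, nx)
  ys <- seq_len(ny) - dy; xs <- seq_len(nx) - dx
  oky <- ys >= 1 & ys <= ny; okx <- xs >= 1 & xs <= nx
  out[oky, okx] <- fr[ys[oky], xs[okx]]
  out
}

## Per-trial kernel rows: n_mg x T matrix of summed transients, one row per
## MG, using amplitude matrix amp_frac (n_mg x n_odours, fractional dF/F0).
build_dff_matrix <- function(amp_frac, odours, protocol, config, n_t) {
  K <- matrix(0, nrow(amp_frac), n_t)
  rate <- protocol$frame_rate_hz
  for (i in seq_len(nrow(protocol$trials))) {
    tr <- protocol$trials[i, ]
    frames <- (tr$onset + 1L):n_t
    kt <- transient_kernel((frames - 1L - tr$onset) / rate,
                           config$rise_s, config$decay_s)
    a <- amp_frac[, match(tr$odour, odours)]
    K[, frames] <- K[, frames] + a %o% kt
  }
  K
}

## Assemble, move and degrade the ideal movie; returns npx x T matrix.
render_movie_matrix <- function(B, S, config, walk, rate_hz) {
  npx <- length(B); n_t <- ncol(S)
  Fm <- as.vector(B) * (1 + S)
  if (config$bleach_per_s > 0) {
    bleach <- exp(-config$bleach_per_s * (seq_len(n_t) - 1L) / rate_hz)
    Fm <- Fm * rep(bleach, each = npx)
  }
  if (any(walk != 0L)) {
    dim_b <- dim(B)
    fill <- stats::median(B)
    for (t in seq_len(n_t)) {
      if (walk[t, 1] != 0L || walk[t, 2] != 0L) {
        fr <- matrix(Fm[, t], dim_b[1], dim_b[2])
        Fm[, t] <- shift_frame(fr, walk[t, 1], walk[t, 2], fill)
      }
    }
  }
  if (config$photon_gain > 0 || config$read_noise_sd > 0) {
    ## Fm >= 0 by construction (B >= 0, S >= 0, bleach > 0)
    Fm <- Fm + stats::rnorm(length(Fm)) * sqrt(config$photon_gain * Fm +
                                                 config$read_noise_sd^2)
    Fm[Fm < 0] <- 0
  }
  Fm
}

#' Simulate a planar calyx recording
#'
#' Generates a single-plane two-photon movie of odour-evoked microglomerular
#' activity with known ground truth: MG centres, per-odour peak amplitudes
#' and active flags, the true motion trajectory, and the noiseless baseline
#' image. Identical `config$seed` gives a bit-identical movie.
#'
#' @param config a [sim_config()].
#' @param layer a [layer_model()] describing per-odour amplitudes.
#' @param odours distinct odour labels (default the layer's odours).
#' @return list with elements `movie` ([MovieStack]), `protocol`
#'   ([StimulusProtocol]) and `ground_truth` (list: `mg` data.frame, `motion`,
#'   `baseline_img`, `odour_order`, `kernel_peak`).
#' @examples
#' cfg <- sim_config(field_px = c(48, 48), n_mg = 6, seed = 2,
#'                   motion_max_px = 0)
#' sim <- simulate_calyx_movie(cfg, layer_presets()$PN_BOUTON)
#' sim$movie
#' @export
simulate_calyx_movie <- function(config, layer, odours = layer$odours) {
  stopifnot(inherits(config, "sim_config"), inherits(layer, "layer_model"))
  if (anyDuplicated(odours)) stop("odour labels must be distinct")
  set.seed(config$seed)
  order <- if (config$randomize_order) sample(odours) else odours
  protocol <- make_protocol(order, config$frame_rate_hz, config$baseline_frames,
                            config$n_puffs, config$puff_s, config$gap_s,
                            config$tail_s, randomized = config$randomize_order)
  n_t <- protocol$n_frames
  centres <- place_mg_centres(config)
  ## per-odour amplitudes (%), zero if inactive or below the floor; the
  ## log-amplitude decomposes into a per-MG responsiveness factor shared
  ## across odours plus an odour-specific part (marginals stay log-normal
  ## with sd = log_sd)
  amp <- matrix(0, config$n_mg, length(odours),
                dimnames = list(NULL, odours))
  sd_shared <- layer$log_sd * sqrt(layer$cross_odour_cor)
  sd_idio <- layer$log_sd * sqrt(1 - layer$cross_odour_cor)
  z_shared <- stats::rnorm(config$n_mg)
  for (od in odours) {
    act <- stats::runif(config$n_mg) < layer$active_fraction
    a <- exp(layer$effective_log_mean[od] + sd_shared * z_shared +
               sd_idio * stats::rnorm(config$n_mg))
    a[!act | a <= config$amplitude_floor] <- 0
    amp[, od] <- a
  }
  G <- mg_footprint_matrix(centres, config)
  K <- build_dff_matrix(amp / 100, odours, protocol, config, n_t)
  S <- G %*% K
  B <- baseline_image(config)
  walk <- motion_walk(n_t, config$motion_max_px, config$motion_step_p)
  Fm <- render_movie_matrix(B, S, config, walk, config$frame_rate_hz)
  movie <- MovieStack(array(Fm, c(config$field_px[1], config$field_px[2], 1L, n_t)),
                      config$pixel_size_um, config$frame_rate_hz, config$z_step_um)
  mg <- data.frame(mg_id = seq_len(config$n_mg),
                   y_px = centres[, 1], x_px = centres[, 2],
                   y_um = centres[, 1] * config$pixel_size_um,
                   x_um = centres[, 2] * config$pixel_size_um,
                   radius_um = config$mg_radius_um)
  for (od in odours) {
    mg[[paste0("amp_", od)]] <- amp[, od]
    mg[[paste0("active_", od)]] <- amp[, od] > config$amplitude_floor
  }
  list(movie = movie, protocol = protocol,
       ground_truth = list(mg = mg,
                           motion = data.frame(frame = seq_len(n_t) - 1L,
                                               dy = walk[, 1], dx = walk[, 2]),
                           baseline_img = B, odour_order = order,
                           kernel_peak = kernel_sampled_peak(config),
                           config = config, layer = layer$layer))
}

#' Simulate a volumetric calyx recording with axial activation gradients
#'
#' Emulates volumetric imaging of the global inhibitory (APL) response:
#' 3D stacks of `config$n_z` slices acquired over time at a volume rate of
#' `frame_rate_hz / n_z`. Each odour has a deterministic base amplitude (the
#' APL is a single neuron) and a per-slice multiplier from its
#' [gradient_spec()], so the true per-slice amplitude is
#' `amplitude[odour] * multiplier[z]`.
#'
#' @param config a [sim_config()] with `n_z > 1`.
#' @param gradients named list (one [gradient_spec()] per odour).
#' @param amplitudes named numeric, base peak dF/F0 (%) per odour.
#' @return list `movie`, `protocol`, `ground_truth` (with `multipliers` and
#'   `slice_amplitude`, both odour x slice).
#' @export
simulate_volumetric_movie <- function(config,
                                      gradients,
                                      amplitudes = c(PA = 100, MP = 80, FA = 90)) {
  odours <- names(amplitudes)
  stopifnot(config$n_z >= 2, !is.null(odours),
            setequal(names(gradients), odours))
  set.seed(config$seed)
  vol_rate <- config$frame_rate_hz / config$n_z
  order <- if (config$randomize_order) sample(odours) else odours
  protocol <- make_protocol(order, vol_rate, config$baseline_frames,
                            config$n_puffs, config$puff_s, config$gap_s,
                            config$tail_s, randomized = config$randomize_order)
  n_t <- protocol$n_frames
  centres <- place_mg_centres(config)
  G <- mg_footprint_matrix(centres, config)
  mult <- t(vapply(odours, function(od) gradients[[od]](config$n_z),
                   numeric(config$n_z)))
  if (any(mult <= 0) || any(mult > 1))
    stop("gradient multipliers must lie in (0, 1]")
  walk <- motion_walk(n_t, config$motion_max_px, config$motion_step_p)
  ny <- config$field_px[1]; nx <- config$field_px[2]
  dat <- array(0, c(ny, nx, config$n_z, n_t))
  for (z in seq_len(config$n_z)) {
    amp_z <- matrix(rep(amplitudes * mult[, z], each = config$n_mg),
                    config$n_mg, length(odours), dimnames = list(NULL, odours))
    K <- build_dff_matrix(amp_z / 100, odours, protocol, config, n_t)
    B <- baseline_image(config)
    Fm <- render_movie_matrix(B, G %*% K, config, walk, vol_rate)
    dat[, , z, ] <- Fm
  }
  movie <- MovieStack(dat, config$pixel_size_um, vol_rate, config$z_step_um)
  slice_amp <- mult * amplitudes[odours]
  dimnames(slice_amp) <- list(odours, paste0("z", seq_len(config$n_z)))
  dimnames(mult) <- dimnames(slice_amp)
  list(movie = movie, protocol = protocol,
       ground_truth = list(multipliers = mult, slice_amplitude = slice_amp,
                           amplitudes = amplitudes, odour_order = order,
                           motion = data.frame(frame = seq_len(n_t) - 1L,
                                               dy = walk[, 1], dx = walk[, 2]),
                           kernel_peak = {
                             cfgv <- config; cfgv$frame_rate_hz <- vol_rate
                             kernel_sampled_peak(cfgv)
                           },
                           config = config))
}
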