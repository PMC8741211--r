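## Active-microglomerulus detection: minimum-image normalization, Otsu
## thresholding of the per-trial response image, and size-gated connected
## components.

## Matrix view of one z-slice: pixels x frames, no per-frame slicing.
slice_matrix <- function(movie_data, z) {
  d <- dim(movie_data)
  m <- movie_data
  dim(m) <- c(d[1] * d[2], d[3], d[4])
  mm <- m[, z, ]
  dim(mm) <- c(d[1] * d[2], d[4])
  mm
}

#' Pixelwise minimum image
#'
#' Minimum over all frames, per z-slice. On a noiseless, bleach-free
#' synthetic movie this recovers the baseline image exactly (the baseline
#' window contains transient-free frames).
#'
#' @param movie a [MovieStack].
#' @return array `Y x X x Z`.
#' @export
min_image <- function(movie) {
  d <- dim(movie$data)
  out <- array(0, d[1:3])
  for (z in seq_len(d[3])) {
    mm <- slice_matrix(movie$data, z)
    m <- mm[, 1]
    for (t in seq_len(d[4])[-1]) m <- pmin(m, mm[, t])
    out[, , z] <- m
  }
  out
}

#' Normalize a movie to its minimum image
#'
#' `N(t, x) = (F(t, x) - M(x)) / (M(x) + eps)`. The divisive form makes the
#' response image invariant to illumination scale and puts it on the same
#' relative-change scale as dF/F0.
#'
#' @param movie a [MovieStack].
#' @param min_img array from [min_image()] (computed if `NULL`).
#' @param eps small positive guard against division by zero.
#' @return array shaped like `movie$data`.
#' @export
normalize_to_min <- function(movie, min_img = NULL, eps = 1e-6) {
  stopifnot(eps > 0)
  if (is.null(min_img)) min_img <- min_image(movie)
  d <- dim(movie$data)
  stopifnot(all(dim(min_img) == d[1:3]))
  ## min_img spans dims 1:3; recycle along t
  (movie$data - as.vector(min_img)) / as.vector(min_img + eps)
}

#' Otsu threshold
#'
#' Threshold maximizing the between-class variance on a 256-bin histogram
#' spanning `[min(x), max(x)]`. When several bin edges tie for the maximum
#' (an empty valley between well-separated classes leaves the criterion
#' flat), the centre of the tied run is returned, placing the threshold
#' mid-valley.
#'
#' @param x numeric vector, matrix or array with at least two distinct values.
#' @param n_bins histogram resolution.
#' @return threshold value.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- as.vector(x)
  rng <- range(x)
  if (!is.finite(diff(rng)) || diff(rng) <= 0)
    stop("otsu_threshold: degenerate input (constant image)")
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- as.numeric(tabulate(pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1L),
                                n_bins), n_bins))
  mids <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  w <- cumsum(h)
  mu <- cumsum(h * mids)
  tot <- w[n_bins]; mu_tot <- mu[n_bins]
  w0 <- w[-n_bins]; w1 <- tot - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, n_bins - 1L)
  bcv[valid] <- (mu_tot * w0[valid] - tot * mu[-n_bins][valid])^2 /
    (w0[valid] * w1[valid])  # proportional to w0*w1*(mu0-mu1)^2
  tied <- which(bcv >= max(bcv) * (1 - 1e-9))
  mean(edges[tied + 1L])
}

#' Connected-component labelling (8-connectivity)
#'
#' Labels connected sets of `TRUE` pixels in a logical matrix using the
#' 8-neighbourhood; labels are contiguous positive integers in raster order.
#'
#' @param mask logical matrix.
#' @return integer matrix of labels (0 = background).
#' @export
label_components <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  lab <- matrix(0L, ny, nx)
  nb_off <- c(-1L, 1L, -ny, ny, -ny - 1L, -ny + 1L, ny - 1L, ny + 1L)
  idx_all <- which(mask)
  cur <- 0L
  stack <- integer(length(idx_all))
  for (seed in idx_all) {
    if (lab[seed] != 0L) next
    cur <- cur + 1L
    lab[seed] <- cur
    sp <- 1L; stack[1L] <- seed
    while (sp > 0L) {
      p <- stack[sp]; sp <- sp - 1L
      py <- ((p - 1L) %% ny) + 1L
      for (o in nb_off) {
        q <- p + o
        if (q < 1L || q > ny * nx) next
        qy <- ((q - 1L) %% ny) + 1L
        if (abs(qy - py) > 1L) next   # column wrap guard
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- cur
          sp <- sp + 1L
          stack[sp] <- q
        }
      }
    }
  }
  lab
}

## Binary erosion of a logical matrix by a (2k+1) square structuring element.
erode_mask <- function(mask, k) {
  if (k <= 0) return(mask)
  out <- mask
  ny <- nrow(mask); nx <- ncol(mask)
  for (dy in -k:k) for (dx in -k:k) {
    if (dy == 0 && dx == 0) next
    sh <- matrix(FALSE, ny, nx)
    ys <- seq_len(ny) - dy; xs <- seq_len(nx) - dx
    oky <- ys >= 1 & ys <= ny; okx <- xs >= 1 & xs <= nx
    sh[oky, okx] <- mask[ys[oky], xs[okx]]
    out <- out & sh
  }
  out
}

## Per-trial response image: pixelwise max of the normalized movie over the
## trial's analysis window, per z-slice. trial = NULL pools all trial
## windows (the whole-recording response image).
response_image <- function(nmovie, protocol, trial = NULL) {
  frames <- if (is.null(trial))
    sort(unique(unlist(lapply(seq_len(nrow(protocol$trials)),
                              function(i) trial_frames(protocol, i)))))
  else trial_frames(protocol, trial)
  d <- dim(nmovie)
  out <- array(0, d[1:3])
  for (z in seq_len(d[3])) {
    mm <- slice_matrix(nmovie, z)
    m <- mm[, frames[1]]
    for (t in frames[-1]) m <- pmax(m, mm[, t])
    out[, , z] <- m
  }
  out
}

## Cap the top fraction of values (robust histogram range for Otsu).
winsorize_top <- function(v, p = 0.995) {
  pmin(v, stats::quantile(v, p, names = FALSE))
}

#' Pre-stimulus response floor
#'
#' An accepted response must exceed the fluctuation envelope observed before
#' any stimulation: the floor is 1.3 times the 99.9th percentile of the
#' baseline-window response image (max of the normalized movie over the
#' baseline frames) within the signal region. On movies with no real
#' responses, Otsu merely splits the noise; this floor is what sends such
#' recordings to an empty result.
#'
#' @param nmovie normalized movie from [normalize_to_min()].
#' @param protocol the [StimulusProtocol].
#' @param region_mask logical `Y x X x Z` restriction.
#' @return floor value.
#' @export
baseline_response_floor <- function(nmovie, protocol, region_mask) {
  d <- dim(nmovie)
  frames <- baseline_frames_idx(protocol)
  vals <- unlist(lapply(seq_len(d[3]), function(z) {
    mm <- slice_matrix(nmovie, z)
    r <- mm[, frames[1]]
    for (t in frames[-1]) r <- pmax(r, mm[, t])
    r[as.vector(region_mask[, , z])]
  }))
  1.3 * stats::quantile(vals, 0.999, names = FALSE)
}

#' Recording-level detection threshold
#'
#' Otsu threshold of the mean of the per-trial response images, restricted
#' to the signal region. Applying one threshold to every trial of a
#' recording keeps the active-ROI criterion identical across the odours
#' being compared (a per-trial threshold adapts to each odour's strength
#' and makes paired comparisons noisier), while averaging the trials --
#' rather than taking their overall maximum -- weights each odour equally
#' instead of letting the strongest response set the criterion.
#'
#' @param nmovie normalized movie from [normalize_to_min()].
#' @param protocol the [StimulusProtocol].
#' @param region_mask logical `Y x X x Z` restriction (already eroded).
#' @return threshold value.
#' @export
recording_threshold <- function(nmovie, protocol, region_mask) {
  n_tr <- nrow(protocol$trials)
  R <- 0
  for (i in seq_len(n_tr)) R <- R + response_image(nmovie, protocol, i)
  max(otsu_threshold(winsorize_top((R / n_tr)[region_mask])),
      baseline_response_floor(nmovie, protocol, region_mask))
}

#' Detect active microglomerular ROIs for one odour trial
#'
#' Implements the active-ROI pipeline: minimum-image normalization, per-trial
#' temporal maximum (the response image), Otsu thresholding, 8-connected
#' components per z-slice, and a size gate keeping components whose area lies
#' within `area_band` times the disc area of the expected ROI diameter
#' (default 5 um). Thresholding and labelling are restricted to the field's
#' signal region (`region_mask`, by default the [calyx_mask()]): dim pixels
#' outside the imaged structure carry the largest relative noise after
#' minimum-image division and would otherwise dominate the histogram's upper
#' tail. An empty result is a valid outcome, not an error.
#'
#' @param movie a registered [MovieStack].
#' @param protocol the [StimulusProtocol].
#' @param trial trial (row) index into `protocol$trials`.
#' @param expected_diameter_um expected ROI diameter.
#' @param area_band multiplicative band `c(lo, hi)` around the expected disc
#'   area.
#' @param eps normalization guard, see [normalize_to_min()].
#' @param nmovie optionally a precomputed normalized movie (saves recomputing
#'   it for every trial of the same recording).
#' @param region_mask logical `Y x X x Z` restriction; computed from the
#'   movie when `NULL`.
#' @param mask_erosion_px pixels eroded off the region mask before use:
#'   residual integer-pixel motion turns the sharp boundary of the imaged
#'   structure into spuriously large normalized responses, so a margin the
#'   size of the residual drift is excluded.
#' @param threshold optional fixed threshold (e.g. a
#'   [recording_threshold()] shared by all trials of a recording, as the
#'   pipeline uses); when `NULL`, Otsu is computed on this trial's response
#'   image.
#' @param response optional precomputed response image for this trial.
#' @return object of class `RoiSet`: list with `labels` (`Y x X x Z` integer
#'   array), `rois` (data.frame: `id`, `area_px`, `equiv_diameter_um`,
#'   `centroid_y`, `centroid_x`, `z`), `threshold`, `trial`, `odour`,
#'   `expected_diameter_um`, `dropped` (components rejected by the size gate).
#' @export
detect_active_rois <- function(movie, protocol, trial,
                               expected_diameter_um = 5,
                               area_band = c(0.25, 4),
                               eps = 1e-6, nmovie = NULL, region_mask = NULL,
                               mask_erosion_px = 2L, threshold = NULL,
                               response = NULL) {
  if (is.null(nmovie) && is.null(response))
    nmovie <- normalize_to_min(movie, eps = eps)
  if (is.null(region_mask)) region_mask <- calyx_mask(movie)
  if (mask_erosion_px > 0) {
    for (z in seq_len(dim(region_mask)[3]))
      region_mask[, , z] <- erode_mask(region_mask[, , z], mask_erosion_px)
  }
  R <- response %||% response_image(nmovie, protocol, trial)
  d <- dim(R)
  odour <- protocol$trials$odour[trial]
  empty <- function() {
    structure(list(labels = array(0L, d), rois = roi_table_empty(),
                   threshold = NA_real_, trial = trial, odour = odour,
                   expected_diameter_um = expected_diameter_um,
                   dropped = c(below = 0L, above = 0L)),
              class = "RoiSet")
  }
  vals <- R[region_mask]
  if (!length(vals) || (is.null(threshold) && diff(range(vals)) <= 0)) {
    warning("degenerate response image; returning empty RoiSet")
    return(empty())
  }
  ## Otsu on winsorized values (top 0.5% capped): isolated hot pixels would
  ## otherwise stretch the histogram range and capture the split, as a
  ## bounded integer-image histogram never lets them do.
  thr <- threshold %||% otsu_threshold(winsorize_top(vals))
  if (is.null(threshold) && !is.null(nmovie))
    thr <- max(thr, baseline_response_floor(nmovie, protocol, region_mask))
  disc_area_px <- pi * (expected_diameter_um / 2 / movie$pixel_size_um)^2
  lo <- area_band[1] * disc_area_px; hi <- area_band[2] * disc_area_px
  labels <- array(0L, d)
  rois <- list()
  dropped <- c(below = 0L, above = 0L)
  next_id <- 0L
  for (z in seq_len(d[3])) {
    lab <- label_components(R[, , z] > thr & region_mask[, , z])
    if (max(lab) == 0L) next
    areas <- tabulate(lab[lab > 0L], max(lab))
    keep <- which(areas >= lo & areas <= hi)
    dropped["below"] <- dropped["below"] + sum(areas < lo)
    dropped["above"] <- dropped["above"] + sum(areas > hi)
    relab <- integer(max(lab))
    for (k in keep) {
      next_id <- next_id + 1L
      relab[k] <- next_id
      px <- which(lab == k)
      cy <- mean(((px - 1L) %% d[1]) + 1L)
      cx <- mean(((px - 1L) %/% d[1]) + 1L)
      rois[[next_id]] <- data.frame(
        id = next_id, area_px = areas[k],
        equiv_diameter_um = 2 * sqrt(areas[k] / pi) * movie$pixel_size_um,
        centroid_y = cy, centroid_x = cx, z = z)
    }
    lz <- array(0L, d[1:2])
    nz <- lab > 0L
    lz[nz] <- relab[lab[nz]]
    labels[, , z] <- lz
  }
  if (next_id == 0L) {
    rs <- empty()
    rs$threshold <- thr
    rs$dropped <- dropped
    return(rs)
  }
  structure(list(labels = labels, rois = do.call(rbind, rois), threshold = thr,
                 trial = trial, odour = odour,
                 expected_diameter_um = expected_diameter_um, dropped = dropped),
            class = "RoiSet")
}

roi_table_empty <- function() {
  data.frame(id = integer(), area_px = integer(), equiv_diameter_um = numeric(),
             centroid_y = numeric(), centroid_x = numeric(), z = integer())
}

#' @export
print.RoiSet <- function(x, ...) {
  cat(sprintf("RoiSet: %d active ROI(s), trial %s (%s), threshold %.4g\n",
              nrow(x$rois), x$trial, x$odour, x$threshold))
  invisible(x)
}

#' Score detections against simulated ground truth
#'
#' A detected ROI matches a true active MG when its centroid lies within one
#' MG radius of the true centre. Sensitivity is the fraction of true active
#' MGs (for the trial's odour) matched by at least one detection; precision
#' the fraction of detections matching at least one true active MG.
#'
#' @param roiset a `RoiSet`.
#' @param ground_truth the `ground_truth` element of [simulate_calyx_movie()].
#' @param match_radius_um matching radius; default one MG radius.
#' @return list `sensitivity`, `precision`, `n_true`, `n_detected`.
#' @export
score_detection <- function(roiset, ground_truth,
                            match_radius_um = ground_truth$mg$radius_um[1]) {
  mg <- ground_truth$mg
  act <- mg[mg[[paste0("active_", roiset$odour)]], , drop = FALSE]
  det <- roiset$rois
  px <- ground_truth$config$pixel_size_um
  r_px <- match_radius_um / px
  if (nrow(det) == 0L)
    return(list(sensitivity = if (nrow(act)) 0 else NA_real_, precision = NA_real_,
                n_true = nrow(act), n_detected = 0L))
  d2 <- outer(act$y_px, det$centroid_y, "-")^2 + outer(act$x_px, det$centroid_x, "-")^2
  matched_true <- apply(d2, 1, function(r) any(r <= r_px^2))
  matched_det <- apply(d2, 2, function(c) any(c <= r_px^2))
  list(sensitivity = if (nrow(act)) mean(matched_true) else NA_real_,
       precision = mean(matched_det),
       n_true = nrow(act), n_detected = nrow(det))
}

#' Whole-field signal mask
#'
#' Pixels above the Otsu threshold of the temporal-mean image, per z-slice:
#' an operator-independent stand-in for a manually drawn region around the
#' entire GCaMP-expressing calyx. Used for global (APL) traces, as the
#' detection region, and for the per-slice signal of the volumetric
#' analysis.
#'
#' @param movie a [MovieStack].
#' @return logical array `Y x X x Z`.
#' @export
calyx_mask <- function(movie) {
  d <- dim(movie$data)
  out <- array(FALSE, d[1:3])
  for (z in seq_len(d[3])) {
    mean_img <- rowMeans(slice_matrix(movie$data, z))
    out[, , z] <- mean_img > otsu_threshold(mean_img)
  }
  out
}
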