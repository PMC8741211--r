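#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

#' Elliptical field mask
#'
#' Logical mask of an axis-aligned ellipse centred in a `ny` x `nx` pixel
#' field. Used both as the calyx-shaped region in which microglomeruli are
#' placed and as the bright interior of the synthetic baseline image.
#'
#' @param ny,nx field size in pixels.
#' @param semi_y,semi_x semi-axes in pixels; default 0.95 * half-size.
#' @return logical `ny` x `nx` matrix.
#' @keywords internal
ellipse_mask <- function(ny, nx, semi_y = 0.475 * ny, semi_x = 0.475 * nx) {
  cy <- (ny + 1) / 2
  cx <- (nx + 1) / 2
  yy <- matrix(seq_len(ny), ny, nx)
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  ((yy - cy) / semi_y)^2 + ((xx - cx) / semi_x)^2 <= 1
}

## Smooth standardized random field (FFT low-pass of white noise); gives the
## baseline image its spatial heterogeneity.
smooth_field <- function(ny, nx, smoothness = 8) {
  w <- matrix(stats::rnorm(ny * nx), ny, nx)
  fy <- c(0:(ny %/% 2), -((ny - ny %/% 2 - 1):1)) / ny
  fx <- c(0:(nx %/% 2), -((nx - nx %/% 2 - 1):1)) / nx
  f2 <- outer(fy^2, fx^2, "+")
  filt <- exp(-(f2) * (smoothness^2) * 2 * pi^2)
  s <- Re(stats::fft(stats::fft(w) * filt, inverse = TRUE)) / (ny * nx)
  s <- s - mean(s)
  sdv <- stats::sd(as.vector(s))
  if (sdv < .Machine$double.eps) return(matrix(0, ny, nx))
  s / sdv
}

## Seconds to frames at a given sampling rate.
s_to_frames <- function(s, rate) as.integer(round(s * rate))

## Deterministic child seed (kept well below 2^31).
child_seed <- function(seed, k) (as.integer(seed) %% 1000000L) * 1000L + as.integer(k) %% 1000L

`%||%` <- function(a, b) if (is.null(a)) b else a
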