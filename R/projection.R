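#' Parallel-beam acquisition parameters
#'
#' Geometry and photon statistics of the simulated acquisition: projection
#' angles uniformly covering `[0, 180)` degrees, a flat detector whose bin
#' pitch equals the pixel pitch, an incident photon count per detector bin,
#' and a quadratic beam-hardening coefficient.
#'
#' @param spec Optional [phantom_spec()]; used only to size the detector.
#' @param n_angles Number of projection angles over 180 degrees (>= 16).
#' @param n_bins Detector bins; must cover the grid diagonal (default does).
#' @param I0 Incident photon count per ray (default 1e5).
#' @param alpha Beam-hardening coefficient (>= 0): the effective line
#'   integral is `p - alpha * p^2`, depressing highly attenuated rays and
#'   producing dark bands between metal objects.
#' @param size Grid side length in pixels when `spec` is not given.
#' @return A list of class `"sinogram_params"`.
#' @export
sinogram_params <- function(spec = NULL, n_angles = 90L, n_bins = NULL,
                            I0 = 1e5, alpha = 0.01,
                            size = if (is.null(spec)) 64L else spec$size) {
  n_angles <- as.integer(n_angles)
  if (n_angles < 16L) stop("'n_angles' must be >= 16")
  diag_px <- ceiling(sqrt(2) * size)
  if (is.null(n_bins)) n_bins <- diag_px + 3L
  n_bins <- as.integer(n_bins)
  if (n_bins < diag_px) stop("'n_bins' must cover the grid diagonal")
  if (I0 <= 0) stop("'I0' must be positive")
  if (alpha < 0) stop("'alpha' must be >= 0")
  structure(list(n_angles = n_angles, n_bins = n_bins, I0 = I0,
                 alpha = alpha, size = as.integer(size)),
            class = "sinogram_params")
}

projection_angles <- function(params) {
  seq(0, pi, length.out = params$n_angles + 1L)[seq_len(params$n_angles)]
}

#' Forward projection (radon transform)
#'
#' Parallel-beam line integrals of a square attenuation map. Every detector
#' bin averages four sub-rays across its aperture; samples along each ray
#' are taken every quarter pixel with bilinear interpolation and scaled by
#' the voxel spacing, so the sinogram carries dimensionless optical
#' thicknesses when the map holds attenuation per mm.
#'
#' @param map Square numeric matrix.
#' @param params A [sinogram_params()].
#' @param spacing Pixel spacing in mm.
#' @return `n_angles x n_bins` sinogram matrix.
#' @export
radon_project <- function(map, params = sinogram_params(size = nrow(map)),
                          spacing = 0.2) {
  map <- as.matrix(map)
  if (nrow(map) != ncol(map)) stop("'map' must be square")
  storage.mode(map) <- "double"
  cpp_radon(map, projection_angles(params), params$n_bins, spacing,
            step = 0.25, nsub = 4L)
}

#' Photon-count corruption of a sinogram
#'
#' Simulates the transmission measurement behind each line integral `p`:
#' beam hardening shrinks it to `p' = p - alpha p^2`, the detector records
#' `Poisson(I0 exp(-p'))` photons, counts are clamped to at least one photon
#' (photon starvation: rays through metal lose essentially all signal and
#' saturate at `log(I0)`), and the corrupted line integral is recovered as
#' `-log(counts / I0)`. Filtered back-projection turns the corrupted traces
#' into the characteristic bright/dark streaks.
#'
#' @param sinogram Matrix from [radon_project()].
#' @param params A [sinogram_params()].
#' @param noise If `FALSE`, use the expected counts instead of Poisson draws
#'   (the clamp still applies).
#' @return Corrupted sinogram, same shape.
#' @export
apply_photon_statistics <- function(sinogram, params, noise = TRUE) {
  stopifnot(inherits(params, "sinogram_params"))
  p <- sinogram
  p_eff <- p - params$alpha * p^2
  lambda <- params$I0 * exp(-p_eff)
  counts <- if (noise) {
    # rpois is limited to lambda < ~2^31; large counts are effectively
    # gaussian, so split off the huge-lambda rays
    cnt <- numeric(length(lambda))
    big <- lambda > 1e9
    cnt[!big] <- rpois(sum(!big), lambda[!big])
    cnt[big] <- round(lambda[big] + sqrt(lambda[big]) * rnorm(sum(big)))
    cnt
  } else lambda
  counts <- pmax(counts, 1)
  out <- -log(counts / params$I0)
  matrix(out, nrow = nrow(sinogram), ncol = ncol(sinogram))
}

# Kak-Slaney discrete ramp filter (spatial domain), tau = detector pitch in mm.
ramp_kernel <- function(n_bins, tau) {
  n <- -(n_bins - 1L):(n_bins - 1L)
  h <- numeric(length(n))
  h[n == 0L] <- 1 / (4 * tau^2)
  odd <- n %% 2L != 0L
  h[odd] <- -1 / (pi^2 * n[odd]^2 * tau^2)
  h
}

#' Filtered back-projection reconstruction
#'
#' Ramp-filters every projection (discrete band-limited ramp, FFT
#' convolution) and back-projects onto the pixel grid. Reconstructs
#' attenuation per mm on the same grid as the projected map, so
#' `fbp_reconstruct(radon_project(x))` approximates `x` for smooth phantoms.
#'
#' @param sinogram `n_angles x n_bins` matrix.
#' @param params The [sinogram_params()] used for projection.
#' @param size Output grid side length in pixels.
#' @param spacing Pixel spacing in mm.
#' @return `size x size` numeric matrix.
#' @export
fbp_reconstruct <- function(sinogram, params, size = params$size,
                            spacing = 0.2) {
  stopifnot(inherits(params, "sinogram_params"))
  if (nrow(sinogram) != params$n_angles || ncol(sinogram) != params$n_bins)
    stop("sinogram shape does not match 'params'")
  nb <- params$n_bins
  tau <- spacing
  h <- ramp_kernel(nb, tau)
  # linear convolution via FFT, zero-padded
  L <- stats::nextn(2L * nb + 1L, 2L)
  hf <- stats::fft(c(h, numeric(L - length(h))))
  filtered <- matrix(0, nrow(sinogram), nb)
  for (a in seq_len(nrow(sinogram))) {
    pf <- stats::fft(c(sinogram[a, ], numeric(L - nb)))
    conv <- Re(stats::fft(pf * hf, inverse = TRUE)) / L
    # centered part of the linear convolution
    filtered[a, ] <- conv[nb:(2L * nb - 1L)] * tau
  }
  cpp_backproject(filtered, projection_angles(params), size, size)
}
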