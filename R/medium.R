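#' Scattering media built from random phase screens
#'
#' A scattering medium is a list of thin phase screens, each a random phase
#' map applied at a stated axial position, optionally combined with a bulk
#' effective attenuation length (EAL). `make_phase_screen()` draws one screen
#' as a Gaussian random field with Gaussian autocorrelation;
#' `scattering_medium()` assembles screens (zero screens give the identity,
#' aberration-free medium).
#'
#' Screen placement follows the memory-effect convention of the simulator:
#' a screen with `z_position = 0` multiplies the pupil field directly
#' (a pupil-plane aberration commutes with the scan tilt, so the speckle
#' pattern simply follows the scan - an infinite memory effect, convenient
#' for unit tests). A screen with `z_position > 0` is applied in the
#' real-space plane `z_position` um from the focal plane via angular-spectrum
#' propagation; scanning then shifts the beam across the fixed screen and the
#' correction decorrelates over a lateral range set by the screen correlation
#' length - the finite, tens-of-micron memory effect of deep tissue.
#'
#' The phase map is generated on the full propagation grid by smoothing white
#' Gaussian noise with a Gaussian kernel, giving autocorrelation
#' `exp(-r^2 / correlation_length^2)`; the kernel normalization makes the
#' pointwise standard deviation equal `phase_std` in expectation.
#' `correlation_length` is measured in grid samples times the focal pitch,
#' i.e. in um at the screen plane.
#'
#' @param cfg An [optical_config()].
#' @param correlation_length Autocorrelation 1/e half-width of the phase map,
#'   um (must be at least two grid pitches).
#' @param phase_std Pointwise standard deviation of the phase, radians.
#' @param z_position Axial screen position, um from the focal plane (positive
#'   toward the objective); 0 places the screen in the pupil plane.
#' @param seed Integer seed; the screen is deterministic given the seed.
#' @param eal Optional effective attenuation length, um. When set, signals
#'   acquired at depth `z` are attenuated: the delivered field amplitude is
#'   scaled by `exp(-z / (2 * eal))`, so two-photon signals fall as
#'   `exp(-2 z / eal)`.
#' @param screens For `scattering_medium()`: a list of screens, each a list
#'   with elements `phase` (matrix on the fft grid) and `z` (um).
#'
#' @return An object of class `scattering_medium`: list with elements
#'   `screens`, `eal`, and (for generated screens) the generation parameters.
#' @examples
#' cfg <- optical_config(superpixels = 16, superpixel_size = 4, fft_grid = 128)
#' med <- make_phase_screen(cfg, correlation_length = 8 * cfg$focal_pitch,
#'                          phase_std = 1.5, z_position = 50, seed = 1)
#' @export
make_phase_screen <- function(cfg, correlation_length, phase_std, z_position,
                              seed, eal = NULL) {
  if (phase_std < 0) stopf("phase_std must be non-negative")
  if (correlation_length < 2 * cfg$focal_pitch)
    stopf("unresolvable screen: correlation_length %.3g um is below two grid pitches (%.3g um)",
          correlation_length, 2 * cfg$focal_pitch)
  if (z_position < 0) stopf("z_position must be non-negative")
  geom <- grid_geometry(cfg)
  N <- geom$N
  phase <- matrix(0, N, N)
  if (phase_std > 0) {
    corr_px <- correlation_length / cfg$focal_pitch
    sg <- corr_px / 2
    r2 <- outer((seq_len(N) - geom$cc)^2, (seq_len(N) - geom$cc)^2, "+")
    kern <- exp(-r2 / (2 * sg^2))
    kern <- kern / sqrt(sum(kern^2))
    noise <- with_seed(seed, matrix(rnorm(N * N), N, N))
    # circular convolution via the unitary centered FFT (scale restores the
    # plain convolution theorem)
    phase <- Re(ift2c(ft2c(noise) * ft2c(kern))) * N * phase_std
  }
  med <- scattering_medium(screens = list(list(phase = phase, z = z_position)),
                           eal = eal)
  med$correlation_length <- correlation_length
  med$phase_std <- phase_std
  med$seed <- as.integer(seed)
  med
}

#' @rdname make_phase_screen
#' @export
scattering_medium <- function(screens = list(), eal = NULL) {
  for (s in screens) {
    if (!is.matrix(s$phase) || !all(is.finite(s$phase)))
      stopf("screen phase maps must be finite matrices")
    if (is.null(s$z) || s$z < 0) stopf("screen z positions must be >= 0")
  }
  if (!is.null(eal) && eal <= 0) stopf("eal must be positive")
  structure(list(screens = screens, eal = eal), class = "scattering_medium")
}

#' @export
print.scattering_medium <- function(x, ...) {
  if (length(x$screens) == 0) {
    cat("Identity medium (no screens)\n")
  } else {
    cat(sprintf("Scattering medium with %d phase screen(s)\n", length(x$screens)))
    for (s in x$screens)
      cat(sprintf("  screen at z = %g um, phase sd %.3g rad\n", s$z, sd(s$phase)))
  }
  if (!is.null(x$eal)) cat(sprintf("  bulk attenuation: EAL %g um\n", x$eal))
  invisible(x)
}

#' @rdname make_phase_screen
#' @export
identity_medium <- function() scattering_medium()
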