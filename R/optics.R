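#' Optical configuration of the virtual two-photon microscope
#'
#' Collects the geometry of the simulated instrument: excitation wavelength,
#' numerical aperture, the DMD superpixel grid at the pupil (Fourier) plane,
#' and the computational grid used for angular-spectrum propagation. All
#' lengths are in micrometres.
#'
#' The pupil is sampled at DMD-pixel resolution: a `superpixels` x
#' `superpixels` grid of superpixels, each `superpixel_size` pixels on a side
#' (defaults 100 and 8, i.e. an 800 x 800 pixel usable DMD region). The full
#' pupil square spans spatial frequencies up to `na / wavelength`; a circular
#' aperture of that radius is applied, so frequencies are always propagating
#' as long as `na < refractive_index` and energy is conserved through
#' phase-only screens. Fields are embedded in an `fft_grid` x `fft_grid`
#' complex array (a power of two) for transform efficiency; the focal-plane
#' sample pitch is `1 / (fft_grid * freq_pitch)`.
#'
#' @param wavelength Excitation wavelength in um (default 1.035, i.e. 1035 nm).
#' @param na Numerical aperture of the objective (default 1.0).
#' @param refractive_index Immersion/tissue refractive index (default 1.33).
#' @param superpixels Superpixels per side of the DMD mask grid (default 100).
#' @param superpixel_size DMD pixels per superpixel side (default 8).
#' @param fft_grid Samples per side of the propagation grid; a power of two at
#'   least as large as the pupil grid. Default: smallest power of two >= 1.25x
#'   the pupil grid.
#' @param scan_pixel_pitch Lateral scan step of the point-scanning image in um
#'   (default 0.44).
#' @param z_step Axial step between image planes in um (default 10).
#'
#' @return An object of class `optical_config`: a list with the arguments plus
#'   derived quantities `pupil_grid` (pixels per side), `freq_pitch` (spatial
#'   frequency per pupil pixel, 1/um) and `focal_pitch` (focal-plane sample
#'   pitch, um).
#' @examples
#' cfg <- optical_config(superpixels = 20, superpixel_size = 4, fft_grid = 128)
#' cfg$focal_pitch
#' @export
optical_config <- function(wavelength = 1.035, na = 1.0, refractive_index = 1.33,
                           superpixels = 100, superpixel_size = 8,
                           fft_grid = NULL, scan_pixel_pitch = 0.44,
                           z_step = 10) {
  if (wavelength <= 0 || scan_pixel_pitch <= 0 || z_step <= 0)
    stopf("all lengths must be positive")
  if (na <= 0 || na >= refractive_index)
    stopf("numerical aperture must lie in (0, refractive_index)")
  superpixels <- as.integer(superpixels)
  superpixel_size <- as.integer(superpixel_size)
  pupil_grid <- superpixels * superpixel_size
  if (is.null(fft_grid)) {
    fft_grid <- 2L
    while (fft_grid < 1.25 * pupil_grid) fft_grid <- fft_grid * 2L
  }
  fft_grid <- as.integer(fft_grid)
  if (!is_power_of_two(fft_grid))
    stopf("fft_grid must be a power of two, got %d", fft_grid)
  if (fft_grid < pupil_grid)
    stopf("fft_grid (%d) must be at least the pupil grid (%d)", fft_grid, pupil_grid)
  freq_pitch <- (2 * na / wavelength) / pupil_grid
  cfg <- list(
    wavelength = wavelength, na = na, refractive_index = refractive_index,
    superpixels = superpixels, superpixel_size = superpixel_size,
    pupil_grid = pupil_grid, fft_grid = fft_grid,
    freq_pitch = freq_pitch, focal_pitch = 1 / (fft_grid * freq_pitch),
    scan_pixel_pitch = scan_pixel_pitch, z_step = z_step
  )
  class(cfg) <- "optical_config"
  cfg
}

#' @export
print.optical_config <- function(x, ...) {
  cat("Optical configuration\n")
  cat(sprintf("  wavelength        %.4g um, NA %.2f (n = %.2f)\n",
              x$wavelength, x$na, x$refractive_index))
  cat(sprintf("  pupil             %d x %d superpixels of %d x %d pixels (%d px)\n",
              x$superpixels, x$superpixels, x$superpixel_size,
              x$superpixel_size, x$pupil_grid))
  cat(sprintf("  propagation grid  %d x %d, focal pitch %.4g um\n",
              x$fft_grid, x$fft_grid, x$focal_pitch))
  cat(sprintf("  scanning          %.3g um/pixel, z step %.3g um\n",
              x$scan_pixel_pitch, x$z_step))
  invisible(x)
}

# ---- internal grid machinery -------------------------------------------------

# Centered frequency coordinates (1/um) for the fft grid; DC at index N/2 + 1.
freq_axis <- function(cfg) (seq_len(cfg$fft_grid) - (cfg$fft_grid / 2 + 1)) * cfg$freq_pitch

# Cache per-config geometry (kz map, apertures) keyed by the defining scalars.
.optics_cache <- new.env(parent = emptyenv())

grid_geometry <- function(cfg) {
  key <- paste(cfg$wavelength, cfg$na, cfg$refractive_index, cfg$pupil_grid,
               cfg$fft_grid, sep = "|")
  g <- .optics_cache[[key]]
  if (!is.null(g)) return(g)
  N <- cfg$fft_grid
  fx <- freq_axis(cfg)
  f2 <- outer(fx^2, fx^2, "+")
  fmax2 <- (cfg$refractive_index / cfg$wavelength)^2
  propagating <- f2 < fmax2
  # evanescent components (outside the NA-limited pupil anyway) are carried
  # with zero axial phase so every propagation step is exactly unitary
  kz <- 2 * pi * sqrt(pmax(fmax2 - f2, 0))
  cc <- N / 2 + 1
  half <- cfg$pupil_grid / 2
  pupil_idx <- (cc - half):(cc + half - 1)
  aperture <- f2[pupil_idx, pupil_idx] <= (cfg$na / cfg$wavelength)^2
  g <- list(N = N, cc = cc, fx = fx, kz = kz, propagating = propagating,
            pupil_idx = pupil_idx, aperture = aperture)
  .optics_cache[[key]] <- g
  g
}

# Angular-spectrum kernel (phase-only, unitary) for propagation over
# distance z (um) toward the plane z from focus.
prop_kernel <- function(geom, z) exp(1i * geom$kz * z)

# Expand a superpixel-grid mask (numeric or logical matrix) to DMD pixels and
# embed it, NA-apertured, as a pupil field on the fft grid.
pupil_field <- function(mask, cfg, geom = grid_geometry(cfg)) {
  m <- as.matrix(mask)
  if (!all(dim(m) == cfg$superpixels))
    stopf("mask is %d x %d but the configuration expects %d x %d superpixels",
          nrow(m), ncol(m), cfg$superpixels, cfg$superpixels)
  idx <- rep(seq_len(cfg$superpixels), each = cfg$superpixel_size)
  px <- m[idx, ][, idx] * geom$aperture
  X <- matrix(0 + 0i, geom$N, geom$N)
  X[geom$pupil_idx, geom$pupil_idx] <- px
  X
}

# Linear phase ramp realizing a lateral focal shift of (dx, dy) um.
tilt_ramp <- function(cfg, geom, shift) {
  if (all(shift == 0)) return(1)
  fx <- geom$fx
  exp(2i * pi * outer(fx * shift[1], fx * shift[2], "+"))
}

# Sum pixel-level values over superpixel blocks (complex-safe).
block_sum <- function(x, block) {
  idx <- rep(seq_len(nrow(x) / block), each = block)
  if (is.complex(x)) {
    t(rowsum(t(rowsum(Re(x), idx)), idx)) +
      1i * t(rowsum(t(rowsum(Im(x), idx)), idx))
  } else {
    t(rowsum(t(rowsum(x, idx)), idx))
  }
}
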