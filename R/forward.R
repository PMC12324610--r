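# Virtual two-photon microscope: coherent propagation from the modulated
# pupil through phase screens to the sample, quartic signal formation, and
# point-scanned image synthesis.

# Propagate the pupil field of `mask` through the medium; returns the angular
# spectrum referenced to the focal plane (field at plane z from focus is
# ft2c(S * prop_kernel(geom, z))). Screens are applied far-to-near; pupil
# screens (z = 0) multiply the spectrum directly.
pupil_spectrum <- function(mask, medium, cfg, scan_shift = c(0, 0),
                           geom = grid_geometry(cfg), amplitude = 1) {
  half_extent <- geom$N / 2 * cfg$focal_pitch
  if (any(abs(scan_shift) >= half_extent))
    stopf("scan tilt shifts the focus by (%.3g, %.3g) um, beyond the +-%.3g um grid",
          scan_shift[1], scan_shift[2], half_extent)
  S <- pupil_field(mask, cfg, geom) * amplitude
  r <- tilt_ramp(cfg, geom, scan_shift)
  if (!identical(r, 1)) S <- S * r
  screens <- order_screens(medium$screens)
  for (s in screens) {
    if (s$z == 0) {
      S <- S * exp(1i * s$phase)
    } else {
      H <- prop_kernel(geom, s$z)
      S <- ift2c(ft2c(S * H) * exp(1i * s$phase)) * Conj(H)
    }
  }
  S
}

#' Propagate a pupil mask through a scattering medium to the focal plane
#'
#' Applies the binary or grayscale mask (and a linear phase ramp realizing the
#' scan tilt) to a uniform, NA-apertured pupil field, propagates it through
#' every phase screen of the medium by the band-limited angular-spectrum
#' method, and returns the complex field in the focal plane. Screens are
#' phase-only, so total power is conserved exactly.
#'
#' @param mask Superpixel-grid matrix (logical or numeric amplitudes).
#' @param medium A [scattering_medium()].
#' @param cfg An [optical_config()].
#' @param scan_shift Lateral focal shift `c(dx, dy)` in um produced by the
#'   scan tilt (default none).
#' @param z Evaluate the field in the plane `z` um from the focal plane
#'   instead of the focal plane itself (default 0).
#' @param amplitude Scalar multiplier on the pupil amplitude (default 1).
#' @return An object of class `field_state`: list with the complex `field`
#'   matrix on the propagation grid, the sample `pitch` (um), the `plane`
#'   label, and `total_power` (sum of squared magnitudes times pixel area).
#' @examples
#' cfg <- optical_config(superpixels = 16, superpixel_size = 4, fft_grid = 128)
#' fs <- propagate_to_focus(blank_mask(16), identity_medium(), cfg)
#' which(Mod(fs$field) == max(Mod(fs$field)), arr.ind = TRUE)  # grid center
#' @export
propagate_to_focus <- function(mask, medium, cfg, scan_shift = c(0, 0), z = 0,
                               amplitude = 1) {
  geom <- grid_geometry(cfg)
  S <- pupil_spectrum(mask, medium, cfg, scan_shift, geom, amplitude)
  E <- if (z == 0) ft2c(S) else ft2c(S * prop_kernel(geom, z))
  field_state(E, pitch = cfg$focal_pitch, plane = "focal")
}

#' @rdname propagate_to_focus
#' @param field Complex field matrix.
#' @param pitch Sample pitch of the field grid, um.
#' @param plane Plane label (`"pupil"`, `"screen"` or `"focal"`).
#' @export
field_state <- function(field, pitch, plane = "focal") {
  structure(list(field = field, pitch = pitch, plane = plane,
                 total_power = sum(Mod(field)^2) * pitch^2),
            class = "field_state")
}

#' @export
print.field_state <- function(x, ...) {
  cat(sprintf("<field_state> %d x %d complex field at %s plane, pitch %.4g um, power %.6g\n",
              nrow(x$field), ncol(x$field), x$plane, x$pitch, x$total_power))
  invisible(x)
}

attenuation_factor <- function(medium, depth) {
  if (is.null(medium$eal) || depth == 0) 1 else exp(-depth / (2 * medium$eal))
}

#' Two-photon fluorescence signal of a masked acquisition
#'
#' Propagates the masked pupil field through the medium, evaluates the field
#' at every phantom plane, and integrates the fluorophore concentration
#' against the fourth power of the field magnitude (two-photon excitation:
#' signal is quadratic in intensity, quartic in field amplitude). The result
#' is in arbitrary units; the package's metrics only ever use ratios.
#'
#' @inheritParams propagate_to_focus
#' @param phantom A [make_phantom()] object.
#' @param focus_offset Axial displacement of the focal plane, um (for
#'   synthesizing z stacks).
#' @param depth Tissue depth of the acquisition, um; only used when the
#'   medium has an effective attenuation length (`eal`), in which case the
#'   delivered amplitude is scaled by `exp(-depth / (2 * eal))`.
#' @return Non-negative scalar signal.
#' @export
two_photon_signal <- function(mask, medium, phantom, cfg, scan_shift = c(0, 0),
                              focus_offset = 0, depth = 0, amplitude = 1) {
  if (all(phantom$conc == 0)) return(0)
  geom <- grid_geometry(cfg)
  S <- pupil_spectrum(mask, medium, cfg, scan_shift, geom, amplitude)
  att <- attenuation_factor(medium, depth)
  dims <- dim(phantom$conc)
  ci <- crop_index(geom$N, dims[1])
  cj <- crop_index(geom$N, dims[2])
  sig <- 0
  for (k in seq_along(phantom$z)) {
    plane <- phantom$conc[, , k]
    if (all(plane == 0)) next
    dz <- phantom$z[k] - focus_offset
    E <- if (dz == 0) ft2c(S) else ft2c(S * prop_kernel(geom, dz))
    sig <- sig + sum(plane * (Mod(E[ci, cj]) * att)^4)
  }
  sig
}

# Indices of a centered crop of width w out of N (both even or both odd work;
# phantom grids are kept even).
crop_index <- function(N, w) {
  cc <- N / 2 + 1
  (cc - floor(w / 2)):(cc + ceiling(w / 2) - 1)
}

# Screens in the order light meets them: pupil screens (z = 0) first, then
# real-space screens from farthest to nearest the focal plane.
order_screens <- function(screens) {
  if (length(screens) < 2) return(screens)
  z <- vapply(screens, function(s) s$z, 0)
  screens[order(ifelse(z == 0, Inf, z), decreasing = TRUE)]
}

#' Per-superpixel complex transmission to a point target
#'
#' The focal field at a single point is linear in the pupil amplitudes, so
#' for a point target the full propagation collapses to
#' `E(target) = sum_j a_j u_j` over superpixel amplitudes `a_j`, and the
#' two-photon signal of any pattern is `|sum_j a_j u_j|^4`. This function
#' computes the coefficient field `u` by propagating the evaluation
#' functional backwards through the medium (one FFT pass per screen), making
#' ten-thousand-measurement acquisitions desk-scale.
#'
#' @inheritParams propagate_to_focus
#' @param target Target position `c(x, y, z)` in um relative to the focal
#'   point (z positive toward the objective).
#' @param scan_shift Lateral focal shift `c(dx, dy)` in um applied as a
#'   pupil tilt during the acquisition (default none). When the instrument
#'   scans to a displaced target, both the tilt and the evaluation point
#'   move together; for a pupil-plane screen the two cancel exactly (the
#'   infinite memory effect), while a defocused screen decorrelates.
#' @return Complex matrix of dimension superpixels x superpixels (class
#'   `transfer_vector`), with the optical configuration in attribute `cfg`.
#' @examples
#' cfg <- optical_config(superpixels = 16, superpixel_size = 4, fft_grid = 128)
#' u <- transfer_vector(identity_medium(), cfg)
#' max(abs(diff(Arg(u[Mod(u) > 1e-9 * max(Mod(u))]))))  # in phase at focus
#' @export
transfer_vector <- function(medium, cfg, target = c(0, 0, 0),
                            scan_shift = c(0, 0)) {
  geom <- grid_geometry(cfg)
  target <- c(target, 0, 0)[1:3]
  w <- transfer_sens(medium, cfg, target, geom)
  r <- tilt_ramp(cfg, geom, scan_shift)
  if (!identical(r, 1)) w <- w * r
  sens <- w[geom$pupil_idx, geom$pupil_idx] * geom$aperture
  u <- block_sum(sens, cfg$superpixel_size)
  attr(u, "cfg") <- cfg
  attr(u, "target") <- target
  class(u) <- c("transfer_vector", class(u))
  u
}

# Backward pass: the evaluation functional of the focal field at `target`,
# pulled back through the medium to the pupil plane (full fft grid).
transfer_sens <- function(medium, cfg, target = c(0, 0, 0),
                          geom = grid_geometry(cfg)) {
  half_extent <- geom$N / 2 * cfg$focal_pitch
  if (any(abs(target[1:2]) >= half_extent))
    stopf("target outside the simulated lateral extent (+-%.3g um)", half_extent)
  # Evaluation functional of the centered unitary FT at the (possibly
  # off-grid) target: <c, S> with c a conjugated plane wave. For even grids
  # the centered FT is its own transpose, which the backward pass exploits.
  d <- matrix(0 + 0i, geom$N, geom$N)
  d[geom$cc, geom$cc] <- 1
  base <- ft2c(d) * geom$N          # sign pattern of the DC row (+-1)
  fx <- geom$fx
  w <- base / geom$N * exp(-2i * pi * outer(fx * target[1], fx * target[2], "+"))
  if (target[3] != 0) w <- w * prop_kernel(geom, target[3])
  screens <- order_screens(medium$screens)
  for (s in rev(screens)) {
    if (s$z == 0) {
      w <- w * exp(1i * s$phase)
    } else {
      H <- prop_kernel(geom, s$z)
      w <- H * ft2c(exp(1i * s$phase) * ift2c(Conj(H) * w))
    }
  }
  w
}

#' Point-scanned two-photon image with per-subregion correction masks
#'
#' Synthesizes an image by scanning the focus across the field of view (the
#' scan is implemented as a pupil-plane tilt, so a finite memory effect
#' degrades off-target correction exactly as in the instrument). Each scan
#' pixel uses the correction mask of its subregion; with a single mask and no
#' subregion map the whole image uses that mask.
#'
#' The scan grid equals the phantom's lateral grid (pitch = phantom pitch),
#' centered on the optical axis.
#'
#' @inheritParams two_photon_signal
#' @param masks A single mask matrix, or a list of masks (one per subregion
#'   label of `subregions`).
#' @param subregions `NULL` for a single global mask, or a subregion map /
#'   schedule whose `labels` matrix matches the scan grid.
#' @param amplitudes Optional numeric vector of pupil-amplitude multipliers,
#'   one per mask (e.g. from [normalize_delivered_power()]).
#' @return Numeric matrix of scanned two-photon signals.
#' @export
scan_image <- function(masks, medium, phantom, cfg, subregions = NULL,
                       focus_offset = 0, depth = 0, amplitudes = NULL) {
  dims <- dim(phantom$conc)
  if (is.matrix(masks)) masks <- list(masks)
  if (is.null(subregions)) {
    if (length(masks) != 1)
      stopf("multiple masks require a subregion map")
    labels <- matrix(1L, dims[1], dims[2])
  } else {
    labels <- if (is.matrix(subregions)) subregions else subregions$labels
    if (!all(dim(labels) == dims[1:2]))
      stopf("subregion label image is %d x %d but the scan grid is %d x %d",
            nrow(labels), ncol(labels), dims[1], dims[2])
    if (anyNA(labels) || any(labels < 1) || any(labels > length(masks)))
      stopf("every scan pixel must be assigned a subregion with a mask")
  }
  if (is.null(amplitudes)) amplitudes <- rep(1, length(masks))
  img <- matrix(0, dims[1], dims[2])
  xs <- (seq_len(dims[1]) - (dims[1] / 2 + 1)) * phantom$pitch
  ys <- (seq_len(dims[2]) - (dims[2] / 2 + 1)) * phantom$pitch
  for (j in seq_len(dims[2])) {
    for (i in seq_len(dims[1])) {
      lab <- labels[i, j]
      m <- masks[[lab]]
      if (!any(m != 0)) { img[i, j] <- 0; next }
      img[i, j] <- two_photon_signal(m, medium, phantom, cfg,
                                     scan_shift = c(xs[i], ys[j]),
                                     focus_offset = focus_offset, depth = depth,
                                     amplitude = amplitudes[lab])
    }
  }
  img
}
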