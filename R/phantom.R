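#' Synthetic fluorophore phantoms
#'
#' Builds a 3D fluorophore concentration map on the focal-plane sample grid
#' of the configuration (lateral pitch = `cfg$focal_pitch`), for use with
#' [two_photon_signal()] and [scan_image()]. Available kinds:
#'
#' * `"bead"` - one spherical bead, modeled as an isotropic 3D Gaussian blob
#'   whose full width at half maximum equals `diameter` (a diffraction-scale
#'   bead such as the 0.71 um beads used for PSF metrology).
#' * `"bead_field"` - `n` beads at uniformly random lateral positions with a
#'   minimum pairwise separation.
#' * `"filament"` - a tube of stated diameter (Gaussian cross-section, FWHM =
#'   `diameter`) along a smooth random lateral path, emulating axons or
#'   capillaries of 1-2 um caliber.
#' * `"uniform"` - constant concentration.
#'
#' @param cfg An [optical_config()].
#' @param kind Phantom kind, see above.
#' @param extent Lateral samples per side of the phantom grid (even; default
#'   64, must not exceed `cfg$fft_grid`).
#' @param diameter Bead or filament diameter (FWHM), um. Default 0.71.
#' @param z_planes Axial plane positions, um from the focal plane (default a
#'   single plane at 0).
#' @param n Number of beads for `"bead_field"`.
#' @param min_separation Minimum bead separation for `"bead_field"`, um.
#' @param positions Optional n x 2 matrix of lateral bead positions (um,
#'   relative to the optical axis) overriding random placement; for `"bead"`
#'   a length-3 `c(x, y, z)` position.
#' @param value Peak concentration (arbitrary units, default 1).
#' @param seed Integer seed for the random kinds.
#' @return Object of class `phantom`: list with `conc` (extent x extent x
#'   length(z_planes) array), `z`, `pitch` (um), `kind`.
#' @examples
#' cfg <- optical_config(superpixels = 16, superpixel_size = 4, fft_grid = 128)
#' ph <- make_phantom(cfg, "bead", extent = 32, diameter = 0.71)
#' sum(ph$conc > 0) > 0
#' @export
make_phantom <- function(cfg, kind = c("bead", "bead_field", "filament", "uniform"),
                         extent = 64, diameter = 0.71, z_planes = 0,
                         n = 5, min_separation = 3, positions = NULL,
                         value = 1, seed = NULL) {
  kind <- match.arg(kind)
  extent <- as.integer(extent)
  if (extent %% 2L != 0L) stopf("extent must be even")
  if (extent > cfg$fft_grid) stopf("phantom extent exceeds the propagation grid")
  if (diameter <= 0 || value <= 0) stopf("geometric parameters must be positive")
  pitch <- cfg$focal_pitch
  nz <- length(z_planes)
  ax <- (seq_len(extent) - (extent / 2 + 1)) * pitch
  conc <- array(0, dim = c(extent, extent, nz))
  sigma <- diameter / (2 * sqrt(2 * log(2)))  # FWHM -> sd
  add_bead <- function(conc, pos) {
    g2 <- exp(-outer((ax - pos[1])^2, (ax - pos[2])^2, "+") / (2 * sigma^2))
    for (k in seq_len(nz))
      conc[, , k] <- conc[, , k] + value * g2 * exp(-(z_planes[k] - pos[3])^2 / (2 * sigma^2))
    conc
  }
  if (kind == "bead") {
    pos <- if (is.null(positions)) c(0, 0, 0) else c(positions, 0, 0)[1:3]
    conc <- add_bead(conc, pos)
  } else if (kind == "bead_field") {
    if (is.null(positions)) {
      positions <- with_seed(seed, {
        pts <- matrix(NA_real_, 0, 2)
        lim <- max(ax) * 0.9
        tries <- 0
        while (nrow(pts) < n && tries < 1000) {
          cand <- runif(2, -lim, lim)
          if (nrow(pts) == 0 ||
              min(sqrt(rowSums(sweep(pts, 2, cand)^2))) >= min_separation)
            pts <- rbind(pts, cand)
          tries <- tries + 1
        }
        pts
      })
    }
    for (i in seq_len(nrow(positions)))
      conc <- add_bead(conc, c(positions[i, ], 0))
  } else if (kind == "filament") {
    # smooth random path y(x) across the field from a few spline knots
    path <- with_seed(seed, {
      nk <- 4
      kx <- seq(min(ax), max(ax), length.out = nk)
      ky <- runif(nk, min(ax) / 2, max(ax) / 2)
      splinefun(kx, ky, method = "natural")
    })
    yc <- path(ax)
    for (j in seq_len(extent)) {
      # y-distance from pixel (i, j) to the path point at the same x
      d2 <- (yc - ax[j])^2
      prof <- value * exp(-d2 / (2 * sigma^2))
      for (k in seq_len(nz))
        conc[, j, k] <- conc[, j, k] + prof * exp(-z_planes[k]^2 / (2 * sigma^2))
    }
  } else { # uniform
    conc[] <- value
  }
  if (any(conc < 0)) stopf("concentration must be non-negative")
  structure(list(conc = conc, z = z_planes, pitch = pitch, kind = kind,
                 diameter = diameter, seed = seed),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  d <- dim(x$conc)
  cat(sprintf("<phantom> kind '%s', %d x %d x %d voxels at %.3g um pitch, z = [%s] um\n",
              x$kind, d[1], d[2], d[3], paste(signif(x$z, 3), collapse = ", ")))
  invisible(x)
}
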