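# Quantitative metrology: enhancement fold, PSF widths and contrast, and
# effective-attenuation-length fitting.

#' Fluorescence enhancement fold
#'
#' Ratio of the corrected to the uncorrected peak signal, both measured at
#' equal delivered power on the sample (apply [normalize_delivered_power()]
#' to the corrected acquisition's pupil amplitude). Values above 1 indicate
#' successful correction.
#'
#' @param corrected_signal,uncorrected_signal Peak signals at equal delivered
#'   power.
#' @return Dimensionless fold.
#' @export
enhancement_fold <- function(corrected_signal, uncorrected_signal) {
  if (uncorrected_signal <= 0)
    stopf("uncorrected signal must be positive (fold undefined)")
  corrected_signal / uncorrected_signal
}

# Peak signal of a binary mask at a point target at equal delivered power,
# using the transfer-vector fast path. The quartic signal law makes the
# equal-power amplitude scale enter to the fourth power.
mask_peak_signal <- function(mask, u, equal_power = TRUE, depth = 0, eal = NULL) {
  s <- if (equal_power) normalize_delivered_power(mask) else 1
  att <- if (!is.null(eal) && depth > 0) exp(-depth / (2 * eal)) else 1
  Mod(sum(as.vector(unclass(u))[as.vector(mask != 0)]) * s * att)^4
}

#' Peak signal of a scanned point emitter under a correction mask
#'
#' The corrected signal reported for an acquisition is the *peak* of the
#' scanned image of the emitter - the maximum over scan positions - not the
#' value at the emitter's nominal coordinate (the corrected focus can sit a
#' fraction of a PSF width away). This evaluates the two-photon signal of a
#' point emitter at `target` over a small grid of scan tilts centered on the
#' target and returns the maximum, at equal delivered power by default.
#' The scan tilt and the evaluation point move together, so a pupil-plane
#' screen shows no decay with target displacement while a defocused screen
#' decorrelates over its memory-effect range.
#'
#' @inheritParams transfer_vector
#' @param mask Binary superpixel mask.
#' @param search_radius Scan search half-width in focal-grid samples
#'   (default 2, i.e. a (2r+1)^2 grid around the target).
#' @param equal_power Scale the pupil amplitude to blank-mask delivered
#'   power (default TRUE).
#' @param sens Optional precomputed backward sensitivity field for this
#'   medium/target (an internal cache for evaluating many masks against one
#'   target).
#' @return Scalar peak signal.
#' @export
corrected_peak_signal <- function(mask, medium, cfg, target = c(0, 0, 0),
                                  search_radius = 2, equal_power = TRUE,
                                  sens = NULL) {
  geom <- grid_geometry(cfg)
  target <- c(target, 0, 0)[1:3]
  if (is.null(sens)) sens <- transfer_sens(medium, cfg, target, geom)
  idx <- rep(seq_len(cfg$superpixels), each = cfg$superpixel_size)
  mpx <- (as.matrix(mask) != 0)[idx, ][, idx] & geom$aperture
  base <- sens[geom$pupil_idx, geom$pupil_idx] * mpx
  fx <- geom$fx[geom$pupil_idx]
  amp <- if (equal_power) normalize_delivered_power(mask) else 1
  offs <- (-search_radius:search_radius) * cfg$focal_pitch
  best <- 0
  for (dx in offs + target[1]) {
    for (dy in offs + target[2]) {
      if (dx == 0 && dy == 0) {
        v <- Mod(sum(base))
      } else {
        v <- Mod(sum(base * exp(2i * pi * outer(fx * dx, fx * dy, "+"))))
      }
      if (v > best) best <- v
    }
  }
  (best * amp)^4
}

#' Point-spread-function metrics from an image stack
#'
#' Measures lateral and axial full widths at half maximum from 1D profiles
#' through the stack's peak (monotone cubic interpolation at the half-maximum
#' crossings) plus an image contrast: peak over the median background in an
#' annulus 5-10 FWHM from the peak (clipped to the image; if the annulus is
#' empty the image border is used).
#'
#' @param stack 3D array (x, y, z) or a 2D matrix (lateral metrics only).
#' @param pixel_pitch Lateral sample pitch, um.
#' @param z_step Axial step, um (for stacks).
#' @param peak_hint Optional index `c(i, j, k)` near the peak; default global
#'   maximum.
#' @return Object of class `psf_metrics`: list with `fwhm_x`, `fwhm_y`,
#'   `fwhm_z` (um; `fwhm_z` is `NA` for 2D input), `contrast`, `peak`, and
#'   the peak index.
#' @examples
#' ax <- (-31:32) * 0.2
#' img <- exp(-outer(ax^2, ax^2, "+") / (2 * 0.8^2))
#' m <- psf_metrics(img, pixel_pitch = 0.2)
#' m$fwhm_x / 0.8  # ~2.355 (Gaussian FWHM/sigma)
#' @export
psf_metrics <- function(stack, pixel_pitch, z_step = NULL, peak_hint = NULL) {
  d <- dim(stack)
  is3d <- length(d) == 3 && d[3] > 1
  if (length(d) == 2) { stack <- array(stack, c(d, 1)); d <- dim(stack) }
  if (is.null(peak_hint)) {
    w <- which.max(stack)
    peak_hint <- arrayInd(w, d)[1, ]
  }
  pk <- stack[peak_hint[1], peak_hint[2], peak_hint[3]]
  if (diff(range(stack)) == 0) stopf("unresolved: image has no peak")
  px <- stack[, peak_hint[2], peak_hint[3]]
  py <- stack[peak_hint[1], , peak_hint[3]]
  fx <- fwhm_1d(px, pixel_pitch, peak_hint[1])
  fy <- fwhm_1d(py, pixel_pitch, peak_hint[2])
  fz <- NA_real_
  if (is3d) {
    if (is.null(z_step)) stopf("z_step needed for a 3D stack")
    fz <- fwhm_1d(stack[peak_hint[1], peak_hint[2], ], z_step, peak_hint[3])
  }
  # contrast over an annulus 5-10 lateral FWHM from the peak
  rpx <- fx / pixel_pitch
  ri <- sqrt(outer((seq_len(d[1]) - peak_hint[1])^2,
                   (seq_len(d[2]) - peak_hint[2])^2, "+"))
  ann <- ri >= 5 * rpx & ri <= 10 * rpx
  plane <- stack[, , peak_hint[3]]
  if (!any(ann)) ann <- ri >= max(ri) * 0.9
  bg <- median(plane[ann])
  contrast <- if (bg > 0) (pk - bg) / bg else Inf
  structure(list(fwhm_x = fx, fwhm_y = fy, fwhm_z = fz, contrast = contrast,
                 peak = pk, peak_index = peak_hint),
            class = "psf_metrics")
}

#' @export
print.psf_metrics <- function(x, ...) {
  cat(sprintf("<psf_metrics> FWHM %.3g x %.3g x %s um, contrast %.3g, peak %.4g\n",
              x$fwhm_x, x$fwhm_y,
              if (is.na(x$fwhm_z)) "-" else sprintf("%.3g", x$fwhm_z),
              x$contrast, x$peak))
  invisible(x)
}

# FWHM of a sampled 1D profile by interpolating the half-maximum crossings
# on each side of the peak with a monotone cubic spline.
fwhm_1d <- function(profile, pitch, peak_index = which.max(profile)) {
  pk <- profile[peak_index]
  half <- pk / 2
  n <- length(profile)
  left <- NA_real_; right <- NA_real_
  i <- peak_index
  while (i > 1 && profile[i - 1] >= half) i <- i - 1
  if (i > 1) {
    idx <- max(1, i - 2):min(n, i + 1)
    f <- splinefun(idx, profile[idx], method = "monoH.FC")
    left <- uniroot(function(t) f(t) - half, c(i - 1, i))$root
  }
  i <- peak_index
  while (i < n && profile[i + 1] >= half) i <- i + 1
  if (i < n) {
    idx <- max(1, i - 1):min(n, i + 2)
    f <- splinefun(idx, profile[idx], method = "monoH.FC")
    right <- uniroot(function(t) f(t) - half, c(i, i + 1))$root
  }
  if (is.na(left) || is.na(right))
    stopf("unresolved: no half-maximum crossing inside the profile")
  (right - left) * pitch
}

#' Effective attenuation length from a depth series of peak signals
#'
#' Fits `ln(signal)` against depth by least squares and converts the slope to
#' an effective attenuation length with the two-photon convention: the
#' excitation power attenuates as `exp(-z / EAL)`, so the two-photon signal
#' falls as `exp(-2 z / EAL)` and `EAL = -2 / slope`. An optional breakpoint
#' fits two segments (tissue layers with different scattering).
#'
#' @param signals Positive peak signals per depth.
#' @param depths Depths, um (at least 3 points).
#' @param breakpoint Optional depth splitting the fit into two segments.
#' @return For a single fit: list with `eal` (um), `slope`, and the `lm` fit.
#'   With a breakpoint: list with `eal` (length 2), `breakpoint`, `fits`.
#'   Non-decaying signals give `eal = Inf` with a warning.
#' @examples
#' z <- seq(0, 300, by = 50)
#' s <- exp(-2 * z / 100)
#' eal_fit(s, z)$eal  # 100
#' @export
eal_fit <- function(signals, depths, breakpoint = NULL) {
  if (length(signals) != length(depths)) stopf("signals and depths differ in length")
  if (length(signals) < 3) stopf("need at least 3 depth points")
  if (any(signals <= 0)) stopf("signals must be positive for a log fit")
  one_fit <- function(s, z) {
    fit <- lm(log(s) ~ z)
    slope <- coef(fit)[["z"]]
    if (slope >= 0) {
      warnf("signals do not decay with depth; EAL reported as infinite")
      return(list(eal = Inf, slope = slope, fit = fit))
    }
    list(eal = -2 / slope, slope = slope, fit = fit)
  }
  if (is.null(breakpoint)) return(one_fit(signals, depths))
  lo <- depths <= breakpoint
  if (sum(lo) < 3 || sum(!lo) < 3)
    stopf("each side of the breakpoint needs at least 3 points")
  f1 <- one_fit(signals[lo], depths[lo])
  f2 <- one_fit(signals[!lo], depths[!lo])
  list(eal = c(f1$eal, f2$eal), breakpoint = breakpoint, fits = list(f1$fit, f2$fit))
}
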