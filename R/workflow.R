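# End-to-end correction experiments: acquisition under random patterns,
# compression-ratio and binarization sweeps.

#' Acquire fluorescence measurements under a pattern set
#'
#' Records one two-photon signal per pattern. For a point target (the usual
#' correction acquisition) the transfer-vector fast path is used:
#' `I_i = |sum_j A_ij u_j|^4`; an extended phantom falls back to full
#' propagation per pattern. Optional shot/read noise and PMT clipping model
#' the detector.
#'
#' @param patterns A [random_patterns()] set.
#' @param medium A [scattering_medium()].
#' @param cfg An [optical_config()].
#' @param target Point target `c(x, y, z)` um (used unless `phantom` given).
#' @param phantom Optional [make_phantom()] object for extended targets.
#' @param depth Acquisition depth, um (attenuation via the medium's EAL).
#' @param dwell_ms Projection time per pattern, ms (metadata; default 0.5).
#' @param noise Optional list: `photons_per_unit` (Poisson shot noise scale),
#'   `read_sd` (Gaussian read noise, signal units), `clip` (PMT saturation
#'   level, signal units). `NULL` (default) disables noise.
#' @param seed Seed for the noise draws.
#' @return Object of class `measurement_set`: list with `intensities`,
#'   `dwell_ms`, `total_time_s`, `noise`, `seed`.
#' @export
acquire_measurements <- function(patterns, medium, cfg, target = c(0, 0, 0),
                                 phantom = NULL, depth = 0, dwell_ms = 0.5,
                                 noise = NULL, seed = NULL) {
  A <- pattern_matrix(patterns)
  att <- attenuation_factor(medium, depth)
  if (is.null(phantom)) {
    u <- transfer_vector(medium, cfg, target)
    E <- A %*% as.vector(unclass(u))
    I <- (Mod(E) * att)^4
  } else {
    grid <- pattern_grid(patterns)
    I <- vapply(seq_len(nrow(A)), function(i) {
      two_photon_signal(matrix(A[i, ], grid[1], grid[2]), medium, phantom, cfg,
                        depth = depth)
    }, 0)
  }
  I <- as.vector(I)
  if (!is.null(noise)) {
    I <- with_seed(seed, {
      out <- I
      if (!is.null(noise$photons_per_unit)) {
        out <- rpois(length(out), out * noise$photons_per_unit) / noise$photons_per_unit
      }
      if (!is.null(noise$read_sd) && noise$read_sd > 0) {
        out <- out + rnorm(length(out), 0, noise$read_sd)
      }
      pmax(out, 0)
    })
  }
  if (!is.null(noise$clip)) I <- pmin(I, noise$clip)
  structure(list(intensities = I, dwell_ms = dwell_ms,
                 total_time_s = length(I) * dwell_ms / 1000,
                 noise = noise, seed = seed),
            class = "measurement_set")
}

#' @export
print.measurement_set <- function(x, ...) {
  cat(sprintf("<measurement_set> %d intensities, dwell %.3g ms (%.3g s total)%s\n",
              length(x$intensities), x$dwell_ms, x$total_time_s,
              if (is.null(x$noise)) ", noise-free" else ", with noise"))
  invisible(x)
}

measurement_vector <- function(m) {
  if (inherits(m, "measurement_set")) m$intensities else as.numeric(m)
}

#' Enhancement versus number of compressive measurements
#'
#' Runs the correction for nested prefixes of one master pattern set (so the
#' curve is nested, not resampled) and records the enhancement fold of each
#' binarized mask at equal delivered power against the blank mask. Counts at
#' least the full superpixel count use the fully-sampled ON-minus-OFF
#' contrast estimator (the full-sampling algorithm) instead of the
#' compressive solve, matching instrument practice.
#'
#' @inheritParams acquire_measurements
#' @param counts Increasing measurement counts; the maximum sets the master
#'   set size.
#' @param power_ratio Binarization power ratio (default 0.30).
#' @param pattern_seed Seed of the master pattern set.
#' @param sparsity Pattern sparsity (default 0.4).
#' @param ... Passed to [cfocus()].
#' @return data.frame with columns `count`, `enhancement`, `iterations`,
#'   `converged`.
#' @export
run_measurement_sweep <- function(medium, cfg, target = c(0, 0, 0),
                                  counts = c(10, 100, 500, 1000, 2000, 5000, 10000),
                                  power_ratio = 0.30, pattern_seed = 1,
                                  sparsity = 0.4, ...) {
  if (is.unsorted(counts)) stopf("counts must be sorted ascending")
  u <- transfer_vector(medium, cfg, target)
  P <- length(u)
  master <- random_patterns(max(counts), grid = cfg$superpixels,
                            sparsity = sparsity, seed = pattern_seed)
  I <- Mod(master$patterns %*% as.vector(unclass(u)))^4
  blank <- mask_peak_signal(blank_mask(cfg$superpixels), u)
  out <- data.frame(count = counts, enhancement = NA_real_,
                    iterations = NA_integer_, converged = NA)
  for (r in seq_along(counts)) {
    n <- counts[r]
    An <- master$patterns[seq_len(n), , drop = FALSE]
    if (n >= P) {
      gray <- suppressWarnings(focus_initial_guess(An, I[seq_len(n)]))
      out$iterations[r] <- 0L; out$converged[r] <- TRUE
    } else {
      fit <- cfocus(An, I[seq_len(n)], ...)
      gray <- coef(fit)
      out$iterations[r] <- fit$iterations; out$converged[r] <- fit$converged
    }
    bin <- binarize_mask(gray, power_ratio)
    out$enhancement[r] <- enhancement_fold(mask_peak_signal(bin, u), blank)
  }
  out
}

#' Metrics versus binarization power ratio
#'
#' Binarizes one grayscale mask at several output-to-input power ratios and
#' records, for each, the enhancement fold at the target and (optionally,
#' when a bead phantom is supplied) lateral/axial FWHM and contrast of the
#' corrected point image - the trade between in-phase beam selection and
#' effective-NA reduction.
#'
#' @inheritParams run_measurement_sweep
#' @param grayscale_mask The grayscale correction mask to binarize.
#' @param ratios Power ratios in (0, 1]; the instrument sweep is
#'   `c(0.43, 0.36, 0.29, 0.22, 0.14, 0.07)`.
#' @param phantom Optional bead [make_phantom()] for PSF metrics.
#' @param psf_halfwidth Half-width (pixels) of the scanned PSF image when
#'   `phantom` is given (default 10).
#' @return data.frame with columns `ratio`, `enhancement`, and (with a
#'   phantom) `fwhm_x_um`, `fwhm_y_um`, `contrast`.
#' @export
run_ratio_sweep <- function(medium, cfg, grayscale_mask,
                            ratios = c(0.43, 0.36, 0.29, 0.22, 0.14, 0.07),
                            target = c(0, 0, 0), phantom = NULL,
                            psf_halfwidth = 10) {
  if (any(ratios <= 0 | ratios > 1)) stopf("ratios must lie in (0, 1]")
  u <- transfer_vector(medium, cfg, target)
  blank <- mask_peak_signal(blank_mask(cfg$superpixels), u)
  out <- data.frame(ratio = ratios, enhancement = NA_real_)
  if (!is.null(phantom)) {
    out$fwhm_x_um <- NA_real_; out$fwhm_y_um <- NA_real_; out$contrast <- NA_real_
  }
  for (r in seq_along(ratios)) {
    bin <- binarize_mask(grayscale_mask, ratios[r])
    out$enhancement[r] <- enhancement_fold(mask_peak_signal(bin, u), blank)
    if (!is.null(phantom)) {
      amp <- normalize_delivered_power(bin)
      img <- scan_image(bin, medium, phantom, cfg, amplitudes = amp)
      m <- try(psf_metrics(img, pixel_pitch = phantom$pitch), silent = TRUE)
      if (!inherits(m, "try-error")) {
        out$fwhm_x_um[r] <- m$fwhm_x; out$fwhm_y_um[r] <- m$fwhm_y
        out$contrast[r] <- m$contrast
      }
    }
  }
  out
}
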