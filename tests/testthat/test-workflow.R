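# End-to-end correction workflow on the scaled-down benchmark: acquisition
# bookkeeping, equal-power auditing, sweeps, memory-effect behavior and
# multi-subregion correction.

test_that("acquisition is deterministic without noise and keeps time metadata", {
  cfg <- small_cfg()
  med <- small_medium(seed = 81)
  ps <- random_patterns(3000, grid = 16, sparsity = 0.4, seed = 2)
  m1 <- acquire_measurements(ps, med, cfg, dwell_ms = 0.5)
  m2 <- acquire_measurements(ps, med, cfg, dwell_ms = 0.5)
  expect_identical(m1$intensities, m2$intensities)
  expect_equal(m1$total_time_s, 1.5)   # 3000 patterns at 0.5 ms
  withnoise <- acquire_measurements(ps, med, cfg,
                                    noise = list(photons_per_unit = 50,
                                                 read_sd = 0.01),
                                    seed = 4)
  expect_false(identical(withnoise$intensities, m1$intensities))
  again <- acquire_measurements(ps, med, cfg,
                                noise = list(photons_per_unit = 50,
                                             read_sd = 0.01),
                                seed = 4)
  expect_identical(withnoise$intensities, again$intensities)
  clipped <- acquire_measurements(ps, med, cfg,
                                  noise = list(clip = median(m1$intensities)))
  expect_lte(max(clipped$intensities), median(m1$intensities))
})

test_that("fast-path acquisition matches the closed-form toy calculation", {
  # 2 x 2 superpixels, identity medium: u_j are real multiples of the
  # aperture pixel count inside each superpixel quadrant (the even grid
  # centers the aperture off the superpixel corners, so counts differ),
  # and the signal of a pattern is |sum of counts|^4 up to one global scale
  cfg <- optical_config(superpixels = 2, superpixel_size = 8, fft_grid = 32,
                        na = 0.8)
  geom <- cfocus:::grid_geometry(cfg)
  counts <- uvec(cfocus:::block_sum(geom$aperture * 1, 8))  # per-quadrant px
  A <- rbind(c(1, 0, 0, 0), c(1, 1, 0, 0), c(1, 1, 1, 0), c(1, 1, 1, 1))
  I <- acquire_measurements(A, identity_medium(), cfg)$intensities
  expected <- Mod(as.vector(A %*% counts))^4
  expect_equal(I / I[1], expected / expected[1], tolerance = 1e-8)
})

test_that("every reported enhancement uses equal delivered power", {
  cfg <- scaled_cfg()
  med <- scaled_medium(seed = 82)
  u <- transfer_vector(med, cfg)
  ps <- random_patterns(500, grid = 32, sparsity = 0.4, seed = 5)
  I <- as.vector(Mod(ps$patterns %*% uvec(u))^4)
  cr <- compute_correction_mask(ps, I, power_ratio = 0.3)
  # audit: delivered power of the corrected arm equals the blank reference
  amp <- cr$amplitude_scale
  expect_lt(abs(sum(cr$binary) * amp^2 - length(cr$binary)), 1e-9)
  fold <- enhancement_fold(peak_signal(cr$binary, u),
                           peak_signal(blank_mask(32), u))
  expect_gt(fold, 1)
})

test_that("enhancement grows with measurement count up to full sampling", {
  cfg <- scaled_cfg()
  P <- cfg$superpixels^2
  tab <- run_measurement_sweep(scaled_medium(seed = 83), cfg,
                               counts = c(20, 100, 300, 600, P),
                               pattern_seed = 6)
  e <- tab$enhancement
  # non-decreasing within one tolerated inversion
  expect_lte(sum(diff(e) < 0), 1)
  expect_gt(e[4], e[1])
  # the fully sampled row uses the contrast estimator (no iterations)
  expect_equal(tab$iterations[5], 0)
})

test_that("identity sensing at full count recovers the mask exactly", {
  # count = P with identity sensing: the solve is separable least squares
  g <- 8
  xt <- matrix(runif(g * g), g, g)
  fit <- cfocus(diag(g * g), as.vector(xt), alpha = 0, max_iter = 1500,
                tol = 0, box = FALSE)
  expect_lt(max(abs(coef(fit) - xt)), 1e-7)
})

test_that("the ratio sweep reports sane metrics across binarization levels", {
  cfg <- scaled_cfg()
  med <- scaled_medium(seed = 86)
  u <- transfer_vector(med, cfg)
  ps <- random_patterns(250, grid = 32, sparsity = 0.4, seed = 106)
  I <- as.vector(Mod(ps$patterns %*% uvec(u))^4)
  fit <- cfocus(ps, I)
  ratios <- c(0.43, 0.29, 0.14)
  ph <- make_phantom(cfg, "bead", extent = 20, diameter = 0.4)
  tab <- run_ratio_sweep(med, cfg, coef(fit), ratios = ratios, phantom = ph,
                         psf_halfwidth = 8)
  expect_equal(tab$ratio, ratios)
  expect_true(all(tab$enhancement > 1))       # correction beats blank
  expect_true(all(is.finite(tab$fwhm_x_um)))
  # lower power ratios cannot widen the pupil: FWHM grows as NA shrinks
  expect_gte(tab$fwhm_x_um[3], tab$fwhm_x_um[1] * 0.8)
})

test_that("a ratio of one reproduces the uncorrected baseline", {
  cfg <- scaled_cfg()
  med <- scaled_medium(seed = 84)
  tab <- run_ratio_sweep(med, cfg, matrix(runif(1024), 32, 32), ratios = 1)
  expect_equal(tab$enhancement, 1.0, tolerance = 1e-12)
  expect_error(run_ratio_sweep(med, cfg, matrix(1, 32, 32), ratios = 1e-5),
               "superpixel")
})

test_that("correction decays with lateral displacement but a pupil screen does not", {
  # scanning to a displaced target applies the tilt and moves the
  # evaluation point together
  cfg <- scaled_cfg()
  shifts <- c(0, 3, 6, 12) * cfg$focal_pitch
  displaced_enh <- function(med, mask, dx) {
    ud <- transfer_vector(med, cfg, target = c(dx, 0, 0),
                          scan_shift = c(dx, 0))
    peak_signal(mask, ud) / peak_signal(blank_mask(32), ud)
  }
  decays <- vapply(1:6, function(s) {
    med <- scaled_medium(seed = s)
    mask <- oracle_mask(transfer_vector(med, cfg), 0.3)
    vapply(shifts, function(dx) displaced_enh(med, mask, dx), 0)
  }, numeric(length(shifts)))
  med_dec <- rowMeans(decays)
  expect_true(all(diff(med_dec) < 0))
  # infinite memory effect: same mask works at any tilt for a pupil screen
  medp <- make_phase_screen(cfg, 4 * cfg$superpixel_size * cfg$focal_pitch,
                            2.5, z_position = 0, seed = 9)
  mask <- oracle_mask(transfer_vector(medp, cfg), 0.3)
  e <- vapply(shifts, function(dx) displaced_enh(medp, mask, dx), 0)
  expect_lt(diff(range(e)) / e[1], 1e-6)
})

test_that("per-subregion masks beat one global mask on a two-bead phantom", {
  cfg <- scaled_cfg()
  sep <- 24 * cfg$focal_pitch    # beyond the memory-effect range
  pos <- rbind(c(-sep / 2, 0), c(sep / 2, 0))
  wins <- vapply(1:10, function(s) {
    med <- scaled_medium(seed = s)
    u1 <- transfer_vector(med, cfg, target = c(pos[1, ], 0), scan_shift = pos[1, ])
    u2 <- transfer_vector(med, cfg, target = c(pos[2, ], 0), scan_shift = pos[2, ])
    m1 <- oracle_mask(u1, 0.3); m2 <- oracle_mask(u2, 0.3)
    # global correction optimized for bead 1 only
    global <- peak_signal(m1, u1) + peak_signal(m1, u2)
    multi <- peak_signal(m1, u1) + peak_signal(m2, u2)
    multi >= global
  }, NA)
  expect_true(all(wins))
})

test_that("scanned two-bead image confirms the multi-subregion advantage", {
  cfg <- small_cfg()
  med <- small_medium(seed = 85, phase_std = 2.5, z = 40)
  sep <- 16 * cfg$focal_pitch
  ph <- make_phantom(cfg, "bead_field", extent = 32,
                     positions = rbind(c(-sep / 2, 0), c(sep / 2, 0)))
  u1 <- transfer_vector(med, cfg, target = c(-sep / 2, 0, 0),
                        scan_shift = c(-sep / 2, 0))
  u2 <- transfer_vector(med, cfg, target = c(sep / 2, 0, 0),
                        scan_shift = c(sep / 2, 0))
  m1 <- oracle_mask(u1, 0.3); m2 <- oracle_mask(u2, 0.3)
  labels <- matrix(1L, 32, 32); labels[17:32, ] <- 2L   # split along x
  a1 <- normalize_delivered_power(m1); a2 <- normalize_delivered_power(m2)
  img_multi <- scan_image(list(m1, m2), med, ph, cfg, subregions = labels,
                          amplitudes = c(a1, a2))
  img_global <- scan_image(m1, med, ph, cfg, amplitudes = a1)
  peak_right <- function(img) max(img[17:32, ])
  expect_gte(peak_right(img_multi), peak_right(img_global))
  # and the left bead is served by its own mask in both cases
  expect_equal(max(img_multi[1:16, ]), max(img_global[1:16, ]), tolerance = 1e-9)
})

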