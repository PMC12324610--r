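# Virtual microscope: propagation physics, phase screens, signal formation,
# transfer-vector fast path, and scanning.

test_that("phase-only propagation conserves energy to 1e-10", {
  cfg <- small_cfg()
  media <- list(
    identity_medium(),
    small_medium(seed = 1, z = 40),
    small_medium(seed = 2, z = 0),                       # pupil screen
    scattering_medium(screens = c(small_medium(seed = 3, z = 25)$screens,
                                  small_medium(seed = 4, z = 60)$screens))
  )
  set.seed(7)
  for (med in media) {
    for (k in 1:3) {
      mask <- matrix(rbinom(256, 1, 0.5), 16, 16)
      if (!any(mask > 0)) mask[1, 1] <- 1
      p_ref <- propagate_to_focus(mask, identity_medium(), cfg)$total_power
      p_out <- propagate_to_focus(mask, med, cfg)$total_power
      expect_lt(abs(p_out - p_ref) / p_ref, 1e-10)
    }
  }
})

test_that("zero-strength medium gives textbook diffraction of the open pupil", {
  cfg <- small_cfg()
  fs <- propagate_to_focus(blank_mask(16), identity_medium(), cfg)
  w <- which(Mod(fs$field) == max(Mod(fs$field)), arr.ind = TRUE)
  expect_equal(unname(w[1, ]), c(65, 65))  # grid center
  # the field must equal the plain Fourier transform of the apertured pupil
  geom <- cfocus:::grid_geometry(cfg)
  X <- cfocus:::pupil_field(blank_mask(16), cfg, geom)
  oracle <- cfocus:::ft2c(X)
  expect_lt(max(Mod(fs$field - oracle)), 1e-12 * max(Mod(oracle)))
})

test_that("scan tilt shifts the focal pattern per the Fourier shift theorem", {
  cfg <- small_cfg()
  med <- identity_medium()
  I0 <- Mod(propagate_to_focus(blank_mask(16), med, cfg)$field)^2
  for (k in c(3, -5)) {
    Ik <- Mod(propagate_to_focus(blank_mask(16), med, cfg,
                                 scan_shift = c(k * cfg$focal_pitch, 0))$field)^2
    w0 <- which(I0 == max(I0), arr.ind = TRUE)
    wk <- which(Ik == max(Ik), arr.ind = TRUE)
    expect_lte(abs(wk[1, 1] - w0[1, 1] - k), 1)   # within one sample
    expect_equal(unname(wk[1, 2]), unname(w0[1, 2]))
  }
  expect_error(propagate_to_focus(blank_mask(16), med, cfg,
                                  scan_shift = c(1e5, 0)),
               "beyond")
})

test_that("two-photon signal scales with the fourth power of pupil amplitude", {
  cfg <- small_cfg()
  med <- small_medium(seed = 5)
  ph <- make_phantom(cfg, "bead", extent = 32)
  s1 <- two_photon_signal(blank_mask(16), med, ph, cfg)
  s2 <- two_photon_signal(blank_mask(16), med, ph, cfg, amplitude = 2)
  expect_equal(s2, 16 * s1, tolerance = 1e-12)
  empty <- make_phantom(cfg, "uniform", extent = 16, value = 1)
  empty$conc[] <- 0
  expect_identical(two_photon_signal(blank_mask(16), med, empty, cfg), 0)
})

test_that("open pupil beats every strict sub-mask for an on-axis point emitter", {
  cfg <- tiny_cfg()
  u <- transfer_vector(identity_medium(), cfg)
  uv <- uvec(u)
  blank_sig <- Mod(sum(uv))^4
  # brute force over all 2^9 masks at the same (un-normalized) amplitude
  for (bits in 1:510) {
    on <- as.logical(bitwAnd(bits, 2^(0:8)))
    expect_lt(Mod(sum(uv[on]))^4, blank_sig)
  }
})

test_that("phase screens have the requested statistics and are reproducible", {
  cfg <- benchmark_config()
  corr <- 4 * cfg$superpixel_size * cfg$focal_pitch
  m1 <- make_phase_screen(cfg, corr, phase_std = 2, z_position = 200, seed = 11)
  m2 <- make_phase_screen(cfg, corr, phase_std = 2, z_position = 200, seed = 11)
  expect_identical(m1$screens[[1]]$phase, m2$screens[[1]]$phase)
  expect_lt(abs(sd(m1$screens[[1]]$phase) - 2) / 2, 0.05)
  m0 <- make_phase_screen(cfg, corr, phase_std = 0, z_position = 200, seed = 1)
  expect_true(all(m0$screens[[1]]$phase == 0))
  expect_error(make_phase_screen(cfg, 0.1 * cfg$focal_pitch, 1, 0, seed = 1),
               "unresolvable")
})

test_that("transfer-vector fast path matches full propagation to 1e-8", {
  cfg <- small_cfg()
  med <- scattering_medium(screens = c(small_medium(seed = 6, z = 30)$screens,
                                       small_medium(seed = 7, z = 0)$screens))
  ps <- random_patterns(50, grid = 16, sparsity = 0.4, seed = 9)
  targets <- list(c(0, 0, 0),
                  c(4 * cfg$focal_pitch, -6 * cfg$focal_pitch, 0),
                  c(0, 0, 8))
  for (tg in targets) {
    u <- transfer_vector(med, cfg, target = tg)
    idx <- c(65 + round(tg[1] / cfg$focal_pitch),
             65 + round(tg[2] / cfg$focal_pitch))
    for (i in seq_len(nrow(ps$patterns))) {
      m <- matrix(ps$patterns[i, ], 16, 16)
      full <- propagate_to_focus(m, med, cfg, z = tg[3])$field[idx[1], idx[2]]
      fast <- sum(ps$patterns[i, ] * uvec(u))
      expect_lt(Mod(full - fast) / Mod(full), 1e-8)
    }
  }
})

test_that("unaberrated transfer vector is in phase at focus and scales quartically", {
  cfg <- small_cfg()
  u <- transfer_vector(identity_medium(), cfg)
  uv <- uvec(u)
  uv <- uv[Mod(uv) > 1e-9 * max(Mod(uv))]
  expect_lt(diff(range(Arg(uv))), 1e-8)
  sig <- function(c) Mod(sum(c * uv))^4
  expect_equal(sig(3), 81 * sig(1), tolerance = 1e-12)
})

test_that("memory effect is finite for a defocused screen and absent at the pupil", {
  cfg <- small_cfg()
  tilts <- c(0, 4, 8, 16, 24)   # grid samples
  align_cor <- function(med, k) {
    E0 <- Mod(propagate_to_focus(blank_mask(16), med, cfg)$field)^2
    Ek <- Mod(propagate_to_focus(blank_mask(16), med, cfg,
                                 scan_shift = c(k * cfg$focal_pitch, 0))$field)^2
    n <- nrow(Ek)
    Ekb <- if (k > 0) rbind(Ek[(k + 1):n, ], Ek[seq_len(k), ]) else Ek
    ctr <- 33:96
    cor(as.vector(E0[ctr, ctr]), as.vector(Ekb[ctr, ctr]))
  }
  # defocused screen: correlation decays monotonically (binned over 10 seeds)
  cors <- rowMeans(vapply(1:10, function(s) {
    med <- small_medium(seed = s, phase_std = 2.5, z = 40)
    vapply(tilts, function(k) align_cor(med, k), 0)
  }, numeric(length(tilts))))
  expect_true(all(diff(cors) < 0))
  # screen in the pupil plane: tilt-invariant speckle
  for (s in 1:3) {
    med0 <- small_medium(seed = s, phase_std = 2.5, z = 0)
    cors0 <- vapply(tilts, function(k) align_cor(med0, k), 0)
    expect_true(all(abs(cors0 - 1) < 1e-6))
  }
})

test_that("scanned image of a point-like bead reproduces the two-photon PSF", {
  cfg <- small_cfg()
  ph <- make_phantom(cfg, "bead", extent = 24, diameter = 0.2)
  img <- scan_image(blank_mask(16), identity_medium(), ph, cfg)
  w <- which(img == max(img), arr.ind = TRUE)
  expect_equal(unname(w[1, ]), c(13, 13))  # bead at phantom center
  m <- psf_metrics(img, pixel_pitch = cfg$focal_pitch)
  # oracle: numerically computed |E|^4 profile of the open apertured pupil
  geom <- cfocus:::grid_geometry(cfg)
  E <- cfocus:::ft2c(cfocus:::pupil_field(blank_mask(16), cfg, geom))
  prof <- Mod(E[, 65])^4
  oracle_fwhm <- cfocus:::fwhm_1d(prof, cfg$focal_pitch)
  expect_lt(abs(m$fwhm_x - oracle_fwhm) / oracle_fwhm, 0.10)
})

test_that("scan schedules compose consistently", {
  cfg <- small_cfg()
  med <- small_medium(seed = 12)
  ph <- make_phantom(cfg, "bead", extent = 16)
  mask <- binarize_mask(matrix(runif(256), 16, 16), 0.3)
  img_global <- scan_image(mask, med, ph, cfg)
  labels <- matrix(rep(1:2, each = 8 * 16), 16, 16)
  img_split <- scan_image(list(mask, mask), med, ph, cfg, subregions = labels)
  expect_identical(img_global, img_split)   # identical masks == one global mask
  off <- matrix(0, 16, 16)
  img_off <- scan_image(list(off, mask), med, ph, cfg, subregions = labels)
  expect_true(all(img_off[labels == 1] == 0))  # all-off pixels are exactly 0
  expect_error(scan_image(list(mask), med, ph, cfg, subregions = labels),
               "assigned|mask")
})

test_that("phantoms integrate and size correctly", {
  cfg <- small_cfg()
  ph <- make_phantom(cfg, "bead", extent = 48, diameter = 0.71)
  sigma <- 0.71 / (2 * sqrt(2 * log(2)))
  analytic <- 2 * pi * sigma^2 / cfg$focal_pitch^2   # 2D Gaussian integral
  expect_lt(abs(sum(ph$conc) - analytic) / analytic, 0.01)
  un <- make_phantom(cfg, "uniform", extent = 16, value = 2)
  expect_true(all(un$conc == 2))
  fil <- make_phantom(cfg, "filament", extent = 48, diameter = 1.5, seed = 3)
  mid <- fil$conc[, , 1]
  fw <- cfocus:::fwhm_1d(mid[24, ], cfg$focal_pitch)  # cross-section at one x
  expect_lt(abs(fw - 1.5), cfg$focal_pitch)  # FWHM within one voxel
})
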