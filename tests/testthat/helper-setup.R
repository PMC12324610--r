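# Small geometries used throughout the unit tests: a 16 x 16 superpixel DMD
# with 4 x 4 pixel superpixels on a 128-point propagation grid, and a tiny
# 3 x 3 superpixel pupil for brute-force enumerations.

small_cfg <- function() {
  optical_config(superpixels = 16, superpixel_size = 4, fft_grid = 128,
                 na = 0.8)
}

tiny_cfg <- function() {
  optical_config(superpixels = 3, superpixel_size = 4, fft_grid = 16,
                 na = 0.8)
}

small_medium <- function(seed = 1, phase_std = 2, z = 40,
                         cfg = small_cfg(), corr_sp = 2) {
  make_phase_screen(cfg, correlation_length = corr_sp * cfg$superpixel_size *
                      cfg$focal_pitch,
                    phase_std = phase_std, z_position = z, seed = seed)
}

# Scaled-down analog of the standard strong-scattering benchmark used for
# statistical trend tests: 32 x 32 superpixels, strong screen at 50 um.
# The screen correlation length is the same *fraction* of the pupil width
# as the full-scale benchmark (4 of 100 superpixels), so the number of
# independent phase cells across the pupil - the quantity that sets the
# in-phase fraction and the compression regime - is preserved.
scaled_cfg <- function() {
  optical_config(superpixels = 32, superpixel_size = 4, fft_grid = 256,
                 na = 0.8)
}

scaled_medium <- function(seed = 1, cfg = scaled_cfg()) {
  make_phase_screen(cfg, correlation_length = 0.04 * cfg$superpixels *
                      cfg$superpixel_size * cfg$focal_pitch,
                    phase_std = 2.5, z_position = 50, seed = seed)
}

uvec <- function(u) as.vector(unclass(u))

derive_seed_for_test <- function(s) 1000L + 7L * s

# literal double-loop isotropic TV (forward differences, reflective
# boundary), independent of the package implementation
tv_reference <- function(x) {
  m <- nrow(x); n <- ncol(x); tv <- 0
  for (i in 1:m) for (j in 1:n) {
    dx <- if (i < m) x[i + 1, j] - x[i, j] else 0
    dy <- if (j < n) x[i, j + 1] - x[i, j] else 0
    tv <- tv + sqrt(dx^2 + dy^2)
  }
  tv
}

with_seed_for_test <- function(s, expr) {
  set.seed(2000L + s)
  expr
}

peak_signal <- function(mask, u, equal_power = TRUE) {
  s <- if (equal_power) normalize_delivered_power(mask) else 1
  Mod(sum(uvec(u)[as.vector(mask != 0)]) * s)^4
}
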