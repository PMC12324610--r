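# The compressive inverse solve: TV, initializer, FISTA oracles, and the
# in-phase selection oracle mask.

test_that("tv_norm matches closed forms and a double-loop reference", {
  expect_equal(tv_norm(matrix(5, 7, 7)), 0)
  step <- matrix(0, 4, 4); step[, 3:4] <- 1.5
  expect_equal(tv_norm(step), 4 * 1.5)    # four vertical edge terms
  set.seed(51)
  for (k in 1:5) {
    x <- matrix(rnorm(100), 10, 10)
    expect_equal(tv_norm(x), tv_reference(x), tolerance = 1e-12)
  }
})

test_that("the TV proximal operator flattens under a dominant weight", {
  set.seed(52)
  b <- matrix(runif(144), 12, 12)
  sm <- cfocus:::prox_tv(b, lambda = 1000, iters = 200, box = FALSE)
  expect_lt(diff(range(sm)), 1e-3 * abs(mean(sm)))
  expect_equal(mean(sm), mean(b), tolerance = 1e-6)  # mean is preserved
})

test_that("the contrast initializer recovers the enumerated toy system", {
  # 4 superpixels, 6 two-on patterns; signal = 1 iff superpixel 2 is on.
  A <- t(combn(4, 2, function(p) { v <- rep(0, 4); v[p] <- 1; v }))
  I <- as.numeric(A[, 2] == 1)
  g <- focus_initial_guess(A, I)
  expect_equal(as.vector(g), c(-1 / 3, 1, -1 / 3, -1 / 3), tolerance = 1e-12)
  # no contrast -> all zero
  expect_equal(as.vector(focus_initial_guess(A, rep(2, 6))), rep(0, 4))
  # anti-correlated superpixel scores negative
  expect_lt(focus_initial_guess(A, 1 - I)[2], 0)
  # a superpixel that never toggles is zeroed with a warning
  A2 <- A; A2[, 4] <- 1
  expect_warning(g2 <- focus_initial_guess(A2, I), "never toggled")
  expect_equal(as.vector(g2)[4], 0)
})

test_that("FISTA with alpha = 0 solves separable and overdetermined systems", {
  set.seed(53)
  I <- runif(16)
  fit <- cfocus(diag(16), I, alpha = 0, max_iter = 2000, tol = 0, box = FALSE)
  expect_lt(max(abs(as.vector(coef(fit)) - I)), 1e-8)
  A <- matrix(rbinom(200 * 16, 1, 0.5), 200, 16)
  xt <- runif(16)
  y <- as.vector(A %*% xt)
  fit2 <- cfocus(A, y, alpha = 0, max_iter = 3000, tol = 0, box = FALSE)
  oracle <- solve(crossprod(A), crossprod(A, y))   # normal equations
  expect_lt(max(abs(as.vector(coef(fit2)) - oracle)) / max(abs(oracle)), 1e-5)
  expect_lt(max(abs(as.vector(coef(fit2)) - xt)) / max(abs(xt)), 1e-5)
})

test_that("a dominant TV weight drives the mask to a constant", {
  set.seed(54)
  ps <- random_patterns(80, grid = 8, sparsity = 0.5, seed = 3)
  I <- runif(80)
  fit <- cfocus(ps, I, alpha = 1e7, max_iter = 500, tol = 0, box = FALSE,
                tv_inner_iter = 500)
  g <- coef(fit)
  expect_lt(diff(range(g)), 1e-3 * abs(mean(g)))
})

test_that("the objective trace is non-increasing on every solve", {
  set.seed(55)
  configs <- list(
    list(ps = random_patterns(120, grid = 8, sparsity = 0.4, seed = 5),
         alpha = 0.008, backtracking = FALSE),
    list(ps = random_patterns(60, grid = 8, sparsity = 0.3, seed = 6),
         alpha = 0.05, backtracking = TRUE)
  )
  for (cc in configs) {
    I <- runif(nrow(cc$ps$patterns))^2
    fit <- cfocus(cc$ps, I, alpha = cc$alpha, max_iter = 300,
                  backtracking = cc$backtracking)
    ob <- fit$objective$objective
    expect_true(all(diff(ob) <= 1e-9 * pmax(abs(ob[-1]), 1e-12)))
  }
})

test_that("raw-unit mode runs with a fixed step like the instrument", {
  ps <- random_patterns(150, grid = 8, sparsity = 0.4, seed = 7)
  xt <- as.vector(outer(1:8, 1:8, function(i, j) exp(-((i - 4)^2 + (j - 5)^2) / 6)))
  I <- as.vector(ps$patterns %*% xt) * 1e4   # PMT-count-like scale
  L <- 2 * max(eigen(crossprod(ps$patterns), only.values = TRUE)$values)
  fit <- cfocus(ps, I, alpha = 0.008, max_iter = 400, step_size = 0.9 / L,
                normalize = FALSE, box = FALSE)
  expect_gt(cor(as.vector(coef(fit)), xt), 0.99)
  ob <- fit$objective$objective
  expect_true(all(diff(ob) <= 1e-9 * pmax(abs(ob[-1]), 1e-12)))
  expect_error(cfocus(ps, I, normalize = FALSE), "step_size")
})

test_that("the correction pipeline returns exact on-counts and sane masks", {
  cfg <- small_cfg()
  u <- transfer_vector(identity_medium(), cfg)
  ps <- random_patterns(400, grid = 16, sparsity = 0.4, seed = 8)
  I <- as.vector(Mod(ps$patterns %*% uvec(u))^4)
  cr <- compute_correction_mask(ps, I, power_ratio = 0.29, max_iter = 300)
  expect_s3_class(cr$fit, "cfocus")
  expect_equal(sum(cr$binary), round(0.29 * 256))
  # identity medium: the full in-phase pupil is optimal at equal delivered
  # power, so any submask can only lose signal (Cauchy-Schwarz); the
  # sub-mask still beats its own power-ratio share
  expect_lte(peak_signal(cr$binary, u), peak_signal(blank_mask(16), u))
  expect_gte(peak_signal(cr$binary, u),
             0.9 * power_ratio(cr$binary)^2 * peak_signal(blank_mask(16), u))
  # all-zero measurements collapse to the zero mask with warnings
  expect_warning(expect_warning(
    cr0 <- compute_correction_mask(ps, rep(0, 400), power_ratio = 0.3,
                                   max_iter = 50),
    "zero"), "tie-break")
  expect_true(all(cr0$grayscale == 0))
})

test_that("the in-phase oracle is near-exhaustive on tiny media", {
  cfg <- tiny_cfg()
  expect_true(all(oracle_mask(transfer_vector(identity_medium(), cfg), 1.0)))
  for (s in 1:6) {
    med <- make_phase_screen(cfg, correlation_length = 3 * cfg$focal_pitch,
                             phase_std = 2.5, z_position = 10, seed = s)
    u <- transfer_vector(med, cfg)
    uv <- uvec(u)
    for (k in c(3, 4, 5)) {
      om <- oracle_mask(u, k / 9)
      expect_equal(sum(om), k)
      sig_o <- Mod(sum(uv[as.vector(om)]))^4
      best <- max(combn(9, k, function(ix) Mod(sum(uv[ix]))^4))
      expect_gte(sig_o, 0.99 * best)
    }
  }
})

test_that("oracle dominates reconstruction, which dominates random masks", {
  cfg <- scaled_cfg()
  enh <- vapply(1:10, function(s) {
    med <- scaled_medium(seed = s)
    u <- transfer_vector(med, cfg)
    ps <- random_patterns(600, grid = cfg$superpixels, sparsity = 0.4,
                          seed = derive_seed_for_test(s))
    I <- as.vector(Mod(ps$patterns %*% uvec(u))^4)
    cr <- compute_correction_mask(ps, I, power_ratio = 0.3)
    blank <- peak_signal(blank_mask(cfg$superpixels), u)
    rnd <- binarize_mask(matrix(with_seed_for_test(s, runif(cfg$superpixels^2)),
                                cfg$superpixels, cfg$superpixels), 0.3)
    c(oracle = peak_signal(oracle_mask(u, 0.3), u) / blank,
      cfocus = peak_signal(cr$binary, u) / blank,
      random = peak_signal(rnd, u) / blank)
  }, numeric(3))
  med_enh <- apply(enh, 1, median)
  expect_gte(med_enh["oracle"], med_enh["cfocus"])
  expect_gte(med_enh["cfocus"], med_enh["random"])
  # and per-seed the oracle is never beaten
  expect_true(all(enh["oracle", ] >= enh["cfocus", ]))
})
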