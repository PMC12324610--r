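# Generation and algebra of DMD patterns: random sensing patterns, blank and
# low-NA controls, binarization by output-to-input power ratio, and
# equal-delivered-power normalization.

#' Random binary sensing patterns
#'
#' Draws `n` binary superpixel patterns with an exact on-count: every pattern
#' has `round(sparsity * P)` superpixels on (positions uniform without
#' replacement), matching the instrument convention of 40% of superpixels on.
#' The fixed on-count (rather than Bernoulli sampling) removes a nuisance
#' variance source from the measurements.
#'
#' @param n Number of patterns.
#' @param grid Superpixels per side (scalar or length-2; default 100).
#' @param sparsity Fraction of superpixels turned on, in (0, 1); default 0.4.
#' @param seed Integer seed; the set is deterministic given the seed.
#' @return Object of class `pattern_set`: list with `patterns` (n x P matrix
#'   of 0/1, rows in acquisition order, superpixels in column-major grid
#'   order), `grid`, `sparsity`, `on_count`, `seed`.
#' @examples
#' ps <- random_patterns(4, grid = 10, sparsity = 0.4, seed = 1)
#' rowSums(ps$patterns)  # exactly 40 each
#' @export
random_patterns <- function(n, grid = 100, sparsity = 0.4, seed = 1) {
  if (n < 1) stopf("need at least one pattern")
  if (sparsity <= 0 || sparsity >= 1)
    stopf("sparsity must be strictly inside (0, 1) for sensing")
  grid <- rep(as.integer(grid), length.out = 2)
  P <- prod(grid)
  k <- round(sparsity * P)
  if (k < 1 || k >= P) stopf("sparsity %g leaves no degrees of freedom on a %d-superpixel grid",
                             sparsity, P)
  A <- with_seed(seed, {
    A <- matrix(0, n, P)
    for (i in seq_len(n)) A[i, sample.int(P, k)] <- 1
    A
  })
  if (n > 1 && n <= 5000) {
    # duplicated patterns would make measurements redundant; astronomically
    # unlikely but cheap to check via random projection hashing
    h <- A %*% rnorm(P)
    if (anyDuplicated(h)) warnf("pattern set contains duplicated patterns")
  }
  structure(list(patterns = A, grid = grid, sparsity = sparsity,
                 on_count = k, seed = as.integer(seed)),
            class = "pattern_set")
}

#' @export
print.pattern_set <- function(x, ...) {
  cat(sprintf("<pattern_set> %d patterns on a %d x %d superpixel grid, %d on (%.0f%%), seed %d\n",
              nrow(x$patterns), x$grid[1], x$grid[2], x$on_count,
              100 * x$sparsity, x$seed))
  invisible(x)
}

# n x P 0/1 matrix from a pattern_set or plain matrix
pattern_matrix <- function(patterns) {
  if (inherits(patterns, "pattern_set")) patterns$patterns else as.matrix(patterns)
}

pattern_grid <- function(patterns, P = NULL) {
  if (inherits(patterns, "pattern_set")) return(patterns$grid)
  if (is.null(P)) P <- ncol(patterns)
  s <- sqrt(P)
  if (s != round(s)) stopf("cannot infer a square superpixel grid from %d columns", P)
  c(s, s)
}

#' Blank and low-NA control masks
#'
#' The blank mask (all superpixels on) is the uncorrected acquisition; the
#' low-NA mask (a centered disk) mimics the DC component of a correction mask
#' and serves as the control showing that correction is more than an
#' effective-NA reduction.
#'
#' @param grid Superpixels per side (scalar or length-2).
#' @param radius Disk radius in superpixels; superpixel (i, j) is on when
#'   `(i - c)^2 + (j - c)^2 <= radius^2` about the grid center. `radius = 0`
#'   turns on the single center superpixel.
#' @return Logical superpixel matrix.
#' @export
blank_mask <- function(grid = 100) {
  grid <- rep(as.integer(grid), length.out = 2)
  matrix(TRUE, grid[1], grid[2])
}

#' @rdname blank_mask
#' @export
low_na_mask <- function(grid = 100, radius) {
  grid <- rep(as.integer(grid), length.out = 2)
  if (radius > min(grid) / 2) stopf("radius exceeds the grid half-width")
  ci <- (grid[1] + 1) / 2
  cj <- (grid[2] + 1) / 2
  outer(seq_len(grid[1]), seq_len(grid[2]),
        function(i, j) (i - ci)^2 + (j - cj)^2 <= radius^2)
}

#' Binarize a grayscale mask at an output-to-input power ratio
#'
#' Turns on exactly `round(power_ratio * P)` superpixels - those with the
#' largest grayscale values (under uniform pupil illumination the DMD
#' output-to-input power ratio equals the on-fraction). Ties are broken by
#' value and then by column-major index, so binarizations at nested ratios
#' are nested sets.
#'
#' @param gray Numeric superpixel matrix (the grayscale correction mask).
#' @param power_ratio Fraction of power to transmit, in (0, 1].
#' @return Logical mask of the same dimension.
#' @examples
#' g <- matrix(1:16, 4, 4)
#' sum(binarize_mask(g, 0.25))  # 4 superpixels on
#' @export
binarize_mask <- function(gray, power_ratio) {
  gray <- as.matrix(gray)
  if (power_ratio <= 0 || power_ratio > 1)
    stopf("power_ratio must be in (0, 1]")
  P <- length(gray)
  k <- round(power_ratio * P)
  if (k < 1) stopf("power ratio %g turns on no superpixel", power_ratio)
  if (diff(range(gray)) == 0)
    warnf("all grayscale values are equal; binarization is arbitrary up to the tie-break")
  ord <- order(as.vector(gray), seq_len(P), decreasing = c(TRUE, FALSE),
               method = "radix")
  m <- matrix(FALSE, nrow(gray), ncol(gray))
  m[ord[seq_len(k)]] <- TRUE
  m
}

#' Output-to-input power ratio of a binary mask
#'
#' Under uniform pupil illumination the transmitted power fraction equals the
#' on-superpixel fraction.
#'
#' @param mask Logical (or 0/1) superpixel matrix.
#' @return Fraction in \[0, 1\].
#' @export
power_ratio <- function(mask) {
  mask <- as.matrix(mask)
  sum(mask != 0) / length(mask)
}

#' Pupil-amplitude scale equalizing delivered power
#'
#' Correction masks block part of the pupil; to compare corrected and
#' uncorrected acquisitions at equal power on the sample, the input power to
#' the DMD is raised so that the delivered power matches the blank-mask
#' reference. Returns the amplitude multiplier `sqrt(1 / power_ratio(mask))`
#' (power scales with its square).
#'
#' @param mask Binary mask.
#' @param reference_ratio Power ratio of the reference acquisition (default 1,
#'   the blank mask).
#' @return Scalar amplitude multiplier.
#' @export
normalize_delivered_power <- function(mask, reference_ratio = 1) {
  pr <- power_ratio(mask)
  if (pr == 0) stopf("all-off mask delivers no power")
  sqrt(reference_ratio / pr)
}
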