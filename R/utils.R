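# Internal helpers shared across modules.

# Evaluate expr under a local RNG seed, restoring the caller's RNG state.
# Mirrors the approach of simulate() methods in stats.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

# Derive a child seed from a base seed and a stream index, staying within
# 32-bit integer range. Distinct streams (medium, patterns, noise, ...) must
# not collide for nearby base seeds.
derive_seed <- function(seed, stream) {
  s <- (as.double(seed) * 48271 + 11 * as.double(stream)) %% 2147483647
  as.integer(max(s, 1))
}

is_power_of_two <- function(n) n > 0 && bitwAnd(as.integer(n), as.integer(n) - 1L) == 0L

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

# Centered 2D FFT helpers. For even grids fftshift and ifftshift coincide,
# and the centered unitary transform is its own transpose, a property the
# transfer-vector computation relies on.
fftshift2 <- function(x) {
  n <- nrow(x)
  x[c((n / 2 + 1):n, 1:(n / 2)), c((n / 2 + 1):n, 1:(n / 2))]
}

ft2c <- function(x) fftshift2(fft(fftshift2(x))) / sqrt(length(x))

ift2c <- function(x) fftshift2(fft(fftshift2(x), inverse = TRUE)) / sqrt(length(x))
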