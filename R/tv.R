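# Isotropic total variation: forward differences with reflective boundary
# (the one-sided difference at the last row/column is zero), and its proximal
# operator by fast gradient projection on the dual.

#' Isotropic total variation of a mask
#'
#' `sum over pixels of sqrt(dx^2 + dy^2)` with forward differences and
#' reflective boundary handling. This is the regularizer of the correction
#' mask inverse problem; it promotes the piecewise-smooth pupil structure of
#' physical in-phase regions.
#'
#' @param x Numeric matrix.
#' @return Non-negative scalar.
#' @examples
#' tv_norm(matrix(1, 5, 5))            # 0 for a constant mask
#' m <- matrix(0, 4, 4); m[, 3:4] <- 2
#' tv_norm(m)                          # 4 vertical edge terms of height 2
#' @export
tv_norm <- function(x) {
  g <- tv_gradient(as.matrix(x))
  sum(sqrt(g$dx^2 + g$dy^2))
}

tv_gradient <- function(x) {
  m <- nrow(x); n <- ncol(x)
  list(dx = rbind(x[-1, , drop = FALSE] - x[-m, , drop = FALSE], 0),
       dy = cbind(x[, -1, drop = FALSE] - x[, -n, drop = FALSE], 0))
}

# Negative adjoint of tv_gradient: <D x, (p, q)> = <x, tv_divergence(p, q)>
# when p, q respect the boundary zeros.
tv_divergence <- function(p, q) {
  m <- nrow(p); n <- ncol(p)
  (p - rbind(0, p[-m, , drop = FALSE])) + (q - cbind(0, q[, -n, drop = FALSE]))
}

# prox of lambda * TV over the box [lo, hi] (or unconstrained), by fast
# gradient projection on the dual (pairwise disc projection for the
# isotropic norm).
prox_tv <- function(b, lambda, iters = 20, lower = 0, upper = 1, box = TRUE) {
  if (lambda <= 0) {
    return(if (box) pmin(pmax(b, lower), upper) else b)
  }
  clampf <- if (box) function(x) pmin(pmax(x, lower), upper) else identity
  m <- nrow(b); n <- ncol(b)
  p <- matrix(0, m, n); q <- p; r <- p; s <- p; tk <- 1
  for (k in seq_len(iters)) {
    x <- clampf(b + lambda * tv_divergence(r, s))
    g <- tv_gradient(x)
    pn <- r + g$dx / (8 * lambda)
    qn <- s + g$dy / (8 * lambda)
    nrm <- pmax(1, sqrt(pn^2 + qn^2))
    pn <- pn / nrm; qn <- qn / nrm
    tn <- (1 + sqrt(1 + 4 * tk^2)) / 2
    r <- pn + ((tk - 1) / tn) * (pn - p)
    s <- qn + ((tk - 1) / tn) * (qn - q)
    p <- pn; q <- qn; tk <- tn
  }
  clampf(b + lambda * tv_divergence(p, q))
}
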