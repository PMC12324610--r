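# S3 methods for fitted correction-mask objects.

#' @export
print.cfocus <- function(x, ...) {
  cat("Compressive correction-mask fit\n")
  cat(sprintf("  %d measurements, %d x %d superpixels, alpha = %g\n",
              x$n, x$grid[1], x$grid[2], x$alpha))
  cat(sprintf("  %d iterations (%s), objective %.6g\n", x$iterations,
              if (x$diverged) "diverged" else if (x$converged) "converged" else "cap reached",
              tail_obj(x)))
  invisible(x)
}

tail_obj <- function(x) x$objective$objective[nrow(x$objective)]

#' Methods for compressive correction-mask fits
#'
#' `coef()` returns the grayscale mask matrix; `predict()` evaluates the
#' fitted linear response for new patterns on the measurement scale;
#' `residuals()`/`fitted()` refer to the training measurements; `plot()`
#' shows the mask and the objective trace; `summary()` reports solver
#' diagnostics and mask statistics.
#'
#' @param object,x A [cfocus()] fit.
#' @param patterns Optional new patterns for `predict` (a
#'   [random_patterns()] set or 0/1 matrix); default: training fit values.
#' @param which Panels to draw: 1 = grayscale mask image, 2 = objective trace.
#' @param ... Unused.
#' @return See the individual generics.
#' @name cfocus-methods
NULL

#' @rdname cfocus-methods
#' @export
coef.cfocus <- function(object, ...) object$coefficients

#' @rdname cfocus-methods
#' @export
predict.cfocus <- function(object, patterns = NULL, ...) {
  if (is.null(patterns)) return(object$fitted.values)
  A <- pattern_matrix(patterns)
  # coefficients are calibrated to measurement units, so prediction is the
  # plain linear response
  as.vector(A %*% as.vector(object$coefficients))
}

#' @rdname cfocus-methods
#' @export
residuals.cfocus <- function(object, ...) object$residuals

#' @rdname cfocus-methods
#' @export
fitted.cfocus <- function(object, ...) object$fitted.values

#' @rdname cfocus-methods
#' @export
plot.cfocus <- function(x, which = 1:2, ...) {
  n_panel <- length(which)
  if (n_panel > 1) {
    old <- par(mfrow = c(1, n_panel))
    on.exit(par(old))
  }
  if (1 %in% which) {
    image(coef(x), col = gray.colors(256), axes = FALSE, asp = 1,
          main = "grayscale correction mask")
  }
  if (2 %in% which) {
    ob <- x$objective
    plot(ob$iter, ob$objective, type = "l", log = "y",
         xlab = "iteration", ylab = "objective",
         main = "FISTA objective (monotone)")
  }
  invisible(x)
}

#' @rdname cfocus-methods
#' @export
summary.cfocus <- function(object, ...) {
  g <- coef(object)
  out <- list(
    n = object$n, grid = object$grid, alpha = object$alpha,
    iterations = object$iterations, converged = object$converged,
    diverged = object$diverged,
    objective = tail_obj(object),
    fidelity = object$objective$fidelity[nrow(object$objective)],
    tv = object$objective$tv[nrow(object$objective)],
    mask_range = range(g),
    residual_sd = sd(object$residuals)
  )
  class(out) <- "summary.cfocus"
  out
}

#' @export
print.summary.cfocus <- function(x, ...) {
  cat("Compressive correction-mask fit\n")
  cat(sprintf("  measurements     %d\n", x$n))
  cat(sprintf("  superpixel grid  %d x %d\n", x$grid[1], x$grid[2]))
  cat(sprintf("  TV weight        %g\n", x$alpha))
  cat(sprintf("  iterations       %d (%s)\n", x$iterations,
              if (x$diverged) "diverged" else if (x$converged) "converged" else "cap reached"))
  cat(sprintf("  objective        %.6g (fidelity %.6g + TV %.6g)\n",
              x$objective, x$fidelity, x$alpha * x$tv))
  cat(sprintf("  mask range       [%.3g, %.3g]\n", x$mask_range[1], x$mask_range[2]))
  cat(sprintf("  residual sd      %.4g\n", x$residual_sd))
  invisible(x)
}
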