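#' Digital post-processing of scanned images
#'
#' The standard cleanup chain for point-scanned images: a frequency-domain
#' notch filter against periodic scan stripes, a 3 x 3 median filter against
#' shot noise, unsharp-mask background subtraction, and - for images acquired
#' with per-subregion masks - boundary refinement that locally matches
#' intensity across subregion borders (median-ratio blending over a small
#' pixel border).
#'
#' @param image Numeric matrix.
#' @param notch_freqs Optional list of `c(fx, fy)` normalized frequencies
#'   (cycles/pixel, in \[-0.5, 0.5\]) to suppress; each notch removes a small
#'   disk around `(fx, fy)` and its mirror.
#' @param notch_radius Notch radius in frequency samples (default 2).
#' @param median_size Median filter window (odd; default 3, `0` disables).
#' @param unsharp_sigma Standard deviation (pixels) of the Gaussian
#'   background estimate subtracted from the image (`NULL` disables).
#' @param labels Optional integer label matrix (from [segment_subregions()])
#'   enabling boundary refinement.
#' @param border Pixels on each side of a subregion boundary to blend
#'   (1-3; default 2).
#' @return Filtered image matrix.
#' @export
postprocess_image <- function(image, notch_freqs = NULL, notch_radius = 2,
                              median_size = 3, unsharp_sigma = NULL,
                              labels = NULL, border = 2) {
  img <- as.matrix(image)
  if (!is.null(notch_freqs)) img <- notch_filter(img, notch_freqs, notch_radius)
  if (median_size > 1) img <- median_filter(img, median_size)
  if (!is.null(unsharp_sigma)) {
    bg <- gaussian_blur(img, unsharp_sigma)
    img <- pmax(img - bg, 0)
  }
  if (!is.null(labels)) img <- blend_borders(img, labels, border)
  img
}

notch_filter <- function(img, freqs, radius) {
  nr <- nrow(img); nc <- ncol(img)
  Fm <- fft(img)
  fi <- ((seq_len(nr) - 1) / nr); fi[fi > 0.5] <- fi[fi > 0.5] - 1
  fj <- ((seq_len(nc) - 1) / nc); fj[fj > 0.5] <- fj[fj > 0.5] - 1
  for (fr in freqs) {
    for (sgn in c(1, -1)) {
      d2 <- outer((fi - sgn * fr[1])^2 * nr^2, (fj - sgn * fr[2])^2 * nc^2, "+")
      Fm[d2 <= radius^2] <- 0
    }
  }
  Re(fft(Fm, inverse = TRUE)) / (nr * nc)
}

median_filter <- function(img, size = 3) {
  h <- (size - 1) %/% 2
  nr <- nrow(img); nc <- ncol(img)
  padded <- img[pmin(pmax(seq_len(nr + 2 * h) - h, 1), nr),
                pmin(pmax(seq_len(nc + 2 * h) - h, 1), nc)]
  shifts <- expand.grid(di = 0:(size - 1), dj = 0:(size - 1))
  stackm <- vapply(seq_len(nrow(shifts)), function(s) {
    padded[shifts$di[s] + seq_len(nr), shifts$dj[s] + seq_len(nc)]
  }, img)
  apply(stackm, c(1, 2), median)
}

gaussian_blur <- function(img, sigma) {
  nr <- nrow(img); nc <- ncol(img)
  gi <- dnorm(((seq_len(nr) - 1 + nr / 2) %% nr) - nr / 2, sd = sigma)
  gj <- dnorm(((seq_len(nc) - 1 + nc / 2) %% nc) - nc / 2, sd = sigma)
  K <- outer(gi / sum(gi), gj / sum(gj))
  Re(fft(fft(img) * fft(K), inverse = TRUE)) / (nr * nc)
}

# Median-ratio blending across vertical and horizontal subregion borders:
# for each boundary pixel pair, the dimmer side's border strip is scaled
# toward the brighter side by a feathered gain estimated from strip medians.
blend_borders <- function(img, labels, border = 2) {
  out <- blend_axis(img, labels, border)
  t(blend_axis(t(out), t(labels), border))
}

blend_axis <- function(img, labels, border) {
  nr <- nrow(img); nc <- ncol(img)
  for (j in seq_len(nc - 1)) {
    bnd <- which(labels[, j] != labels[, j + 1])
    if (length(bnd) == 0) next
    runs <- split(bnd, cumsum(c(1, diff(bnd) != 1)))
    for (rn in runs) {
      lcols <- max(1, j - border + 1):j
      rcols <- (j + 1):min(nc, j + border)
      lmed <- median(img[rn, lcols])
      rmed <- median(img[rn, rcols])
      if (lmed <= 0 || rmed <= 0) next
      g <- lmed / rmed
      # feathered gain on the dimmer side: full correction at the boundary
      # column, fading to none at the strip's far edge
      if (g > 1) {
        w <- seq(1, 0, length.out = length(rcols) + 1)[seq_along(rcols)]
        for (ci in seq_along(rcols))
          img[rn, rcols[ci]] <- img[rn, rcols[ci]] * g^w[ci]
      } else if (g < 1) {
        w <- seq(0, 1, length.out = length(lcols) + 1)[-1]
        for (ci in seq_along(lcols))
          img[rn, lcols[ci]] <- img[rn, lcols[ci]] * (1 / g)^w[ci]
      }
    }
  }
  img
}
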