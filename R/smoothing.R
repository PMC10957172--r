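#' Gaussian smoothing kernel
#'
#' Unit-sum Gaussian kernel used for both spatial rate maps and reward-epoch
#' time histograms.  `sigma` is expressed in bins; the kernel support spans
#' `half_width` bins on each side of the centre.
#'
#' @param sigma Kernel standard deviation, in bins.
#' @param half_width Half-width of the kernel support, in bins.
#' @return Numeric vector of length `2 * half_width + 1` summing to 1.
#' @export
gaussian_kernel <- function(sigma = 5, half_width = 10) {
  stopifnot(sigma > 0, half_width >= 1)
  x <- seq(-half_width, half_width)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# n x n smoothing operator with rows renormalized at the edges, so that a
# constant vector is preserved exactly (no zero-padding inflation).
smoothing_matrix <- function(n, sigma = 5, half_width = 10) {
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  k <- exp(-d^2 / (2 * sigma^2)) * (d <= half_width)
  k / rowSums(k)
}

#' Smooth a binned rate vector
#'
#' Convolves a rate vector with a unit-sum Gaussian kernel.  Edge bins are
#' handled by renormalizing the kernel over the available support, so a
#' constant vector comes back unchanged.  Missing bins (`NA`) are linearly
#' interpolated before smoothing and re-flagged as `NA` afterwards unless
#' `keep_interpolated = TRUE`.
#'
#' @param x Numeric rate vector (may contain `NA` for unvisited bins).
#' @param sigma,half_width Kernel parameters, in bins (see
#'   [gaussian_kernel()]).
#' @param keep_interpolated Keep interpolated values in originally missing
#'   bins instead of restoring `NA`.
#' @return Smoothed numeric vector, same length as `x`.
#' @export
smooth_rate <- function(x, sigma = 5, half_width = 10,
                        keep_interpolated = FALSE) {
  if (all(!is.finite(x))) {
    abort("cannot smooth an all-missing rate vector")
  }
  miss <- !is.finite(x)
  xf <- interp_na(x)
  out <- drop(smoothing_matrix(length(x), sigma, half_width) %*% xf)
  if (!keep_interpolated) out[miss] <- NA_real_
  out
}

# Smooth the rows of a matrix (e.g. permutation replicates x bins) in one
# matrix product.  Rows containing non-finite entries are interpolated first.
smooth_rows <- function(m, sigma = 5, half_width = 10) {
  bad <- !is.finite(m)
  if (any(bad)) {
    for (i in which(rowSums(bad) > 0L)) m[i, ] <- interp_na(m[i, ])
  }
  sm <- smoothing_matrix(ncol(m), sigma, half_width)
  m %*% t(sm)
}
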