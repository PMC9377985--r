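# Replicate-padded convolution primitives. All spatial filtering in the
# package goes through these so the boundary rule (edge-clamp) is uniform:
# zero padding would manufacture spurious edge response at the image frame
# and attract the contour to it.

#' Discrete 2-D Gaussian kernel
#'
#' Gaussian truncated at radius `ceiling(4 * sigma)` and normalized to sum
#' exactly 1. The side length is odd, `2 * ceiling(4 * sigma) + 1`.
#'
#' @param sigma Kernel width in pixels; must be positive.
#' @return A square numeric matrix with odd side length, non-negative
#'   entries, summing to 1.
#' @examples
#' k <- gaussian_kernel(1)
#' sum(k)  # 1
#' @export
gaussian_kernel <- function(sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0) {
    stop("`sigma` must be a single positive number, got ",
         deparse(substitute(sigma)), " = ", format(sigma))
  }
  g <- gaussian_kernel_1d(sigma)
  outer(g, g) # outer product of normalized 1-D kernels sums to 1 exactly
}

# Normalized 1-D Gaussian, radius ceiling(4 * sigma).
gaussian_kernel_1d <- function(sigma) {
  r <- as.integer(ceiling(4 * sigma))
  x <- seq.int(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  g / sum(g)
}

# True 2-D convolution (kernel flipped 180 degrees) with replicate padding.
# Output has the input's shape. Vectorized as a shift-and-add over kernel
# taps; intended for small kernels (3x3 gradient operators, oracles).
conv2_replicate <- function(m, k) {
  stopifnot(is.matrix(m), is.matrix(k))
  if (nrow(k) %% 2L == 0L || ncol(k) %% 2L == 0L) {
    stop("kernel must have odd dimensions")
  }
  kf <- k[rev(seq_len(nrow(k))), rev(seq_len(ncol(k))), drop = FALSE]
  rr <- (nrow(k) - 1L) %/% 2L
  rc <- (ncol(k) - 1L) %/% 2L
  nr <- nrow(m)
  nc <- ncol(m)
  ri <- c(rep.int(1L, rr), seq_len(nr), rep.int(nr, rr))
  ci <- c(rep.int(1L, rc), seq_len(nc), rep.int(nc, rc))
  p <- m[ri, ci, drop = FALSE]
  out <- matrix(0, nr, nc)
  for (u in seq_len(nrow(kf))) {
    for (v in seq_len(ncol(kf))) {
      if (kf[u, v] != 0) {
        out <- out + kf[u, v] * p[u:(u + nr - 1L), v:(v + nc - 1L),
                                  drop = FALSE]
      }
    }
  }
  out
}

#' Gaussian smoothing with replicate padding
#'
#' Separable convolution with the normalized Gaussian of [gaussian_kernel()]
#' (truncated at radius `ceiling(4 * sigma)`), edge-clamp boundary. Equals
#' full 2-D convolution with the outer-product kernel to floating
#' tolerance, at O(k) per pixel instead of O(k^2).
#'
#' @param m Numeric matrix.
#' @param sigma Gaussian width in pixels (> 0).
#' @return Smoothed matrix, same shape.
#' @export
conv_gaussian <- function(m, sigma) {
  g <- gaussian_kernel_1d(sigma)
  r <- (length(g) - 1L) %/% 2L
  nr <- nrow(m)
  nc <- ncol(m)
  ri <- c(rep.int(1L, r), seq_len(nr), rep.int(nr, r))
  p <- m[ri, , drop = FALSE]
  out <- matrix(0, nr, nc)
  for (k in seq_along(g)) {
    out <- out + g[k] * p[k:(k + nr - 1L), , drop = FALSE]
  }
  ci <- c(rep.int(1L, r), seq_len(nc), rep.int(nc, r))
  p <- out[, ci, drop = FALSE]
  out <- matrix(0, nr, nc)
  for (k in seq_along(g)) {
    out <- out + g[k] * p[, k:(k + nc - 1L), drop = FALSE]
  }
  out
}

# Central-difference gradients with replicate boundary (one-sided halved
# differences at the frame, consistent with edge-clamp padding).
grad_central <- function(m) {
  nr <- nrow(m)
  nc <- ncol(m)
  up <- m[c(1L, seq_len(nr - 1L)), , drop = FALSE]
  dn <- m[c(seq_len(nr - 1L) + 1L, nr), , drop = FALSE]
  lf <- m[, c(1L, seq_len(nc - 1L)), drop = FALSE]
  rt <- m[, c(seq_len(nc - 1L) + 1L, nc), drop = FALSE]
  list(gy = (dn - up) / 2, gx = (rt - lf) / 2)
}

# 5-point Laplacian, replicate boundary.
laplacian <- function(m) {
  nr <- nrow(m)
  nc <- ncol(m)
  up <- m[c(1L, seq_len(nr - 1L)), , drop = FALSE]
  dn <- m[c(seq_len(nr - 1L) + 1L, nr), , drop = FALSE]
  lf <- m[, c(1L, seq_len(nc - 1L)), drop = FALSE]
  rt <- m[, c(seq_len(nc - 1L) + 1L, nc), drop = FALSE]
  up + dn + lf + rt - 4 * m
}

# Mean curvature of the level sets of phi: div(grad(phi)/|grad(phi)|),
# gradient-magnitude denominator floored to keep flat regions finite.
curvature <- function(phi, floor = 1e-8) {
  g <- grad_central(phi)
  n <- sqrt(g$gx^2 + g$gy^2)
  n <- pmax(n, floor)
  nx <- g$gx / n
  ny <- g$gy / n
  grad_central(nx)$gx + grad_central(ny)$gy
}
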