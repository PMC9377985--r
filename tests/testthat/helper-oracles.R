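# Independent brute-force oracles: direct nested-loop realizations of every
# discrete sum, kept free of the package's vectorized code paths. Replicate
# (edge-clamp) boundary handling is realized by index clamping.

clamp <- function(i, n) min(max(i, 1L), n)

# True 2-D convolution (kernel flipped), replicate padding, per-pixel sum.
oracle_conv2 <- function(m, k) {
  nr <- nrow(m); nc <- ncol(m)
  rr <- (nrow(k) - 1L) %/% 2L
  rc <- (ncol(k) - 1L) %/% 2L
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    s <- 0
    for (u in -rr:rr) for (v in -rc:rc) {
      s <- s + k[u + rr + 1L, v + rc + 1L] *
        m[clamp(i - u, nr), clamp(j - v, nc)]
    }
    out[i, j] <- s
  }
  out
}

oracle_gauss_kernel <- function(sigma) {
  r <- ceiling(4 * sigma)
  k <- matrix(0, 2 * r + 1, 2 * r + 1)
  for (u in -r:r) for (v in -r:r) {
    k[u + r + 1, v + r + 1] <- exp(-(u^2 + v^2) / (2 * sigma^2))
  }
  k / sum(k)
}

oracle_eg <- function(m, kernels, squared = FALSE) {
  ex <- oracle_conv2(m, kernels$px)
  ey <- oracle_conv2(m, kernels$py)
  eg <- ex^2 + ey^2
  if (!squared) eg <- sqrt(eg)
  rng <- range(eg)
  if (rng[2] - rng[1] <= 0) return(matrix(0, nrow(m), ncol(m)))
  (eg - rng[1]) / (rng[2] - rng[1])
}

oracle_heaviside <- function(z, eps) 0.5 * (1 + (2 / pi) * atan(z / eps))
oracle_dirac <- function(z, eps) (1 / pi) * eps / (eps^2 + z^2)

oracle_global_energy <- function(eg, phi, k1, k2, kappa1, kappa2, eps) {
  s <- 0
  for (i in seq_len(nrow(eg))) for (j in seq_len(ncol(eg))) {
    h <- oracle_heaviside(phi[i, j], eps)
    s <- s + kappa1 * (eg[i, j] - k1)^2 * h +
      kappa2 * (eg[i, j] - k2)^2 * (1 - h)
  }
  s
}

# Local energy: quadruple-nested double sum
#   sum_y H(phi(y)) sum_off S(off) (EG(y) - l1(y - off))^2  (+ outside term)
oracle_local_energy <- function(eg, phi, l1, l2, sigma, kappa1, kappa2,
                                eps) {
  g1 <- exp(-(seq(-ceiling(4 * sigma), ceiling(4 * sigma)))^2 /
              (2 * sigma^2))
  g1 <- g1 / sum(g1)
  r <- (length(g1) - 1L) %/% 2L
  nr <- nrow(eg); nc <- ncol(eg)
  s <- 0
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    h <- oracle_heaviside(phi[i, j], eps)
    e1 <- 0; e2 <- 0
    for (u in -r:r) for (v in -r:r) {
      w <- g1[u + r + 1] * g1[v + r + 1]
      ii <- clamp(i - u, nr); jj <- clamp(j - v, nc)
      e1 <- e1 + w * (eg[i, j] - l1[ii, jj])^2
      e2 <- e2 + w * (eg[i, j] - l2[ii, jj])^2
    }
    s <- s + kappa1 * e1 * h + kappa2 * e2 * (1 - h)
  }
  s
}

# Central differences with replicate boundary, per pixel.
oracle_gx <- function(m, i, j) {
  (m[i, clamp(j + 1, ncol(m))] - m[i, clamp(j - 1, ncol(m))]) / 2
}
oracle_gy <- function(m, i, j) {
  (m[clamp(i + 1, nrow(m)), j] - m[clamp(i - 1, nrow(m)), j]) / 2
}

# Interior-pixel sum of 0.5 * (|grad phi| - 1)^2 (the implementation
# excludes the one-pixel frame, whose one-sided differences would penalize
# exact distance functions).
oracle_regularization <- function(phi) {
  s <- 0
  for (i in 2:(nrow(phi) - 1)) for (j in 2:(ncol(phi) - 1)) {
    n <- sqrt(oracle_gx(phi, i, j)^2 + oracle_gy(phi, i, j)^2)
    s <- s + 0.5 * (n - 1)^2
  }
  s
}

oracle_length <- function(phi, eps, variant = "dirac_length") {
  s <- 0
  for (i in seq_len(nrow(phi))) for (j in seq_len(ncol(phi))) {
    n2 <- oracle_gx(phi, i, j)^2 + oracle_gy(phi, i, j)^2
    s <- s + if (variant == "dirac_length") {
      oracle_dirac(phi[i, j], eps) * sqrt(n2)
    } else {
      n2
    }
  }
  s
}

# Curvature div(grad(phi)/|grad(phi)|) per pixel, denominator floored.
oracle_curvature <- function(phi, floor = 1e-8) {
  nr <- nrow(phi); nc <- ncol(phi)
  nx <- matrix(0, nr, nc); ny <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    gx <- oracle_gx(phi, i, j); gy <- oracle_gy(phi, i, j)
    n <- max(sqrt(gx^2 + gy^2), floor)
    nx[i, j] <- gx / n; ny[i, j] <- gy / n
  }
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    out[i, j] <- oracle_gx(nx, i, j) + oracle_gy(ny, i, j)
  }
  out
}

oracle_laplacian <- function(phi) {
  nr <- nrow(phi); nc <- ncol(phi)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    out[i, j] <- phi[clamp(i - 1, nr), j] + phi[clamp(i + 1, nr), j] +
      phi[i, clamp(j - 1, nc)] + phi[i, clamp(j + 1, nc)] - 4 * phi[i, j]
  }
  out
}

# One explicit step of the gradient flow, recomputed term by term.
oracle_evolve_step <- function(phi, eg, consts, fits, params) {
  nr <- nrow(phi); nc <- ncol(phi)
  # local residuals e_i(y) = sum_off S(off) (EG(y) - l_i(y - off))^2
  sigma <- fits$kernel_sigma
  g1 <- exp(-(seq(-ceiling(4 * sigma), ceiling(4 * sigma)))^2 /
              (2 * sigma^2))
  g1 <- g1 / sum(g1)
  r <- (length(g1) - 1L) %/% 2L
  curv <- oracle_curvature(phi)
  lap <- oracle_laplacian(phi)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    e1 <- 0; e2 <- 0
    for (u in -r:r) for (v in -r:r) {
      w <- g1[u + r + 1] * g1[v + r + 1]
      ii <- clamp(i - u, nr); jj <- clamp(j - v, nc)
      e1 <- e1 + w * (eg[i, j] - fits$l1[ii, jj])^2
      e2 <- e2 + w * (eg[i, j] - fits$l2[ii, jj])^2
    }
    d <- oracle_dirac(phi[i, j], params$epsilon)
    eg_force <- params$kappa1 * (eg[i, j] - consts$k1)^2 -
      params$kappa2 * (eg[i, j] - consts$k2)^2
    local_force <- params$kappa1 * e1 - params$kappa2 * e2
    len_force <- if (params$length_variant == "dirac_length") {
      d * curv[i, j]
    } else {
      lap[i, j]
    }
    rhs <- -d * (params$alpha * eg_force +
                   (1 - params$alpha) * local_force) +
      params$beta * (lap[i, j] - curv[i, j]) + params$lam * len_force
    out[i, j] <- phi[i, j] + params$dt * rhs
  }
  out
}

oracle_metrics <- function(p, q) {
  inter <- 0; np <- 0; nq <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p))) {
    if (p[i, j] != 0) np <- np + 1
    if (q[i, j] != 0) nq <- nq + 1
    if (p[i, j] != 0 && q[i, j] != 0) inter <- inter + 1
  }
  list(ccr = inter / np, disc = 2 * inter / (np + nq))
}

rand_mat <- function(nr, nc = nr, lo = 0, hi = 1) {
  matrix(stats::runif(nr * nc, lo, hi), nr, nc)
}

# Signed distance to a centered circle of radius r on an n x n grid.
circle_sdf <- function(n, radius, ctr = (n + 1) / 2) {
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  radius - sqrt((rows - ctr)^2 + (cols - ctr)^2)
}

rel_diff <- function(a, b) {
  max(abs(a - b)) / max(max(abs(b)), 1e-12)
}
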