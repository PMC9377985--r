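test_that("smoothed Heaviside: midpoint, limits, odd symmetry", {
  expect_equal(smoothed_heaviside(0, 1), 0.5)
  expect_equal(smoothed_heaviside(1e6, 1), 1, tolerance = 1e-5)
  expect_equal(smoothed_heaviside(-1e6, 1), 0, tolerance = 1e-5)
  set.seed(1)
  z <- stats::rnorm(50, sd = 3)
  expect_equal(smoothed_heaviside(z, 0.7) + smoothed_heaviside(-z, 0.7),
               rep(1, 50), tolerance = 1e-12)
  expect_true(all(diff(smoothed_heaviside(seq(-5, 5, 0.1), 2)) > 0))
})

test_that("Gaussian kernel: normalization, symmetry, analytic center", {
  for (sigma in c(0.5, 1, 2.5)) {
    k <- gaussian_kernel(sigma)
    expect_equal(sum(k), 1, tolerance = 1e-12)
    expect_equal(k, k[nrow(k):1, ], tolerance = 1e-15)
    expect_equal(k, k[, ncol(k):1], tolerance = 1e-15)
    expect_equal(nrow(k) %% 2, 1)
  }
  k <- gaussian_kernel(1)
  r <- ceiling(4)
  raw <- outer(-r:r, -r:r, function(u, v) exp(-(u^2 + v^2) / 2))
  expect_equal(k[r + 1, r + 1], 1 / sum(raw), tolerance = 1e-12)
  expect_error(gaussian_kernel(0), "positive")
  expect_error(gaussian_kernel(-1), "positive")
})

test_that("global energy: matched partitions give zero, oracle agreement", {
  p <- model_params()
  eg <- matrix(0.4, 5, 5)
  phi <- circle_sdf(5, 2)
  expect_equal(global_energy(eg, phi, list(k1 = 0.4, k2 = 0.4), p), 0)

  eg2 <- rbind(matrix(0, 1, 2), matrix(1, 1, 2))
  phi2 <- rbind(matrix(100, 1, 2), matrix(-100, 1, 2))
  p2 <- model_params(kappa1 = 1, kappa2 = 1, epsilon = 0.01)
  expect_equal(global_energy(eg2, phi2, list(k1 = 0, k2 = 1), p2), 0,
               tolerance = 1e-3)

  set.seed(5)
  for (trial in 1:20) {
    eg <- rand_mat(6, 6)
    phi <- rand_mat(6, 6, -3, 3)
    k1 <- stats::runif(1); k2 <- stats::runif(1)
    pp <- model_params(kappa1 = 1.3, kappa2 = 0.6, epsilon = 0.8)
    expect_equal(global_energy(eg, phi, list(k1 = k1, k2 = k2), pp),
                 oracle_global_energy(eg, phi, k1, k2, 1.3, 0.6, 0.8),
                 tolerance = 1e-10)
  }
  expect_error(global_energy(matrix(0, 4, 4), matrix(0, 5, 5),
                             list(k1 = 0, k2 = 0), p), "shape")
})

test_that("region constants are the Heaviside-weighted means", {
  eg <- matrix(0.7, 6, 6)
  cst <- update_region_constants(eg, rand_mat(6, 6, -2, 2))
  expect_equal(cst$k1, 0.7, tolerance = 1e-12)
  expect_equal(cst$k2, 0.7, tolerance = 1e-12)

  eg2 <- rbind(matrix(0, 1, 2), matrix(1, 1, 2))
  phi2 <- rbind(matrix(10, 1, 2), matrix(-10, 1, 2))
  cst2 <- update_region_constants(eg2, phi2, epsilon = 0.01)
  expect_equal(cst2$k1, 0, tolerance = 1e-3)
  expect_equal(cst2$k2, 1, tolerance = 1e-3)
})

test_that("region constants minimize the global energy", {
  set.seed(7)
  p <- model_params()
  for (trial in 1:10) {
    eg <- rand_mat(8, 8)
    phi <- rand_mat(8, 8, -3, 3)
    cst <- update_region_constants(eg, phi, p$epsilon)
    e_opt <- global_energy(eg, phi, cst, p)
    for (j in 1:100) {
      pert <- list(k1 = cst$k1 + stats::rnorm(1, 0, 0.2),
                   k2 = cst$k2 + stats::rnorm(1, 0, 0.2))
      expect_gte(global_energy(eg, phi, pert, p), e_opt)
    }
  }
})

test_that("degenerate one-phase states reuse previous constants, stay finite", {
  eg <- rand_mat(6, 6)
  phi_all_in <- matrix(1e9, 6, 6)  # outside phase soft area ~ 0
  prev <- list(k1 = 0.3, k2 = 0.9)
  cst <- update_region_constants(eg, phi_all_in, epsilon = 1e-4,
                                 prev = prev)
  expect_true(is.finite(cst$k1) && is.finite(cst$k2))
  expect_equal(cst$k2, 0.9)
  cst0 <- update_region_constants(eg, phi_all_in, epsilon = 1e-4)
  expect_true(is.finite(cst0$k2))
})

test_that("local fits: constant image, one-sided degeneracy, minimizer", {
  p <- model_params(sigma = 1)
  eg <- matrix(0.42, 8, 8)
  f <- update_local_fits(eg, rand_mat(8, 8, -2, 2), p)
  expect_equal(f$l1, eg, tolerance = 1e-9)
  expect_equal(f$l2, eg, tolerance = 1e-9)

  set.seed(8)
  eg2 <- rand_mat(8, 8)
  f2 <- update_local_fits(eg2, matrix(10, 8, 8), p)
  expect_equal(f2$l1, conv_gaussian(eg2, p$sigma), tolerance = 1e-6)
  expect_true(all(is.finite(f2$l2)))

  for (trial in 1:5) {
    eg3 <- rand_mat(8, 8)
    phi3 <- rand_mat(8, 8, -3, 3)
    f3 <- update_local_fits(eg3, phi3, p)
    e_opt <- local_energy(eg3, phi3, f3, p)
    for (j in 1:100) {
      pert <- f3
      pert$l1 <- f3$l1 + conv_gaussian(rand_mat(8, 8, -0.3, 0.3), 1)
      pert$l2 <- f3$l2 + conv_gaussian(rand_mat(8, 8, -0.3, 0.3), 1)
      expect_gte(local_energy(eg3, phi3, pert, p) + 1e-12, e_opt)
    }
  }
})

test_that("local energy matches the quadruple-loop oracle and is nonnegative", {
  set.seed(9)
  p <- model_params(sigma = 1, kappa1 = 1.2, kappa2 = 0.7)
  for (trial in 1:10) {
    eg <- rand_mat(5, 5)
    phi <- rand_mat(5, 5, -3, 3)
    fits <- update_local_fits(eg, phi, p)
    expect_equal(local_energy(eg, phi, fits, p),
                 oracle_local_energy(eg, phi, fits$l1, fits$l2, 1,
                                     1.2, 0.7, p$epsilon),
                 tolerance = 1e-8)
  }
  eg <- matrix(0.5, 5, 5)
  fits <- list(l1 = eg, l2 = eg, kernel_sigma = 1)
  expect_equal(local_energy(eg, rand_mat(5, 5, -1, 1), fits, p), 0,
               tolerance = 1e-12)
  for (trial in 1:200) {
    eg <- rand_mat(4, 4)
    phi <- rand_mat(4, 4, -2, 2)
    fits <- list(l1 = rand_mat(4, 4), l2 = rand_mat(4, 4),
                 kernel_sigma = 1)
    expect_gte(local_energy(eg, phi, fits, p), -1e-12)
  }
})

test_that("regularization energy: distance plane is exact, constants cost 1/2", {
  phi <- matrix(rep(seq_len(8), each = 8), 8, 8) - 3.5  # phi = col - c
  expect_equal(regularization_energy(phi), 0, tolerance = 1e-12)
  expect_equal(regularization_energy(matrix(2, 6, 6)), 0.5 * 16)
  set.seed(10)
  for (trial in 1:10) {
    phi <- rand_mat(6, 6, -3, 3)
    expect_equal(regularization_energy(phi), oracle_regularization(phi),
                 tolerance = 1e-10)
  }
})

test_that("length energy: flat fields, circle length, variants, oracle", {
  expect_equal(length_energy(matrix(3, 6, 6), model_params()), 0,
               tolerance = 1e-10)
  expect_equal(length_energy(matrix(1.5, 6, 6),
                             model_params(length_variant = "dirichlet")), 0)
  phi <- circle_sdf(128, 20)
  expect_equal(length_energy(phi, model_params()), 2 * pi * 20,
               tolerance = 0.05)
  expect_error(model_params(length_variant = "bogus"), "length_variant")
  set.seed(12)
  for (variant in c("dirac_length", "dirichlet")) {
    p <- model_params(length_variant = variant, epsilon = 0.8)
    for (trial in 1:5) {
      phi <- rand_mat(6, 6, -2, 2)
      expect_equal(length_energy(phi, p),
                   oracle_length(phi, 0.8, variant), tolerance = 1e-10)
    }
  }
})

test_that("total energy recomposes the four weighted terms", {
  set.seed(13)
  eg <- rand_mat(8, 8)
  phi <- rand_mat(8, 8, -3, 3)
  p <- model_params(alpha = 0.5, beta = 0.2, lam = 1, sigma = 1)
  cst <- update_region_constants(eg, phi, p$epsilon)
  fits <- update_local_fits(eg, phi, p)
  expect_equal(total_energy(eg, phi, cst, fits, p),
               0.5 * global_energy(eg, phi, cst, p) +
                 0.5 * local_energy(eg, phi, fits, p) +
                 0.2 * regularization_energy(phi) +
                 1 * length_energy(phi, p),
               tolerance = 1e-10)
  # weight collapse
  p1 <- model_params(alpha = 1, beta = 0, lam = 0, sigma = 1)
  expect_equal(total_energy(eg, phi, cst, fits, p1),
               global_energy(eg, phi, cst, p1))
  p0 <- model_params(alpha = 0, beta = 0, lam = 0, sigma = 1)
  expect_equal(total_energy(eg, phi, cst, fits, p0),
               local_energy(eg, phi, fits, p0))
  # affine in each weight: doubling beta doubles the regularization part
  pb <- model_params(alpha = 0.5, beta = 0.4, lam = 1, sigma = 1)
  expect_equal(total_energy(eg, phi, cst, fits, pb) -
                 total_energy(eg, phi, cst, fits, p),
               0.2 * regularization_energy(phi), tolerance = 1e-10)
})

test_that("every energy term is nonnegative on random inputs", {
  set.seed(14)
  p <- model_params(sigma = 1)
  for (trial in 1:25) {
    eg <- rand_mat(6, 6)
    phi <- rand_mat(6, 6, -4, 4)
    cst <- update_region_constants(eg, phi, p$epsilon)
    fits <- update_local_fits(eg, phi, p)
    expect_gte(global_energy(eg, phi, cst, p), 0)
    expect_gte(local_energy(eg, phi, fits, p), -1e-12)
    expect_gte(regularization_energy(phi), 0)
    expect_gte(length_energy(phi, p), 0)
  }
})
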