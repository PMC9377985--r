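# The four energy terms of the segmentation functional and the closed-form
# minimizers of their fitting constants. Region membership "inside/outside
# the evolving contour" is realized by a smoothed Heaviside of the level-set
# function (inside = phi > 0); discrete sums over pixels realize the
# integrals.

#' Smoothed Heaviside function
#'
#' `H_eps(z) = 1/2 * (1 + (2/pi) * atan(z / eps))`, the differentiable
#' surrogate for region membership: values in `(0, 1)`, strictly increasing,
#' `H_eps(0) = 1/2`.
#'
#' @param z Numeric vector/matrix (typically a level-set field).
#' @param epsilon Smoothing width in pixels (> 0).
#' @return Same shape as `z`, values in `(0, 1)`.
#' @export
smoothed_heaviside <- function(z, epsilon = 1) {
  check_scalar(epsilon, "epsilon", 0, strict_lower = TRUE)
  0.5 * (1 + (2 / pi) * atan(z / epsilon))
}

#' Smoothed Dirac delta
#'
#' Derivative of [smoothed_heaviside()]:
#' `delta_eps(z) = (1/pi) * eps / (eps^2 + z^2)`. Concentrates weight near
#' the zero level set (the contour) but has global support, which lets the
#' region forces act away from the current interface.
#'
#' @inheritParams smoothed_heaviside
#' @return Same shape as `z`, positive values.
#' @export
dirac_delta <- function(z, epsilon = 1) {
  check_scalar(epsilon, "epsilon", 0, strict_lower = TRUE)
  (1 / pi) * epsilon / (epsilon^2 + z^2)
}

check_same_shape <- function(a, b, na, nb) {
  if (!is.matrix(a) || !is.matrix(b) || any(dim(a) != dim(b))) {
    stop("`", na, "` and `", nb, "` must be matrices of identical shape")
  }
}

# Soft-area fraction below which a phase is considered degenerate and the
# previous iterate's constant/fit is reused.
.area_guard_frac <- 1e-6
# Floor for convolution denominators in the local-fit update.
.den_guard <- 1e-8

#' Global (piecewise-constant) region energy
#'
#' `kappa1 * sum((EG - k1)^2 * H) + kappa2 * sum((EG - k2)^2 * (1 - H))`
#' with `H = H_eps(phi)`: the Chan-Vese-style fit of the edge-guided image
#' by one constant inside the contour and one outside.
#'
#' @param eg Edge-guided image matrix.
#' @param phi Level-set field, same shape as `eg`.
#' @param consts List with scalars `k1` (inside) and `k2` (outside), e.g.
#'   from [update_region_constants()].
#' @param params [model_params()] object (uses `kappa1`, `kappa2`,
#'   `epsilon`).
#' @return Non-negative scalar.
#' @export
global_energy <- function(eg, phi, consts, params = model_params()) {
  check_same_shape(eg, phi, "eg", "phi")
  h <- smoothed_heaviside(phi, params$epsilon)
  params$kappa1 * sum((eg - consts$k1)^2 * h) +
    params$kappa2 * sum((eg - consts$k2)^2 * (1 - h))
}

#' Optimal region constants
#'
#' Closed-form minimizers of the global energy with the contour fixed: the
#' Heaviside-weighted means of the edge-guided image inside and outside,
#' `k1 = sum(EG * H) / sum(H)`, `k2 = sum(EG * (1 - H)) / sum(1 - H)`.
#' When a phase's soft area falls below 1e-6 of the image the previous
#' constant (argument `prev`, or the overall image mean) is reused so
#' degenerate one-phase states never produce non-finite values.
#'
#' @inheritParams global_energy
#' @param epsilon Heaviside smoothing width (pixels).
#' @param prev Optional previous constants, reused for degenerate phases.
#' @return List with scalars `k1`, `k2`.
#' @export
update_region_constants <- function(eg, phi, epsilon = 1, prev = NULL) {
  check_same_shape(eg, phi, "eg", "phi")
  h <- smoothed_heaviside(phi, epsilon)
  a1 <- sum(h)
  a2 <- sum(1 - h)
  guard <- .area_guard_frac * length(eg)
  fallback <- function(p) if (is.null(prev)) mean(eg) else p
  k1 <- if (a1 < guard) fallback(prev$k1) else sum(eg * h) / a1
  k2 <- if (a2 < guard) fallback(prev$k2) else sum(eg * (1 - h)) / a2
  list(k1 = k1, k2 = k2)
}

#' Optimal local fitting fields
#'
#' Closed-form minimizers of the local energy with the contour fixed:
#' Gaussian-weighted means of the edge-guided image restricted to each
#' phase, `l1 = (S * (EG H)) / (S * H)` and
#' `l2 = (S * (EG (1 - H))) / (S * (1 - H))` where `S` is the normalized
#' Gaussian window (replicate-padded convolution). Denominators are floored
#' at 1e-8; where a phase's soft area is globally degenerate the previous
#' fit (or the smoothed image) is reused.
#'
#' @inheritParams global_energy
#' @param prev Optional previous fits, reused for degenerate phases.
#' @return List with matrices `l1`, `l2` and scalar `kernel_sigma`.
#' @export
update_local_fits <- function(eg, phi, params = model_params(),
                              prev = NULL) {
  check_same_shape(eg, phi, "eg", "phi")
  local_fits_impl(eg, phi, params,
                  s_eg = conv_gaussian(eg, params$sigma), prev = prev)
}

# Pointwise local fitting residuals
#   e_i(y) = sum_x S(x - y) * (EG(y) - l_i(x))^2
# via the expansion EG^2 - 2 EG (S*l) + S*(l^2); S is normalized and
# replicate-padded so S*1 = 1 exactly.
local_residuals <- function(eg, fits) {
  s_l1 <- conv_gaussian(fits$l1, fits$kernel_sigma)
  s_l1sq <- conv_gaussian(fits$l1^2, fits$kernel_sigma)
  s_l2 <- conv_gaussian(fits$l2, fits$kernel_sigma)
  s_l2sq <- conv_gaussian(fits$l2^2, fits$kernel_sigma)
  list(e1 = eg^2 - 2 * eg * s_l1 + s_l1sq,
       e2 = eg^2 - 2 * eg * s_l2 + s_l2sq)
}

#' Local (Gaussian-window) region energy
#'
#' The local-binary-fitting energy
#' `kappa1 * sum_y e1(y) H(phi(y)) + kappa2 * sum_y e2(y) (1 - H(phi(y)))`
#' with `e_i(y) = sum_x S(x - y) (EG(y) - l_i(x))^2`, evaluated via three
#' convolutions (expansion of the square). Robust to intensity
#' inhomogeneity because the fits `l1`, `l2` vary over the image.
#'
#' @inheritParams global_energy
#' @param fits Local fits from [update_local_fits()].
#' @return Non-negative scalar (up to floating round-off).
#' @export
local_energy <- function(eg, phi, fits, params = model_params()) {
  check_same_shape(eg, phi, "eg", "phi")
  check_same_shape(eg, fits$l1, "eg", "fits$l1")
  h <- smoothed_heaviside(phi, params$epsilon)
  e <- local_residuals(eg, fits)
  params$kappa1 * sum(e$e1 * h) + params$kappa2 * sum(e$e2 * (1 - h))
}

#' Distance-regularization energy
#'
#' `sum(0.5 * (|grad(phi)| - 1)^2)` over interior pixels, with
#' central-difference gradients: penalizes deviation of the level-set field
#' from a signed-distance profile so it stays well conditioned without
#' reinitialization. The one-pixel frame is excluded from the sum because
#' its one-sided (replicate-boundary) differences halve the gradient there
#' and would spuriously penalize exact distance functions.
#'
#' @param phi Level-set field (finite values), at least 3x3.
#' @return Non-negative scalar.
#' @export
regularization_energy <- function(phi) {
  if (!all(is.finite(phi))) stop("`phi` contains non-finite values")
  g <- grad_central(phi)
  n <- sqrt(g$gx^2 + g$gy^2)
  interior <- 0.5 * (n - 1)^2
  sum(interior[2:(nrow(phi) - 1), 2:(ncol(phi) - 1)])
}

#' Contour-length energy
#'
#' Default variant `"dirac_length"`: `sum(delta_eps(phi) * |grad(phi)|)`,
#' the smoothed length of the zero level set. Variant `"dirichlet"`:
#' `sum(|grad(phi)|^2)`, a Dirichlet-energy reading of the length penalty
#' retained as an alternative.
#'
#' @param phi Level-set field.
#' @param params [model_params()] object (uses `epsilon`,
#'   `length_variant`).
#' @return Non-negative scalar.
#' @export
length_energy <- function(phi, params = model_params()) {
  if (!all(is.finite(phi))) stop("`phi` contains non-finite values")
  g <- grad_central(phi)
  n2 <- g$gx^2 + g$gy^2
  switch(params$length_variant,
    dirac_length = sum(dirac_delta(phi, params$epsilon) * sqrt(n2)),
    dirichlet = sum(n2),
    stop("unknown `length_variant` \"", params$length_variant, "\"")
  )
}

#' Total segmentation energy
#'
#' `alpha * F_global + (1 - alpha) * F_local + beta * F_reg + lam * F_len`.
#'
#' @inheritParams local_energy
#' @param consts Region constants (see [update_region_constants()]).
#' @return Scalar total energy.
#' @export
total_energy <- function(eg, phi, consts, fits, params = model_params()) {
  params$alpha * global_energy(eg, phi, consts, params) +
    (1 - params$alpha) * local_energy(eg, phi, fits, params) +
    params$beta * regularization_energy(phi) +
    params$lam * length_energy(phi, params)
}
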