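# Synthetic OCT phantom generator. Emulates a cross-sectional OCT image of
# a coronary artery: dark lumen, bright intima band, dark media band,
# mid-intensity adventitia, optional low-intensity plaque sector,
# multiplicative Gamma speckle, radial signal attenuation, and additive
# Gaussian noise, with exact ground-truth masks derived from the geometry
# alone. Stands in for clinical images so every component is testable
# without patient data.

#' Phantom specification
#'
#' Geometry, layer intensities and noise profile of a synthetic OCT
#' cross-section. The image is a square of side `size`; concentric layers
#' around the center are, outward: lumen (radius `lumen_radius`), intima,
#' media and adventitia bands of the given thicknesses, then a dark
#' background floor (intensity 0.02). The intima must be brighter than the
#' media (the characteristic OCT contrast of the vessel wall).
#'
#' Noise model: a multiplicative Gamma speckle field with `speckle_looks`
#' looks (shape `L`, mean 1, variance `1/L` — the standard first-order
#' model for coherent-imaging speckle), then additive Gaussian noise, then
#' clipping to `[0, 1]`. `speckle_looks >= 1e6` (or `Inf`) is treated as
#' the exact no-speckle limit. A radial attenuation factor
#' `exp(-attenuation_coeff * r)` is applied outside the lumen (signal decay
#' with depth). All randomness derives from the single `seed`.
#'
#' @param size Image side length in pixels.
#' @param lumen_radius Lumen radius in pixels.
#' @param intima_thickness,media_thickness,adventitia_thickness Band
#'   thicknesses in pixels (the adventitia band bounds the ground-truth
#'   vessel annulus).
#' @param layer_intensities Named numeric vector with entries `lumen`,
#'   `intima`, `media`, `adventitia`, each in `[0, 1]`.
#' @param plaque `NULL`, or a list with `start_deg` (sector start angle,
#'   degrees), `extent_deg` (angular extent), `depth_px` (radial depth from
#'   the lumen boundary), `intensity` (in `[0, 1]`): a lipid-like sector
#'   replacing wall tissue.
#' @param speckle_looks Positive number of speckle looks `L`.
#' @param gaussian_noise_sd Additive noise standard deviation (intensity
#'   units).
#' @param attenuation_coeff Radial decay per pixel (>= 0).
#' @param seed Integer seed for all randomness.
#' @return A list of class `"phantom_spec"`.
#' @export
phantom_spec <- function(size = 128L,
                         lumen_radius = 18,
                         intima_thickness = 5,
                         media_thickness = 5,
                         adventitia_thickness = 14,
                         layer_intensities = c(lumen = 0.05, intima = 0.85,
                                               media = 0.30,
                                               adventitia = 0.55),
                         plaque = list(start_deg = 30, extent_deg = 90,
                                       depth_px = 10, intensity = 0.35),
                         speckle_looks = 4,
                         gaussian_noise_sd = 0.01,
                         attenuation_coeff = 0.005,
                         seed = 1L) {
  size <- as.integer(check_scalar(size, "size", 16))
  check_scalar(lumen_radius, "lumen_radius", 1, strict_lower = TRUE)
  check_scalar(intima_thickness, "intima_thickness", 0, strict_lower = TRUE)
  check_scalar(media_thickness, "media_thickness", 0, strict_lower = TRUE)
  check_scalar(adventitia_thickness, "adventitia_thickness", 0,
               strict_lower = TRUE)
  li <- layer_intensities
  need <- c("lumen", "intima", "media", "adventitia")
  if (!all(need %in% names(li))) {
    stop("`layer_intensities` must name ", paste(need, collapse = ", "))
  }
  for (nm in need) check_scalar(li[[nm]], paste0("layer_intensities$", nm),
                                0, 1)
  if (li[["intima"]] <= li[["media"]]) {
    stop("`layer_intensities`: intima (bright band) must exceed media ",
         "(dark band); got ", li[["intima"]], " <= ", li[["media"]])
  }
  if (lumen_radius + intima_thickness + media_thickness >= size / 2) {
    stop("`lumen_radius` + `intima_thickness` + `media_thickness` must be ",
         "< size/2 = ", size / 2)
  }
  if (lumen_radius + intima_thickness + media_thickness +
      adventitia_thickness >= size / 2) {
    stop("`adventitia_thickness` pushes the wall past size/2 = ", size / 2)
  }
  if (!is.null(plaque)) {
    for (nm in c("start_deg", "extent_deg", "depth_px", "intensity")) {
      if (is.null(plaque[[nm]])) stop("`plaque$", nm, "` is missing")
    }
    check_scalar(plaque$extent_deg, "plaque$extent_deg", 0, 360,
                 strict_lower = TRUE)
    check_scalar(plaque$depth_px, "plaque$depth_px", 0, strict_lower = TRUE)
    check_scalar(plaque$intensity, "plaque$intensity", 0, 1)
  }
  check_scalar(speckle_looks, "speckle_looks", 0, strict_lower = TRUE)
  check_scalar(gaussian_noise_sd, "gaussian_noise_sd", 0)
  check_scalar(attenuation_coeff, "attenuation_coeff", 0)
  structure(list(
    size = size, lumen_radius = lumen_radius,
    intima_thickness = intima_thickness,
    media_thickness = media_thickness,
    adventitia_thickness = adventitia_thickness,
    layer_intensities = li, plaque = plaque,
    speckle_looks = speckle_looks,
    gaussian_noise_sd = gaussian_noise_sd,
    attenuation_coeff = attenuation_coeff,
    seed = as.integer(seed)
  ), class = "phantom_spec")
}

.background_intensity <- 0.02

#' Generate a synthetic OCT phantom
#'
#' Renders the phantom described by `spec` on the Cartesian grid (pixel
#' centers at integer `(row, col)` coordinates; the geometric center is at
#' `(size + 1) / 2`). Ground-truth masks depend on the geometry only, never
#' on the noise parameters.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `"phantom_bundle"` with `image` (noisy, clipped
#'   to `[0, 1]`), `clean` (noise-free, attenuated), `gt_vessel_mask`
#'   (intima+media+adventitia annulus, 0/1 matrix), `gt_plaque_mask`
#'   (plaque sector, subset of the vessel mask; all-zero when no plaque),
#'   and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$size
  ctr <- (n + 1) / 2
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  r <- sqrt((rows - ctr)^2 + (cols - ctr)^2)
  li <- spec$layer_intensities
  r1 <- spec$lumen_radius
  r2 <- r1 + spec$intima_thickness
  r3 <- r2 + spec$media_thickness
  r4 <- r3 + spec$adventitia_thickness
  img <- matrix(.background_intensity, n, n)
  img[r <= r4] <- li[["adventitia"]]
  img[r <= r3] <- li[["media"]]
  img[r <= r2] <- li[["intima"]]
  img[r <= r1] <- li[["lumen"]]
  gt_vessel <- (r > r1 & r <= r4) * 1L
  gt_plaque <- matrix(0L, n, n)
  if (!is.null(spec$plaque)) {
    # angle measured counter-clockwise from the +x (column) axis, degrees
    theta <- (atan2(-(rows - ctr), cols - ctr) * 180 / pi) %% 360
    a0 <- spec$plaque$start_deg %% 360
    rel <- (theta - a0) %% 360
    in_sector <- rel < spec$plaque$extent_deg
    in_depth <- r > r1 & r <= min(r1 + spec$plaque$depth_px, r4)
    sel <- in_sector & in_depth
    img[sel] <- spec$plaque$intensity
    gt_plaque[sel] <- 1L
  }
  atten <- ifelse(r > r1, exp(-spec$attenuation_coeff * r), 1)
  clean <- img * atten
  set.seed(spec$seed)
  noisy <- clean
  if (is.finite(spec$speckle_looks) && spec$speckle_looks < 1e6) {
    looks <- spec$speckle_looks
    speckle <- matrix(stats::rgamma(n * n, shape = looks, rate = looks),
                      n, n)
    noisy <- noisy * speckle
  }
  if (spec$gaussian_noise_sd > 0) {
    noisy <- noisy + matrix(stats::rnorm(n * n, 0, spec$gaussian_noise_sd),
                            n, n)
  }
  noisy <- pmin(pmax(noisy, 0), 1)
  structure(list(image = noisy, clean = clean,
                 gt_vessel_mask = gt_vessel, gt_plaque_mask = gt_plaque,
                 spec = spec), class = "phantom_bundle")
}

#' Seeded phantom fixture suite
#'
#' A reproducible population of phantoms with jittered geometry: the lumen
#' radius and each band thickness are scaled by independent
#' `Uniform(0.8, 1.2)` factors and the plaque sector start angle is drawn
#' uniformly on `[0, 360)`; the noise profile of `base` is kept fixed.
#' Phantom `k` uses seed `base_seed + k - 1` for both the jitter and the
#' noise.
#'
#' @param n Number of phantoms (>= 1).
#' @param base_seed First seed.
#' @param base Template [phantom_spec()] providing the un-jittered geometry
#'   and the noise profile.
#' @return List of `n` `phantom_bundle` objects.
#' @export
fixture_suite <- function(n = 20L, base_seed = 1L, base = phantom_spec()) {
  n <- as.integer(check_scalar(n, "n", 1))
  lapply(seq_len(n), function(k) {
    seed_k <- as.integer(base_seed + k - 1L)
    set.seed(seed_k)
    jit <- stats::runif(4, 0.8, 1.2)
    plaque <- base$plaque
    if (!is.null(plaque)) plaque$start_deg <- stats::runif(1, 0, 360)
    spec <- phantom_spec(
      size = base$size,
      lumen_radius = base$lumen_radius * jit[1],
      intima_thickness = base$intima_thickness * jit[2],
      media_thickness = base$media_thickness * jit[3],
      adventitia_thickness = base$adventitia_thickness * jit[4],
      layer_intensities = base$layer_intensities,
      plaque = plaque,
      speckle_looks = base$speckle_looks,
      gaussian_noise_sd = base$gaussian_noise_sd,
      attenuation_coeff = base$attenuation_coeff,
      seed = seed_k
    )
    generate_phantom(spec)
  })
}
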