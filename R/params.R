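# Model parameter containers and config resolution. All scalar knobs of the
# energy functional live in one validated object so the CLI, the config file
# and the defaults share a single schema.

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("`", name, "` must be a single finite number")
  }
  bad_lo <- if (strict_lower) x <= lower else x < lower
  bad_hi <- if (strict_upper) x >= upper else x > upper
  if (bad_lo || bad_hi) {
    stop("`", name, "` = ", format(x), " is out of range [",
         format(lower), ", ", format(upper), "]")
  }
  as.numeric(x)
}

#' Model parameters of the adaptive segmentation energy
#'
#' All weights and discretization controls of the four-term functional
#' `F = alpha * F_global + (1 - alpha) * F_local + beta * F_reg +
#' lam * F_len`.
#'
#' @param alpha Global-term weight in `[0, 1]`; `1 - alpha` weights the
#'   local term, so the region fit is a convex combination of the two.
#' @param beta Distance-regularization weight (>= 0). Keeps `|grad(phi)|`
#'   near 1 so the level-set function needs no reinitialization.
#' @param lam Contour-length weight (>= 0).
#' @param kappa1,kappa2 Inside/outside fitting weights (> 0) shared by the
#'   global and local terms. The default 50 balances the data forces
#'   against the geometric terms for edge-guided images normalized to
#'   `[0, 1]`, whose squared fitting residuals are of order 1e-2; with
#'   unit weights the gradient flow is too weak to move the contour to the
#'   minimizer within any practical iteration budget.
#' @param sigma Gaussian window width of the local term, in pixels (> 0).
#' @param epsilon Smoothing width, in pixels, of the regularized Heaviside
#'   and Dirac surrogates for region membership and contour localization.
#' @param dt Evolution time step (> 0). `dt * beta > 0.25` triggers a
#'   diffusion-stability warning at evolution time.
#' @param max_iter Iteration cap (>= 1).
#' @param tol Relative total-energy convergence tolerance (> 0), assessed
#'   over a 10-iteration window.
#' @param length_variant `"dirac_length"` (default): smoothed contour
#'   length `sum(delta_eps(phi) * |grad(phi)|)`; `"dirichlet"`: the
#'   Dirichlet energy `sum(|grad(phi)|^2)`, a literal alternative reading
#'   of the length penalty.
#' @return A list of class `"pdeac_params"`.
#' @export
model_params <- function(alpha = 0.5, beta = 0.2, lam = 1.0,
                         kappa1 = 50, kappa2 = 50, sigma = 3.0,
                         epsilon = 1.0, dt = 0.5, max_iter = 800L,
                         tol = 1e-6,
                         length_variant = c("dirac_length", "dirichlet")) {
  if (length(length_variant) == 1L &&
      !length_variant %in% c("dirac_length", "dirichlet")) {
    stop("unknown `length_variant` \"", length_variant,
         "\"; use \"dirac_length\" or \"dirichlet\"")
  }
  length_variant <- match.arg(length_variant)
  p <- list(
    alpha = check_scalar(alpha, "alpha", 0, 1),
    beta = check_scalar(beta, "beta", 0),
    lam = check_scalar(lam, "lam", 0),
    kappa1 = check_scalar(kappa1, "kappa1", 0, strict_lower = TRUE),
    kappa2 = check_scalar(kappa2, "kappa2", 0, strict_lower = TRUE),
    sigma = check_scalar(sigma, "sigma", 0, strict_lower = TRUE),
    epsilon = check_scalar(epsilon, "epsilon", 0, strict_lower = TRUE),
    dt = check_scalar(dt, "dt", 0, strict_lower = TRUE),
    max_iter = as.integer(check_scalar(max_iter, "max_iter", 1)),
    tol = check_scalar(tol, "tol", 0, strict_lower = TRUE),
    length_variant = length_variant
  )
  structure(p, class = "pdeac_params")
}

#' @export
print.pdeac_params <- function(x, ...) {
  cat("pdeac model parameters:\n")
  cat(sprintf("  alpha=%g beta=%g lam=%g kappa1=%g kappa2=%g\n",
              x$alpha, x$beta, x$lam, x$kappa1, x$kappa2))
  cat(sprintf("  sigma=%g epsilon=%g dt=%g max_iter=%d tol=%g (%s)\n",
              x$sigma, x$epsilon, x$dt, x$max_iter, x$tol,
              x$length_variant))
  invisible(x)
}

#' Initial-contour specification
#'
#' Describes the initial level-set region: a circle, an axis-aligned box, or
#' an explicit binary mask. The initial region must intersect both the image
#' and its complement (both phases nonempty), checked at materialization
#' time by [initialize_level_set()].
#'
#' @param mode One of `"circle"`, `"box"`, `"mask"`.
#' @param center Pixel coordinates `c(row, col)`, 1-based (circle/box).
#' @param radius Circle radius in pixels.
#' @param half_size Box half side length in pixels.
#' @param mask Binary matrix (nonzero = inside) for `mode = "mask"`.
#' @param c0 Initial plateau magnitude (> 0); the level-set function starts
#'   as the binary step `+c0` inside / `-c0` outside.
#' @return A list of class `"pdeac_init"`.
#' @export
init_spec <- function(mode = c("circle", "box", "mask"), center = NULL,
                      radius = NULL, half_size = NULL, mask = NULL,
                      c0 = 2) {
  mode <- match.arg(mode)
  c0 <- check_scalar(c0, "c0", 0, strict_lower = TRUE)
  out <- list(mode = mode, center = center, radius = radius,
              half_size = half_size, mask = mask, c0 = c0)
  if (mode == "circle") {
    if (is.null(center) || is.null(radius)) {
      stop("circle init needs `center` and `radius`")
    }
  } else if (mode == "box") {
    if (is.null(center) || is.null(half_size)) {
      stop("box init needs `center` and `half_size`")
    }
  } else if (is.null(mask)) {
    stop("mask init needs `mask`")
  }
  structure(out, class = "pdeac_init")
}

#' Geodesic active-contour baseline parameters
#'
#' @param edge_sigma Gaussian pre-smoothing width (pixels, > 0) used to
#'   build the edge-stopping function.
#' @param balloon Signed propagation weight; negative shrinks the contour,
#'   positive inflates it.
#' @param dt Time step (> 0).
#' @param max_iter Iteration cap (>= 1).
#' @param epsilon Dirac smoothing width (pixels, > 0).
#' @return A list of class `"pdeac_gac_params"`.
#' @export
gac_params <- function(edge_sigma = 2.0, balloon = -0.3, dt = 0.5,
                       max_iter = 2000L, epsilon = 1.0) {
  structure(list(
    edge_sigma = check_scalar(edge_sigma, "edge_sigma", 0,
                              strict_lower = TRUE),
    balloon = check_scalar(balloon, "balloon"),
    dt = check_scalar(dt, "dt", 0, strict_lower = TRUE),
    max_iter = as.integer(check_scalar(max_iter, "max_iter", 1)),
    epsilon = check_scalar(epsilon, "epsilon", 0, strict_lower = TRUE)
  ), class = "pdeac_gac_params")
}

#' Resolve model configuration from file and overrides
#'
#' Reads a YAML or JSON configuration whose keys are [model_params()],
#' [init_spec()] and [gac_params()] argument names grouped under `model`,
#' `init` and `gac` (any group may be absent), applies CLI-style overrides
#' on top, and validates. Precedence: overrides > file > documented
#' defaults. Unknown keys are rejected.
#'
#' @param file Path to a `.yaml`/`.yml`/`.json` config, or `NULL`.
#' @param overrides Named list of the same grouped shape, applied last.
#' @return List with elements `model`, `init` (may be `NULL` if neither
#'   source specified one), and `gac`.
#' @export
resolve_config <- function(file = NULL, overrides = list()) {
  cfg <- list()
  if (!is.null(file)) {
    if (!file.exists(file)) stop("config file not found: ", file)
    ext <- tolower(tools::file_ext(file))
    cfg <- switch(ext,
      "yaml" = ,
      "yml" = yaml::read_yaml(file),
      "json" = jsonlite::read_json(file, simplifyVector = TRUE),
      stop("unsupported config format \".", ext,
           "\"; supported: yaml, yml, json")
    )
    if (is.null(cfg)) cfg <- list()
  }
  merge_group <- function(base, extra, where) {
    if (is.null(extra)) return(base)
    if (!is.list(extra)) stop("config group `", where, "` must be a mapping")
    for (k in names(extra)) base[[k]] <- extra[[k]]
    base
  }
  known_groups <- c("model", "init", "gac")
  for (src in list(cfg, overrides)) {
    unknown <- setdiff(names(src), known_groups)
    if (length(unknown)) {
      stop("unknown config key(s): ", paste(unknown, collapse = ", "),
           "; expected groups: ", paste(known_groups, collapse = ", "))
    }
  }
  groups <- lapply(stats::setNames(known_groups, known_groups), function(g) {
    merge_group(merge_group(list(), cfg[[g]], g), overrides[[g]], g)
  })
  check_keys <- function(vals, fml, where) {
    unknown <- setdiff(names(vals), names(fml))
    if (length(unknown)) {
      stop("unknown key(s) in `", where, "`: ",
           paste(unknown, collapse = ", "))
    }
  }
  check_keys(groups$model, formals(model_params), "model")
  check_keys(groups$init, formals(init_spec), "init")
  check_keys(groups$gac, formals(gac_params), "gac")
  init <- if (length(groups$init)) do.call(init_spec, groups$init) else NULL
  list(model = do.call(model_params, groups$model),
       init = init,
       gac = do.call(gac_params, groups$gac))
}

#' Write a run manifest
#'
#' Records, next to a command's outputs, everything needed to reproduce the
#' run: the command, a digest of the resolved parameters, seeds, input and
#' output paths, package version and timestamp.
#'
#' @param path Destination JSON path.
#' @param command Command string being recorded.
#' @param config Resolved parameter list (digested, and embedded verbatim).
#' @param seeds Integer vector of seeds used (may be empty).
#' @param inputs,outputs Character vectors of file paths.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, command, config = list(),
                               seeds = integer(), inputs = character(),
                               outputs = character()) {
  tmp <- tempfile()
  on.exit(unlink(tmp), add = TRUE)
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  manifest <- list(
    command = command,
    config = config,
    config_hash = unname(tools::md5sum(tmp)),
    seeds = as.integer(seeds),
    input_paths = inputs,
    output_paths = outputs,
    package_version = as.character(utils::packageVersion("pdeac")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  invisible(path)
}
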