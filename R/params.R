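#' Build a validated biosensor parameter set
#'
#' Assembles the full parameterization of the cylindrical single-enzyme
#' biosensor model: geometry, per-region transport (free-volume fraction
#' `alpha`, diffusion permeability `theta`), free diffusion coefficients,
#' first-order breakdown rates, and the far-field analyte concentration.
#' The defaults are the reference parameter set used throughout the package
#' (50-um core diameter glucose-type sensor, brain-tissue transport values).
#'
#' The four supported configurations and their annular regions are
#' * `"calibration"`: enzyme layer only (free-flow bath at its surface),
#' * `"agar"`: enzyme layer + agar block out to `r3`,
#' * `"tissue"`: enzyme layer + semi-infinite tissue,
#' * `"tissue_gap"`: enzyme layer + free-diffusion gap out to `r_s` + tissue.
#'
#' Units are fixed: micrometres, seconds, micromolar; currents are reported
#' in picoamperes.
#'
#' @param configuration One of `"calibration"`, `"agar"`, `"tissue"`,
#'   `"tissue_gap"`.
#' @param r1 Electrode core radius, um.
#' @param r2 Enzyme-layer outer radius, um.
#' @param r3 Agar-block outer radius, um (agar configuration only).
#' @param r_s Free-gap outer radius, um (tissue_gap only; default a 5-um gap).
#' @param z_b Biosensor length, um.
#' @param D_A,D_H Analyte and H2O2 free diffusion coefficients, um^2/s.
#' @param v_b First-order analyte breakdown rate in the enzyme layer, 1/s.
#' @param alpha_b,theta_b Enzyme-layer free-volume fraction and permeability.
#' @param alpha_g,theta_g Agar free-volume fraction and permeability.
#' @param v_t First-order analyte clearance rate in tissue, 1/s.
#' @param alpha_t,theta_t Tissue free-volume fraction and permeability.
#' @param A_star Far-field/bath analyte concentration, uM.
#'
#' @return An object of class `biosensor_params`: a list with elements
#'   `configuration`, `geometry`, `regions` (a tibble with one row per
#'   annular region: `role`, `r_in`, `r_out`, `alpha`, `theta`, `D_A`,
#'   `D_H`, `v`), `far_field`, `faraday`, `electrons_per_molecule`, and
#'   `values` (the scalar inputs, used for serialization).
#'
#' @examples
#' p <- biosensor_params("tissue")
#' p$regions
#' @export
biosensor_params <- function(configuration = c("calibration", "agar",
                                               "tissue", "tissue_gap"),
                             r1 = 25, r2 = 50, r3 = 150, r_s = r2 + 5,
                             z_b = 500,
                             D_A = 860, D_H = 1700,
                             v_b = 100, alpha_b = 0.4, theta_b = 1,
                             alpha_g = 1, theta_g = 1,
                             v_t = 0.1, alpha_t = 0.2, theta_t = 0.4,
                             A_star = 1) {
  if (length(configuration) != 1 && !identical(configuration, CONFIGURATIONS)) {
    abort("`configuration` must be a single configuration name",
          class = "biosensim_configuration_error")
  }
  configuration <- match.arg(configuration)
  force(r_s)
  values <- list(r1 = r1, r2 = r2, r3 = r3, r_s = r_s, z_b = z_b,
                 D_A = D_A, D_H = D_H,
                 v_b = v_b, alpha_b = alpha_b, theta_b = theta_b,
                 alpha_g = alpha_g, theta_g = theta_g,
                 v_t = v_t, alpha_t = alpha_t, theta_t = theta_t,
                 A_star = A_star)

  geometry <- list(r1 = r1, r2 = r2, z_b = z_b)
  if (configuration == "agar") geometry$r3 <- r3
  if (configuration == "tissue_gap") geometry$r_s <- r_s

  enzyme <- tibble(role = "enzyme", r_in = r1, r_out = r2,
                   alpha = alpha_b, theta = theta_b,
                   D_A = D_A, D_H = D_H, v = v_b)
  regions <- switch(configuration,
    calibration = enzyme,
    agar = dplyr::bind_rows(enzyme,
      tibble(role = "agar", r_in = r2, r_out = r3,
             alpha = alpha_g, theta = theta_g, D_A = D_A, D_H = D_H, v = 0)),
    tissue = dplyr::bind_rows(enzyme,
      tibble(role = "tissue", r_in = r2, r_out = Inf,
             alpha = alpha_t, theta = theta_t, D_A = D_A, D_H = D_H, v = v_t)),
    tissue_gap = {
      rows <- list(enzyme)
      if (is.finite(r_s) && r_s > r2) {
        # a zero-width gap degenerates to the plain tissue configuration
        rows <- c(rows, list(tibble(role = "free_gap", r_in = r2, r_out = r_s,
                                    alpha = 1, theta = 1,
                                    D_A = D_A, D_H = D_H, v = 0)))
      }
      tissue_inner <- max(r2, r_s)
      rows <- c(rows, list(tibble(role = "tissue", r_in = tissue_inner,
                                  r_out = Inf, alpha = alpha_t,
                                  theta = theta_t, D_A = D_A, D_H = D_H,
                                  v = v_t)))
      dplyr::bind_rows(rows)
    })

  params <- structure(list(configuration = configuration,
                           geometry = geometry,
                           regions = regions,
                           far_field = list(A_star = A_star),
                           faraday = FARADAY,
                           electrons_per_molecule = ELECTRONS_PER_MOLECULE,
                           values = values),
                      class = "biosensor_params")
  validate_params(params)
}

#' Validate a biosensor parameter set
#'
#' Checks every type invariant (radius ordering, positivity, `alpha` and
#' `theta` in (0, 1], non-negative rates and concentrations, contiguous
#' non-overlapping regions) and returns the parameter set unchanged if all
#' hold.
#'
#' @param params A `biosensor_params` object.
#' @return `params`, invisibly unchanged, if valid; otherwise an error of
#'   class `biosensim_validation_error` naming the offending field.
#' @export
validate_params <- function(params) {
  fail <- function(msg) abort(msg, class = "biosensim_validation_error")
  if (!inherits(params, "biosensor_params")) {
    fail("`params` must be a biosensor_params object")
  }
  v <- params$values
  if (!(v$r1 > 0)) fail("r1: core radius must be positive")
  if (!(v$r1 < v$r2)) fail("r1, r2: radius ordering requires 0 < r1 < r2")
  if (params$configuration == "agar" && !(v$r2 < v$r3)) {
    fail("r3: agar outer radius must satisfy r2 < r3")
  }
  if (params$configuration == "tissue_gap" && !(v$r2 <= v$r_s)) {
    fail("r_s: free-gap outer radius must satisfy r2 <= r_s")
  }
  if (!(v$z_b > 0)) fail("z_b: biosensor length must be positive")
  for (f in c("D_A", "D_H")) {
    if (!(v[[f]] > 0)) fail(paste0(f, ": diffusion coefficient must be positive"))
  }
  for (f in c("alpha_b", "alpha_g", "alpha_t")) {
    if (!(v[[f]] > 0 && v[[f]] <= 1)) fail(paste0(f, ": must lie in (0, 1]"))
  }
  for (f in c("theta_b", "theta_g", "theta_t")) {
    if (!(v[[f]] > 0 && v[[f]] <= 1)) fail(paste0(f, ": must lie in (0, 1]"))
  }
  for (f in c("v_b", "v_t")) {
    if (v[[f]] < 0) fail(paste0(f, ": breakdown rate must be >= 0"))
  }
  if (v$A_star < 0) fail("A_star: far-field concentration must be >= 0")
  reg <- params$regions
  if (reg$r_in[1] != v$r1) fail("regions: innermost region must start at r1")
  if (nrow(reg) > 1 &&
      any(abs(reg$r_in[-1] - reg$r_out[-nrow(reg)]) > 1e-12)) {
    fail("regions: radial extents must be contiguous and non-overlapping")
  }
  invisible(params)
}

#' Extract one annular region from a parameter set
#'
#' @param params A `biosensor_params` object.
#' @param role Region role: `"enzyme"`, `"agar"`, `"free_gap"` or `"tissue"`.
#' @return A one-row tibble describing the region.
#' @export
region_of <- function(params, role) {
  out <- dplyr::filter(params$regions, .data$role == !!role)
  if (nrow(out) == 0) {
    abort(paste0("configuration '", params$configuration,
                 "' has no region with role '", role, "'"),
          class = "biosensim_configuration_error")
  }
  out
}

#' Characteristic diffusion length of a reacting region
#'
#' The typical distance `sqrt(theta * D_A / v)` a molecule of analyte
#' diffuses into a region before first-order breakdown.  For the reference
#' tissue parameters this is 58.7 um (the biosensor's range of influence in
#' tissue); for the reference enzyme layer it is 2.93 um, much smaller than
#' the layer thickness, making the sensor diffusion limited.
#'
#' @param region A one-row data frame with columns `theta`, `D_A` and `v`
#'   (for example a row of `biosensor_params()$regions`), or a
#'   `biosensor_params` object together with `role`.
#' @param ... Passed to methods.
#' @return The diffusion length in um.
#' @export
diffusion_length <- function(region, ...) UseMethod("diffusion_length")

#' @rdname diffusion_length
#' @export
diffusion_length.data.frame <- function(region, ...) {
  if (any(region$v <= 0)) {
    abort("diffusion length is not finite in a reaction-free region (v = 0)",
          class = "biosensim_no_finite_length_error")
  }
  sqrt(region$theta * region$D_A / region$v)
}

#' @param role Region role used when `region` is a full parameter set.
#' @rdname diffusion_length
#' @export
diffusion_length.biosensor_params <- function(region, role = "enzyme", ...) {
  diffusion_length(region_of(region, role))
}

#' Re-derive a parameter set for a different environment
#'
#' Returns a parameter set with the same scalar values but a different
#' configuration (used when switching environments in insertion protocols
#' and when comparing a diffusive environment with its free-flow
#' calibration).
#'
#' @param params A `biosensor_params` object.
#' @param configuration Target configuration name.
#' @return A validated `biosensor_params` object.
#' @export
set_configuration <- function(params, configuration) {
  do.call(biosensor_params,
          c(list(configuration = configuration), params$values))
}

#' Read and write parameter sets as JSON
#'
#' The on-disk format is a flat JSON document with the configuration name
#' and every scalar field in the fixed unit system (um, s, uM).  A
#' write/read round trip reproduces the parameter set field for field.
#'
#' @param params A `biosensor_params` object.
#' @param path File path.
#' @return `write_params()` returns `path` invisibly; `read_params()`
#'   returns a validated `biosensor_params` object.
#' @export
write_params <- function(params, path) {
  doc <- c(list(configuration = params$configuration), params$values)
  # 17 significant digits keep the write/read round trip bit-exact
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path),
          class = "biosensim_io_error")
  }
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$configuration) || !doc$configuration %in% CONFIGURATIONS) {
    abort("config file must name a valid 'configuration'",
          class = "biosensim_configuration_error")
  }
  known <- c("r1", "r2", "r3", "r_s", "z_b", "D_A", "D_H", "v_b", "alpha_b",
             "theta_b", "alpha_g", "theta_g", "v_t", "alpha_t", "theta_t",
             "A_star")
  args <- doc[intersect(names(doc), c("configuration", known))]
  do.call(biosensor_params, args)
}

#' @exportS3Method base::print
print.biosensor_params <- function(x, ...) {
  cat("<biosensor_params> configuration:", x$configuration, "\n")
  cat(sprintf("  geometry: r1 = %g um, r2 = %g um, z_b = %g um",
              x$geometry$r1, x$geometry$r2, x$geometry$z_b))
  if (!is.null(x$geometry$r3)) cat(sprintf(", r3 = %g um", x$geometry$r3))
  if (!is.null(x$geometry$r_s)) cat(sprintf(", r_s = %g um", x$geometry$r_s))
  cat("\n  far field: A* =", x$far_field$A_star, "uM\n")
  print(x$regions)
  invisible(x)
}
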