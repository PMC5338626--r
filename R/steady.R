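# Steady-state solves, biosensor currents, and diagnostic balances.

# enzyme-layer shape function X(r): solution of l^2 grad^2 X = X with
# X'(r1) = 0, normalized X(r2) = 1.  Evaluated in scaled form.
enzyme_shape <- function(params, r, deriv = FALSE) {
  v <- params$values
  l <- sqrt(v$theta_b * v$D_A / v$v_b)
  r1 <- v$r1; r2 <- v$r2
  # numerator: I0(r/l) K1(r1/l) + K0(r/l) I1(r1/l), scaled so the growing
  # exponential is referenced at r2 and the decaying one at r1
  num <- function(r, d) {
    e_up <- exp((r - r2) / l)
    e_dn <- exp(-(r - r1) / l) * exp((r1 - r2) / l)
    k1 <- besselK(r1 / l, 1, TRUE)
    i1 <- besselI(r1 / l, 1, TRUE)
    if (d) {
      (besselI(r / l, 1, TRUE) * e_up * k1 - besselK(r / l, 1, TRUE) * e_dn * i1) / l
    } else {
      besselI(r / l, 0, TRUE) * e_up * k1 + besselK(r / l, 0, TRUE) * e_dn * i1
    }
  }
  num(r, deriv) / num(r2, FALSE)
}

#' Biosensor current from the peroxide field
#'
#' The measured amperometric current is proportional to the H2O2 flux into
#' the electrode core: `I = 2F * 2 pi r1 z_b * alpha_b theta_b D_H *
#' dH/dr | r1`, converted to picoamperes.
#'
#' @param params A validated `biosensor_params` object.
#' @param peroxide_solution A `basis_solution` for species `"peroxide"`;
#'   solved on the fly when omitted.
#' @return Current in pA (non-negative for valid parameter sets).
#' @export
current_from_solution <- function(params, peroxide_solution = NULL) {
  if (is.null(peroxide_solution)) {
    peroxide_solution <- solve_radial_system(params, "peroxide")
  }
  v <- params$values
  hp <- eval_solution(peroxide_solution, v$r1, deriv = TRUE, region = 1)
  ELECTRONS_PER_MOLECULE * FARADAY * 2 * pi * v$r1 * v$z_b *
    v$alpha_b * v$theta_b * v$D_H * hp * CURRENT_TO_PA
}

#' Closed-form free-flow calibration current
#'
#' The calibration current `I_c = 2F z_b 2 pi alpha_b D_Ab / log(r2/r1) *
#' (A_b(r2) - A_b(r1))`, which is independent of the peroxide diffusion
#' coefficient.  With `simplified = TRUE` the diffusion-limited form is
#' returned, which drops `A_b(r1)` (valid when the enzyme-layer diffusion
#' length is much smaller than the layer thickness) and is additionally
#' independent of the breakdown rate.
#'
#' @param params A `biosensor_params` with configuration `"calibration"`.
#' @param simplified Use the diffusion-limited approximation.
#' @return Current in pA.
#' @export
calibration_current <- function(params, simplified = FALSE) {
  stopifnot(params$configuration == "calibration")
  v <- params$values
  pref <- ELECTRONS_PER_MOLECULE * FARADAY * v$z_b * 2 * pi *
    v$alpha_b * v$theta_b * v$D_A / log(v$r2 / v$r1) * CURRENT_TO_PA
  if (simplified) {
    return(pref * v$A_star)
  }
  asol <- solve_radial_system(params, "analyte")
  pref * (eval_solution(asol, v$r2) - eval_solution(asol, v$r1))
}

#' Solve the full steady state of one configuration
#'
#' Solves the analyte and peroxide systems, reconstructs the radial
#' concentration profiles, computes the biosensor current, and populates the
#' configuration's calibration-correction factors.
#'
#' @param params A validated `biosensor_params` object.
#' @param n_per_region Radial evaluation points per region for the profile.
#' @param tissue_extent Extent of the reported (and numerically truncated)
#'   tissue profile, in multiples of the tissue diffusion length.
#' @return A `steady_state` object: list with `profile` (tibble `r`,
#'   `region`, `A`, `H`), `current_pA`, `A_surface`, `A_core`, `factors`
#'   (named list; see [agar_factors()], [tissue_factor()],
#'   [gap_mismatch()]), `method = "analytic"`, and the underlying
#'   `solutions`.
#' @export
solve_steady <- function(params, n_per_region = 120, tissue_extent = 10) {
  validate_params(params)
  v <- params$values
  asol <- solve_radial_system(params, "analyte")
  hsol <- solve_radial_system(params, "peroxide")

  grids <- purrr::pmap(params$regions, function(role, r_in, r_out, ...) {
    if (!is.finite(r_out)) {
      lt <- sqrt(params$values$theta_t * params$values$D_A / params$values$v_t)
      r_out <- r_in + tissue_extent * lt
    }
    tibble(r = seq(r_in, r_out, length.out = n_per_region), region = role)
  })
  profile <- dplyr::bind_rows(grids)
  profile$A <- eval_solution(asol, profile$r)
  h_max <- max(hsol$regions$r_out)
  profile$H <- ifelse(profile$r <= h_max, eval_solution(hsol, profile$r), 0)

  current <- current_from_solution(params, hsol)
  A_surface <- eval_solution(asol, v$r2, region = 1)
  A_core <- eval_solution(asol, v$r1, region = 1)

  factors <- switch(params$configuration,
    calibration = list(),
    agar = {
      f <- agar_factors(params)
      list(c_g = f$c_g, kappa_b = f$kappa_b, mismatch = f$inferred_ratio)
    },
    tissue = list(c_t = A_surface / v$A_star,
                  mismatch = A_surface / v$A_star),
    tissue_gap = {
      f <- gap_mismatch(params)
      list(kappa_b = f$kappa_b, gamma_b = f$gamma_b, mismatch = f$mismatch)
    })

  structure(list(params = params, profile = profile,
                 current_pA = current, A_surface = A_surface,
                 A_core = A_core, factors = factors,
                 method = "analytic",
                 solutions = list(analyte = asol, peroxide = hsol)),
            class = "steady_state")
}

#' Steady-state mass balances
#'
#' Closure diagnostics for the analytic solution: the analyte influx across
#' the enzyme-layer surface must equal the volume-integrated breakdown
#' inside the layer, and the peroxide production must equal the sum of the
#' core (measured) flux and the outflux across the outer peroxide boundary.
#'
#' @param params A validated `biosensor_params` object.
#' @return A tibble with one row per species and the relative closure error.
#' @export
mass_balance <- function(params) {
  v <- params$values
  asol <- solve_radial_system(params, "analyte")
  hsol <- solve_radial_system(params, "peroxide")
  geom <- 2 * pi * v$z_b

  # volume-integrated analyte breakdown in the enzyme layer
  consumed <- geom * v$alpha_b * v$v_b *
    integrate(function(r) r * eval_solution(asol, r, region = 1),
              v$r1, v$r2, rel.tol = 1e-12)$value
  influx <- geom * v$r2 * v$alpha_b * v$theta_b * v$D_A *
    eval_solution(asol, v$r2, deriv = TRUE, region = 1)
  a_rel <- abs(influx - consumed) / max(abs(consumed), .Machine$double.xmin)

  produced <- consumed  # one H2O2 molecule per analyte molecule broken down
  core_flux <- geom * v$r1 * v$alpha_b * v$theta_b * v$D_H *
    eval_solution(hsol, v$r1, deriv = TRUE, region = 1)
  nh <- nrow(hsol$regions)
  r_out <- hsol$regions$r_out[nh]
  out_flux <- -geom * r_out * hsol$regions$weight[nh] * v$D_H *
    eval_solution(hsol, r_out, deriv = TRUE, region = nh)
  h_rel <- abs(core_flux + out_flux - produced) /
    max(abs(produced), .Machine$double.xmin)

  tibble(species = c("analyte", "peroxide"),
         supplied = c(influx, produced),
         removed = c(consumed, core_flux + out_flux),
         rel_error = c(a_rel, h_rel))
}
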