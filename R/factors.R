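# Calibration-correction factors for the diffusive environments.
#
# Free-flow calibration fixes the analyte concentration at the biosensor
# surface; in agar or tissue the sensor's own breakdown sets up a radial
# density gradient, so the surface concentration -- and hence the inferred
# concentration -- falls below the far-field value.  These factors quantify
# that mismatch.

#' Surface-depletion and current-reduction factors in agar
#'
#' For a biosensor embedded in a cylindrical agar block with bath
#' concentration at the block surface:
#' * `c_g`: ratio of the analyte concentration at the biosensor surface to
#'   the bath value (exact surface value of the basis solution).
#' * `kappa_b = 1 / (1 + (alpha_b theta_b / alpha_g theta_g) *
#'   log(r3/r2) / log(r2/r1))`: the closed-form reduction of the
#'   current-equivalent concentration.
#' * `inferred_ratio`: the exact inferred-to-true concentration ratio
#'   `kappa_b (1 - c_g X(r1)) / (1 - X(r1))`, where `X` is the enzyme-layer
#'   shape function; it reduces to `kappa_b` for diffusion-limited sensors
#'   (`X(r1) << 1`).
#'
#' @param params A `biosensor_params` with configuration `"agar"`.
#' @return A one-row tibble with columns `c_g`, `kappa_b`, `inferred_ratio`.
#' @export
agar_factors <- function(params) {
  stopifnot(params$configuration == "agar")
  v <- params$values
  asol <- solve_radial_system(params, "analyte")
  c_g <- eval_solution(asol, v$r2, region = 1) / v$A_star
  beta <- (v$alpha_b * v$theta_b) / (v$alpha_g * v$theta_g)
  kappa_b <- 1 / (1 + beta * log(v$r3 / v$r2) / log(v$r2 / v$r1))
  X1 <- enzyme_shape(params, v$r1)
  tibble(c_g = c_g, kappa_b = kappa_b,
         inferred_ratio = kappa_b * (1 - c_g * X1) / (1 - X1))
}

# small-length approximation to c_g, valid when l_b << r1
cg_small_length_approx <- function(params) {
  v <- params$values
  lb <- sqrt(v$theta_b * v$D_A / v$v_b)
  beta <- (v$alpha_b * v$theta_b) / (v$alpha_g * v$theta_g)
  lb / (lb + beta * v$r2 * log(v$r3 / v$r2))
}

#' Tissue calibration-mismatch factor
#'
#' The ratio `c_t` of the analyte concentration at the biosensor surface to
#' the bulk tissue concentration, for a sensor in semi-infinite tissue with
#' instantly removed peroxide:
#' `c_t = (1 - (alpha_b D_Ab / alpha_t D_At) X'(r2) / Y'(r2))^-1`,
#' where `X` is the enzyme-layer shape (zero core flux, normalized at the
#' surface) and `Y(r) = K0(r / l_t) / K0(r2 / l_t)` is the decaying tissue
#' solution.  Because the peroxide boundary condition matches the
#' calibration case, `c_t` is also the inferred-to-true concentration
#' ratio.
#'
#' @param params A `biosensor_params` with configuration `"tissue"`.
#' @return The dimensionless factor `c_t` in (0, 1].
#' @export
tissue_factor <- function(params) {
  stopifnot(params$configuration == "tissue")
  v <- params$values
  if (v$v_b == 0) return(1)  # no consumption, no gradient
  lt <- sqrt(v$theta_t * v$D_A / v$v_t)
  Xp2 <- enzyme_shape(params, v$r2, deriv = TRUE)
  # Y'(r2)/Y(r2) with Y = K0(r/lt): -K1/(lt K0), strictly negative
  Yp2 <- -besselK(v$r2 / lt, 1, TRUE) / (lt * besselK(v$r2 / lt, 0, TRUE))
  ratio <- (v$alpha_b * v$theta_b) / (v$alpha_t * v$theta_t)
  1 / (1 - ratio * Xp2 / Yp2)
}

#' Calibration mismatch with an insertion-damage gap
#'
#' For a biosensor in tissue separated from it by a free-diffusion annulus
#' (`r2` to `r_s`), the inferred-to-true concentration ratio factorizes as
#' `kappa_b * gamma_b`, with `kappa_b` the agar-type current factor of the
#' free gap (`alpha = theta = 1`) and `gamma_b` the remaining
#' surface-depletion factor.  The mismatch itself is computed as the exact
#' ratio of the steady currents in the gap and calibration configurations at
#' equal far-field concentration.
#'
#' @param params A `biosensor_params` with configuration `"tissue_gap"`.
#' @return A one-row tibble with columns `mismatch`, `kappa_b`, `gamma_b`.
#' @export
gap_mismatch <- function(params) {
  stopifnot(params$configuration == "tissue_gap")
  v <- params$values
  I_gap <- current_from_solution(params)
  I_cal <- current_from_solution(set_configuration(params, "calibration"))
  mismatch <- I_gap / I_cal
  kappa_b <- if (v$r_s > v$r2) {
    1 / (1 + v$alpha_b * v$theta_b * log(v$r_s / v$r2) / log(v$r2 / v$r1))
  } else {
    1
  }
  tibble(mismatch = mismatch, kappa_b = kappa_b, gamma_b = mismatch / kappa_b)
}
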