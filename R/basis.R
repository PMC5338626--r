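# Piecewise basis-function solution of the steady-state radial equations.
#
# Each annular region contributes two basis functions: {1, log r} where the
# species does not react (Laplace), or the zero-order modified Bessel
# functions {I0(r/l), K0(r/l)} where it does (modified Helmholtz,
# l^2 grad^2 u = u about the region's far-field offset).  Both Bessel
# branches are evaluated in exponentially scaled form, the growing branch
# referenced at the region's outer edge and the decaying branch at its inner
# edge, so that every basis value stays O(1) even when r/l reaches O(10^3)
# in rate sweeps.  A semi-infinite tissue region keeps only the decaying
# K0 branch, with the far-field concentration as additive offset.

# regions table for one species (analyte carries the reaction terms; the
# peroxide field is homogeneous with an enzyme-layer particular solution)
species_regions <- function(params, species) {
  reg <- params$regions
  if (species == "peroxide") reg <- reg[reg$role != "tissue", , drop = FALSE]
  v <- if (species == "analyte") reg$v else rep(0, nrow(reg))
  D <- if (species == "analyte") reg$D_A else reg$D_H
  offset <- if (species == "analyte") {
    ifelse(reg$role == "tissue", params$far_field$A_star, 0)
  } else {
    rep(0, nrow(reg))
  }
  tibble(role = reg$role, r_in = reg$r_in, r_out = reg$r_out,
         weight = reg$alpha * reg$theta,
         type = ifelse(v > 0, "bessel", "log"),
         ell = ifelse(v > 0, sqrt(reg$theta * D / v), NA_real_),
         offset = offset,
         semi_infinite = !is.finite(reg$r_out))
}

# both basis functions (and derivatives) of one region at radii r
basis_pair <- function(reg, r, deriv = FALSE) {
  if (reg$type == "log") {
    if (deriv) cbind(rep(0, length(r)), 1 / r) else cbind(rep(1, length(r)), log(r))
  } else {
    l <- reg$ell
    x <- r / l
    # growing branch I0 referenced at the outer edge (zero if semi-infinite)
    b1 <- if (is.finite(reg$r_out)) {
      s <- exp((r - reg$r_out) / l)
      if (deriv) besselI(x, 1, TRUE) * s / l else besselI(x, 0, TRUE) * s
    } else {
      rep(0, length(r))
    }
    # decaying branch K0 referenced at the inner edge
    s <- exp(-(r - reg$r_in) / l)
    b2 <- if (deriv) -besselK(x, 1, TRUE) * s / l else besselK(x, 0, TRUE) * s
    cbind(b1, b2)
  }
}

#' Solve the steady-state radial profile as a piecewise basis expansion
#'
#' Assembles and solves the linear system whose unknowns are the two basis
#' coefficients of every annular region (one for the semi-infinite tissue,
#' which keeps only the decaying Bessel branch) and whose rows are the
#' configuration's boundary conditions: zero analyte flux / zero peroxide
#' concentration at the electrode core, continuity of concentration and of
#' `alpha * theta`-weighted flux at every internal interface, and the outer
#' Dirichlet condition (bath concentration for the analyte, zero for the
#' peroxide, which is washed away or instantly cleared by tissue).
#'
#' The peroxide field in the enzyme layer carries the particular solution
#' `-(D_A / D_H) * A_b(r)` of its production equation, so the analyte system
#' is solved first.
#'
#' @param params A validated `biosensor_params` object.
#' @param species `"analyte"` or `"peroxide"`.
#' @return A `basis_solution` object; evaluate it with [eval_solution()].
#' @export
solve_radial_system <- function(params, species = c("analyte", "peroxide")) {
  species <- match.arg(species)
  validate_params(params)
  regs <- species_regions(params, species)

  part <- NULL
  if (species == "peroxide" && params$regions$v[1] > 0) {
    asol <- solve_radial_system(params, "analyte")
    part <- list(scale = -params$values$D_A / params$values$D_H,
                 analyte = asol)
  }
  # the particular lives in the enzyme layer only: always evaluate the
  # analyte with the enzyme-region expansion (interface radii are shared)
  p_val <- function(r, d = FALSE) {
    if (is.null(part)) {
      0
    } else {
      part$scale * eval_solution(part$analyte, r, deriv = d, region = 1)
    }
  }

  nreg <- nrow(regs)
  ncoef <- ifelse(regs$semi_infinite, 1L, 2L)
  col0 <- cumsum(c(0L, ncoef))
  n <- sum(ncoef)
  M <- matrix(0, n, n)
  b <- numeric(n)

  take <- function(i, r, d = FALSE) {
    bv <- basis_pair(regs[i, ], r, deriv = d)
    if (regs$semi_infinite[i]) bv[, 2] else drop(bv)
  }
  cols <- function(i) col0[i] + seq_len(ncoef[i])

  row <- 1L
  r1 <- regs$r_in[1]
  if (species == "analyte") {        # zero flux at the core
    M[row, cols(1)] <- take(1, r1, d = TRUE)
    b[row] <- 0
  } else {                           # H electrolysed at the core
    M[row, cols(1)] <- take(1, r1)
    b[row] <- -p_val(r1)
  }
  row <- row + 1L

  if (nreg > 1) {
    for (i in seq_len(nreg - 1)) {
      rk <- regs$r_out[i]
      pL <- if (i == 1) p_val(rk) else 0
      pLd <- if (i == 1) p_val(rk, d = TRUE) else 0
      # concentration continuity
      M[row, cols(i)] <- take(i, rk)
      M[row, cols(i + 1)] <- -take(i + 1, rk)
      b[row] <- regs$offset[i + 1] - regs$offset[i] - pL
      row <- row + 1L
      # alpha*theta-weighted flux continuity (free D cancels within a species)
      M[row, cols(i)] <- regs$weight[i] * take(i, rk, d = TRUE)
      M[row, cols(i + 1)] <- -regs$weight[i + 1] * take(i + 1, rk, d = TRUE)
      b[row] <- -regs$weight[i] * pLd
      row <- row + 1L
    }
  }

  if (!regs$semi_infinite[nreg]) {   # outer Dirichlet value
    rout <- regs$r_out[nreg]
    bc <- if (species == "analyte") params$far_field$A_star else 0
    pN <- if (nreg == 1) p_val(rout) else 0
    M[row, cols(nreg)] <- take(nreg, rout)
    b[row] <- bc - regs$offset[nreg] - pN
  }

  coef <- tryCatch(solve(M, b), error = function(e) {
    abort(paste0("interface matrix is singular for these parameters: ",
                 conditionMessage(e)),
          class = "biosensim_illconditioned_error")
  })

  regs$c1 <- ifelse(regs$semi_infinite, 0, coef[col0[seq_len(nreg)] + 1])
  regs$c2 <- coef[col0[seq_len(nreg)] + ncoef]

  structure(list(regions = regs, species = species, particular = part,
                 params = params),
            class = "basis_solution")
}

#' Evaluate a basis solution
#'
#' @param sol A `basis_solution` from [solve_radial_system()].
#' @param r Radii, um (within the solution's domain).
#' @param deriv If `TRUE`, return the radial derivative instead.
#' @param region Optional region index forcing evaluation with that
#'   region's expansion (used at interface radii, which belong to two
#'   regions).
#' @return Numeric vector of concentrations (uM) or gradients (uM/um).
#' @export
eval_solution <- function(sol, r, deriv = FALSE, region = NULL) {
  regs <- sol$regions
  breaks <- c(regs$r_in[1], regs$r_out)
  idx <- if (is.null(region)) {
    findInterval(r, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  } else {
    rep(region, length(r))
  }
  out <- numeric(length(r))
  for (i in unique(idx)) {
    sel <- idx == i
    bv <- basis_pair(regs[i, ], r[sel], deriv = deriv)
    val <- regs$c1[i] * bv[, 1] + regs$c2[i] * bv[, 2]
    if (!deriv) val <- val + regs$offset[i]
    if (i == 1 && !is.null(sol$particular)) {
      val <- val + sol$particular$scale *
        eval_solution(sol$particular$analyte, r[sel], deriv = deriv,
                      region = 1)
    }
    out[sel] <- val
  }
  out
}

#' Interface continuity residuals of a basis solution
#'
#' Diagnostic used to confirm that the reconstructed concentration and the
#' `alpha * theta`-weighted flux are continuous at every internal interface.
#'
#' @param sol A `basis_solution`.
#' @return A tibble with one row per internal interface and the relative
#'   mismatches `value_rel` and `flux_rel`.
#' @export
interface_mismatch <- function(sol) {
  regs <- sol$regions
  n <- nrow(regs)
  if (n < 2) {
    return(tibble(r = numeric(), value_rel = numeric(), flux_rel = numeric()))
  }
  purrr::map_dfr(seq_len(n - 1), function(i) {
    rk <- regs$r_out[i]
    vL <- eval_solution(sol, rk, region = i)
    vR <- eval_solution(sol, rk, region = i + 1)
    fL <- regs$weight[i] * eval_solution(sol, rk, deriv = TRUE, region = i)
    fR <- regs$weight[i + 1] * eval_solution(sol, rk, deriv = TRUE, region = i + 1)
    sv <- max(abs(vL), abs(vR), .Machine$double.xmin)
    sf <- max(abs(fL), abs(fR), .Machine$double.xmin)
    tibble(r = rk, value_rel = abs(vL - vR) / sv, flux_rel = abs(fL - fR) / sf)
  })
}
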