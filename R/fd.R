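# Direct finite-volume steady-state solve (independent of the basis-function
# route; used as the numerical oracle for the analytic module).

solve_tridiag_fv <- function(g, vol_rate, rhs, dirichlet_left, dirichlet_right,
                             bc_left = 0, bc_right = 0) {
  # Steady balance per cell i:
  #   g[i] (u[i-1] - u[i]) + g[i+1] (u[i+1] - u[i]) - vol_rate[i] u[i] + rhs[i] = 0
  # with Dirichlet values folded in at closed boundaries and zero-flux
  # otherwise (g[1] or g[n+1] entries are only used when dirichlet_* is TRUE).
  n <- length(vol_rate)
  gl <- g[1:n]
  gr <- g[2:(n + 1)]
  if (!dirichlet_left) gl[1] <- 0
  if (!dirichlet_right) gr[n] <- 0
  diag_main <- -(gl + gr) - vol_rate
  b <- -rhs
  if (dirichlet_left) b[1] <- b[1] - g[1] * bc_left
  if (dirichlet_right) b[n] <- b[n] - g[n + 1] * bc_right
  if (n == 1) return(b / diag_main)
  M <- Matrix::bandSparse(n, n, k = c(-1, 0, 1),
                          diagonals = list(g[2:n], diag_main, g[2:n]))
  as.numeric(Matrix::solve(M, b))
}

#' Finite-difference steady state (numerical oracle)
#'
#' Solves the discrete steady-state equations of the finite-volume
#' discretization directly (a tridiagonal linear system per species: the
#' analyte first, then the peroxide with the analyte breakdown as source).
#' This is the converged limit of the explicit time integration and serves
#' as the independent numerical check on the analytic basis-function
#' solution.
#'
#' @param params A validated `biosensor_params` object.
#' @param dr,tissue_extent Passed to [discretize()].
#' @return A `steady_state` object with `method = "finite_difference"`.
#' @export
fd_steady <- function(params, dr = NULL, tissue_extent = 10) {
  grid <- discretize(params, dr = dr, tissue_extent = tissue_extent)
  nc <- length(grid$r)
  v <- params$values

  # analyte: zero flux at core, Dirichlet A* at the outer face
  A <- solve_tridiag_fv(grid$gA,
                        vol_rate = grid$alpha * grid$vol * grid$v,
                        rhs = grid$alpha * grid$vol * grid$v * grid$target,
                        dirichlet_left = FALSE, dirichlet_right = TRUE,
                        bc_right = grid$A_outer)

  # peroxide on its subdomain: Dirichlet 0 both ends, source alpha v_b A
  nh <- grid$n_h
  enz <- grid$role[seq_len(nh)] == "enzyme"
  H <- solve_tridiag_fv(grid$gH,
                        vol_rate = rep(0, nh),
                        rhs = ifelse(enz, grid$alpha[seq_len(nh)] *
                                       grid$vol[seq_len(nh)] *
                                       grid$v[seq_len(nh)] * A[seq_len(nh)], 0),
                        dirichlet_left = TRUE, dirichlet_right = TRUE)

  current <- ELECTRONS_PER_MOLECULE * FARADAY * 2 * pi * v$z_b *
    grid$gH[1] * H[1] * CURRENT_TO_PA

  A_surface <- fv_face_value(grid, A, v$r2, species = "A")

  profile <- tibble(r = grid$r, region = grid$role, A = A,
                    H = c(H, rep(0, nc - nh)))

  factors <- switch(params$configuration,
    calibration = list(),
    agar = {
      I_cal <- fd_steady_current(set_configuration(params, "calibration"),
                                 dr = dr, tissue_extent = tissue_extent)
      list(c_g = A_surface / v$A_star, mismatch = current / I_cal)
    },
    tissue = list(c_t = A_surface / v$A_star,
                  mismatch = A_surface / v$A_star),
    tissue_gap = {
      I_cal <- fd_steady_current(set_configuration(params, "calibration"),
                                 dr = dr, tissue_extent = tissue_extent)
      list(mismatch = current / I_cal)
    })

  structure(list(params = params, profile = profile, current_pA = current,
                 A_surface = A_surface, A_core = A[1], factors = factors,
                 method = "finite_difference", grid = grid),
            class = "steady_state")
}

fd_steady_current <- function(params, ...) {
  fd_steady(params, ...)$current_pA
}

# concentration reconstructed at a face radius from the adjacent cells,
# weighting each side by its conductivity over the half-cell distance
fv_face_value <- function(grid, values, r_face, species = c("A", "H")) {
  species <- match.arg(species)
  j <- which.min(abs(grid$faces - r_face))
  nc <- length(grid$r)
  if (j == 1) return(values[1])
  if (j == nc + 1) {
    # outer face is Dirichlet for the analyte
    return(if (species == "A") grid$A_outer else 0)
  }
  reg <- grid$params$regions
  kcol <- if (species == "A") reg$D_A else reg$D_H
  k_of <- function(i) {
    row <- match(grid$role[i], reg$role)
    reg$alpha[row] * reg$theta[row] * kcol[row]
  }
  dl <- grid$faces[j] - grid$r[j - 1]
  dr_ <- grid$r[j] - grid$faces[j]
  wL <- k_of(j - 1) / dl
  wR <- k_of(j) / dr_
  (wL * values[j - 1] + wR * values[j]) / (wL + wR)
}
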