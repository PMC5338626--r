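# Finite-volume discretization of the radial domain.
#
# Cell-centered grid on the cylindrical measure r dr, with cell faces
# aligned exactly to every region interface.  Interface fluxes use the
# two-point transmission built from distance-weighted alpha*theta*D
# conductivities, which reproduces the continuum matching conditions
# (concentration and alpha*theta-weighted flux continuous; the free
# diffusion coefficient cancels within a species) discretely.

default_spacing <- function(params) {
  v <- params$values
  lt <- sqrt(v$theta_t * v$D_A / max(v$v_t, 1e-12))
  c(enzyme = 0.25, agar = 0.5, free_gap = 0.25,
    tissue = min(2, max(0.5, lt / 40)))
}

#' Discretize a biosensor configuration on a radial finite-volume grid
#'
#' @param params A validated `biosensor_params` object.
#' @param dr Named spacings per region role, um (defaults: 0.25 in the
#'   enzyme layer and free gap, 0.5 in agar, about `l_t / 40` in tissue).
#' @param tissue_extent Truncation radius of the semi-infinite tissue, in
#'   multiples of the tissue diffusion length (Dirichlet far-field value is
#'   imposed there; the K0 decay makes the truncation error negligible).
#' @return A `fv_grid` list: faces, cell centres/volumes/roles, per-cell
#'   transport and reaction coefficients, face conductances for both
#'   species, and the peroxide subdomain size.
#' @export
discretize <- function(params, dr = NULL, tissue_extent = 10) {
  validate_params(params)
  spacing <- default_spacing(params)
  if (!is.null(dr)) spacing[names(dr)] <- dr

  reg <- params$regions
  v <- params$values
  faces <- c()
  cell <- list()
  for (i in seq_len(nrow(reg))) {
    r_in <- reg$r_in[i]
    r_out <- reg$r_out[i]
    if (!is.finite(r_out)) {
      lt <- sqrt(reg$theta[i] * reg$D_A[i] / reg$v[i])
      r_out <- r_in + tissue_extent * lt
    }
    n <- max(2L, ceiling((r_out - r_in) / spacing[[reg$role[i]]]))
    f <- seq(r_in, r_out, length.out = n + 1)
    faces <- c(faces, if (i == 1) f else f[-1])
    targ_i <- if (reg$role[i] == "tissue") params$far_field$A_star else 0
    cell[[i]] <- tibble(role = reg$role[i],
                        alpha = reg$alpha[i],
                        kA = reg$alpha[i] * reg$theta[i] * reg$D_A[i],
                        kH = reg$alpha[i] * reg$theta[i] * reg$D_H[i],
                        v = reg$v[i],
                        target = targ_i,
                        n = n)
  }
  cells <- dplyr::bind_rows(cell)
  cells <- cells[rep(seq_len(nrow(cells)), cells$n), ]
  cells$n <- NULL
  nc <- nrow(cells)
  stopifnot(nc == length(faces) - 1)
  r <- (faces[-1] + faces[-(nc + 1)]) / 2
  vol <- (faces[-1]^2 - faces[-(nc + 1)]^2) / 2   # per unit angle and length
  dl <- r - faces[-(nc + 1)]                      # centre-to-face distances
  dr_ <- faces[-1] - r

  conduct <- function(k) {
    g <- numeric(nc + 1)
    inner <- 2:nc
    g[inner] <- faces[inner] / (dr_[inner - 1] / k[inner - 1] + dl[inner] / k[inner])
    g[1] <- faces[1] * k[1] / dl[1]               # core face (Dirichlet use)
    g[nc + 1] <- faces[nc + 1] * k[nc] / dr_[nc]  # outer face
    g
  }

  n_h <- sum(cells$role != "tissue")   # peroxide lives inside the H boundary
  gH <- conduct(cells$kH)[seq_len(n_h + 1)]
  # H outer face carries a Dirichlet zero; its conductance must use the
  # H-domain half-cell only (the face may be internal to the analyte grid)
  gH[n_h + 1] <- faces[n_h + 1] * cells$kH[n_h] / dr_[n_h]
  structure(list(params = params, faces = faces, r = r, vol = vol,
                 role = cells$role, alpha = cells$alpha,
                 v = cells$v, target = cells$target,
                 gA = conduct(cells$kA),
                 gH = gH,
                 n_h = n_h,
                 n_enzyme = sum(cells$role == "enzyme"),
                 A_outer = v$A_star),
            class = "fv_grid")
}
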