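# Time-dependent finite-volume solution of the coupled analyte/peroxide
# equations, with multi-environment insertion protocols.

rk_stability_dt <- function(grid, order) {
  # Gershgorin bound on the spectral radius of the discrete operator,
  # combined with the explicit scheme's negative-real-axis stability limit
  # (about 2.785 for classical RK4, 2 for the midpoint scheme).
  nA <- length(grid$r)
  nH <- grid$n_h
  gl <- grid$gA[1:nA]; gl[1] <- 0
  gr <- grid$gA[2:(nA + 1)]
  lamA <- (gl + gr) / (grid$alpha * grid$vol) + grid$v
  glh <- grid$gH[1:nH]
  grh <- grid$gH[2:(nH + 1)]
  lamH <- (glh + grh) / (grid$alpha[1:nH] * grid$vol[1:nH])
  lam <- 2 * max(lamA, lamH)
  limit <- if (order == 4) 2.785 else 2
  limit / lam
}

initial_state <- function(grid, init = c("insertion", "zero")) {
  init <- match.arg(init)
  A <- if (init == "zero") {
    rep(0, length(grid$r))
  } else {
    # insertion condition: external regions at their unperturbed state,
    # enzyme layer analyte-free
    ifelse(grid$role == "enzyme", 0, grid$A_outer)
  }
  list(A = A, H = rep(0, grid$n_h))
}

#' Integrate the transient reaction-diffusion equations
#'
#' Explicit Runge-Kutta (classical order 4 by default, midpoint order 2
#' selectable) advance of the coupled analyte/peroxide finite-volume
#' semi-discretization.  The biosensor current is recorded from the
#' discrete peroxide flux into the core.
#'
#' The default initial condition is the insertion state: external regions
#' at their unperturbed concentrations (bath/agar/tissue at the far-field
#' value), the enzyme layer analyte-free.  `init = "zero"` starts every
#' cell at zero instead, and `state` resumes from a previous result.
#'
#' @param params A validated `biosensor_params` object.
#' @param t_end Integration time, s.
#' @param dt Time step, s; `NULL` picks half the stability bound.  A value
#'   above the bound raises a stability error naming the bound.
#' @param scheme `"rk4"` or `"rk2"`.
#' @param snapshot_times Times (s) at which to store full radial profiles
#'   (taken at the nearest completed step).
#' @param init Initial condition rule when `state` is not supplied.
#' @param state Optional list `(A, H)` of cell values to resume from.
#' @param dr,tissue_extent Passed to [discretize()].
#' @param record_every Record the current every this many steps (default
#'   keeps about 2000 trace points).
#' @param steady_tol Relative current drift per second below which the
#'   final state is flagged as steady.
#' @return A `transient_result`: list with `trace` (tibble `time`,
#'   `current_pA`), `snapshots` (tibble `time`, `r`, `region`, `A`, `H`),
#'   `steady_reached`, `steady_time`, the final `state`, and the `grid`.
#' @export
simulate_transient <- function(params, t_end, dt = NULL,
                               scheme = c("rk4", "rk2"),
                               snapshot_times = NULL,
                               init = c("insertion", "zero"),
                               state = NULL,
                               dr = NULL, tissue_extent = 10,
                               record_every = NULL,
                               steady_tol = 1e-4) {
  scheme <- match.arg(scheme)
  order <- if (scheme == "rk4") 4L else 2L
  stopifnot(t_end > 0)
  grid <- discretize(params, dr = dr, tissue_extent = tissue_extent)

  dt_max <- rk_stability_dt(grid, order)
  if (is.null(dt)) {
    dt <- dt_max / 2
  } else if (dt > dt_max) {
    abort(sprintf(
      "dt = %.3g s exceeds the explicit %s stability bound %.3g s for this grid",
      dt, scheme, dt_max), class = "biosensim_stability_error")
  }
  n_steps <- max(1L, as.integer(ceiling(t_end / dt)))
  dt <- t_end / n_steps

  if (is.null(state)) state <- initial_state(grid, init)
  if (is.null(record_every)) record_every <- max(1L, n_steps %/% 2000L)

  snap_steps <- integer(0)
  if (!is.null(snapshot_times)) {
    snap_steps <- sort(unique(pmin(n_steps, pmax(1L, as.integer(
      round(snapshot_times / dt)
    )))))
  }

  v <- params$values
  nh <- grid$n_h
  res <- rk_integrate_cpp(
    A0 = state$A, H0 = state$H,
    gA = grid$gA, gH = grid$gH,
    volA = grid$alpha * grid$vol,
    volH = grid$alpha[seq_len(nh)] * grid$vol[seq_len(nh)],
    vA = grid$v, targA = grid$target,
    prodH = ifelse(grid$role[seq_len(nh)] == "enzyme",
                   grid$v[seq_len(nh)], 0),
    A_outer = grid$A_outer, dt = dt, n_steps = n_steps, order = order,
    record_every = as.integer(record_every), snap_steps = snap_steps,
    current_scale = ELECTRONS_PER_MOLECULE * FARADAY * 2 * pi * v$z_b *
      CURRENT_TO_PA)

  trace <- tibble(time = res$times, current_pA = res$current)

  snapshots <- purrr::map_dfr(res$snapshots, function(s) {
    tibble(time = s$time, r = grid$r, region = grid$role,
           A = s$A, H = c(s$H, rep(0, length(grid$r) - nh)))
  })

  nt <- nrow(trace)
  drift <- if (nt >= 2 && trace$current_pA[nt] > 0) {
    abs(trace$current_pA[nt] - trace$current_pA[nt - 1]) /
      (trace$current_pA[nt] * (trace$time[nt] - trace$time[nt - 1]))
  } else {
    Inf
  }
  steady_reached <- is.finite(drift) && drift < steady_tol
  steady_time <- NA_real_
  if (steady_reached) {
    final <- trace$current_pA[nt]
    ok <- abs(trace$current_pA - final) <= 1e-3 * abs(final)
    first_bad <- if (all(ok)) 1L else max(which(!ok)) + 1L
    if (first_bad <= nt) steady_time <- trace$time[first_bad]
  }

  structure(list(params = params, trace = trace, snapshots = snapshots,
                 steady_reached = steady_reached, steady_time = steady_time,
                 state = list(A = res$A, H = res$H), grid = grid,
                 dt = dt, scheme = scheme),
            class = "transient_result")
}

#' Integrate to steady state and report it in steady-state form
#'
#' Integrates forward in chunks until the relative current drift
#' `|dI/dt| * (1 s) / I` falls below `tol`, then returns profiles, current
#' and the configuration's mismatch factor in the same shape as
#' [solve_steady()].
#'
#' @param params A validated `biosensor_params` object.
#' @param tol Relative current drift per second at which to stop.
#' @param chunk Chunk length, s.
#' @param max_time Integration budget, s; exceeding it raises a
#'   convergence error.
#' @param ... Passed to [simulate_transient()] (grid controls, scheme).
#' @return A `steady_state` object with `method = "integration"`.
#' @export
steady_by_integration <- function(params, tol = 1e-6, chunk = 0.5,
                                  max_time = 300, ...) {
  stopifnot(tol > 0)
  state <- NULL
  I_prev <- NA_real_
  t_total <- 0
  repeat {
    res <- simulate_transient(params, t_end = chunk, state = state, ...)
    state <- res$state
    t_total <- t_total + chunk
    I_now <- res$trace$current_pA[nrow(res$trace)]
    if (!is.na(I_prev) && I_now > 0) {
      drift <- abs(I_now - I_prev) / (I_now * chunk)
      if (drift < tol) break
    }
    if (!is.na(I_prev) && I_now == 0 && I_prev == 0) break  # A* = 0 case
    if (t_total > max_time) {
      abort(sprintf(
        "no steady state within %g s of simulated time (drift tolerance %g)",
        max_time, tol), class = "biosensim_convergence_error")
    }
    I_prev <- I_now
  }

  grid <- res$grid
  nh <- grid$n_h
  v <- params$values
  A <- state$A
  A_surface <- fv_face_value(grid, A, v$r2, species = "A")
  profile <- tibble(r = grid$r, region = grid$role, A = A,
                    H = c(state$H, rep(0, length(A) - nh)))
  factors <- switch(params$configuration,
    calibration = list(),
    agar = list(c_g = A_surface / v$A_star),
    tissue = list(c_t = A_surface / v$A_star,
                  mismatch = A_surface / v$A_star),
    tissue_gap = list())

  structure(list(params = params, profile = profile,
                 current_pA = I_now, A_surface = A_surface,
                 A_core = A[1], factors = factors,
                 method = "integration", grid = grid),
            class = "steady_state")
}

#' Define an insertion protocol
#'
#' An ordered sequence of environments the biosensor is moved through, with
#' a duration for each.  On every switch the enzyme-layer profile is
#' carried over while the external region is reset to the new environment's
#' unperturbed state.
#'
#' @param environment Character vector of configuration names.
#' @param duration Segment durations, s (positive).
#' @return A `biosensor_protocol` tibble with columns `environment`,
#'   `duration`.
#' @export
protocol <- function(environment, duration) {
  if (length(environment) < 1 || length(environment) != length(duration)) {
    abort("protocol needs at least one segment and matching durations",
          class = "biosensim_protocol_error")
  }
  if (!all(environment %in% CONFIGURATIONS)) {
    abort("unknown environment in protocol", class = "biosensim_protocol_error")
  }
  if (!all(duration > 0)) {
    abort("protocol durations must be positive",
          class = "biosensim_protocol_error")
  }
  structure(tibble(environment = environment, duration = duration),
            class = c("biosensor_protocol", class(tibble())))
}

#' Run a multi-environment insertion protocol
#'
#' Simulates the ordered segments of `protocol`, carrying the enzyme-layer
#' concentration profile across environment switches and resetting each new
#' external region to its unperturbed initial condition (which reproduces a
#' manual insertion).  All segments share the biosensor geometry and
#' enzyme-layer parameters of `params`; per-segment parameter sets may be
#' supplied but must agree on those fields.
#'
#' @param protocol A `biosensor_protocol` (see [protocol()]).
#' @param params Shared `biosensor_params`; its configuration is ignored in
#'   favour of each segment's environment.
#' @param segment_params Optional list of full parameter sets, one per
#'   segment, overriding `params` for that segment.
#' @param dr,tissue_extent Grid controls shared by every segment (the
#'   enzyme-layer cells must coincide across environments).
#' @param ... Passed to [simulate_transient()].
#' @return A `transient_result` whose trace covers all segments (with a
#'   `segment` column) and whose snapshots, state and grid are those of the
#'   final segment.
#' @export
run_protocol <- function(protocol, params, segment_params = NULL,
                         dr = NULL, tissue_extent = 10, ...) {
  stopifnot(nrow(protocol) >= 1)
  plist <- if (is.null(segment_params)) {
    purrr::map(protocol$environment, ~ set_configuration(params, .x))
  } else {
    if (length(segment_params) != nrow(protocol)) {
      abort("segment_params must have one parameter set per segment",
            class = "biosensim_protocol_error")
    }
    segment_params
  }
  enzyme_fields <- c("r1", "r2", "z_b", "D_A", "D_H", "v_b",
                     "alpha_b", "theta_b")
  ref <- plist[[1]]$values[enzyme_fields]
  for (p in plist[-1]) {
    if (!isTRUE(all.equal(ref, p$values[enzyme_fields]))) {
      abort("segments disagree on biosensor geometry or enzyme-layer parameters",
            class = "biosensim_protocol_error")
    }
  }

  carry <- NULL
  t0 <- 0
  traces <- list()
  res <- NULL
  for (k in seq_len(nrow(protocol))) {
    pk <- plist[[k]]
    grid_k <- discretize(pk, dr = dr, tissue_extent = tissue_extent)
    state_k <- initial_state(grid_k, "insertion")
    if (!is.null(carry)) {
      ne <- grid_k$n_enzyme
      state_k$A[seq_len(ne)] <- carry$A[seq_len(ne)]
      state_k$H[seq_len(min(ne, grid_k$n_h))] <-
        carry$H[seq_len(min(ne, grid_k$n_h))]
    }
    res <- simulate_transient(pk, t_end = protocol$duration[k],
                              state = state_k, dr = dr,
                              tissue_extent = tissue_extent, ...)
    carry <- list(A = res$state$A[seq_len(res$grid$n_enzyme)],
                  H = res$state$H[seq_len(min(res$grid$n_enzyme,
                                              res$grid$n_h))])
    tr <- res$trace
    tr$time <- tr$time + t0
    tr$segment <- k
    tr$environment <- protocol$environment[k]
    traces[[k]] <- if (k > 1) tr[-1, ] else tr
    t0 <- t0 + protocol$duration[k]
  }

  out <- res
  out$trace <- dplyr::bind_rows(traces)
  out
}
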