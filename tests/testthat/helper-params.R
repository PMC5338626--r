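# Shared test utilities: randomized valid parameter sets and oracle grids.

runif1 <- function(lo, hi) stats::runif(1, lo, hi)

# A random valid parameter set for any configuration.  Ranges stay inside
# regimes where the default-oracle resolution resolves the enzyme boundary
# layer (l_b >= ~0.8 um).
random_params <- function(configuration) {
  r1 <- runif1(10, 40)
  r2 <- r1 + runif1(10, 40)
  biosensor_params(
    configuration,
    r1 = r1, r2 = r2,
    r3 = r2 + runif1(30, 150),
    r_s = r2 + runif1(1, 15),
    z_b = runif1(200, 800),
    D_A = runif1(400, 1200),
    D_H = runif1(800, 2500),
    v_b = runif1(20, 400),
    alpha_b = runif1(0.2, 0.8),
    theta_b = runif1(0.3, 1),
    alpha_g = runif1(0.5, 1),
    theta_g = runif1(0.5, 1),
    v_t = runif1(0.02, 0.5),
    alpha_t = runif1(0.1, 0.4),
    theta_t = runif1(0.2, 0.6),
    A_star = runif1(0.5, 5))
}

# oracle grid spacings fine enough to resolve the enzyme boundary layer
oracle_dr <- function(params) {
  v <- params$values
  lb <- sqrt(v$theta_b * v$D_A / max(v$v_b, 1e-9))
  c(enzyme = min(0.2, lb / 15),
    agar = 0.5,
    free_gap = max(0.05, min(0.25, (v$r_s - v$r2) / 10)),
    tissue = NA)[c("enzyme", "agar", "free_gap")]
}

# coarse grids for transient runs (keeps explicit stepping cheap)
coarse_dr <- c(enzyme = 0.5, agar = 1, free_gap = 0.5, tissue = 2)

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual / expected - 1), tol)
}
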