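# Explicit finite-volume time integration: convergence to the analytic
# steady state, qualitative trace shapes, protocols, and numerical
# properties.

test_that("calibration transient rises quickly and converges to the analytic steady state", {
  p <- biosensor_params("calibration")
  res <- simulate_transient(p, t_end = 2, dr = coarse_dr)
  I_an <- current_from_solution(p)
  I_end <- res$trace$current_pA[nrow(res$trace)]
  expect_rel(I_end, I_an, 5e-3)
  expect_true(res$steady_reached)
  # rapid responsiveness: 95% of steady current in under a second
  t95 <- res$trace$time[which(res$trace$current_pA >= 0.95 * I_an)[1]]
  expect_lt(t95, 1)
  # positivity throughout
  expect_true(all(res$trace$current_pA >= 0))
  expect_true(all(res$state$A >= -1e-12) && all(res$state$H >= -1e-12))
})

test_that("tissue transient is initially high and decays after its early peak", {
  p <- biosensor_params("tissue")
  res <- simulate_transient(p, t_end = 10, dr = coarse_dr)
  tr <- res$trace
  pk <- which.max(tr$current_pA)
  I_steady <- solve_steady(p)$current_pA
  expect_gt(tr$current_pA[pk], 3 * I_steady)  # early peak well above steady
  expect_lt(tr$time[pk], 1)
  post <- tr$current_pA[pk:nrow(tr)]
  expect_true(all(diff(post) <= 1e-9 * max(post)))
})

test_that("time steps above the stability bound are refused, naming the bound", {
  p <- biosensor_params("calibration")
  expect_error(simulate_transient(p, t_end = 1, dt = 1, dr = coarse_dr),
               regexp = "stability bound",
               class = "biosensim_stability_error")
})

test_that("halving the time step leaves the trace unchanged to 1e-4 relative", {
  p <- biosensor_params("calibration")
  r1 <- simulate_transient(p, t_end = 0.2, dt = 2e-5, dr = coarse_dr,
                           record_every = 1000, scheme = "rk2")
  r2 <- simulate_transient(p, t_end = 0.2, dt = 1e-5, dr = coarse_dr,
                           record_every = 2000, scheme = "rk2")
  expect_equal(r1$trace$time, r2$trace$time, tolerance = 1e-12)
  sup <- max(abs(r1$trace$current_pA - r2$trace$current_pA))
  expect_lt(sup / max(r2$trace$current_pA), 1e-4)
})

test_that("halving the grid spacing changes the steady current by < 0.1%", {
  for (cf in c("calibration", "agar")) {
    p <- biosensor_params(cf)
    I1 <- fd_steady(p, dr = c(enzyme = 0.25, agar = 0.5))$current_pA
    I2 <- fd_steady(p, dr = c(enzyme = 0.125, agar = 0.25))$current_pA
    expect_rel(I1, I2, 1e-3)
  }
})

test_that("steady_by_integration reproduces the analytic steady state", {
  p <- biosensor_params("calibration")
  ss <- steady_by_integration(p, tol = 1e-5, dr = coarse_dr)
  expect_rel(ss$current_pA, current_from_solution(p), 5e-3)
  expect_identical(ss$method, "integration")

  # no analyte anywhere: zero profiles and zero current
  p0 <- biosensor_params("calibration", A_star = 0)
  ss0 <- steady_by_integration(p0, tol = 1e-5, dr = coarse_dr)
  expect_equal(ss0$current_pA, 0)
  expect_equal(max(abs(ss0$profile$A)), 0)
})

test_that("agar insertion protocol shows the transient overshoot and fast recovery", {
  p <- biosensor_params("agar")
  proto <- protocol(c("calibration", "agar", "calibration"), c(3, 12, 5))
  res <- run_protocol(proto, p, dr = coarse_dr)
  tr <- res$trace
  I_cal <- tr$current_pA[max(which(tr$segment == 1))]
  seg2 <- tr[tr$segment == 2, ]
  # local H2O2 build-up on insertion raises the current transiently ...
  expect_gt(max(seg2$current_pA), 1.02 * I_cal)
  # ... before decay towards the lower agar steady level
  I_agar <- solve_steady(p)$current_pA
  expect_rel(seg2$current_pA[nrow(seg2)], I_agar, 2e-2)
  expect_lt(I_agar, I_cal)

  # recovery to calibration is much faster than agar equilibration
  within5 <- function(seg, target) {
    t0 <- seg$time[1]
    seg$time[which(abs(seg$current_pA - target) <= 0.05 * target)[1]] - t0
  }
  t_equil <- within5(seg2, I_agar)
  seg3 <- tr[tr$segment == 3, ]
  t_recov <- within5(seg3, I_cal)
  expect_lt(t_recov, t_equil)
  expect_rel(seg3$current_pA[nrow(seg3)], I_cal, 2e-2)
})

test_that("a bath-to-bath switch is equivalent to a single calibration run", {
  p <- biosensor_params("calibration")
  single <- simulate_transient(p, t_end = 1, dr = coarse_dr)
  double <- run_protocol(protocol(c("calibration", "calibration"),
                                  c(0.5, 0.5)), p, dr = coarse_dr)
  I_end_single <- single$trace$current_pA[nrow(single$trace)]
  I_end_double <- double$trace$current_pA[nrow(double$trace)]
  expect_rel(I_end_double, I_end_single, 1e-6)
})

test_that("protocols reject inconsistent enzyme layers and bad segments", {
  p <- biosensor_params("agar")
  expect_error(protocol(character(), numeric()),
               class = "biosensim_protocol_error")
  expect_error(protocol("calibration", -1),
               class = "biosensim_protocol_error")
  expect_error(protocol("vacuum", 1), class = "biosensim_protocol_error")
  other <- biosensor_params("agar", v_b = 50)
  expect_error(
    run_protocol(protocol(c("calibration", "agar"), c(1, 1)), p,
                 segment_params = list(set_configuration(p, "calibration"),
                                       other),
                 dr = coarse_dr),
    class = "biosensim_protocol_error")
})

test_that("transient results carry tidy trace, summary and plot", {
  p <- biosensor_params("calibration")
  res <- simulate_transient(p, t_end = 0.5, dr = coarse_dr,
                            snapshot_times = c(0.1, 0.4))
  expect_named(tidy(res), c("time", "current_pA"))
  expect_equal(sort(unique(res$snapshots$time)), c(0.1, 0.4),
               tolerance = 1e-6)
  gl <- glance(res)
  expect_identical(gl$scheme, "rk4")
  expect_s3_class(autoplot(res), "ggplot")
})
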