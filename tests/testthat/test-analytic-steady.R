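# Analytic steady-state solutions: boundary conditions, closed-form
# currents and correction factors, and their internal consistency.

test_that("boundary and interface conditions hold for every configuration", {
  set.seed(21)
  for (cf in c("calibration", "agar", "tissue", "tissue_gap")) {
    for (k in 1:3) {
      p <- random_params(cf)
      for (sp in c("analyte", "peroxide")) {
        sol <- solve_radial_system(p, sp)
        mm <- interface_mismatch(sol)
        if (nrow(mm)) {
          expect_lt(max(mm$value_rel), 1e-10)
          expect_lt(max(mm$flux_rel), 1e-10)
        }
        if (sp == "analyte") {
          # zero flux at the core
          expect_lt(abs(eval_solution(sol, p$values$r1, deriv = TRUE,
                                      region = 1)),
                    1e-10 * p$values$A_star / p$values$r1)
        } else {
          # H electrolysed at the core
          expect_lt(abs(eval_solution(sol, p$values$r1)),
                    1e-10 * p$values$A_star)
        }
      }
    }
  }
})

test_that("outer analyte conditions: Dirichlet at the bath, far-field in tissue", {
  pc <- biosensor_params("calibration")
  sol <- solve_radial_system(pc, "analyte")
  expect_equal(eval_solution(sol, 50), 1, tolerance = 1e-12)

  pt <- biosensor_params("tissue")
  solt <- solve_radial_system(pt, "analyte")
  lt <- diffusion_length(pt, "tissue")
  expect_rel(eval_solution(solt, 50 + 10 * lt), 1, 1e-4)
})

test_that("steady profiles are physical: non-negative, analyte non-decreasing", {
  set.seed(22)
  for (cf in c("calibration", "agar", "tissue", "tissue_gap")) {
    ss <- solve_steady(random_params(cf))
    expect_true(all(ss$profile$A >= -1e-12))
    expect_true(all(ss$profile$H >= -1e-12))
    expect_true(all(diff(ss$profile$A) >= -1e-9 * max(ss$profile$A)))
    expect_gte(ss$current_pA, 0)
    if (length(ss$factors)) {
      f <- unlist(ss$factors)
      expect_true(all(f > 0 & f <= 1 + 1e-12))
    }
  }
})

test_that("closed-form calibration current matches the core peroxide flux", {
  p <- biosensor_params("calibration")
  expect_rel(calibration_current(p), current_from_solution(p), 1e-10)
  # diffusion-limited regime: full expression approaches the simplified form
  pfast <- biosensor_params("calibration", v_b = 1e6)
  expect_rel(calibration_current(pfast),
             calibration_current(pfast, simplified = TRUE), 1e-2)
  # no analyte, no current
  p0 <- biosensor_params("calibration", A_star = 0)
  expect_equal(current_from_solution(p0), 0, tolerance = 1e-15)
})

test_that("calibration current does not depend on the peroxide diffusion coefficient", {
  p1 <- biosensor_params("calibration")
  p2 <- biosensor_params("calibration", D_H = 3400)
  expect_rel(current_from_solution(p1), current_from_solution(p2), 1e-10)
})

test_that("steady-state mass balances close to 1e-6 relative", {
  set.seed(23)
  for (cf in c("calibration", "agar", "tissue", "tissue_gap")) {
    mb <- mass_balance(random_params(cf))
    expect_lt(max(mb$rel_error), 1e-6)
  }
})

test_that("agar factors: exact surface depletion, closed-form kappa_b, Eq-consistency", {
  p <- biosensor_params("agar")
  f <- agar_factors(p)
  # substantial surface depletion at reference parameters (~88%)
  expect_equal(round(100 * (1 - f$c_g)), 88)
  # the small-length approximation agrees when l_b << r1
  expect_rel(f$c_g, biosensim:::cg_small_length_approx(p), 0.05)
  expect_equal(f$kappa_b, 1 / (1 + 0.4 * log(3) / log(2)), tolerance = 1e-12)
  # inferred ratio equals the exact current ratio against free-flow calibration
  I_ratio <- current_from_solution(p) /
    current_from_solution(set_configuration(p, "calibration"))
  expect_rel(f$inferred_ratio, I_ratio, 1e-10)

  # symmetric layers and log-symmetric radii halve the inferred concentration
  psym <- biosensor_params("agar", alpha_g = 0.4, theta_g = 1, r3 = 100)
  expect_equal(agar_factors(psym)$kappa_b, 0.5, tolerance = 1e-12)

  # degenerate block: no agar layer recovers calibration
  peps <- biosensor_params("agar", r3 = 50 + 1e-9)
  feps <- agar_factors(peps)
  expect_equal(feps$kappa_b, 1, tolerance = 1e-9)
  expect_equal(feps$c_g, 1, tolerance = 1e-6)
})

test_that("tissue factor matches the surface ratio and behaves in limits", {
  p <- biosensor_params("tissue")
  ct <- tissue_factor(p)
  ss <- solve_steady(p)
  expect_rel(ct, ss$A_surface / p$far_field$A_star, 1e-8)
  expect_equal(round(100 * ct, 1), 1.5)
  # vanishing enzyme activity removes the gradient
  expect_gt(tissue_factor(biosensor_params("tissue", v_b = 1e-6)), 0.999)
  # faster tissue turnover reduces the mismatch severity
  expect_gt(tissue_factor(biosensor_params("tissue", v_t = 1)), ct)
})

test_that("gap mismatch reduces to the tissue factor as the gap closes", {
  p5 <- biosensor_params("tissue_gap")     # 5-um gap
  g5 <- gap_mismatch(p5)
  expect_equal(round(100 * g5$mismatch, 1), 2.5)
  expect_equal(g5$mismatch, g5$kappa_b * g5$gamma_b, tolerance = 1e-12)

  p0 <- biosensor_params("tissue_gap", r_s = 50)
  g0 <- gap_mismatch(p0)
  ct <- tissue_factor(biosensor_params("tissue"))
  expect_rel(g0$mismatch, ct, 1e-6)
  expect_equal(g0$kappa_b, 1)

  # closed-form route: kappa_b * (A(r_s) - A(r1)) / (A* (1 - X(r1)))
  asol <- solve_radial_system(p5, "analyte")
  X1 <- eval_solution(asol, 25, region = 1) / eval_solution(asol, 50, region = 1)
  closed <- g5$kappa_b *
    (eval_solution(asol, 55) - eval_solution(asol, 25)) / (1 - X1)
  expect_rel(g5$mismatch, closed, 1e-10)
})

test_that("analytic currents agree with the finite-difference oracle", {
  set.seed(24)
  for (cf in c("calibration", "agar", "tissue", "tissue_gap")) {
    for (k in 1:3) {
      p <- random_params(cf)
      I_an <- current_from_solution(p)
      I_fd <- fd_steady(p, dr = oracle_dr(p))$current_pA
      expect_rel(I_an, I_fd, 5e-3)
    }
  }
})

test_that("result tidiers expose profile and summary", {
  ss <- solve_steady(biosensor_params("tissue"))
  td <- tidy(ss)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("r", "region", "A", "H"))
  gl <- glance(ss)
  expect_equal(gl$current_pA, ss$current_pA)
  expect_true("c_t" %in% names(gl))
  expect_s3_class(autoplot(ss), "ggplot")
})
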