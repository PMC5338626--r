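test_that("reference parameter set carries the expected defaults and validates", {
  p <- biosensor_params("calibration")
  expect_s3_class(p, "biosensor_params")
  expect_identical(p$values[c("r1", "r2", "r3", "z_b")],
                   list(r1 = 25, r2 = 50, r3 = 150, z_b = 500))
  expect_equal(p$values$D_A, 860)
  expect_equal(p$values$D_H, 1700)
  expect_equal(p$values$v_b, 100)
  expect_equal(p$values$alpha_b, 0.4)
  expect_equal(p$values$theta_b, 1)
  expect_equal(p$values$v_t, 0.1)
  expect_equal(p$values$alpha_t, 0.2)
  expect_equal(p$values$theta_t, 0.4)
  expect_equal(p$far_field$A_star, 1)
  expect_identical(p$faraday, 96485)
  expect_identical(p$electrons_per_molecule, 2)

  # every configuration's preset validates and builds the right regions
  expect_identical(biosensor_params("calibration")$regions$role, "enzyme")
  expect_identical(biosensor_params("agar")$regions$role, c("enzyme", "agar"))
  expect_equal(region_of(biosensor_params("agar"), "agar")$r_out, 150)
  expect_identical(biosensor_params("tissue")$regions$role,
                   c("enzyme", "tissue"))
  expect_identical(biosensor_params("tissue_gap")$regions$role,
                   c("enzyme", "free_gap", "tissue"))
  expect_error(biosensor_params("bath"))
})

test_that("invariant violations are rejected with the offending field named", {
  expect_error(biosensor_params("calibration", r1 = 50, r2 = 25),
               regexp = "r1, r2", class = "biosensim_validation_error")
  expect_error(biosensor_params("calibration", alpha_b = 1.2),
               regexp = "alpha_b", class = "biosensim_validation_error")
  expect_error(biosensor_params("agar", r3 = 40),
               regexp = "r3", class = "biosensim_validation_error")
  expect_error(biosensor_params("tissue", v_t = -1),
               regexp = "v_t", class = "biosensim_validation_error")
  expect_error(biosensor_params("calibration", theta_b = 0),
               regexp = "theta_b", class = "biosensim_validation_error")
  expect_error(biosensor_params("calibration", A_star = -2),
               regexp = "A_star", class = "biosensim_validation_error")
})

test_that("serialization round-trips field for field", {
  set.seed(11)
  for (cf in c("calibration", "agar", "tissue", "tissue_gap")) {
    p <- random_params(cf)
    path <- withr::local_tempfile(fileext = ".json")
    write_params(p, path)
    q <- read_params(path)
    expect_identical(q$configuration, p$configuration)
    expect_equal(q$values, p$values, tolerance = 0)
    expect_equal(q$regions, p$regions)
  }
  expect_error(read_params(file.path(tempdir(), "nope.json")),
               class = "biosensim_io_error")
})

test_that("diffusion length follows sqrt(theta D / v) and rejects inert regions", {
  pt <- biosensor_params("tissue")
  # tissue range of influence: ~59 um at reference parameters
  expect_equal(diffusion_length(pt, "tissue"), sqrt(0.4 * 860 / 0.1),
               tolerance = 1e-12)
  expect_equal(round(diffusion_length(pt, "tissue")), 59)
  expect_equal(diffusion_length(pt, "enzyme"), sqrt(8.6), tolerance = 1e-12)
  pg <- biosensor_params("agar")
  expect_error(diffusion_length(pg, "agar"),
               class = "biosensim_no_finite_length_error")
})

test_that("a zero-width gap degenerates to the plain tissue layout", {
  p <- biosensor_params("tissue_gap", r_s = 50)
  expect_identical(p$regions$role, c("enzyme", "tissue"))
  expect_equal(region_of(p, "tissue")$r_in, 50)
})
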