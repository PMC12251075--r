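test_that("calibration set generation: blanks, reproducibility, stock guard", {
  dyes <- fix_dyes()
  geo <- fix_geometry()

  pts <- generate_calibration_set(dyes$EG, 0, geo, fix_detector(0))
  expect_equal(pts$concentration_ug_ml, 0)
  expect_equal(pts$normalized_transmission, 1.0)

  lv <- seq(0, 25, by = 5)
  a <- generate_calibration_set(dyes$EG, lv, geo, fix_detector(0))
  b <- generate_calibration_set(dyes$EG, lv, geo, fix_detector(0))
  expect_identical(a, b)

  # noise can push the blank level's I/I0 above 1, which warns (flagged)
  s1 <- suppressWarnings(generate_calibration_set(
    dyes$EG, lv, geo, fix_detector(0.005, seed = 3), replicates = 4))
  s2 <- suppressWarnings(generate_calibration_set(
    dyes$EG, lv, geo, fix_detector(0.005, seed = 3), replicates = 4))
  expect_identical(s1, s2)

  expect_error(generate_calibration_set(dyes$EG, 30, geo, fix_detector(0)),
               "above_stock")
})

test_that("replicate means track the noiseless forward model (CLT bound)", {
  dyes <- fix_dyes()
  geo <- fix_geometry()
  lv <- c(5, 10, 20)
  noiseless <- generate_calibration_set(dyes$EG, lv, geo, fix_detector(0))
  noisy <- generate_calibration_set(dyes$EG, lv, geo,
                                    fix_detector(0.005, seed = 11),
                                    replicates = 10)
  for (i in seq_along(lv)) {
    m <- mean(noisy$normalized_transmission[noisy$concentration_ug_ml == lv[i]])
    truth <- noiseless$normalized_transmission[i]
    expect_lt(abs(m - truth), 3 * 0.005 * truth / sqrt(10))
  }
})

test_that("exponential fit recovers its generating model exactly (noiseless)", {
  conc <- seq(0, 40, by = 4)
  pts <- calibration_points(conc, gen_exponential(conc, a = 1, b = 0.04, c = 0))
  cv <- fit_calibration(pts, "single_exponential")
  expect_equal(unname(cv$parameters[["a"]]), 1, tolerance = 1e-6)
  expect_equal(unname(cv$parameters[["b"]]), 0.04, tolerance = 1e-6)
  expect_equal(unname(cv$parameters[["c"]]), 0, tolerance = 1e-6)
  expect_lt(cv$fit_residual_rms, 1e-8)

  # with offset
  pts2 <- calibration_points(conc, gen_exponential(conc, a = 0.9, b = 0.05, c = 0.08))
  cv2 <- fit_calibration(pts2, "single_exponential")
  expect_equal(unname(cv2$parameters), c(0.9, 0.05, 0.08), tolerance = 1e-5)
})

test_that("linear fit through two points is the interpolating line", {
  pts <- calibration_points(c(0, 10), c(1.0, 0.6))
  cv <- fit_calibration(pts, "linear")
  expect_equal(unname(cv$parameters[["slope"]]), -0.04)
  expect_equal(unname(cv$parameters[["intercept"]]), 1.0)
  expect_equal(invert_calibration(cv, 0.8), 5)
})

test_that("fit guards: insufficient points, constant conc, non-monotone", {
  expect_error(fit_calibration(calibration_points(c(0, 1), c(1, 0.9)),
                               "single_exponential"), "insufficient")
  expect_error(fit_calibration(calibration_points(c(5, 5, 5), c(0.5, 0.5, 0.5)),
                               "single_exponential"), "equal")
  # increasing transmission with concentration cannot be calibrated
  pts_up <- calibration_points(c(0, 5, 10), c(0.5, 0.7, 0.9))
  expect_error(fit_calibration(pts_up, "linear"), "nonmonotone_calibration")
})

test_that("inversion is the exact inverse of prediction on the valid range", {
  conc <- seq(0, 30, by = 3)
  cv <- fit_calibration(
    calibration_points(conc, gen_exponential(conc, 0.95, 0.045, 0.03)),
    "single_exponential")

  expect_equal(invert_calibration(cv, predict_calibration(cv, 0)), 0,
               tolerance = 1e-9)
  expect_equal(invert_calibration(cv, predict_calibration(cv, 12.5)), 12.5,
               tolerance = 1e-9)

  set.seed(99)
  cr <- runif(1000, 0, 30)
  back <- invert_calibration(cv, predict_calibration(cv, cr))
  expect_equal(back, cr, tolerance = 1e-9)

  expect_error(invert_calibration(cv, 1.01), "out_of_calibration_range")
  expect_error(invert_calibration(cv, predict_calibration(cv, 30) - 0.01),
               "out_of_calibration_range")
})

test_that("pure Beer-Lambert calibration has slope b = eps(peak) * L", {
  dyes <- fix_dyes(cross_fraction = 0)
  geo <- fix_geometry()
  lv <- seq(0, 25, by = 2.5)
  pts <- generate_calibration_set(dyes$EG, lv, geo, fix_detector(0), band_nm = 0)
  cv <- fit_calibration(pts, "single_exponential", dye_name = "EG")
  eps_l <- absorptivity_at(dyes$EG$spectrum, 631) * geo$path_length_mm
  expect_equal(unname(cv$parameters[["b"]]), eps_l, tolerance = 1e-6)
  expect_equal(unname(cv$parameters[["a"]]), 1, tolerance = 1e-6)
  expect_equal(unname(cv$parameters[["c"]]), 0, tolerance = 1e-6)
})

test_that("calibration curve JSON round-trips", {
  conc <- seq(0, 20, by = 2)
  cv <- fit_calibration(
    calibration_points(conc, gen_exponential(conc), wavelength_nm = 631),
    "single_exponential", dye_name = "EG")
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration_curve_json(cv, path)
  back <- read_calibration_curve_json(path)
  expect_equal(back$parameters, cv$parameters)
  expect_equal(back$model_kind, cv$model_kind)
  expect_equal(invert_calibration(back, 0.5), invert_calibration(cv, 0.5))
})
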