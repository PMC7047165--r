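test_that("the default wedge carries 17 thicknesses from 0.5 to 4.5 mm", {
  tt <- wedge_thicknesses(step_wedge_spec())
  expect_length(tt, 17L)
  expect_equal(tt[1L], 0.5)
  expect_equal(tt[17L], 4.5)
  expect_equal(unique(round(diff(tt), 10)), 0.25)
})

test_that("wedge specs are validated", {
  expect_error(step_wedge_spec(n_steps = 3), ">= 4")
  expect_error(step_wedge_spec(increment = 0), "increasing")
  expect_error(step_wedge_spec(step_rois = list(c(0, 0, 1, 1))), "one rectangle per step")
})

test_that("step grays are trimmed ROI means", {
  ph <- generate_phantom(truth = phantom_truth(
    response = detector_response("linear", a = 100, b = 20), seed = 2))
  g <- measure_step_grays(ph$image, ph$wedge_spec)
  tt <- wedge_thicknesses(ph$wedge_spec)
  expect_equal(g$background_gray, 100)
  expect_equal(g$step_grays[9L], 100 + 20 * tt[9L])  # 2.5 mm -> 150
  expect_equal(g$step_grays, 100 + 20 * tt)

  ## constant image: every ROI returns the constant
  flat <- matrix(7, nrow(ph$image), ncol(ph$image))
  gf <- measure_step_grays(flat, ph$wedge_spec)
  expect_equal(gf$background_gray, 7)
  expect_equal(unique(gf$step_grays), 7)

  ## degenerate ROI
  spec_bad <- ph$wedge_spec
  spec_bad$background_roi <- c(xmin = 10, ymin = 10, xmax = 5, ymax = 12)
  expect_error(measure_step_grays(ph$image, spec_bad), "zero or negative extent")
  spec_out <- ph$wedge_spec
  spec_out$background_roi <- c(xmin = -5, ymin = 0, xmax = 5, ymax = 5)
  expect_error(measure_step_grays(ph$image, spec_out), "outside the image")
})

test_that("a cubic fit to exactly linear data returns the line", {
  cal <- linear_calibration()
  expect_lt(cal$fit_residual, 1e-9)
  expect_equal(as.numeric(gray_to_mm_al(cal, 140)), 2.0, tolerance = 1e-8)
  expect_equal(as.numeric(gray_to_mm_al(cal, 200)), 0.0, tolerance = 1e-8)
  expect_equal(as.numeric(gray_to_mm_al(cal, 65)), 4.5, tolerance = 1e-8)
  expect_equal(cal$direction, -1)   # gray falls with thickness here
})

test_that("out-of-range grays are clamped and flagged", {
  cal <- linear_calibration()   # gray range [65, 200]
  v <- gray_to_mm_al(cal, c(50, 140, 250))
  expect_equal(attr(v, "clamped"), c(TRUE, FALSE, TRUE))
  expect_equal(as.numeric(v[1L]), 4.5, tolerance = 1e-8)  # value at g_lo
  expect_equal(as.numeric(v[3L]), 0.0, tolerance = 1e-8)
})

test_that("non-monotone or degenerate step grays are rejected", {
  tt <- wedge_thicknesses(step_wedge_spec())
  g <- 200 - 30 * tt
  g[8L] <- g[7L] + 5   # one inversion
  expect_error(fit_calibration(200, g, tt), "offending step")
  expect_error(fit_calibration(100, rep(100, 17), tt), "degenerate")
})

test_that("calibration round-trips the ladder for generator responses", {
  tt <- wedge_thicknesses(step_wedge_spec())
  for (type in c("linear", "cubic")) {
    resp <- detector_response(type)
    g <- resp$forward(tt)
    bg <- resp$forward(0)
    cal <- fit_calibration(bg, g, tt)
    expect_lt(cal$fit_residual, 1e-6)
    expect_lt(max(abs(as.numeric(gray_to_mm_al(cal, g)) - tt)), 1e-6)
    expect_true(cal$monotone)
  }
  ## the saturating response is outside the cubic model space: the fit
  ## still reproduces the ladder within a few RMS residuals
  resp <- detector_response("saturating")
  g <- resp$forward(tt)
  cal <- fit_calibration(resp$forward(0), g, tt)
  expect_gt(cal$fit_residual, 1e-6)
  expect_lt(max(abs(as.numeric(gray_to_mm_al(cal, g)) - tt)),
            4 * cal$fit_residual + 1e-6)
})

test_that("mapped thicknesses are invariant to gray rescaling", {
  tt <- wedge_thicknesses(step_wedge_spec())
  resp <- detector_response("linear")
  g <- resp$forward(tt); bg <- resp$forward(0)
  cal1 <- fit_calibration(bg, g, tt)
  for (c_scale in c(0.25, 3.7)) {
    cal2 <- fit_calibration(bg * c_scale, g * c_scale, tt)
    expect_equal(as.numeric(gray_to_mm_al(cal2, g * c_scale)),
                 as.numeric(gray_to_mm_al(cal1, g)), tolerance = 1e-8)
  }
})

test_that("fitted curves are monotone along the thickness direction", {
  for (type in c("linear", "cubic", "saturating")) {
    resp <- detector_response(type)
    tt <- wedge_thicknesses(step_wedge_spec())
    cal <- fit_calibration(resp$forward(0), resp$forward(tt), tt)
    grid <- seq(cal$gray_range[1L], cal$gray_range[2L], length.out = 256L)
    expect_true(all(diff(as.numeric(gray_to_mm_al(cal, grid))) * cal$direction
                    >= -1e-9))
  }
})

test_that("calibration reports round-trip through JSON", {
  cal <- linear_calibration()
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration(cal, path)
  cal2 <- read_calibration(path)
  expect_equal(cal2$coefficients, cal$coefficients)
  expect_equal(as.numeric(gray_to_mm_al(cal2, 140)),
               as.numeric(gray_to_mm_al(cal, 140)))
})
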