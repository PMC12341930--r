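test_that("an exact linear relationship calibrates to the identity map", {
  au <- seq(0, 1000, length.out = 20)
  cal <- build_calibration(au, au / 1000, channel = "gfp")
  expect_s3_class(cal, "calibration_curve")
  expect_equal(as.numeric(predict(cal, 500)), 0.5, tolerance = 1e-6)
  expect_lt(cal$rmse_od, 1e-8)
})

test_that("calibration needs enough points and a monotone relationship", {
  au <- seq(100, 500, length.out = 5)
  expect_error(build_calibration(au, au / 1000), "at least 10")
  set.seed(1)
  x <- seq(0, 1000, length.out = 30)
  expect_error(build_calibration(x, sin(x / 50)), "monotone")
})

test_that("out-of-range fluorescence is clamped to boundary ODs and flagged", {
  au <- seq(100, 1000, length.out = 20)
  cal <- build_calibration(au, au / 1000)
  lo <- predict(cal, 100)
  expect_equal(as.numeric(lo), 0.1, tolerance = 1e-9)
  expect_false(attr(lo, "out_of_range"))
  oob <- od_x_from_gfp(c(50, 500, 2000), cal)
  expect_equal(attr(oob, "out_of_range"), c(TRUE, FALSE, TRUE))
  expect_equal(as.numeric(oob[1]), 0.1, tolerance = 1e-9)
  expect_equal(as.numeric(oob[3]), 1.0, tolerance = 1e-9)
})

test_that("round trip on noise-free synthetic monoculture recovers the OD", {
  fix <- generate_calibration_fixture("CP-X", n_points = 40, yield = 1000,
                                      fluor_sd = 0, od_sd = 0, seed = 1)
  cal <- build_calibration(fix$gfp_au, fix$od600, channel = "gfp")
  od_hat <- od_x_from_gfp(fix$gfp_au, cal)
  expect_equal(as.numeric(od_hat), fix$od600, tolerance = 1e-3)
})

test_that("calibration on a noisy monoculture reproduces its OD within 2x noise sd", {
  sd_au <- 20; yield <- 1000
  fix <- generate_calibration_fixture("CP-X", n_points = 60, yield = yield,
                                      fluor_sd = sd_au, od_sd = 0, seed = 4)
  cal <- build_calibration(fix$gfp_au, fix$od600, channel = "gfp")
  od_hat <- od_x_from_gfp(fix$gfp_au, cal)
  sd_od <- sd_au / yield
  expect_lt(sqrt(mean((as.numeric(od_hat) - fix$od600)^2)), 2 * sd_od)
})

test_that("a curved but monotone relationship is fitted by the two-segment model", {
  # saturating detector response: linear at low signal, compressive above
  od <- seq(0.01, 1, length.out = 50)
  au <- 1500 * od - 500 * pmax(od - 0.5, 0)^2
  cal <- build_calibration(au, od)
  od_hat <- predict(cal, au)
  expect_lt(sqrt(mean((as.numeric(od_hat) - od)^2)), 0.01)
  # fitted curve is monotone over its range
  grid <- seq(cal$range_au[1], cal$range_au[2], length.out = 200)
  expect_true(all(diff(as.numeric(predict(cal, grid))) >= -1e-9))
})

test_that("CP-G deconvolution subtracts, clamps and conserves the total", {
  expect_equal(as.numeric(od_g_from_total(0.5, 0.2)), 0.3)
  clamped <- od_g_from_total(0.2, 0.25)
  expect_equal(as.numeric(clamped), 0)
  expect_equal(attr(clamped, "n_clamped"), 1L)
  x <- c(0, 0.1, 0.7)
  expect_equal(as.numeric(od_g_from_total(x, rep(0, 3))), x)
  # conservation when no clamping occurs
  tot <- c(0.3, 0.5, 0.8); odx <- c(0.1, 0.2, 0.3)
  odg <- od_g_from_total(tot, odx)
  expect_equal(odx + as.numeric(odg), tot)
  expect_error(od_g_from_total(-0.1, 0), "non-negative")
})

test_that("calibration curves survive a JSON round trip", {
  od <- seq(0.01, 1, length.out = 30)
  au <- 1200 * od - 300 * pmax(od - 0.4, 0)^2
  cal <- build_calibration(au, od, channel = "mscarlet")
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration_json(cal, path)
  cal2 <- read_calibration_json(path)
  grid <- seq(min(au), max(au), length.out = 50)
  expect_equal(as.numeric(predict(cal2, grid)),
               as.numeric(predict(cal, grid)), tolerance = 1e-10)
  expect_equal(cal2$channel, "mscarlet")
})
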