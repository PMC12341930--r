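test_that("noise-free plate generator is exactly proportional to the trajectory", {
  scen <- scenario(t_end = 48)
  pr <- generate_plate_reader(scen, yield_x = 1000, yield_g = 800,
                              maturation_halftime_h = 0,
                              noise = noise_model(od_sd = 0, fluor_sd = 0))
  truth <- attr(pr, "truth")
  expect_equal(pr$od600, truth$od_total, tolerance = 1e-12)
  expect_equal(pr$gfp_au, 1000 * truth$od_x, tolerance = 1e-12)
  expect_equal(pr$mscarlet_au, 800 * truth$od_g, tolerance = 1e-12)
})

test_that("all generators are bit-reproducible given the seed", {
  n1 <- noise_model(od_sd = 0.01, fluor_sd = 15, seed = 7)
  p1 <- generate_plate_reader(scenario(t_end = 24), noise = n1)
  p2 <- generate_plate_reader(scenario(t_end = 24), noise = n1)
  expect_identical(p1, p2)
  h1 <- generate_hplc(seed = 7)
  h2 <- generate_hplc(seed = 7)
  expect_identical(h1, h2)
  f1 <- generate_calibration_fixture("CP-G", fluor_sd = 10, seed = 7)
  f2 <- generate_calibration_fixture("CP-G", fluor_sd = 10, seed = 7)
  expect_identical(f1, f2)
  # a different seed changes the noise
  expect_false(identical(generate_hplc(seed = 8), h1))
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(123)
  a <- runif(1)
  set.seed(123)
  invisible(generate_hplc(seed = 5))
  b <- runif(1)
  expect_identical(a, b)
})

test_that("maturation filter matches the first-order step response and tracks steady input", {
  t <- seq(0, 10, 0.1)
  half <- 0.67
  step <- rep(1, length(t))
  m <- mature_lag(t, step, half, init = 0)
  expect_equal(m, 1 - exp(-log(2) / half * t), tolerance = 1e-10)
  # converges to the input at steady state
  expect_equal(m[length(m)], 1, tolerance = 1e-4)
  # zero half time is the identity
  expect_identical(mature_lag(t, step, 0, init = 0), step)
  # during growth the matured signal lags the instantaneous one
  g <- 0.01 * exp(0.3 * t)
  expect_true(all(mature_lag(t, g, half) <= g + 1e-12))
})

test_that("mscarlet channel lags biomass under slow maturation", {
  pr <- generate_plate_reader(scenario(t_end = 48), yield_g = 1000,
                              maturation_halftime_h = 0.67,
                              noise = noise_model(od_sd = 0, fluor_sd = 0))
  truth <- attr(pr, "truth")
  grow <- which(diff(truth$od_g) > 1e-5)
  expect_true(all(pr$mscarlet_au[grow] <= 1000 * truth$od_g[grow] + 1e-9))
})

test_that("HPLC mass balance is exact at zero noise", {
  h <- generate_hplc(c(cellobiose = 1, xylobiose = 2),
                     c(cellobiose = 0.014, xylobiose = 0.006),
                     noise_sd = 0, times = seq(0, 60, 2))
  # hydration gain ratios from the molar masses
  r_glu <- 360.32 / 342.30
  r_xyl <- 300.26 / 282.25
  expect_equal(h$glucose, r_glu * (1 - h$cellobiose), tolerance = 1e-12)
  expect_equal(h$xylose, r_xyl * (2 - h$xylobiose), tolerance = 1e-12)
  expect_true(all(h$cellobiose >= 0 & h$xylobiose >= 0))
})

test_that("full hydrolysis plateaus glucose at the hydration gain", {
  # 1 g/l cellobiose fully hydrolysed: glucose -> 360.32/342.30 = 1.0526 g/l
  h <- generate_hplc(c(cellobiose = 1, xylobiose = 0),
                     c(cellobiose = 0.014, xylobiose = 0),
                     noise_sd = 0, times = seq(0, 100, 5))
  expect_equal(h$glucose[h$time_h == 100], 1.0526, tolerance = 1e-4)
  expect_equal(h$cellobiose[h$time_h == 100], 0)
  # depletion at 0.014 from 2 g/l hits zero at ~142.9 h
  h2 <- generate_hplc(c(cellobiose = 2, xylobiose = 0),
                      c(cellobiose = 0.014, xylobiose = 0),
                      noise_sd = 0, times = seq(0, 160, 1))
  expect_equal(min(h2$time_h[h2$cellobiose == 0]), 143, tolerance = 1)
  # zero conversion rates leave every channel constant
  h3 <- generate_hplc(conversion_rates_g_per_l_h =
                        c(cellobiose = 0, xylobiose = 0),
                      noise_sd = 0, times = seq(0, 24, 2))
  expect_true(all(h3$cellobiose == 2 & h3$xylobiose == 2))
  expect_true(all(h3$glucose == 0 & h3$xylose == 0))
})

test_that("calibration fixture refits its generating yield", {
  fix0 <- generate_calibration_fixture("CP-X", n_points = 30, yield = 1000,
                                       fluor_sd = 0, od_sd = 0)
  fit0 <- lm(gfp_au ~ 0 + od600, data = fix0)
  expect_equal(unname(coef(fit0)), 1000, tolerance = 1e-9)
  fix <- generate_calibration_fixture("CP-X", n_points = 50, yield = 1000,
                                      fluor_sd = 20, od_sd = 0, seed = 2)
  fit <- lm(gfp_au ~ 0 + od600, data = fix)
  expect_equal(unname(coef(fit)), 1000, tolerance = 0.02)
  expect_error(generate_calibration_fixture("CP-X", n_points = 5),
               "n_points >= 10")
})

test_that("evaporation drift concentrates signals only after its start time", {
  nm <- noise_model(od_sd = 0, fluor_sd = 0, evaporation_rate = 0.005,
                    evaporation_start_h = 48)
  pr <- generate_plate_reader(scenario(t_end = 72), noise = nm)
  truth <- attr(pr, "truth")
  before <- pr$time_h <= 48
  expect_equal(pr$od600[before], truth$od_total[before], tolerance = 1e-12)
  after <- pr$time_h > 48
  expect_true(all(pr$od600[after] > truth$od_total[after]))
  # at 72 h the factor is 1.005^24
  expect_equal(pr$od600[pr$time_h == 72],
               truth$od_total[truth$time_h == 72] * 1.005^24,
               tolerance = 1e-10)
  expect_error(noise_model(evaporation_rate = 0.02), "0.01")
})

test_that("plate + calibration + deconvolution round trip recovers X(t) within 2x noise", {
  sd_od <- 0.005; yield <- 10000; sd_au <- yield * sd_od
  scen <- scenario(t_end = 72)
  pr <- generate_plate_reader(scen, yield_x = yield,
                              noise = noise_model(od_sd = sd_od,
                                                  fluor_sd = sd_au,
                                                  seed = 31))
  fix <- generate_calibration_fixture("CP-X", n_points = 60, yield = yield,
                                      fluor_sd = 0, od_sd = 0)
  cal <- build_calibration(fix$gfp_au, fix$od600, channel = "gfp")
  od_x_hat <- od_x_from_gfp(pr$gfp_au, cal)
  od_g_hat <- od_g_from_total(pr$od600, as.numeric(od_x_hat))
  truth <- attr(pr, "truth")
  expect_lt(sqrt(mean((as.numeric(od_x_hat) - truth$od_x)^2)), 2 * sd_od)
  expect_lt(sqrt(mean((as.numeric(od_g_hat) - truth$od_g)^2)),
            2 * sqrt(2) * sd_od)
})
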