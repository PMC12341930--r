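test_that("baseline simulation reaches the fitted carrying capacity", {
  traj <- simulate_consortium(scenario(t_end = 300))
  expect_s3_class(traj, "trajectory")
  expect_equal(traj$od_total[nrow(traj)], 0.82, tolerance = 1e-3 / 0.82)
  expect_true(all(traj$od_x >= 0 & traj$od_g >= 0))
  expect_lte(max(traj$od_total), 0.82 * (1 + 1e-6))
})

test_that("capacity scales by the most restrictive alpha factor", {
  traj <- simulate_consortium(
    scenario(scaling = scaling_factors(alpha_Dx = 0.5), t_end = 300))
  expect_equal(traj$od_total[nrow(traj)], 0.41, tolerance = 1e-3 / 0.41)
})

test_that("mutual obligacy freezes the trajectory when one strain is absent", {
  traj <- simulate_consortium(
    scenario(initial = consortium_state(X = 0.05, G = 0), t_end = 72))
  expect_equal(traj$od_x, rep(0.05, nrow(traj)), tolerance = 1e-9)
  expect_equal(traj$od_g, rep(0, nrow(traj)))
  traj2 <- simulate_consortium(
    scenario(initial = consortium_state(X = 0, G = 0.03), t_end = 72))
  expect_equal(traj2$od_g, rep(0.03, nrow(traj2)), tolerance = 1e-9)
})

test_that("adaptive solver agrees with an independent fixed-step RK4 oracle", {
  cases <- list(
    list(p = baseline_parameters(), a = scaling_factors()),
    list(p = model_parameters(0.22, 0.34, 0.08, 0.02, 0.82),
         a = scaling_factors()),
    list(p = baseline_parameters(),
         a = scaling_factors(alpha_Dx = 0.6, alpha_Dg = 1.4,
                             alpha_Bx = 1.3, alpha_Ex = 0.8))
  )
  times <- seq(0, 72, by = 2)
  for (cs in cases) {
    init <- consortium_state(0.01, 0.01)
    adaptive <- simulate_consortium(
      scenario(params = cs$p, scaling = cs$a, initial = init), times = times)
    oracle <- rk4_consortium(cs$p, cs$a, init, times)
    expect_equal(adaptive$od_x, oracle$od_x, tolerance = 1e-5)
    expect_equal(adaptive$od_g, oracle$od_g, tolerance = 1e-5)
  }
})

test_that("increasing burden never increases X(t) anywhere on the grid", {
  base <- scenario(t_end = 150)
  prev <- simulate_consortium(base)$od_x
  for (b in c(1.5, 2.5, 4)) {
    cur <- simulate_consortium(
      scenario(scaling = scaling_factors(alpha_Bx = b), t_end = 150))$od_x
    expect_true(all(cur <= prev + 1e-9))
    prev <- cur
  }
})

test_that("inoculation ratios split the total exactly", {
  s <- inoculation_ratio_to_state(0.02, 1)
  expect_equal(unname(unclass(s)), c(0.01, 0.01))
  s10 <- inoculation_ratio_to_state(0.02, 10)
  expect_equal(round(unname(unclass(s10)), 4), c(0.0182, 0.0018))
  expect_equal(sum(inoculation_ratio_to_state(0.05, 4)), 0.05)
  expect_equal(unname(unclass(inoculation_ratio_to_state(0.05, 4))),
               c(0.04, 0.01))
  expect_error(inoculation_ratio_to_state(0, 1), "positive")
  expect_error(inoculation_ratio_to_state(0.02, -2), "positive")
})

test_that("substrate amounts map proportionally onto the alpha factors", {
  a <- substrate_ratio_to_scaling(1, 1)
  expect_equal(unclass(a)[c("alpha_Dx", "alpha_Dg")],
               c(alpha_Dx = 1, alpha_Dg = 1))
  a2 <- substrate_ratio_to_scaling(0.6, 1.4)
  expect_equal(a2[["alpha_Dx"]], 0.6)
  expect_equal(a2[["alpha_Dg"]], 1.4)
  # the 9:1 xylobiose:cellobiose experiment at 2 g/l total
  a3 <- substrate_ratio_to_scaling(0.2, 1.8)
  expect_equal(unname(unclass(a3)), c(0.2, 1.8, 1, 1))
  expect_error(substrate_ratio_to_scaling(-0.1, 1), "non-negative")
})

test_that("scenario battery summarises variants and propagates names", {
  base <- scenario(t_end = 300)
  out <- scenario_battery(base, list(
    baseline = list(),
    degtag = list(params = model_parameters(0.22, 0.34, 0.08, 0.02, 0.82)),
    skewed = list(initial = inoculation_ratio_to_state(0.02, 10))
  ))
  expect_equal(nrow(out), 3L)
  expect_equal(out$final_od_total[out$variant == "baseline"], 0.82,
               tolerance = 1e-3 / 0.82)
  expect_true(all(is.finite(out$final_od_total)))
  expect_true(all(is.finite(out$t_half_capacity_h)))
  expect_error(scenario_battery(base, list()), "non-empty")
})

test_that("total converges to the effective capacity from any positive start", {
  set.seed(3)
  for (i in 1:3) {
    p <- model_parameters(runif(1, 0.1, 0.4), runif(1, 0.1, 0.4),
                          runif(1, 0.01, 0.1), runif(1, 0.01, 0.1),
                          runif(1, 0.4, 1.2))
    a <- scaling_factors(alpha_Dx = runif(1, 0.5, 1.5),
                         alpha_Dg = runif(1, 0.5, 1.5))
    horizon <- 10 / min(p[["r_mx"]], p[["r_mg"]]) * 5
    traj <- simulate_consortium(
      scenario(params = p, scaling = a,
               initial = consortium_state(0.01, 0.01), t_end = horizon,
               dt_out = horizon / 100))
    cap <- effective_alpha_K(a) * p[["K"]]
    expect_equal(traj$od_total[nrow(traj)], cap, tolerance = 1e-3 / cap)
  }
})
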