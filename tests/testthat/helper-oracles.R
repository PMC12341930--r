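# Independent fixed-step RK4 integrator of the consortium equations,
# written directly from the rate definitions.  Used only as an oracle
# against the adaptive solver; shares no code with simulate_consortium().
rk4_consortium <- function(params, scaling, initial, times, n_sub = 20L) {
  a_K <- min(scaling[["alpha_Ex"]], scaling[["alpha_Dx"]],
             scaling[["alpha_Dg"]])
  f <- function(y) {
    X <- y[1L]; G <- y[2L]
    free <- 1 - (G + X) / (a_K * params[["K"]])
    c((params[["r_mx"]] / scaling[["alpha_Bx"]]) *
        scaling[["alpha_Dg"]] * G / (params[["C_g"]] + G) * free * X,
      params[["r_mg"]] *
        scaling[["alpha_Dx"]] * X /
        (params[["C_x"]] / scaling[["alpha_Ex"]] + X) * free * G)
  }
  y <- c(initial[["X"]], initial[["G"]])
  out <- matrix(NA_real_, nrow = length(times), ncol = 2L)
  out[1L, ] <- y
  for (i in seq_along(times)[-1L]) {
    h <- (times[i] - times[i - 1L]) / n_sub
    for (s in seq_len(n_sub)) {
      k1 <- f(y)
      k2 <- f(y + h / 2 * k1)
      k3 <- f(y + h / 2 * k2)
      k4 <- f(y + h * k3)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    out[i, ] <- y
  }
  data.frame(time_h = times, od_x = out[, 1L], od_g = out[, 2L])
}

# Seeded noisy replicate of a trajectory, as plate-reader fitting input.
noisy_fit_obs <- function(traj, sd, seed) {
  set.seed(seed)
  n <- nrow(traj)
  fit_observations(traj$time_h,
                   pmax(traj$od_total + rnorm(n, 0, sd), 0),
                   pmax(traj$od_x + rnorm(n, 0, sd), 0))
}
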