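#' Define a simulation scenario
#'
#' Bundles parameters, scaling factors, initial state, and the output time
#' grid.  Defaults mirror the plate-reader protocol: 72 h horizon with one
#' output point every half hour, starting from equal inocula of 0.01 OD.
#'
#' @param params `model_parameters` (default [baseline_parameters()]).
#' @param scaling `scaling_factors` (default identity).
#' @param initial `consortium_state` (default `X = G = 0.01`).
#' @param t_end Simulation horizon in hours (> 0).
#' @param dt_out Output step in hours (> 0).
#' @return An object of class `scenario`.
#' @export
scenario <- function(params = baseline_parameters(),
                     scaling = scaling_factors(),
                     initial = consortium_state(0.01, 0.01),
                     t_end = 72, dt_out = 0.5) {
  stopifnot(is.numeric(t_end), length(t_end) == 1L,
            is.numeric(dt_out), length(dt_out) == 1L)
  if (!is.finite(t_end) || t_end <= 0) {
    stop("scenario: t_end must be a positive number of hours", call. = FALSE)
  }
  if (!is.finite(dt_out) || dt_out <= 0) {
    stop("scenario: dt_out must be a positive number of hours", call. = FALSE)
  }
  structure(list(params = as_model_parameters(params),
                 scaling = as_scaling_factors(scaling),
                 initial = as_consortium_state(initial),
                 t_end = t_end, dt_out = dt_out),
            class = "scenario")
}

#' Simulate the consortium ODEs
#'
#' Integrates the two growth equations with an adaptive solver
#' (`deSolve::lsoda`, rtol 1e-8, atol 1e-10) and returns the trajectory on
#' the requested output grid.  Round-off excursions below zero (down to
#' -1e-8) are clipped to 0 at output; anything more negative raises an
#' error, since the dynamics preserve non-negativity.
#'
#' @param scen A `scenario`, or arguments to build one via [scenario()].
#' @param times Optional explicit output time vector (hours, strictly
#'   increasing, starting at 0); overrides `t_end`/`dt_out`.
#' @param ... Passed on to [scenario()] when `scen` is not already one.
#' @return A `trajectory`: data frame with columns `time_h`, `od_x`,
#'   `od_g`, `od_total`.
#' @examples
#' traj <- simulate_consortium(scenario(t_end = 300))
#' tail(traj, 1)  # total settles at the carrying capacity K = 0.82
#' @export
simulate_consortium <- function(scen = scenario(...), times = NULL, ...) {
  if (!inherits(scen, "scenario")) scen <- do.call(scenario, as.list(scen))
  if (is.null(times)) {
    times <- seq(0, scen$t_end, by = scen$dt_out)
    if (times[length(times)] < scen$t_end) times <- c(times, scen$t_end)
  }
  if (length(times) < 2L || any(diff(times) <= 0)) {
    stop("simulate_consortium: output grid must contain at least two ",
         "strictly increasing time points", call. = FALSE)
  }

  rhs <- function(t, y, parms) {
    list(consortium_rhs_raw(y, parms$params, parms$scaling, parms$a_K))
  }
  parms <- list(params = scen$params, scaling = scen$scaling,
                a_K = effective_alpha_K(scen$scaling))
  sol <- deSolve::ode(y = c(X = scen$initial[["X"]], G = scen$initial[["G"]]),
                      times = times, func = rhs, parms = parms,
                      method = "lsoda", rtol = 1e-8, atol = 1e-10)
  diagn <- attr(sol, "istate")
  if (!is.null(diagn) && diagn[1] < 0) {
    stop("simulate_consortium: integrator failed (istate = ", diagn[1],
         "); try a shorter horizon or check parameters", call. = FALSE)
  }
  sol <- as.data.frame(sol)
  if (nrow(sol) < length(times)) {
    stop("simulate_consortium: integrator returned a truncated solution",
         call. = FALSE)
  }
  for (col in c("X", "G")) {
    v <- sol[[col]]
    if (any(v < -1e-8)) {
      stop("simulate_consortium: solution went substantially negative in ",
           col, " (min = ", min(v), ")", call. = FALSE)
    }
    sol[[col]] <- pmax(v, 0)
  }
  new_trajectory(time_h = sol$time, od_x = sol$X, od_g = sol$G)
}

# un-validated RHS used inside the integrator (validation done once at entry)
consortium_rhs_raw <- function(y, params, scaling, a_K) {
  X <- y[[1L]]
  G <- y[[2L]]
  free <- 1 - (G + X) / (a_K * params[["K"]])
  c((params[["r_mx"]] / scaling[["alpha_Bx"]]) *
      (scaling[["alpha_Dg"]] * G / (params[["C_g"]] + G)) * free * X,
    params[["r_mg"]] *
      (scaling[["alpha_Dx"]] * X /
         (params[["C_x"]] / scaling[["alpha_Ex"]] + X)) * free * G)
}

new_trajectory <- function(time_h, od_x, od_g) {
  structure(data.frame(time_h = time_h, od_x = od_x, od_g = od_g,
                       od_total = od_x + od_g),
            class = c("trajectory", "data.frame"))
}

#' Split a total inoculum into per-strain initial ODs
#'
#' Converts a total inoculation density and an X:G ratio into the initial
#' state: `X = total * r / (r + 1)`, `G = total / (r + 1)`, so that
#' `X + G = total` exactly.  Ratios are expressed as CP-X : CP-G, matching
#' the convention "10:1 in favour of CP-X" = `ratio_x_to_g = 10`.
#'
#' @param total_od Total initial OD600 (> 0).
#' @param ratio_x_to_g Inoculation ratio X:G (> 0).
#' @return A `consortium_state`.
#' @examples
#' inoculation_ratio_to_state(0.02, 1)    # (0.01, 0.01)
#' inoculation_ratio_to_state(0.02, 10)   # (0.0182, 0.0018)
#' @export
inoculation_ratio_to_state <- function(total_od, ratio_x_to_g) {
  stopifnot(is.numeric(total_od), length(total_od) == 1L,
            is.numeric(ratio_x_to_g), length(ratio_x_to_g) == 1L)
  if (!is.finite(total_od) || total_od <= 0) {
    stop("inoculation_ratio_to_state: total_od must be positive",
         call. = FALSE)
  }
  if (!is.finite(ratio_x_to_g) || ratio_x_to_g <= 0) {
    stop("inoculation_ratio_to_state: ratio must be positive", call. = FALSE)
  }
  G <- total_od / (ratio_x_to_g + 1)
  consortium_state(X = total_od - G, G = G)
}

#' Substrate amounts to scenario scaling factors
#'
#' The cross-feeding factors are scaled proportionally to the initial
#' disaccharide amounts: `alpha_Dx = cellobiose / reference`,
#' `alpha_Dg = xylobiose / reference`.  The reference is 1 g/l per
#' disaccharide — the 1 + 1 g/l cultivation on which the baseline fit
#' (all alphas = 1) was made.  Enzyme-related factors are left at 1.
#'
#' @param cellobiose_g_per_l Initial cellobiose concentration (g/l, >= 0).
#' @param xylobiose_g_per_l Initial xylobiose concentration (g/l, >= 0).
#' @param reference_g_per_l Reference concentration (g/l, > 0; default 1).
#' @return A `scaling_factors` object with `alpha_Bx = alpha_Ex = 1`.
#' @examples
#' substrate_ratio_to_scaling(0.6, 1.4)   # the high-xylobiose scenario
#' @export
substrate_ratio_to_scaling <- function(cellobiose_g_per_l, xylobiose_g_per_l,
                                       reference_g_per_l = 1.0) {
  conc <- c(cellobiose_g_per_l, xylobiose_g_per_l)
  stopifnot(is.numeric(conc), length(conc) == 2L, all(is.finite(conc)),
            is.numeric(reference_g_per_l), reference_g_per_l > 0)
  if (any(conc < 0)) {
    stop("substrate_ratio_to_scaling: concentrations must be non-negative",
         call. = FALSE)
  }
  scaling_factors(alpha_Dx = cellobiose_g_per_l / reference_g_per_l,
                  alpha_Dg = xylobiose_g_per_l / reference_g_per_l)
}

#' Run a battery of scenario variants and summarise outcomes
#'
#' Simulates the base scenario under a list of named overrides (any of
#' `params`, `scaling`, `initial`) and returns one summary row per
#' variant: final per-strain ODs, final X:G ratio, and the time at which
#' the total first reaches half of the effective carrying capacity
#' `alpha_K * K`.
#'
#' @param base A `scenario` used as the template.
#' @param variants Named list; each element is a list with optional
#'   components `params`, `scaling`, `initial` overriding the base.  Use
#'   `list(baseline = list())` to run the base itself.
#' @return Data frame with columns `variant`, `final_od_x`, `final_od_g`,
#'   `final_od_total`, `final_ratio_x_to_g`, `t_half_capacity_h`.
#' @examples
#' scenario_battery(scenario(t_end = 300), list(
#'   baseline = list(),
#'   degtag   = list(params = model_parameters(0.22, 0.34, 0.08, 0.02, 0.82))
#' ))
#' @export
scenario_battery <- function(base, variants) {
  stopifnot(inherits(base, "scenario"))
  if (!is.list(variants) || length(variants) == 0L) {
    stop("scenario_battery: variants must be a non-empty named list",
         call. = FALSE)
  }
  if (is.null(names(variants)) || any(!nzchar(names(variants)))) {
    stop("scenario_battery: every variant must be named", call. = FALSE)
  }
  rows <- lapply(names(variants), function(nm) {
    ov <- variants[[nm]]
    scen <- base
    if (!is.null(ov$params)) scen$params <- as_model_parameters(ov$params)
    if (!is.null(ov$scaling)) scen$scaling <- as_scaling_factors(ov$scaling)
    if (!is.null(ov$initial)) scen$initial <- as_consortium_state(ov$initial)
    traj <- tryCatch(simulate_consortium(scen), error = function(e) {
      stop("scenario_battery: variant '", nm, "' failed: ",
           conditionMessage(e), call. = FALSE)
    })
    n <- nrow(traj)
    cap <- effective_alpha_K(scen$scaling) * scen$params[["K"]]
    hit <- which(traj$od_total >= cap / 2)
    data.frame(variant = nm,
               final_od_x = traj$od_x[n],
               final_od_g = traj$od_g[n],
               final_od_total = traj$od_total[n],
               final_ratio_x_to_g = traj$od_x[n] / traj$od_g[n],
               t_half_capacity_h = if (length(hit)) traj$time_h[hit[1L]]
                                   else NA_real_)
  })
  do.call(rbind, rows)
}
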