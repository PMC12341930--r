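#' Observations for parameter fitting
#'
#' A plate-reader time series prepared for fitting: total coculture OD and
#' the CP-X OD recovered from the GFP calibration, on a common strictly
#' increasing time grid, with optional per-point weights.
#'
#' @param t Time points (hours, strictly increasing).
#' @param od_total Total OD600 at each time point (>= 0).
#' @param od_x CP-X OD600 at each time point (>= 0).
#' @param weights Optional positive per-point weights (default all 1).
#' @return An object of class `fit_observations`.
#' @export
fit_observations <- function(t, od_total, od_x, weights = NULL) {
  stopifnot(is.numeric(t), is.numeric(od_total), is.numeric(od_x))
  n <- length(t)
  if (length(od_total) != n || length(od_x) != n) {
    stop("fit_observations: t, od_total and od_x must have equal length",
         call. = FALSE)
  }
  if (n < 2L || any(diff(t) <= 0)) {
    stop("fit_observations: t must be strictly increasing with >= 2 points",
         call. = FALSE)
  }
  if (any(od_total < 0) || any(od_x < 0)) {
    stop("fit_observations: optical densities must be non-negative",
         call. = FALSE)
  }
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights <= 0)) {
    stop("fit_observations: weights must be positive and match the series",
         call. = FALSE)
  }
  structure(list(t = t, od_total = od_total, od_x = od_x, weights = weights),
            class = "fit_observations")
}

# normalise obs argument: single series -> list of one
as_obs_list <- function(obs) {
  if (inherits(obs, "fit_observations")) return(list(obs))
  if (is.list(obs) && length(obs) &&
      all(vapply(obs, inherits, logical(1), "fit_observations"))) {
    return(obs)
  }
  stop("expected a fit_observations object or a list of them", call. = FALSE)
}

#' Residuals of the model against observed growth curves
#'
#' Simulates the model on each observation grid and returns the
#' concatenated, weighted residual vector: for every replicate first
#' `sim(X+G) - od_total`, then `sim(X) - od_x`.  Both blocks carry equal
#' weight, matching the use of the total-OD series and the calibrated
#' CP-X series on the same footing.
#'
#' @param params `model_parameters` (or a named vector coercible to one).
#' @param obs A `fit_observations` object or a list of replicates.
#' @param scaling `scaling_factors` for the cultivation scenario.
#' @param initial `consortium_state` at the first observation time.
#' @return Numeric residual vector of length `2 * sum(n_points)`.
#' @export
consortium_residuals <- function(params, obs, scaling = scaling_factors(),
                                 initial) {
  params <- as_model_parameters(params)
  obs <- as_obs_list(obs)
  initial <- as_consortium_state(initial)
  unlist(lapply(obs, function(o) {
    scen <- scenario(params = params, scaling = scaling, initial = initial,
                     t_end = max(o$t), dt_out = max(diff(o$t)))
    traj <- simulate_consortium(scen, times = o$t)
    c(o$weights * (traj$od_total - o$od_total),
      o$weights * (traj$od_x - o$od_x))
  }), use.names = FALSE)
}

#' Fit the consortium model to growth curves
#'
#' Bounded multistart least squares (Levenberg-Marquardt via
#' `minpack.lm::nls.lm`) over the five model parameters, minimising the
#' pooled residuals of [consortium_residuals()].  Starting points are drawn
#' log-uniformly inside the bounds; the first start is the centre of the
#' log-bounds box.  The fit is deterministic given `seed`.
#'
#' @param obs A `fit_observations` object or a list of replicate series.
#' @param scaling `scaling_factors` of the cultivation scenario.
#' @param initial Initial `consortium_state`; by default taken from the
#'   first time point of the data (`X = mean od_x`, `G = mean od_total -
#'   od_x` across replicates, floored at 1e-4).
#' @param lower,upper Named bounds on `(r_mx, r_mg, C_x, C_g, K)`.
#'   Defaults are generous brackets: rates in `[1e-3, 2]` per hour,
#'   half-saturation constants in `[1e-4, 1]` OD, `K` in `[0.05, 5]` OD.
#' @param n_starts Number of multistart draws (default 8).
#' @param seed Integer seed for the start draws.
#' @return An object of class `consortium_fit`: list with `params`
#'   (`model_parameters`), `residual_norm`, `n_iter`, `converged`,
#'   `bounds_hit` (named logical), `starts` (per-start diagnostics),
#'   and `initial`.
#' @examples
#' \donttest{
#' traj <- simulate_consortium(scenario())
#' obs <- fit_observations(traj$time_h, traj$od_total, traj$od_x)
#' fit <- fit_consortium(obs, n_starts = 2, seed = 1)
#' fit$params
#' }
#' @export
fit_consortium <- function(obs, scaling = scaling_factors(), initial = NULL,
                           lower = c(r_mx = 1e-3, r_mg = 1e-3, C_x = 1e-4,
                                     C_g = 1e-4, K = 0.05),
                           upper = c(r_mx = 2, r_mg = 2, C_x = 1,
                                     C_g = 1, K = 5),
                           n_starts = 8, seed = 1) {
  obs <- as_obs_list(obs)
  scaling <- as_scaling_factors(scaling)
  pnames <- c("r_mx", "r_mg", "C_x", "C_g", "K")
  lower <- lower[pnames]; upper <- upper[pnames]
  if (any(is.na(lower)) || any(is.na(upper)) || any(lower >= upper) ||
      any(lower <= 0)) {
    stop("fit_consortium: bounds must be positive, named, and well-ordered",
         call. = FALSE)
  }
  n_pts <- vapply(obs, function(o) length(o$t), integer(1))
  if (sum(n_pts) < 10L) {
    stop("fit_consortium: need at least 10 observation points in total",
         call. = FALSE)
  }
  # growth signal check: flat series carry no information on the rates
  tot <- unlist(lapply(obs, `[[`, "od_total"))
  if (max(tot) < 1.2 * max(min(tot), 1e-6)) {
    stop("fit_consortium: degenerate data - no growth signal in od_total ",
         "(max/min < 1.2)", call. = FALSE)
  }

  if (is.null(initial)) {
    x0 <- mean(vapply(obs, function(o) o$od_x[1L], numeric(1)))
    g0 <- mean(vapply(obs, function(o) o$od_total[1L] - o$od_x[1L],
                      numeric(1)))
    initial <- consortium_state(max(x0, 1e-4), max(g0, 1e-4))
  } else {
    initial <- as_consortium_state(initial)
  }

  obj <- function(logp) {
    p <- exp(logp)
    names(p) <- pnames
    tryCatch(
      consortium_residuals(p, obs, scaling, initial),
      error = function(e) rep(1e6, 2L * sum(n_pts))
    )
  }

  llo <- log(lower); lup <- log(upper)
  starts <- matrix(NA_real_, nrow = n_starts, ncol = 5L,
                   dimnames = list(NULL, pnames))
  starts[1L, ] <- (llo + lup) / 2
  if (n_starts > 1L) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    set.seed(seed)
    for (i in 2:n_starts) starts[i, ] <- llo + runif(5L) * (lup - llo)
    if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
      rm(".Random.seed", envir = globalenv())
  }

  best <- NULL
  diag_rows <- vector("list", n_starts)
  for (i in seq_len(n_starts)) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], lower = llo, upper = lup,
                         fn = obj,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-10)),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      diag_rows[[i]] <- data.frame(start = i, norm = NA_real_,
                                   message = conditionMessage(res))
      next
    }
    nrm <- sqrt(res$deviance)
    diag_rows[[i]] <- data.frame(start = i, norm = nrm,
                                 message = res$message)
    if (is.null(best) || nrm < sqrt(best$deviance)) best <- res
  }
  if (is.null(best)) {
    stop("fit_consortium: all starts failed:\n",
         paste(vapply(diag_rows, function(d) d$message, character(1)),
               collapse = "\n"), call. = FALSE)
  }

  phat <- exp(best$par)
  names(phat) <- pnames
  tol_b <- 1e-6
  bounds_hit <- (best$par - llo < tol_b) | (lup - best$par < tol_b)
  names(bounds_hit) <- pnames
  structure(list(
    params = do.call(model_parameters, as.list(phat)),
    residual_norm = sqrt(best$deviance),
    n_iter = best$niter,
    converged = best$info %in% 1:4,
    bounds_hit = bounds_hit,
    starts = do.call(rbind, diag_rows),
    initial = initial,
    scaling = scaling
  ), class = "consortium_fit")
}

#' @export
print.consortium_fit <- function(x, ...) {
  cat("Consortium model fit (", if (x$converged) "converged" else
      "NOT converged", ", ", x$n_iter, " iterations)\n", sep = "")
  print(unclass(x$params))
  cat("residual norm:", format(x$residual_norm), "\n")
  if (any(x$bounds_hit)) {
    cat("at bounds:", paste(names(x$bounds_hit)[x$bounds_hit],
                            collapse = ", "), "\n")
  }
  invisible(x)
}
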