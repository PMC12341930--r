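# molar masses (g/mol) fixing the hydrolysis mass-gain ratios:
# one disaccharide + water -> two monosaccharides
MM <- c(cellobiose = 342.30, glucose = 180.16,
        xylobiose = 282.25, xylose = 150.13)
GLUCOSE_PER_CELLOBIOSE <- 2 * MM[["glucose"]] / MM[["cellobiose"]]  # 1.0526
XYLOSE_PER_XYLOBIOSE <- 2 * MM[["xylose"]] / MM[["xylobiose"]]      # 1.0638

# evaluate expr with a fixed seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Measurement-noise model for synthetic plate-reader data
#'
#' Gaussian read noise on OD and fluorescence plus a late-time evaporation
#' drift: from `evaporation_start_h` onwards all signals are multiplied by
#' `(1 + evaporation_rate)^(t - start)`, emulating the concentration of the
#' culture as well volume evaporates towards the end of a 72 h run.
#'
#' @param od_sd Standard deviation of OD600 read noise (default 0.01).
#' @param fluor_sd Standard deviation of fluorescence read noise in AU.
#' @param evaporation_rate Fractional concentration increase per hour after
#'   the start time; must lie in `[0, 0.01)`.  Default 0 (off).
#' @param evaporation_start_h Hour at which evaporation drift begins.
#' @param seed Integer seed; every generator is a pure function of its
#'   inputs and this seed.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(od_sd = 0.01, fluor_sd = 20,
                        evaporation_rate = 0, evaporation_start_h = 48,
                        seed = 1L) {
  stopifnot(is.numeric(od_sd), od_sd >= 0,
            is.numeric(fluor_sd), fluor_sd >= 0,
            is.numeric(evaporation_rate),
            is.numeric(evaporation_start_h))
  if (evaporation_rate < 0 || evaporation_rate >= 0.01) {
    stop("noise_model: evaporation_rate must be in [0, 0.01)", call. = FALSE)
  }
  structure(list(od_sd = od_sd, fluor_sd = fluor_sd,
                 evaporation_rate = evaporation_rate,
                 evaporation_start_h = evaporation_start_h,
                 seed = as.integer(seed)),
            class = "noise_model")
}

evaporation_factor <- function(noise, t) {
  ifelse(t > noise$evaporation_start_h,
         (1 + noise$evaporation_rate)^(t - noise$evaporation_start_h), 1)
}

#' First-order maturation lag filter
#'
#' Applies the exponential low-pass that models slow fluorophore
#' maturation: the matured signal `M` relaxes towards the instantaneous
#' biomass signal `x` with rate `ln(2) / half_time`.  The discrete update
#' is exact for piecewise-constant input, so a step input reproduces the
#' closed-form response `1 - exp(-k t)`.  A half time of 0 returns the
#' input unchanged.
#'
#' @param t Time grid (hours, strictly increasing).
#' @param x Input signal on the grid.
#' @param half_time_h Maturation half time in hours (>= 0).
#' @param init Initial matured level (default `x[1]`, i.e. a
#'   pre-equilibrated inoculum).
#' @return Matured signal vector, same length as `x`.
#' @export
mature_lag <- function(t, x, half_time_h, init = x[1L]) {
  stopifnot(is.numeric(t), is.numeric(x), length(t) == length(x),
            is.numeric(half_time_h), half_time_h >= 0)
  if (half_time_h == 0) return(x)
  k <- log(2) / half_time_h
  m <- numeric(length(x))
  m[1L] <- init
  for (i in seq_along(x)[-1L]) {
    decay <- exp(-k * (t[i] - t[i - 1L]))
    m[i] <- x[i] + (m[i - 1L] - x[i]) * decay
  }
  m
}

#' Generate a synthetic plate-reader well
#'
#' Simulates the consortium under a scenario and converts the trajectory
#' to the three measured channels: `od600 = X + G`, `gfp_au = yield_x * X`
#' (msfGFP matures fast), and `mscarlet_au = yield_g * M(G)` where `M` is
#' the first-order maturation lag of [mature_lag()].  Evaporation drift
#' and Gaussian read noise are then applied per the noise model, and all
#' signals are clipped at 0.  Deterministic given the noise model's seed.
#'
#' @param scen A `scenario`.
#' @param yield_x GFP yield of CP-X (AU per OD, default 10000).
#' @param yield_g mScarlet yield of CP-G (AU per OD, default 8000).
#' @param maturation_halftime_h mScarlet maturation half time (hours,
#'   default 0.67, i.e. about 40 min).
#' @param noise A `noise_model`.
#' @param well Well identifier string.
#' @return A data frame of class `plate_reader_series` with columns
#'   `well`, `time_h`, `od600`, `gfp_au`, `mscarlet_au`; the noise-free
#'   trajectory is attached as attribute `truth`.
#' @export
generate_plate_reader <- function(scen = scenario(),
                                  yield_x = 10000, yield_g = 8000,
                                  maturation_halftime_h = 0.67,
                                  noise = noise_model(), well = "A1") {
  stopifnot(inherits(noise, "noise_model"),
            is.numeric(yield_x), yield_x >= 0,
            is.numeric(yield_g), yield_g >= 0,
            is.numeric(maturation_halftime_h), maturation_halftime_h >= 0)
  traj <- simulate_consortium(scen)
  m_g <- mature_lag(traj$time_h, traj$od_g, maturation_halftime_h)
  ev <- evaporation_factor(noise, traj$time_h)
  n <- nrow(traj)
  sig <- with_local_seed(noise$seed, {
    list(od = traj$od_total * ev + stats::rnorm(n, 0, noise$od_sd),
         gfp = yield_x * traj$od_x * ev + stats::rnorm(n, 0, noise$fluor_sd),
         msc = yield_g * m_g * ev + stats::rnorm(n, 0, noise$fluor_sd))
  })
  out <- data.frame(well = well, time_h = traj$time_h,
                    od600 = pmax(sig$od, 0),
                    gfp_au = pmax(sig$gfp, 0),
                    mscarlet_au = pmax(sig$msc, 0))
  class(out) <- c("plate_reader_series", "data.frame")
  attr(out, "truth") <- traj
  out
}

#' Generate a synthetic HPLC saccharide time series
#'
#' Disaccharides deplete linearly at the given conversion rates (clipped
#' at 0, matching zero-order hydrolysis by a fixed amount of resting-cell
#' enzyme); each hydrolysed gram yields monosaccharide with the water
#' mass gain of hydrolysis (glucose: 360.32/342.30 per g cellobiose;
#' xylose: 300.26/282.25 per g xylobiose), from which linear consumption
#' is subtracted (clipped at 0).  Gaussian noise is added to every
#' channel and negative readings are clipped.  Deterministic given `seed`.
#'
#' @param initial_disaccharides_g_per_l Named vector
#'   `c(cellobiose = , xylobiose = )` of starting concentrations (g/l).
#' @param conversion_rates_g_per_l_h Named vector of depletion rates
#'   `c(cellobiose = , xylobiose = )` (g/l/h, >= 0).
#' @param consumption_rates_g_per_l_h Named vector of monosaccharide
#'   consumption rates `c(glucose = , xylose = )` (g/l/h, >= 0).
#' @param noise_sd Gaussian noise standard deviation (g/l).
#' @param seed Integer seed.
#' @param times Sampling grid in hours (default 0-72 h every 3 h).
#' @return A data frame of class `hplc_series` with columns `time_h`,
#'   `glucose`, `xylose`, `cellobiose`, `xylobiose`.
#' @examples
#' hplc <- generate_hplc(c(cellobiose = 2, xylobiose = 2),
#'                       c(cellobiose = 0.014, xylobiose = 0.006),
#'                       noise_sd = 0, times = seq(0, 48, 3))
#' @export
generate_hplc <- function(initial_disaccharides_g_per_l =
                            c(cellobiose = 2, xylobiose = 2),
                          conversion_rates_g_per_l_h =
                            c(cellobiose = 0.014, xylobiose = 0.006),
                          consumption_rates_g_per_l_h =
                            c(glucose = 0, xylose = 0),
                          noise_sd = 0.02, seed = 1L,
                          times = seq(0, 72, by = 3)) {
  d0 <- initial_disaccharides_g_per_l
  cr <- conversion_rates_g_per_l_h
  cons <- consumption_rates_g_per_l_h
  stopifnot(all(c("cellobiose", "xylobiose") %in% names(d0)),
            all(c("cellobiose", "xylobiose") %in% names(cr)),
            all(c("glucose", "xylose") %in% names(cons)),
            is.numeric(noise_sd), length(times) >= 2L)
  if (any(c(d0, cr, cons) < 0) || noise_sd < 0) {
    stop("generate_hplc: concentrations, rates and noise_sd must be ",
         "non-negative", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("generate_hplc: times must be strictly increasing", call. = FALSE)
  }

  cb <- pmax(d0[["cellobiose"]] - cr[["cellobiose"]] * times, 0)
  xb <- pmax(d0[["xylobiose"]] - cr[["xylobiose"]] * times, 0)
  glu <- pmax(GLUCOSE_PER_CELLOBIOSE * (d0[["cellobiose"]] - cb) -
                cons[["glucose"]] * times, 0)
  xyl <- pmax(XYLOSE_PER_XYLOBIOSE * (d0[["xylobiose"]] - xb) -
                cons[["xylose"]] * times, 0)

  out <- with_local_seed(seed, {
    n <- length(times)
    data.frame(time_h = times,
               glucose = pmax(glu + stats::rnorm(n, 0, noise_sd), 0),
               xylose = pmax(xyl + stats::rnorm(n, 0, noise_sd), 0),
               cellobiose = pmax(cb + stats::rnorm(n, 0, noise_sd), 0),
               xylobiose = pmax(xb + stats::rnorm(n, 0, noise_sd), 0))
  })
  class(out) <- c("hplc_series", "data.frame")
  out
}

#' Generate a monoculture calibration fixture
#'
#' Paired (OD, fluorescence) points for one strain and channel spanning
#' OD 0.01 to 1, as produced by the calibration wells grown on the
#' strain's monosaccharide: fluorescence is `yield * od` plus Gaussian
#' noise.  Deterministic given `seed`.
#'
#' @param strain `"CP-X"` (GFP) or `"CP-G"` (mScarlet).
#' @param channel Channel label; defaults to the strain's tag.
#' @param n_points Number of calibration pairs (>= 10).
#' @param yield Fluorescence yield (AU per OD).
#' @param fluor_sd Gaussian noise sd on fluorescence (AU).
#' @param od_sd Gaussian noise sd on OD.
#' @param seed Integer seed.
#' @return A data frame of class `plate_reader_series` with columns
#'   `well`, `time_h`, `od600` and the channel column (`gfp_au` or
#'   `mscarlet_au`); the unused channel is 0.
#' @export
generate_calibration_fixture <- function(strain = c("CP-X", "CP-G"),
                                         channel = NULL, n_points = 30L,
                                         yield = 10000, fluor_sd = 0,
                                         od_sd = 0, seed = 1L) {
  strain <- match.arg(strain)
  if (is.null(channel)) channel <- if (strain == "CP-X") "gfp" else "mscarlet"
  if (!channel %in% c("gfp", "mscarlet")) {
    stop("generate_calibration_fixture: channel must be 'gfp' or 'mscarlet'",
         call. = FALSE)
  }
  if (!is.numeric(n_points) || n_points < 10L) {
    stop("generate_calibration_fixture: need n_points >= 10", call. = FALSE)
  }
  od <- seq(0.01, 1, length.out = n_points)
  out <- with_local_seed(seed, {
    data.frame(well = paste0("CAL-", strain),
               time_h = seq_along(od) * 0.5 - 0.5,
               od600 = pmax(od + stats::rnorm(n_points, 0, od_sd), 0),
               au = pmax(yield * od + stats::rnorm(n_points, 0, fluor_sd), 0))
  })
  names(out)[names(out) == "au"] <- paste0(channel, "_au")
  other <- setdiff(c("gfp_au", "mscarlet_au"), paste0(channel, "_au"))
  out[[other]] <- 0
  out <- out[, c("well", "time_h", "od600", "gfp_au", "mscarlet_au")]
  class(out) <- c("plate_reader_series", "data.frame")
  out
}
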