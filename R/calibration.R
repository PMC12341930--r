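#' Build a fluorescence-to-OD calibration curve
#'
#' Fits a continuous, monotone mapping from a fluorescence channel (AU) to
#' single-strain OD600 using paired monoculture measurements.  The curve is
#' a two-segment model — linear in the low-fluorescence range, quadratic in
#' the high range, continuous at the breakpoint — with the breakpoint
#' chosen to minimise in-sample RMSE among candidates that keep the fitted
#' mapping monotone non-decreasing.  A single linear fit is used when it
#' wins or when the quadratic segment would be non-monotone.
#'
#' @param fluor_au Fluorescence readings (AU), same length as `od`.
#' @param od Reference OD600 readings (>= 10 points spanning growth).
#' @param channel Channel label, e.g. `"gfp"` or `"mscarlet"`.
#' @param min_points Minimum number of calibration pairs (default 10).
#' @return An object of class `calibration_curve`: list with `channel`,
#'   `breakpoint` (AU, or NA for a single segment), coefficient sets,
#'   `range_au`, `range_od`, and in-sample `rmse_od`.
#' @examples
#' au <- seq(0, 1000, length.out = 20)
#' cal <- build_calibration(au, au / 1000, channel = "gfp")
#' predict(cal, 500)   # 0.5
#' @export
build_calibration <- function(fluor_au, od, channel = "gfp",
                              min_points = 10L) {
  stopifnot(is.numeric(fluor_au), is.numeric(od))
  if (length(fluor_au) != length(od)) {
    stop("build_calibration: fluor_au and od must have equal length",
         call. = FALSE)
  }
  keep <- is.finite(fluor_au) & is.finite(od)
  fluor_au <- fluor_au[keep]; od <- od[keep]
  if (length(od) < min_points) {
    stop("build_calibration: need at least ", min_points,
         " calibration points, got ", length(od), call. = FALSE)
  }
  o <- order(fluor_au)
  au <- fluor_au[o]; odv <- od[o]

  # the raw relationship must be essentially monotone before any fit
  rho <- stats::cor(au, odv, method = "spearman")
  if (!is.finite(rho) || rho < 0.9) {
    stop("build_calibration: raw fluorescence-OD relationship is not ",
         "monotone (Spearman rho = ", format(rho, digits = 3), ")",
         call. = FALSE)
  }

  rmse <- function(pred) sqrt(mean((pred - odv)^2))

  # candidate 1: global linear fit
  lin <- stats::lm.fit(cbind(1, au), odv)
  best <- list(breakpoint = NA_real_,
               low = c(intercept = lin$coefficients[[1L]],
                       slope = lin$coefficients[[2L]]),
               high = NULL,
               rmse = rmse(cbind(1, au) %*% lin$coefficients))
  if (best$low[["slope"]] < 0) {
    stop("build_calibration: fitted calibration is decreasing", call. = FALSE)
  }

  # candidate 2: linear low segment + quadratic high segment, continuous
  n <- length(au)
  cand_idx <- unique(round(seq(4L, n - 4L, length.out = min(12L, n - 7L))))
  for (k in cand_idx) {
    au_bp <- au[k]
    ilo <- seq_len(k); ihi <- k:n
    flo <- stats::lm.fit(cbind(1, au[ilo]), odv[ilo])
    a <- flo$coefficients[[1L]]; b <- flo$coefficients[[2L]]
    if (!is.finite(b) || b < 0) next
    od_bp <- a + b * au_bp
    # high segment: od = od_bp + c1*(au-au_bp) + c2*(au-au_bp)^2
    du <- au[ihi] - au_bp
    fhi <- stats::lm.fit(cbind(du, du^2), odv[ihi] - od_bp)
    c1 <- fhi$coefficients[[1L]]; c2 <- fhi$coefficients[[2L]]
    if (!is.finite(c1) || !is.finite(c2)) next
    # monotone on [au_bp, max(au)]: derivative c1 + 2 c2 du >= 0 at both ends
    if (c1 < 0 || c1 + 2 * c2 * (au[n] - au_bp) < 0) next
    pred <- ifelse(au <= au_bp, a + b * au,
                   od_bp + c1 * (au - au_bp) + c2 * (au - au_bp)^2)
    r <- rmse(pred)
    if (r < best$rmse) {
      best <- list(breakpoint = au_bp,
                   low = c(intercept = a, slope = b),
                   high = c(od_bp = od_bp, c1 = c1, c2 = c2),
                   rmse = r)
    }
  }

  structure(list(channel = channel,
                 breakpoint = best$breakpoint,
                 low = best$low,
                 high = best$high,
                 range_au = range(au),
                 range_od = c(predict_cal_raw(best, au[1L]),
                              predict_cal_raw(best, au[n])),
                 rmse_od = best$rmse,
                 n_points = n),
            class = "calibration_curve")
}

predict_cal_raw <- function(cal, au) {
  bp <- cal$breakpoint
  lo <- cal$low
  if (is.na(bp)) return(lo[["intercept"]] + lo[["slope"]] * au)
  hi <- cal$high
  ifelse(au <= bp,
         lo[["intercept"]] + lo[["slope"]] * au,
         hi[["od_bp"]] + hi[["c1"]] * (au - bp) + hi[["c2"]] * (au - bp)^2)
}

#' Predict OD from fluorescence using a calibration curve
#'
#' Values outside the calibrated fluorescence range are clamped to the
#' boundary ODs; the returned vector carries an `out_of_range` logical
#' attribute flagging the clamped positions.
#'
#' @param object A `calibration_curve`.
#' @param fluor_au Fluorescence values (AU) to convert.
#' @param ... Unused.
#' @return Numeric OD vector with attribute `out_of_range`.
#' @export
predict.calibration_curve <- function(object, fluor_au, ...) {
  stopifnot(is.numeric(fluor_au))
  lo <- object$range_au[1L]; hi <- object$range_au[2L]
  oob <- fluor_au < lo | fluor_au > hi
  au <- pmin(pmax(fluor_au, lo), hi)
  od <- predict_cal_raw(object, au)
  od <- pmin(pmax(od, min(object$range_od)), max(object$range_od))
  attr(od, "out_of_range") <- oob
  od
}

#' CP-X OD from the GFP channel
#'
#' Thin wrapper around [predict.calibration_curve()] for the reliable GFP
#' signal of strain CP-X.
#'
#' @param gfp_au GFP fluorescence (AU).
#' @param curve A `calibration_curve` built on the GFP channel.
#' @return CP-X OD600 vector with attribute `out_of_range`.
#' @export
od_x_from_gfp <- function(gfp_au, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  predict(curve, gfp_au)
}

#' CP-G OD by subtraction from the total
#'
#' The slow maturation of mScarlet makes the red channel lag the biomass,
#' so CP-G is quantified as total OD minus the GFP-derived CP-X OD.
#' Negative differences are clamped to 0; the result carries a `clamped`
#' attribute counting and flagging such points.
#'
#' @param od_total Total coculture OD600 (>= 0).
#' @param od_x CP-X OD600 (>= 0).
#' @return CP-G OD vector with attributes `clamped` (logical vector) and
#'   `n_clamped`.
#' @examples
#' od_g_from_total(0.5, 0.2)   # 0.3
#' @export
od_g_from_total <- function(od_total, od_x) {
  stopifnot(is.numeric(od_total), is.numeric(od_x),
            length(od_total) == length(od_x))
  if (any(od_total < 0) || any(od_x < 0)) {
    stop("od_g_from_total: optical densities must be non-negative",
         call. = FALSE)
  }
  diff <- od_total - od_x
  clamped <- diff < 0
  out <- pmax(diff, 0)
  attr(out, "clamped") <- clamped
  attr(out, "n_clamped") <- sum(clamped)
  out
}

#' Serialize a calibration curve to JSON
#'
#' @param cal A `calibration_curve`.
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_calibration_json <- function(cal, path) {
  stopifnot(inherits(cal, "calibration_curve"))
  out <- unclass(cal)
  out$low <- as.list(out$low)
  if (!is.null(out$high)) out$high <- as.list(out$high)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a calibration curve from JSON
#'
#' @param path File written by [write_calibration_json()].
#' @return A `calibration_curve`.
#' @export
read_calibration_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$breakpoint <- if (is.null(x$breakpoint)) NA_real_ else x$breakpoint
  if (!is.null(x$high)) x$high <- unlist(x$high)
  x$low <- unlist(x$low)
  structure(x, class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("Fluorescence calibration (", x$channel, "): ",
      if (is.na(x$breakpoint)) "single linear segment"
      else paste0("linear + quadratic, breakpoint at ",
                  format(x$breakpoint), " AU"),
      "\n  range ", format(x$range_au[1L]), "-", format(x$range_au[2L]),
      " AU -> ", format(x$range_od[1L]), "-", format(x$range_od[2L]),
      " OD; in-sample RMSE ", format(x$rmse_od, digits = 3), " OD\n",
      sep = "")
  invisible(x)
}
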