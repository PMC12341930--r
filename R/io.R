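# column schemas for the three tabular interchange formats
TS_SCHEMAS <- list(
  plate = list(required = c("time_h", "od600", "gfp_au", "mscarlet_au"),
               optional = "well", class = "plate_reader_series"),
  hplc = list(required = c("time_h", "glucose", "xylose", "cellobiose",
                           "xylobiose"),
              optional = character(), class = "hplc_series"),
  fit = list(required = c("time_h", "od_total", "od_x"),
             optional = "weight", class = NULL),
  trajectory = list(required = c("time_h", "od_x", "od_g", "od_total"),
                    optional = character(), class = "trajectory")
)

#' Read and validate a time-series CSV
#'
#' Reads one of the package's tabular formats (UTF-8, '.' decimal, header
#' required), checks the column schema, coerces to numeric, sorts by time,
#' and rejects duplicate time points and negative measurements with
#' messages naming the offending column and row.
#'
#' @param path Path to a CSV file.
#' @param schema One of `"plate"` (`time_h, od600, gfp_au, mscarlet_au`),
#'   `"hplc"` (`time_h, glucose, xylose, cellobiose, xylobiose`),
#'   `"fit"` (`time_h, od_total, od_x[, weight]`), or `"trajectory"`
#'   (`time_h, od_x, od_g, od_total`).
#' @return A validated data frame; `"fit"` returns a `fit_observations`
#'   object.
#' @export
read_timeseries_csv <- function(path, schema = c("plate", "hplc", "fit",
                                                 "trajectory")) {
  schema <- match.arg(schema)
  sch <- TS_SCHEMAS[[schema]]
  if (!file.exists(path)) {
    stop("read_timeseries_csv: file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(sch$required, names(df))
  if (length(missing_cols)) {
    stop("read_timeseries_csv: missing column(s) ",
         paste(missing_cols, collapse = ", "), " in ", path, call. = FALSE)
  }
  num_cols <- setdiff(c(sch$required, intersect(sch$optional, names(df))),
                      "well")
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (any(is.na(v))) {
      row <- if (length(bad)) bad[1L] else which(is.na(v))[1L]
      stop("read_timeseries_csv: non-numeric or missing value in column '",
           col, "', row ", row, call. = FALSE)
    }
    if (col != "weight" && any(v < 0)) {
      stop("read_timeseries_csv: negative value in column '", col,
           "', row ", which(v < 0)[1L], call. = FALSE)
    }
    df[[col]] <- v
  }
  df <- df[order(df$time_h), , drop = FALSE]
  if (anyDuplicated(df$time_h)) {
    stop("read_timeseries_csv: duplicate time point at time_h = ",
         df$time_h[which(duplicated(df$time_h))[1L]], call. = FALSE)
  }
  rownames(df) <- NULL
  if (schema == "fit") {
    return(fit_observations(df$time_h, df$od_total, df$od_x,
                            weights = df$weight))
  }
  if (!is.null(sch$class)) class(df) <- c(sch$class, "data.frame")
  df
}

#' Write a trajectory (or any package series) to CSV
#'
#' @param x A data frame (`trajectory`, `plate_reader_series`,
#'   `hplc_series`, or a battery summary).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_timeseries_csv <- function(x, path) {
  stopifnot(is.data.frame(x))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Write a fit result to JSON
#'
#' @param fit A `consortium_fit` from [fit_consortium()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "consortium_fit"))
  out <- list(params = as.list(unclass(fit$params)),
              residual_norm = fit$residual_norm,
              n_iter = fit$n_iter,
              converged = fit$converged,
              bounds_hit = as.list(fit$bounds_hit),
              initial = as.list(unclass(fit$initial)),
              scaling = as.list(unclass(fit$scaling)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a fit result from JSON
#'
#' @param path File written by [write_fit_json()].
#' @return A `consortium_fit` (without the per-start diagnostics).
#' @export
read_fit_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(params = do.call(model_parameters, as.list(x$params)),
                 residual_norm = x$residual_norm,
                 n_iter = x$n_iter,
                 converged = x$converged,
                 bounds_hit = unlist(x$bounds_hit),
                 starts = NULL,
                 initial = consortium_state(x$initial$X, x$initial$G),
                 scaling = do.call(scaling_factors, as.list(x$scaling))),
            class = "consortium_fit")
}

#' Read a run configuration file
#'
#' Parses a YAML configuration with sections `params` (the five model
#' parameters; all required, no silent defaults), and optional sections
#' `scaling` (the four alpha factors), `initial` (`X`, `G`), `scenario`
#' (`t_end`, `dt_out`), `fitting` (`n_starts`, `seed`, `lower`, `upper`),
#' and `noise`.  Unknown sections or keys are rejected.
#'
#' @param path Path to the YAML file.
#' @return A list with validated components `params`
#'   (`model_parameters`), `scaling` (`scaling_factors`), `initial`
#'   (`consortium_state`), `scenario`, `fitting`, `noise`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop("read_run_config: file not found: ", path, call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  known_sections <- c("params", "scaling", "initial", "scenario", "fitting",
                      "noise")
  unknown <- setdiff(names(cfg), known_sections)
  if (length(unknown)) {
    stop("read_run_config: unknown section(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  check_keys <- function(section, allowed) {
    extra <- setdiff(names(cfg[[section]]), allowed)
    if (length(extra)) {
      stop("read_run_config: unknown key(s) in section '", section, "': ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
  }
  if (is.null(cfg$params)) {
    stop("read_run_config: required section 'params' is missing",
         call. = FALSE)
  }
  check_keys("params", c("r_mx", "r_mg", "C_x", "C_g", "K"))
  need <- setdiff(c("r_mx", "r_mg", "C_x", "C_g", "K"), names(cfg$params))
  if (length(need)) {
    stop("read_run_config: section 'params' is missing: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  out <- list(params = do.call(model_parameters, cfg$params))

  check_keys("scaling", c("alpha_Dx", "alpha_Dg", "alpha_Bx", "alpha_Ex"))
  out$scaling <- do.call(scaling_factors,
                         if (is.null(cfg$scaling)) list() else cfg$scaling)

  check_keys("initial", c("X", "G"))
  out$initial <- if (is.null(cfg$initial)) consortium_state(0.01, 0.01)
                 else do.call(consortium_state, cfg$initial)

  check_keys("scenario", c("t_end", "dt_out"))
  out$scenario <- utils::modifyList(list(t_end = 72, dt_out = 0.5),
                                    if (is.null(cfg$scenario)) list()
                                    else cfg$scenario)

  check_keys("fitting", c("n_starts", "seed", "lower", "upper"))
  out$fitting <- utils::modifyList(list(n_starts = 8L, seed = 1L),
                                   if (is.null(cfg$fitting)) list()
                                   else cfg$fitting)

  check_keys("noise", c("od_sd", "fluor_sd", "evaporation_rate",
                        "evaporation_start_h", "seed"))
  out$noise <- do.call(noise_model,
                       if (is.null(cfg$noise)) list() else cfg$noise)
  out
}

#' Build a scenario from a run configuration
#'
#' @param cfg A list from [read_run_config()].
#' @return A `scenario`.
#' @export
config_to_scenario <- function(cfg) {
  scenario(params = cfg$params, scaling = cfg$scaling,
           initial = cfg$initial, t_end = cfg$scenario$t_end,
           dt_out = cfg$scenario$dt_out)
}
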