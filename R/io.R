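#' Load a scenario configuration from YAML or JSON
#'
#' Reads a run configuration: either `scenario: <builtin name>` or an
#' inline regime (`k`, `Ct`, `initial`), plus optional integrator
#' `settings` overrides.  Unknown keys are rejected; defaults are
#' filled in.  [save_config()] writes the same dialect and the round
#' trip is the identity on the configuration contents.
#'
#' @param path File path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return A [scenario_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  known <- c("scenario", "name", "k", "Ct", "initial", "settings", "note")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(raw$scenario) &&
      any(c("k", "Ct", "initial") %in% names(raw)))
    stop("give either `scenario` (a built-in name) or an inline regime, ",
         "not both", call. = FALSE)

  settings <- NULL
  if (!is.null(raw$settings)) {
    ok <- names(formals(integrator_settings))
    bad <- setdiff(names(raw$settings), ok)
    if (length(bad))
      stop("unknown settings key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    settings <- do.call(integrator_settings, raw$settings)
  }

  if (!is.null(raw$scenario)) {
    cfg <- builtin_scenario(raw$scenario)
    cfg$settings <- settings
    return(cfg)
  }
  init <- unlist(raw$initial)
  missing <- setdiff(.species, names(init))
  if (length(missing))
    stop("initial state is missing species: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (init[["C"]] > 1 || init[["C"]] < 0)
    stop("initial cerous fraction C must lie in [0, 1], got ",
         init[["C"]], call. = FALSE)
  k <- if (is.null(raw$k)) rate_constants() else {
    kk <- unlist(raw$k)
    rate_constants(kk[["k1"]], kk[["k2"]], kk[["k3"]], kk[["k4"]])
  }
  scenario_config(name = if (is.null(raw$name)) "custom" else raw$name,
                  k = k, Ct = if (is.null(raw$Ct)) 1 else raw$Ct,
                  initial = init[.species], settings = settings,
                  note = if (is.null(raw$note)) "" else raw$note)
}

#' @rdname load_config
#' @param config A [scenario_config()] to write.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  out <- list(name = config$name, k = as.list(unclass(config$k)),
              Ct = config$Ct,
              initial = as.list(unclass(config$initial)),
              note = config$note)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(out, path)
  invisible(path)
}

#' Write / read a trajectory as CSV
#'
#' Header is exactly `t,P,O,D,S,C,F,H`; values are written with 15
#' significant digits so the round trip preserves them to at least 12.
#' The ceric column `F` is always emitted even though it is algebraic.
#'
#' @param ts A `ros_timeseries` (or any data frame with those columns).
#' @param path Output path.
#' @export
write_timeseries_csv <- function(ts, path) {
  cols <- c("t", "P", "O", "D", "S", "C", "F", "H")
  stopifnot(is.data.frame(ts), all(cols %in% names(ts)))
  df <- as.data.frame(ts)[, cols, drop = FALSE]
  for (cc in cols) df[[cc]] <- sprintf("%.15g", df[[cc]])
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("failed to write time series to '", path, "': ",
         conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' @rdname write_timeseries_csv
#' @return `read_timeseries_csv` returns a `ros_timeseries` data frame
#'   (non-dimensional space assumed).
#' @export
read_timeseries_csv <- function(path) {
  if (!file.exists(path)) stop("time-series file not found: ", path,
                               call. = FALSE)
  df <- utils::read.csv(path)
  cols <- c("t", "P", "O", "D", "S", "C", "F", "H")
  if (!identical(names(df), cols))
    stop("unexpected CSV header in '", path, "'; expected exactly ",
         paste(cols, collapse = ","), call. = FALSE)
  structure(df, space = "nondim", Ct = 1,
            class = c("ros_timeseries", "data.frame"))
}

#' Write a scenario result as JSON
#'
#' Serializes the result record: scenario name and note, rate
#' constants, Ct, dimensionless groups, characteristic scales, steady
#' flag and horizon, endpoint, matching family labels, and outcome.
#' The trajectory itself belongs in CSV ([write_timeseries_csv()]).
#'
#' @param result A `scenario_result` from [run_scenario()].
#' @param path Output path.
#' @export
write_result_json <- function(result, path) {
  stopifnot(inherits(result, "scenario_result"))
  cfg <- result$config
  out <- list(
    scenario = cfg$name,
    note = cfg$note,
    k = as.list(unclass(cfg$k)),
    Ct = cfg$Ct,
    groups = as.list(unclass(cfg$groups)),
    scales = as.list(unclass(characteristic_scales(cfg$k, cfg$Ct))),
    steady = list(reached = result$steady$reached,
                  t_end = result$steady$t_end,
                  max_rate = result$steady$max_rate),
    endpoint = as.list(unclass(result$endpoint)),
    families = as.character(result$families),
    outcome = result$outcome
  )
  ok <- tryCatch({
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("failed to write result to '", path, "': ",
         conditionMessage(ok), call. = FALSE)
  invisible(path)
}
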