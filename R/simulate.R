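#' Integrator settings
#'
#' Settings for the adaptive explicit Runge-Kutta 4(5) integration
#' (Dormand-Prince pair, deSolve's `"ode45"`).
#'
#' @param rtol,atol Relative and absolute error tolerances.
#' @param t_end Integration horizon in hatted time units.
#' @param max_doublings Number of times [run_to_steady()] may double
#'   `t_end` when the steady criterion is not met (default 3, i.e. up to
#'   `8 * t_end`).
#' @param steady_window Fraction of the trajectory (from the end) over
#'   which steadiness is judged.
#' @param steady_threshold Steadiness threshold on the largest absolute
#'   component of the right-hand side over the window.  The system
#'   relaxes with slow algebraic tails, so the default (1e-5) is chosen
#'   to detect the plateau rather than true asymptotic rest.
#' @param classify_tol Constraint tolerance used when classifying a
#'   computed endpoint against the steady-state families.
#' @param n_out Number of equally spaced output times.
#' @param times Optional explicit output grid overriding `t_end`/`n_out`.
#' @param hini Initial step size passed to the integrator.
#' @param maxsteps Maximum internal steps between output times.
#' @param method deSolve integration method; `"ode45"` by default, any
#'   deSolve method name (e.g. `"lsoda"`) as a stiff-capable fallback.
#' @return A list of class `"integrator_settings"`.
#' @export
integrator_settings <- function(rtol = 1e-8, atol = 1e-10, t_end = 100,
                                max_doublings = 3L, steady_window = 0.1,
                                steady_threshold = 1e-5,
                                classify_tol = 0.02,
                                n_out = 501L, times = NULL,
                                hini = 1e-4, maxsteps = 1e6,
                                method = "ode45") {
  stopifnot(rtol > 0, atol > 0, t_end > 0, steady_window > 0,
            steady_window <= 1, steady_threshold > 0, n_out >= 2L)
  structure(list(rtol = rtol, atol = atol, t_end = t_end,
                 max_doublings = as.integer(max_doublings),
                 steady_window = steady_window,
                 steady_threshold = steady_threshold,
                 classify_tol = classify_tol,
                 n_out = as.integer(n_out), times = times,
                 hini = hini, maxsteps = maxsteps, method = method),
            class = "integrator_settings")
}

# shared deSolve driver; y0 in canonical order, compiled RHS
.integrate_core <- function(y0, parms, initfunc, derivfunc, settings) {
  times <- settings$times
  if (is.null(times))
    times <- seq(0, settings$t_end, length.out = settings$n_out)
  out <- deSolve::ode(y = y0, times = times, func = derivfunc,
                      parms = parms, initfunc = initfunc,
                      dllname = "ceriakin", method = settings$method,
                      rtol = settings$rtol, atol = settings$atol,
                      hini = settings$hini, maxsteps = settings$maxsteps)
  m <- unclass(out)
  if (any(!is.finite(m)))
    stop("integration failed: non-finite state encountered; last good t = ",
         format(max(m[stats::complete.cases(m), 1])), call. = FALSE)
  m
}

# clip physical bounds; warn only on undershoot beyond 10*atol
.clip_states <- function(m, settings, lower_names, upper1 = "C") {
  clipped <- FALSE
  vals <- m[, lower_names, drop = FALSE]
  if (any(vals < 0)) {
    if (any(vals < -10 * settings$atol))
      warning("integration undershoot beyond 10*atol; states clipped to 0",
              call. = FALSE)
    m[, lower_names][vals < 0] <- 0
    clipped <- TRUE
  }
  if (!is.null(upper1) && any(m[, upper1] > 1)) {
    m[, upper1] <- pmin(m[, upper1], 1)
    clipped <- TRUE
  }
  list(m = m, clipped = clipped)
}

#' Integrate the non-dimensional system
#'
#' Integrates the hatted six-variable system with an adaptive
#' Dormand-Prince 4(5) pair (compiled right-hand side).  The hatted
#' ceric fraction `F = 1 - C` is reported alongside the integrated
#' variables, so ceria conservation holds exactly by construction.
#' Negative floating-point undershoot is clipped to zero for reporting
#' (flagged in the `"clipped"` attribute); undershoot beyond
#' `10 * atol` triggers a warning.
#'
#' @param initial A [nondim_state()] (or named numeric over
#'   P, O, D, S, C, H).
#' @param groups A [dimensionless_groups()] result.
#' @param settings An [integrator_settings()] list.
#' @return A `"ros_timeseries"` data frame with columns
#'   `t, P, O, D, S, C, F, H` and attributes `groups`, `settings`,
#'   `space = "nondim"`, `Ct = 1`, `clipped`.
#' @examples
#' ts <- integrate_nondim(nondim_state(1, 1, 1, 1, 0, 1),
#'                        c(a = 1, b = 1, g = 1),
#'                        integrator_settings(t_end = 10, n_out = 51))
#' tail(ts, 1)
#' @export
integrate_nondim <- function(initial, groups,
                             settings = integrator_settings()) {
  x0 <- .as_nondim_state(initial)
  groups <- .as_groups(groups)
  stopifnot(inherits(settings, "integrator_settings"))
  m <- .integrate_core(stats::setNames(as.numeric(x0), .species),
                       as.numeric(groups),
                       "ceriakin_nondim_init", "ceriakin_nondim_deriv",
                       settings)
  cl <- .clip_states(m, settings, .species)
  m <- cl$m
  ts <- data.frame(t = m[, 1], P = m[, "P"], O = m[, "O"], D = m[, "D"],
                   S = m[, "S"], C = m[, "C"], F = 1 - m[, "C"],
                   H = m[, "H"])
  structure(ts, groups = groups, settings = settings, space = "nondim",
            Ct = 1, clipped = cl$clipped,
            class = c("ros_timeseries", "data.frame"))
}

#' Integrate the dimensional system
#'
#' Same integrator applied to the dimensional mass-action equations.
#' The ceric concentration is reconstructed as `F = Ct - C`.
#'
#' @param initial A [dim_state()].
#' @param k A [rate_constants()] object.
#' @param settings An [integrator_settings()] list (`t_end` in seconds).
#' @return A `"ros_timeseries"` data frame (columns
#'   `t, P, O, D, S, C, F, H`, molarity) with attributes `k`, `Ct`,
#'   `scales`, `settings`, `space = "dimensional"`, `clipped`.
#' @export
integrate_dimensional <- function(initial, k,
                                  settings = integrator_settings()) {
  stopifnot(inherits(initial, "dim_state"))
  k <- .as_rate_constants(k)
  y0 <- stats::setNames(
    as.numeric(unlist(initial[c("P", "O", "D", "S", "C", "H")])), .species)
  m <- .integrate_core(y0, c(as.numeric(k), initial$Ct),
                       "ceriakin_dim_init", "ceriakin_dim_deriv", settings)
  cl <- .clip_states(m, settings, .species, upper1 = NULL)
  m <- cl$m
  C <- pmin(m[, "C"], initial$Ct)
  ts <- data.frame(t = m[, 1], P = m[, "P"], O = m[, "O"], D = m[, "D"],
                   S = m[, "S"], C = C, F = initial$Ct - C, H = m[, "H"])
  structure(ts, k = k, Ct = initial$Ct,
            scales = characteristic_scales(k, initial$Ct),
            settings = settings, space = "dimensional",
            clipped = cl$clipped,
            class = c("ros_timeseries", "data.frame"))
}

# right-hand-side magnitudes along a nondim trajectory
.rates_along <- function(ts, groups) {
  vapply(seq_len(nrow(ts)), function(i) {
    x <- c(P = ts$P[i], O = ts$O[i], D = ts$D[i], S = ts$S[i],
           C = ts$C[i], H = ts$H[i])
    max(abs(rhs_nondim(x, groups)))
  }, numeric(1))
}

#' Detect steadiness of a trajectory
#'
#' A non-dimensional trajectory is judged steady when the largest
#' absolute right-hand-side component, over the final `window` fraction
#' of the trajectory, stays below `threshold` for all six variables.
#'
#' @param ts A `ros_timeseries` from [integrate_nondim()].
#' @param window Final fraction of the trajectory to examine.
#' @param threshold Threshold on `max |dX/dt|`.
#' @param groups Dimensionless groups; default from the trajectory.
#' @return A list with `reached` (logical), `endpoint` (the final
#'   [nondim_state()]), and `max_rate` over the window.
#' @export
detect_steady <- function(ts, window = 0.1, threshold = 1e-5,
                          groups = attr(ts, "groups")) {
  stopifnot(inherits(ts, "ros_timeseries"), nrow(ts) >= 1L)
  groups <- .as_groups(groups)
  t1 <- ts$t[nrow(ts)]
  t0 <- t1 - window * (t1 - ts$t[1])
  idx <- which(ts$t >= t0)
  mx <- max(.rates_along(ts[idx, , drop = FALSE], groups))
  endpoint <- with(ts[nrow(ts), ],
                   nondim_state(P, O, D, S, min(C, 1), H))
  list(reached = mx < threshold, endpoint = endpoint, max_rate = mx)
}

#' Time at which a trajectory becomes steady
#'
#' Earliest sampled time from which the largest absolute
#' right-hand-side component stays below `threshold` through the end of
#' the trajectory.  Used to compare relaxation speeds between regimes.
#'
#' @inheritParams detect_steady
#' @return A time, or `NA` if the trajectory never settles below
#'   `threshold`.
#' @export
steady_time <- function(ts, threshold = 1e-5, groups = attr(ts, "groups")) {
  stopifnot(inherits(ts, "ros_timeseries"))
  rates <- .rates_along(ts, .as_groups(groups))
  ok <- rev(cumprod(rev(rates < threshold))) == 1
  if (!any(ok)) return(NA_real_)
  ts$t[which(ok)[1]]
}

#' Integrate until steady and classify the endpoint
#'
#' Composes [integrate_nondim()], [detect_steady()] and
#' [classify_endpoint()].  If the steady criterion is not met by
#' `t_end`, the horizon is doubled (up to `max_doublings` times) and the
#' run repeated; a run that still has not settled is flagged, with a
#' warning or error according to `on_unsteady`.
#'
#' @inheritParams integrate_nondim
#' @param on_unsteady One of `"warn"`, `"error"`, `"silent"`.
#' @return A list of class `"steady_run"` with `ts` (the trajectory at
#'   the final horizon), `steady` (the [detect_steady()] record plus the
#'   horizon used), and `families` (matching family labels of the
#'   endpoint at `classify_tol`).
#' @export
run_to_steady <- function(initial, groups,
                          settings = integrator_settings(),
                          on_unsteady = c("warn", "error", "silent")) {
  on_unsteady <- match.arg(on_unsteady)
  groups <- .as_groups(groups)
  s <- settings
  for (i in 0:s$max_doublings) {
    ts <- integrate_nondim(initial, groups, s)
    st <- detect_steady(ts, s$steady_window, s$steady_threshold, groups)
    if (st$reached) break
    if (i < s$max_doublings) {
      s <- integrator_settings(rtol = s$rtol, atol = s$atol,
                               t_end = 2 * s$t_end,
                               max_doublings = s$max_doublings,
                               steady_window = s$steady_window,
                               steady_threshold = s$steady_threshold,
                               classify_tol = s$classify_tol,
                               n_out = s$n_out, hini = s$hini,
                               maxsteps = s$maxsteps, method = s$method)
    }
  }
  if (!st$reached) {
    msg <- sprintf(paste0("steady state not reached by t = %g ",
                          "(max rate %.3g > threshold %.3g)"),
                   s$t_end, st$max_rate, s$steady_threshold)
    if (on_unsteady == "error") stop(msg, call. = FALSE)
    if (on_unsteady == "warn") warning(msg, call. = FALSE)
  }
  st$t_end <- s$t_end
  fams <- classify_endpoint(st$endpoint, tol = settings$classify_tol)
  structure(list(ts = ts, steady = st, families = fams),
            class = "steady_run")
}

#' @export
print.steady_run <- function(x, ...) {
  cat(sprintf("<steady_run> horizon t = %g, steady = %s (max rate %.3g)\n",
              x$steady$t_end, x$steady$reached, x$steady$max_rate))
  cat("endpoint:\n"); print(x$steady$endpoint)
  cat("families:",
      if (length(x$families)) paste(x$families, collapse = "  ")
      else "(none)", "\n")
  invisible(x)
}

#' @export
print.ros_timeseries <- function(x, ...) {
  cat(sprintf("<ros_timeseries> %d samples, t in [%g, %g], %s\n",
              nrow(x), x$t[1], x$t[nrow(x)], attr(x, "space")))
  print(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("...\n")
  invisible(x)
}
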