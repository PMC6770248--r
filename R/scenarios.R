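# Built-in regimes.  Baseline: all rate-constant ratios and Ct equal 1,
# and every species not otherwise constrained starts at hatted value 1.
# fig7/fig8 triple the hydronium along with the superoxide: those two
# regimes study ceria underdosing "with particular regard to the amount
# of H+ also present", with hydronium matching the superoxide load (the
# condition under which a large superoxide excess can still be
# eliminated, the two species decreasing at the same rate).
.builtin_table <- function() {
  base <- c(P = 1, O = 1, D = 1, S = 1, C = 0, H = 1)
  st <- function(...) { x <- base; x[names(c(...))] <- c(...); x }
  k1 <- rate_constants(1, 1, 1, 1)
  list(
    fig2 = list(k = k1, Ct = 1, initial = st(C = 1),
                note = paste("Only Ce3+ present (Ce2O3); all other species",
                             "and rate constants equal.  Superoxide rises",
                             "slightly, then returns to its original",
                             "level.")),
    fig3 = list(k = k1, Ct = 1, initial = st(),
                note = paste("Only Ce4+ present (CeO2); all other species",
                             "and rate constants equal.  Superoxide is",
                             "eliminated as the ceria converts to Ce3+.")),
    fig4 = list(k = rate_constants(5, 1, 1, 1), Ct = 1, initial = st(),
                note = paste("Superoxide generation k1 five times the",
                             "other rate constants; starting as CeO2.",
                             "A severe disease state: the system relaxes",
                             "much more slowly.")),
    fig5 = list(k = rate_constants(1, 1, 1, 5), Ct = 1, initial = st(),
                note = paste("Catalase constant k4 dominant (factor 5,",
                             "chosen for symmetry with the k1 regime);",
                             "fast recovery, superoxide not completely",
                             "eliminated.")),
    fig6 = list(k = k1, Ct = 1, initial = st(S = 1 / 3),
                note = paste("Ceria dose three times the superoxide",
                             "(hatted S0 = 1/3 against the ceria scale);",
                             "superoxide eliminated, mixed +3/+4 balance",
                             "remains.")),
    fig7 = list(k = k1, Ct = 1, initial = st(S = 3, C = 1, H = 3),
                note = paste("Superoxide three times the ceria, all ceria",
                             "+3, hydronium matching the superoxide.",
                             "Superoxide is not well controlled.")),
    fig8 = list(k = k1, Ct = 1, initial = st(S = 3, H = 3),
                note = paste("Superoxide three times the ceria, all ceria",
                             "+4, hydronium matching the superoxide.",
                             "Superoxide is eliminated; all ceria ends",
                             "as Ce3+.")),
    fig9 = list(k = k1, Ct = 1, initial = st(S = 3, H = 3),
                note = paste("Ce3+/Ce4+ ratio view of the superoxide-",
                             "overrun regimes: the all-Ce3+ case holds a",
                             "high ratio throughout, the all-Ce4+ case",
                             "(this configuration) diverges as C -> 1.")),
    fig10 = list(k = k1, Ct = 1, initial = st(D = 3),
                 note = paste("Hydroxide triple the other species, rate",
                              "constants equal.  Superoxide increases",
                              "from its initial amount: it nearly",
                              "doubles."))
  )
}

#' Scenario configuration
#'
#' A named initial-condition and parameter regime.  Rate constants and
#' `Ct` are stored and the dimensionless groups derived from them.
#'
#' @param name Scenario name.
#' @param k A [rate_constants()] object.
#' @param Ct Total ceria concentration (the non-dimensional reference).
#' @param initial Named hatted initial state over `P, O, D, S, C, H`
#'   (cerous fraction `C` in \[0, 1\]).
#' @param settings Optional [integrator_settings()] overrides.
#' @param note Free-text provenance note.
#' @return A list of class `"scenario_config"`.
#' @export
scenario_config <- function(name, k = rate_constants(), Ct = 1,
                            initial, settings = NULL, note = "") {
  initial <- .as_nondim_state(initial)
  if (!is.null(settings)) stopifnot(inherits(settings,
                                             "integrator_settings"))
  structure(list(name = name, k = .as_rate_constants(k), Ct = Ct,
                 initial = initial,
                 groups = dimensionless_groups(k, Ct),
                 settings = settings, note = note),
            class = "scenario_config")
}

#' Built-in scenario registry
#'
#' `builtin_scenario()` returns one of the nine built-in regimes
#' (`"fig2"` ... `"fig10"`); `list_scenarios()` lists them.
#'
#' @param name Scenario name, e.g. `"fig3"`.
#' @return A [scenario_config()]; or for `list_scenarios()` a character
#'   vector of names.
#' @examples
#' builtin_scenario("fig3")$initial
#' list_scenarios()
#' @export
builtin_scenario <- function(name) {
  tab <- .builtin_table()
  if (!name %in% names(tab))
    stop("unknown scenario '", name, "'; available: ",
         paste(names(tab), collapse = ", "), call. = FALSE)
  e <- tab[[name]]
  scenario_config(name, k = e$k, Ct = e$Ct, initial = e$initial,
                  note = e$note)
}

#' @rdname builtin_scenario
#' @export
list_scenarios <- function() names(.builtin_table())

#' Qualitative outcome of a superoxide trajectory
#'
#' Classifies the superoxide trace of a trajectory:
#' \describe{
#'   \item{eliminated}{final `S` below `tol`;}
#'   \item{returned_to_initial}{final `S` within `tol` of its initial
#'     value after a transient excursion larger than `tol`;}
#'   \item{amplified}{final `S` above initial by more than `tol`;}
#'   \item{persistent}{anything else.}
#' }
#'
#' @param ts A `ros_timeseries`.
#' @param tol Classification tolerance on the hatted superoxide
#'   (default 0.01, i.e. 1 percent of the ceria scale).
#' @param require_steady If TRUE, refuse (return `NA` with a warning)
#'   unless the trajectory satisfies [detect_steady()] at its recorded
#'   settings.
#' @return A single string, one of the four labels above.
#' @export
superoxide_outcome <- function(ts, tol = 0.01, require_steady = FALSE) {
  stopifnot(inherits(ts, "ros_timeseries"), nrow(ts) >= 1L)
  if (require_steady) {
    s <- attr(ts, "settings")
    st <- detect_steady(ts, s$steady_window, s$steady_threshold)
    if (!st$reached) {
      warning("trajectory not steady; outcome not classified",
              call. = FALSE)
      return(NA_character_)
    }
  }
  s0 <- ts$S[1]
  s1 <- ts$S[nrow(ts)]
  excursion <- max(abs(ts$S - s0))
  if (s1 < tol) "eliminated"
  else if (abs(s1 - s0) < tol && excursion > tol) "returned_to_initial"
  else if (s1 > s0 + tol) "amplified"
  else "persistent"
}

#' Cerous/ceric ratio trace of a trajectory
#'
#' Pointwise `C / (1 - C)` along a non-dimensional trajectory.  Where
#' the ceric fraction `1 - C` falls below `1e-12` (the all-cerous
#' endpoint, at which the ratio diverges) the value is capped at the
#' sentinel `cap`.
#'
#' @param ts A `ros_timeseries`.
#' @param cap Sentinel value substituted where the ratio diverges.
#' @return A data frame with columns `t` and `ratio`, plus attribute
#'   `"capped"` (logical vector marking sentinel entries).
#' @export
ratio_trace <- function(ts, cap = 1e12) {
  stopifnot(inherits(ts, "ros_timeseries"))
  f <- 1 - ts$C
  capped <- f < 1e-12
  ratio <- ifelse(capped, cap, ts$C / ifelse(capped, 1, f))
  structure(data.frame(t = ts$t, ratio = ratio), capped = capped)
}

#' Run a scenario end to end
#'
#' Integrates a scenario to (near) steady state, classifies the
#' endpoint against the steady-state families, classifies the
#' superoxide outcome, and computes the cerous/ceric ratio trace.
#'
#' @param scenario A [scenario_config()] or a built-in scenario name.
#' @param settings [integrator_settings()]; a scenario's own settings
#'   override this default.
#' @param outcome_tol Tolerance for [superoxide_outcome()].
#' @param on_unsteady Passed to [run_to_steady()].
#' @return A list of class `"scenario_result"` with `config`, `ts`,
#'   `steady`, `families`, `outcome`, `ratio` and `endpoint`.
#' @examples
#' \donttest{
#' res <- run_scenario("fig3")
#' res$outcome
#' }
#' @export
run_scenario <- function(scenario, settings = integrator_settings(),
                         outcome_tol = 0.01, on_unsteady = "silent") {
  if (is.character(scenario)) scenario <- builtin_scenario(scenario)
  stopifnot(inherits(scenario, "scenario_config"))
  if (!is.null(scenario$settings)) settings <- scenario$settings
  run <- run_to_steady(scenario$initial, scenario$groups, settings,
                       on_unsteady = on_unsteady)
  structure(list(config = scenario, ts = run$ts, steady = run$steady,
                 families = run$families,
                 outcome = superoxide_outcome(run$ts, tol = outcome_tol),
                 ratio = ratio_trace(run$ts),
                 endpoint = run$steady$endpoint),
            class = "scenario_result")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario_config '%s'> Ct = %g\n", x$name, x$Ct))
  cat("  k:      ", paste(sprintf("%s=%g", names(x$k), x$k),
                          collapse = " "), "\n")
  cat("  groups: ", paste(sprintf("%s=%g", names(x$groups), x$groups),
                          collapse = " "), "\n")
  cat("  initial:", paste(sprintf("%s=%g", names(x$initial), x$initial),
                          collapse = " "), "\n")
  if (nzchar(x$note)) cat("  note:   ", x$note, "\n")
  invisible(x)
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result '%s'> outcome: %s\n",
              x$config$name, x$outcome))
  cat(sprintf("  steady %s by t = %g (max rate %.3g)\n",
              if (x$steady$reached) "reached" else "NOT reached",
              x$steady$t_end, x$steady$max_rate))
  cat("  endpoint:",
      paste(sprintf("%s=%.4g", names(x$endpoint), x$endpoint),
            collapse = " "), "\n")
  cat("  families:",
      if (length(x$families)) paste(x$families, collapse = "  ")
      else "(none)", "\n")
  invisible(x)
}
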