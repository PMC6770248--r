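# shared helpers for the test suite

# random nonnegative dimensional state with C <= Ct
random_dim_state <- function() {
  Ct <- runif(1, 0.2, 3)
  dim_state(P = runif(1, 0, 2), O = runif(1, 0, 2), D = runif(1, 0, 2),
            S = runif(1, 0, 2), C = runif(1, 0, Ct), H = runif(1, 0, 2),
            Ct = Ct)
}

random_rate_constants <- function() {
  rate_constants(runif(1, 0.1, 5), runif(1, 0.1, 5),
                 runif(1, 0.1, 5), runif(1, 0.1, 5))
}

# hand-rolled synthetic trajectory (for detect_steady / outcome tests)
make_ts <- function(df, groups = c(a = 1, b = 1, g = 1)) {
  if (!"F" %in% names(df)) df$F <- 1 - df$C
  df <- df[, c("t", "P", "O", "D", "S", "C", "F", "H")]
  structure(df, groups = structure(groups, class = "dimensionless_groups"),
            settings = integrator_settings(), space = "nondim", Ct = 1,
            class = c("ros_timeseries", "data.frame"))
}

# cache scenario runs within a test file
scenario_cache <- local({
  env <- new.env(parent = emptyenv())
  function(name, ...) {
    if (is.null(env[[name]])) env[[name]] <- run_scenario(name, ...)
    env[[name]]
  }
})
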