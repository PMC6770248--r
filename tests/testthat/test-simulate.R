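unit_groups <- c(a = 1, b = 1, g = 1)

test_that("the zero state is absorbing", {
  ts <- integrate_nondim(nondim_state(0, 0, 0, 0, 0, 0), unit_groups,
                         integrator_settings(t_end = 10, n_out = 21))
  expect_equal(max(abs(as.matrix(ts[, c("P", "O", "D", "S", "C", "H")]))), 0)

  run <- run_to_steady(nondim_state(0, 0, 0, 0, 0, 0), unit_groups)
  expect_true(run$steady$reached)
})

test_that("compiled and R right-hand sides drive identical dynamics", {
  r_rhs <- function(t, y, p) list(unname(rhs_nondim(y, p)))
  y0 <- c(P = 1, O = 1, D = 1, S = 1, C = 0.5, H = 1)
  times <- seq(0, 5, length.out = 51)
  ref <- deSolve::ode(y = y0, times = times, func = r_rhs,
                      parms = structure(c(a = 1.2, b = 0.7, g = 2),
                                        class = "dimensionless_groups"),
                      method = "ode45", rtol = 1e-10, atol = 1e-12)
  ts <- integrate_nondim(y0, c(a = 1.2, b = 0.7, g = 2),
                         integrator_settings(t_end = 5, n_out = 51,
                                             rtol = 1e-10, atol = 1e-12))
  expect_equal(as.matrix(ts[, c("P", "O", "D", "S", "C", "H")]),
               unname(ref[, 2:7]), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("dimensional and non-dimensional integrations are equivalent", {
  set.seed(31)
  for (i in 1:3) {
    k <- random_rate_constants()
    Ct <- runif(1, 0.5, 2)
    sc <- characteristic_scales(k, Ct)
    g <- dimensionless_groups(k, Ct)
    x0 <- dim_state(P = runif(1, 0.1, 1), O = runif(1, 0.1, 1),
                    D = runif(1, 0.1, 1), S = runif(1, 0.1, 1),
                    C = runif(1, 0, Ct), H = runif(1, 0.1, 1), Ct = Ct)
    t_hat_end <- 5
    nd <- integrate_nondim(to_nondim(x0, sc), g,
                           integrator_settings(t_end = t_hat_end,
                                               n_out = 21))
    dm <- integrate_dimensional(x0, k,
                                integrator_settings(
                                  t_end = t_hat_end * sc[["tc"]],
                                  n_out = 21,
                                  hini = 1e-4 * sc[["tc"]]))
    for (sp in c("P", "O", "D", "S", "C", "H"))
      expect_equal(dm[[sp]] / sc[[paste0(sp, "c")]], nd[[sp]],
                   tolerance = 1e-6)
  }
})

test_that("ceria conservation holds exactly and D, H never increase", {
  for (nm in c("fig2", "fig3", "fig5", "fig10")) {
    ts <- scenario_cache(nm)$ts
    expect_equal(ceria_conservation_defect(ts), 0)
    expect_true(all(diff(ts$D) <= 1e-9))
    expect_true(all(diff(ts$H) <= 1e-9))
    expect_true(all(ts$C >= 0 & ts$C <= 1))
  }
})

test_that("steadiness detection distinguishes settled from moving", {
  const <- make_ts(data.frame(t = 0:10, P = 0.5, O = 1, D = 0, S = 0,
                              C = 0.3, H = 0))
  st <- detect_steady(const, window = 0.5, threshold = 1e-6)
  expect_true(st$reached)
  expect_equal(st$max_rate, 0)

  # linear growth in superoxide: RHS is nonzero throughout
  grow <- make_ts(data.frame(t = 0:10, P = 1, O = 1, D = 1,
                             S = seq(1, 2, length.out = 11), C = 0.5,
                             H = 1))
  expect_false(detect_steady(grow, window = 0.5, threshold = 1e-6)$reached)

  run <- scenario_cache("fig3")
  expect_true(run$steady$reached)
  expect_lt(run$steady$max_rate, 1e-5)
})

test_that("steady_time finds the earliest settled sample", {
  s <- make_ts(data.frame(t = 0:10, P = 1, O = 1,
                          D = c(1, 0.5, 0.2, rep(0, 8)),
                          S = 0, C = 1, H = 0))
  # rates vanish once D = 0 (S = 0 kills the other monomials)
  expect_equal(steady_time(s, threshold = 1e-9), 3)
  expect_true(is.na(steady_time(make_ts(
    data.frame(t = 0:10, P = 1, O = 1, D = 1, S = 1, C = 0.5, H = 1)),
    threshold = 1e-9)))
})

test_that("halving the tolerances leaves scenario endpoints unchanged", {
  for (nm in c("fig3", "fig5", "fig10")) {
    cfg <- builtin_scenario(nm)
    base <- integrate_nondim(cfg$initial, cfg$groups,
                             integrator_settings(t_end = 100))
    fine <- integrate_nondim(cfg$initial, cfg$groups,
                             integrator_settings(t_end = 100,
                                                 rtol = 5e-9,
                                                 atol = 5e-11))
    e1 <- unlist(base[nrow(base), -1])
    e2 <- unlist(fine[nrow(fine), -1])
    expect_lt(max(abs(e1 - e2)), 1e-4)
  }
})

test_that("every scenario endpoint lies in at least one steady family", {
  for (nm in setdiff(list_scenarios(), "fig9")) {
    run <- scenario_cache(nm)
    expect_gte(length(run$families), 1)
  }
})
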