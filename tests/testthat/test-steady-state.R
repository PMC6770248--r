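family_tuples <- c(
  # superoxide possibly nonzero: all-cerous, hydronium exhausted
  "(P*,O*,0,S*,1,0)", "(0,O*,D*,S*,1,0)", "(P*,0,D*,S*,1,0)",
  # ideal: superoxide identically zero
  "(P*,0,D*,0,0,H*)", "(P*,O*,0,0,0,H*)", "(P*,0,D*,0,C*,0)",
  "(P*,O*,0,0,C*,0)", "(0,O*,D*,0,C*,H*)")

test_that("case analysis yields exactly the eight families", {
  set.seed(21)
  fams <- enumerate_families(c(a = 1, b = 1, g = 1))
  expect_length(fams, 8)
  labels <- vapply(fams, `[[`, character(1), "label")
  expect_setequal(labels, family_tuples)

  nonideal <- Filter(function(f) !f$ideal, fams)
  expect_length(nonideal, 3)
  for (f in nonideal) {
    expect_true("S" %in% f$free)          # superoxide unconstrained
    expect_equal(f$fixed, c(C = 1))       # all ceria cerous
    expect_true("H" %in% f$zero)          # hydronium exhausted
  }
  ideal <- Filter(function(f) f$ideal, fams)
  expect_length(ideal, 5)
  for (f in ideal) expect_true("S" %in% f$zero)
})

test_that("every family zeroes the RHS for random free-variable values", {
  set.seed(22)
  groups <- c(a = 1, b = 1, g = 1)
  for (f in enumerate_families(groups, verify = 0L)) {
    for (i in 1:200) {
      x <- family_member(f, runif_free = TRUE)
      expect_identical(unname(rhs_nondim(x, groups)), rep(0, 6))
    }
  }
})

test_that("the family list is invariant to the group values", {
  set.seed(23)
  for (i in 1:5) {
    g <- runif(3, 0.05, 20)
    labels <- vapply(enumerate_families(g, verify = 10L), `[[`,
                     character(1), "label")
    expect_setequal(labels, family_tuples)
  }
})

test_that("endpoint classification matches constraint satisfaction", {
  # D = S = H = 0, others free: exactly the (P*,O*,0,0,C*,0) family
  hits <- classify_endpoint(nondim_state(0.4, 1.2, 0, 0, 0.3, 0))
  expect_equal(as.character(hits), "(P*,O*,0,0,C*,0)")

  # the origin satisfies every ideal family's constraints (C = 0 fails
  # the non-ideal C = 1 requirement)
  hits <- classify_endpoint(nondim_state(0, 0, 0, 0, 0, 0))
  expect_length(hits, 5)
  expect_true(all(grepl(",0,", vapply(attr(hits, "families"), `[[`,
                                      character(1), "label"))))

  # a state in the interior of phase space is steady for no family
  expect_length(classify_endpoint(nondim_state(1, 1, 1, 1, 0.5, 1)), 0)
})

test_that("classification agrees with the RHS on a dense grid", {
  fams <- enumerate_families(verify = 0L)
  groups <- c(a = 1, b = 1, g = 1)
  grid <- seq(0, 1, by = 0.25)
  pts <- as.matrix(expand.grid(P = grid, O = grid, D = grid,
                               S = grid, C = grid, H = grid))
  missed <- 0L     # steady grid points the classifier fails to match
  spurious <- 0L   # clearly non-steady points it matches anyway
  for (i in seq_len(nrow(pts))) {
    x <- pts[i, ]
    nrm <- max(abs(rhs_nondim(x, groups)))
    n_hit <- length(classify_endpoint(x, tol = 1e-6, families = fams))
    if (nrm < 1e-12 && n_hit == 0L) missed <- missed + 1L
    if (nrm > 1e-3 && n_hit > 0L) spurious <- spurious + 1L
  }
  expect_identical(missed, 0L)
  expect_identical(spurious, 0L)
})

test_that("steady-state ratio and its limiting cases agree", {
  k <- rate_constants()
  expect_equal(steady_state_ratio(S = 1, P = 0, H = 1, k), 1)
  expect_equal(steady_state_ratio(S = 0, P = 1, H = 1, k), 0)

  # disease-state limit: ratio -> k2/(k3 H)
  k2 <- rate_constants(1, 2, 1, 1)
  expect_equal(ratio_case1(k2, H = 0.5), 4)
  expect_equal(steady_state_ratio(S = 1, P = 0, H = 0.5, k2), 4)
  expect_equal(steady_state_ratio(S = 1, P = 1e-12, H = 0.5, k2),
               ratio_case1(k2, H = 0.5), tolerance = 1e-10)

  # healthy-state limit: ratio -> k2 S / (k4 H P)
  set.seed(24)
  for (i in 1:20) {
    k <- random_rate_constants()
    P <- runif(1, 0.5, 2); H <- runif(1, 0.5, 2); S <- 1e-8 * P
    expect_equal(steady_state_ratio(S, P, H, k), ratio_case2(k, S, P, H),
                 tolerance = 1e-6)
  }

  expect_error(steady_state_ratio(S = 0, P = 0, H = 1, rate_constants()), "zero")
  expect_error(ratio_case1(rate_constants(), H = 0), "zero")
  expect_error(ratio_case2(rate_constants(), S = 1, P = 0, H = 1), "zero")
})

test_that("the ratio increases with k2 and decreases with H", {
  set.seed(25)
  for (i in 1:20) {
    S <- runif(1, 0.1, 2); P <- runif(1, 0.1, 2); H <- runif(1, 0.1, 2)
    k_lo <- rate_constants(1, 1, 1, 1)
    k_hi <- rate_constants(1, 1 + runif(1, 0.1, 3), 1, 1)
    expect_gt(steady_state_ratio(S, P, H, k_hi), steady_state_ratio(S, P, H, k_lo))
    expect_lt(steady_state_ratio(S, P, H + runif(1, 0.1, 2), k_lo),
              steady_state_ratio(S, P, H, k_lo))
  }
})

test_that("the mass-action ceria balance holds exactly where constructed", {
  k <- rate_constants(2, 3, 1, 1)
  # choose F so that k2 F S = k3 C S H^2 + 2 k4 P C^2 H^2
  C <- 0.5; S <- 1; H <- 1; P <- 0.25
  F <- (1 * C * S * H^2 + 2 * 1 * P * C^2 * H^2) / (3 * S)
  st <- dim_state(P = P, O = 1, D = 1, S = S, C = C, H = H,
                  Ct = C + F, F = F)
  bal <- mass_action_ceria_balance(st, k)
  expect_true(bal$balanced)
  expect_equal(bal$residual, 0, tolerance = 1e-14)

  # and fails away from balance
  st2 <- dim_state(P = 1, O = 1, D = 1, S = 1, C = 0.9, H = 1, Ct = 1)
  expect_false(mass_action_ceria_balance(st2, k)$balanced)
})
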