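test_that("mass-action rate laws evaluate correctly", {
  k <- rate_constants(1, 1, 1, 1)

  zero <- dim_state(0, 0, 0, 0, 0, 0, Ct = 0)
  expect_equal(unname(reaction_rates(zero, k)), c(0, 0, 0, 0))

  unit <- dim_state(1, 1, 1, 1, 1, 1, Ct = 2)  # F = 1
  expect_equal(unname(reaction_rates(unit, k)), c(1, 1, 1, 1))

  # r1 = 1*2*1*9 = 18, r4 = 1*2*1*1 = 2, superoxide absent kills r2, r3
  s <- dim_state(P = 2, O = 1, D = 3, S = 0, C = 1, H = 1, Ct = 1)
  expect_equal(unname(reaction_rates(s, k)), c(18, 0, 0, 2))
})

test_that("invalid states are rejected naming the offending species", {
  expect_error(dim_state(P = -1, O = 1, D = 1, S = 1, C = 0, H = 1, Ct = 1),
               "P")
  expect_error(dim_state(P = 1, O = 1, D = 1, S = -2, C = 0, H = 1, Ct = 1),
               "S")
  expect_error(dim_state(1, 1, 1, 1, C = 2, H = 1, Ct = 1), "exceeds")
  expect_error(dim_state(1, 1, 1, 1, C = 0.2, H = 1, Ct = 1, F = 0.4),
               "conservation")
})

test_that("dimensional RHS matches the hand-computed system", {
  k <- rate_constants()

  zero <- dim_state(0, 0, 0, 0, 0, 0, Ct = 0)
  expect_equal(unname(rhs_dimensional(zero, k)), rep(0, 6))

  # r = (1,1,1,1); derivatives assembled by hand from the stoichiometry
  s <- dim_state(1, 1, 1, 1, 1, 1, Ct = 2)
  expect_equal(rhs_dimensional(s, k),
               c(P = -1, O = 0, D = -2, S = 0, C = -2, H = -4))

  # P = 0 and S = 0 silences every reaction (an ideal steady family)
  s0 <- dim_state(P = 0, O = 2, D = 1.5, S = 0, C = 0.3, H = 0.7, Ct = 1)
  expect_equal(unname(rhs_dimensional(s0, k)), rep(0, 6))
})

test_that("RHS equals the stoichiometry-matrix product N %*% r", {
  net <- stoich_network()
  set.seed(41)
  for (i in 1:200) {
    s <- random_dim_state()
    k <- random_rate_constants()
    r <- reaction_rates(s, k)
    expect_true(all(r >= 0))
    expect_identical(unname(rhs_dimensional(s, k)),
                     unname(drop(net$N %*% r)))
  }
})

test_that("hydroxide and hydronium are only consumed", {
  set.seed(42)
  for (i in 1:100) {
    d <- rhs_dimensional(random_dim_state(), random_rate_constants())
    expect_lte(d[["D"]], 0)
    expect_lte(d[["H"]], 0)
  }
})

test_that("the stoichiometric network conserves lattice ceria and balances", {
  net <- stoich_network()
  Nf <- net$N_full
  # every reaction: cerous change mirrors ceric change
  expect_equal(unname(Nf["C", ]), unname(-Nf["F", ]))
  # mass balance: elemental H, O, Ce and charge conserved per reaction
  composition <- rbind(
    Hyd = c(P = 2, O = 0, D = 1, S = 0, C = 0, F = 0, H = 1, W = 2),
    Oxy = c(P = 2, O = 2, D = 1, S = 2, C = 0, F = 0, H = 0, W = 1),
    Ce  = c(P = 0, O = 0, D = 0, S = 0, C = 1, F = 1, H = 0, W = 0),
    Chg = c(P = 0, O = 0, D = -1, S = -1, C = 3, F = 4, H = 1, W = 0))
  expect_equal(unname(composition %*% Nf),
               matrix(0, 4, 4), tolerance = 0)
})

test_that("the reaction cycle reduces to the net reaction with ceria cancelling", {
  nr <- net_reaction()
  # reaction (1) consumes hydroxide, which the net reaction lacks, so its
  # multiplicity is forced to zero; 2 x (2) + 1 x (4) is the unique cover
  expect_equal(nr$multiplicities, c(r1 = 0, r2 = 2, r3 = 0, r4 = 1))
  expect_equal(nr$net[["C"]], 0)
  expect_equal(nr$net[["F"]], 0)
  # independent check: apply the multiplicities to the stoichiometry matrix
  achieved <- drop(stoich_network()$N_full %*% c(0, 2, 0, 1))
  expect_equal(achieved,
               c(P = -1, O = 2, D = 0, S = -2, C = 0, F = 0, H = -2, W = 2))
})

test_that("ceria conservation defect is zero for algebraic F", {
  one <- make_ts(data.frame(t = 0, P = 1, O = 1, D = 1, S = 1,
                            C = 0.3, F = 0.7, H = 1))
  expect_equal(ceria_conservation_defect(one, Ct = 1), 0)

  const <- make_ts(data.frame(t = 0:10, P = 1, O = 1, D = 1, S = 1,
                              C = 0.4, H = 1))
  expect_equal(ceria_conservation_defect(const), 0)

  set.seed(7)
  for (i in 1:5) {
    s0 <- random_dim_state()
    k <- random_rate_constants()
    ts <- integrate_dimensional(s0, k,
                                integrator_settings(t_end = 5, n_out = 51))
    expect_lte(ceria_conservation_defect(ts, Ct = s0$Ct), 1e-8)
  }
})

test_that("the plain-text reaction listing round-trips", {
  net <- stoich_network()
  lines <- format_reactions(net)
  expect_length(lines, 4)
  expect_match(lines[1], "H2O2 \\+ O2 \\+ 2 OH- -> 2 O2- \\+ 2 H2O ; k1")
  back <- parse_reactions(lines)
  for (j in 1:4) {
    expect_equal(back[[j]]$orders, net$reactions[[j]]$orders)
    expect_equal(back[[j]]$net, net$reactions[[j]]$net)
    expect_equal(back[[j]]$rate_constant, net$reactions[[j]]$rate_constant)
  }
  expect_error(parse_reactions("H2O2 -> H2O"), "rate-constant tag")
  expect_error(parse_reactions("XYZ -> H2O ; k1"), "XYZ")
})
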