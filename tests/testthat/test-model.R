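test_that("effective Tyr15 rates follow the linear converter formulas", {
  p <- default_parameters()
  r <- effective_rates(g2_state(), p)           # Cdc25 = 0, Wee1 = 1
  expect_equal(unname(r), c(0.01, 1))
  s <- model_state(MPF = 0.5, Cdc25 = 1, Wee1 = 0, Gwl = 0,
                   ENSAPt = 0.4, PP2 = 0.2)
  r <- effective_rates(s, p)                    # fully shifted converters
  expect_equal(unname(r), c(1, 0.01))
  # both catalytic constants equal -> rate collapses to c * total
  pc <- default_parameters(k25_p = 0.3, k25_pp = 0.3)
  for (x in c(0, 0.37, 1)) {
    s <- model_state(MPF = 0, Cdc25 = x, Wee1 = 1, Gwl = 0,
                     ENSAPt = 0, PP2 = 0.5)
    expect_equal(effective_rates(s, pc)[["k25"]], 0.3)
  }
})

test_that("right-hand side reproduces hand-evaluated cases", {
  p <- default_parameters()
  # G2 state: only the basal Cdc25 route moves, everything else balances
  expect_equal(unname(model_rhs(g2_state(), p)),
               c(0.01, 0, 0, 0, 0, 0))
  # empty network, no free PP2A: pure complex release (kdis+kiensa)*PP2T
  s0 <- model_state(MPF = 0, Cdc25 = 0, Wee1 = 0, Gwl = 0,
                    ENSAPt = 0, PP2 = 0)
  expect_equal(model_rhs(s0, p, check = FALSE)[["PP2"]], 0.8)
  # no free phospho-ENSA (ENSAPt equals the bound complex):
  # the association term vanishes, leaving only complex release
  s1 <- model_state(MPF = 0.3, Cdc25 = 0.2, Wee1 = 0.5, Gwl = 0.1,
                    ENSAPt = 0.3, PP2 = 0.2)
  expect_equal(model_rhs(s1, p)[["PP2"]],
               (p[["kdis"]] + p[["kiensa"]]) * (p[["PP2T"]] - 0.2))
  expect_error(model_rhs(model_state(MPF = NaN, Cdc25 = 0, Wee1 = 1,
                                     Gwl = 0, ENSAPt = 0, PP2 = 0.5), p),
               "non-finite")
})

test_that("observables apply the dose corrections and pool complements", {
  p <- default_parameters(RO = 100)
  s <- model_state(MPF = 0.96, Cdc25 = 0.97, Wee1 = 0.03, Gwl = 0.9,
                   ENSAPt = 0.75, PP2 = 0.027)
  ob <- model_observables(s, p)
  expect_equal(ob[["MPFa"]], 0.96 / 101)
  expect_equal(ob[["preMPF"]], 0.04)
  expect_equal(ob[["complex"]], 0.5 - 0.027)
  expect_equal(model_observables(s, default_parameters())[["PP2a"]], 0.027)
})

test_that("rhs matches an independent second transcription at random states", {
  for (sc in c("pp2a_b55", "oa_insensitive", "oa_sensitive")) {
    p <- scenario_parameters(sc, RO = 2, OA = 5)
    states <- random_valid_states(100, p, seed = 42)
    pv <- setNames(as.numeric(p[names(default_parameters())]),
                   names(default_parameters()))
    for (i in seq_len(nrow(states))) {
      s <- model_state(setNames(states[i, ],
                                c("MPF", "Cdc25", "Wee1", "Gwl",
                                  "ENSAPt", "PP2")))
      expect_equal(unname(model_rhs(s, p)),
                   unname(oracle_rhs(states[i, ], pv)),
                   tolerance = 1e-12)
    }
  }
})

test_that("analytic Jacobian agrees with central finite differences", {
  p <- scenario_parameters("oa_sensitive", RO = 3, OA = 10)
  states <- random_valid_states(20, p, seed = 7)
  for (i in seq_len(nrow(states))) {
    s <- model_state(setNames(states[i, ],
                              c("MPF", "Cdc25", "Wee1", "Gwl",
                                "ENSAPt", "PP2")))
    J <- model_jacobian(s, p)
    Jfd <- mitoswitch:::fd_jacobian(s, p)
    expect_lt(max(abs(J - Jfd)), 1e-6)
  }
})

test_that("active fractions fall strictly with inhibitor dose", {
  s <- metaphase_state()
  pp2a_vals <- sapply(c(0, 1, 10, 100, 1000), function(oa)
    model_observables(s, default_parameters(OA = oa))[["PP2a"]])
  expect_true(all(diff(pp2a_vals) < 0))
  mpfa_vals <- sapply(c(0, 1, 25, 100, 1000), function(ro)
    model_observables(s, default_parameters(RO = ro))[["MPFa"]])
  expect_true(all(diff(mpfa_vals) < 0))
})

test_that("state validation rejects or clamps out-of-box states", {
  p <- default_parameters()
  bad <- model_state(MPF = 1.2, Cdc25 = 0, Wee1 = 1, Gwl = 0,
                     ENSAPt = 0, PP2 = 0.5)
  expect_error(validate_state(bad, p), "outside box")
  expect_warning(cl <- validate_state(bad, p, action = "clamp"),
                 "clamping")
  expect_equal(cl[["MPF"]], 1)
  # complex bookkeeping: total phospho-ENSA cannot be below the bound pool
  bad2 <- model_state(MPF = 0, Cdc25 = 0, Wee1 = 1, Gwl = 0,
                      ENSAPt = 0, PP2 = 0.1)
  expect_error(validate_state(bad2, p), "complex")
})
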