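state_names <- c("MPF", "Cdc25", "Wee1", "Gwl", "ENSAPt", "PP2")

test_that("CycT = 0 has the unique closed-form resting state", {
  # with no Cyclin B every activation term vanishes: MPF = Cdc25 = Gwl =
  # ENSAPt = 0, Wee1 = Wee1T, and the PP2 balance factors as
  # (PP2T - PP2)(kas PP2 + kdis + kiensa) = 0, so PP2 = PP2T
  p <- default_parameters(CycT = 0)
  eqs <- find_equilibria(p)
  expect_length(eqs, 1)
  expect_equal(as.numeric(eqs[[1]]$state), c(0, 0, 1, 0, 0, 0.5),
               tolerance = 1e-8)
  expect_true(eqs[[1]]$stable)
})

test_that("Newton refinement converges, classifies and rejects properly", {
  eq <- find_steady_state(scenario_parameters("oa_sensitive"),
                          metaphase_state())
  expect_lt(eq$residual, 1e-10)
  expect_true(eq$stable)
  expect_lt(eq$leading_eigenvalue, -1e-9)
  expect_lt(max(abs(model_rhs(eq$state,
                              scenario_parameters("oa_sensitive")))),
            1e-10)
  expect_error(
    find_steady_state(default_parameters(),
                      model_state(MPF = 2, Cdc25 = 0, Wee1 = 1, Gwl = 0,
                                  ENSAPt = 0, PP2 = 0.5)),
    "outside box")
})

test_that("the bistable window holds two stable states and a saddle", {
  p <- default_parameters(CycT = 0.12)   # inside the default window
  eqs <- find_equilibria(p)
  expect_length(eqs, 3)
  stab <- vapply(eqs, `[[`, TRUE, "stable")
  expect_equal(sum(stab), 2)
  # integration consistency: stable states attract; the saddle, nudged
  # along its unstable eigenvector, departs
  for (eq in eqs) {
    if (eq$stable) {
      traj <- integrate_model(p, eq$state, horizon = 100,
                              output_step = 100)
      drift <- max(abs(traj$states[nrow(traj$states), ] -
                         as.numeric(eq$state)))
      expect_lt(drift, 1e-6)
    } else {
      J <- model_jacobian(eq$state, p)
      ev <- eigen(J)
      v <- Re(ev$vectors[, which.max(Re(ev$values))])
      s0 <- model_state(setNames(
        pmin(pmax(as.numeric(eq$state) + 1e-4 * v, 0), 1),
        names(eq$state)))
      traj <- integrate_model(p, s0, horizon = 100, output_step = 100)
      drift <- max(abs(traj$states[nrow(traj$states), ] -
                         as.numeric(eq$state)))
      expect_gt(drift, 1e-2)
    }
  }
  # both basins: long integrations from the G2 side and from a mitotic-
  # like state land on the two stable equilibria found by Newton
  mitotic_side <- model_state(MPF = 0.12, Cdc25 = 0.97, Wee1 = 0.03,
                              Gwl = 0.9, ENSAPt = 0.75, PP2 = 0.027)
  ends <- lapply(list(g2_state(), mitotic_side), function(s0) {
    traj <- integrate_model(p, s0, horizon = 400, output_step = 400)
    traj$states[nrow(traj$states), ]
  })
  stable_states <- lapply(eqs[stab], function(e) as.numeric(e$state))
  for (e in ends) {
    d <- vapply(stable_states, function(s) max(abs(e - s)), 0)
    expect_lt(min(d), 1e-6)
  }
  expect_gt(max(abs(ends[[1]] - ends[[2]])), 0.1)  # genuinely distinct
})

test_that("balance curve of the default model has two paired folds", {
  br <- balance_curve("pp2a_b55", n = 51)
  folds <- attr(br, "folds")
  expect_length(folds, 2)
  w <- bistable_window(br)
  # counts: 3 equilibria strictly inside the window, 1 outside
  counts <- table(br$control)
  inside <- as.numeric(names(counts)) > w[1] & as.numeric(names(counts)) < w[2]
  expect_true(all(counts[inside] == 3))
  expect_true(all(counts[!inside] == 1))
  # within the window: exactly two stable, one unstable
  for (ct in unique(br$control)[inside]) {
    stab <- br$stable[br$control == ct]
    expect_equal(sum(stab), 2)
    expect_equal(sum(!stab), 1)
  }
})

test_that("PP2A/B55 feedback widens the bistable Cyclin B window", {
  w_pp <- bistable_window(balance_curve("pp2a_b55", n = 51))
  w_ins <- bistable_window(balance_curve("oa_insensitive", n = 51))
  expect_false(is.null(w_pp))
  expect_false(is.null(w_ins))
  expect_gte(diff(w_pp), diff(w_ins))
})

test_that("bistability map classifies reference parameter points", {
  rg <- bistability_region("pp2a_b55", "kagwl", "kiensa",
                           c(5, 10), c(0.6, 1.0))
  expect_true(all(rg$bistable))
  expect_equal(nrow(rg), 4)
  expect_error(bistability_region("pp2a_b55", "kagwl", "bogus", 1, 1),
               "unknown parameter")
  expect_error(bistability_region("pp2a_b55", "kagwl", "kiensa", -1, 1),
               "non-negative")
})
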