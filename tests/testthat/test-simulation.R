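test_that("the default model runs from G2 into mitosis within the horizon", {
  traj <- integrate_model(default_parameters(), g2_state(), horizon = 30)
  final <- traj$states[nrow(traj$states), ]
  # approaches the mitotic attractor (MPF ~ 0.96) by t = 30
  expect_gt(final[["MPF"]], 0.95)
  expect_lt(final[["Wee1"]], 0.05)
  expect_gt(final[["Gwl"]], 0.9)
  expect_in_box(traj)
})

test_that("degenerate and fixed-point initial conditions behave", {
  # CycT = 0: MPF decays towards zero
  p0 <- default_parameters(CycT = 0)
  traj <- integrate_model(p0, model_state(MPF = 0, Cdc25 = 0.5, Wee1 = 0.5,
                                          Gwl = 0.5, ENSAPt = 0.5,
                                          PP2 = 0.1), horizon = 30)
  expect_lt(max(traj$states[, "MPF"]), 1e-8)
  # an exact steady state stays put
  eq <- find_steady_state(default_parameters(), metaphase_state())
  traj <- integrate_model(default_parameters(), eq$state, horizon = 30)
  drift <- max(abs(sweep(traj$states, 2, as.numeric(eq$state))))
  expect_lt(drift, 1e-8)
})

test_that("stiff adaptive integration matches the fixed-step Euler oracle", {
  p <- default_parameters()
  pv <- setNames(as.numeric(p[names(p)]), names(p))
  traj <- integrate_model(p, g2_state(), horizon = 5, output_step = 0.05)
  eul <- oracle_euler(pv, g2_state(), dt = 1e-5, horizon = 5,
                      keep_every = 5000)
  expect_equal(nrow(eul), length(traj$times))
  expect_lt(max(abs(traj$states - eul)), 1e-3)
})

test_that("protocols are deterministic and stay inside the state box", {
  for (proto in c("entry_release", "entry_oa", "exit")) {
    a <- run_protocol("pp2a_b55", proto)
    b <- run_protocol("pp2a_b55", proto)
    expect_identical(a$states, b$states)
    expect_in_box(a)
    # the bound complex never exceeds total phospho-ENSA
    expect_gt(min(a$states[, "ENSAPt"] -
                    (a$params[["PP2T"]] - a$states[, "PP2"])), -1e-6)
  }
})

test_that("entry protocols start from the Cdk1-inhibited steady state", {
  traj <- run_protocol("oa_sensitive", "entry_release")
  pre <- traj$protocol$pre
  expect_true(pre$converged)
  inhibited <- scenario_parameters("oa_sensitive", RO = 25)
  expect_lt(max(abs(model_rhs(pre$state, inhibited))), 1e-8)
  expect_lt(pre$state[["MPF"]], 0.05)
})

test_that("t_cross interpolates excursion-fraction crossings", {
  # synthetic monotone linear rise 0 -> 1 over [0, 10]
  p <- default_parameters()
  lin <- structure(list(
    times = seq(0, 10, 0.5),
    states = cbind(MPF = seq(0, 1, 0.05), Cdc25 = 0, Wee1 = 0, Gwl = 0,
                   ENSAPt = 0.5, PP2 = 0.25),
    observables = cbind(MPFa = seq(0, 1, 0.05), PP2a = 0.25,
                        preMPF = seq(1, 0, -0.05), complex = 0.25),
    params = p, protocol = NULL), class = "mito_trajectory")
  expect_equal(t_cross(lin, "MPF", 0.5, "up"), 5)
  expect_equal(t_cross(lin, "MPF", 0.2, "up"), 2)
  expect_equal(t_cross(lin, "preMPF", 0.5, "down"), 5)
  # direction against the excursion, or a flat variable: not found
  expect_true(is.na(t_cross(lin, "MPF", 0.5, "down")))
  expect_true(is.na(t_cross(lin, "ENSAPt", 0.5, "up")))
  # boundary behaviour: small fractions interpolate near the start
  expect_equal(t_cross(lin, "MPF", 0.05, "up"), 0.5)
  # non-monotone series: the first crossing counts, not the last
  lin$states[, "Gwl"] <- c(0.8, 0.1, rep(0.75, 9),
                           seq(0.7, 0, length.out = 10))
  expect_equal(t_cross(lin, "Gwl", 0.25, "down"), 0.5 * 0.2 / 0.7)
})

test_that("Tyr15 dephosphorylation is faster on release than under OA", {
  for (sc in c("pp2a_b55", "oa_insensitive", "oa_sensitive")) {
    rel <- run_protocol(sc, "entry_release")
    oa <- run_protocol(sc, "entry_oa")
    t_rel <- t_cross(rel, "preMPF", direction = "down")
    t_oa <- t_cross(oa, "preMPF", direction = "down")
    expect_true(is.finite(t_rel))
    expect_true(is.finite(t_oa))
    expect_lt(t_rel, t_oa)
  }
})

test_that("Gwl inactivation at exit is delayed only under PP2A/B55", {
  t50 <- sapply(c("pp2a_b55", "oa_insensitive", "oa_sensitive"),
                function(sc) t_cross(run_protocol(sc, "exit"), "Gwl",
                                     direction = "down"))
  expect_gt(t50[["pp2a_b55"]], t50[["oa_insensitive"]])
  expect_gt(t50[["pp2a_b55"]], t50[["oa_sensitive"]])
})

test_that("trajectory CSV round-trips through write/read", {
  traj <- run_protocol("pp2a_b55", "exit", horizon = 5, output_step = 0.5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(traj, path)
  back <- read_trajectory(path)
  expect_equal(back$times, traj$times)
  expect_equal(back$states, traj$states, tolerance = 1e-12)
  expect_equal(as.numeric(back$params[names(default_parameters())]),
               as.numeric(traj$params[names(default_parameters())]))
})
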