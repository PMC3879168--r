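# shared fixtures: an exit trajectory and an OA-entry trajectory long
# enough to span the slow OA-driven transition
exit_traj <- run_protocol("pp2a_b55", "exit")
oa_traj <- run_protocol("pp2a_b55", "entry_oa", horizon = 120)

test_that("noiseless readouts equal interpolated trajectory values", {
  rd <- generate_readout(exit_traj, times = seq(0, 30, 3), sigma = 0,
                         background = 0, seed = 1)
  expect_equal(rd$signals, rd$truth)
  idx <- match(seq(0, 30, 3), exit_traj$times)
  expect_equal(unname(rd$signals[, "pThr194"]),
               unname(exit_traj$states[idx, "Gwl"]))
  expect_equal(unname(rd$signals[, "pTyr15"]),
               unname(exit_traj$observables[idx, "preMPF"]))
})

test_that("readout generation is reproducible and leaves the RNG alone", {
  a <- generate_readout(exit_traj, times = seq(0, 30, 3), sigma = 0.1,
                        seed = 11)
  b <- generate_readout(exit_traj, times = seq(0, 30, 3), sigma = 0.1,
                        seed = 11)
  expect_identical(a$signals, b$signals)
  c <- generate_readout(exit_traj, times = seq(0, 30, 3), sigma = 0.1,
                        seed = 12)
  expect_false(identical(a$signals, c$signals))
  set.seed(99); before <- runif(1)
  set.seed(99); generate_readout(exit_traj, times = 0:5, sigma = 0.1,
                                 seed = 5)
  expect_identical(runif(1), before)
})

test_that("readout rejects invalid sampling requests", {
  expect_error(generate_readout(exit_traj, times = c(0, 40), sigma = 0.1),
               "outside the trajectory span")
  expect_error(generate_readout(exit_traj, times = 0:5, sigma = -1),
               "sigma")
})

test_that("log-normal noise has the expected multiplicative mean", {
  sigma <- 0.1
  times <- c(0, 5, 10, 20)
  n <- 1000
  draws <- sapply(seq_len(n), function(r)
    generate_readout(exit_traj, times = times, sigma = sigma,
                     seed = r)$signals[, "pSer67"])
  truth <- generate_readout(exit_traj, times = times, sigma = 0,
                            seed = 1)$signals[, "pSer67"]
  expected <- truth * exp(sigma^2 / 2)
  se <- apply(draws, 1, stats::sd) / sqrt(n)
  expect_true(all(abs(rowMeans(draws) - expected) < 3 * se + 1e-12))
})

test_that("t50 estimation recovers the trajectory crossing time", {
  rd <- generate_readout(exit_traj, times = seq(0, 30, 0.5), sigma = 0,
                         seed = 1)
  est <- estimate_t50(rd, "pThr194", "down", n_boot = 50, seed = 2)
  truth <- t_cross(exit_traj, "Gwl", direction = "down")
  expect_lt(abs(est$t50 - truth), 0.5)   # within one sampling step
  # constant channel: no transition
  flat <- generate_readout(exit_traj, times = seq(25, 30, 0.5), sigma = 0,
                           seed = 1)
  expect_true(is.na(estimate_t50(flat, "pTyr15", "down",
                                 n_boot = 10)$t50))
  # too-sparse sampling is a precondition violation
  sparse <- generate_readout(exit_traj, times = c(0, 15, 30), sigma = 0,
                             seed = 1)
  expect_error(estimate_t50(sparse, "pThr194", "down"),
               "at least 4 sampling times")
})

test_that("noisy t50 estimates concentrate near the truth", {
  truth <- t_cross(oa_traj, "preMPF", direction = "down")
  times <- seq(0, 120, 8)
  errs <- sapply(1:50, function(r) {
    rd <- generate_readout(oa_traj, times = times, sigma = 0.05, seed = r)
    estimate_t50(rd, "pTyr15", "down", n_boot = 0)$t50 - truth
  })
  expect_gt(mean(abs(errs) / truth < 0.1), 0.95)
})

test_that("ordering test behaves symmetrically and detects the ordering", {
  rd <- generate_readout(oa_traj, times = seq(0, 120, 8), sigma = 0.05,
                         seed = 21)
  f <- ordering_test(rd, "pThr194", "pTyr15", c("up", "down"),
                     n_boot = 200, seed = 5)
  expect_gt(f, 0.95)                       # Gwl rise precedes Tyr15 fall
  f_rev <- ordering_test(rd, "pTyr15", "pThr194", c("down", "up"),
                         n_boot = 200, seed = 5)
  expect_equal(f + f_rev, 1, tolerance = 1e-12)
  # identical channels tie at one half
  f_tie <- ordering_test(rd, "pThr194", "pThr194", c("up", "up"),
                         n_boot = 100, seed = 6)
  expect_equal(f_tie, 0.5, tolerance = 0.1)
  expect_identical(
    ordering_test(rd, "pThr194", "pTyr15", c("up", "down"), seed = 9),
    ordering_test(rd, "pThr194", "pTyr15", c("up", "down"), seed = 9))
})

test_that("readout CSV export carries the long tidy format", {
  rd <- generate_readout(exit_traj, times = seq(0, 30, 5), sigma = 0.1,
                         seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_readout(rd, path)
  lines <- readLines(path)
  expect_true(any(grepl("^# sigma=0.1", lines)))
  df <- read.csv(path, comment.char = "#")
  expect_equal(nrow(df), length(rd$times) * ncol(rd$signals))
  expect_setequal(unique(df$channel), colnames(rd$signals))
})
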