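# Independent oracles used across the suite.
#
# oracle_rhs is a second, independently typed transcription of the six
# mass-action rate laws, arranged differently from the package internals
# (explicit complex/free-ENSA bookkeeping, premultiplied lumped rates).
# oracle_euler is a fixed-step explicit Euler integrator built on it.

oracle_rhs <- function(y, p) {
  active_cdk1 <- y[1] / (1 + p[["RO"]])
  active_pp2a <- y[6] / (1 + p[["OA"]])
  bound_pp2a <- p[["PP2T"]] - y[6]
  free_ensap <- y[5] - bound_pp2a
  tyr_dephos <- p[["k25_p"]] * (p[["Cdc25T"]] - y[2]) + p[["k25_pp"]] * y[2]
  tyr_phos <- p[["kwee_p"]] * (p[["Wee1T"]] - y[3]) + p[["kwee_pp"]] * y[3]
  gwl_off <- p[["kigwl_p"]] +
    p[["kigwl_pp"]] * p[["PP2T"]] / (1 + p[["OA"]]) +
    p[["kigwl"]] * active_pp2a
  c(tyr_dephos * (p[["CycT"]] - y[1]) - tyr_phos * y[1],
    p[["Va25"]] * active_cdk1 * (p[["Cdc25T"]] - y[2]) -
      p[["Vi25"]] * active_pp2a * y[2],
    p[["Vawee"]] * active_pp2a * (p[["Wee1T"]] - y[3]) -
      p[["Viwee"]] * active_cdk1 * y[3],
    p[["kagwl"]] * active_cdk1 * (p[["GwlT"]] - y[4]) - gwl_off * y[4],
    p[["kaensa"]] * y[4] * (p[["ENSAT"]] - y[5]) - p[["kiensa"]] * y[5],
    -p[["kas"]] * free_ensap * y[6] +
      (p[["kdis"]] + p[["kiensa"]]) * bound_pp2a)
}

# fixed-step explicit Euler; returns states sampled every keep_every steps
oracle_euler <- function(p, y0, dt, horizon, keep_every) {
  n <- round(horizon / dt)
  y <- as.numeric(y0)
  kept <- matrix(NA_real_, nrow = n %/% keep_every + 1, ncol = 6)
  kept[1, ] <- y
  k <- 1
  for (i in seq_len(n)) {
    y <- y + dt * oracle_rhs(y, p)
    if (i %% keep_every == 0) {
      k <- k + 1
      kept[k, ] <- y
    }
  }
  colnames(kept) <- c("MPF", "Cdc25", "Wee1", "Gwl", "ENSAPt", "PP2")
  kept
}

# uniform random states satisfying the box and complex constraints
random_valid_states <- function(n, params, seed) {
  set.seed(seed)
  hi <- as.numeric(params[c("CycT", "Cdc25T", "Wee1T", "GwlT",
                            "ENSAT", "PP2T")])
  t(replicate(n, {
    s <- runif(6, 0, hi)
    lo5 <- max(0, params[["PP2T"]] - s[6])
    s[5] <- runif(1, lo5, params[["ENSAT"]])
    s
  }))
}

expect_in_box <- function(traj, tol = 1e-6) {
  hi <- as.numeric(traj$params[c("CycT", "Cdc25T", "Wee1T", "GwlT",
                                 "ENSAT", "PP2T")])
  lo_ok <- apply(traj$states, 2, min) >= -tol
  hi_ok <- apply(traj$states, 2, max) <= hi + tol
  expect_true(all(lo_ok) && all(hi_ok))
}
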