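# Trajectory integration, inhibitor protocols and event timing.

#' Integrate the model
#'
#' Solves the six ordinary differential equations with a stiff adaptive
#' solver (`deSolve::ode`, lsoda) and samples the dense solution on a
#' regular output grid.  Tolerances default to `rtol = 1e-8`,
#' `atol = 1e-10`, tight enough that the sampled output is insensitive to
#' further tightening; the output step only controls sampling, not solver
#' accuracy.
#'
#' @param params a `"mito_params"` vector (or scenario label).
#' @param init initial `"mito_state"`; default the G2 state.
#' @param horizon integration horizon in model time units.
#' @param output_step sampling interval of the returned trajectory.
#' @param rtol,atol relative/absolute solver tolerances.
#' @param jacobian use the analytic Jacobian (default `TRUE`).
#' @return A `"mito_trajectory"`: list with `times`, `states` (matrix,
#'   one row per time), `observables` (MPFa, PP2a, preMPF, complex),
#'   `params` and `protocol` (annotation, `NULL` for plain runs).
#' @examples
#' traj <- integrate_model(default_parameters(), g2_state(), horizon = 30)
#' tail(as.data.frame(traj), 1)
#' @export
integrate_model <- function(params, init = g2_state(), horizon = 30,
                            output_step = 0.05, rtol = 1e-8, atol = 1e-10,
                            jacobian = TRUE) {
  params <- as_parameters(params)
  validate_parameters(params)
  # reject genuine violations, absorb solver-level roundoff (< 1e-6)
  validate_state(model_state(init), params, tol = 1e-6)
  init <- clamp_roundoff(model_state(init), params)
  if (!is.finite(horizon) || horizon <= 0) stop("'horizon' must be > 0")
  if (!is.finite(output_step) || output_step <= 0)
    stop("'output_step' must be > 0")
  times <- seq(0, horizon, by = output_step)
  if (times[length(times)] < horizon) times <- c(times, horizon)
  pv <- setNames(as.numeric(params[.param_names]), .param_names)
  f <- function(t, y, p) list(rhs_raw(y, p))
  jf <- if (jacobian)
    function(t, y, p) model_jacobian(y, params) else NULL
  out <- deSolve::ode(
    y = setNames(as.numeric(init), .state_names), times = times,
    func = f, parms = pv, method = "lsoda",
    rtol = rtol, atol = atol, jacfunc = jf,
    jactype = if (jacobian) "fullusr" else "fullint")
  if (nrow(out) < length(times)) {
    stop(sprintf(
      "integration failed at t = %.6g (requested horizon %.6g)",
      out[nrow(out), 1], horizon))
  }
  states <- unname(out[, 1 + seq_along(.state_names), drop = FALSE])
  colnames(states) <- .state_names
  new_trajectory(times = out[, 1], states = states, params = params)
}

new_trajectory <- function(times, states, params, protocol = NULL) {
  obs <- cbind(
    MPFa = states[, "MPF"] / (1 + params[["RO"]]),
    PP2a = states[, "PP2"] / (1 + params[["OA"]]),
    preMPF = params[["CycT"]] - states[, "MPF"],
    complex = params[["PP2T"]] - states[, "PP2"])
  structure(list(times = times, states = states, observables = obs,
                 params = params, protocol = protocol),
            class = "mito_trajectory")
}

#' Relax the model to steady state at fixed doses
#'
#' Integrates from `init` in successive blocks until the right-hand side
#' max-norm falls below `tol`, or `max_time` is reached.  Used to prepare
#' the Cdk1-inhibited starting state of the entry protocols.
#'
#' @inheritParams integrate_model
#' @param tol convergence tolerance on the right-hand-side max-norm.
#' @param max_time time budget for convergence.
#' @param block integration block length between convergence checks.
#' @return List with `state`, `time`, `residual`, `converged`.
#' @export
equilibrate <- function(params, init = g2_state(), tol = 1e-9,
                        max_time = 500, block = 50) {
  params <- as_parameters(params)
  y <- model_state(init)
  pv <- setNames(as.numeric(params[.param_names]), .param_names)
  t_done <- 0
  repeat {
    res <- max(abs(rhs_raw(as.numeric(y), pv)))
    if (res < tol || t_done >= max_time) break
    traj <- integrate_model(params, y, horizon = block, output_step = block)
    y <- model_state(traj$states[nrow(traj$states), ])
    t_done <- t_done + block
  }
  list(state = y, time = t_done, residual = res, converged = res < tol)
}

#' Run an inhibitor perturbation protocol
#'
#' The three in-silico counterparts of the chemical-inhibitor experiments,
#' each returning a trajectory whose time origin is the dose switch:
#'
#' * `"entry_release"`: the network is first relaxed to its
#'   Cdk1-inhibited steady state (`RO = 25`), then the inhibitor is
#'   removed (`RO = 0`) and mitotic entry through the Tyr15 feedback
#'   loops is followed.
#' * `"entry_oa"`: from the same Cdk1-inhibited state, okadaic acid is
#'   added on top of the Cdk1 inhibitor (`RO = 25`, `OA = 100`); entry is
#'   driven by phosphatase inhibition rather than kinase release.
#' * `"exit"`: from the metaphase state, Cdk1 is inhibited strongly
#'   (`RO = 100`) and mitotic exit is followed.
#'
#' Dose switches are instantaneous (inhibitor binding is treated as a
#' fast reversible equilibrium, consistent with the algebraic `MPFa`,
#' `PP2a` dose corrections).
#'
#' @param scenario scenario label or `"mito_params"` vector (see
#'   [scenario_parameters()]).
#' @param protocol `"entry_release"`, `"entry_oa"` or `"exit"`
#'   (hyphens accepted).
#' @param horizon simulated time after the dose switch.
#' @param output_step output sampling interval.
#' @param pre_tol,pre_max_time convergence tolerance and time budget of
#'   the pre-equilibration stage (entry protocols).
#' @param ... further arguments to [integrate_model()].
#' @return A `"mito_trajectory"` with a `protocol` annotation listing the
#'   protocol name, pre- and post-switch doses and the pre-equilibrated
#'   state.
#' @examples
#' traj <- run_protocol("pp2a_b55", "exit", horizon = 30)
#' t_cross(traj, "Gwl", direction = "down")
#' @export
run_protocol <- function(scenario, protocol = c("entry_release", "entry_oa",
                                                "exit"),
                         horizon = 30, output_step = 0.05,
                         pre_tol = 1e-9, pre_max_time = 500, ...) {
  protocol <- gsub("-", "_", tolower(protocol[1]), fixed = TRUE)
  protocol <- match.arg(protocol, c("entry_release", "entry_oa", "exit"))
  base <- as_parameters(scenario)
  label <- attr(base, "scenario")
  if (protocol == "exit") {
    params <- set_parameters(base, RO = 100, OA = 0)
    init <- metaphase_state()
    pre <- list(dose = c(RO = 0, OA = 0), state = init,
                converged = NA, time = 0)
  } else {
    inhibited <- set_parameters(base, RO = 25, OA = 0)
    eq <- equilibrate(inhibited, g2_state(), tol = pre_tol,
                      max_time = pre_max_time)
    if (!eq$converged)
      stop(sprintf(
        "pre-equilibration did not converge within %g time units (residual %.3g)",
        pre_max_time, eq$residual))
    init <- eq$state
    params <- if (protocol == "entry_release")
      set_parameters(base, RO = 0, OA = 0)
    else
      set_parameters(base, RO = 25, OA = 100)
    pre <- list(dose = c(RO = 25, OA = 0), state = init,
                converged = eq$converged, time = eq$time)
  }
  traj <- integrate_model(params, init, horizon = horizon,
                          output_step = output_step, ...)
  traj$protocol <- list(
    name = protocol, scenario = label,
    pre = pre,
    dose = c(RO = params[["RO"]], OA = params[["OA"]]),
    switch_time = 0)
  traj
}

#' First threshold-crossing time of a trajectory variable
#'
#' Timing metric used to compare protocols: the excursion of a variable is
#' measured between its value at the start of the trajectory (the dose
#' switch) and its final value; `t_cross` returns the linearly
#' interpolated first time the variable passes
#' `start + fraction * (end - start)` in the stated direction.  A
#' trajectory whose excursion is smaller than `min_excursion`, or one
#' whose excursion runs against `direction`, yields `NA` (no transition).
#'
#' @param traj a `"mito_trajectory"`.
#' @param variable a state (`"MPF"`, ..., `"PP2"`) or observable
#'   (`"MPFa"`, `"PP2a"`, `"preMPF"`, `"complex"`) name.
#' @param fraction excursion fraction defining the threshold (default 0.5,
#'   the half-transition time t50).
#' @param direction `"up"` or `"down"`.
#' @param min_excursion smallest |end - start| treated as a transition.
#' @return Crossing time (numeric), or `NA_real_` if the variable never
#'   crosses.
#' @examples
#' traj <- run_protocol("pp2a_b55", "exit")
#' t_cross(traj, "Gwl", direction = "down")   # delayed Gwl inactivation
#' @export
t_cross <- function(traj, variable, fraction = 0.5,
                    direction = c("up", "down"), min_excursion = 1e-3) {
  direction <- match.arg(direction)
  if (fraction <= 0 || fraction >= 1) stop("'fraction' must be in (0, 1)")
  v <- trajectory_variable(traj, variable)
  tt <- traj$times
  v0 <- v[1]; vf <- v[length(v)]
  if (abs(vf - v0) < min_excursion) return(NA_real_)
  if ((direction == "up") != (vf > v0)) return(NA_real_)
  th <- v0 + fraction * (vf - v0)
  hit <- if (direction == "up") v >= th else v <= th
  i <- which(hit)[1]
  if (is.na(i)) return(NA_real_)
  if (i == 1) return(tt[1])
  # linear interpolation inside the bracketing output interval
  tt[i - 1] + (th - v[i - 1]) / (v[i] - v[i - 1]) * (tt[i] - tt[i - 1])
}

trajectory_variable <- function(traj, variable) {
  stopifnot(inherits(traj, "mito_trajectory"))
  if (variable %in% colnames(traj$states)) return(traj$states[, variable])
  if (variable %in% colnames(traj$observables))
    return(traj$observables[, variable])
  stop("unknown trajectory variable '", variable, "'")
}

#' @export
as.data.frame.mito_trajectory <- function(x, ...) {
  data.frame(time = x$times, x$states, x$observables,
             check.names = FALSE)
}

#' @export
print.mito_trajectory <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("Mitotic-switch trajectory: %d samples over [0, %g]\n",
              n, x$times[n]))
  if (!is.null(x$protocol))
    cat(sprintf("  protocol: %s (%s), dose RO=%g OA=%g\n",
                x$protocol$name,
                if (is.null(x$protocol$scenario)) "custom parameters"
                else x$protocol$scenario,
                x$protocol$dose[["RO"]], x$protocol$dose[["OA"]]))
  cat("  final state:\n")
  print(round(x$states[n, ], 4))
  invisible(x)
}

#' Plot a trajectory
#'
#' Simple base-graphics time-course plot of a selection of variables.
#'
#' @param x a `"mito_trajectory"`.
#' @param variables variables to draw.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.mito_trajectory <- function(x, variables = c("preMPF", "Cdc25",
                                                  "ENSAPt", "PP2a", "Gwl"),
                                 ...) {
  m <- sapply(variables, function(v) trajectory_variable(x, v))
  graphics::matplot(x$times, m, type = "l", lty = 1, lwd = 2,
                    xlab = "time (model units)", ylab = "level", ...)
  graphics::legend("right", legend = variables, col = seq_along(variables),
                   lty = 1, lwd = 2, bty = "n")
  invisible(x)
}

#' Write a trajectory to CSV
#'
#' Tidy wide CSV (`time`, six states, four observables) preceded by
#' `#`-prefixed metadata lines echoing the parameters and protocol.
#'
#' @param traj a `"mito_trajectory"`.
#' @param path output path.
#' @return Invisibly `path`.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "mito_trajectory"))
  hdr <- c("# mitoswitch trajectory",
           paste0("# params: ",
                  paste0(.param_names, "=",
                         format(as.numeric(traj$params[.param_names]),
                                digits = 17, trim = TRUE),
                         collapse = " ")))
  if (!is.null(traj$protocol))
    hdr <- c(hdr, sprintf("# protocol: %s scenario=%s RO=%g OA=%g",
                          traj$protocol$name,
                          if (is.null(traj$protocol$scenario)) "custom"
                          else traj$protocol$scenario,
                          traj$protocol$dose[["RO"]],
                          traj$protocol$dose[["OA"]]))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(format(as.data.frame(traj), digits = 15, trim = TRUE),
              con, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param path CSV path.
#' @return A `"mito_trajectory"`.
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- lines[startsWith(lines, "#")]
  pline <- sub("^# params: ", "", meta[startsWith(meta, "# params: ")][1])
  p <- default_parameters()
  for (kv in strsplit(strsplit(pline, " ")[[1]], "=")) {
    p[[kv[1]]] <- as.numeric(kv[2])
  }
  df <- read.table(text = lines[!startsWith(lines, "#")], sep = ",",
                   header = TRUE, check.names = FALSE)
  new_trajectory(times = df$time,
                 states = as.matrix(df[, .state_names]),
                 params = p)
}
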