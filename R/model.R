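# Core model definitions: state handling, right-hand side, observables,
# effective Tyr15 modification rates, analytic Jacobian.
#
# The six dynamic variables:
#   MPF    active (Tyr15-dephosphorylated) Cdk1/CycB
#   Cdc25  phosphorylated, active Cdc25
#   Wee1   unphosphorylated, active Wee1
#   Gwl    phosphorylated, active Greatwall
#   ENSAPt total phosphorylated ENSA/ARPP19 (free + PP2A-bound)
#   PP2    free, active PP2A/B55
#
# Chemical inhibition is a fast reversible binding equilibrium, entering the
# rate laws only through the active fractions MPFa = MPF/(1+RO) and
# PP2a = PP2/(1+OA).

#' Construct a model state
#'
#' @param MPF,Cdc25,Wee1,Gwl,ENSAPt,PP2 the six state variables; a single
#'   named vector may instead be passed as `MPF`.
#' @return A named numeric vector of class `"mito_state"`.
#' @examples
#' model_state(MPF = 0, Cdc25 = 0, Wee1 = 1, Gwl = 0, ENSAPt = 0, PP2 = 0.5)
#' @export
model_state <- function(MPF, Cdc25, Wee1, Gwl, ENSAPt, PP2) {
  if (length(MPF) == 6 && !is.null(names(MPF))) {
    s <- as.numeric(MPF[.state_names])
  } else {
    s <- c(MPF, Cdc25, Wee1, Gwl, ENSAPt, PP2)
  }
  if (length(s) != 6)
    stop("a model state needs the six components ",
         paste(.state_names, collapse = ", "))
  if (any(!is.finite(s)))
    stop("non-finite state component(s)")
  s <- setNames(s, .state_names)
  class(s) <- "mito_state"
  s
}

#' The G2 (interphase-like) initial condition
#'
#' All Cdk1/CycB Tyr15-phosphorylated, Wee1 active, Cdc25 and the
#' Gwl/ENSA pathway off, all PP2A/B55 free.
#' @return A `"mito_state"` vector.
#' @export
g2_state <- function() {
  model_state(MPF = 0, Cdc25 = 0, Wee1 = 1, Gwl = 0, ENSAPt = 0, PP2 = 0.5)
}

#' The metaphase (mitotic) initial condition
#'
#' The printed mitotic state used to start mitotic-exit simulations: Cdk1
#' almost fully active, Cdc25 on, Wee1 off, Gwl high, most PP2A/B55
#' sequestered by phosphorylated ENSA.  (To two printed decimals this is
#' the mitotic steady state of the OA-sensitive Gwl-phosphatase variant;
#' under the PP2A/B55 variant the nearby steady state has Gwl about 0.99.)
#' @return A `"mito_state"` vector.
#' @export
metaphase_state <- function() {
  model_state(MPF = 0.96, Cdc25 = 0.97, Wee1 = 0.03, Gwl = 0.9,
              ENSAPt = 0.75, PP2 = 0.027)
}

#' Validate a state against the box constraints
#'
#' Each pool is bounded by its total: `0 <= MPF <= CycT`,
#' `0 <= Cdc25 <= Cdc25T`, ..., `0 <= PP2 <= PP2T`; additionally the
#' PP2A-bound complex (`PP2T - PP2`) cannot exceed total phospho-ENSA
#' (`ENSAPt >= PP2T - PP2`).
#'
#' @param state a `"mito_state"` vector.
#' @param params a `"mito_params"` vector supplying the totals.
#' @param action `"error"` (default) to reject violations, `"clamp"` to
#'   project onto the box with a warning.  Silent clamping is deliberately
#'   not offered: out-of-box states usually indicate a solver pathology.
#' @param tol numerical slack on the bounds.
#' @return The (possibly clamped) state, invisibly for `"error"`.
#' @export
validate_state <- function(state, params = default_parameters(),
                           action = c("error", "clamp"), tol = 1e-9) {
  action <- match.arg(action)
  s <- as.numeric(state)[1:6]
  if (any(!is.finite(s)))
    stop("non-finite state component(s)")
  hi <- as.numeric(params[c("CycT", "Cdc25T", "Wee1T", "GwlT",
                            "ENSAT", "PP2T")])
  bad_box <- s < -tol | s > hi + tol
  bad_cplx <- s[5] < (params[["PP2T"]] - s[6]) - tol
  if (any(bad_box) || bad_cplx) {
    msg <- paste0(
      if (any(bad_box))
        paste0("state outside box: ",
               paste(.state_names[bad_box], collapse = ", "))
      else "bound PP2A:ENSAP complex exceeds total phospho-ENSA")
    if (action == "error") stop(msg)
    warning(msg, "; clamping")
    s <- pmin(pmax(s, 0), hi)
    s[5] <- max(s[5], params[["PP2T"]] - s[6])
  }
  out <- model_state(setNames(s, .state_names))
  if (action == "error") invisible(out) else out
}

# project roundoff-level box violations back onto the box
clamp_roundoff <- function(state, params) {
  s <- as.numeric(state)
  hi <- as.numeric(params[c("CycT", "Cdc25T", "Wee1T", "GwlT",
                            "ENSAT", "PP2T")])
  s <- pmin(pmax(s, 0), hi)
  model_state(setNames(s, .state_names))
}

#' Effective Tyr15 modification rates
#'
#' The lumped Cdk1-Tyr15 dephosphorylation and phosphorylation rate
#' constants, linear combinations of the unmodified (basal) and modified
#' (shifted) forms of the two converter enzymes:
#' `k25 = k25' (Cdc25T - Cdc25) + k25'' Cdc25` and
#' `kwee = kwee' (Wee1T - Wee1) + kwee'' Wee1`.
#'
#' @param state a `"mito_state"` vector.
#' @param params a `"mito_params"` vector.
#' @return Named numeric vector `c(k25, kwee)`.
#' @examples
#' effective_rates(g2_state(), default_parameters())
#' @export
effective_rates <- function(state, params = default_parameters()) {
  c(k25 = params[["k25_p"]] * (params[["Cdc25T"]] - state[["Cdc25"]]) +
      params[["k25_pp"]] * state[["Cdc25"]],
    kwee = params[["kwee_p"]] * (params[["Wee1T"]] - state[["Wee1"]]) +
      params[["kwee_pp"]] * state[["Wee1"]])
}

#' Derived observables
#'
#' Inhibitor-corrected activities and conserved-pool complements:
#' `MPFa = MPF/(1+RO)` (Cdk1 activity left free by the reversible Cdk1
#' inhibitor), `PP2a = PP2/(1+OA)` (PP2A/B55 activity under okadaic
#' acid), `preMPF = CycT - MPF` (the Tyr15-phosphorylated pool) and
#' `complex = PP2T - PP2` (PP2A/B55 sequestered by phospho-ENSA).
#'
#' @inheritParams effective_rates
#' @return Named numeric vector `c(MPFa, PP2a, preMPF, complex)`.
#' @examples
#' model_observables(metaphase_state(), default_parameters(RO = 100))
#' @export
model_observables <- function(state, params = default_parameters()) {
  c(MPFa = state[["MPF"]] / (1 + params[["RO"]]),
    PP2a = state[["PP2"]] / (1 + params[["OA"]]),
    preMPF = params[["CycT"]] - state[["MPF"]],
    complex = params[["PP2T"]] - state[["PP2"]])
}

#' Model right-hand side
#'
#' Time derivatives of the six state variables under mass-action kinetics.
#' Cdk1 acts as a kinase only through its uninhibited fraction `MPFa`;
#' PP2A/B55 acts only through `PP2a`.  The Gwl inactivation rate sums the
#' three candidate phosphatase routes: OA-insensitive (`kigwl_p`),
#' OA-sensitive but outside the B55 feedback (`kigwl_pp`, proportional to
#' total PP2A scaled by the okadaic acid dose) and PP2A/B55 itself
#' (`kigwl`, proportional to free active `PP2a`).  Free PP2A/B55 is
#' consumed by association with free phospho-ENSA
#' (`ENSAPt - (PP2T - PP2)`) and regenerated by complex dissociation and
#' by dephosphorylation of bound ENSA (`kdis + kiensa`).
#'
#' @inheritParams effective_rates
#' @param check validate the state box constraints first (default `TRUE`).
#' @return Named numeric vector of the six derivatives.
#' @examples
#' model_rhs(g2_state(), default_parameters())
#' @export
model_rhs <- function(state, params = default_parameters(), check = TRUE) {
  s <- as.numeric(state)
  p <- as.numeric(params[.param_names])
  if (any(!is.finite(s)) || any(!is.finite(p)))
    stop("non-finite input to model_rhs")
  if (check) validate_state(state, params)
  setNames(rhs_raw(s, setNames(p, .param_names)), .state_names)
}

# unchecked numeric core shared by the integrator and the equilibrium code
rhs_raw <- function(s, p) {
  MPFa <- s[1] / (1 + p[["RO"]])
  PP2a <- s[6] / (1 + p[["OA"]])
  k25 <- p[["k25_p"]] * (p[["Cdc25T"]] - s[2]) + p[["k25_pp"]] * s[2]
  kwee <- p[["kwee_p"]] * (p[["Wee1T"]] - s[3]) + p[["kwee_pp"]] * s[3]
  cplx <- p[["PP2T"]] - s[6]
  c(k25 * (p[["CycT"]] - s[1]) - kwee * s[1],
    p[["Va25"]] * MPFa * (p[["Cdc25T"]] - s[2]) - p[["Vi25"]] * PP2a * s[2],
    p[["Vawee"]] * PP2a * (p[["Wee1T"]] - s[3]) - p[["Viwee"]] * MPFa * s[3],
    p[["kagwl"]] * MPFa * (p[["GwlT"]] - s[4]) -
      (p[["kigwl_p"]] + p[["kigwl_pp"]] * p[["PP2T"]] / (1 + p[["OA"]]) +
         p[["kigwl"]] * PP2a) * s[4],
    p[["kaensa"]] * s[4] * (p[["ENSAT"]] - s[5]) - p[["kiensa"]] * s[5],
    -p[["kas"]] * (s[5] - cplx) * s[6] +
      (p[["kdis"]] + p[["kiensa"]]) * cplx)
}

#' Analytic Jacobian of the right-hand side
#'
#' Exact partial derivatives of [model_rhs()] with respect to the six
#' state variables; used by the Newton steady-state solver and for linear
#' stability (eigenvalues).
#'
#' @inheritParams effective_rates
#' @return A 6 x 6 numeric matrix, rows = equations, columns = variables.
#' @export
model_jacobian <- function(state, params = default_parameters()) {
  s <- as.numeric(state)
  p <- params
  A <- 1 + p[["RO"]]; B <- 1 + p[["OA"]]
  MPFa <- s[1] / A; PP2a <- s[6] / B
  k25 <- p[["k25_p"]] * (p[["Cdc25T"]] - s[2]) + p[["k25_pp"]] * s[2]
  kwee <- p[["kwee_p"]] * (p[["Wee1T"]] - s[3]) + p[["kwee_pp"]] * s[3]
  J <- matrix(0, 6, 6, dimnames = list(.state_names, .state_names))
  J[1, 1] <- -k25 - kwee
  J[1, 2] <- (p[["k25_pp"]] - p[["k25_p"]]) * (p[["CycT"]] - s[1])
  J[1, 3] <- -(p[["kwee_pp"]] - p[["kwee_p"]]) * s[1]
  J[2, 1] <- p[["Va25"]] * (p[["Cdc25T"]] - s[2]) / A
  J[2, 2] <- -p[["Va25"]] * MPFa - p[["Vi25"]] * PP2a
  J[2, 6] <- -p[["Vi25"]] * s[2] / B
  J[3, 1] <- -p[["Viwee"]] * s[3] / A
  J[3, 3] <- -p[["Vawee"]] * PP2a - p[["Viwee"]] * MPFa
  J[3, 6] <- p[["Vawee"]] * (p[["Wee1T"]] - s[3]) / B
  J[4, 1] <- p[["kagwl"]] * (p[["GwlT"]] - s[4]) / A
  J[4, 4] <- -p[["kagwl"]] * MPFa -
    (p[["kigwl_p"]] + p[["kigwl_pp"]] * p[["PP2T"]] / B + p[["kigwl"]] * PP2a)
  J[4, 6] <- -p[["kigwl"]] * s[4] / B
  J[5, 4] <- p[["kaensa"]] * (p[["ENSAT"]] - s[5])
  J[5, 5] <- -p[["kaensa"]] * s[4] - p[["kiensa"]]
  J[6, 5] <- -p[["kas"]] * s[6]
  J[6, 6] <- -p[["kas"]] * (s[5] - (p[["PP2T"]] - s[6])) - p[["kas"]] * s[6] -
    (p[["kdis"]] + p[["kiensa"]])
  J
}

# central finite-difference Jacobian, kept as an independent cross-check
fd_jacobian <- function(state, params, h = 1e-7) {
  s <- as.numeric(state)
  p <- setNames(as.numeric(params[.param_names]), .param_names)
  J <- matrix(0, 6, 6, dimnames = list(.state_names, .state_names))
  for (j in 1:6) {
    e <- numeric(6); e[j] <- h
    J[, j] <- (rhs_raw(s + e, p) - rhs_raw(s - e, p)) / (2 * h)
  }
  J
}

#' @export
print.mito_state <- function(x, ...) {
  print(setNames(as.numeric(x), .state_names))
  invisible(x)
}
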