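# Steady states, linear stability, balance curves and bistability maps.
#
# Enumeration of equilibria exploits an exact reduction: at steady state
# Cdc25, Wee1, Gwl and ENSAPt have closed-form expressions in terms of MPF
# and PP2 alone (each of their rate balances is linear in the variable),
# so the full 6-D root problem collapses to two residuals in (MPF, PP2).
# A multi-start Newton iteration on the reduced pair, vectorized over all
# starts, locates candidate roots; each candidate is reconstructed to a
# full state, polished by 6-D Newton with the analytic Jacobian, kept if
# the residual max-norm is below tolerance and the state lies in the box,
# and classified by Jacobian eigenvalues.

#' Find one steady state by Newton iteration
#'
#' Damped Newton refinement of [model_rhs()]`= 0` from a user-supplied
#' guess, using the analytic Jacobian.  The converged root must lie
#' inside the state box (each pool within its total) and reach a residual
#' max-norm below `tol`, otherwise the result is rejected.
#'
#' Stability is classified from the eigenvalues of the Jacobian at the
#' root: stable if all real parts are below `-1e-9`, unstable if any
#' exceeds `+1e-9`; eigenvalues inside that band flag the equilibrium as
#' marginal rather than silently classifying it.
#'
#' @param params a `"mito_params"` vector or scenario label.
#' @param guess starting `"mito_state"`.
#' @param tol residual max-norm tolerance.
#' @param max_iter Newton iteration cap.
#' @return A `"mito_equilibrium"`: list with `state`, `residual`,
#'   `stable`, `marginal`, `leading_eigenvalue`, `eigenvalues`.
#' @examples
#' eq <- find_steady_state(scenario_parameters("oa_sensitive"),
#'                         metaphase_state())
#' round(as.numeric(eq$state), 3)
#' @export
find_steady_state <- function(params, guess, tol = 1e-10, max_iter = 100) {
  params <- as_parameters(params)
  validate_parameters(params)
  validate_state(model_state(guess), params, tol = 1e-6)
  s <- as.numeric(model_state(guess))
  pv <- setNames(as.numeric(params[.param_names]), .param_names)
  res <- max(abs(rhs_raw(s, pv)))
  for (it in seq_len(max_iter)) {
    if (res < tol) break
    f <- rhs_raw(s, pv)
    J <- model_jacobian(s, params)
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step))
      stop("singular Jacobian in Newton iteration (best residual ",
           format(res, digits = 3), ")")
    lambda <- 1
    repeat {
      s_new <- s + lambda * step
      res_new <- max(abs(rhs_raw(s_new, pv)))
      if (res_new < res || lambda < 1 / 1024) break
      lambda <- lambda / 2
    }
    s <- s_new; res <- res_new
  }
  if (res >= tol)
    stop("Newton iteration did not converge (best residual ",
         format(res, digits = 3), ")")
  hi <- as.numeric(params[c("CycT", "Cdc25T", "Wee1T", "GwlT",
                            "ENSAT", "PP2T")])
  if (any(s < -1e-8) || any(s > hi + 1e-8))
    stop("converged point lies outside the state box")
  classify_equilibrium(pmin(pmax(s, 0), hi), params, res)
}

classify_equilibrium <- function(s, params, res) {
  ev <- eigen(model_jacobian(s, params), only.values = TRUE)$values
  re <- Re(ev)
  lead <- max(re)
  structure(list(
    state = model_state(setNames(s, .state_names)),
    residual = res,
    stable = all(re < -1e-9),
    marginal = any(abs(re) <= 1e-9),
    leading_eigenvalue = lead,
    eigenvalues = ev), class = "mito_equilibrium")
}

#' @export
print.mito_equilibrium <- function(x, ...) {
  cat(sprintf("Steady state (%s%s), residual %.2e, leading Re(eig) %.3g\n",
              if (x$stable) "stable" else "unstable",
              if (x$marginal) ", marginal" else "",
              x$residual, x$leading_eigenvalue))
  print(round(as.numeric(x$state), 5))
  invisible(x)
}

# ---- reduced 2-D system ---------------------------------------------------

# closed-form steady-state values of the four "fast" variables given
# (MPF, PP2); vectorized over equally long m, q (CycT does not enter)
reduced_state <- function(m, q, p) {
  MPFa <- m / (1 + p[["RO"]])
  PP2a <- q / (1 + p[["OA"]])
  d <- p[["Va25"]] * MPFa + p[["Vi25"]] * PP2a
  c25 <- ifelse(d > 0, p[["Va25"]] * MPFa * p[["Cdc25T"]] / pmax(d, 1e-300), 0)
  d <- p[["Vawee"]] * PP2a + p[["Viwee"]] * MPFa
  w <- ifelse(d > 0, p[["Vawee"]] * PP2a * p[["Wee1T"]] / pmax(d, 1e-300),
              p[["Wee1T"]])
  kig <- p[["kigwl_p"]] + p[["kigwl_pp"]] * p[["PP2T"]] / (1 + p[["OA"]]) +
    p[["kigwl"]] * PP2a
  d <- p[["kagwl"]] * MPFa + kig
  g <- ifelse(d > 0, p[["kagwl"]] * MPFa * p[["GwlT"]] / pmax(d, 1e-300), 0)
  d <- p[["kaensa"]] * g + p[["kiensa"]]
  e <- ifelse(d > 0, p[["kaensa"]] * g * p[["ENSAT"]] / pmax(d, 1e-300), 0)
  list(MPF = m, Cdc25 = c25, Wee1 = w, Gwl = g, ENSAPt = e, PP2 = q)
}

# residual pair (MPF equation, PP2 equation) of the reduced system;
# ct may be a scalar or a vector parallel to m, q
reduced_residual <- function(m, q, ct, p) {
  s <- reduced_state(m, q, p)
  k25 <- p[["k25_p"]] * (p[["Cdc25T"]] - s$Cdc25) + p[["k25_pp"]] * s$Cdc25
  kwee <- p[["kwee_p"]] * (p[["Wee1T"]] - s$Wee1) + p[["kwee_pp"]] * s$Wee1
  cplx <- p[["PP2T"]] - q
  list(
    f1 = k25 * (ct - m) - kwee * m,
    f2 = -p[["kas"]] * (s$ENSAPt - cplx) * q +
      (p[["kdis"]] + p[["kiensa"]]) * cplx)
}

# vectorized damped-free Newton on the reduced pair; all starts iterate
# in lockstep (finite-difference 2x2 Jacobians solved by Cramer's rule)
reduced_newton <- function(m, q, ct, p, iters = 40, h = 1e-7) {
  pt <- p[["PP2T"]]
  for (it in seq_len(iters)) {
    f <- reduced_residual(m, q, ct, p)
    fpm <- reduced_residual(m + h, q, ct, p)
    fmm <- reduced_residual(m - h, q, ct, p)
    fpq <- reduced_residual(m, q + h, ct, p)
    fmq <- reduced_residual(m, q - h, ct, p)
    j11 <- (fpm$f1 - fmm$f1) / (2 * h); j12 <- (fpq$f1 - fmq$f1) / (2 * h)
    j21 <- (fpm$f2 - fmm$f2) / (2 * h); j22 <- (fpq$f2 - fmq$f2) / (2 * h)
    det <- j11 * j22 - j12 * j21
    bad <- !is.finite(det) | abs(det) < 1e-300
    det[bad] <- 1
    dm <- (-f$f1 * j22 + f$f2 * j12) / det
    dq <- (-f$f2 * j11 + f$f1 * j21) / det
    dm[bad] <- 0; dq[bad] <- 0
    m <- pmin(pmax(m + dm, 0), ct)
    q <- pmin(pmax(q + dq, 0), pt)
    if (max(abs(dm), abs(dq)) < 1e-14) break
  }
  f <- reduced_residual(m, q, ct, p)
  list(m = m, q = q, f1 = f$f1, f2 = f$f2)
}

# candidate (MPF, PP2) roots of the reduced system for each CycT value:
# one batched Newton solve across the whole CycT grid x start grid
reduced_candidates <- function(p, ct_values, n_starts = 5,
                               res_tol = 1e-8, sep_tol = 1e-6) {
  fm <- seq(0, 1, length.out = n_starts)
  fq <- seq(0, 1, length.out = n_starts)
  s_m <- rep(fm, times = n_starts)
  s_q <- rep(fq, each = n_starts)
  S <- length(s_m)
  K <- length(ct_values)
  ct <- rep(ct_values, each = S)
  m <- ct * rep(s_m, times = K)
  q <- p[["PP2T"]] * rep(s_q, times = K)
  sol <- reduced_newton(m, q, ct, p)
  ok <- abs(sol$f1) < res_tol & abs(sol$f2) < res_tol
  idx <- rep(seq_len(K), each = S)
  lapply(seq_len(K), function(k) {
    sel <- which(ok & idx == k)
    if (!length(sel)) return(matrix(numeric(), ncol = 2))
    pts <- cbind(sol$m[sel], sol$q[sel])
    keep <- !duplicated(round(pts / sep_tol))
    pts[keep, , drop = FALSE]
  })
}

#' Enumerate all equilibria of the model
#'
#' Multi-start Newton on the reduced (MPF, PP2) system (see the file
#' header), vectorized over a `n_starts` x `n_starts` grid of starting
#' points plus any `extra_starts` (used for continuation seeding along
#' balance curves).  Distinct roots (state max-norm separation above
#' `merge_tol`) are polished by [find_steady_state()] and classified.
#'
#' @param params a `"mito_params"` vector or scenario label.
#' @param n_starts starts per axis of the (MPF, PP2) grid.
#' @param extra_starts list of additional starting states.
#' @param tol residual tolerance passed to the polish stage.
#' @param merge_tol duplicate-merging tolerance (state max-norm).
#' @return List of `"mito_equilibrium"` objects (possibly length 1).
#' @examples
#' eqs <- find_equilibria(default_parameters(CycT = 0.12))
#' length(eqs)   # three in the bistable window
#' @export
find_equilibria <- function(params, n_starts = 6, extra_starts = list(),
                            tol = 1e-10, merge_tol = 1e-6) {
  params <- as_parameters(params)
  validate_parameters(params)
  p <- setNames(as.numeric(params[.param_names]), .param_names)
  ct <- p[["CycT"]]; pt <- p[["PP2T"]]
  m <- rep(seq(0, ct, length.out = n_starts), times = n_starts)
  q <- rep(seq(0, pt, length.out = n_starts), each = n_starts)
  if (length(extra_starts)) {
    m <- c(m, vapply(extra_starts, function(s) min(s[["MPF"]], ct), 0))
    q <- c(q, vapply(extra_starts, function(s) min(s[["PP2"]], pt), 0))
  }
  sol <- reduced_newton(m, q, ct, p)
  ok <- which(abs(sol$f1) < 1e-8 & abs(sol$f2) < 1e-8)
  polish_candidates(cbind(sol$m[ok], sol$q[ok]), params, p,
                    tol = tol, merge_tol = merge_tol)
}

# reconstruct full states from reduced candidates, polish by 6-D Newton,
# drop failures and duplicates, classify stability
polish_candidates <- function(pts, params, p, tol = 1e-10,
                              merge_tol = 1e-6) {
  eqs <- list()
  for (i in seq_len(nrow(pts))) {
    s <- reduced_state(pts[i, 1], pts[i, 2], p)
    cand <- as.numeric(unlist(s))
    dup <- any(vapply(eqs, function(e)
      max(abs(as.numeric(e$state) - cand)) < merge_tol, TRUE))
    if (dup) next
    eq <- tryCatch(
      find_steady_state(params, setNames(cand, .state_names), tol = tol),
      error = function(e) NULL)
    if (is.null(eq)) next
    dup <- any(vapply(eqs, function(e)
      max(abs(as.numeric(e$state) - as.numeric(eq$state))) < merge_tol, TRUE))
    if (!dup) eqs[[length(eqs) + 1]] <- eq
  }
  eqs
}

# ---- balance curves -------------------------------------------------------

#' Balance curve: equilibria versus a control parameter
#'
#' Sweeps a control parameter (by default total Cyclin B, the natural
#' control since its level is untouched by the switch dynamics) over a
#' grid, enumerating all equilibria at each value with continuation
#' seeding from the neighbouring grid point, and locates saddle-node
#' folds by bisection on every interval where the equilibrium count
#' changes (to a parameter tolerance of `fold_tol`).
#'
#' @param scenario scenario label or `"mito_params"` vector.
#' @param control name of the swept parameter.
#' @param range length-2 numeric range of the sweep.
#' @param n number of grid points.
#' @param RO,OA inhibitor doses applied on top of the scenario.
#' @param fold_tol bisection tolerance for fold location.
#' @param n_starts multi-start density (see [find_equilibria()]).
#' @return A `"mito_branch"`: data frame with columns `control` (the
#'   parameter value), `index`, the six state coordinates, `preMPF`,
#'   `stable` and `leading_eigenvalue`; attributes `folds` (numeric
#'   vector of fold parameter values), `control_name`, `params`.
#' @examples
#' \donttest{
#' br <- balance_curve("pp2a_b55", n = 51)
#' attr(br, "folds")   # two saddle-node folds delimit the bistable window
#' }
#' @export
balance_curve <- function(scenario, control = "CycT", range = c(0, 1),
                          n = 101, RO = 0, OA = 0, fold_tol = 1e-4,
                          n_starts = 6) {
  params <- as_parameters(scenario, RO = RO, OA = OA)
  if (!control %in% .param_names)
    stop("unknown control parameter '", control, "'")
  if (length(range) != 2 || !all(is.finite(range)) || range[1] >= range[2])
    stop("'range' must be a finite increasing pair")
  grid <- seq(range[1], range[2], length.out = n)
  rows <- list(); counts <- integer(n)
  prev <- list()
  for (i in seq_len(n)) {
    pg <- set_parameters(params, validate = FALSE)
    pg[[control]] <- grid[i]
    eqs <- find_equilibria(pg, n_starts = n_starts,
                           extra_starts = lapply(prev, `[[`, "state"))
    counts[i] <- length(eqs)
    prev <- eqs
    for (k in seq_along(eqs)) {
      e <- eqs[[k]]
      rows[[length(rows) + 1]] <- data.frame(
        control = grid[i], index = k,
        as.list(setNames(as.numeric(e$state), .state_names)),
        preMPF = pg[["CycT"]] - e$state[["MPF"]],
        stable = e$stable,
        leading_eigenvalue = e$leading_eigenvalue)
    }
  }
  folds <- numeric()
  count_at <- function(x) {
    pg <- set_parameters(params, validate = FALSE)
    pg[[control]] <- x
    length(find_equilibria(pg, n_starts = n_starts))
  }
  for (i in seq_len(n - 1)) {
    if (counts[i] != counts[i + 1]) {
      lo <- grid[i]; hi <- grid[i + 1]
      clo <- counts[i]
      while (hi - lo > fold_tol) {
        mid <- (lo + hi) / 2
        if (count_at(mid) == clo) lo <- mid else hi <- mid
      }
      folds <- c(folds, (lo + hi) / 2)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, folds = folds, control_name = control, params = params,
            class = c("mito_branch", "data.frame"))
}

#' Bistable window of a balance curve
#'
#' @param branch a `"mito_branch"` from [balance_curve()].
#' @return Length-2 numeric (window limits in the control parameter), or
#'   `NULL` if the branch is monostable throughout.
#' @export
bistable_window <- function(branch) {
  folds <- attr(branch, "folds")
  if (length(folds) < 2) return(NULL)
  range(folds)
}

#' @export
print.mito_branch <- function(x, ...) {
  folds <- attr(x, "folds")
  cat(sprintf("Balance curve in %s: %d grid points, %d equilibria rows\n",
              attr(x, "control_name"), length(unique(x$control)), nrow(x)))
  if (length(folds))
    cat("  folds at ", paste(format(folds, digits = 5), collapse = ", "),
        "\n", sep = "")
  else cat("  no folds (monostable)\n")
  invisible(x)
}

#' Plot a balance curve
#'
#' @param x a `"mito_branch"`.
#' @param variable state coordinate (or `"preMPF"`) on the y axis.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mito_branch <- function(x, variable = "preMPF", ...) {
  graphics::plot(x$control, x[[variable]],
                 pch = ifelse(x$stable, 16, 1),
                 col = ifelse(x$stable, "black", "grey50"),
                 xlab = attr(x, "control_name"), ylab = variable, ...)
  for (f in attr(x, "folds")) graphics::abline(v = f, lty = 3)
  invisible(x)
}

#' Write a balance curve (and folds) to CSV
#'
#' @param branch a `"mito_branch"`.
#' @param path path of the branch CSV; folds go to a companion file with
#'   suffix `"_folds.csv"`.
#' @return Invisibly `path`.
#' @export
write_branch <- function(branch, path) {
  df <- as.data.frame(branch)
  write.table(format(df, digits = 15, trim = TRUE), path, sep = ",",
              quote = FALSE, row.names = FALSE)
  folds <- attr(branch, "folds")
  fold_path <- sub("\\.csv$", "_folds.csv", path)
  if (fold_path == path) fold_path <- paste0(path, "_folds.csv")
  write.table(
    data.frame(fold = seq_along(folds),
               value = format(folds, digits = 15)),
    fold_path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- bistability maps -----------------------------------------------------

#' Test a parameter set for bistability in total Cyclin B
#'
#' Scans total Cyclin B over `cyct` and reports whether two distinct
#' stable steady states coexist at any value: one batched reduced-Newton
#' solve over the whole CycT grid (see the file header), with full
#' polishing and eigenvalue classification only where multiple candidate
#' roots coexist.
#'
#' @param params a `"mito_params"` vector or scenario label.
#' @param cyct CycT values probed.
#' @param n_starts multi-start density per axis.
#' @return `TRUE`, `FALSE`, or `NA` if the solver failed.
#' @examples
#' is_bistable(default_parameters())            # reference set: bistable
#' is_bistable(default_parameters(kiensa = 0))  # degenerate limit: not
#' @export
is_bistable <- function(params, cyct = seq(0.02, 1, by = 0.01),
                        n_starts = 5) {
  params <- as_parameters(params)
  p <- setNames(as.numeric(params[.param_names]), .param_names)
  cands <- tryCatch(reduced_candidates(p, cyct, n_starts = n_starts),
                    error = function(e) NULL)
  if (is.null(cands)) return(NA)
  counts <- vapply(cands, nrow, 0L)
  for (k in order(-counts)) {
    if (counts[k] < 2) break
    pg <- set_parameters(params, CycT = cyct[k], validate = FALSE)
    eqs <- polish_candidates(cands[[k]], pg, replace(p, "CycT", cyct[k]))
    if (sum(vapply(eqs, `[[`, TRUE, "stable")) >= 2) return(TRUE)
  }
  FALSE
}

#' Two-parameter bistability map
#'
#' Classifies each cell of a two-parameter grid as bistable or
#' monostable: a cell is bistable when the balance sweep in total Cyclin
#' B over `cyct` finds two coexisting stable steady states at some CycT.
#' Solver failures are recorded as `NA` ("unknown"), never silently
#' monostable.
#'
#' @param scenario scenario label or `"mito_params"` vector.
#' @param param_x,param_y names of the two swept parameters.
#' @param x_values,y_values grids for the two parameters.
#' @param cyct CycT values probed within each cell.
#' @return A `"mito_region"`: data frame with `x`, `y`, `bistable`
#'   (logical, `NA` = unknown); attribute `boundary` holds a polyline
#'   (list of data frames) tracing the bistable/monostable interface.
#' @examples
#' \donttest{
#' rg <- bistability_region("pp2a_b55", "kagwl", "kiensa",
#'                          c(2, 5, 10), c(0, 0.6, 1.5, 2.5))
#' all(rg$bistable)
#' }
#' @export
bistability_region <- function(scenario, param_x, param_y, x_values,
                               y_values, cyct = seq(0.02, 1, by = 0.01)) {
  params <- as_parameters(scenario)
  for (nm in c(param_x, param_y))
    if (!nm %in% .param_names) stop("unknown parameter '", nm, "'")
  if (!all(is.finite(c(x_values, y_values))) ||
      any(c(x_values, y_values) < 0))
    stop("parameter grids must be finite and non-negative")
  grid <- expand.grid(x = x_values, y = y_values)
  bist <- logical(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    pg <- params
    pg[[param_x]] <- grid$x[i]
    pg[[param_y]] <- grid$y[i]
    bist[i] <- is_bistable(pg, cyct = cyct)
  }
  out <- data.frame(x = grid$x, y = grid$y, bistable = bist)
  names(out)[1:2] <- c(param_x, param_y)
  z <- matrix(as.numeric(bist), nrow = length(x_values))
  boundary <- if (length(x_values) > 1 && length(y_values) > 1 &&
                  !anyNA(z) && length(unique(as.vector(z))) > 1)
    lapply(grDevices::contourLines(x_values, y_values, z, levels = 0.5),
           function(cl) data.frame(x = cl$x, y = cl$y))
  else list()
  structure(out, boundary = boundary, class = c("mito_region", "data.frame"))
}
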