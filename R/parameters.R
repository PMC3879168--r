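# Parameter handling: defaults, scenario presets, validation, key=value I/O.
#
# All quantities are in dimensionless model units. Primed symbols from the
# original rate law notation are spelled with ASCII suffixes: kigwl_p is
# kigwl', kigwl_pp is kigwl'' (and likewise k25_p/k25_pp, kwee_p/kwee_pp).

.param_names <- c(
  "CycT", "Va25", "Vi25", "Vawee", "Viwee",
  "kagwl", "kigwl_p", "kigwl_pp", "kigwl", "kaensa", "kiensa",
  "kas", "kdis",
  "Cdc25T", "Wee1T", "GwlT", "ENSAT", "PP2T",
  "k25_p", "k25_pp", "kwee_p", "kwee_pp",
  "RO", "OA")

.state_names <- c("MPF", "Cdc25", "Wee1", "Gwl", "ENSAPt", "PP2")
.obs_names <- c("MPFa", "PP2a", "preMPF", "complex")

# primed aliases accepted when parsing parameter files
.param_aliases <- c(
  "kigwl′" = "kigwl_p",  "kigwl'"  = "kigwl_p",
  "kigwl″" = "kigwl_pp", "kigwl''" = "kigwl_pp",
  "k25′"   = "k25_p",    "k25'"    = "k25_p",
  "k25″"   = "k25_pp",   "k25''"   = "k25_pp",
  "kwee′"  = "kwee_p",   "kwee'"   = "kwee_p",
  "kwee″"  = "kwee_pp",  "kwee''"  = "kwee_pp",
  "CycBT" = "CycT", "PP2t" = "PP2T")

.primed_symbol <- c(
  kigwl_p = "kigwl'", kigwl_pp = "kigwl''",
  k25_p = "k25'", k25_pp = "k25''",
  kwee_p = "kwee'", kwee_pp = "kwee''")

.scenario_labels <- c("pp2a_b55", "oa_insensitive", "oa_sensitive")

#' Default model parameters
#'
#' The reference parameter set of the switch model: total concentrations of
#' Cdc25, Wee1, Gwl and ENSA equal to 1, total PP2A/B55 (`PP2T = 0.5`) kept
#' below its stoichiometric inhibitor ENSA, symmetric Cdc25/Wee1
#' (de)phosphorylation rates, a 100-fold activity ratio between modified and
#' unmodified Cdc25/Wee1 (`k25_p = kwee_p = 0.01`, `k25_pp = kwee_pp = 1`),
#' tight ENSA-P:PP2A binding (`kas = 100`, `kdis = 1`), and inhibitor doses
#' `RO` (Cdk1 inhibitor) and `OA` (okadaic acid) of zero.  This preset
#' corresponds to Gwl dephosphorylation by PP2A/B55 (`kigwl = 2`,
#' `kigwl_p = 0.02`, `kigwl_pp = 0`); see [scenario_parameters()] for the
#' other two Gwl-phosphatase assumptions.
#'
#' @param ... named overrides of individual parameters, e.g. `CycT = 0.5`.
#' @return A named numeric vector of class `"mito_params"` with the 24
#'   model parameters.
#' @examples
#' p <- default_parameters()
#' p["PP2T"]
#' default_parameters(RO = 25)["RO"]
#' @seealso [scenario_parameters()], [validate_parameters()]
#' @export
default_parameters <- function(...) {
  p <- c(
    CycT = 1, Va25 = 2, Vi25 = 2, Vawee = 2, Viwee = 2,
    kagwl = 10, kigwl_p = 0.02, kigwl_pp = 0, kigwl = 2,
    kaensa = 2, kiensa = 0.6,
    kas = 100, kdis = 1,
    Cdc25T = 1, Wee1T = 1, GwlT = 1, ENSAT = 1, PP2T = 0.5,
    k25_p = 0.01, k25_pp = 1, kwee_p = 0.01, kwee_pp = 1,
    RO = 0, OA = 0)
  class(p) <- "mito_params"
  if (...length() > 0) p <- set_parameters(p, ...)
  p
}

#' Modify parameters by name
#'
#' @param params a `"mito_params"` vector.
#' @param ... named numeric overrides.
#' @param validate check invariants after modification (default `TRUE`).
#' @return The modified parameter vector.
#' @export
set_parameters <- function(params, ..., validate = TRUE) {
  ov <- list(...)
  if (length(ov) == 0) return(params)
  nm <- names(ov)
  if (is.null(nm) || any(nm == ""))
    stop("parameter overrides must be named")
  unknown <- setdiff(nm, .param_names)
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  params[nm] <- as.numeric(unlist(ov))
  if (validate) validate_parameters(params)
  params
}

#' Gwl-phosphatase scenario presets
#'
#' The phosphatase that removes the activating Cdk1 phosphorylation of
#' Greatwall is not established; three variants of the model cover the
#' possibilities, all sharing the default parameter set except for the
#' route of Gwl inactivation:
#'
#' * `"pp2a_b55"`: Gwl is dephosphorylated by PP2A/B55 itself
#'   (`kigwl = 2`, the default preset).  This closes an additional
#'   double-negative feedback loop Gwl -| PP2A/B55 -| Gwl.
#' * `"oa_insensitive"`: an okadaic-acid-insensitive phosphatase
#'   (`kigwl_p = 2`, `kigwl = 0`); Gwl inactivation is constitutive.
#' * `"oa_sensitive"`: an OA-sensitive phosphatase (PP2A) outside the B55
#'   feedback (`kigwl_pp = 2`, `kigwl = 0`); the activity scales with
#'   total PP2A and the okadaic acid dose but not with ENSA sequestration.
#'
#' @param scenario one of `"pp2a_b55"`, `"oa_insensitive"`,
#'   `"oa_sensitive"` (hyphens accepted in place of underscores).
#' @param ... further named parameter overrides applied after the scenario
#'   preset (e.g. inhibitor doses `RO`, `OA`).
#' @return A `"mito_params"` vector with attribute `"scenario"`.
#' @examples
#' scenario_parameters("oa_insensitive")[c("kigwl_p", "kigwl_pp", "kigwl")]
#' scenario_parameters("oa_sensitive", RO = 25, OA = 100)
#' @export
scenario_parameters <- function(scenario = .scenario_labels, ...) {
  scenario <- normalize_scenario(scenario)
  p <- switch(scenario,
    pp2a_b55 = default_parameters(),
    oa_insensitive = default_parameters(kigwl_p = 2, kigwl = 0),
    oa_sensitive = default_parameters(kigwl_pp = 2, kigwl = 0))
  p <- set_parameters(p, ...)
  attr(p, "scenario") <- scenario
  p
}

normalize_scenario <- function(scenario) {
  if (inherits(scenario, "mito_params")) return(scenario)
  if (!is.character(scenario))
    stop("'scenario' must be a scenario label or a mito_params vector")
  s <- gsub("-", "_", tolower(scenario[1]), fixed = TRUE)
  if (length(scenario) > 1) s <- match.arg(s, .scenario_labels)
  if (!s %in% .scenario_labels)
    stop("unknown scenario '", scenario[1], "'; valid labels: ",
         paste(.scenario_labels, collapse = ", "))
  s
}

# resolve a scenario label or parameter vector to parameters
as_parameters <- function(scenario, ...) {
  if (inherits(scenario, "mito_params")) {
    set_parameters(scenario, ...)
  } else {
    scenario_parameters(scenario, ...)
  }
}

#' Validate a parameter vector
#'
#' Checks that all 24 parameters are present, finite and non-negative, and
#' that total PP2A/B55 stays below total ENSA (the phosphatase must remain
#' substoichiometric to its inhibitor for full sequestration to be
#' possible).
#'
#' @param params a `"mito_params"` vector.
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_parameters <- function(params) {
  missing <- setdiff(.param_names, names(params))
  if (length(missing))
    stop("missing parameter(s): ", paste(missing, collapse = ", "))
  v <- as.numeric(params[.param_names])
  if (any(!is.finite(v)))
    stop("non-finite parameter(s): ",
         paste(.param_names[!is.finite(v)], collapse = ", "))
  if (any(v < 0))
    stop("negative parameter(s): ",
         paste(.param_names[v < 0], collapse = ", "))
  if (params[["PP2T"]] >= params[["ENSAT"]])
    stop("PP2T must be < ENSAT (PP2A/B55 substoichiometric to ENSA)")
  invisible(TRUE)
}

#' @export
print.mito_params <- function(x, ...) {
  sc <- attr(x, "scenario")
  cat("Mitotic-switch model parameters",
      if (!is.null(sc)) paste0(" (scenario: ", sc, ")"), "\n", sep = "")
  print(setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Write parameters as a flat key = value file
#'
#' The file uses one `name = value` line per parameter; parameters whose
#' conventional symbols carry primes are annotated with the primed form in
#' a trailing comment.  [read_parameters()] restores the exact values
#' (round trip at full double precision).
#'
#' @param params a `"mito_params"` vector.
#' @param path output file path.
#' @return Invisibly `path`.
#' @export
write_parameters <- function(params, path) {
  validate_parameters(params)
  sc <- attr(params, "scenario")
  lines <- c(
    "# mitoswitch model parameters (dimensionless units)",
    if (!is.null(sc)) paste0("# scenario: ", sc))
  for (nm in .param_names) {
    val <- format(params[[nm]], digits = 17)
    cmt <- if (nm %in% names(.primed_symbol))
      paste0("  # ", .primed_symbol[[nm]]) else ""
    lines <- c(lines, paste0(nm, " = ", val, cmt))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read parameters from a key = value file
#'
#' Accepts the format written by [write_parameters()].  Primed symbol
#' spellings (`kigwl'`, unicode primes, `PP2t`, `CycBT`) are accepted as
#' aliases of the ASCII names.
#'
#' @param path file path.
#' @return A validated `"mito_params"` vector.
#' @export
read_parameters <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  p <- default_parameters()
  seen <- character()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2)
      stop("cannot parse parameter line: '", ln, "'")
    key <- trimws(kv[1])
    if (key %in% names(.param_aliases)) key <- .param_aliases[[key]]
    if (!key %in% .param_names)
      stop("unknown parameter '", key, "' in ", path)
    val <- suppressWarnings(as.numeric(trimws(kv[2])))
    if (!is.finite(val))
      stop("non-numeric value for '", key, "' in ", path)
    p[[key]] <- val
    seen <- c(seen, key)
  }
  validate_parameters(p)
  p
}
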