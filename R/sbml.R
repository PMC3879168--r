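# Optional SBML Level 3 export (rate-rule form). Additive convenience for
# interoperability with other simulators; nothing in the package depends
# on it. Requires the 'xml2' package.

#' Export the model as SBML Level 3 (rate rules)
#'
#' Writes an SBML L3V2 document in which each of the six state variables
#' is a boundary species governed by a rate rule transcribing
#' [model_rhs()], and every parameter (plus the derived `MPFa`/`PP2a`
#' activities as assignment rules) is declared.  Primed rate-constant
#' symbols keep their ASCII spelling (`kigwl_p` for kigwl').
#'
#' @param params a `"mito_params"` vector or scenario label.
#' @param path output file path.
#' @param initial_state initial condition recorded in the document.
#' @return Invisibly `path`.
#' @export
export_sbml <- function(params, path, initial_state = g2_state()) {
  if (!requireNamespace("xml2", quietly = TRUE))
    stop("SBML export requires the 'xml2' package")
  params <- as_parameters(params)
  validate_parameters(params)
  s0 <- model_state(initial_state)

  rate_laws <- c(
    MPF = paste0("(k25_p*(Cdc25T-Cdc25)+k25_pp*Cdc25)*(CycT-MPF)",
                 "-(kwee_p*(Wee1T-Wee1)+kwee_pp*Wee1)*MPF"),
    Cdc25 = "Va25*MPFa*(Cdc25T-Cdc25)-Vi25*PP2a*Cdc25",
    Wee1 = "Vawee*PP2a*(Wee1T-Wee1)-Viwee*MPFa*Wee1",
    Gwl = paste0("kagwl*MPFa*(GwlT-Gwl)",
                 "-(kigwl_p+kigwl_pp*PP2T/(1+OA)+kigwl*PP2a)*Gwl"),
    ENSAPt = "kaensa*Gwl*(ENSAT-ENSAPt)-kiensa*ENSAPt",
    PP2 = "-kas*(ENSAPt-(PP2T-PP2))*PP2+(kdis+kiensa)*(PP2T-PP2)")
  assignments <- c(MPFa = "MPF/(1+RO)", PP2a = "PP2/(1+OA)")

  doc <- xml2::xml_new_root(
    "sbml", xmlns = "http://www.sbml.org/sbml/level3/version2/core",
    level = "3", version = "2")
  model <- xml2::xml_add_child(doc, "model", id = "mitoswitch",
                               name = "Mitotic Cdk1-Gwl-PP2A/B55 switch")
  comps <- xml2::xml_add_child(model, "listOfCompartments")
  xml2::xml_add_child(comps, "compartment", id = "cell", size = "1",
                      constant = "true")
  species <- xml2::xml_add_child(model, "listOfSpecies")
  for (nm in .state_names)
    xml2::xml_add_child(species, "species", id = nm, compartment = "cell",
                        initialConcentration =
                          format(s0[[nm]], digits = 17),
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = "true", constant = "false")
  pars <- xml2::xml_add_child(model, "listOfParameters")
  for (nm in .param_names)
    xml2::xml_add_child(pars, "parameter", id = nm,
                        value = format(params[[nm]], digits = 17),
                        constant = "true")
  for (nm in names(assignments))
    xml2::xml_add_child(pars, "parameter", id = nm, constant = "false")
  rules <- xml2::xml_add_child(model, "listOfRules")
  for (nm in names(assignments)) {
    rule <- xml2::xml_add_child(rules, "assignmentRule", variable = nm)
    add_mathml(rule, assignments[[nm]])
  }
  for (nm in .state_names) {
    rule <- xml2::xml_add_child(rules, "rateRule", variable = nm)
    add_mathml(rule, rate_laws[[nm]])
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

# translate an R arithmetic expression string into content MathML
add_mathml <- function(node, expr_text) {
  math <- xml2::xml_add_child(node, "math",
                              xmlns = "http://www.w3.org/1998/Math/MathML")
  build_mathml(math, str2lang(expr_text))
  math
}

build_mathml <- function(parent, e) {
  if (is.numeric(e)) {
    xml2::xml_add_child(parent, "cn", format(e, digits = 17))
  } else if (is.name(e)) {
    xml2::xml_add_child(parent, "ci", as.character(e))
  } else if (is.call(e)) {
    op <- as.character(e[[1]])
    if (op == "(") return(build_mathml(parent, e[[2]]))
    tag <- switch(op, "+" = "plus", "-" = "minus", "*" = "times",
                  "/" = "divide",
                  stop("unsupported operator '", op, "' in SBML export"))
    node <- xml2::xml_add_child(parent, "apply")
    xml2::xml_add_child(node, tag)
    for (arg in as.list(e)[-1]) build_mathml(node, arg)
  } else stop("unsupported expression in SBML export")
}
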