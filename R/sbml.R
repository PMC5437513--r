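# SBML Level 3 Version 1 export of the model, for exchange with
# simulation environments and cross-checking against deposited
# parameterizations.  The writer emits compartments, species, global
# parameters and reactions with MathML kinetic laws; a small MathML
# reader evaluates exported laws numerically for round-trip checks.

.sbml_id <- function(x) {
  x <- gsub("\\*\\*$", "_tt", x)
  gsub("\\*$", "_t", x)
}

#' Export the model as SBML L3V1
#'
#' @param model an [build_model()] object.
#' @param path output file (.xml).
#' @return the path, invisibly.
#' @export
export_sbml <- function(model, path) {
  stopifnot(inherits(model, "iron_model"))
  doc <- xml2::xml_new_root(
    "sbml", xmlns = "http://www.sbml.org/sbml/level3/version1/core",
    level = "3", version = "1")
  mdl <- xml2::xml_add_child(doc, "model", id = "mouse_iron_distribution",
                             timeUnits = "time", substanceUnits = "mole")
  lc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (i in seq_len(nrow(model$compartments))) {
    co <- model$compartments[i, ]
    xml2::xml_add_child(lc, "compartment", id = co$name,
                        size = format(if (is.na(co$volume)) 1 else co$volume,
                                      digits = 15),
                        constant = "true", spatialDimensions = "3")
  }
  ls <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$species))) {
    sp <- model$species[i, ]
    xml2::xml_add_child(ls, "species", id = .sbml_id(sp$name),
                        name = sp$name, compartment = sp$compartment,
                        initialConcentration = "0",
                        hasOnlySubstanceUnits =
                          if (sp$unit == "amount") "true" else "false",
                        boundaryCondition = "false", constant = "false")
  }
  lp <- xml2::xml_add_child(mdl, "listOfParameters")
  for (nm in names(model$params))
    xml2::xml_add_child(lp, "parameter", id = nm,
                        value = format(model$params[[nm]], digits = 15),
                        constant = "true")
  lr <- xml2::xml_add_child(mdl, "listOfReactions")
  for (r in model$reactions) {
    rn <- xml2::xml_add_child(lr, "reaction", id = r$name,
                              reversible = "false")
    if (length(r$reactants)) {
      lre <- xml2::xml_add_child(rn, "listOfReactants")
      for (s in names(r$reactants))
        xml2::xml_add_child(lre, "speciesReference",
                            species = .sbml_id(s),
                            stoichiometry = format(r$reactants[[s]]),
                            constant = "true")
    }
    if (length(r$products)) {
      lpr <- xml2::xml_add_child(rn, "listOfProducts")
      for (s in names(r$products))
        xml2::xml_add_child(lpr, "speciesReference",
                            species = .sbml_id(s),
                            stoichiometry = format(r$products[[s]]),
                            constant = "true")
    }
    kl <- xml2::xml_add_child(rn, "kineticLaw")
    math <- xml2::xml_add_child(kl, "math",
                                xmlns = "http://www.w3.org/1998/Math/MathML")
    .add_mathml(math, .rate_expression(r))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

# rate law as a nested list expression: list(op, args...) | name | number
.rate_expression <- function(r) {
  switch(r$kind,
    constant = list("times", r$par, r$comp),
    mass_action = list("times", r$par, r$substrate, r$comp),
    bimolecular = {
      ab <- names(r$reactants)
      list("times", r$par, ab[1], ab[2], r$comp)
    },
    ferroportin = {
      den1 <- if (is.null(r$competitor))
        list("plus", "Km", r$substrate)
      else list("plus", "Km", r$substrate, r$competitor)
      list("divide",
           list("times", r$par, r$comp, r$substrate),
           list("times", den1,
                list("plus", 1,
                     list("divide", "Hepcidin", "Ki")))) },
    stop("unknown rate-law kind: ", r$kind)
  )
}

.add_mathml <- function(parent, expr) {
  if (is.list(expr)) {
    ap <- xml2::xml_add_child(parent, "apply")
    xml2::xml_add_child(ap, expr[[1]])
    for (a in expr[-1]) .add_mathml(ap, a)
  } else if (is.numeric(expr)) {
    cn <- xml2::xml_add_child(parent, "cn")
    xml2::xml_text(cn) <- format(expr, digits = 15)
  } else {
    ci <- xml2::xml_add_child(parent, "ci")
    xml2::xml_text(ci) <- .sbml_id(expr)
  }
  invisible(parent)
}

#' Read back an exported SBML model
#'
#' A light reader for round-trip checks: returns species ids/names,
#' compartment sizes, parameter values and, per reaction, a function that
#' evaluates the MathML kinetic law numerically given an environment of
#' species concentrations.
#'
#' @param path SBML file written by [export_sbml()].
#' @return list with `species` (data.frame id/name/compartment),
#'   `parameters` (named vector), `compartments` (named vector), and
#'   `kinetic_law(reaction_id, env)` evaluator.
#' @export
read_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          m = "http://www.w3.org/1998/Math/MathML")
  spn <- xml2::xml_find_all(doc, ".//s:species", ns)
  species <- data.frame(
    id = xml2::xml_attr(spn, "id"),
    name = xml2::xml_attr(spn, "name"),
    compartment = xml2::xml_attr(spn, "compartment"),
    stringsAsFactors = FALSE)
  prn <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  parameters <- setNames(as.numeric(xml2::xml_attr(prn, "value")),
                         xml2::xml_attr(prn, "id"))
  cpn <- xml2::xml_find_all(doc, ".//s:compartment", ns)
  compartments <- setNames(as.numeric(xml2::xml_attr(cpn, "size")),
                           xml2::xml_attr(cpn, "id"))
  eval_math <- function(node, env) {
    nm <- xml2::xml_name(node)
    if (nm == "ci") {
      key <- trimws(xml2::xml_text(node))
      if (!key %in% names(env)) stop("unbound symbol in kinetic law: ", key)
      return(env[[key]])
    }
    if (nm == "cn") return(as.numeric(xml2::xml_text(node)))
    if (nm == "apply") {
      kids <- xml2::xml_children(node)
      op <- xml2::xml_name(kids[[1]])
      args <- vapply(kids[-1], eval_math, numeric(1), env = env)
      return(switch(op,
                    times = prod(args),
                    plus = sum(args),
                    divide = args[1] / args[2],
                    minus = if (length(args) == 1) -args[1] else args[1] - args[2],
                    stop("unsupported MathML operator: ", op)))
    }
    stop("unsupported MathML node: ", nm)
  }
  kinetic_law <- function(reaction_id, env) {
    rn <- xml2::xml_find_first(
      doc, sprintf(".//s:reaction[@id='%s']/s:kineticLaw/m:math/*", reaction_id), ns)
    if (inherits(rn, "xml_missing")) stop("no such reaction: ", reaction_id)
    full <- c(as.list(parameters), as.list(compartments), as.list(env))
    eval_math(rn, full)
  }
  list(species = species, parameters = parameters,
       compartments = compartments, kinetic_law = kinetic_law)
}
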