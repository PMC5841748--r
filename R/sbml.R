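#' Export a model as SBML-qual
#'
#' Writes an SBML Level 3 Version 1 document using the qualitative-models
#' package: one binary qualitative species per node and one transition per
#' rule, with the rule's Boolean expression as the MathML condition for
#' result level 1. Temporal window operators have no SBML-qual counterpart:
#' exporting a model that contains them is an error unless
#' `approximate = TRUE`, in which case each window term is replaced by its
#' plain current-time atom and the document is annotated as an
#' instantaneous approximation.
#'
#' @param model A `network_model`.
#' @param file Output path.
#' @param approximate Replace window terms by plain atoms (see above).
#' @return The path, invisibly.
#' @export
export_sbml_qual <- function(model, file, approximate = FALSE) {
  validate_model(model)
  if (!approximate) {
    temporal <- vapply(model$rules, function(r)
      expr_max_width(r$expr, model$parameters) > 0L, logical(1))
    if (any(temporal))
      stop(sprintf(paste0("rule for '%s' contains temporal window operators, ",
                          "which SBML-qual cannot represent; set ",
                          "approximate = TRUE for an instantaneous ",
                          "approximation"),
                   names(model$rules)[temporal][1]), call. = FALSE)
  }

  sbml_ns <- "http://www.sbml.org/sbml/level3/version1/core"
  qual_ns <- "http://www.sbml.org/sbml/level3/version1/qual/version1"
  math_ns <- "http://www.w3.org/1998/Math/MathML"

  doc <- xml2::xml_new_root("sbml",
                            xmlns = sbml_ns, "xmlns:qual" = qual_ns,
                            level = "3", version = "1",
                            "qual:required" = "true")
  mdl <- xml2::xml_add_child(doc, "model",
                             id = gsub("[^A-Za-z0-9_]", "_",
                                       model$metadata$title %||% "model"))
  if (approximate) {
    notes <- xml2::xml_add_child(mdl, "notes")
    body <- xml2::xml_add_child(notes, "body",
                                xmlns = "http://www.w3.org/1999/xhtml")
    xml2::xml_add_child(body, "p", paste(
      "Instantaneous approximation: temporal window operators of the source",
      "model were replaced by the current value of the referenced node."))
  }
  comps <- xml2::xml_add_child(mdl, "listOfCompartments")
  xml2::xml_add_child(comps, "compartment", id = "default", constant = "true")

  species <- xml2::xml_add_child(mdl, "qual:listOfQualitativeSpecies")
  for (nm in model_nodes(model))
    xml2::xml_add_child(species, "qual:qualitativeSpecies",
                        "qual:id" = nm, "qual:compartment" = "default",
                        "qual:constant" = "false", "qual:maxLevel" = "1")

  transitions <- xml2::xml_add_child(mdl, "qual:listOfTransitions")
  for (rule in model$rules) {
    expr <- if (approximate) strip_windows(rule$expr) else rule$expr
    tr <- xml2::xml_add_child(transitions, "qual:transition",
                              "qual:id" = paste0("tr_", rule$target))
    regs <- expr_occurrences(expr, negated = FALSE)
    if (nrow(regs)) {
      inputs <- xml2::xml_add_child(tr, "qual:listOfInputs")
      regs <- unique(regs["node"])
      for (reg in regs$node)
        xml2::xml_add_child(inputs, "qual:input",
                            "qual:qualitativeSpecies" = reg,
                            "qual:transitionEffect" = "none")
    }
    outputs <- xml2::xml_add_child(tr, "qual:listOfOutputs")
    xml2::xml_add_child(outputs, "qual:output",
                        "qual:qualitativeSpecies" = rule$target,
                        "qual:transitionEffect" = "assignmentLevel")
    fts <- xml2::xml_add_child(tr, "qual:listOfFunctionTerms")
    xml2::xml_add_child(fts, "qual:defaultTerm", "qual:resultLevel" = "0")
    ft <- xml2::xml_add_child(fts, "qual:functionTerm",
                              "qual:resultLevel" = "1")
    math <- xml2::xml_add_child(ft, "math", xmlns = math_ns)
    add_mathml(math, expr)
  }
  xml2::write_xml(doc, file)
  invisible(file)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Replace window terms by their plain atoms.
strip_windows <- function(expr) {
  switch(expr$type,
    atom = expr,
    not  = bn_not(strip_windows(expr$child)),
    and  = nary("and", lapply(expr$children, strip_windows)),
    or   = nary("or", lapply(expr$children, strip_windows)),
    all  = ,
    any  = bn_atom(expr$node)
  )
}

# Append the MathML encoding of a (temporal-free) expression to `parent`.
add_mathml <- function(parent, expr) {
  switch(expr$type,
    atom = {
      ap <- xml2::xml_add_child(parent, "apply")
      xml2::xml_add_child(ap, "eq")
      xml2::xml_add_child(ap, "ci", expr$node)
      cn <- xml2::xml_add_child(ap, "cn", "1")
      xml2::xml_set_attr(cn, "type", "integer")
    },
    not = {
      ap <- xml2::xml_add_child(parent, "apply")
      xml2::xml_add_child(ap, "not")
      add_mathml(ap, expr$child)
    },
    and = ,
    or = {
      ap <- xml2::xml_add_child(parent, "apply")
      xml2::xml_add_child(ap, expr$type)
      for (ch in expr$children) add_mathml(ap, ch)
    },
    stop("temporal operators cannot be encoded in SBML-qual", call. = FALSE)
  )
}
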