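# SBML Level 2 subset reader and writer. The supported subset is: species
# with integer-interpretable initial amounts, global and reaction-local
# parameters, and reactions whose kinetic laws are MathML expressions built
# from times/plus/minus/divide/power over <ci>/<cn>. Events, rules,
# function definitions and compartments with volume != 1 are rejected by
# name, since copy-number semantics are the only ones this package defines.

mathml_to_expr <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "math") {
    kids <- xml2::xml_children(node)
    if (length(kids) != 1L) stop("unsupported-construct: empty math element")
    return(mathml_to_expr(kids[[1L]]))
  }
  if (nm == "ci") return(trimws(xml2::xml_text(node)))
  if (nm == "cn") {
    type <- xml2::xml_attr(node, "type")
    if (!is.na(type) && !(type %in% c("integer", "real")))
      stop("unsupported-construct: cn type ", type)
    return(trimws(xml2::xml_text(node)))
  }
  if (nm != "apply") stop("unsupported-construct: MathML element ", nm)
  kids <- xml2::xml_children(node)
  op <- xml2::xml_name(kids[[1L]])
  args <- lapply(kids[-1L], mathml_to_expr)
  paren <- function(s) paste0("(", s, ")")
  switch(op,
    times = paren(paste(unlist(args), collapse = " * ")),
    plus = paren(paste(unlist(args), collapse = " + ")),
    minus = if (length(args) == 1L) paren(paste0("-", args[[1L]]))
            else paren(paste(unlist(args), collapse = " - ")),
    divide = paren(paste(unlist(args), collapse = " / ")),
    power = paren(paste(unlist(args), collapse = " ^ ")),
    stop("unsupported-construct: MathML operator ", op))
}

#' Import an SBML Level 2 subset document
#'
#' Reads a restricted SBML Level 2 model into an [ssa_model()]: species
#' initial amounts are interpreted as copy numbers, `boundaryCondition`
#' species become fixed species, and kinetic laws become expression rate
#' laws (a law that is a single parameter identifier becomes a mass-action
#' constant). Documents containing events, rules, function definitions, or
#' compartments with volume other than 1 raise an unsupported-construct
#' error naming the construct.
#'
#' @param path Path to the SBML file (or a string of XML).
#' @param round_amounts If `TRUE`, non-integer `initialAmount` values are
#'   rounded with a warning instead of raising an error.
#' @param allow_volume If `TRUE`, compartments with volume other than 1 are
#'   accepted and ignored (copy-number reinterpretation).
#' @return An `ssa_model`.
#' @export
import_sbml_subset <- function(path, round_amounts = FALSE,
                               allow_volume = FALSE) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  if (xml2::xml_name(doc) != "sbml") stop("not an SBML document")
  level <- xml2::xml_attr(doc, "level")
  if (!is.na(level) && level != "2")
    stop("unsupported-construct: SBML level ", level)
  for (construct in c("event", "assignmentRule", "algebraicRule",
                      "rateRule", "functionDefinition")) {
    if (length(xml2::xml_find_all(doc, paste0("//", construct))))
      stop("unsupported-construct: ", construct)
  }
  for (comp in xml2::xml_find_all(doc, "//listOfCompartments/compartment")) {
    size <- xml2::xml_attr(comp, "size")
    if (!is.na(size) && as.numeric(size) != 1 && !allow_volume)
      stop("unsupported-construct: compartment volume ", size,
           " (set allow_volume = TRUE for copy-number reinterpretation)")
  }
  species <- list()
  for (sp in xml2::xml_find_all(doc, "//listOfSpecies/species")) {
    id <- xml2::xml_attr(sp, "id")
    amt <- as.numeric(xml2::xml_attr(sp, "initialAmount"))
    if (is.na(amt)) stop("species '", id, "' has no initialAmount")
    if (amt != round(amt)) {
      if (!round_amounts)
        stop("species '", id, "' initialAmount ", amt, " is not an ",
             "integer copy number (set round_amounts = TRUE to round)")
      warning("rounding initialAmount of '", id, "' from ", amt, " to ",
              round(amt))
      amt <- round(amt)
    }
    fixed <- identical(xml2::xml_attr(sp, "boundaryCondition"), "true")
    species[[length(species) + 1L]] <- ssa_species(id, amt, fixed = fixed)
  }
  parameters <- numeric(0)
  for (pa in xml2::xml_find_all(doc, "//model/listOfParameters/parameter")) {
    parameters[[xml2::xml_attr(pa, "id")]] <-
      as.numeric(xml2::xml_attr(pa, "value"))
  }
  reactions <- list()
  for (rx in xml2::xml_find_all(doc, "//listOfReactions/reaction")) {
    id <- xml2::xml_attr(rx, "id")
    get_side <- function(tag) {
      refs <- xml2::xml_find_all(rx, paste0(tag, "/speciesReference"))
      if (!length(refs)) return(NULL)
      st <- vapply(refs, function(r) {
        s <- xml2::xml_attr(r, "stoichiometry")
        if (is.na(s)) 1 else as.numeric(s)
      }, 0)
      stats::setNames(as.integer(st),
                      vapply(refs, xml2::xml_attr, "", "species"))
    }
    kl <- xml2::xml_find_first(rx, "kineticLaw")
    if (inherits(kl, "xml_missing"))
      stop("reaction '", id, "' has no kineticLaw")
    for (pa in xml2::xml_find_all(kl, "listOfParameters/parameter")) {
      pid <- xml2::xml_attr(pa, "id")
      pval <- as.numeric(xml2::xml_attr(pa, "value"))
      if (pid %in% names(parameters) && parameters[[pid]] != pval)
        stop("local parameter '", pid, "' conflicts with a global value")
      parameters[[pid]] <- pval
    }
    math <- xml2::xml_find_first(kl, "math")
    if (inherits(math, "xml_missing"))
      stop("reaction '", id, "' kineticLaw has no math element")
    expr <- mathml_to_expr(math)
    bare <- gsub("[() ]", "", expr)
    rate <- if (grepl("^[A-Za-z][A-Za-z0-9_]*$", bare) &&
                bare %in% names(parameters)) parameters[[bare]]
            else if (grepl("^[0-9.eE+-]+$", bare) &&
                     !is.na(suppressWarnings(as.numeric(bare))))
              as.numeric(bare)
            else expr
    reactions[[length(reactions) + 1L]] <-
      ssa_reaction(id, get_side("listOfReactants"),
                   get_side("listOfProducts"), rate)
  }
  ssa_model(species, reactions, parameters)
}

#' Export a model to the SBML Level 2 subset
#'
#' Writes the same subset [import_sbml_subset()] reads: species with
#' integer initial amounts in a unit compartment, global parameters, and
#' reactions with MathML kinetic laws equal to the model's propensity
#' expressions (mass-action laws are expanded to explicit products of the
#' rate constant and reactant counts, valid for multiplicity-1 reactants).
#'
#' @param model An `ssa_model`.
#' @param path File to write.
#' @return The path, invisibly.
#' @export
export_sbml_subset <- function(model, path) {
  esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="4">',
    '  <model id="ssakit_export">',
    '    <listOfCompartments>',
    '      <compartment id="cell" size="1"/>',
    '    </listOfCompartments>',
    '    <listOfSpecies>')
  for (s in model$species)
    lines <- c(lines, sprintf(
      '      <species id="%s" compartment="cell" initialAmount="%d"%s/>',
      s$name, s$initial,
      if (s$fixed) ' boundaryCondition="true"' else ""))
  lines <- c(lines, "    </listOfSpecies>")
  if (length(model$parameters)) {
    lines <- c(lines, "    <listOfParameters>")
    for (p in names(model$parameters))
      lines <- c(lines, sprintf('      <parameter id="%s" value="%s"/>',
                                p, format(model$parameters[[p]], digits = 17)))
    lines <- c(lines, "    </listOfParameters>")
  }
  lines <- c(lines, "    <listOfReactions>")
  mathml_atom <- function(tok) {
    if (grepl("^[0-9.]", tok)) paste0("<cn>", tok, "</cn>")
    else paste0("<ci>", tok, "</ci>")
  }
  for (r in model$reactions) {
    lines <- c(lines, sprintf('      <reaction id="%s" reversible="false">',
                              r$name))
    side <- function(v, tag) {
      if (!length(v)) return(character(0))
      c(sprintf("        <%s>", tag),
        sprintf('          <speciesReference species="%s" stoichiometry="%d"/>',
                names(v), v),
        sprintf("        </%s>", tag))
    }
    lines <- c(lines, side(r$reactants, "listOfReactants"),
               side(r$products, "listOfProducts"))
    expr <- if (r$law$type == "expression") r$law$expr else {
      terms <- format(r$law$c, digits = 17)
      for (sp in names(r$reactants))
        terms <- c(terms, rep(sp, r$reactants[[sp]]))
      paste(terms, collapse = " * ")
    }
    math <- expr_to_mathml(expr)
    lines <- c(lines,
               "        <kineticLaw>",
               '          <math xmlns="http://www.w3.org/1998/Math/MathML">',
               paste0("            ", math),
               "          </math>",
               "        </kineticLaw>",
               "      </reaction>")
  }
  lines <- c(lines, "    </listOfReactions>", "  </model>", "</sbml>")
  writeLines(lines, path)
  invisible(path)
}

# minimal infix -> MathML conversion for the restricted expression grammar:
# every identifier is compiled as a "species" so its name survives
expr_to_mathml <- function(expr) {
  ids <- expr_identifiers(expr)
  prog <- compile_expr(expr, ids, numeric(0))
  stack <- list()
  opname <- c("3" = "plus", "4" = "minus", "5" = "times", "6" = "divide",
              "7" = "power")
  for (k in seq_along(prog$code)) {
    op <- prog$code[[k]]; a <- prog$arg[[k]]
    if (op == .OP_CONST) {
      stack[[length(stack) + 1L]] <-
        paste0("<cn>", format(a, digits = 17), "</cn>")
    } else if (op == .OP_SPEC) {
      stack[[length(stack) + 1L]] <- paste0("<ci>", ids[[a]], "</ci>")
    } else if (op %in% c(.OP_ADD, .OP_SUB, .OP_MUL, .OP_DIV, .OP_POW)) {
      b <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      a1 <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      stack[[length(stack) + 1L]] <-
        paste0("<apply><", opname[[as.character(op)]], "/>", a1, b,
               "</apply>")
    } else if (op == .OP_NEG) {
      a1 <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      stack[[length(stack) + 1L]] <- paste0("<apply><minus/>", a1, "</apply>")
    } else stop("expression uses a function not representable in the SBML ",
                "subset writer (min/max/exp/log)")
  }
  stack[[1L]]
}
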