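#' Export the reaction network as SBML Level 3
#'
#' Writes an SBML Level 3 Version 2 document with one species per state
#' variable, one (constant) parameter per model parameter, and one reaction
#' per network reaction, each with its kinetic law serialized to MathML.
#' `max(a, b)` in the transport law is emitted as a MathML `piecewise`, so
#' the document uses only core MathML constructs.
#'
#' @param net A `cd_network` from [build_network()].
#' @param path Optional output path; when given, the document is written
#'   there.
#' @return An `xml2` document (invisibly when `path` is given).
#' @examples
#' doc <- export_sbml(build_network(cd_parameters(), "healthy"))
#' @export
export_sbml <- function(net, path = NULL) {
  comp_of <- setNames(cd_species(net$variant)$compartment, net$species)
  compartments <- unique(comp_of)

  doc <- xml2::xml_new_root(
    "sbml",
    xmlns = "http://www.sbml.org/sbml/level3/version2/core",
    level = "3", version = "2")
  model <- xml2::xml_add_child(doc, "model",
                               id = paste0("celiac_", net$variant))

  loc <- xml2::xml_add_child(model, "listOfCompartments")
  for (cmp in compartments) {
    xml2::xml_add_child(loc, "compartment", id = cmp, size = "1",
                        constant = "true", spatialDimensions = "3")
  }

  los <- xml2::xml_add_child(model, "listOfSpecies")
  for (sp in net$species) {
    xml2::xml_add_child(los, "species", id = sp,
                        compartment = comp_of[[sp]],
                        initialConcentration = "0",
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false", constant = "false")
  }

  lop <- xml2::xml_add_child(model, "listOfParameters")
  for (nm in names(net$params)) {
    xml2::xml_add_child(lop, "parameter", id = nm,
                        value = format(net$params[[nm]], digits = 17),
                        constant = "true")
  }

  lor <- xml2::xml_add_child(model, "listOfReactions")
  for (j in seq_len(nrow(net$reactions))) {
    id <- net$reactions$id[j]
    st <- net$stoich[[j]]
    rxn <- xml2::xml_add_child(lor, "reaction", id = id,
                               reversible = "false")
    reac <- st[st < 0]
    prod <- st[st > 0]
    if (length(reac) > 0) {
      lr <- xml2::xml_add_child(rxn, "listOfReactants")
      for (s in names(reac)) {
        xml2::xml_add_child(lr, "speciesReference", species = s,
                            stoichiometry = format(abs(reac[[s]])),
                            constant = "true")
      }
    }
    if (length(prod) > 0) {
      lp <- xml2::xml_add_child(rxn, "listOfProducts")
      for (s in names(prod)) {
        xml2::xml_add_child(lp, "speciesReference", species = s,
                            stoichiometry = format(prod[[s]]),
                            constant = "true")
      }
    }
    kl <- xml2::xml_add_child(rxn, "kineticLaw")
    math <- xml2::read_xml(paste0(
      "<math xmlns=\"http://www.w3.org/1998/Math/MathML\">",
      expr_to_mathml(net$reactions$rate[[j]]),
      "</math>"))
    xml2::xml_add_child(kl, math)
  }

  if (!is.null(path)) {
    xml2::write_xml(doc, path)
    return(invisible(doc))
  }
  doc
}

# R expression -> MathML string. Supports the arithmetic the rate laws use;
# anything else is an error naming the offending reaction construct.
expr_to_mathml <- function(e) {
  if (is.numeric(e)) {
    return(paste0("<cn>", format(e, digits = 17), "</cn>"))
  }
  if (is.name(e)) {
    return(paste0("<ci>", as.character(e), "</ci>"))
  }
  if (is.call(e)) {
    op <- as.character(e[[1]])
    args <- as.list(e)[-1]
    wrap <- function(tag) {
      paste0("<apply><", tag, "/>",
             paste0(vapply(args, expr_to_mathml, ""), collapse = ""),
             "</apply>")
    }
    if (op == "(") return(expr_to_mathml(args[[1]]))
    if (op == "+") return(wrap("plus"))
    if (op == "-") return(wrap("minus"))
    if (op == "*") return(wrap("times"))
    if (op == "/") return(wrap("divide"))
    if (op == "^") return(wrap("power"))
    if (op == "max" && length(args) == 2) {
      a <- expr_to_mathml(args[[1]])
      b <- expr_to_mathml(args[[2]])
      return(paste0(
        "<piecewise><piece>", a,
        "<apply><geq/>", a, b, "</apply></piece>",
        "<otherwise>", b, "</otherwise></piecewise>"))
    }
  }
  abort(paste0("unsupported rate-law construct for SBML export: ",
               deparse(e)))
}

# MathML node -> R expression (inverse of expr_to_mathml).
mathml_to_expr <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "math") {
    kids <- xml2::xml_children(node)
    return(mathml_to_expr(kids[[1]]))
  }
  if (nm == "cn") return(as.numeric(xml2::xml_text(node)))
  if (nm == "ci") return(as.name(trimws(xml2::xml_text(node))))
  if (nm == "apply") {
    kids <- xml2::xml_children(node)
    op <- xml2::xml_name(kids[[1]])
    args <- lapply(kids[-1], mathml_to_expr)
    fun <- switch(op, plus = "+", minus = "-", times = "*",
                  divide = "/", power = "^", geq = ">=",
                  abort(paste0("unsupported MathML operator: ", op)))
    if (length(args) == 1) return(call(fun, args[[1]]))
    out <- args[[1]]
    for (a in args[-1]) out <- call(fun, out, a)
    return(out)
  }
  if (nm == "piecewise") {
    piece <- xml2::xml_find_first(node, "./*[local-name()='piece']")
    other <- xml2::xml_find_first(node, "./*[local-name()='otherwise']")
    pk <- xml2::xml_children(piece)
    val <- mathml_to_expr(pk[[1]])
    alt <- mathml_to_expr(xml2::xml_children(other)[[1]])
    ## piecewise(a, a >= b, b) round-trips to max(a, b)
    return(call("max", val, alt))
  }
  abort(paste0("unsupported MathML node: ", nm))
}

#' Import an SBML document written by [export_sbml()]
#'
#' Rebuilds a simulatable network (species, stoichiometry, kinetic laws,
#' parameter values) from an SBML Level 3 file. Intended for round-trip
#' verification of the export; it supports the MathML subset the exporter
#' emits.
#'
#' @param path Path to an SBML file (or an `xml2` document).
#' @return A `cd_network` whose [rhs()] matches the exported model.
#' @export
read_sbml_network <- function(path) {
  doc <- if (inherits(path, "xml_document")) path else xml2::read_xml(path)
  ns_strip <- xml2::xml_ns_strip(doc)

  sp_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  sp <- xml2::xml_attr(sp_nodes, "id")

  par_nodes <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  pvec <- setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                   xml2::xml_attr(par_nodes, "id"))

  rxn_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  rx <- lapply(rxn_nodes, function(rn) {
    id <- xml2::xml_attr(rn, "id")
    reac <- xml2::xml_find_all(rn, "./listOfReactants/speciesReference")
    prod <- xml2::xml_find_all(rn, "./listOfProducts/speciesReference")
    st <- c(
      setNames(-as.numeric(xml2::xml_attr(reac, "stoichiometry")),
               xml2::xml_attr(reac, "species")),
      setNames(as.numeric(xml2::xml_attr(prod, "stoichiometry")),
               xml2::xml_attr(prod, "species"))
    )
    math <- xml2::xml_find_first(rn, "./kineticLaw/math")
    list(id = id, fig = NA_integer_, label = id,
         stoich = st, rate = mathml_to_expr(math))
  })
  model_id <- xml2::xml_attr(xml2::xml_find_first(doc, ".//model"), "id")
  variant <- if (grepl("healthy", model_id %||% "")) "healthy" else "patient"
  compile_network(sp, rx, pvec, variant, diet = "imported")
}
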