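## SBML Level 3 + FBC version 2
##
## The subset written/read here covers what constraint-based models need:
## compartments, species with chemical formulas, reactions with
## reactant/product stoichiometries, flux bounds as shared parameters,
## gene-product associations (nested and/or), and the FBC objective.
## Ids follow the SBML convention of prefixing metabolites with "M_",
## reactions with "R_", and gene products with "G_"; the prefixes are
## stripped on read. Pseudo-reaction kinds are encoded as SBO terms
## (exchange 627, demand 628, biomass 629, ATP maintenance 630).
##
## Charge is not tracked; chemical formulas may contain fractional counts
## and the carrier pseudo-element R (both beyond strict FBC, by design).

.SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
.FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

.KIND_SBO <- c(exchange = "SBO:0000627", demand = "SBO:0000628",
               biomass = "SBO:0000629", maintenance = "SBO:0000630")

read_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  mnode <- xml2::xml_find_first(doc, "//model")
  if (inherits(mnode, "xml_missing")) stop("no <model> element in ", path)

  comps <- xml2::xml_find_all(doc, "//listOfCompartments/compartment")
  comp_codes <- xml2::xml_attr(comps, "id")
  comp_names <- xml2::xml_attr(comps, "name")
  comp_names[is.na(comp_names)] <- comp_codes[is.na(comp_names)]
  compartments <- stats::setNames(comp_names, comp_codes)
  if (length(compartments) == 0L) {
    compartments <- c(c = "cytosol", p = "periplasm", e = "extracellular space")
  }

  model <- empty_model(id = xml2::xml_attr(mnode, "id"),
                       compartments = compartments)

  ## flux-bound parameters
  pars <- xml2::xml_find_all(doc, "//listOfParameters/parameter")
  par_vals <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                              xml2::xml_attr(pars, "id"))

  sp <- xml2::xml_find_all(doc, "//listOfSpecies/species")
  ids <- sub("^M_", "", xml2::xml_attr(sp, "id"))
  if (anyDuplicated(ids)) {
    stop("duplicate species id in SBML: ", ids[duplicated(ids)][1])
  }
  nm <- xml2::xml_attr(sp, "name"); nm[is.na(nm)] <- ids[is.na(nm)]
  model <- add_metabolites(model, id = ids, name = nm,
                           compartment = xml2::xml_attr(sp, "compartment"),
                           formula = xml2::xml_attr(sp, "chemicalFormula"))

  parse_gpa <- function(node) {
    kids <- xml2::xml_children(node)
    parts <- vapply(kids, function(k) {
      switch(xml2::xml_name(k),
             geneProductRef = sub("^G_", "", xml2::xml_attr(k, "geneProduct")),
             and = paste0("(", parse_gpa(k), ")"),
             or = paste0("(", parse_gpa(k), ")"),
             stop("unsupported element in geneProductAssociation: ",
                  xml2::xml_name(k)))
    }, character(1))
    op <- switch(xml2::xml_name(node), and = " and ", or = " or ", "")
    if (xml2::xml_name(node) == "geneProductAssociation") parts[1]
    else paste(parts, collapse = op)
  }

  rxs <- xml2::xml_find_all(doc, "//listOfReactions/reaction")
  objective <- NA_character_
  fo <- xml2::xml_find_first(doc, "//*[local-name()='fluxObjective']")
  if (!inherits(fo, "xml_missing")) {
    objective <- sub("^R_", "", xml2::xml_attr(fo, "reaction"))
  }
  sbo_to_kind <- stats::setNames(names(.KIND_SBO), .KIND_SBO)
  for (rx in rxs) {
    rid <- sub("^R_", "", xml2::xml_attr(rx, "id"))
    st <- numeric()
    for (sr in xml2::xml_find_all(rx, "./listOfReactants/speciesReference")) {
      met <- sub("^M_", "", xml2::xml_attr(sr, "species"))
      st[met] <- (if (met %in% names(st)) st[[met]] else 0) -
        as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    for (sr in xml2::xml_find_all(rx, "./listOfProducts/speciesReference")) {
      met <- sub("^M_", "", xml2::xml_attr(sr, "species"))
      st[met] <- (if (met %in% names(st)) st[[met]] else 0) +
        as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    lb_ref <- xml2::xml_attr(rx, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(rx, "upperFluxBound")
    lb <- if (!is.na(lb_ref) && lb_ref %in% names(par_vals)) par_vals[[lb_ref]]
          else stop("reaction ", rid, ": unresolved lower flux bound")
    ub <- if (!is.na(ub_ref) && ub_ref %in% names(par_vals)) par_vals[[ub_ref]]
          else stop("reaction ", rid, ": unresolved upper flux bound")
    gpa <- xml2::xml_find_first(rx, "./*[local-name()='geneProductAssociation']")
    gpr <- if (inherits(gpa, "xml_missing")) "" else parse_gpa(gpa)
    sbo <- xml2::xml_attr(rx, "sboTerm")
    kind <- if (!is.na(sbo) && sbo %in% names(sbo_to_kind)) {
      unname(sbo_to_kind[sbo])
    } else NULL
    nmr <- xml2::xml_attr(rx, "name"); if (is.na(nmr)) nmr <- rid
    ssys <- xml2::xml_attr(rx, "subsystem"); if (is.na(ssys)) ssys <- ""
    model <- add_reaction(model, id = rid, stoichiometry = st, lb = lb,
                          ub = ub, name = nmr, subsystem = ssys, gpr = gpr,
                          kind = kind)
  }
  if (!is.na(objective)) model <- set_objective(model, objective)
  model
}

write_model_sbml <- function(model, path) {
  root <- xml2::xml_new_root(
    "sbml", xmlns = .SBML_NS, "xmlns:fbc" = .FBC_NS,
    level = "3", version = "1", "fbc:required" = "false")
  mnode <- xml2::xml_add_child(root, "model", id = model$id,
                               "fbc:strict" = "false")

  loc <- xml2::xml_add_child(mnode, "listOfCompartments")
  for (i in seq_along(model$compartments)) {
    xml2::xml_add_child(loc, "compartment",
                        id = names(model$compartments)[i],
                        name = unname(model$compartments[i]),
                        constant = "true")
  }

  los <- xml2::xml_add_child(mnode, "listOfSpecies")
  for (i in seq_len(nrow(model$mets))) {
    m <- model$mets[i, ]
    sp <- xml2::xml_add_child(los, "species", id = paste0("M_", m$id),
                              name = m$name, compartment = m$compartment,
                              hasOnlySubstanceUnits = "false",
                              boundaryCondition = "false", constant = "false")
    if (!is.na(m$formula) && nzchar(m$formula)) {
      xml2::xml_set_attr(sp, "fbc:chemicalFormula", m$formula)
    }
  }

  ## shared flux-bound parameters, one per distinct value
  vals <- sort(unique(c(model$rxns$lb, model$rxns$ub)))
  par_id <- stats::setNames(sprintf("fb_%d", seq_along(vals)),
                            vapply(vals, format, character(1), digits = 17))
  lop <- xml2::xml_add_child(mnode, "listOfParameters")
  for (i in seq_along(vals)) {
    xml2::xml_add_child(lop, "parameter", id = sprintf("fb_%d", i),
                        value = format(vals[i], digits = 17),
                        constant = "true", units = "mmol_per_gDW_per_hr")
  }

  write_gpa <- function(parent, tree) {
    if (is.character(tree)) {
      xml2::xml_add_child(parent, "fbc:geneProductRef",
                          "fbc:geneProduct" = paste0("G_", tree))
    } else {
      node <- xml2::xml_add_child(parent, paste0("fbc:", tree$op))
      for (a in tree$args) write_gpa(node, a)
    }
  }

  lor <- xml2::xml_add_child(mnode, "listOfReactions")
  for (j in seq_len(nrow(model$rxns))) {
    r <- model$rxns[j, ]
    rx <- xml2::xml_add_child(lor, "reaction", id = paste0("R_", r$id),
                              name = r$name,
                              reversible = tolower(r$lb < 0),
                              fast = "false",
                              "fbc:lowerFluxBound" = par_id[[format(r$lb, digits = 17)]],
                              "fbc:upperFluxBound" = par_id[[format(r$ub, digits = 17)]])
    if (nzchar(r$subsystem)) xml2::xml_set_attr(rx, "subsystem", r$subsystem)
    if (r$kind %in% names(.KIND_SBO)) {
      xml2::xml_set_attr(rx, "sboTerm", .KIND_SBO[[r$kind]])
    }
    nz <- which(model$S[, j] != 0)
    coef <- model$S[nz, j]
    mets <- model$mets$id[nz]
    if (any(coef < 0)) {
      lre <- xml2::xml_add_child(rx, "listOfReactants")
      for (k in which(coef < 0)) {
        xml2::xml_add_child(lre, "speciesReference",
                            species = paste0("M_", mets[k]),
                            stoichiometry = format(-coef[k], digits = 17),
                            constant = "true")
      }
    }
    if (any(coef > 0)) {
      lpr <- xml2::xml_add_child(rx, "listOfProducts")
      for (k in which(coef > 0)) {
        xml2::xml_add_child(lpr, "speciesReference",
                            species = paste0("M_", mets[k]),
                            stoichiometry = format(coef[k], digits = 17),
                            constant = "true")
      }
    }
    if (nzchar(r$gpr)) {
      gpa <- xml2::xml_add_child(rx, "fbc:geneProductAssociation")
      write_gpa(gpa, parse_gpr(r$gpr))
    }
  }

  if (length(model$genes) > 0L) {
    lgp <- xml2::xml_add_child(mnode, "fbc:listOfGeneProducts")
    for (g in model$genes) {
      xml2::xml_add_child(lgp, "fbc:geneProduct", "fbc:id" = paste0("G_", g),
                          "fbc:label" = g)
    }
  }

  if (!is.na(model$objective)) {
    loo <- xml2::xml_add_child(mnode, "fbc:listOfObjectives",
                               "fbc:activeObjective" = "obj")
    ob <- xml2::xml_add_child(loo, "fbc:objective", "fbc:id" = "obj",
                              "fbc:type" = "maximize")
    lfo <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
    xml2::xml_add_child(lfo, "fbc:fluxObjective",
                        "fbc:reaction" = paste0("R_", model$objective),
                        "fbc:coefficient" = "1")
  }

  xml2::write_xml(root, path)
  invisible(path)
}
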