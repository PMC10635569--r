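## COBRA JSON dialect
##
## The schema used by COBRApy: top-level arrays `metabolites`, `reactions`,
## `genes`, plus `compartments` and `id`. Reaction stoichiometry is a map
## metabolite id -> coefficient; the objective is the reaction with
## `objective_coefficient` 1. Pseudo-reaction kinds (biomass, maintenance,
## demand) that cannot be recovered from topology are carried in each
## reaction's `notes.kind`.

read_model_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (field in c("metabolites", "reactions")) {
    if (is.null(doc[[field]])) stop("JSON model lacks '", field, "' array")
  }
  comp <- if (!is.null(doc$compartments) && length(doc$compartments)) {
    vapply(doc$compartments, as.character, character(1))
  } else c(c = "cytosol", p = "periplasm", e = "extracellular space")
  model <- empty_model(id = if (!is.null(doc$id)) doc$id else "model",
                       compartments = comp)

  met_ids <- vapply(doc$metabolites, function(m) as.character(m$id), character(1))
  if (anyDuplicated(met_ids)) {
    stop("duplicate metabolite id in JSON: ", met_ids[duplicated(met_ids)][1])
  }
  grab <- function(x, field, default) {
    if (is.null(x[[field]]) || length(x[[field]]) == 0L) default
    else as.character(x[[field]])
  }
  model <- add_metabolites(
    model, id = met_ids,
    name = vapply(doc$metabolites, grab, character(1), "name", ""),
    compartment = vapply(doc$metabolites, grab, character(1), "compartment", ""),
    formula = vapply(doc$metabolites, grab, character(1), "formula",
                     NA_character_))

  objective <- NA_character_
  for (r in doc$reactions) {
    rid <- as.character(r$id)
    st <- vapply(r$metabolites, as.numeric, numeric(1))
    kind <- if (!is.null(r$notes) && !is.null(r$notes$kind)) {
      as.character(r$notes$kind)
    } else NULL
    model <- add_reaction(
      model, id = rid, stoichiometry = st,
      lb = as.numeric(r$lower_bound), ub = as.numeric(r$upper_bound),
      name = grab(r, "name", rid), subsystem = grab(r, "subsystem", ""),
      gpr = grab(r, "gene_reaction_rule", ""), kind = kind)
    oc <- if (!is.null(r$objective_coefficient)) as.numeric(r$objective_coefficient) else 0
    if (oc != 0) objective <- rid
  }
  if (!is.na(objective)) model <- set_objective(model, objective)

  ## genes listed but unused in any rule are not representable in this
  ## container (gene list == union of rule leaves); they are dropped.
  model
}

write_model_json <- function(model, path) {
  mets <- lapply(seq_len(nrow(model$mets)), function(i) {
    m <- model$mets[i, ]
    list(id = m$id, name = m$name, compartment = m$compartment,
         formula = if (is.na(m$formula)) NULL else m$formula)
  })
  rxns <- lapply(seq_len(nrow(model$rxns)), function(j) {
    r <- model$rxns[j, ]
    nz <- which(model$S[, j] != 0)
    st <- as.list(model$S[nz, j])
    names(st) <- model$mets$id[nz]
    out <- list(id = r$id, name = r$name,
                metabolites = st,
                lower_bound = r$lb, upper_bound = r$ub,
                gene_reaction_rule = r$gpr, subsystem = r$subsystem,
                objective_coefficient =
                  if (!is.na(model$objective) && r$id == model$objective) 1 else 0)
    if (r$kind %in% c("biomass", "maintenance", "demand")) {
      out$notes <- list(kind = r$kind)
    }
    out
  })
  genes <- lapply(model$genes, function(g) list(id = g, name = g))
  doc <- list(id = model$id,
              metabolites = mets, reactions = rxns, genes = genes,
              compartments = as.list(model$compartments),
              version = "1")
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
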