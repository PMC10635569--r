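## Reading and writing models
##
## Three dialects are supported:
##   - "sbml":    SBML Level 3 + FBC v2 (the community exchange standard)
##   - "json":    the COBRA JSON schema (metabolites/reactions/genes arrays)
##   - "tabular": this package's two-sheet TSV dialect (a directory holding
##                metabolites.tsv and reactions.tsv with documented columns)
## All three round-trip stoichiometry, bounds, gene rules, kinds, and the
## objective.

#' Read a metabolic model
#'
#' @param path File path (`.xml`/`.sbml`, `.json`) or directory (tabular).
#' @param format `"sbml"`, `"json"`, `"tabular"`, or `"auto"` (from the
#'   extension; a directory means tabular).
#' @return A validated `metabolic_model`.
#' @export
read_model <- function(path, format = c("auto", "sbml", "json", "tabular")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "tabular"
    else switch(tolower(tools::file_ext(path)),
                xml = , sbml = "sbml",
                json = "json",
                stop("cannot infer model format from: ", path))
  }
  if (!file.exists(path)) stop("no such file or directory: ", path)
  model <- switch(format,
                  sbml = read_model_sbml(path),
                  json = read_model_json(path),
                  tabular = read_model_tabular(path))
  validate_model(model)
  model
}

#' Write a metabolic model
#'
#' @param model A `metabolic_model`.
#' @param path Output file (sbml/json) or directory (tabular).
#' @param format As in [read_model()]; `"auto"` infers from the extension.
#' @return Invisibly, `path`.
#' @export
write_model <- function(model, path, format = c("auto", "sbml", "json", "tabular")) {
  format <- match.arg(format)
  validate_model(model)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     xml = , sbml = "sbml",
                     json = "json",
                     "tabular")
  }
  switch(format,
         sbml = write_model_sbml(model, path),
         json = write_model_json(model, path),
         tabular = write_model_tabular(model, path))
  invisible(path)
}

## ---- tabular dialect ----
## metabolites.tsv: id, name, compartment, formula
## reactions.tsv:   id, name, subsystem, equation, lower_bound, upper_bound,
##                  gene_rule, kind, objective (0/1)

read_model_tabular <- function(path) {
  met_file <- file.path(path, "metabolites.tsv")
  rxn_file <- file.path(path, "reactions.tsv")
  for (f in c(met_file, rxn_file)) {
    if (!file.exists(f)) stop("tabular model is missing ", f)
  }
  mets <- utils::read.delim(met_file, stringsAsFactors = FALSE,
                            colClasses = "character", na.strings = c("NA", ""))
  rxns <- utils::read.delim(rxn_file, stringsAsFactors = FALSE,
                            na.strings = c("NA"))
  need_m <- c("id", "name", "compartment", "formula")
  need_r <- c("id", "name", "subsystem", "equation", "lower_bound",
              "upper_bound", "gene_rule", "kind", "objective")
  if (!all(need_m %in% names(mets))) {
    stop("metabolites.tsv must have columns: ", paste(need_m, collapse = ", "))
  }
  if (!all(need_r %in% names(rxns))) {
    stop("reactions.tsv must have columns: ", paste(need_r, collapse = ", "))
  }
  if (anyDuplicated(mets$id)) {
    stop("duplicate metabolite id in metabolites.tsv: ",
         mets$id[duplicated(mets$id)][1])
  }
  if (anyDuplicated(rxns$id)) {
    stop("duplicate reaction id in reactions.tsv: ",
         rxns$id[duplicated(rxns$id)][1])
  }
  model <- empty_model(id = basename(normalizePath(path, mustWork = FALSE)),
                       compartments = c(c = "cytosol", p = "periplasm",
                                        e = "extracellular space"))
  model <- add_metabolites(model, id = mets$id, name = mets$name,
                           compartment = mets$compartment,
                           formula = mets$formula)
  for (i in seq_len(nrow(rxns))) {
    st <- tryCatch(parse_equation(rxns$equation[i]),
                   error = function(e) stop("reactions.tsv row '", rxns$id[i],
                                            "': ", conditionMessage(e)))
    gpr <- rxns$gene_rule[i]
    if (is.na(gpr)) gpr <- ""
    kind <- rxns$kind[i]
    if (is.na(kind) || !nzchar(kind)) kind <- NULL
    model <- add_reaction(model, id = rxns$id[i],
                          stoichiometry = st$stoichiometry,
                          lb = as.numeric(rxns$lower_bound[i]),
                          ub = as.numeric(rxns$upper_bound[i]),
                          name = rxns$name[i], subsystem = rxns$subsystem[i],
                          gpr = gpr, kind = kind)
  }
  obj <- rxns$id[rxns$objective %in% c(1, "1", TRUE)]
  if (length(obj) == 1L) model <- set_objective(model, obj)
  model
}

write_model_tabular <- function(model, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  mets <- model$mets
  rxns <- data.frame(
    id = model$rxns$id, name = model$rxns$name,
    subsystem = model$rxns$subsystem,
    equation = vapply(model$rxns$id, function(id) format_equation(model, id),
                      character(1)),
    lower_bound = model$rxns$lb, upper_bound = model$rxns$ub,
    gene_rule = model$rxns$gpr, kind = model$rxns$kind,
    objective = as.integer(!is.na(model$objective) &
                             model$rxns$id == model$objective),
    stringsAsFactors = FALSE)
  utils::write.table(mets, file.path(path, "metabolites.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  utils::write.table(rxns, file.path(path, "reactions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}
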