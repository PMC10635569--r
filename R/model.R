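## The metabolic model container
##
## A `metabolic_model` is an S3 list with:
##   mets  - data.frame(id, name, compartment, formula)
##   rxns  - data.frame(id, name, subsystem, lb, ub, gpr, kind)
##   S     - sparse stoichiometric matrix (metabolites x reactions),
##           dimnames = (met ids, reaction ids); negative = consumed
##   genes - character vector, the union of gene-rule leaves
##   objective - reaction id of the objective (usually the biomass reaction)
##   compartments - named character: code -> descriptive name
##   id    - model identifier string
##
## Compartment codes follow the BiGG convention: metabolite ids carry the
## suffix _c (cytosol), _p (periplasm), _e (extracellular). Fluxes are in
## mmol/gDW/h; exchange reactions are written "met_e <=> (nothing)" so
## negative exchange flux is uptake and positive is secretion.

.REACTION_KINDS <- c("exchange", "transport", "metabolic", "biomass",
                     "maintenance", "demand")

#' Create an empty metabolic model
#'
#' @param id Model identifier.
#' @param compartments Named character vector of compartment codes; defaults
#'   to cytosol, periplasm, and extracellular space.
#' @return A `metabolic_model` with no metabolites or reactions.
#' @export
empty_model <- function(id = "model",
                        compartments = c(c = "cytosol", p = "periplasm",
                                         e = "extracellular space")) {
  structure(list(
    id = id,
    mets = data.frame(id = character(), name = character(),
                      compartment = character(), formula = character(),
                      stringsAsFactors = FALSE),
    rxns = data.frame(id = character(), name = character(),
                      subsystem = character(), lb = numeric(), ub = numeric(),
                      gpr = character(), kind = character(),
                      stringsAsFactors = FALSE),
    S = Matrix::Matrix(0, 0, 0, sparse = TRUE),
    genes = character(),
    objective = NA_character_,
    compartments = compartments
  ), class = "metabolic_model")
}

#' Add metabolites to a model
#'
#' @param model A `metabolic_model`.
#' @param id Metabolite ids (with compartment suffix, e.g. `"glc_c"`).
#' @param name Display names (defaults to ids).
#' @param compartment Compartment codes; inferred from the id suffix when
#'   missing.
#' @param formula Elemental formula strings (`NA` = unknown).
#' @return The extended model.
#' @export
add_metabolites <- function(model, id, name = id, compartment = NULL,
                            formula = NA_character_) {
  stopifnot(inherits(model, "metabolic_model"))
  if (any(id %in% model$mets$id)) {
    stop("duplicate metabolite id(s): ",
         paste(intersect(id, model$mets$id), collapse = ", "))
  }
  if (is.null(compartment)) {
    compartment <- sub("^.*_([a-z])$", "\\1", id)
    if (any(!compartment %in% names(model$compartments))) {
      bad <- id[!compartment %in% names(model$compartments)]
      stop("cannot infer compartment from metabolite id(s): ",
           paste(bad, collapse = ", "))
    }
  }
  if (any(!compartment %in% names(model$compartments))) {
    stop("unknown compartment code(s): ",
         paste(setdiff(compartment, names(model$compartments)), collapse = ", "))
  }
  add <- data.frame(id = id, name = rep_len(as.character(name), length(id)),
                    compartment = rep_len(compartment, length(id)),
                    formula = rep_len(as.character(formula), length(id)),
                    stringsAsFactors = FALSE)
  model$mets <- rbind(model$mets, add)
  model$S <- rbind(model$S,
                   Matrix::Matrix(0, length(id), ncol(model$S), sparse = TRUE))
  dimnames(model$S) <- list(model$mets$id, model$rxns$id)
  model
}

#' Add one reaction to a model
#'
#' @param model A `metabolic_model`.
#' @param id Reaction id.
#' @param stoichiometry Named numeric vector of coefficients over metabolite
#'   ids (negative = consumed), or an equation string such as
#'   `"sub_c + 2 adp_c --> 2 prod_c + 2 atp_c"` (see [parse_equation()]).
#' @param lb,ub Flux bounds in mmol/gDW/h. Irreversible reactions use
#'   `lb = 0`; the network-wide default span is +/- 1000.
#' @param name,subsystem Annotation strings.
#' @param gpr Gene rule string (`""` = no gene association).
#' @param kind One of exchange, transport, metabolic, biomass, maintenance,
#'   demand; inferred from the stoichiometry when `NULL`.
#' @return The extended model.
#' @export
add_reaction <- function(model, id, stoichiometry, lb = 0, ub = 1000,
                         name = id, subsystem = "", gpr = "", kind = NULL) {
  stopifnot(inherits(model, "metabolic_model"), length(id) == 1L)
  if (id %in% model$rxns$id) stop("duplicate reaction id: ", id)
  if (is.character(stoichiometry) && is.null(names(stoichiometry))) {
    stoichiometry <- parse_equation(stoichiometry)$stoichiometry
  }
  stoichiometry <- stoichiometry[stoichiometry != 0]
  unknown <- setdiff(names(stoichiometry), model$mets$id)
  if (length(unknown) > 0L) {
    stop("reaction ", id, " references unknown metabolite(s): ",
         paste(unknown, collapse = ", "))
  }
  if (lb > ub) stop("reaction ", id, ": lower bound exceeds upper bound")
  if (is.null(kind)) kind <- .infer_kind(model, stoichiometry)
  kind <- match.arg(kind, .REACTION_KINDS)
  if (is.na(gpr)) gpr <- ""
  gpr <- format_gpr(gpr)   # canonical form, so all dialects round-trip

  col <- Matrix::Matrix(0, nrow(model$S), 1, sparse = TRUE)
  col[match(names(stoichiometry), model$mets$id), 1] <- unname(stoichiometry)
  model$S <- cbind(model$S, col)
  model$rxns <- rbind(model$rxns, data.frame(
    id = id, name = name, subsystem = subsystem, lb = lb, ub = ub,
    gpr = gpr, kind = kind, stringsAsFactors = FALSE))
  dimnames(model$S) <- list(model$mets$id, model$rxns$id)
  new_genes <- setdiff(gpr_genes(gpr), model$genes)
  model$genes <- c(model$genes, new_genes)
  model
}

## exchange: touches exactly one metabolite, extracellular;
## transport: participants span >= 2 compartments; else metabolic.
.infer_kind <- function(model, stoichiometry) {
  comps <- model$mets$compartment[match(names(stoichiometry), model$mets$id)]
  if (length(stoichiometry) == 1L && comps == "e") return("exchange")
  if (length(unique(comps)) >= 2L) return("transport")
  "metabolic"
}

#' Remove reactions from a model
#'
#' @param model A `metabolic_model`.
#' @param ids Reaction ids to drop. Orphaned genes are pruned from the gene
#'   list; the objective becomes `NA` if removed.
#' @return The reduced model.
#' @export
remove_reactions <- function(model, ids) {
  stopifnot(all(ids %in% model$rxns$id))
  keep <- !model$rxns$id %in% ids
  model$rxns <- model$rxns[keep, , drop = FALSE]
  rownames(model$rxns) <- NULL
  model$S <- model$S[, keep, drop = FALSE]
  model$genes <- unique(unlist(lapply(model$rxns$gpr, gpr_genes)))
  if (!is.na(model$objective) && model$objective %in% ids) {
    model$objective <- NA_character_
  }
  model
}

#' Set reaction flux bounds
#'
#' @param model A `metabolic_model`.
#' @param ids Reaction ids.
#' @param lb,ub New bounds (recycled); `NULL` leaves a side unchanged.
#' @return The updated model.
#' @export
set_bounds <- function(model, ids, lb = NULL, ub = NULL) {
  idx <- match(ids, model$rxns$id)
  if (anyNA(idx)) stop("unknown reaction id(s): ",
                       paste(ids[is.na(idx)], collapse = ", "))
  if (!is.null(lb)) model$rxns$lb[idx] <- rep_len(lb, length(idx))
  if (!is.null(ub)) model$rxns$ub[idx] <- rep_len(ub, length(idx))
  bad <- model$rxns$lb[idx] > model$rxns$ub[idx]
  if (any(bad)) stop("lower bound exceeds upper bound for: ",
                     paste(ids[bad], collapse = ", "))
  model
}

#' Set the objective reaction
#'
#' @param model A `metabolic_model`.
#' @param id Reaction id to optimize (usually the biomass reaction).
#' @return The updated model.
#' @export
set_objective <- function(model, id) {
  if (!id %in% model$rxns$id) stop("unknown objective reaction: ", id)
  model$objective <- id
  model
}

#' Exchange reaction ids of a model
#'
#' @param model A `metabolic_model`.
#' @return Character vector of exchange reaction ids.
#' @export
exchanges <- function(model) model$rxns$id[model$rxns$kind == "exchange"]

#' The sparse stoichiometric matrix
#'
#' Metabolite instances in rows, reactions in columns; `S[i, j]` is the
#' signed coefficient of metabolite i in reaction j. Exchange columns have
#' exactly one nonzero by construction.
#'
#' @param model A `metabolic_model`.
#' @return A sparse `Matrix` with dimnames (metabolite ids, reaction ids).
#' @export
stoichiometric_matrix <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  model$S
}

#' Validate model invariants
#'
#' Checks id uniqueness, stoichiometry resolution, bound ordering, exchange
#' topology (single extracellular metabolite), objective resolution, and
#' gene-list consistency with the rule leaves.
#'
#' @param model A `metabolic_model`.
#' @return Invisibly `TRUE`; errors describe the first violated invariant.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  if (anyDuplicated(model$mets$id)) stop("duplicate metabolite ids")
  if (anyDuplicated(model$rxns$id)) stop("duplicate reaction ids")
  if (!identical(rownames(model$S), model$mets$id) ||
      !identical(colnames(model$S), model$rxns$id)) {
    stop("stoichiometric matrix dimnames out of sync with tables")
  }
  if (any(model$rxns$lb > model$rxns$ub)) stop("lb > ub for some reaction")
  if (any(!model$mets$compartment %in% names(model$compartments))) {
    stop("metabolite in undeclared compartment")
  }
  ex <- which(model$rxns$kind == "exchange")
  for (j in ex) {
    nz <- which(model$S[, j] != 0)
    if (length(nz) != 1L || model$mets$compartment[nz] != "e") {
      stop("exchange reaction ", model$rxns$id[j],
           " must touch exactly one extracellular metabolite")
    }
  }
  if (!is.na(model$objective) && !model$objective %in% model$rxns$id) {
    stop("objective reaction not in model: ", model$objective)
  }
  rule_genes <- unique(unlist(lapply(model$rxns$gpr, gpr_genes)))
  if (!setequal(rule_genes, model$genes)) {
    stop("gene list out of sync with gene-rule leaves")
  }
  invisible(TRUE)
}

#' Summary statistics of a model
#'
#' Counts reactions by kind (exchange, transport, metabolic, plus biomass /
#' maintenance / demand pseudo-reactions), metabolite instances
#' (compartment-distinct), unique metabolites (compartment suffix stripped),
#' and genes. Transport classification is recomputed from the stoichiometry:
#' a non-exchange reaction whose participants span at least two compartments.
#'
#' @param model A `metabolic_model`.
#' @return A list of class `model_statistics`.
#' @export
model_statistics <- function(model) {
  validate_model(model)
  kind <- .recompute_kinds(model)
  out <- list(
    n_reactions = nrow(model$rxns),
    n_metabolite_instances = nrow(model$mets),
    n_unique_metabolites = length(unique(sub("_[a-z]$", "", model$mets$id))),
    n_genes = length(model$genes),
    n_exchange = sum(kind == "exchange"),
    n_transport = sum(kind == "transport"),
    n_metabolic = sum(kind == "metabolic"),
    n_biomass = sum(kind == "biomass"),
    n_maintenance = sum(kind == "maintenance"),
    n_demand = sum(kind == "demand")
  )
  structure(out, class = "model_statistics")
}

## pseudo-reaction kinds are kept as declared; the rest reclassified
.recompute_kinds <- function(model) {
  kind <- model$rxns$kind
  for (j in seq_len(nrow(model$rxns))) {
    if (kind[j] %in% c("biomass", "maintenance", "demand")) next
    nz <- which(model$S[, j] != 0)
    st <- model$S[nz, j]
    names(st) <- model$mets$id[nz]
    kind[j] <- .infer_kind(model, st)
  }
  kind
}

#' @export
print.model_statistics <- function(x, ...) {
  cat("Model statistics\n")
  cat(sprintf("  reactions:             %d\n", x$n_reactions))
  cat(sprintf("    exchange:            %d\n", x$n_exchange))
  cat(sprintf("    transport:           %d\n", x$n_transport))
  cat(sprintf("    metabolic:           %d\n", x$n_metabolic))
  cat(sprintf("    biomass/maint/demand: %d/%d/%d\n",
              x$n_biomass, x$n_maintenance, x$n_demand))
  cat(sprintf("  metabolite instances:  %d\n", x$n_metabolite_instances))
  cat(sprintf("  unique metabolites:    %d\n", x$n_unique_metabolites))
  cat(sprintf("  genes:                 %d\n", x$n_genes))
  invisible(x)
}

#' Check elemental mass balance of all reactions
#'
#' Every metabolic, transport, and maintenance reaction must conserve every
#' element except hydrogen (proton bookkeeping is deliberately ignored, since
#' charge is not tracked). The carrier pseudo-element R must balance too:
#' carriers are cycled, never created or destroyed. Exchange, biomass, and
#' demand pseudo-reactions are exempt by construction.
#'
#' @param model A `metabolic_model`.
#' @param ignore_elements Elements excluded from the check (default `"H"`).
#' @return A data.frame with one row per (reaction, element) imbalance;
#'   attribute `"unverifiable"` lists reactions skipped because a participant
#'   formula is unknown.
#' @export
check_mass_balance <- function(model, ignore_elements = "H") {
  validate_model(model)
  checked_kinds <- c("metabolic", "transport", "maintenance")
  rows <- list()
  unverifiable <- character()
  for (j in which(model$rxns$kind %in% checked_kinds)) {
    nz <- which(model$S[, j] != 0)
    formulas <- model$mets$formula[nz]
    parsed <- lapply(formulas, function(f) {
      if (is.na(f) || !nzchar(f)) NULL else parse_formula(f)
    })
    if (any(vapply(parsed, is.null, logical(1)))) {
      unverifiable <- c(unverifiable, model$rxns$id[j])
      next
    }
    net <- numeric()
    for (k in seq_along(nz)) {
      cnt <- parsed[[k]] * model$S[nz[k], j]
      for (el in names(cnt)) {
        net[el] <- (if (el %in% names(net)) net[[el]] else 0) + cnt[[el]]
      }
    }
    net <- net[!(names(net) %in% ignore_elements)]
    bad <- names(net)[abs(net) > 1e-9]
    for (el in bad) {
      rows[[length(rows) + 1L]] <- data.frame(
        reaction = model$rxns$id[j], element = el, imbalance = net[[el]],
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(reaction = character(), element = character(),
               imbalance = numeric(), stringsAsFactors = FALSE)
  attr(out, "unverifiable") <- unverifiable
  out
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model '%s': %d metabolites, %d reactions, %d genes>\n",
              x$id, nrow(x$mets), nrow(x$rxns), length(x$genes)))
  if (!is.na(x$objective)) cat("  objective:", x$objective, "\n")
  invisible(x)
}

#' Parse a reaction equation string
#'
#' Understands `"-->"` / `"->"` (irreversible as written) and `"<=>"` / `"<->"`
#' (reversible); coefficients precede metabolite ids, defaulting to 1. One
#' side may be empty (boundary/demand reactions), e.g. `"glc_e <=>"`.
#'
#' @param equation Equation string.
#' @return A list with `stoichiometry` (named numeric, negative = left side)
#'   and `reversible` (logical, from the arrow).
#' @export
parse_equation <- function(equation) {
  arrow <- regmatches(equation, regexpr("<=>|<->|-->|->", equation))
  if (length(arrow) == 0L) stop("no reaction arrow in: '", equation, "'")
  reversible <- arrow %in% c("<=>", "<->")
  sides <- strsplit(equation, "<=>|<->|-->|->")[[1]]
  lhs <- if (length(sides) >= 1L) trimws(sides[1]) else ""
  rhs <- if (length(sides) >= 2L) trimws(sides[2]) else ""
  parse_side <- function(side, sign) {
    if (!nzchar(side)) return(numeric())
    terms <- trimws(strsplit(side, "\\+")[[1]])
    out <- numeric()
    for (term in terms[nzchar(terms)]) {
      parts <- strsplit(term, "\\s+")[[1]]
      if (length(parts) == 2L) {
        coef <- suppressWarnings(as.numeric(parts[1]))
        if (is.na(coef)) stop("bad coefficient in term '", term, "'")
        met <- parts[2]
      } else if (length(parts) == 1L) {
        coef <- 1
        met <- parts[1]
      } else stop("cannot parse term '", term, "'")
      out[met] <- (if (met %in% names(out)) out[[met]] else 0) + sign * coef
    }
    out
  }
  lhs_st <- parse_side(lhs, -1)
  rhs_st <- parse_side(rhs, +1)
  st <- lhs_st
  for (met in names(rhs_st)) {
    st[met] <- (if (met %in% names(st)) st[[met]] else 0) + rhs_st[[met]]
  }
  list(stoichiometry = st[st != 0], reversible = reversible)
}

#' Format a reaction as an equation string
#'
#' @param model A `metabolic_model`.
#' @param id Reaction id.
#' @return Equation string; the arrow reflects the bounds (`<=>` when
#'   `lb < 0`).
#' @export
format_equation <- function(model, id) {
  j <- match(id, model$rxns$id)
  if (is.na(j)) stop("unknown reaction: ", id)
  nz <- which(model$S[, j] != 0)
  coef <- model$S[nz, j]
  mets <- model$mets$id[nz]
  fmt <- function(cc, mm) {
    paste(vapply(seq_along(cc), function(i) {
      if (abs(cc[i] - 1) < 1e-12) mm[i]
      else paste(format(cc[i], digits = 12), mm[i])
    }, character(1)), collapse = " + ")
  }
  lhs <- fmt(-coef[coef < 0], mets[coef < 0])
  rhs <- fmt(coef[coef > 0], mets[coef > 0])
  arrow <- if (model$rxns$lb[j] < 0) "<=>" else "-->"
  trimws(paste(lhs, arrow, rhs))
}
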