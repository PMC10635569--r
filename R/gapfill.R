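## Component-driven gap filling
##
## A draft reconstruction usually cannot synthesize every biomass
## precursor. Candidate reactions from a universal pool (database-derived,
## no gene rules) are screened greedily: with all exchanges open, a
## candidate is added when it strictly increases the number of producible
## biomass components; this repeats until every component is producible or
## no candidate (or candidate pair) helps. Added reactions are flagged for
## downstream evidence review -- sequence or literature support is a
## separate, manual step.

#' Producible biomass components
#'
#' Opens every exchange to uptake (-1000) and tests each structural biomass
#' component (carrier-charged or free form actually consumed by the biomass
#' reaction, excluding the ATP-hydrolysis currency) for positive maximal
#' production via [component_producibility()].
#'
#' @param model A `metabolic_model` with a biomass objective.
#' @param components Component metabolite ids; defaults to the stored
#'   structural components of the biomass reaction, or all biomass
#'   substrates except the GAM currency metabolites.
#' @param tol Production flux above which a component counts as producible.
#' @return Character vector of producible component ids.
#' @export
producible_components <- function(model, components = NULL,
                                  tol = .FLUX_ZERO_TOL) {
  if (is.null(components)) components <- structural_components(model)
  open <- set_bounds(model, exchanges(model), lb = -1000, ub = 1000)
  ok <- vapply(components, function(met) {
    component_producibility(open, met, require_in_biomass = FALSE) > tol
  }, logical(1))
  components[ok]
}

#' Structural components of the biomass reaction
#'
#' Biomass substrates minus the ATP-maintenance currency metabolites
#' (atp/h2o consumed by GAM are energy bookkeeping, not building blocks).
#'
#' @param model A `metabolic_model` with a biomass objective.
#' @param currency Currency metabolite ids excluded from the component list.
#' @return Character vector of component metabolite ids.
#' @export
structural_components <- function(model,
                                  currency = c("atp_c", "adp_c", "pi_c",
                                               "h2o_c", "h_c")) {
  stored <- attr(model, "biomass_structural_components")
  if (!is.null(stored)) return(intersect(stored, model$mets$id))
  setdiff(biomass_components(model), currency)
}

#' Greedy component-driven gap filling
#'
#' In each round, every pool reaction not yet added is grafted into the
#' model in turn and scored by the resulting number of producible biomass
#' components; the reaction with the largest strict gain is kept (ties
#' broken by lexicographic reaction id). When no single reaction helps and
#' `try_pairs` is on, unordered pairs are scored the same way (joint gaps
#' need two serial reactions at once). The loop stops when all components
#' are producible or nothing helps; any still-unproducible components are
#' reported, not raised.
#'
#' @param model A `metabolic_model` with a biomass objective.
#' @param pool A `metabolic_model` acting as the universal reaction pool
#'   (ids must not clash with the model's).
#' @param medium `NULL` to gap-fill with all exchanges open (the default
#'   component-producibility convention), or a `medium_spec` to restrict
#'   candidate evaluation to one growth condition.
#' @param try_pairs Score reaction pairs when no single reaction helps.
#' @param max_pairs Budget on the number of pairs scored per round.
#' @return A `gap_fill_result`: `added` (ordered ids), `producible_before`,
#'   `producible_after`, `unproducible` (components still missing),
#'   `rounds` (per-round log), and `model` (the augmented model).
#' @export
gap_fill <- function(model, pool, medium = NULL, try_pairs = TRUE,
                     max_pairs = 200L) {
  stopifnot(inherits(pool, "metabolic_model"))
  if (nrow(pool$rxns) == 0L) stop("empty reaction pool")
  clash <- intersect(pool$rxns$id, model$rxns$id)
  if (length(clash) > 0L) {
    stop("pool reaction id(s) already in the model: ",
         paste(clash, collapse = ", "))
  }
  if (!is.null(medium)) model <- apply_medium(model, medium)

  components <- structural_components(model)
  count <- function(m) length(producible_components(m, components))
  graft <- function(m, rids) {
    for (rid in rids) {
      j <- match(rid, pool$rxns$id)
      nz <- which(pool$S[, j] != 0)
      st <- stats::setNames(pool$S[nz, j], pool$mets$id[nz])
      new_mets <- setdiff(names(st), m$mets$id)
      if (length(new_mets) > 0L) {
        mi <- match(new_mets, pool$mets$id)
        m <- add_metabolites(m, new_mets,
                             compartment = pool$mets$compartment[mi],
                             formula = pool$mets$formula[mi])
      }
      m <- add_reaction(m, rid, st, lb = pool$rxns$lb[j], ub = pool$rxns$ub[j],
                        name = pool$rxns$name[j], subsystem = "Gap filling",
                        kind = pool$rxns$kind[j])
    }
    m
  }

  before <- producible_components(model, components)
  added <- character()
  rounds <- list()
  current <- length(before)

  repeat {
    if (current >= length(components)) break
    remaining <- sort(setdiff(pool$rxns$id, added))
    if (length(remaining) == 0L) break

    gains <- vapply(remaining, function(rid) {
      count(graft(model, rid)) - current
    }, numeric(1))
    best_gain <- max(gains)
    pick <- NULL
    if (best_gain > 0) {
      pick <- remaining[gains == best_gain][1]   # sorted: lexicographic tie-break
    } else if (try_pairs && length(remaining) >= 2L) {
      pairs <- utils::combn(remaining, 2, simplify = FALSE)
      if (length(pairs) > max_pairs) pairs <- pairs[seq_len(max_pairs)]
      pair_gain <- vapply(pairs, function(pr) {
        count(graft(model, pr)) - current
      }, numeric(1))
      if (max(pair_gain) > 0) {
        pick <- pairs[[which.max(pair_gain)]]    # first best: deterministic
        best_gain <- max(pair_gain)
      }
    }
    if (is.null(pick)) break

    model <- graft(model, pick)
    added <- c(added, pick)
    current <- current + best_gain
    rounds[[length(rounds) + 1L]] <- list(added = pick, gain = best_gain,
                                          producible = current)
  }

  after <- producible_components(model, components)
  structure(list(
    added = added,
    producible_before = before,
    producible_after = after,
    unproducible = setdiff(components, after),
    rounds = rounds,
    model = model
  ), class = "gap_fill_result")
}

#' @export
print.gap_fill_result <- function(x, ...) {
  cat(sprintf("<gap_fill_result: %d reaction(s) added, %d -> %d producible components>\n",
              length(x$added), length(x$producible_before),
              length(x$producible_after)))
  if (length(x$added)) cat("  added:", paste(x$added, collapse = ", "), "\n")
  if (length(x$unproducible)) {
    cat("  still unproducible:", paste(x$unproducible, collapse = ", "), "\n")
  }
  invisible(x)
}
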