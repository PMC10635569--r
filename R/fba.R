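## Flux balance analysis engine
##
## The LP is the classic constraint-based formulation: choose the flux
## vector v maximizing (or minimizing) the objective reaction's flux subject
## to steady state S v = 0 and bounds lb <= v <= ub. Growth-window devices
## (FVA at a fraction of the optimum, production envelopes) are imposed by
## tightening the objective reaction's own bounds, which is equivalent to
## the usual c'v >= f * opt row because the objective here is always a
## single reaction.

.FLUX_ZERO_TOL <- 1e-6    # below this a flux is "zero" (blocked, no growth)
.GROWTH_ESSENTIAL_TOL <- 1e-6  # growth below this counts as "no growth"

#' Define a growth medium
#'
#' A medium is a map from exchange-reaction id to the maximal uptake rate in
#' mmol/gDW/h (a non-negative number). Applying it sets each listed
#' exchange's lower bound to minus the limit, closes uptake on every other
#' exchange, and sets all exchange upper bounds to the secretion policy.
#'
#' @param uptake_limits Named numeric vector, names = exchange reaction ids.
#' @param secretion_ub Default upper (secretion) bound for all exchanges.
#' @return A `medium_spec`.
#' @examples
#' medium_spec(c(EX_glc_e = 20, EX_nh3_e = 1000))
#' @export
medium_spec <- function(uptake_limits = numeric(), secretion_ub = 1000) {
  stopifnot(is.numeric(uptake_limits))
  if (length(uptake_limits) > 0L && is.null(names(uptake_limits))) {
    stop("uptake_limits must be named by exchange reaction id")
  }
  if (any(uptake_limits < 0)) stop("uptake limits must be non-negative")
  structure(list(uptake_limits = uptake_limits, secretion_ub = secretion_ub),
            class = "medium_spec")
}

#' Apply a medium to a model
#'
#' @param model A `metabolic_model`.
#' @param medium A `medium_spec` (or named numeric vector of uptake limits).
#' @return A copy of the model with exchange bounds set: listed exchanges get
#'   `[-limit, secretion_ub]`, all others `[0, secretion_ub]`.
#' @export
apply_medium <- function(model, medium) {
  if (is.numeric(medium)) medium <- medium_spec(medium)
  stopifnot(inherits(medium, "medium_spec"))
  ex <- exchanges(model)
  unknown <- setdiff(names(medium$uptake_limits), ex)
  if (length(unknown) > 0L) {
    stop("medium names exchange reactions absent from the model: ",
         paste(unknown, collapse = ", "),
         "; valid exchanges are: ", paste(ex, collapse = ", "))
  }
  model <- set_bounds(model, ex, lb = 0, ub = medium$secretion_ub)
  if (length(medium$uptake_limits) > 0L) {
    model <- set_bounds(model, names(medium$uptake_limits),
                        lb = -unname(medium$uptake_limits))
  }
  model
}

#' Flux balance analysis
#'
#' Solves max (or min) of the objective reaction's flux subject to
#' steady-state mass balance and the model's bounds.
#'
#' @param model A `metabolic_model` (bounds already reflect the medium).
#' @param objective Reaction id to optimize; defaults to `model$objective`.
#' @param direction `"max"` (default) or `"min"`.
#' @return A `flux_solution`: list with `status` (`"optimal"`,
#'   `"infeasible"`, `"unbounded"`), `objective_value`, and `fluxes` (named
#'   vector over reactions). When the objective is the biomass reaction the
#'   objective value is the specific growth rate in 1/h.
#' @export
fba <- function(model, objective = NULL, direction = c("max", "min")) {
  direction <- match.arg(direction)
  if (is.null(objective)) objective <- model$objective
  if (is.na(objective) || !objective %in% model$rxns$id) {
    stop("objective reaction not found: ", objective)
  }
  n <- nrow(model$rxns)
  obj <- numeric(n)
  obj[match(objective, model$rxns$id)] <- 1
  res <- solve_lp(obj, model$S, rep(0, nrow(model$mets)),
                  model$rxns$lb, model$rxns$ub, direction)
  fluxes <- res$x
  names(fluxes) <- model$rxns$id
  structure(list(status = res$status, objective_value = res$value,
                 objective = objective, fluxes = fluxes),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat(sprintf("<flux_solution: %s", x$status))
  if (x$status == "optimal") {
    cat(sprintf(", %s = %.6g", x$objective, x$objective_value))
  }
  cat(">\n")
  invisible(x)
}

#' Flux variability analysis
#'
#' For every reaction, the minimum and maximum steady-state flux subject to
#' the objective being at least `fraction_of_optimum` times its optimum.
#' `fraction_of_optimum = 0` spans the whole feasible region.
#'
#' @param model A `metabolic_model`.
#' @param fraction_of_optimum Fraction in \[0, 1\].
#' @param reactions Reaction ids to scan (default: all).
#' @return A data.frame (id, min_flux, max_flux) with attribute
#'   `"optimum"`.
#' @export
flux_variability <- function(model, fraction_of_optimum = 1,
                             reactions = NULL) {
  stopifnot(fraction_of_optimum >= 0, fraction_of_optimum <= 1)
  base <- fba(model)
  if (base$status != "optimal") {
    stop("base FBA problem is ", base$status, "; cannot run FVA")
  }
  opt <- base$objective_value
  if (fraction_of_optimum > 0) {
    j <- match(model$objective, model$rxns$id)
    ## threshold below the current lb is vacuous; keep the tighter one
    model$rxns$lb[j] <- max(model$rxns$lb[j], fraction_of_optimum * opt)
  }
  if (is.null(reactions)) reactions <- model$rxns$id
  n <- nrow(model$rxns)
  b <- rep(0, nrow(model$mets))
  out <- data.frame(id = reactions, min_flux = NA_real_, max_flux = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_along(reactions)) {
    obj <- numeric(n)
    obj[match(reactions[k], model$rxns$id)] <- 1
    lo <- solve_lp(obj, model$S, b, model$rxns$lb, model$rxns$ub, "min")
    hi <- solve_lp(obj, model$S, b, model$rxns$lb, model$rxns$ub, "max")
    out$min_flux[k] <- lo$value
    out$max_flux[k] <- hi$value
  }
  attr(out, "optimum") <- opt
  attr(out, "fraction_of_optimum") <- fraction_of_optimum
  out
}

#' Reactions unable to carry flux
#'
#' With every exchange opened to uptake (lower bound -1000, upper 1000), a
#' reaction is blocked when both its FVA minimum and maximum are within
#' tolerance of zero. Blocked reactions are typically disconnected fragments
#' (orphan secondary metabolism, incomplete pathways).
#'
#' @param model A `metabolic_model`.
#' @param tol Zero-flux tolerance.
#' @return Character vector of blocked reaction ids.
#' @export
blocked_reactions <- function(model, tol = .FLUX_ZERO_TOL) {
  ex <- exchanges(model)
  model <- set_bounds(model, ex, lb = -1000, ub = 1000)
  n <- nrow(model$rxns)
  b <- rep(0, nrow(model$mets))
  blocked <- character()
  for (k in seq_len(n)) {
    obj <- numeric(n); obj[k] <- 1
    hi <- solve_lp(obj, model$S, b, model$rxns$lb, model$rxns$ub, "max")
    if (hi$status == "optimal" && hi$value > tol) next
    lo <- solve_lp(obj, model$S, b, model$rxns$lb, model$rxns$ub, "min")
    if (lo$status == "optimal" && lo$value < -tol) next
    blocked <- c(blocked, model$rxns$id[k])
  }
  blocked
}

#' Dead-end metabolites
#'
#' A metabolite is a dead end when, accounting for reaction reversibility,
#' it can only ever be produced or only ever be consumed -- including the
#' case of a metabolite touched by a single reversible reaction, which has
#' no partner to cycle with and therefore forces that reaction silent at
#' steady state.
#'
#' @param model A `metabolic_model`.
#' @return Character vector of dead-end metabolite ids.
#' @export
dead_end_metabolites <- function(model) {
  dead <- character()
  for (i in seq_len(nrow(model$mets))) {
    js <- which(model$S[i, ] != 0)
    producers <- integer(); consumers <- integer()
    for (j in js) {
      coef <- model$S[i, j]
      can_fwd <- model$rxns$ub[j] > 0
      can_rev <- model$rxns$lb[j] < 0
      if ((coef > 0 && can_fwd) || (coef < 0 && can_rev)) producers <- c(producers, j)
      if ((coef < 0 && can_fwd) || (coef > 0 && can_rev)) consumers <- c(consumers, j)
    }
    if (length(producers) == 0L || length(consumers) == 0L) {
      dead <- c(dead, model$mets$id[i])
    } else if (length(js) == 1L) {
      ## single reversible reaction: production and consumption are the same
      ## reaction run in opposite directions; no steady-state cycling partner
      dead <- c(dead, model$mets$id[i])
    }
  }
  dead
}

#' Simulate single-gene knockouts
#'
#' For each gene, every reaction whose gene rule evaluates to FALSE under
#' the knockout has its bounds closed to zero, and the model is re-optimized.
#' A gene is essential when the knockout growth rate falls below
#' `essentiality_tol` (binary "no growth").
#'
#' @param model A `metabolic_model` with its medium already applied.
#' @param genes Genes to delete one at a time (default: all model genes).
#' @param essentiality_tol Growth threshold for the `essential` flag.
#' @return A data.frame (gene, growth, essential) with attribute
#'   `"wild_type"` (the unperturbed growth rate).
#' @export
single_gene_deletion <- function(model, genes = NULL,
                                 essentiality_tol = .GROWTH_ESSENTIAL_TOL) {
  if (is.null(genes)) genes <- model$genes
  wt <- fba(model)
  wt_mu <- if (wt$status == "optimal") wt$objective_value else 0
  trees <- lapply(model$rxns$gpr, parse_gpr)
  has_rule <- !vapply(trees, is.null, logical(1))
  out <- data.frame(gene = genes, growth = NA_real_, essential = NA,
                    stringsAsFactors = FALSE)
  for (k in seq_along(genes)) {
    g <- genes[k]
    hit <- which(has_rule & vapply(trees, function(tr) {
      !is.null(tr) && !evaluate_gene_rule(tr, g)
    }, logical(1)))
    if (length(hit) == 0L) {
      out$growth[k] <- wt_mu
    } else {
      ko <- model
      ko$rxns$lb[hit] <- 0
      ko$rxns$ub[hit] <- 0
      sol <- fba(ko)
      out$growth[k] <- if (sol$status == "optimal") sol$objective_value else 0
    }
    out$essential[k] <- out$growth[k] < essentiality_tol
  }
  attr(out, "wild_type") <- wt_mu
  out
}

#' Maximal production rate of a biomass component
#'
#' Installs a temporary demand reaction consuming the component, maximizes
#' its flux under the model's current bounds, and removes it again. For a
#' carrier-charged component (an aa-tRNA or nucleotide-sugar form recorded
#' by [build_biomass()]), the demand also releases the free carrier, as the
#' biomass reaction itself would -- otherwise the carrier pool could never
#' cycle and every charged component would look unproducible.
#'
#' @param model A `metabolic_model` whose objective is a biomass reaction.
#' @param component Metabolite id; must be consumed by the biomass reaction.
#' @param require_in_biomass Set `FALSE` to probe arbitrary metabolites.
#' @return Maximal production flux (mmol/gDW/h); 0 when infeasible.
#' @export
component_producibility <- function(model, component,
                                    require_in_biomass = TRUE) {
  if (require_in_biomass) {
    comps <- biomass_components(model)
    if (!component %in% comps) {
      stop("'", component, "' is not consumed by the biomass reaction")
    }
  }
  releases <- list(character())
  cm <- attr(model, "biomass_carriers")
  if (!is.null(cm) && component %in% cm$charged) {
    released <- cm$released[match(component, cm$charged)]
    if (released %in% model$mets$id) releases <- list(released)
  } else if (is.null(cm)) {
    ## no stored carrier map (e.g. a model read back from disk): recover
    ## candidate free carriers structurally from the reactions able to
    ## produce the charged form -- the co-consumed R-containing metabolite
    ## of a charging reaction is its free carrier
    releases <- c(releases, .carrier_candidates(model, component))
  }
  dm_id <- paste0(".DM_", component)
  best <- 0
  for (rel in releases) {
    st <- stats::setNames(-1, component)
    if (length(rel) > 0L) st[rel] <- 1
    probe <- add_reaction(model, dm_id, st, lb = 0, ub = 1000, kind = "demand")
    sol <- fba(probe, objective = dm_id)
    if (sol$status == "optimal" && sol$objective_value > best) {
      best <- sol$objective_value
    }
  }
  best
}

## candidate free carriers for a charged biomass component: for each
## reaction that can produce the component, any other R-containing
## metabolite it consumes
.carrier_candidates <- function(model, component) {
  i <- match(component, model$mets$id)
  f <- model$mets$formula[i]
  if (is.na(f) || !grepl("R", f, fixed = TRUE)) return(list())
  has_R <- function(idx) {
    ff <- model$mets$formula[idx]
    !is.na(ff) & vapply(ff, function(x) {
      cnt <- parse_formula(x)
      !is.null(cnt) && "R" %in% names(cnt)
    }, logical(1))
  }
  out <- list()
  for (j in seq_len(nrow(model$rxns))) {
    coef <- model$S[i, j]
    if (coef == 0) next
    produces <- (coef > 0 && model$rxns$ub[j] > 0) ||
      (coef < 0 && model$rxns$lb[j] < 0)
    if (!produces) next
    others <- which(model$S[, j] != 0)
    others <- others[others != i]
    consumed <- others[sign(model$S[others, j]) == -sign(coef)]
    consumed <- consumed[has_R(consumed)]
    for (k in consumed) out <- c(out, list(model$mets$id[k]))
  }
  unique(out)
}

#' Metabolites consumed by the biomass reaction
#'
#' @param model A `metabolic_model` with a biomass objective.
#' @return Character vector of component metabolite ids (negative biomass
#'   coefficients; currency metabolites used for growth-associated ATP
#'   hydrolysis are included unless filtered by the caller).
#' @export
biomass_components <- function(model) {
  j <- match(model$objective, model$rxns$id)
  if (is.na(j)) stop("model has no objective reaction")
  ids <- model$mets$id[which(model$S[, j] < 0)]
  ids
}

#' Maximize a product at a constrained growth rate
#'
#' Computes the optimal growth rate, pins the biomass flux into the window
#' `[growth_fraction * mu_opt, mu_opt]`, and maximizes the product's exchange
#' flux. The full flux vector is returned so co-produced metabolites can be
#' read off the same solution.
#'
#' @param model A `metabolic_model` (medium already applied).
#' @param product Exchange reaction id of the product.
#' @param growth_fraction Lower edge of the growth window as a fraction of
#'   the optimum (0.95 reproduces the usual "95% of optimal growth" device).
#' @return A `flux_solution` for the product maximization, with attribute
#'   `"mu_opt"`.
#' @export
max_product_at_growth <- function(model, product, growth_fraction = 0.95) {
  if (!product %in% model$rxns$id) stop("unknown product reaction: ", product)
  base <- fba(model)
  if (base$status != "optimal" || base$objective_value < .FLUX_ZERO_TOL) {
    stop("model does not grow in this medium (status ", base$status, ")")
  }
  mu <- base$objective_value
  j <- match(model$objective, model$rxns$id)
  model$rxns$lb[j] <- growth_fraction * mu
  model$rxns$ub[j] <- mu
  sol <- fba(model, objective = product)
  if (sol$status != "optimal") {
    stop("product maximization infeasible within the growth window")
  }
  attr(sol, "mu_opt") <- mu
  sol
}
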