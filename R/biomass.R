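## Biomass objective assembly
##
## The biomass pseudo-reaction consumes precursor metabolites in the molar
## proportions implied by measured macromolecular composition (mass fraction
## of dry weight per category, monomer distribution within each category)
## and is normalized so that the summed mass of all consumed components is
## exactly 1 g per gDW of biomass. Monomers that are incorporated via
## carrier molecules (tRNAs for amino acids, nucleotide sugars for
## carbohydrate monomers) are consumed in their carrier-bound form with the
## free carrier released; the mass entering the normalization is always that
## of the FREE monomer, and carriers themselves (pseudo-element R) weigh
## nothing. Growth-associated ATP maintenance (GAM) is an ATP hydrolysis
## term inside the biomass reaction; non-growth-associated maintenance
## (NGAM) is a dedicated hydrolysis reaction with a forced lower bound.

#' Macromolecular composition of dry weight
#'
#' @param fractions Named numeric vector of mass fractions of dry weight per
#'   category (e.g. `c(protein = 0.55, carbohydrate = 0.20, lipid = 0.15)`).
#'   Must be non-negative and sum to at most 1; the remainder is the
#'   unmeasured cofactor/mineral/metabolite contribution.
#' @return A `macro_composition` (fractions plus the derived remainder).
#' @export
macro_composition <- function(fractions) {
  stopifnot(is.numeric(fractions), !is.null(names(fractions)))
  if (any(fractions < 0)) stop("mass fractions must be non-negative")
  s <- sum(fractions)
  if (s > 1 + 1e-9) stop("mass fractions sum to ", format(s), " > 1")
  structure(list(fractions = fractions, remainder = max(0, 1 - s)),
            class = "macro_composition")
}

#' Monomer distribution within a composition category
#'
#' @param category Category name matching one in the composition.
#' @param shares Named numeric vector: monomer metabolite id -> share.
#' @param basis `"mass"` (shares are mass fractions of the category) or
#'   `"mole"` (shares are mole fractions).
#' @param normalize Rescale shares to sum to 1 (default). With
#'   `normalize = FALSE` the shares must already sum to 1, e.g. after
#'   [redistribute_missing()].
#' @return A `monomer_distribution`.
#' @export
monomer_distribution <- function(category, shares, basis = c("mass", "mole"),
                                 normalize = TRUE) {
  basis <- match.arg(basis)
  stopifnot(is.numeric(shares), !is.null(names(shares)))
  if (any(shares < 0)) stop("shares must be non-negative")
  s <- sum(shares)
  if (normalize) {
    if (s <= 0) stop("shares sum to zero")
    shares <- shares / s
  } else if (s > 1 + 1e-9) {
    ## raw measured tables may be incomplete (sum < 1) pending
    ## redistribute_missing(), but can never exceed 1
    stop("shares sum to ", format(s), " > 1")
  }
  structure(list(category = category, shares = shares, basis = basis),
            class = "monomer_distribution")
}

#' Spread unaccounted abundance over unmeasured monomers
#'
#' When a measured monomer table does not sum to 1 (e.g. an amino-acid assay
#' that cannot resolve asparagine, glutamine, and tryptophan), the missing
#' abundance is divided equally between the named unmeasured monomers.
#'
#' @param dist A `monomer_distribution` whose shares sum to s <= 1
#'   (construct with `normalize = FALSE` semantics by passing raw shares).
#' @param missing Character vector of monomer ids absent from the table.
#' @return A `monomer_distribution` whose shares sum to 1.
#' @export
redistribute_missing <- function(dist, missing) {
  stopifnot(inherits(dist, "monomer_distribution"))
  shares <- dist$shares
  s <- sum(shares)
  if (s > 1 + 1e-9) stop("measured shares already sum to ", format(s), " > 1")
  if (length(missing) == 0L) {
    if (abs(s - 1) > 1e-9) {
      stop("no missing monomers named but shares sum to ", format(s))
    }
    return(dist)
  }
  if (any(missing %in% names(shares))) {
    stop("monomer(s) both measured and declared missing: ",
         paste(intersect(missing, names(shares)), collapse = ", "))
  }
  add <- stats::setNames(rep((1 - s) / length(missing), length(missing)),
                         missing)
  monomer_distribution(dist$category, c(shares, add), dist$basis,
                       normalize = FALSE)
}

#' Divide lipid class mass equally among representative species
#'
#' Lipid assays resolve chain length and saturation classes but not head
#' groups; each class's mass share is split equally among the model's
#' representative lipids for that class.
#'
#' @param category_fraction Mass fraction of dry weight in the lipid
#'   category (used only to label the result; shares remain within-category).
#' @param chain_classes Named list: class -> character vector of
#'   representative lipid metabolite ids (each non-empty).
#' @param class_shares Named numeric of within-category mass shares per
#'   class; defaults to equal shares across classes.
#' @return A mass-basis `monomer_distribution` over all representatives.
#' @export
equal_split_lipids <- function(category_fraction, chain_classes,
                               class_shares = NULL) {
  stopifnot(is.list(chain_classes), length(chain_classes) > 0L)
  empty <- vapply(chain_classes, length, integer(1)) == 0L
  if (any(empty)) {
    stop("lipid class(es) with no representative species: ",
         paste(names(chain_classes)[empty], collapse = ", "))
  }
  if (is.null(class_shares)) {
    class_shares <- stats::setNames(
      rep(1 / length(chain_classes), length(chain_classes)),
      names(chain_classes))
  }
  stopifnot(setequal(names(class_shares), names(chain_classes)))
  class_shares <- class_shares / sum(class_shares)
  shares <- numeric()
  for (cl in names(chain_classes)) {
    reps <- chain_classes[[cl]]
    shares[reps] <- class_shares[[cl]] / length(reps)
  }
  monomer_distribution("lipid", shares, basis = "mass", normalize = FALSE)
}

#' Carrier map for monomers incorporated via charged carriers
#'
#' @param monomer Monomer metabolite ids (the free form whose mass counts).
#' @param charged Charged-carrier metabolite ids consumed by biomass.
#' @param released Free-carrier metabolite ids released by biomass.
#' @return A `carrier_map` data.frame.
#' @export
carrier_map <- function(monomer = character(), charged = character(),
                        released = character()) {
  stopifnot(length(monomer) == length(charged),
            length(monomer) == length(released))
  structure(data.frame(monomer = monomer, charged = charged,
                       released = released, stringsAsFactors = FALSE),
            class = c("carrier_map", "data.frame"))
}

#' Full biomass specification
#'
#' @param composition A `macro_composition`.
#' @param distributions List of `monomer_distribution`, one per modeled
#'   category.
#' @param carriers A `carrier_map` (may be empty).
#' @param gam Growth-associated ATP maintenance, mmol ATP per gDW biomass.
#' @param ngam Non-growth-associated maintenance, mmol ATP/gDW/h.
#' @return A `biomass_spec`.
#' @export
biomass_spec <- function(composition, distributions, carriers = carrier_map(),
                         gam = 0, ngam = 0) {
  stopifnot(inherits(composition, "macro_composition"),
            all(vapply(distributions, inherits, logical(1),
                       "monomer_distribution")),
            inherits(carriers, "carrier_map"), gam >= 0, ngam >= 0)
  cats <- vapply(distributions, function(d) d$category, character(1))
  if (anyDuplicated(cats)) stop("duplicate category distributions")
  incomplete <- vapply(distributions, function(d) {
    abs(sum(d$shares) - 1) > 1e-9
  }, logical(1))
  if (any(incomplete)) {
    stop("monomer shares do not sum to 1 for: ",
         paste(cats[incomplete], collapse = ", "),
         " (apply redistribute_missing() first)")
  }
  missing_cat <- setdiff(cats, names(composition$fractions))
  if (length(missing_cat) > 0L) {
    stop("distribution(s) for unmeasured category: ",
         paste(missing_cat, collapse = ", "))
  }
  structure(list(composition = composition, distributions = distributions,
                 carriers = carriers, gam = gam, ngam = ngam),
            class = "biomass_spec")
}

#' Derive biomass coefficients from a specification
#'
#' Converts category mass fractions and monomer shares to molar
#' coefficients (mmol per gDW), using free-monomer molar masses, and
#' rescales so the summed component mass is exactly 1 g/gDW.
#'
#' @param model A `metabolic_model` providing metabolite formulas.
#' @param spec A `biomass_spec`.
#' @return Named numeric vector: free-monomer metabolite id -> mmol/gDW.
#' @export
biomass_coefficients <- function(model, spec) {
  coefs <- numeric()
  for (dist in spec$distributions) {
    f_cat <- spec$composition$fractions[[dist$category]]
    ids <- names(dist$shares)
    miss <- setdiff(ids, model$mets$id)
    if (length(miss) > 0L) {
      stop("biomass monomer(s) not in model: ", paste(miss, collapse = ", "))
    }
    mw <- vapply(model$mets$formula[match(ids, model$mets$id)], molar_mass,
                 numeric(1))
    if (anyNA(mw) || any(mw <= 0)) {
      stop("missing or massless formula for biomass monomer(s): ",
           paste(ids[is.na(mw) | mw <= 0], collapse = ", "))
    }
    n <- if (dist$basis == "mass") {
      1000 * f_cat * dist$shares / mw          # mg of monomer / (mg/mmol)
    } else {
      1000 * f_cat * dist$shares / sum(dist$shares * mw)
    }
    for (i in seq_along(ids)) {
      coefs[ids[i]] <- (if (ids[i] %in% names(coefs)) coefs[[ids[i]]] else 0) + n[i]
    }
  }
  ids <- names(coefs)
  mw <- vapply(model$mets$formula[match(ids, model$mets$id)], molar_mass,
               numeric(1))
  total_mg <- sum(coefs * mw)
  coefs * (1000 / total_mg)
}

#' Install a biomass objective reaction
#'
#' Builds the biomass reaction from a specification: carrier-charged forms
#' are consumed (free carriers released) where the carrier map says so, free
#' monomers otherwise; growth-associated ATP hydrolysis is added at `gam`
#' mmol/gDW; the reaction becomes the model objective; and the NGAM
#' constraint is installed via [set_maintenance()].
#'
#' @param model A `metabolic_model` containing all referenced metabolites.
#' @param spec A `biomass_spec`.
#' @param id Reaction id for the biomass reaction.
#' @param currency Named character vector locating the ATP hydrolysis
#'   metabolites (atp, adp, pi, h2o, h).
#' @return The model with the biomass reaction installed and selected as
#'   objective. The free-monomer coefficient vector is kept in
#'   `attr(model, "biomass_free_coefficients")` for mass accounting.
#' @export
build_biomass <- function(model, spec, id = "BIOMASS",
                          currency = c(atp = "atp_c", adp = "adp_c",
                                       pi = "pi_c", h2o = "h2o_c", h = "h_c")) {
  stopifnot(inherits(spec, "biomass_spec"))
  coefs <- biomass_coefficients(model, spec)

  st <- numeric()
  bump <- function(st, met, delta) {
    st[met] <- (if (met %in% names(st)) st[[met]] else 0) + delta
    st
  }
  cm <- spec$carriers
  for (met in names(coefs)) {
    k <- match(met, cm$monomer)
    if (!is.na(k)) {
      for (needed in c(cm$charged[k], cm$released[k])) {
        if (!needed %in% model$mets$id) {
          stop("carrier metabolite not in model: ", needed)
        }
      }
      st <- bump(st, cm$charged[k], -coefs[[met]])
      st <- bump(st, cm$released[k], +coefs[[met]])
    } else {
      st <- bump(st, met, -coefs[[met]])
    }
  }
  if (id %in% model$rxns$id) model <- remove_reactions(model, id)
  attr(model, "gam") <- 0  # GAM terms are installed below by set_maintenance()
  model <- add_reaction(model, id, st, lb = 0, ub = 1000,
                        name = "biomass assembly", subsystem = "Biomass",
                        kind = "biomass")
  model <- set_objective(model, id)
  model <- set_maintenance(model, gam = spec$gam, ngam = spec$ngam,
                           currency = currency, biomass_id = id)
  attr(model, "biomass_free_coefficients") <- coefs
  ## structural components = what the reaction consumes before GAM is added
  attr(model, "biomass_structural_components") <- names(st)[st < 0]
  ## charged -> released pairs, so producibility probes can cycle carriers
  attr(model, "biomass_carriers") <- cm[cm$monomer %in% names(coefs), ]
  model
}

#' Set ATP maintenance coefficients
#'
#' Rewrites the growth-associated maintenance (GAM) ATP-hydrolysis term of
#' the biomass reaction to `gam` mmol/gDW and enforces non-growth-associated
#' maintenance (NGAM) as a dedicated hydrolysis reaction
#' (`atp + h2o -> adp + pi + h`) with lower bound `ngam` mmol/gDW/h.
#'
#' @param model A `metabolic_model` with a biomass reaction.
#' @param gam,ngam Maintenance coefficients (non-negative).
#' @param currency Named character vector as in [build_biomass()].
#' @param biomass_id Biomass reaction id; defaults to the objective.
#' @param ngam_id Id of the maintenance reaction (created if absent).
#' @return The updated model, with `attr(model, "gam")` recording the
#'   installed GAM.
#' @export
set_maintenance <- function(model, gam, ngam,
                            currency = c(atp = "atp_c", adp = "adp_c",
                                         pi = "pi_c", h2o = "h2o_c", h = "h_c"),
                            biomass_id = NULL, ngam_id = "ATPM") {
  stopifnot(gam >= 0, ngam >= 0)
  if (is.null(biomass_id)) biomass_id <- model$objective
  j <- match(biomass_id, model$rxns$id)
  if (is.na(j)) stop("biomass reaction not found: ", biomass_id)
  old_gam0 <- attr(model, "gam")
  if (gam == 0 && ngam == 0 && (is.null(old_gam0) || old_gam0 == 0) &&
      !ngam_id %in% model$rxns$id &&
      !all(currency %in% model$mets$id)) {
    ## a currency-free model with no maintenance to install stays valid;
    ## models that do carry currency metabolites always get the ATPM sink
    ## (lower bound 0) so surplus ATP can be hydrolyzed
    attr(model, "gam") <- 0
    attr(model, "ngam") <- 0
    return(model)
  }
  missing_cur <- setdiff(currency, model$mets$id)
  if (length(missing_cur) > 0L) {
    stop("currency metabolite(s) missing: ",
         paste(missing_cur, collapse = ", "))
  }

  old_gam <- attr(model, "gam")
  if (is.null(old_gam)) old_gam <- 0
  delta <- gam - old_gam
  mi <- match(currency, model$mets$id)
  model$S[mi[[1]], j] <- model$S[mi[[1]], j] - delta  # atp
  model$S[mi[[4]], j] <- model$S[mi[[4]], j] - delta  # h2o
  model$S[mi[[2]], j] <- model$S[mi[[2]], j] + delta  # adp
  model$S[mi[[3]], j] <- model$S[mi[[3]], j] + delta  # pi
  model$S[mi[[5]], j] <- model$S[mi[[5]], j] + delta  # h
  attr(model, "gam") <- gam

  if (!ngam_id %in% model$rxns$id) {
    st <- stats::setNames(c(-1, -1, 1, 1, 1),
                          currency[c("atp", "h2o", "adp", "pi", "h")])
    model <- add_reaction(model, ngam_id, st, lb = ngam, ub = 1000,
                          name = "non-growth ATP maintenance",
                          subsystem = "Maintenance", kind = "maintenance")
  } else {
    model <- set_bounds(model, ngam_id, lb = ngam)
  }
  attr(model, "ngam") <- ngam
  model
}

#' Summed free-monomer mass of the biomass reaction
#'
#' @param model A model built with [build_biomass()].
#' @return Total component mass in g per gDW (should be 1 within 0.1%).
#' @export
biomass_mass <- function(model) {
  coefs <- attr(model, "biomass_free_coefficients")
  if (is.null(coefs)) stop("model has no stored biomass coefficients")
  mw <- vapply(model$mets$formula[match(names(coefs), model$mets$id)],
               molar_mass, numeric(1))
  sum(coefs * mw) / 1000
}
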