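## Headline analysis workflows
##
## Reproducible pipelines over any model + media: nutrient-utilization
## screening against experimental calls, fermentation-product envelopes at
## a constrained growth rate, exchange carbon balancing, growth efficiency
## per C-mmol of substrate, co-metabolism of fermentation products and
## amino acids with differential gene essentiality, and a supplementation
## scan ranking nutrients by their effect on product maxima.

#' In-silico nutrient utilization screen
#'
#' Simulates the model with and without each nutrient added to a base
#' medium; a nutrient is called positive when the growth-rate increase
#' reaches `growth_threshold`. When experimental calls are supplied the
#' confusion matrix and sensitivity/specificity are computed over the
#' testable nutrients.
#'
#' @param model A `metabolic_model` with a biomass objective.
#' @param base_medium A `medium_spec` (dilute background that permits some
#'   baseline growth).
#' @param nutrients Exchange reaction ids to test.
#' @param per_nutrient_uptake Uptake cap for the added nutrient, mmol/gDW/h.
#' @param growth_threshold Minimal growth increase (1/h) for a positive
#'   call.
#' @param experimental Optional named logical vector (by exchange id):
#'   experimentally observed utilization.
#' @return A `screen_result`: `table` (per-nutrient delta and calls),
#'   `untestable` (ids without an exchange reaction), and, with labels,
#'   `sensitivity`, `specificity`, and the confusion counts.
#' @export
nutrient_screen <- function(model, base_medium, nutrients,
                            per_nutrient_uptake = 20,
                            growth_threshold = 0.01,
                            experimental = NULL) {
  untestable <- setdiff(nutrients, exchanges(model))
  nutrients <- intersect(nutrients, exchanges(model))
  base <- fba(apply_medium(model, base_medium))
  mu0 <- if (base$status == "optimal") base$objective_value else 0

  rows <- lapply(nutrients, function(nx) {
    lim <- base_medium$uptake_limits
    lim[nx] <- max(per_nutrient_uptake,
                   if (nx %in% names(lim)) lim[[nx]] else 0)
    sol <- fba(apply_medium(model, medium_spec(lim, base_medium$secretion_ub)))
    mu <- if (sol$status == "optimal") sol$objective_value else 0
    data.frame(nutrient = nx, mu_base = mu0, mu_with = mu,
               delta = mu - mu0, predicted = (mu - mu0) >= growth_threshold,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)

  out <- list(table = tab, untestable = untestable, base_growth = mu0)
  if (!is.null(experimental)) {
    exp_call <- experimental[tab$nutrient]
    keep <- !is.na(exp_call)
    tp <- sum(tab$predicted[keep] & exp_call[keep])
    fn <- sum(!tab$predicted[keep] & exp_call[keep])
    tn <- sum(!tab$predicted[keep] & !exp_call[keep])
    fp <- sum(tab$predicted[keep] & !exp_call[keep])
    out$table$experimental <- unname(exp_call)
    out$confusion <- c(TP = tp, FP = fp, TN = tn, FN = fn)
    out$sensitivity <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    out$specificity <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  }
  structure(out, class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("<screen_result: %d nutrients, base growth %.4g/h>\n",
              nrow(x$table), x$base_growth))
  if (!is.null(x$sensitivity)) {
    cat(sprintf("  sensitivity %.3g, specificity %.3g\n",
                x$sensitivity, x$specificity))
  }
  invisible(x)
}

#' Fermentation product envelope at constrained growth
#'
#' For each product, pins growth into `[growth_fraction * mu_opt, mu_opt]`
#' and maximizes that product's secretion; each row of the result records
#' the co-secretion of every listed product (plus CO2 when the model has a
#' CO2 exchange) in the same optimal solution. The diagonal entries are the
#' reproducible per-product maxima; off-diagonal entries depend on which
#' optimal vertex the solver returns and should be read as one attainable
#' profile, not a unique prediction.
#'
#' @param model A `metabolic_model`.
#' @param medium A `medium_spec`.
#' @param products Exchange reaction ids of the fermentation products.
#' @param growth_fraction Growth window fraction (default 0.95).
#' @param co2 CO2 exchange id appended to the columns when present in the
#'   model (`NULL` to disable).
#' @return An `envelope_table` data.frame (rows = maximized product,
#'   columns = co-product fluxes) with attributes `"growth_window"` and
#'   `"mu_opt"`.
#' @export
fermentation_envelope <- function(model, medium, products,
                                  growth_fraction = 0.95,
                                  co2 = "EX_co2_e") {
  missing_p <- setdiff(products, model$rxns$id)
  if (length(missing_p) > 0L) {
    stop("product exchange(s) not in model: ",
         paste(missing_p, collapse = ", "))
  }
  model <- apply_medium(model, medium)
  cols <- products
  if (!is.null(co2) && co2 %in% model$rxns$id) cols <- union(cols, co2)
  tab <- matrix(NA_real_, length(products), length(cols),
                dimnames = list(products, cols))
  mu_opt <- NA_real_
  for (p in products) {
    sol <- max_product_at_growth(model, p, growth_fraction)
    mu_opt <- attr(sol, "mu_opt")
    v <- sol$fluxes[cols]
    v[abs(v) < .FLUX_ZERO_TOL] <- 0
    tab[p, ] <- v
  }
  out <- as.data.frame(tab)
  attr(out, "mu_opt") <- mu_opt
  attr(out, "growth_window") <- c(growth_fraction * mu_opt, mu_opt)
  class(out) <- c("envelope_table", "data.frame")
  out
}

#' Carbon balance of a flux solution
#'
#' Sums carbon atoms crossing the boundary: influx over uptaking exchanges,
#' efflux over secreting exchanges; at steady state the difference is the
#' carbon fixed into biomass.
#'
#' @param model A `metabolic_model`.
#' @param solution A `flux_solution` from this model.
#' @param tol Exchange fluxes below this are ignored.
#' @return A list: `c_in`, `c_out_products`, `c_in_biomass` (all
#'   C-mmol/gDW/h), and `fraction_to_products`.
#' @export
carbon_balance <- function(model, solution, tol = .FLUX_ZERO_TOL) {
  stopifnot(inherits(solution, "flux_solution"))
  ex <- exchanges(model)
  c_in <- 0; c_out <- 0
  for (rx in ex) {
    v <- solution$fluxes[[rx]]
    if (abs(v) <= tol) next
    j <- match(rx, model$rxns$id)
    i <- which(model$S[, j] != 0)
    nC <- element_count(model$mets$formula[i], "C")
    if (is.na(nC)) {
      stop("exchanged metabolite ", model$mets$id[i],
           " has no formula; carbon balance impossible")
    }
    if (nC == 0) next
    if (v < 0) c_in <- c_in + (-v) * nC else c_out <- c_out + v * nC
  }
  list(c_in = c_in, c_out_products = c_out, c_in_biomass = c_in - c_out,
       fraction_to_products = if (c_in > 0) c_out / c_in else NA_real_)
}

#' Growth efficiency on carbon sources
#'
#' Each substrate's uptake is capped at `total_c_flux / (carbon atoms per
#' molecule)`, so all substrates offer the same carbon flux; efficiency is
#' the resulting growth rate per realized C-mmol of uptake -- how well a
#' carbon source is incorporated into biomass.
#'
#' @param model A `metabolic_model`.
#' @param substrates Exchange reaction ids of candidate carbon sources.
#' @param base_medium Carbon-free background medium (minerals, nitrogen).
#' @param total_c_flux Offered carbon flux, C-mmol/gDW/h (default 120).
#' @return An `efficiency_result` data.frame: substrate, carbon_atoms,
#'   uptake_bound, realized_uptake, realized_c_uptake, growth, efficiency.
#' @export
growth_efficiency <- function(model, substrates, base_medium,
                              total_c_flux = 120) {
  rows <- lapply(substrates, function(sx) {
    j <- match(sx, model$rxns$id)
    if (is.na(j) || model$rxns$kind[j] != "exchange") {
      stop("not an exchange reaction: ", sx)
    }
    i <- which(model$S[, j] != 0)
    nC <- element_count(model$mets$formula[i], "C")
    if (is.na(nC) || nC < 1) {
      stop("substrate ", model$mets$id[i], " has no carbon (formula ",
           model$mets$formula[i], ")")
    }
    bound <- total_c_flux / nC
    lim <- base_medium$uptake_limits
    lim[sx] <- bound
    sol <- fba(apply_medium(model, medium_spec(lim, base_medium$secretion_ub)))
    mu <- if (sol$status == "optimal") sol$objective_value else 0
    realized <- if (sol$status == "optimal") max(0, -sol$fluxes[[sx]]) else 0
    data.frame(substrate = sx, carbon_atoms = nC, uptake_bound = bound,
               realized_uptake = realized,
               realized_c_uptake = realized * nC, growth = mu,
               efficiency = if (realized > 0) mu / (realized * nC) else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("efficiency_result", "data.frame")
  out
}

#' Co-metabolism of fermentation products and amino acids
#'
#' Simulates each carbon source under four supplement regimes -- nothing, a
#' fermentation-product (VFA) mixture, an amino-acid mixture, or both, all
#' capped at `cap` mmol/gDW/h per compound -- and flags growth improvements
#' above `improvement_threshold`. Optionally repeats single-gene deletion
#' under chosen regimes on a designated medium, counting per essential gene
#' how many biomass components its knockout blocks, and reporting the
#' differentially essential genes.
#'
#' @param model A `metabolic_model`.
#' @param carbon_sources Exchange ids tested as the main carbon source
#'   (`character(0)` allowed: the regimes alone are simulated once).
#' @param vfa_mix,aa_mix Exchange ids of the two supplement mixtures.
#' @param base_medium Mineral background medium.
#' @param cap Per-compound uptake cap for carbon sources and supplements.
#' @param improvement_threshold Minimal growth-rate gain (1/h) counted as
#'   an improvement.
#' @param essentiality_source Carbon source (exchange id) on which gene
#'   essentiality is compared across regimes; `NULL` skips the knockout
#'   analysis.
#' @param essentiality_regimes Regimes compared in the knockout analysis.
#' @param aa_cap_essentiality Optional tighter amino-acid cap for the
#'   essentiality comparison (robustness device; e.g. 0.01 mmol/gDW/h).
#' @return A `co_metabolism_result`: `growth` (source x regime data.frame),
#'   `improvement` (logical flags vs the "none" regime), and, when
#'   requested, `essential` (list of gene sets per regime),
#'   `blocked_components` (per-gene counts per regime), `mean_blocked`
#'   (means over essential genes), `differential` (genes essential in the
#'   first regime but not the second).
#' @export
co_metabolism <- function(model, carbon_sources, vfa_mix, aa_mix,
                          base_medium, cap = 20,
                          improvement_threshold = 0.001,
                          essentiality_source = NULL,
                          essentiality_regimes = c("none", "aa"),
                          aa_cap_essentiality = NULL) {
  regimes <- c("none", "vfa", "aa", "both")
  regime_medium <- function(source, regime, aa_cap = cap) {
    lim <- base_medium$uptake_limits
    if (!is.null(source)) lim[source] <- cap
    if (regime %in% c("vfa", "both")) lim[vfa_mix] <- cap
    if (regime %in% c("aa", "both")) lim[aa_mix] <- aa_cap
    medium_spec(lim, base_medium$secretion_ub)
  }
  grow <- function(medium) {
    sol <- fba(apply_medium(model, medium))
    if (sol$status == "optimal") sol$objective_value else 0
  }

  sources <- if (length(carbon_sources) > 0L) carbon_sources else "(no carbon source)"
  growth <- matrix(NA_real_, length(sources), length(regimes),
                   dimnames = list(sources, regimes))
  for (s in seq_along(sources)) {
    src <- if (sources[s] == "(no carbon source)") NULL else sources[s]
    for (r in regimes) growth[s, r] <- grow(regime_medium(src, r))
  }
  improvement <- growth[, c("vfa", "aa", "both"), drop = FALSE] -
    growth[, "none"] > improvement_threshold

  out <- list(growth = as.data.frame(growth),
              improvement = as.data.frame(improvement),
              improvement_threshold = improvement_threshold)

  if (!is.null(essentiality_source)) {
    aa_cap <- if (is.null(aa_cap_essentiality)) cap else aa_cap_essentiality
    ess <- list(); blocked <- list()
    for (r in essentiality_regimes) {
      med <- regime_medium(essentiality_source, r, aa_cap = aa_cap)
      applied <- apply_medium(model, med)
      del <- single_gene_deletion(applied)
      genes <- del$gene[del$essential]
      ess[[r]] <- genes
      blocked[[r]] <- blocked_components_per_gene(applied, genes)
    }
    out$essential <- ess
    out$blocked_components <- blocked
    out$mean_blocked <- vapply(blocked, function(b) {
      if (length(b)) mean(b) else NA_real_
    }, numeric(1))
    if (length(essentiality_regimes) >= 2L) {
      out$differential <- setdiff(ess[[essentiality_regimes[1]]],
                                  ess[[essentiality_regimes[2]]])
    }
  }
  structure(out, class = "co_metabolism_result")
}

#' Biomass components blocked by each gene knockout
#'
#' For each gene, closes the reactions its knockout disables and counts the
#' structural biomass components whose maximal production falls below
#' tolerance under the model's current medium.
#'
#' @param model A `metabolic_model` with its medium applied.
#' @param genes Genes to evaluate.
#' @param tol Producibility threshold.
#' @return Named integer vector: gene -> number of blocked components.
#' @export
blocked_components_per_gene <- function(model, genes, tol = .FLUX_ZERO_TOL) {
  comps <- structural_components(model)
  trees <- lapply(model$rxns$gpr, parse_gpr)
  has_rule <- !vapply(trees, is.null, logical(1))
  out <- stats::setNames(integer(length(genes)), genes)
  for (g in genes) {
    hit <- which(has_rule & vapply(trees, function(tr) {
      !is.null(tr) && !evaluate_gene_rule(tr, g)
    }, logical(1)))
    ko <- model
    if (length(hit) > 0L) {
      ko$rxns$lb[hit] <- 0
      ko$rxns$ub[hit] <- 0
    }
    out[g] <- sum(vapply(comps, function(met) {
      component_producibility(ko, met, require_in_biomass = FALSE) <= tol
    }, logical(1)))
  }
  out
}

#' Rank supplements by their effect on product maxima
#'
#' Each candidate supplement is added on top of the medium at an extra
#' carbon flux of `supplement_c_flux` C-mmol/gDW/h (converted to a molar
#' uptake via its carbon count), and every product's constrained maximum is
#' recomputed. Carbon-free candidates are skipped unless
#' `include_carbon_free` is set, in which case the cap is applied in
#' mmol/gDW/h directly (nitrogen-source mode).
#'
#' @param model A `metabolic_model`.
#' @param medium The unsupplemented `medium_spec`.
#' @param products Product exchange ids (see [fermentation_envelope()]).
#' @param supplements Candidate exchange ids; default: every exchange whose
#'   metabolite contains carbon.
#' @param supplement_c_flux Added carbon flux per supplement.
#' @param growth_fraction Growth window fraction.
#' @param ratio_pair Two product ids whose diagonal-maximum ratio is
#'   tracked (defaults to the first two products); `NULL` disables.
#' @param include_carbon_free Also test carbon-free supplements.
#' @return A `supplement_scan` data.frame in long format (supplement,
#'   product, baseline, with_supplement, delta) with attributes
#'   `"ranking"` (per-product supplement order by delta) and `"ratios"`
#'   (baseline and per-supplement product ratios).
#' @export
supplementation_scan <- function(model, medium, products, supplements = NULL,
                                 supplement_c_flux = 10,
                                 growth_fraction = 0.95,
                                 ratio_pair = NULL,
                                 include_carbon_free = FALSE) {
  if (is.null(supplements)) {
    supplements <- Filter(function(rx) {
      i <- which(model$S[, match(rx, model$rxns$id)] != 0)
      nC <- element_count(model$mets$formula[i], "C")
      !is.na(nC) && nC > 0
    }, exchanges(model))
  }
  if (is.null(ratio_pair) && length(products) >= 2L) {
    ratio_pair <- products[1:2]
  }

  diag_maxima <- function(med) {
    applied <- apply_medium(model, med)
    vapply(products, function(p) {
      max_product_at_growth(applied, p, growth_fraction)$objective_value
    }, numeric(1))
  }
  base <- diag_maxima(medium)

  rows <- list(); ratios <- c(baseline = if (!is.null(ratio_pair))
    base[[ratio_pair[1]]] / base[[ratio_pair[2]]] else NA_real_)
  for (sx in supplements) {
    i <- which(model$S[, match(sx, model$rxns$id)] != 0)
    nC <- element_count(model$mets$formula[i], "C")
    if (is.na(nC)) stop("supplement metabolite without formula: ", sx)
    if (nC == 0 && !include_carbon_free) next
    extra <- if (nC > 0) supplement_c_flux / nC else supplement_c_flux
    lim <- medium$uptake_limits
    lim[sx] <- (if (sx %in% names(lim)) lim[[sx]] else 0) + extra
    vals <- diag_maxima(medium_spec(lim, medium$secretion_ub))
    rows[[sx]] <- data.frame(supplement = sx, product = products,
                             baseline = unname(base),
                             with_supplement = unname(vals),
                             delta = unname(vals - base),
                             stringsAsFactors = FALSE)
    if (!is.null(ratio_pair)) {
      ratios[sx] <- vals[[ratio_pair[1]]] / vals[[ratio_pair[2]]]
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  ranking <- lapply(stats::setNames(products, products), function(p) {
    sub <- out[out$product == p, ]
    sub$supplement[order(-sub$delta, sub$supplement)]
  })
  attr(out, "ranking") <- ranking
  attr(out, "ratios") <- ratios
  class(out) <- c("supplement_scan", "data.frame")
  out
}
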