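## Synthetic fixture generators
##
## Small fermenter networks whose LP optima are hand-computable, mirroring
## the topology of saccharolytic gut bacteria: one sugar substrate, a
## glycolysis-like branch per fermentation product with an explicit ATP
## stoichiometry, amino-acid and lipid precursor synthesis, carrier-cycled
## biomass incorporation (tRNA and nucleotide-sugar analogues), and GAM /
## NGAM hooks. Everything is mass-balanced except hydrogen (by policy) and
## seeded, so identical seeds give identical fixtures.

## run code with a seed without clobbering the caller's RNG stream
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Specification for a toy fermenter network
#'
#' @param seed Integer seed (used by downstream jittered fixtures).
#' @param n_branches Number of fermentation branches (>= 1); each branch i
#'   converts one substrate into two units of fermentation product i and
#'   `atp_yield[i]` ATP.
#' @param atp_yield ATP stoichiometry per branch; defaults to 4 for branch
#'   1, 2 for branch 2, and 1 for any further branch, so branch yields are
#'   distinct and the optimal allocation is hand-computable.
#' @param biomass Subset of `c("protein", "carbohydrate", "lipid")` to
#'   include as biomass categories; an empty vector gives a pure
#'   ATP-hydrolysis biomass (useful for closed-form maintenance tests).
#' @param include_periplasm Route substrate import through a periplasm
#'   compartment (two transport steps instead of one).
#' @param gam Growth-associated ATP maintenance, mmol/gDW.
#' @param ngam Non-growth-associated ATP maintenance, mmol/gDW/h.
#' @param sub_uptake Default substrate uptake bound, mmol/gDW/h.
#' @return A `toy_spec` list.
#' @export
toy_spec <- function(seed = 1L, n_branches = 2L, atp_yield = NULL,
                     biomass = c("protein", "carbohydrate", "lipid"),
                     include_periplasm = FALSE, gam = 30, ngam = 5,
                     sub_uptake = 10) {
  stopifnot(n_branches >= 1L)
  if (is.null(atp_yield)) {
    atp_yield <- c(4, 2, rep(1, max(0L, n_branches - 2L)))[seq_len(n_branches)]
  }
  stopifnot(length(atp_yield) == n_branches, all(atp_yield >= 0))
  structure(list(seed = as.integer(seed), n_branches = as.integer(n_branches),
                 atp_yield = atp_yield, biomass = biomass,
                 include_periplasm = include_periplasm, gam = gam,
                 ngam = ngam, sub_uptake = sub_uptake),
            class = "toy_spec")
}

## fixed formulas of the toy universe; everything balances except H
.TOY_FORMULAS <- c(
  sub = "C6H12O6",       # glucose-like hexose
  prod = "C3H6O3",       # lactate-like C3 fermentation product
  nh3 = "H3N", h2o = "H2O", h = "H",
  atp = "C10H16N5O13P3", adp = "C10H15N5O10P2", pi = "H3PO4",
  ser = "C3H7NO3",       # amino-acid analogue from prod + NH3
  aa2 = "C3H7NO3",
  aa3 = "C6H13NO6",      # condensation of two C3 products + NH3
  trnaA = "R", trnaB = "R", nds = "R",
  sertrna = "C3H7NO3R", aa2trna = "C3H7NO3R", ndsglc = "C6H10O5R",
  lip = "C6H10O5"        # lipid-like polymer from 2 C3 products + ATP
)

#' Default medium for the toy fermenter
#'
#' Substrate-limited: the sugar uptake is capped, while ammonia and water
#' are freely available ("minerals"); amino acids and fermentation products
#' are closed unless listed in `extra`.
#'
#' @param sub_uptake Substrate uptake cap, mmol/gDW/h.
#' @param extra Additional named uptake limits, e.g. `c(EX_prod1_e = 20)`.
#' @return A `medium_spec`.
#' @export
toy_medium <- function(sub_uptake = 10, extra = numeric()) {
  base <- c(EX_sub_e = sub_uptake, EX_nh3_e = 1000, EX_h2o_e = 1000)
  base[names(extra)] <- extra
  medium_spec(base)
}

#' The default composition tables behind the toy biomass
#'
#' With `seed = NULL` the canonical (unjittered) tables are returned; with a
#' seed the shares and fractions are perturbed multiplicatively (about 5%)
#' while keeping the table schema, so tests can exercise many compositions.
#' The protein table is deliberately incomplete -- the third amino-acid
#' analogue is unmeasured -- so the pipeline must apply
#' [redistribute_missing()]; the lipid table goes through
#' [equal_split_lipids()].
#'
#' @param seed `NULL` for the canonical tables, or an integer jitter seed.
#' @return A list with the raw tables (`composition`, `protein_measured`,
#'   `protein_missing`, `carbohydrate`, `lipid_classes`, `carriers`,
#'   `gam`, `ngam`) and the assembled `spec` (a [biomass_spec()]).
#' @export
composition_fixture <- function(seed = NULL) {
  fr <- c(protein = 0.55, carbohydrate = 0.20, lipid = 0.15)
  prot <- c(ser_c = 0.55, aa2_c = 0.35)   # sums to 0.90: aa3 unmeasured
  if (!is.null(seed)) {
    jit <- .with_seed(seed, stats::runif(5, 0.95, 1.05))
    fr <- fr * jit[1:3]
    fr <- fr / sum(fr) * 0.90             # keep a nonzero remainder
    prot <- prot * jit[4:5]
    prot <- prot / sum(prot) * 0.90
  }
  composition <- macro_composition(fr)
  protein_measured <- monomer_distribution("protein", prot, basis = "mass",
                                           normalize = FALSE)
  protein <- redistribute_missing(protein_measured, "aa3_c")
  carbohydrate <- monomer_distribution("carbohydrate", c(sub_c = 1),
                                       basis = "mass")
  lipid_classes <- list(c6 = "lip_c")
  lipid <- equal_split_lipids(fr[["lipid"]], lipid_classes)
  carriers <- carrier_map(
    monomer = c("ser_c", "aa2_c", "sub_c"),
    charged = c("sertrna_c", "aa2trna_c", "ndsglc_c"),
    released = c("trnaA_c", "trnaB_c", "nds_c"))
  spec <- biomass_spec(composition, list(protein, carbohydrate, lipid),
                       carriers = carriers)
  list(composition = composition, protein_measured = protein_measured,
       protein_missing = "aa3_c", carbohydrate = carbohydrate,
       lipid_classes = lipid_classes, carriers = carriers, spec = spec)
}

#' Generate a toy fermenter model
#'
#' Builds the network described in [toy_spec()]: substrate exchange and
#' transport, `n_branches` fermentation branches with explicit ATP
#' stoichiometry, precursor synthesis for three amino-acid analogues and a
#' lipid, carrier charging reactions, a composition-derived biomass
#' reaction, and GAM/NGAM maintenance. Gene rules include an isozyme pair
#' (branch 2), an enzyme complex (first amino-acid synthesis), and
#' porin-like transports with no gene association. The default medium
#' (substrate-limited, see [toy_medium()]) is already applied.
#'
#' The hand-derived optimal growth rate for the default wiring is available
#' from [toy_expected_growth()], which is pure arithmetic and independent of
#' the LP engine.
#'
#' @param spec A `toy_spec`.
#' @return A validated `metabolic_model`.
#' @export
toy_fermenter <- function(spec = toy_spec()) {
  stopifnot(inherits(spec, "toy_spec"))
  nb <- spec$n_branches
  m <- empty_model(id = sprintf("toy_fermenter_%db", nb))

  fml <- .TOY_FORMULAS
  add_pair <- function(m, base) {
    add_metabolites(m, c(paste0(base, "_e"), paste0(base, "_c")),
                    formula = fml[[base]])
  }
  m <- add_pair(m, "sub")
  for (i in seq_len(nb)) {
    m <- add_metabolites(m, sprintf(c("prod%d_e", "prod%d_c"), i),
                         formula = fml[["prod"]])
  }
  for (base in c("nh3", "h2o", "h", "ser", "aa2")) m <- add_pair(m, base)
  for (base in c("atp", "adp", "pi", "aa3", "trnaA", "trnaB", "nds",
                 "sertrna", "aa2trna", "ndsglc", "lip")) {
    m <- add_metabolites(m, paste0(base, "_c"), formula = fml[[base]])
  }
  if (spec$include_periplasm) {
    m <- add_metabolites(m, "sub_p", formula = fml[["sub"]])
  }

  ## exchanges (baseline closed for organics; medium opens what it lists)
  for (met in c("sub", sprintf("prod%d", seq_len(nb)), "nh3", "h2o", "h",
                "ser", "aa2")) {
    m <- add_reaction(m, sprintf("EX_%s_e", met),
                      stats::setNames(-1, sprintf("%s_e", met)),
                      lb = 0, ub = 1000, kind = "exchange",
                      name = sprintf("%s exchange", met))
  }

  ## transports
  if (spec$include_periplasm) {
    m <- add_reaction(m, "SUBt_ep", "sub_e --> sub_p", gpr = "",
                      name = "substrate porin (outer)")
    m <- add_reaction(m, "SUBt_pc", "sub_p --> sub_c", gpr = "g_subT",
                      name = "substrate transport (inner)")
  } else {
    m <- add_reaction(m, "SUBt", "sub_e --> sub_c", gpr = "g_subT",
                      name = "substrate transport")
  }
  for (i in seq_len(nb)) {
    m <- add_reaction(m, sprintf("PROD%dt", i),
                      sprintf("prod%d_c <=> prod%d_e", i, i),
                      lb = -1000, gpr = sprintf("g_prod%dT", i),
                      name = sprintf("product %d transport", i))
  }
  m <- add_reaction(m, "NH3t", "nh3_e --> nh3_c", gpr = "g_nh3T")
  m <- add_reaction(m, "H2Ot", "h2o_e <=> h2o_c", lb = -1000, gpr = "")
  m <- add_reaction(m, "Ht", "h_c --> h_e", gpr = "")
  m <- add_reaction(m, "SERt", "ser_e --> ser_c", gpr = "g_serT")
  m <- add_reaction(m, "AA2t", "aa2_e --> aa2_c", gpr = "g_aa2T")

  ## fermentation branches: sub + y adp + y pi -> 2 prod_i + y atp + y h2o
  for (i in seq_len(nb)) {
    y <- spec$atp_yield[i]
    st <- stats::setNames(
      c(-1, 2, -y, -y, y, y),
      c("sub_c", sprintf("prod%d_c", i), "adp_c", "pi_c", "atp_c", "h2o_c"))
    gpr <- if (i == 2L) "g_br2a or g_br2b" else sprintf("g_br%d", i)
    m <- add_reaction(m, sprintf("BR%d", i), st[st != 0], gpr = gpr,
                      subsystem = "Fermentation",
                      name = sprintf("fermentation branch %d (%g ATP)", i, y))
  }

  prec2 <- sprintf("prod%d_c", min(2L, nb))
  m <- add_reaction(m, "SER_SYN", "prod1_c + nh3_c --> ser_c",
                    gpr = "g_ser1 and g_ser2", subsystem = "Amino acids",
                    name = "amino acid 1 synthesis (complex)")
  m <- add_reaction(m, "AA2_SYN", paste(prec2, "+ nh3_c --> aa2_c"),
                    gpr = "g_aa2", subsystem = "Amino acids")
  m <- add_reaction(m, "AA3_SYN",
                    paste("prod1_c +", prec2, "+ nh3_c --> aa3_c"),
                    gpr = "g_aa3", subsystem = "Amino acids")
  m <- add_reaction(m, "SER_CHARGE",
                    "ser_c + atp_c + h2o_c + trnaA_c --> sertrna_c + adp_c + pi_c",
                    gpr = "g_chS", subsystem = "Carrier charging")
  m <- add_reaction(m, "AA2_CHARGE",
                    "aa2_c + atp_c + h2o_c + trnaB_c --> aa2trna_c + adp_c + pi_c",
                    gpr = "g_chA", subsystem = "Carrier charging")
  m <- add_reaction(m, "GLC_CHARGE",
                    "sub_c + atp_c + nds_c --> ndsglc_c + adp_c + pi_c",
                    gpr = "g_chG", subsystem = "Carrier charging")
  m <- add_reaction(m, "LIP_SYN",
                    "2 prod1_c + atp_c --> lip_c + adp_c + pi_c",
                    gpr = "g_lip", subsystem = "Lipids")

  ## biomass from the canonical composition tables, restricted to the
  ## requested categories
  fixture <- composition_fixture(NULL)
  dists <- list(protein = redistribute_missing(fixture$protein_measured,
                                               fixture$protein_missing),
                carbohydrate = fixture$carbohydrate,
                lipid = equal_split_lipids(0.15, fixture$lipid_classes))
  keep <- spec$biomass
  if (length(keep) > 0L) {
    comp <- macro_composition(fixture$composition$fractions[keep])
    bspec <- biomass_spec(comp, dists[keep], carriers = fixture$carriers,
                          gam = spec$gam, ngam = spec$ngam)
    m <- build_biomass(m, bspec)
  } else {
    ## pure maintenance biomass: growth is ATP hydrolysis only
    m <- add_reaction(m, "BIOMASS", stats::setNames(numeric(0), character(0)),
                      lb = 0, ub = 1000, kind = "biomass",
                      name = "biomass (ATP drain only)")
    m <- set_objective(m, "BIOMASS")
    attr(m, "gam") <- 0
    m <- set_maintenance(m, gam = spec$gam, ngam = spec$ngam)
  }
  m <- apply_medium(m, toy_medium(spec$sub_uptake))
  validate_model(m)
  m
}

#' Hand-derived optimal growth rate of the toy fermenter
#'
#' Pure closed-form arithmetic, independent of the LP engine: with the
#' substrate exhausted and the ATP balance binding, surplus substrate flows
#' through the highest-yield branch and the growth rate solves a linear
#' equation in the biomass demands. Used as the stored oracle the engine
#' must reproduce to 1e-8.
#'
#' For the default (full biomass) wiring:
#' \deqn{\mu = (y_k U - ngam) / (A + y_k c_{carb} +
#'       \sum_{i \ne k} (y_k - y_i) d_i / 2)}
#' where k is the best-yield branch, A the ATP demand per unit growth, and
#' d_i the branch-i product demand per unit growth. With no biomass
#' categories the pure maintenance form \eqn{\mu = (y_k U - ngam)/gam}
#' applies.
#'
#' @param spec A `toy_spec`.
#' @param sub_uptake Substrate uptake; defaults to the spec's value.
#' @return The optimal growth rate in 1/h.
#' @export
toy_expected_growth <- function(spec = toy_spec(), sub_uptake = NULL) {
  if (is.null(sub_uptake)) sub_uptake <- spec$sub_uptake
  U <- sub_uptake
  y <- spec$atp_yield
  k <- which.max(y)
  yk <- y[k]

  if (length(spec$biomass) == 0L) {
    return(max(0, (yk * U - spec$ngam) / spec$gam))
  }
  if (!setequal(spec$biomass, c("protein", "carbohydrate", "lipid"))) {
    stop("closed form is derived for the full biomass or the empty one")
  }

  ## independent re-derivation of the coefficients (free-monomer masses)
  mw <- c(ser = 105.093, aa2 = 105.093, aa3 = 195.171,
          sub = 180.156, lip = 162.141)
  f <- c(protein = 0.55, carbohydrate = 0.20, lipid = 0.15)
  scale <- 1 / sum(f)                     # renormalize to 1 g
  c_ser <- 1000 * f[["protein"]] * scale * 0.55 / mw[["ser"]]
  c_aa2 <- 1000 * f[["protein"]] * scale * 0.35 / mw[["aa2"]]
  c_aa3 <- 1000 * f[["protein"]] * scale * 0.10 / mw[["aa3"]]
  c_carb <- 1000 * f[["carbohydrate"]] * scale / mw[["sub"]]
  c_lip <- 1000 * f[["lipid"]] * scale / mw[["lip"]]

  nb <- spec$n_branches
  ## product demands per unit growth, by branch
  d <- numeric(nb)
  d[1] <- c_ser + 2 * c_lip + c_aa3
  i2 <- min(2L, nb)
  d[i2] <- d[i2] + c_aa2 + c_aa3
  ## ATP demand per unit growth: three charging steps, lipid synthesis, GAM
  A <- c_ser + c_aa2 + c_carb + c_lip + spec$gam

  denom <- A + yk * c_carb + sum((yk - y[-k]) * d[-k] / 2)
  mu <- (yk * U - spec$ngam) / denom

  ## verify the closed form's feasibility assumptions
  b_other <- d[-k] * mu / 2
  b_k <- U - c_carb * mu - sum(b_other)
  stopifnot(b_k >= d[k] * mu / 2 - 1e-9)
  max(0, mu)
}

#' Remove reactions and build a repair pool
#'
#' Removes non-exchange reactions from the model (chosen by id, or sampled
#' under a seed until at least one biomass component becomes unproducible)
#' and returns the gapped model together with a universal reaction pool
#' containing the removed reactions plus seeded decoy reactions over fresh
#' metabolites. The pool is itself a `metabolic_model` whose reactions are
#' candidates for [gap_fill()].
#'
#' @param model A toy model with a biomass objective.
#' @param removed_ids Reaction ids to remove; `NULL` to sample.
#' @param n_remove Number of reactions to sample when `removed_ids` is NULL.
#' @param seed Seed for sampling and decoy generation.
#' @param n_decoys Number of irrelevant decoy reactions in the pool.
#' @return list(model = gapped model, pool = pool model,
#'   removed = removed ids, lost_components = component ids no longer
#'   producible).
#' @export
make_gapped <- function(model, removed_ids = NULL, n_remove = 1L, seed = 1L,
                        n_decoys = 5L) {
  before <- producible_components(model)
  candidates <- model$rxns$id[!model$rxns$kind %in%
                                c("exchange", "biomass", "maintenance")]
  if (is.null(removed_ids)) {
    order <- .with_seed(seed, sample(candidates))
    removed_ids <- character()
    cur_count <- length(before)
    for (rid in order) {
      trial <- remove_reactions(model, c(removed_ids, rid))
      n_trial <- length(producible_components(trial))
      if (n_trial < cur_count) {         # this removal breaks something new
        removed_ids <- c(removed_ids, rid)
        cur_count <- n_trial
      }
      if (length(removed_ids) >= n_remove) break
    }
    if (length(removed_ids) == 0L) {
      stop("could not find a removal that breaks a biomass component")
    }
  } else {
    stopifnot(all(removed_ids %in% candidates))
  }

  gapped <- remove_reactions(model, removed_ids)
  after <- producible_components(gapped)
  if (length(after) == length(before)) {
    warning("removal of ", paste(removed_ids, collapse = ", "),
            " blocks no biomass component")
  }

  pool <- empty_model(id = "repair_pool")
  ## the removed reactions, verbatim
  for (rid in removed_ids) {
    j <- match(rid, model$rxns$id)
    nz <- which(model$S[, j] != 0)
    st <- stats::setNames(model$S[nz, j], model$mets$id[nz])
    new_mets <- setdiff(names(st), pool$mets$id)
    mi <- match(new_mets, model$mets$id)
    pool <- add_metabolites(pool, new_mets,
                            compartment = model$mets$compartment[mi],
                            formula = model$mets$formula[mi])
    pool <- add_reaction(pool, rid, st, lb = model$rxns$lb[j],
                         ub = model$rxns$ub[j], name = model$rxns$name[j],
                         kind = model$rxns$kind[j])
  }
  ## seeded decoys: conversions among fresh, disconnected metabolites
  decoy_pairs <- .with_seed(seed + 1L, {
    lapply(seq_len(n_decoys), function(i) sample(1000, 2))
  })
  for (i in seq_len(n_decoys)) {
    ids <- sprintf("xmet%d_c", decoy_pairs[[i]])
    ids <- make.unique(ids)
    new_mets <- setdiff(ids, pool$mets$id)
    if (length(new_mets) > 0L) {
      pool <- add_metabolites(pool, new_mets, compartment = "c",
                              formula = "C2H4O2")
    }
    pool <- add_reaction(pool, sprintf("DECOY%d", i),
                         stats::setNames(c(-1, 1), ids),
                         name = sprintf("decoy conversion %d", i))
  }
  list(model = gapped, pool = pool, removed = removed_ids,
       lost_components = setdiff(before, after))
}

#' Synthesize growth observations from known maintenance parameters
#'
#' Runs the model with the given (GAM, NGAM) in each medium and records the
#' predicted growth as the "observed" rate, optionally with multiplicative
#' log-normal noise, yielding a calibration dataset whose ground truth is
#' known. Non-growing media are excluded with a warning; a single-medium
#' design triggers an identifiability warning (GAM and NGAM cannot be
#' separated from one equation).
#'
#' @param model A toy model with a biomass objective.
#' @param gam,ngam Ground-truth maintenance parameters.
#' @param media Named list of `medium_spec` objects.
#' @param noise_sd Standard deviation of log-multiplicative noise (0 =
#'   noiseless).
#' @param seed Seed for the noise draws.
#' @return A list of `growth_observation`s.
#' @export
synth_calibration <- function(model, gam, ngam, media, noise_sd = 0,
                              seed = 1L) {
  stopifnot(is.list(media), length(media) >= 1L)
  if (is.null(names(media))) {
    names(media) <- sprintf("condition_%d", seq_along(media))
  }
  if (length(media) < 2L) {
    warning("a single medium cannot identify GAM and NGAM separately")
  }
  noise <- if (noise_sd > 0) {
    .with_seed(seed, exp(stats::rnorm(length(media), 0, noise_sd)))
  } else rep(1, length(media))
  obs <- list()
  for (i in seq_along(media)) {
    mu <- predict_mu(model, gam, ngam, media[[i]])
    if (mu < .GROWTH_ESSENTIAL_TOL) {
      warning("medium '", names(media)[i], "' supports no growth at the ",
              "given parameters; excluded")
      next
    }
    obs[[length(obs) + 1L]] <- growth_observation(
      label = names(media)[i], medium = media[[i]],
      observed_mu = mu * noise[i])
  }
  obs
}
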