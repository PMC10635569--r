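# LP core: FBA, FVA, blocked reactions, dead ends, gene deletions,
# producibility, and constrained product maximization.

test_that("media application sets exchange bounds by convention", {
  m <- toy_fermenter()
  m2 <- apply_medium(m, medium_spec(c(EX_sub_e = 20)))
  j <- match("EX_sub_e", m2$rxns$id)
  expect_equal(m2$rxns$lb[j], -20)
  expect_equal(m2$rxns$ub[j], 1000)
  others <- setdiff(exchanges(m2), "EX_sub_e")
  expect_true(all(m2$rxns$lb[match(others, m2$rxns$id)] == 0))

  m3 <- apply_medium(m, medium_spec(c(EX_sub_e = 10)))
  expect_equal(m3$rxns$lb[match("EX_sub_e", m3$rxns$id)], -10)

  expect_error(apply_medium(m, medium_spec(c(EX_nope_e = 5))),
               "EX_nope_e.*valid exchanges")
  expect_error(medium_spec(c(EX_sub_e = -3)), "non-negative")
})

test_that("FBA reproduces hand-derived optima and reports empty media as zero growth", {
  chain <- toy_chain_model(10)
  sol <- fba(chain)
  expect_identical(sol$status, "optimal")
  expect_equal(sol$objective_value, 20, tolerance = 1e-9)  # 10 uptake, doubled
  expect_equal(unname(sol$fluxes[["EX_s_e"]]), -10, tolerance = 1e-9)

  closed <- apply_medium(chain, medium_spec())
  expect_equal(fba(closed)$objective_value, 0, tolerance = 1e-9)

  # with no fixed maintenance drain, the closed fermenter idles at zero
  # growth (a positive NGAM would make a sealed system rightly infeasible)
  closed_toy <- apply_medium(toy_fermenter(toy_spec(ngam = 0)), medium_spec())
  expect_equal(fba(closed_toy)$objective_value, 0, tolerance = 1e-9)
})

test_that("FBA equals exhaustive vertex enumeration on small branching networks", {
  # a 6-reaction network with two competing branches of unequal worth
  m <- empty_model()
  m <- add_metabolites(m, c("s_e", "s_c", "x_c", "y_c"))
  m <- add_reaction(m, "EX_s_e", c(s_e = -1), lb = -8)
  m <- add_reaction(m, "St", "s_e --> s_c")
  m <- add_reaction(m, "B1", "s_c --> 2 x_c", ub = 5)
  m <- add_reaction(m, "B2", "s_c --> x_c + y_c")
  m <- add_reaction(m, "SINKY", c(y_c = -1), kind = "demand")
  m <- add_reaction(m, "BIO", c(x_c = -1), kind = "biomass")
  m <- set_objective(m, "BIO")
  sol <- fba(m)
  oracle <- enum_lp(as.numeric(m$rxns$id == "BIO"), as.matrix(m$S),
                    rep(0, nrow(m$mets)), m$rxns$lb, m$rxns$ub, "max")
  expect_equal(sol$objective_value, oracle, tolerance = 1e-8)
  expect_equal(sol$objective_value, 13, tolerance = 1e-8)  # 2*5 + 3 by hand
})

test_that("FVA pins unique pathways and spreads flux over duplicates", {
  chain <- toy_chain_model(10)
  fv <- flux_variability(chain, 1)
  expect_true(all(abs(fv$max_flux - fv$min_flux) < 1e-7))

  par2 <- parallel_path_model(10)
  fv2 <- flux_variability(par2, 1)
  dup <- fv2[fv2$id %in% c("SPLIT", "SPLIT_DUP"), ]
  expect_equal(dup$min_flux, c(0, 0), tolerance = 1e-7)
  expect_equal(dup$max_flux, c(10, 10), tolerance = 1e-7)

  # fraction 0: full feasible ranges, against the enumeration oracle
  fv0 <- flux_variability(chain, 0)
  for (k in seq_len(nrow(fv0))) {
    obj <- as.numeric(chain$rxns$id == fv0$id[k])
    lo <- enum_lp(obj, as.matrix(chain$S), rep(0, nrow(chain$mets)),
                  chain$rxns$lb, chain$rxns$ub, "min")
    hi <- enum_lp(obj, as.matrix(chain$S), rep(0, nrow(chain$mets)),
                  chain$rxns$lb, chain$rxns$ub, "max")
    expect_equal(fv0$min_flux[k], lo, tolerance = 1e-8)
    expect_equal(fv0$max_flux[k], hi, tolerance = 1e-8)
  }
})

test_that("FVA brackets optimal-solution fluxes and respects feasible-region nesting", {
  m <- toy_fermenter()
  sol <- fba(m)
  fv <- flux_variability(m, 0.9)
  for (k in seq_len(nrow(fv))) {
    expect_gte(sol$fluxes[[fv$id[k]]], fv$min_flux[k] - 1e-6)
    expect_lte(sol$fluxes[[fv$id[k]]], fv$max_flux[k] + 1e-6)
  }

  # enlarging any uptake limit never decreases the optimum
  mu0 <- fba(m)$objective_value
  for (up in c(12, 20, 50)) {
    mu <- fba(apply_medium(m, toy_medium(up)))$objective_value
    expect_gte(mu, mu0 - 1e-9)
    mu0 <- mu
  }
})

test_that("blocked reactions are detected and invariant to uniform bound scaling", {
  m <- toy_fermenter()
  expect_length(blocked_reactions(m), 0)

  # a consumer of a metabolite nothing produces is blocked
  m2 <- add_metabolites(m, "orphan_c", formula = "CH4")
  m2 <- add_reaction(m2, "ORPHANASE", "orphan_c --> prod1_c")
  b <- blocked_reactions(m2)
  expect_identical(b, "ORPHANASE")

  for (k in c(0.5, 2)) {
    scaled <- m2
    finite <- is.finite(scaled$rxns$lb)
    scaled$rxns$lb <- scaled$rxns$lb * k
    scaled$rxns$ub <- scaled$rxns$ub * k
    expect_identical(blocked_reactions(scaled), b)
  }
})

test_that("dead-end metabolites follow the reversibility-aware definition", {
  m <- empty_model()
  m <- add_metabolites(m, c("a_c", "b_c", "c_c", "d_c"))
  m <- add_reaction(m, "MAKE_A", c(a_c = 1))            # a: produced only
  m <- add_reaction(m, "AB", "a_c --> b_c")
  m <- add_reaction(m, "LONER", c(c_c = -1, d_c = 1), lb = -1000)
  de <- dead_end_metabolites(m)
  expect_true("b_c" %in% de)       # only consumed... only produced, no consumer
  expect_true("c_c" %in% de)       # single reversible reaction
  expect_true("d_c" %in% de)
  expect_false("a_c" %in% de)      # produced by MAKE_A, consumed by AB

  chain <- toy_chain_model()
  expect_false(any(c("s_c", "p_c") %in% dead_end_metabolites(chain)))
})

test_that("single-gene deletion honors GPR logic", {
  m <- toy_fermenter()
  wt <- fba(m)$objective_value

  del <- single_gene_deletion(m)
  expect_equal(attr(del, "wild_type"), wt, tolerance = 1e-9)

  # isozyme pair on branch 2: either knockout alone keeps wild-type growth
  expect_equal(del$growth[del$gene == "g_br2a"], wt, tolerance = 1e-6)
  expect_equal(del$growth[del$gene == "g_br2b"], wt, tolerance = 1e-6)
  # complex on amino-acid synthesis: each subunit is essential
  expect_true(del$essential[del$gene == "g_ser1"])
  expect_true(del$essential[del$gene == "g_ser2"])
  # severing the only substrate transport kills growth
  expect_true(del$essential[del$gene == "g_subT"])

  # a gene absent from all rules leaves growth untouched
  del2 <- single_gene_deletion(m, genes = "g_ghost")
  expect_equal(del2$growth, wt, tolerance = 1e-9)
  expect_false(del2$essential)

  # double knockout of the isozyme pair (rule evaluation check)
  expect_false(evaluate_gene_rule("g_br2a or g_br2b", c("g_br2a", "g_br2b")))
})

test_that("component producibility reflects open, closed, and severed routes", {
  chain <- toy_chain_model(10)
  expect_equal(component_producibility(chain, "p_c"), 20, tolerance = 1e-8)

  closed <- apply_medium(chain, medium_spec())
  expect_equal(component_producibility(closed, "p_c"), 0, tolerance = 1e-9)

  severed <- set_bounds(chain, "SPLIT", lb = 0, ub = 0)
  expect_equal(component_producibility(severed, "p_c"), 0, tolerance = 1e-9)

  expect_error(component_producibility(chain, "s_c"),
               "not consumed by the biomass reaction")
})

test_that("product maximization in a growth window matches FBA at fraction 1", {
  m <- toy_fermenter()
  sol0 <- fba(m)
  sol1 <- max_product_at_growth(m, "EX_prod2_e", growth_fraction = 1)
  # at the unique optimum there is no slack: the product flux equals its
  # FBA value
  expect_equal(sol1$objective_value, sol0$fluxes[["EX_prod2_e"]],
               tolerance = 1e-6)
  expect_equal(attr(sol1, "mu_opt"), sol0$objective_value, tolerance = 1e-9)

  expect_error(max_product_at_growth(apply_medium(m, medium_spec()),
                                     "EX_prod1_e"),
               "does not grow")
})

test_that("degenerate optima still give reproducible objective values", {
  par2 <- parallel_path_model(10)   # flux split across duplicates is free
  v1 <- fba(par2)$objective_value
  v2 <- fba(par2)$objective_value
  expect_identical(v1, v2)          # bitwise reproducible
  expect_equal(v1, 20, tolerance = 1e-9)
})

test_that("infeasible problems are reported as status, never silent zeros", {
  m <- mini_atp_toy(y = 4, gam = 30, ngam = 5, uptake = 10)
  # NGAM above the ATP capacity of the medium: 4 * 1 < 20
  m <- set_bounds(m, "ATPM", lb = 20)
  m <- apply_medium(m, medium_spec(c(EX_s_e = 1, EX_h2o_e = 1000)))
  expect_identical(fba(m)$status, "infeasible")
})
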