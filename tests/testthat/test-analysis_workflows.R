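# Screening, envelopes, carbon accounting, efficiency, co-metabolism,
# supplementation.

test_that("nutrient screen calls positives, negatives, and untestables", {
  m <- toy_fermenter()
  # baseline with a little substrate so the background grows
  base <- toy_medium(2)
  scr <- nutrient_screen(m, base,
                         c("EX_sub_e", "EX_prod1_e", "EX_ser_e", "EX_none_e"),
                         per_nutrient_uptake = 20,
                         experimental = c(EX_sub_e = TRUE, EX_prod1_e = FALSE,
                                          EX_ser_e = FALSE))
  tab <- scr$table
  expect_true(tab$predicted[tab$nutrient == "EX_sub_e"])      # more carbon
  expect_false(tab$predicted[tab$nutrient == "EX_prod1_e"])   # no ATP from it
  expect_identical(scr$untestable, "EX_none_e")
  expect_equal(scr$sensitivity, 1)
  expect_equal(scr$specificity, 1)
  expect_equal(unname(scr$confusion), c(1, 0, 2, 0))   # TP FP TN FN

  # a nutrient already saturating in the base medium adds nothing
  sat <- nutrient_screen(m, toy_medium(1000), "EX_sub_e")
  expect_false(sat$table$predicted)
  expect_lt(abs(sat$table$delta), 1e-6)
})

test_that("nutrients with no transport path always screen negative", {
  m <- toy_fermenter()
  m <- add_metabolites(m, "inert_e", formula = "C2H6O")
  m <- add_reaction(m, "EX_inert_e", c(inert_e = -1), lb = 0, ub = 1000)
  scr <- nutrient_screen(m, toy_medium(2), "EX_inert_e")
  expect_false(scr$table$predicted)
  expect_equal(scr$table$delta, 0, tolerance = 1e-9)
})

test_that("the fermentation envelope has dominant diagonals and a growth window", {
  m <- toy_fermenter()
  med <- toy_medium(10)
  products <- c("EX_prod1_e", "EX_prod2_e")
  env <- fermentation_envelope(m, med, products, growth_fraction = 0.95,
                               co2 = NULL)
  expect_equal(dim(env), c(2L, 2L))
  expect_true(all(as.matrix(env) >= 0))

  # diagonal dominance, checked independently by FVA in the same window
  applied <- apply_medium(m, med)
  mu <- attr(env, "mu_opt")
  jb <- match(applied$objective, applied$rxns$id)
  applied$rxns$lb[jb] <- 0.95 * mu
  applied$rxns$ub[jb] <- mu
  fv <- flux_variability(applied, 0, reactions = products)
  for (p in products) {
    expect_equal(env[p, p], fv$max_flux[fv$id == p], tolerance = 1e-6)
    expect_true(all(env[[p]] <= env[p, p] + 1e-6))
  }

  # window fraction 1 with a unique optimum: all rows coincide
  env1 <- fermentation_envelope(m, med, products, growth_fraction = 1,
                                co2 = NULL)
  expect_equal(unname(as.matrix(env1)[1, ]), unname(as.matrix(env1)[2, ]),
               tolerance = 1e-6)
})

test_that("carbon balance closes exactly at steady state", {
  m <- toy_fermenter()
  sol <- fba(m)
  cb <- carbon_balance(m, sol)
  expect_equal(cb$c_in, 60, tolerance = 1e-6)   # 10 hexose = 60 C-mmol/h

  # biomass carbon recomputed from the free-monomer coefficients
  coefs <- attr(m, "biomass_free_coefficients")
  cpm <- vapply(names(coefs), function(id) {
    element_count(m$mets$formula[match(id, m$mets$id)], "C")
  }, numeric(1))
  expect_equal(cb$c_in_biomass, sol$objective_value * sum(coefs * cpm),
               tolerance = 1e-6)

  # zero growth: all carbon in is carbon out (ATPM stays open as the ATP
  # sink; it carries no carbon)
  nogrow <- set_bounds(m, "BIOMASS", lb = 0, ub = 0)
  sol0 <- fba(nogrow, objective = "EX_prod1_e")
  cb0 <- carbon_balance(nogrow, sol0)
  expect_equal(cb0$fraction_to_products, 1, tolerance = 1e-6)
})

test_that("growth efficiency normalizes carbon and spots unusable substrates", {
  m <- toy_fermenter()
  minerals <- medium_spec(c(EX_nh3_e = 1000, EX_h2o_e = 1000))
  eff <- growth_efficiency(m, c("EX_sub_e", "EX_ser_e"), minerals,
                           total_c_flux = 120)
  expect_equal(eff$uptake_bound[1], 20)   # 120 C-mmol over 6 carbons
  expect_equal(eff$uptake_bound[2], 40)   # 3-carbon amino acid
  expect_gt(eff$efficiency[1], 0)
  expect_equal(eff$efficiency[2], 0)      # no ATP from the amino acid alone

  expect_error(growth_efficiency(m, "EX_h2o_e", minerals), "no carbon")
})

test_that("efficiency is invariant to the offered carbon flux when uptake binds", {
  m <- toy_fermenter(toy_spec(ngam = 0))   # no fixed drain: LP scales linearly
  minerals <- medium_spec(c(EX_nh3_e = 1000, EX_h2o_e = 1000))
  e1 <- growth_efficiency(m, "EX_sub_e", minerals, total_c_flux = 120)
  e2 <- growth_efficiency(m, "EX_sub_e", minerals, total_c_flux = 240)
  expect_equal(e1$efficiency, e2$efficiency, tolerance = 1e-8)
})

test_that("substrates with the same catabolic entry point tie in efficiency", {
  m <- toy_fermenter()
  m <- add_metabolites(m, "sub2_e", formula = "C6H12O6")
  m <- add_reaction(m, "EX_sub2_e", c(sub2_e = -1), lb = 0, ub = 1000)
  m <- add_reaction(m, "SUB2t", "sub2_e --> sub_c", gpr = "g_sub2T")
  minerals <- medium_spec(c(EX_nh3_e = 1000, EX_h2o_e = 1000))
  eff <- growth_efficiency(m, c("EX_sub_e", "EX_sub2_e"), minerals)
  expect_equal(eff$efficiency[1], eff$efficiency[2], tolerance = 1e-8)
})

test_that("co-metabolism flags improvements and differential essentiality", {
  m <- toy_fermenter()
  minerals <- medium_spec(c(EX_nh3_e = 1000, EX_h2o_e = 1000))
  res <- co_metabolism(m, carbon_sources = "EX_sub_e",
                       vfa_mix = c("EX_prod1_e", "EX_prod2_e"),
                       aa_mix = c("EX_ser_e", "EX_aa2_e"),
                       base_medium = minerals,
                       essentiality_source = "EX_sub_e",
                       essentiality_regimes = c("none", "aa", "vfa"))
  g <- res$growth["EX_sub_e", ]
  expect_true(all(g[c("vfa", "aa", "both")] >= g[["none"]] - 1e-9))

  # the VFA mixture feeds the fermentation-product pool directly, so the
  # only gene it can rescue is the branch producing that pool; biosynthesis
  # and charging genes stay essential
  expect_setequal(setdiff(res$essential$none, res$essential$vfa), "g_br1")

  # amino-acid supplementation rescues exactly the synthesis genes of the
  # importable amino acids; the transporter-less one stays essential
  rescued <- setdiff(res$essential$none, res$essential$aa)
  expect_setequal(rescued, c("g_ser1", "g_ser2", "g_aa2"))
  expect_true("g_aa3" %in% res$essential$aa)
  expect_setequal(res$differential, rescued)

  # robustness survives a minute amino-acid cap
  tiny <- co_metabolism(m, carbon_sources = "EX_sub_e",
                        vfa_mix = c("EX_prod1_e", "EX_prod2_e"),
                        aa_mix = c("EX_ser_e", "EX_aa2_e"),
                        base_medium = minerals,
                        essentiality_source = "EX_sub_e",
                        aa_cap_essentiality = 0.01)
  expect_setequal(tiny$differential, rescued)

  # knocking out a rescued gene blocks fewer components under amino acids
  expect_lt(res$mean_blocked[["aa"]], res$mean_blocked[["none"]] + 1e-9)
})

test_that("supplementing the base carbon source equals raising its bound", {
  m <- toy_fermenter()
  med <- toy_medium(10)
  products <- c("EX_prod1_e", "EX_prod2_e")
  scan <- supplementation_scan(m, med, products, supplements = "EX_sub_e",
                               supplement_c_flux = 12)
  # 12 C-mmol over 6 carbons = +2 mmol uptake
  raised <- fermentation_envelope(m, toy_medium(12), products,
                                  growth_fraction = 0.95, co2 = NULL)
  for (p in products) {
    expect_equal(scan$with_supplement[scan$product == p],
                 raised[p, p], tolerance = 1e-6)
  }
})

test_that("supplements never decrease any product maximum", {
  m <- toy_fermenter()
  scan <- supplementation_scan(m, toy_medium(10),
                               c("EX_prod1_e", "EX_prod2_e"),
                               supplements = c("EX_sub_e", "EX_ser_e",
                                               "EX_aa2_e", "EX_prod1_e"))
  expect_true(all(scan$delta >= -1e-6))
  rk <- attr(scan, "ranking")
  expect_named(rk, c("EX_prod1_e", "EX_prod2_e"))
  ratios <- attr(scan, "ratios")
  # nitrogenous supplement raises the product-1 : product-2 ratio,
  # extra sugar lowers it
  expect_gt(ratios[["EX_ser_e"]], ratios[["baseline"]])
  expect_lt(ratios[["EX_sub_e"]], ratios[["baseline"]])
})
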