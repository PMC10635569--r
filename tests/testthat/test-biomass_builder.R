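# Biomass objective assembly: composition tables, carrier cycling, mass
# normalization, and maintenance terms.

test_that("missing monomer abundance is split equally", {
  d <- monomer_distribution("protein",
                            c(a = 0.5, b = 0.3, c = 0.11),
                            basis = "mass", normalize = FALSE)
  out <- redistribute_missing(d, c("asn", "gln", "trp"))
  expect_equal(sum(out$shares), 1)
  expect_equal(unname(out$shares[c("asn", "gln", "trp")]),
               rep(0.03, 3), tolerance = 1e-12)

  full <- monomer_distribution("protein", c(a = 1), normalize = FALSE)
  expect_identical(redistribute_missing(full, character()), full)

  half <- monomer_distribution("protein", c(a = 0.5), normalize = FALSE)
  out2 <- redistribute_missing(half, "x")
  expect_equal(unname(out2$shares[["x"]]), 0.5)

  expect_error(monomer_distribution("protein", c(a = 0.9, b = 0.2),
                                    normalize = FALSE), "> 1")
  expect_error(redistribute_missing(full, "a"), "both measured and declared")
})

test_that("lipid class mass is split equally among representatives", {
  d <- equal_split_lipids(0.4, list(short = c("l1_c", "l2_c")),
                          class_shares = c(short = 1))
  expect_equal(unname(d$shares), c(0.5, 0.5))

  d1 <- equal_split_lipids(0.1, list(only = "l1_c"))
  expect_equal(unname(d1$shares), 1)

  d3 <- equal_split_lipids(0.3, list(a = "x1", b = c("y1", "y2"),
                                     c = c("z1", "z2", "z3")))
  expect_equal(unname(d3$shares[c("x1", "y1", "z1")]),
               c(1 / 3, 1 / 6, 1 / 9), tolerance = 1e-12)
  expect_equal(sum(d3$shares), 1)

  expect_error(equal_split_lipids(0.1, list(bad = character())),
               "no representative")
})

test_that("single-monomer biomass gets coefficient 1000/MW and carriers cycle", {
  m <- empty_model()
  m <- add_metabolites(m, c("aa_c", "trna_c", "aatrna_c"),
                       formula = c("C3H7NO3", "R", "C3H7NO3R"))
  comp <- macro_composition(c(protein = 1))
  dist <- monomer_distribution("protein", c(aa_c = 1))
  spec_free <- biomass_spec(comp, list(dist))
  built_free <- build_biomass(m, spec_free)
  coef <- attr(built_free, "biomass_free_coefficients")
  expect_equal(unname(coef[["aa_c"]]), 1000 / molar_mass("C3H7NO3"),
               tolerance = 1e-12)
  expect_equal(biomass_mass(built_free), 1, tolerance = 1e-12)

  spec_car <- biomass_spec(comp, list(dist),
                           carriers = carrier_map("aa_c", "aatrna_c",
                                                  "trna_c"))
  built_car <- build_biomass(m, spec_car)
  S <- stoichiometric_matrix(built_car)
  j <- match("BIOMASS", built_car$rxns$id)
  expect_equal(S["aatrna_c", j], -unname(coef[["aa_c"]]), tolerance = 1e-12)
  expect_equal(S["trna_c", j], +unname(coef[["aa_c"]]), tolerance = 1e-12)
  expect_equal(S["aa_c", j], 0)               # free form untouched
  # mass check still uses the free amino acid
  expect_equal(biomass_mass(built_car), 1, tolerance = 1e-12)
})

test_that("mass normalization holds to 0.1% for every accepted composition", {
  base <- toy_fermenter()
  for (seed in 1:8) {
    fx <- composition_fixture(seed)
    m <- build_biomass(base, fx$spec)
    expect_equal(biomass_mass(m), 1, tolerance = 1e-3,
                 info = paste("seed", seed))
  }
})

test_that("mole-basis distributions are converted via free-monomer mass", {
  m <- empty_model()
  m <- add_metabolites(m, c("a_c", "b_c"), formula = c("C2H4O2", "C6H12O6"))
  comp <- macro_composition(c(protein = 1))
  # equimolar: coefficients equal; total mass still 1 g
  dist <- monomer_distribution("protein", c(a_c = 1, b_c = 1), basis = "mole")
  built <- build_biomass(m, biomass_spec(comp, list(dist)))
  coef <- attr(built, "biomass_free_coefficients")
  expect_equal(unname(coef[["a_c"]]), unname(coef[["b_c"]]), tolerance = 1e-12)
  expect_equal(biomass_mass(built), 1, tolerance = 1e-12)
})

test_that("maintenance terms relax and constrain growth as expected", {
  relaxed <- toy_fermenter(toy_spec(gam = 0, ngam = 0))
  strict <- toy_fermenter(toy_spec(gam = 24.9, ngam = 10))
  expect_gt(fba(relaxed)$objective_value, fba(strict)$objective_value)

  # monotonicity: raising either coefficient never raises growth
  mus <- vapply(list(c(10, 2), c(20, 2), c(20, 8), c(40, 8)), function(p) {
    fba(toy_fermenter(toy_spec(gam = p[1], ngam = p[2])))$objective_value
  }, numeric(1))
  expect_true(all(diff(mus) <= 1e-9))

  # NGAM beyond the medium's ATP capacity makes the problem infeasible
  over <- set_maintenance(mini_atp_toy(y = 2, uptake = 5), gam = 10,
                          ngam = 100)
  expect_identical(fba(over)$status, "infeasible")
})

test_that("the ATP-limited fermenter obeys mu = (y U - ngam) / gam exactly", {
  for (p in list(c(4, 30, 5, 10), c(2, 12, 1, 7), c(6, 50, 20, 25))) {
    m <- mini_atp_toy(y = p[1], gam = p[2], ngam = p[3], uptake = p[4])
    expect_equal(fba(m)$objective_value, (p[1] * p[4] - p[3]) / p[2],
                 tolerance = 1e-8,
                 info = sprintf("y=%g gam=%g ngam=%g U=%g", p[1], p[2],
                                p[3], p[4]))
  }
})

test_that("builder errors name missing metabolites and formulas", {
  m <- empty_model()
  m <- add_metabolites(m, "aa_c", formula = "C3H7NO3")
  comp <- macro_composition(c(protein = 1))
  ghost <- monomer_distribution("protein", c(ghost_c = 1))
  expect_error(build_biomass(m, biomass_spec(comp, list(ghost))), "ghost_c")

  m2 <- add_metabolites(empty_model(), "aa_c", formula = NA)
  noform <- monomer_distribution("protein", c(aa_c = 1))
  expect_error(build_biomass(m2, biomass_spec(comp, list(noform))),
               "formula")
})
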