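# Model container, formulas, gene rules, and the three I/O dialects.

test_that("formula parsing handles integers, fractions, and the carrier pseudo-element", {
  f <- parse_formula("C6H12O6")
  expect_equal(f[["C"]], 6)
  expect_equal(f[["H"]], 12)
  expect_equal(f[["O"]], 6)
  expect_equal(molar_mass("C6H12O6"), 180.156, tolerance = 1e-6)

  avg <- parse_formula("C17.1H32.6O2")
  expect_equal(avg[["C"]], 17.1)

  expect_equal(molar_mass("R"), 0)            # carriers weigh nothing
  expect_equal(molar_mass("C6H10O5R"), molar_mass("C6H10O5"))
  expect_true(is.na(molar_mass(NA_character_)))
  expect_equal(element_count("C3H7NO3", "C"), 3)
  expect_equal(element_count("H2O", "C"), 0)
  expect_error(parse_formula("C6H12O6!"), "malformed")
})

test_that("gene rules parse, canonicalize, and evaluate", {
  expect_true(evaluate_gene_rule("g1 or g2", "g1"))      # isozyme survives
  expect_false(evaluate_gene_rule("g1 and g2", "g1"))    # complex broken
  expect_true(evaluate_gene_rule("", c("g1", "g2")))     # no association
  expect_true(evaluate_gene_rule("(g1 and g2) or g3", "g2"))
  expect_false(evaluate_gene_rule("(g1 and g2) or g3", c("g2", "g3")))

  expect_setequal(gpr_genes("(g1 and g2) or g3"), c("g1", "g2", "g3"))
  expect_identical(gpr_genes(""), character())

  expect_identical(format_gpr(parse_gpr("g1 AND g2 OR g3")),
                   "(g1 and g2) or g3")
  expect_error(parse_gpr("g1 and (g2"), "malformed")
  expect_error(parse_gpr("and g1"), "malformed")
})

test_that("a small tabular model reads with the declared dimensions", {
  dir <- withr::local_tempdir()
  writeLines(c("id\tname\tcompartment\tformula",
               "glc_e\tglucose\te\tC6H12O6",
               "glc_c\tglucose\tc\tC6H12O6",
               "pyr_c\tpyruvate\tc\tC3H4O3",
               "lac_e\tlactate\te\tC3H6O3"),
             file.path(dir, "metabolites.tsv"))
  writeLines(c(paste("id", "name", "subsystem", "equation", "lower_bound",
                     "upper_bound", "gene_rule", "kind", "objective",
                     sep = "\t"),
               "EX_glc_e\tglc exch\t\tglc_e <=>\t-10\t1000\t\texchange\t0",
               "GLCt\tglc transport\t\tglc_e --> glc_c\t0\t1000\tgT\t\t0",
               "GLY\tglycolysis\tGlycolysis\tglc_c --> 2 pyr_c\t0\t1000\tg1 or g2\t\t0",
               "LDH\tlactate exit\t\tpyr_c --> lac_e\t0\t1000\t\t\t0",
               "EX_lac_e\tlac exch\t\tlac_e <=>\t0\t1000\t\texchange\t1"),
             file.path(dir, "reactions.tsv"))
  m <- read_model(dir)
  expect_s3_class(m, "metabolic_model")
  expect_equal(nrow(m$rxns), 5)
  expect_equal(nrow(m$mets), 4)
  expect_identical(m$objective, "EX_lac_e")
  expect_identical(m$rxns$kind[m$rxns$id == "GLCt"], "transport")
  stats <- model_statistics(m)
  expect_equal(stats$n_exchange, 2)
  # GLCt, plus LDH whose participants span cytosol and extracellular space
  expect_equal(stats$n_transport, 2)
})

test_that("models round-trip identically through all three dialects", {
  m <- toy_fermenter()
  dir <- withr::local_tempdir()
  paths <- c(sbml = file.path(dir, "m.xml"),
             json = file.path(dir, "m.json"),
             tabular = file.path(dir, "tab"))
  for (fmt in names(paths)) {
    write_model(m, paths[[fmt]], format = fmt)
    b <- read_model(paths[[fmt]])
    expect_identical(b$mets$id, m$mets$id, info = fmt)
    expect_identical(b$rxns$id, m$rxns$id, info = fmt)
    expect_identical(b$mets$formula, m$mets$formula, info = fmt)
    expect_identical(b$rxns$kind, m$rxns$kind, info = fmt)
    expect_identical(b$rxns$gpr, m$rxns$gpr, info = fmt)
    expect_identical(b$objective, m$objective, info = fmt)
    expect_equal(b$rxns$lb, m$rxns$lb, info = fmt)
    expect_equal(b$rxns$ub, m$rxns$ub, info = fmt)
    expect_equal(max(abs(stoichiometric_matrix(b) -
                           stoichiometric_matrix(m))), 0, info = fmt)
    expect_setequal(b$genes, m$genes)
  }
})

test_that("duplicate and malformed records raise informative errors", {
  dir <- withr::local_tempdir()
  writeLines(c("id\tname\tcompartment\tformula",
               "a_c\ta\tc\tCH4",
               "a_c\ta\tc\tCH4"),
             file.path(dir, "metabolites.tsv"))
  writeLines(paste("id", "name", "subsystem", "equation", "lower_bound",
                   "upper_bound", "gene_rule", "kind", "objective",
                   sep = "\t"),
             file.path(dir, "reactions.tsv"))
  expect_error(read_model(dir), "duplicate metabolite id.*a_c")

  m <- toy_fermenter()
  dup <- m
  dup$rxns$id[2] <- dup$rxns$id[1]
  expect_error(validate_model(dup), "duplicate reaction ids")
  expect_error(read_model(file.path(dir, "missing.json")), "no such file")

  dir2 <- withr::local_tempdir()
  writeLines(c("id\tname\tcompartment\tformula", "a_c\ta\tc\tCH4"),
             file.path(dir2, "metabolites.tsv"))
  writeLines(c(paste("id", "name", "subsystem", "equation", "lower_bound",
                     "upper_bound", "gene_rule", "kind", "objective",
                     sep = "\t"),
               "BAD\tx\t\tno arrow here\t0\t1000\t\t\t0"),
             file.path(dir2, "reactions.tsv"))
  expect_error(read_model(dir2), "BAD")
})

test_that("the stoichiometric matrix matches definitions and the steady state", {
  m <- empty_model()
  m <- add_metabolites(m, c("a_c", "b_c"))
  m <- add_reaction(m, "R1", "a_c --> 2 b_c")
  S <- stoichiometric_matrix(m)
  expect_equal(as.numeric(S[, "R1"]), c(-1, 2))

  toy <- toy_fermenter()
  S <- stoichiometric_matrix(toy)
  for (rx in exchanges(toy)) {
    expect_equal(sum(S[, rx] != 0), 1)   # exchange columns are unit-support
  }
  sol <- fba(toy)
  expect_lt(max(abs(S %*% sol$fluxes)), 1e-6)
})

test_that("transport classification is invariant under reaction reordering", {
  build <- function(order) {
    m <- empty_model()
    m <- add_metabolites(m, c("a_e", "a_c", "b_c"))
    rxns <- list(
      EX_a_e = function(m) add_reaction(m, "EX_a_e", c(a_e = -1), lb = -5),
      At = function(m) add_reaction(m, "At", "a_e --> a_c"),
      AB = function(m) add_reaction(m, "AB", "a_c --> b_c"),
      BIO = function(m) add_reaction(m, "BIO", c(b_c = -1), kind = "biomass"))
    for (nm in order) m <- rxns[[nm]](m)
    set_objective(m, "BIO")
  }
  s1 <- model_statistics(build(c("EX_a_e", "At", "AB", "BIO")))
  s2 <- model_statistics(build(c("BIO", "AB", "At", "EX_a_e")))
  for (field in c("n_exchange", "n_transport", "n_metabolic")) {
    expect_equal(s1[[field]], s2[[field]])
  }
})

test_that("mass-balance checking ignores hydrogen, honors carriers, reports gaps", {
  m <- empty_model()
  m <- add_metabolites(m, c("a_c", "b_c", "t_c", "ta_c", "u_c"),
                       formula = c("C6H12O6", "C3H6O3", "R", "C6H12O6R",
                                   NA))
  m <- add_reaction(m, "OK", "a_c --> 2 b_c")         # 2 x C3 = C6, balanced
  m <- add_reaction(m, "BAD", "a_c --> b_c")          # loses C3, O3
  m <- add_reaction(m, "CARRIER", "a_c + t_c --> ta_c")  # R cycles
  m <- add_reaction(m, "UNKNOWN", "a_c --> u_c")
  rep <- check_mass_balance(m)
  expect_false("OK" %in% rep$reaction)
  expect_setequal(rep$element[rep$reaction == "BAD"], c("C", "O"))
  expect_equal(rep$imbalance[rep$reaction == "BAD" & rep$element == "C"], -3)
  expect_false("CARRIER" %in% rep$reaction)           # R balances; O balances
  expect_identical(attr(rep, "unverifiable"), "UNKNOWN")

  expect_identical(nrow(check_mass_balance(toy_fermenter())), 0L)
})
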