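test_that("model construction enforces the basic invariants", {
  S <- matrix(c(1, -1, 0, 0), 2, 2, dimnames = list(c("A", "B"), c("U", "Z")))
  expect_error(metabolic_model(S, c(0, 0), c(1, 1), c(U = 1)),
               "all-zero stoichiometry")
  S[, 2] <- c(-1, 1)
  expect_error(metabolic_model(S, c(2, 0), c(1, 1), c(U = 1)), "lower_bound")
  expect_error(metabolic_model(S, c(0, 0), c(1, 1), c(NOPE = 1)), "objective")
})

test_that("JSON round trip preserves stoichiometry, bounds and objective", {
  w <- make_toy_network("respirofermentative")
  path <- withr::local_tempfile(fileext = ".json")
  write_model(w$model, path)
  m2 <- read_model(path)
  expect_equal(m2$S[rownames(w$model$S), colnames(w$model$S)], w$model$S)
  expect_equal(m2$lower_bound, w$model$lower_bound)
  expect_equal(m2$upper_bound, w$model$upper_bound)
  expect_equal(m2$objective, w$model$objective)
  # toy fixture shape: 10 reactions, 7 metabolites
  expect_length(m2$reaction_ids, 10)
  expect_length(m2$metabolite_ids, 7)
})

test_that("SBML (L3+FBC) round trip preserves the model", {
  w <- make_toy_network("chain")
  path <- withr::local_tempfile(fileext = ".xml")
  write_model(w$model, path, format = "sbml")
  m2 <- read_model(path)
  expect_equal(m2$S[rownames(w$model$S), colnames(w$model$S)], w$model$S)
  expect_equal(unname(m2$lower_bound), unname(w$model$lower_bound))
  expect_equal(names(m2$objective), names(w$model$objective))
})

test_that("a JSON reaction with all-zero stoichiometry is a validation error", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(
    id = "bad",
    metabolites = list(list(id = "A")),
    reactions = list(list(id = "R1", metabolites = list(A = 0),
                          lower_bound = 0, upper_bound = 1)),
    genes = list()), auto_unbox = TRUE), path)
  expect_error(read_model(path), "all-zero stoichiometry")
})

test_that("FBA solves chains, closed models, and matches the LP oracle", {
  m <- chain_model(cap = 10)
  f <- solve_fba(m)
  expect_identical(f$status, "optimal")
  expect_equal(f$objective_value, 10)
  # mass balance of any optimal solution
  expect_lt(max(abs(m$S %*% f$values)), 1e-6)
  # all exchanges closed -> zero growth
  m0 <- chain_model(cap = 0)
  expect_equal(solve_fba(m0)$objective_value, 0)
  # branched fixture vs exhaustive vertex check
  wb <- make_toy_network("branched")
  fb <- solve_fba(wb$model)
  oracle <- brute_lp(
    stats::setNames(as.numeric(wb$model$reaction_ids == "EB"), NULL),
    wb$model$S, rep(0, 3), wb$model$lower_bound, wb$model$upper_bound,
    maximize = TRUE)
  expect_equal(fb$objective_value, oracle, tolerance = 1e-8)
})

test_that("pFBA keeps the growth optimum and minimises total flux", {
  m <- parallel_model(10)
  fba <- solve_fba(m)
  pfba <- solve_pfba(m)
  expect_equal(pfba$objective_value, fba$objective_value, tolerance = 1e-6)
  # redundant parallel paths: all flux through one of them
  expect_equal(min(pfba$values[c("P1", "P2")]), 0, tolerance = 1e-8)
  expect_lte(attr(pfba, "total_flux"), sum(abs(fba$values)) + 1e-9)
  # chain model: unique optimum, pFBA == FBA
  mc <- chain_model(10)
  expect_equal(solve_pfba(mc)$values, solve_fba(mc)$values, tolerance = 1e-8)
})

test_that("production envelopes hit the LP endpoints and nest for submodels", {
  w <- make_toy_network("respirofermentative")
  env <- production_envelope(w$model, "EX_Ac", n_points = 5)
  expect_equal(nrow(env), 5)
  expect_true(all(diff(env$target_flux) > 0))
  expect_true(all(env$growth_min <= env$growth_max + 1e-9, na.rm = TRUE))
  # endpoints: zero product at max growth; zero growth at max product
  expect_equal(env$target_flux[1], 0, tolerance = 1e-8)
  expect_equal(env$growth_max[1], solve_fba(w$model)$objective_value,
               tolerance = 1e-8)
  expect_equal(env$growth_max[nrow(env)], 0, tolerance = 1e-6)
  # n_points = 2 evaluates only the extremes
  env2 <- production_envelope(w$model, "EX_Ac", n_points = 2)
  expect_equal(nrow(env2), 2)
  expect_equal(range(env2$target_flux), range(env$target_flux))
  # nesting: the fermentation-only submodel lies inside the parent envelope
  sub <- w$model
  keep <- setdiff(sub$reaction_ids, c("RESP", "T_O2", "EX_O2"))
  sub$S <- sub$S[, keep]; sub$reaction_ids <- keep
  sub$lower_bound <- sub$lower_bound[keep]; sub$upper_bound <- sub$upper_bound[keep]
  envs <- production_envelope(sub, "EX_Ac", n_points = 4)
  for (i in seq_len(nrow(envs))) {
    fixed <- fluxkit:::with_bounds(w$model, "EX_Ac", lb = envs$target_flux[i],
                                   ub = envs$target_flux[i])
    hi <- solve_fba(fixed, "max")
    lo <- solve_fba(fixed, "min")
    expect_lte(envs$growth_max[i], hi$objective_value + 1e-7)
    expect_gte(envs$growth_min[i], lo$objective_value - 1e-7)
  }
})

test_that("set_condition applies uptake, oxygen and maintenance bounds", {
  w <- make_toy_network("respirofermentative")
  m <- w$model
  # maintenance handle named as in the parent-model convention
  m$reaction_ids; mm <- set_condition(m, "EX_S", uptake_bound = 10,
                                      aerobic = FALSE, maintenance_bound = 6.86,
                                      oxygen_exchange = "EX_O2",
                                      maintenance_reaction = "ATPM")
  expect_equal(unname(mm$lower_bound["EX_S"]), -10)
  expect_equal(unname(mm$lower_bound["EX_O2"]), 0)
  expect_equal(unname(mm$lower_bound["ATPM"]), 6.86)
  # idempotent
  mm2 <- set_condition(mm, "EX_S", uptake_bound = 10, aerobic = FALSE,
                       maintenance_bound = 6.86, oxygen_exchange = "EX_O2",
                       maintenance_reaction = "ATPM")
  expect_identical(mm$lower_bound, mm2$lower_bound)
  expect_identical(mm$upper_bound, mm2$upper_bound)
  # zero uptake abolishes growth on a single-carbon-source fixture
  m0 <- set_condition(w$model, "EX_S", uptake_bound = 0, aerobic = TRUE,
                      maintenance_bound = 0, oxygen_exchange = "EX_O2",
                      maintenance_reaction = "ATPM")
  expect_equal(solve_fba(m0)$objective_value, 0, tolerance = 1e-9)
  expect_error(set_condition(m, "EX_nope"), "unknown reaction")
})

test_that("equivalent-biomass lumping preserves stoichiometry and growth", {
  # single-path bookkeeping: precursor -> P -> BM with 2 P per BM
  S <- matrix(0, 2, 3, dimnames = list(c("pre", "P"), c("R1", "BM", "U")))
  S["pre", "R1"] <- -1; S["P", "R1"] <- 1
  S["P", "BM"] <- -2
  S["pre", "U"] <- 1
  m <- metabolic_model(S, rep(0, 3), c(1000, 1000, 10), c(BM = 1))
  ref <- solve_fba(m)
  lump <- lump_equivalent_biomass(m, ref, "pre")
  expect_equal(unname(lump[["pre"]]), -2)
  # retained = all metabolites -> the original biomass column
  lump_all <- lump_equivalent_biomass(m, ref, c("pre", "P"))
  expect_equal(lump_all[["P"]], -2)
  expect_false("pre" %in% names(lump_all))
  # two-pathway fixture: reduced model reproduces the extended growth rate
  w <- make_toy_network("respirofermentative")
  ref2 <- solve_pfba(w$model)
  retained <- c("S_e", "S", "O2_e", "O2", "Ac", "Ac_e")
  lump2 <- lump_equivalent_biomass(w$model, ref2, retained)
  lumped_rxns <- attr(lump2, "lumped_reactions")
  keep <- setdiff(w$model$reaction_ids, lumped_rxns)
  S2 <- w$model$S[retained, keep, drop = FALSE]
  S2 <- cbind(S2, BM_eq = 0)
  S2[names(lump2), "BM_eq"] <- lump2
  S2 <- S2[, colSums(abs(S2)) > 0, drop = FALSE]
  red <- metabolic_model(S2, c(w$model$lower_bound[colnames(S2)[-ncol(S2)]], 0),
                         c(w$model$upper_bound[colnames(S2)[-ncol(S2)]], 1000),
                         c(BM_eq = 1))
  expect_equal(solve_fba(red)$objective_value, ref2$objective_value,
               tolerance = 1e-6)
  # error paths
  bad <- ref2; bad$values["FERM"] <- bad$values["FERM"] + 1
  expect_error(lump_equivalent_biomass(w$model, bad, retained), "mass balance")
})
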