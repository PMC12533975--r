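test_that("enumeration returns the textbook mode sets on small fixtures", {
  # chain: exactly one mode
  wc <- make_toy_network("chain")
  expect_length(enumerate_efms(wc$model), 1)
  # branched: two modes
  wb <- make_toy_network("branched")
  ms <- enumerate_efms(wb$model)
  expect_length(ms, 2)
  expect_setequal(lapply(ms, function(m) sort(m$support)),
                  list(c("EB", "R1", "U"), c("EC", "R2", "U")))
  # single reversible internal reaction, exchanges on both sides: fwd + rev
  S <- matrix(c(1, -1, 0, 0, 1, -1), 2, 3, byrow = TRUE,
              dimnames = list(c("A", "B"), c("EA", "R", "EB")))
  m <- metabolic_model(S, c(-10, -10, -10), c(10, 10, 10), c(R = 1))
  ms2 <- enumerate_efms(m)
  expect_length(ms2, 2)
  v1 <- ms2[[1]]$flux; v2 <- ms2[[2]]$flux
  expect_equal(v1, -v2[names(v1)])
  # the size guard refuses large models unless overridden
  big <- random_network(10, 41, seed = 1)
  expect_error(enumerate_efms(big), "allow_large")
})

test_that("double description agrees with the brute-force oracle", {
  fixtures <- list(make_toy_network("chain")$model,
                   make_toy_network("branched")$model,
                   make_toy_network("respirofermentative")$model)
  for (m in fixtures) {
    expect_same_modes(enumerate_efms(m), brute_force_efms(m))
  }
  # randomized networks, mixed reversibility
  n_nonempty <- 0
  for (seed in 1:12) {
    m <- random_network(n_mets = sample(2:4, 1), n_rxns = sample(5:8, 1),
                        seed = 1000 + seed)
    a <- enumerate_efms(m)
    b <- brute_force_efms(m)
    expect_same_modes(a, b)
    if (length(a) > 0) n_nonempty <- n_nonempty + 1
  }
  expect_gte(n_nonempty, 5)
})

test_that("every enumerated mode is balanced, sign-correct and support-minimal", {
  for (seed in 21:26) {
    m <- random_network(3, 7, seed = seed)
    ms <- enumerate_efms(m)
    supports <- lapply(ms, function(x) x$support)
    for (i in seq_along(ms)) {
      v <- ms[[i]]$flux
      expect_lt(max(abs(m$S %*% v)), 1e-8)
      irrev <- m$lower_bound >= 0
      expect_true(all(v[irrev] >= -1e-10))
      expect_equal(max(abs(v)), 1)
      for (j in seq_along(ms)) {
        if (i != j)
          expect_false(all(supports[[j]] %in% supports[[i]]) &&
                         length(supports[[j]]) < length(supports[[i]]))
      }
    }
  }
})

test_that("an FBA optimum decomposes into a conic combination of modes", {
  w <- make_toy_network("respirofermentative")
  ms <- enumerate_efms(w$model)
  v <- solve_pfba(w$model)$values
  M <- vapply(ms, function(m) m$flux[names(v)], numeric(length(v)))
  res <- fluxkit:::solve_lp(rep(0, ncol(M)), M, v,
                            rep(0, ncol(M)), rep(Inf, ncol(M)))
  expect_identical(res$status, "optimal")
})

test_that("physiological filtering drops non-growing and excluded modes", {
  w <- make_toy_network("respirofermentative")
  ms <- enumerate_efms(w$model)
  expect_length(ms, 4)                       # 2 growth + 2 maintenance-only
  grown <- filter_modes(ms, aerobic = FALSE, biomass = "BM")
  expect_length(grown, 2)
  # aerobic: require oxygen uptake and exclude the fermentative reaction
  aer <- filter_modes(ms, aerobic = TRUE, biomass = "BM",
                      oxygen_uptake = "T_O2",
                      excluded_reactions = "FERM")
  expect_length(aer, 1)
  expect_true("RESP" %in% aer[[1]]$support)
  # the anaerobic filter ignores the exclusion list
  ana <- filter_modes(ms, aerobic = FALSE, biomass = "BM",
                      excluded_reactions = "FERM")
  expect_length(ana, 2)
})

test_that("mode scoring is scale-invariant and can flip the growth ranking", {
  w <- make_toy_network("respirofermentative")
  ec <- toy_ec_model(w)
  cost <- enzyme_costs(ec)
  ms <- filter_modes(enumerate_efms(w$model), aerobic = FALSE, biomass = "BM")
  sc <- lapply(ms, score_mode, cost = cost, biomass = "BM",
               substrate_uptake = "EX_S")
  yields <- vapply(sc, function(m) m$yield_biomass, 0)
  mus <- vapply(sc, function(m) m$growth_estimate, 0)
  # the high-yield respiratory mode grows slower: ranking flips
  expect_false(identical(order(yields), order(mus)))
  # Eq-style arithmetic: mu = f_enz * v_BM / c_enz
  m1 <- sc[[1]]
  expect_equal(m1$growth_estimate,
               0.285 * m1$flux[["BM"]] / m1$enzyme_cost)
  # scaling a mode leaves (yield, mu) unchanged
  scaled <- ms[[1]]; scaled$flux <- scaled$flux * 7
  s2 <- score_mode(scaled, cost, "BM", "EX_S")
  expect_equal(s2$yield_biomass, sc[[1]]$yield_biomass)
  expect_equal(s2$growth_estimate, sc[[1]]$growth_estimate)
  # zero uptake is an error
  noup <- ms[[1]]; noup$flux["EX_S"] <- 0
  expect_error(score_mode(noup, cost, "BM", "EX_S"), "uptake")
})

test_that("the Pareto front matches pairwise dominance on random points", {
  mk <- function(y, g) {
    m <- structure(list(flux = c(x = 1), support = "x"), class = "flux_mode")
    m$yield_biomass <- y; m$growth_estimate <- g; m
  }
  pts <- list(mk(1, 1), mk(2, 0.5), mk(1.5, 0.4))
  pf <- pareto_front(pts)
  expect_length(pf, 2)
  expect_equal(vapply(pf, function(m) m$yield_biomass, 0), c(2, 1))
  expect_length(pareto_front(pts[1]), 1)
  # random cloud vs O(n^2) oracle
  set.seed(42)
  y <- runif(400); g <- runif(400)
  cloud <- Map(mk, y, g)
  pf2 <- pareto_front(cloud)
  dominated <- vapply(seq_along(y), function(i)
    any(y >= y[i] & g >= g[i] & (y > y[i] | g > g[i])), TRUE)
  expect_length(pf2, sum(!dominated))
})

test_that("scaling oxygen costs broadens the growth/yield Pareto front", {
  w <- make_toy_network("respirofermentative")
  cost <- enzyme_costs(toy_ec_model(w))
  c2 <- scale_oxygen_cost(cost, c("RESP", "T_O2"), 1000)
  expect_equal(unname(c2["RESP"]), unname(cost["RESP"]) * 1000)
  expect_equal(c2[setdiff(names(cost), c("RESP", "T_O2"))],
               cost[setdiff(names(cost), c("RESP", "T_O2"))])
  expect_equal(scale_oxygen_cost(cost, "RESP", 1), cost)
  expect_error(scale_oxygen_cost(cost, "NOPE", 2), "unknown")
  # under oxygen scarcity the respiratory mode falls off the front
  ms <- filter_modes(enumerate_efms(w$model), aerobic = FALSE, biomass = "BM")
  sc1 <- lapply(ms, score_mode, cost = cost, biomass = "BM",
                substrate_uptake = "EX_S")
  sc2 <- lapply(ms, score_mode, cost = c2, biomass = "BM",
                substrate_uptake = "EX_S")
  mu_resp <- function(sc) {
    i <- which(vapply(sc, function(m) "RESP" %in% m$support, TRUE))
    sc[[i]]$growth_estimate
  }
  expect_lt(mu_resp(sc2), mu_resp(sc1) / 100)
})
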