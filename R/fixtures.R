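#' Deterministic toy worlds for testing and simulation
#'
#' Builds a small metabolic model together with a matching knowledge graph
#' and ground-truth turnover numbers. Variants:
#' \describe{
#'   \item{`chain`}{linear uptake -> transport -> conversion -> biomass
#'     (one elementary flux mode).}
#'   \item{`branched`}{one substrate feeding two secretion branches (two
#'     elementary flux modes), with isozymes on the first branch for
#'     knockout tests.}
#'   \item{`respirofermentative`}{a substrate fuelling either a high-yield,
#'     enzyme-expensive respiratory route (consuming oxygen) or a low-yield,
#'     enzyme-cheap fermentative route secreting a byproduct; the biomass
#'     reaction drains substrate and ATP, so the growth/yield Pareto front
#'     holds at least two modes and saturation FBA switches between them.}
#' }
#' Stoichiometries are small integers so that brute-force oracles stay
#' exact. The same seed always returns an identical world.
#'
#' @param variant one of `"chain"`, `"branched"`, `"respirofermentative"`.
#' @param seed integer seed (stored; construction is deterministic).
#' @return object of class `toy_world`: list with `model`, `graph`,
#'   `true_kcat`, `masses`, `biomass`, `substrate_exchange`, `transporter`,
#'   `oxygen_exchange`, `maintenance`, `seed`.
#' @export
make_toy_network <- function(variant = c("chain", "branched",
                                         "respirofermentative"),
                             seed = 1L) {
  variant <- match.arg(variant)
  world <- switch(variant,
                  chain = toy_chain(),
                  branched = toy_branched(),
                  respirofermentative = toy_respiroferm())
  world$variant <- variant
  world$seed <- as.integer(seed)
  class(world) <- "toy_world"
  world
}

#' @export
print.toy_world <- function(x, ...) {
  cat("toy_world '", x$variant, "': ", sep = "")
  print(x$model)
  invisible(x)
}

toy_chain <- function() {
  mets <- c("S_e", "S_c", "X_c")
  rxns <- c("EX_S", "T_S", "R1", "BM")
  S <- matrix(0, 3, 4, dimnames = list(mets, rxns))
  S["S_e", "EX_S"] <- -1
  S["S_e", "T_S"] <- -1; S["S_c", "T_S"] <- 1
  S["S_c", "R1"] <- -1; S["X_c", "R1"] <- 1
  S["X_c", "BM"] <- -1
  model <- metabolic_model(S,
                           lower_bound = c(-10, 0, 0, 0),
                           upper_bound = c(1000, 1000, 1000, 1000),
                           objective = c(BM = 1))
  graph <- knowledge_graph(
    nodes = data.frame(
      id = c("T_S", "R1", "BM", "E_ts", "E_r1", "P_ts", "P_r1",
             "g_ts", "g_r1"),
      type = c("reaction", "reaction", "reaction", "protein", "protein",
               "polypeptide", "polypeptide", "gene", "gene"),
      molecular_mass = c(NA, NA, NA, NA, NA, 40, 50, NA, NA)),
    edges = data.frame(
      from = c("E_ts", "E_r1", "E_ts", "E_r1", "g_ts", "g_r1"),
      to = c("T_S", "R1", "P_ts", "P_r1", "P_ts", "P_r1"),
      type = c("catalysis", "catalysis", "subunit_composition",
               "subunit_composition", "coding", "coding"),
      stoichiometry = c(NA, NA, 1, 2, NA, NA)))
  list(model = model, graph = graph,
       true_kcat = turnover_set(c("T_S", "R1"), "fwd", c(65, 100),
                                c("default_transporter", "measured")),
       masses = c(E_ts = 40, E_r1 = 100),
       biomass = "BM", substrate_exchange = "EX_S", transporter = "T_S",
       oxygen_exchange = NULL, maintenance = NULL)
}

toy_branched <- function() {
  mets <- c("A", "B", "C")
  rxns <- c("U", "R1", "R2", "EB", "EC")
  S <- matrix(0, 3, 5, dimnames = list(mets, rxns))
  S["A", "U"] <- 1
  S["A", "R1"] <- -1; S["B", "R1"] <- 1
  S["A", "R2"] <- -1; S["C", "R2"] <- 1
  S["B", "EB"] <- -1
  S["C", "EC"] <- -1
  model <- metabolic_model(S,
                           lower_bound = rep(0, 5),
                           upper_bound = c(10, 1000, 1000, 1000, 1000),
                           objective = c(EB = 1))
  # R1: primary monomer E1(g1) + secondary monomer E1s(g1s)
  # R2: primary heterodimer E2(g2a, g2b)
  graph <- knowledge_graph(
    nodes = data.frame(
      id = c("R1", "R2", "E1", "E1s", "E2", "P1", "P1s", "P2a", "P2b",
             "g1", "g1s", "g2a", "g2b"),
      type = c("reaction", "reaction", "protein", "protein", "protein",
               "polypeptide", "polypeptide", "polypeptide", "polypeptide",
               "gene", "gene", "gene", "gene"),
      molecular_mass = c(NA, NA, NA, NA, NA, 30, 35, 20, 25, NA, NA, NA, NA)),
    edges = data.frame(
      from = c("E1", "E1s", "E2",
               "E1", "E1s", "E2", "E2",
               "g1", "g1s", "g2a", "g2b"),
      to = c("R1", "R1", "R2",
             "P1", "P1s", "P2a", "P2b",
             "P1", "P1s", "P2a", "P2b"),
      type = c("catalysis", "catalysis", "catalysis",
               rep("subunit_composition", 4), rep("coding", 4)),
      stoichiometry = c(NA, NA, NA, 1, 1, 1, 1, NA, NA, NA, NA),
      catalysis_class = c("primary", "secondary", "primary",
                          rep(NA, 8))))
  list(model = model, graph = graph,
       true_kcat = turnover_set(c("R1", "R2"), "fwd", c(80, 120)),
       masses = c(E1 = 30, E1s = 35, E2 = 45),
       biomass = "EB", substrate_exchange = "U", transporter = NULL,
       oxygen_exchange = NULL, maintenance = NULL)
}

toy_respiroferm <- function() {
  mets <- c("S_e", "S", "O2_e", "O2", "Ac", "Ac_e", "ATP")
  rxns <- c("EX_S", "T_S", "EX_O2", "T_O2", "RESP", "FERM", "T_Ac",
            "EX_Ac", "ATPM", "BM")
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  S["S_e", "EX_S"] <- -1
  S["S_e", "T_S"] <- -1; S["S", "T_S"] <- 1
  S["O2_e", "EX_O2"] <- -1
  S["O2_e", "T_O2"] <- -1; S["O2", "T_O2"] <- 1
  S["S", "RESP"] <- -1; S["O2", "RESP"] <- -1; S["ATP", "RESP"] <- 4
  S["S", "FERM"] <- -1; S["ATP", "FERM"] <- 1; S["Ac", "FERM"] <- 1
  S["Ac", "T_Ac"] <- -1; S["Ac_e", "T_Ac"] <- 1
  S["Ac_e", "EX_Ac"] <- -1
  S["ATP", "ATPM"] <- -1
  S["S", "BM"] <- -100; S["ATP", "BM"] <- -400
  # wide internal bounds: fluxes are meant to be limited by the enzyme
  # pool (or an explicit uptake bound), never by default box bounds
  lb <- c(-10, 0, -1e5, 0, 0, 0, 0, 0, 0, 0)
  ub <- rep(1e5, length(rxns))
  model <- metabolic_model(S, lb, ub, objective = c(BM = 1))
  # enzymes: expensive respiratory complex, cheap fermentative dimer
  graph <- knowledge_graph(
    nodes = data.frame(
      id = c("T_S", "T_O2", "RESP", "FERM",
             "E_ts", "E_to2", "E_resp", "E_ferm", "E_ferm2",
             "P_ts", "P_to2", "P_ra", "P_rb", "P_f", "P_f2",
             "g_ts", "g_to2", "g_ra", "g_rb", "g_f", "g_f2"),
      type = c(rep("reaction", 4), rep("protein", 5),
               rep("polypeptide", 6), rep("gene", 6)),
      molecular_mass = c(rep(NA, 9), 45, 40, 100, 50, 25, 55, rep(NA, 6))),
    edges = data.frame(
      from = c("E_ts", "E_to2", "E_resp", "E_ferm", "E_ferm2",
               "E_ts", "E_to2", "E_resp", "E_resp", "E_ferm", "E_ferm2",
               "g_ts", "g_to2", "g_ra", "g_rb", "g_f", "g_f2"),
      to = c("T_S", "T_O2", "RESP", "FERM", "FERM",
             "P_ts", "P_to2", "P_ra", "P_rb", "P_f", "P_f2",
             "P_ts", "P_to2", "P_ra", "P_rb", "P_f", "P_f2"),
      type = c(rep("catalysis", 5), rep("subunit_composition", 6),
               rep("coding", 6)),
      stoichiometry = c(rep(NA, 5), 1, 1, 2, 2, 2, 1, rep(NA, 6)),
      catalysis_class = c("primary", "primary", "primary", "primary",
                          "secondary", rep(NA, 12))))
  # per-polypeptide turnovers; the enzyme-level rates absorb the subunit
  # multiplier at cost-computation time
  kc <- turnover_set(c("T_S", "T_O2", "RESP", "FERM"), "fwd",
                     c(65, 100, 15, 150),
                     c("default_transporter", rep("measured", 3)))
  list(model = model, graph = graph, true_kcat = kc,
       masses = c(E_ts = 45, E_to2 = 40, E_resp = 300, E_ferm = 50,
                  E_ferm2 = 55),
       biomass = "BM", substrate_exchange = "EX_S", transporter = "T_S",
       oxygen_exchange = "EX_O2", oxygen_transport = "T_O2",
       fermentation = "FERM", respiration = "RESP",
       byproduct_exchange = "EX_Ac", maintenance = "ATPM")
}

#' Build the enzyme-constrained variant of a toy world
#'
#' @param world a `toy_world`.
#' @param etot enzyme budget (g/gDW).
#' @param sigma saturation scalar.
#' @param turnovers turnover set (default the world's ground truth).
#' @return an `ec_model`.
#' @export
toy_ec_model <- function(world, etot = 0.285, sigma = 1,
                         turnovers = world$true_kcat) {
  transporters <- c(world$transporter, world$oxygen_transport)
  build_ec_model(world$model, world$graph, turnovers, etot = etot,
                 sigma = sigma, transporters = transporters)
}

#' Simulate multi-condition proteomics from a toy world
#'
#' Draws ground-truth log10 turnover adjustments `u*` (centred to mean zero
#' over the enzymatic reactions, since a uniform shift is absorbed by the
#' condition scalings and is not identifiable), applies them to the world's
#' turnover numbers, computes the minimum-cost enzyme allocation at each
#' condition's growth rate, divides by a drawn condition saturation
#' `sigma_c`, and perturbs each abundance by `10^eps`,
#' `eps ~ N(0, noise_sd_log10)`. Deterministic under `seed`.
#'
#' @param world a `toy_world` (the `respirofermentative` variant exposes the
#'   richest condition structure).
#' @param conditions named list; each element `list(growth = , uptake_bound
#'   = )`. The default picks uptake bounds that force a respiro-fermentative
#'   mixture so that every enzyme carries flux.
#' @param noise_sd_log10 multiplicative log10 noise standard deviation.
#' @param seed integer seed.
#' @param u_sd standard deviation of the drawn true adjustments.
#' @param sigma_range range of the drawn condition saturations.
#' @return list with `abundance` (data frame: condition, enzyme,
#'   abundance), `true_u` (named, per base reaction), `true_sigma`
#'   (named, per condition), `true_kcat` (adjusted turnover set),
#'   `conditions`.
#' @export
simulate_proteomics <- function(world, conditions = NULL,
                                noise_sd_log10 = 0, seed = 1L,
                                u_sd = 0.3, sigma_range = c(0.35, 0.75)) {
  if (is.null(conditions)) {
    # substrate and oxygen bounds chosen so that both routes are forced at
    # exactly determined fluxes: the flux vector is then fixed by
    # stoichiometry alone, independent of the drawn turnover adjustments,
    # and every enzyme carries flux in every condition
    growth <- c(0.2, 0.28, 0.36, 0.44, 0.52, 0.6, 0.68, 0.76)
    conditions <- stats::setNames(
      lapply(growth, function(g) list(growth = g, uptake_bound = 350 * g,
                                      oxygen_bound = 50 * g)),
      paste0("cond", seq_along(growth)))
  }
  set.seed(seed)
  enz_rxns <- sort(unique(world$true_kcat$reaction))
  u_true <- stats::rnorm(length(enz_rxns), 0, u_sd)
  u_true <- u_true - mean(u_true)
  names(u_true) <- enz_rxns
  kc_true <- world$true_kcat
  kc_true$kcat_s <- kc_true$kcat_s * 10^(u_true[kc_true$reaction])
  ec_true <- toy_ec_model(world, etot = 10, sigma = 1, turnovers = kc_true)
  sig_c <- stats::setNames(stats::runif(length(conditions), sigma_range[1],
                                        sigma_range[2]), names(conditions))
  rows <- list()
  for (cn in names(conditions)) {
    cond <- conditions[[cn]]
    ecc <- ec_set_condition(ec_true, world$substrate_exchange,
                            uptake_bound = cond$uptake_bound,
                            oxygen_exchange = world$oxygen_exchange,
                            oxygen_uptake_bound = cond$oxygen_bound)
    alloc <- predict_allocation(ecc, cond$growth)
    e <- alloc$enzyme_abundance
    e <- e[e > 0]
    eps <- stats::rnorm(length(e), 0, noise_sd_log10)
    rows[[cn]] <- data.frame(condition = cn, enzyme = names(e),
                             abundance = as.numeric(e / sig_c[[cn]] * 10^eps),
                             stringsAsFactors = FALSE)
  }
  ref_conditions <- lapply(conditions, function(x) {
    out <- list(growth = x$growth,
                carbon_exchange = world$substrate_exchange,
                uptake_bound = x$uptake_bound)
    if (!is.null(x$oxygen_bound)) {
      out$oxygen_exchange <- world$oxygen_exchange
      out$oxygen_uptake_bound <- x$oxygen_bound
    }
    out
  })
  list(abundance = do.call(rbind, rows), true_u = u_true,
       true_sigma = sig_c, true_kcat = kc_true, conditions = conditions,
       ref_conditions = ref_conditions)
}

#' Simulate a thermodynamic parameter set for a toy world
#'
#' Means are fixed negative standard reaction energies consistent with a
#' forward-running pathway; the covariance is either diagonal (`sd^2 I`) or
#' a rank-one, fully correlated pathway factor (`sd^2 w w'` with unit
#' loadings), both positive semidefinite by construction.
#'
#' @param world a `toy_world`.
#' @param sd kJ/mol uncertainty scale.
#' @param correlation `"independent"` or `"pathway_correlated"`.
#' @param seed integer seed (deterministic means; kept for interface
#'   symmetry).
#' @return a `thermo_parameter_set` over the internal (non-exchange,
#'   non-pseudo) reactions of the world.
#' @export
simulate_thermo_params <- function(world, sd = 2,
                                   correlation = c("independent",
                                                   "pathway_correlated"),
                                   seed = 1L) {
  correlation <- match.arg(correlation)
  model <- world$model
  excl <- c(exchange_reactions(model), world$biomass, world$maintenance)
  rxns <- setdiff(model$reaction_ids, excl)
  mean <- stats::setNames(seq(-12, -20, length.out = length(rxns)), rxns)
  n <- length(rxns)
  cov <- if (correlation == "independent") diag(sd^2, n)
         else sd^2 * tcrossprod(rep(1, n))
  thermo_parameter_set(rxns, mean, cov)
}
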