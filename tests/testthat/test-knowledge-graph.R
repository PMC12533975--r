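toy_graph <- function() {
  # R1 catalysed by complex E12 (g1 AND g2, via 2xP1 + 1xP2) and monomer
  # E3 (g3); R2 catalysed only by E12 (shared subunit across isozymes)
  knowledge_graph(
    nodes = data.frame(
      id = c("R1", "R2", "E12", "E3", "P1", "P2", "P3", "g1", "g2", "g3"),
      type = c("reaction", "reaction", "protein", "protein",
               "polypeptide", "polypeptide", "polypeptide",
               "gene", "gene", "gene"),
      molecular_mass = c(NA, NA, NA, NA, 50, 25, 30, NA, NA, NA)),
    edges = data.frame(
      from = c("E12", "E3", "E12", "E12", "E12", "E3",
               "g1", "g2", "g3"),
      to = c("R1", "R1", "R2", "P1", "P2", "P3", "P1", "P2", "P3"),
      type = c("catalysis", "catalysis", "catalysis",
               "subunit_composition", "subunit_composition",
               "subunit_composition", "coding", "coding", "coding"),
      stoichiometry = c(NA, NA, NA, 2, 1, 1, NA, NA, NA),
      catalysis_class = c("primary", "secondary", "primary",
                          rep(NA, 6))))
}

test_that("validate_graph reports typed-edge and acyclicity violations", {
  g <- toy_graph()
  expect_identical(validate_graph(g), character(0))
  bad <- g
  bad$edges$from[1] <- "g1"                     # gene -> reaction catalysis
  expect_match(validate_graph(bad), "protein->reaction", all = FALSE)
  cyc <- g
  cyc$edges <- rbind(cyc$edges, data.frame(
    from = c("E12", "E3"), to = c("E3", "E12"), type = "subunit_composition",
    stoichiometry = 1, catalysis_class = NA, evidence = NA))
  expect_match(validate_graph(cyc), "cycle", all = FALSE)
  frac <- g
  frac$edges$stoichiometry[4] <- 1.5
  expect_match(validate_graph(frac), "integer", all = FALSE)
})

test_that("protein_mass is the recursive stoichiometry-weighted sum", {
  g <- toy_graph()
  expect_equal(protein_mass(g, "E12"), 2 * 50 + 1 * 25)   # 125 kDa
  expect_equal(protein_mass(g, "P3"), 30)                 # leaf identity
  # complex of complexes: 2 x (dimer of 10 kDa) = 40
  g2 <- knowledge_graph(
    nodes = data.frame(id = c("C", "D", "P"),
                       type = c("protein", "protein", "polypeptide"),
                       molecular_mass = c(NA, NA, 10)),
    edges = data.frame(from = c("C", "D"), to = c("D", "P"),
                       type = "subunit_composition", stoichiometry = c(2, 2)))
  expect_equal(protein_mass(g2, "C"), 40)
  expect_equal(n_subunits(g2, "C"), 4L)
  # missing leaf mass is an error naming the polypeptide
  g3 <- toy_graph()
  g3$nodes$molecular_mass[g3$nodes$id == "P2"] <- NA
  expect_error(protein_mass(g3, "E12"), "P2")
})

test_that("derived GPRs match the catalyst structure", {
  g <- toy_graph()
  r1 <- derive_gpr(g, "R1")
  expect_false(r1$orphan)
  expect_true(eval_gpr(r1, character(0)))
  expect_setequal(names(r1$terms), c("E12", "E3"))
  expect_identical(format(derive_gpr(g, "R2")), "(g1 and g2)")
  # orphan reaction: constant TRUE
  g$nodes <- rbind(g$nodes, data.frame(id = "Rspont", type = "reaction",
                                       molecular_mass = NA))
  spont <- derive_gpr(g, "Rspont")
  expect_true(spont$orphan)
  expect_true(eval_gpr(spont, c("g1", "g2", "g3")))
})

test_that("GPR evaluation and knockout propagation agree on every gene state", {
  worlds <- list(toy_graph(),
                 make_toy_network("branched")$graph,
                 make_toy_network("respirofermentative")$graph)
  for (g in worlds) {
    genes <- g$nodes$id[g$nodes$type == "gene"]
    rxns <- g$nodes$id[g$nodes$type == "reaction"]
    gprs <- lapply(rxns, derive_gpr, graph = g)
    names(gprs) <- rxns
    for (mask in 0:(2^length(genes) - 1)) {
      ko <- genes[bitwAnd(mask, 2^(seq_along(genes) - 1)) > 0]
      surviving <- propagate_knockout(g, ko)
      for (r in rxns) {
        has_cat <- nrow(fluxkit:::catalysts_of(g, r)) > 0
        if (!has_cat) next
        expect_identical(eval_gpr(gprs[[r]], ko),
                         r %in% surviving$to,
                         label = paste("reaction", r, "KO",
                                       paste(ko, collapse = "+")))
      }
    }
  }
})

test_that("disruption classes follow the definitions and precedence", {
  g <- make_toy_network("respirofermentative")$graph
  # FERM: primary E_ferm (g_f), secondary E_ferm2 (g_f2)
  expect_identical(classify_disruption(g, "FERM", "g_f"), "full_primary")
  expect_identical(classify_disruption(g, "FERM", "g_f2"), "secondary")
  expect_identical(classify_disruption(g, "FERM", c("g_f", "g_f2")), "complete")
  expect_identical(classify_disruption(g, "FERM", character(0)), "none")
  # two primary isozymes, one knocked out
  g2 <- toy_graph()
  g2$edges$catalysis_class[2] <- "primary"
  expect_identical(classify_disruption(g2, "R1", "g3"), "partial_primary")
  # monotone in the knocked set
  lv <- c("complete", "full_primary", "partial_primary", "secondary", "none")
  genes <- g$nodes$id[g$nodes$type == "gene"]
  for (mask in 0:(2^length(genes) - 1)) {
    ko <- genes[bitwAnd(mask, 2^(seq_along(genes) - 1)) > 0]
    c1 <- match(classify_disruption(g, "FERM", ko), lv)
    for (extra in setdiff(genes, ko)) {
      c2 <- match(classify_disruption(g, "FERM", c(ko, extra)), lv)
      expect_lte(c2, c1)
    }
  }
})

test_that("disruption analysis labels genes by most severe essential loss", {
  wb <- make_toy_network("branched")
  conds <- list(std = list(carbon_exchange = "U", uptake_bound = 10,
                           oxygen_exchange = NULL,
                           maintenance_reaction = NULL))
  rep <- disruption_analysis(wb$model, wb$graph, conds)
  # R1 (the only route to the objective) is essential; R2 is not
  expect_setequal(rep$gene, c("g1", "g1s"))
  expect_identical(rep$disruption_class[rep$gene == "g1"], "full_primary")
  expect_identical(rep$disruption_class[rep$gene == "g1s"], "secondary")
  expect_false(any(grepl("R2", rep$affected_reactions)))
})

test_that("complex abundance estimation solves NNLS with KKT optimality", {
  # homodimer: p = 10 with stoichiometry 2 -> e = 5
  g <- knowledge_graph(
    nodes = data.frame(id = c("R", "E", "P", "g"),
                       type = c("reaction", "protein", "polypeptide", "gene"),
                       molecular_mass = c(NA, NA, 20, NA)),
    edges = data.frame(from = c("E", "E", "g"), to = c("R", "P", "P"),
                       type = c("catalysis", "subunit_composition", "coding"),
                       stoichiometry = c(NA, 2, NA)))
  e <- estimate_complex_abundances(g, c(P = 10))
  expect_equal(unname(e[["E"]]), 5)
  # heterodimer 1:1 with p = (10, 8): least squares e = 9
  gh <- toy_graph()
  e2 <- estimate_complex_abundances(gh, c(P1 = 10, P2 = 8, P3 = 1),
                                    proteins = "E12")
  # E12 uses 2xP1 + 1xP2: lsq of (10 - 2e)^2 + (8 - e)^2 -> e = 28/5
  expect_equal(unname(e2[["E12"]]), 28 / 5, tolerance = 1e-8)
  # shared-subunit recovery: forward-simulate then fit
  e_true <- c(E12 = 3, E3 = 7)
  p <- c(P1 = 2 * 3, P2 = 3, P3 = 7)
  e3 <- estimate_complex_abundances(gh, p)
  expect_equal(e3[names(e_true)], e_true, tolerance = 1e-6)
  # KKT: e >= 0 and min(e, grad) ~ 0
  P <- matrix(c(2, 1, 0, 0, 0, 1), 3, 2,
              dimnames = list(c("P1", "P2", "P3"), c("E12", "E3")))
  grad <- crossprod(P, P %*% e3[colnames(P)] - p[rownames(P)])
  expect_lt(max(abs(pmin(e3[colnames(P)], grad))), 1e-6)
  # missing polypeptide is an error listing the gap
  expect_error(estimate_complex_abundances(gh, c(P1 = 1, P2 = 1)), "P3")
})

test_that("GML round trip preserves nodes, edges and attributes", {
  g <- make_toy_network("respirofermentative")$graph
  path <- withr::local_tempfile(fileext = ".gml")
  write_graph_gml(g, path)
  g2 <- read_graph_gml(path)
  expect_identical(validate_graph(g2), character(0))
  expect_setequal(g2$nodes$id, g$nodes$id)
  expect_equal(nrow(g2$edges), nrow(g$edges))
  expect_equal(protein_mass(g2, "E_resp"), protein_mass(g, "E_resp"))
  key <- function(e) paste(e$from, e$to, e$type, e$catalysis_class)
  expect_setequal(key(g2$edges), key(g$edges))
})
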