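#' Construct a reaction-enzyme-polypeptide-gene knowledge graph
#'
#' The graph is a typed directed graph linking the stoichiometric model to
#' the proteins behind it. Node types: `reaction`, `protein`, `polypeptide`,
#' `gene`, `compound`. Edge types: `catalysis` (protein -> reaction, with a
#' `catalysis_class` of `"primary"` or `"secondary"`), `subunit_composition`
#' (complex -> component, with integer stoichiometry), `coding`
#' (gene -> polypeptide), plus `regulation` and `modification`, which are
#' stored and round-tripped but carry no knockout semantics.
#'
#' @param nodes data frame with columns `id`, `type`, and optionally
#'   `molecular_mass` (kDa, for polypeptides).
#' @param edges data frame with columns `from`, `to`, `type`, and optionally
#'   `stoichiometry`, `catalysis_class`, `evidence`. Catalysis edges with a
#'   missing class default to `"primary"`.
#' @return an object of class `knowledge_graph`.
#' @export
knowledge_graph <- function(nodes, edges) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "type") %in% names(nodes)),
            all(c("from", "to", "type") %in% names(edges)))
  if (is.null(nodes$molecular_mass)) nodes$molecular_mass <- NA_real_
  if (is.null(edges$stoichiometry)) edges$stoichiometry <- NA_real_
  if (is.null(edges$catalysis_class)) edges$catalysis_class <- NA_character_
  if (is.null(edges$evidence)) edges$evidence <- NA_character_
  # missing catalysis class defaults to primary unless evidence says otherwise
  is_cat <- edges$type == "catalysis"
  edges$catalysis_class[is_cat & is.na(edges$catalysis_class)] <- "primary"
  structure(list(nodes = nodes, edges = edges), class = "knowledge_graph")
}

#' @export
print.knowledge_graph <- function(x, ...) {
  cat("knowledge_graph:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  print(table(x$nodes$type))
  invisible(x)
}

node_type <- function(graph, id) {
  graph$nodes$type[match(id, graph$nodes$id)]
}

edges_of_type <- function(graph, type) {
  graph$edges[graph$edges$type == type, , drop = FALSE]
}

#' Validate knowledge graph invariants
#'
#' Checks endpoint types of catalysis/coding/subunit edges, integer subunit
#' stoichiometry, and acyclicity of the subunit-composition subgraph.
#'
#' @param graph a `knowledge_graph`.
#' @return character vector of violations (empty if the graph is valid).
#' @export
validate_graph <- function(graph) {
  v <- character(0)
  n <- graph$nodes
  e <- graph$edges
  allowed_nodes <- c("reaction", "protein", "polypeptide", "gene", "compound")
  bad <- !n$type %in% allowed_nodes
  if (any(bad))
    v <- c(v, sprintf("node '%s': unknown type '%s'", n$id[bad], n$type[bad]))
  miss <- !(e$from %in% n$id) | !(e$to %in% n$id)
  if (any(miss))
    v <- c(v, sprintf("edge %s->%s: endpoint not a declared node",
                      e$from[miss], e$to[miss]))
  ft <- node_type(graph, e$from)
  tt <- node_type(graph, e$to)
  ct <- e$type == "catalysis"
  bad <- ct & !(ft == "protein" & tt == "reaction")
  if (any(bad, na.rm = TRUE))
    v <- c(v, sprintf("catalysis edge %s->%s: must connect protein->reaction",
                      e$from[which(bad)], e$to[which(bad)]))
  cd <- e$type == "coding"
  bad <- cd & !(ft == "gene" & tt == "polypeptide")
  if (any(bad, na.rm = TRUE))
    v <- c(v, sprintf("coding edge %s->%s: must connect gene->polypeptide",
                      e$from[which(bad)], e$to[which(bad)]))
  su <- e$type == "subunit_composition"
  bad <- su & !(ft == "protein" & tt %in% c("protein", "polypeptide"))
  if (any(bad, na.rm = TRUE))
    v <- c(v, sprintf("subunit edge %s->%s: must connect protein->protein|polypeptide",
                      e$from[which(bad)], e$to[which(bad)]))
  st <- e$stoichiometry[su]
  bad <- is.na(st) | st < 1 | st != round(st)
  if (any(bad))
    v <- c(v, sprintf("subunit edge %s->%s: stoichiometry must be an integer >= 1",
                      e$from[which(su)][bad], e$to[which(su)][bad]))
  # acyclicity of the subunit subgraph
  sub <- e[su & !miss, c("from", "to"), drop = FALSE]
  if (nrow(sub) > 0) {
    g <- igraph::graph_from_data_frame(sub, directed = TRUE)
    if (!igraph::is_dag(g))
      v <- c(v, "subunit_composition subgraph contains a cycle")
  }
  v
}

subunit_children <- function(graph, protein) {
  e <- graph$edges
  sel <- e$type == "subunit_composition" & e$from == protein
  list(ids = e$to[sel], stoich = e$stoichiometry[sel])
}

#' Recursive molecular mass of a protein node
#'
#' The mass of a complex is the stoichiometry-weighted sum of the masses of
#' its components, computed recursively down to polypeptide leaves, which
#' must carry a `molecular_mass` attribute (kDa).
#'
#' @param graph a `knowledge_graph`.
#' @param protein node id of a protein or polypeptide.
#' @return mass in kDa.
#' @export
protein_mass <- function(graph, protein) {
  rec <- function(id, stack) {
    if (id %in% stack) stop("subunit cycle detected at node '", id, "'")
    ty <- node_type(graph, id)
    if (is.na(ty)) stop("unknown node: ", id)
    if (ty == "polypeptide") {
      m <- graph$nodes$molecular_mass[match(id, graph$nodes$id)]
      if (is.na(m)) stop("polypeptide '", id, "' has no molecular_mass")
      return(m)
    }
    ch <- subunit_children(graph, id)
    if (length(ch$ids) == 0) {
      m <- graph$nodes$molecular_mass[match(id, graph$nodes$id)]
      if (!is.na(m)) return(m)
      stop("protein '", id, "' has no subunits and no molecular_mass")
    }
    sum(ch$stoich * vapply(ch$ids, rec, 0, stack = c(stack, id)))
  }
  rec(protein, character(0))
}

#' Total polypeptide composition of a protein
#'
#' @param graph a `knowledge_graph`.
#' @param protein protein node id.
#' @return named numeric vector: total copy number of each polypeptide in
#'   one copy of the protein (recursively through sub-complexes).
#' @export
polypeptide_composition <- function(graph, protein) {
  rec <- function(id, mult, stack) {
    if (id %in% stack) stop("subunit cycle detected at node '", id, "'")
    if (node_type(graph, id) == "polypeptide")
      return(stats::setNames(mult, id))
    ch <- subunit_children(graph, id)
    if (length(ch$ids) == 0)
      stop("protein '", id, "' has no subunit composition")
    out <- numeric(0)
    for (k in seq_along(ch$ids)) {
      part <- rec(ch$ids[k], mult * ch$stoich[k], c(stack, id))
      for (p in names(part)) {
        out[p] <- (if (p %in% names(out)) out[[p]] else 0) + part[[p]]
      }
    }
    out
  }
  rec(protein, 1, character(0))
}

#' Number of polypeptide subunits of a protein
#'
#' Turnover numbers reported per polypeptide are multiplied by this count to
#' obtain per-enzyme turnover.
#'
#' @inheritParams polypeptide_composition
#' @return integer total subunit count.
#' @export
n_subunits <- function(graph, protein) {
  if (node_type(graph, protein) == "polypeptide") return(1L)
  as.integer(round(sum(polypeptide_composition(graph, protein))))
}

catalysts_of <- function(graph, reaction) {
  e <- graph$edges
  sel <- e$type == "catalysis" & e$to == reaction
  data.frame(protein = e$from[sel],
             catalysis_class = e$catalysis_class[sel],
             stringsAsFactors = FALSE)
}

coding_genes <- function(graph, polypeptide) {
  e <- graph$edges
  e$from[e$type == "coding" & e$to == polypeptide]
}

# per-protein gene requirement: a list of OR-sets (one per required
# polypeptide with at least one coding gene)
protein_gene_requirement <- function(graph, protein) {
  polys <- names(polypeptide_composition(graph, protein))
  sets <- lapply(polys, function(p) coding_genes(graph, p))
  sets[vapply(sets, length, 0L) > 0]
}

#' Derive the Boolean gene-protein-reaction rule of a reaction
#'
#' The GPR is the OR over catalysing proteins of the AND over that protein's
#' required polypeptides, each polypeptide contributing an OR over its coding
#' genes. Reactions with no catalysis edge are flagged spontaneous/orphan and
#' evaluate to constant `TRUE`.
#'
#' @param graph a `knowledge_graph`.
#' @param reaction reaction node id.
#' @return an object of class `gpr` with fields `reaction`, `terms` (per
#'   protein, a list of gene OR-sets) and `orphan`.
#' @export
derive_gpr <- function(graph, reaction) {
  if (!reaction %in% graph$nodes$id) stop("unknown reaction node: ", reaction)
  cats <- catalysts_of(graph, reaction)
  terms <- lapply(cats$protein, function(p) protein_gene_requirement(graph, p))
  names(terms) <- cats$protein
  structure(list(reaction = reaction, terms = terms,
                 orphan = nrow(cats) == 0), class = "gpr")
}

#' Evaluate a GPR under a gene knockout set
#'
#' @param gpr a `gpr` object from [derive_gpr()].
#' @param knocked_genes character vector of knocked-out gene ids.
#' @return logical: does the reaction retain a functional catalyst?
#' @export
eval_gpr <- function(gpr, knocked_genes) {
  if (gpr$orphan) return(TRUE)
  any(vapply(gpr$terms, function(sets) {
    all(vapply(sets, function(g) any(!g %in% knocked_genes), TRUE))
  }, TRUE))
}

#' @export
format.gpr <- function(x, ...) {
  if (x$orphan) return("TRUE  # spontaneous/orphan")
  or_terms <- vapply(x$terms, function(sets) {
    ands <- vapply(sets, function(g) {
      if (length(g) == 1) g else paste0("(", paste(g, collapse = " or "), ")")
    }, "")
    if (length(ands) == 0) "TRUE"
    else if (length(ands) == 1) ands
    else paste0("(", paste(ands, collapse = " and "), ")")
  }, "")
  paste(or_terms, collapse = " or ")
}

#' @export
print.gpr <- function(x, ...) {
  cat(x$reaction, ":", format(x), "\n")
  invisible(x)
}

#' Propagate gene knockouts through the knowledge graph
#'
#' A polypeptide is lost iff all of its coding genes are knocked out; a
#' protein is lost iff any recursively required polypeptide is lost; a
#' catalysis edge survives iff its protein survives. This walks the graph
#' directly (it does not evaluate GPR expressions), so it serves as an
#' independent route to the same Boolean semantics.
#'
#' @param graph a `knowledge_graph`.
#' @param knocked_genes character vector of gene node ids.
#' @return the surviving catalysis edges (data frame with `from`, `to`,
#'   `catalysis_class`).
#' @export
propagate_knockout <- function(graph, knocked_genes) {
  genes <- graph$nodes$id[graph$nodes$type == "gene"]
  unknown <- setdiff(knocked_genes, genes)
  if (length(unknown)) stop("unknown gene id(s): ", paste(unknown, collapse = ", "))
  memo <- new.env(parent = emptyenv())
  survives <- function(id) {
    if (!is.null(memo[[id]])) return(memo[[id]])
    ty <- node_type(graph, id)
    out <- if (ty == "polypeptide") {
      g <- coding_genes(graph, id)
      length(g) == 0 || any(!g %in% knocked_genes)
    } else {
      ch <- subunit_children(graph, id)
      if (length(ch$ids) == 0) TRUE else all(vapply(ch$ids, survives, TRUE))
    }
    memo[[id]] <- out
    out
  }
  e <- edges_of_type(graph, "catalysis")
  keep <- vapply(e$from, survives, TRUE)
  e[keep, c("from", "to", "catalysis_class"), drop = FALSE]
}

disruption_levels <- c("complete", "full_primary", "partial_primary",
                       "secondary", "none")

#' Classify the catalytic disruption of a reaction under a knockout
#'
#' Classes, by decreasing severity: `complete` (all catalysis edges lost),
#' `full_primary` (all primary edges lost, some secondary left),
#' `partial_primary` (some but not all primary edges lost), `secondary`
#' (only secondary edges lost), `none`.
#'
#' @param graph a `knowledge_graph`.
#' @param reaction reaction node id with at least one catalysis edge.
#' @param knocked_genes character vector of gene ids.
#' @return one of `"complete"`, `"full_primary"`, `"partial_primary"`,
#'   `"secondary"`, `"none"`.
#' @export
classify_disruption <- function(graph, reaction, knocked_genes) {
  before <- catalysts_of(graph, reaction)
  if (nrow(before) == 0) stop("reaction '", reaction, "' has no catalysis edges")
  after <- propagate_knockout(graph, knocked_genes)
  surv <- after$from[after$to == reaction]
  lost <- setdiff(before$protein, surv)
  prim <- before$protein[before$catalysis_class == "primary"]
  sec <- before$protein[before$catalysis_class == "secondary"]
  lost_prim <- intersect(lost, prim)
  if (length(surv) == 0) return("complete")
  if (length(prim) > 0 && length(lost_prim) == length(prim)) return("full_primary")
  if (length(lost_prim) > 0) return("partial_primary")
  if (length(intersect(lost, sec)) > 0) return("secondary")
  "none"
}

reaction_genes <- function(graph, reaction) {
  cats <- catalysts_of(graph, reaction)
  unique(unlist(lapply(cats$protein, function(p)
    unlist(protein_gene_requirement(graph, p)))))
}

#' Condition-specific catalytic disruption analysis
#'
#' For each condition, essential reactions are those whose single-reaction
#' knockout drops growth below `threshold` times wild-type growth. Each gene
#' of each essential reaction is knocked out in silico, the knockout is
#' propagated through the graph, and the gene is labelled with its most
#' severe disruption class over the essential reactions it affects
#' (precedence: complete > full_primary > partial_primary > secondary).
#'
#' @param model a `metabolic_model`.
#' @param graph a `knowledge_graph`.
#' @param conditions named list; each element is a list of arguments for
#'   [set_condition()] (e.g. `list(carbon_exchange = "EX_glc_e")`).
#' @param threshold relative growth threshold for essentiality (default
#'   `1e-6`).
#' @param excluded_reactions reaction ids excluded as known false essentials.
#' @return data frame with columns `condition`, `gene`, `disruption_class`,
#'   `affected_reactions`.
#' @export
disruption_analysis <- function(model, graph, conditions, threshold = 1e-6,
                                excluded_reactions = character(0)) {
  out <- list()
  for (cn in names(conditions)) {
    mod <- do.call(set_condition, c(list(model), conditions[[cn]]))
    wt <- solve_fba(mod)
    if (wt$status != "optimal" || wt$objective_value <= threshold)
      stop("wild type infeasible or non-growing in condition '", cn, "'")
    candidates <- setdiff(intersect(model$reaction_ids,
                                    graph$nodes$id[graph$nodes$type == "reaction"]),
                          excluded_reactions)
    essential <- candidates[vapply(candidates, function(r) {
      ko <- with_bounds(mod, r, lb = 0, ub = 0)
      g <- solve_fba(ko)
      g$status != "optimal" || g$objective_value < threshold * wt$objective_value
    }, TRUE)]
    # orphan/spontaneous reactions cannot be disrupted genetically
    essential <- essential[vapply(essential, function(r)
      nrow(catalysts_of(graph, r)) > 0, TRUE)]
    gene_map <- lapply(essential, function(r) reaction_genes(graph, r))
    names(gene_map) <- essential
    genes <- unique(unlist(gene_map))
    for (g in genes) {
      affected <- essential[vapply(essential, function(r) g %in% gene_map[[r]], TRUE)]
      classes <- vapply(affected, function(r)
        classify_disruption(graph, r, g), "")
      affected <- affected[classes != "none"]
      classes <- classes[classes != "none"]
      if (length(affected) == 0) next
      worst <- disruption_levels[min(match(classes, disruption_levels))]
      out[[length(out) + 1]] <- data.frame(
        condition = cn, gene = g, disruption_class = worst,
        affected_reactions = paste(affected, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(condition = character(0), gene = character(0),
                      disruption_class = character(0),
                      affected_reactions = character(0)))
  do.call(rbind, out)
}

#' Estimate protein-complex abundances from polypeptide counts
#'
#' Solves the non-negative least-squares problem `min ||P e - p||_2`,
#' `e >= 0`, where `P` is the polypeptide x complex stoichiometry matrix
#' derived from the subunit-composition edges. Degenerate (rank-deficient)
#' fits are resolved towards the minimum-norm solution by a vanishing ridge.
#'
#' @param graph a `knowledge_graph`.
#' @param polypeptide_abundance named nonnegative numeric vector of measured
#'   (or imputed) polypeptide counts.
#' @param proteins protein ids to estimate; default: all proteins with at
#'   least one catalysis edge.
#' @return named numeric vector of complex abundances `e`.
#' @export
estimate_complex_abundances <- function(graph, polypeptide_abundance,
                                        proteins = NULL) {
  if (is.null(proteins)) {
    proteins <- unique(edges_of_type(graph, "catalysis")$from)
  }
  stopifnot(length(proteins) > 0)
  comp <- lapply(proteins, function(p) polypeptide_composition(graph, p))
  polys <- unique(unlist(lapply(comp, names)))
  gaps <- setdiff(polys, names(polypeptide_abundance))
  if (length(gaps))
    stop("polypeptide(s) without measured or imputed abundance: ",
         paste(gaps, collapse = ", "))
  if (any(polypeptide_abundance < 0)) stop("abundances must be nonnegative")
  P <- matrix(0, length(polys), length(proteins),
              dimnames = list(polys, proteins))
  for (k in seq_along(proteins)) P[names(comp[[k]]), k] <- comp[[k]]
  p <- polypeptide_abundance[polys]
  e <- nnls_fit(P, p)
  stats::setNames(e, proteins)
}

# non-negative least squares via quadprog; vanishing ridge when the Gram
# matrix is singular (minimum-norm tie-break)
nnls_fit <- function(P, p) {
  D <- crossprod(P)
  if (rcond(D) < 1e-12) {
    D <- D + diag(1e-10 * max(diag(D)), ncol(D))
  }
  d <- crossprod(P, p)
  sol <- quadprog::solve.QP(D, d, diag(ncol(P)), rep(0, ncol(P)))
  pmax(sol$solution, 0)
}

#' Read a knowledge graph from GML
#'
#' @param path GML file path.
#' @return a `knowledge_graph`.
#' @export
read_graph_gml <- function(path) {
  g <- igraph::read_graph(path, format = "gml")
  nodes <- data.frame(
    id = igraph::vertex_attr(g, "label"),
    type = igraph::vertex_attr(g, "nodetype"),
    molecular_mass = igraph::vertex_attr(g, "mass") %||% NA_real_,
    stringsAsFactors = FALSE)
  nodes$molecular_mass[nodes$molecular_mass < 0] <- NA_real_
  el <- igraph::as_edgelist(g, names = FALSE)
  edges <- data.frame(
    from = nodes$id[el[, 1]],
    to = nodes$id[el[, 2]],
    type = igraph::edge_attr(g, "edgetype"),
    stoichiometry = igraph::edge_attr(g, "stoichiometry") %||% NA_real_,
    catalysis_class = igraph::edge_attr(g, "catclass") %||% NA_character_,
    stringsAsFactors = FALSE)
  edges$stoichiometry[edges$stoichiometry < 0] <- NA_real_
  edges$catalysis_class[edges$catalysis_class == ""] <- NA_character_
  knowledge_graph(nodes, edges)
}

#' Write a knowledge graph to GML
#'
#' @param graph a `knowledge_graph`.
#' @param path output path.
#' @export
write_graph_gml <- function(graph, path) {
  g <- igraph::graph_from_data_frame(
    graph$edges[, c("from", "to")], directed = TRUE,
    vertices = graph$nodes$id)
  igraph::vertex_attr(g, "label") <- graph$nodes$id
  igraph::vertex_attr(g, "nodetype") <- graph$nodes$type
  mm <- graph$nodes$molecular_mass
  igraph::vertex_attr(g, "mass") <- ifelse(is.na(mm), -1, mm)
  igraph::edge_attr(g, "edgetype") <- graph$edges$type
  st <- graph$edges$stoichiometry
  igraph::edge_attr(g, "stoichiometry") <- ifelse(is.na(st), -1, st)
  cc <- graph$edges$catalysis_class
  igraph::edge_attr(g, "catclass") <- ifelse(is.na(cc), "", cc)
  igraph::write_graph(g, path, format = "gml")
  invisible(path)
}
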