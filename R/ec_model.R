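#' Turnover number set
#'
#' Direction-specific turnover numbers (s^-1) per reaction, with provenance
#' (`measured`, `default_transporter`, or `adjusted`). If
#' `subunit_applied = FALSE` (the default), values are understood per
#' polypeptide and are multiplied by the number of polypeptide subunits of
#' the catalysing enzyme when enzyme costs are computed; this multiplier is
#' applied exactly once.
#'
#' @param reaction,direction,kcat_s,provenance vectors of equal length;
#'   `direction` is `"fwd"` or `"rev"`.
#' @param subunit_applied logical flag.
#' @return object of class `turnover_set` (a data frame).
#' @export
turnover_set <- function(reaction, direction = "fwd", kcat_s,
                         provenance = "measured", subunit_applied = FALSE) {
  stopifnot(all(direction %in% c("fwd", "rev")))
  if (any(kcat_s <= 0)) stop("all turnover numbers must be positive")
  out <- data.frame(reaction = reaction, direction = direction,
                    kcat_s = kcat_s, provenance = provenance,
                    stringsAsFactors = FALSE)
  attr(out, "subunit_applied") <- subunit_applied
  class(out) <- c("turnover_set", class(out))
  out
}

lookup_kcat <- function(turnovers, reaction, direction) {
  hit <- turnovers$reaction == reaction & turnovers$direction == direction
  if (any(hit)) return(turnovers$kcat_s[which(hit)[1]])
  # fall back to the opposite direction when only one is reported
  hit <- turnovers$reaction == reaction
  if (any(hit)) return(turnovers$kcat_s[which(hit)[1]])
  NA_real_
}

#' Read / write a turnover-number TSV table
#'
#' Columns: `reaction`, `direction`, `kcat_s`, `provenance`.
#' @param path file path.
#' @return a `turnover_set`.
#' @export
read_turnovers <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  turnover_set(d$reaction, d$direction, d$kcat_s, d$provenance)
}

#' @rdname read_turnovers
#' @param turnovers a `turnover_set`.
#' @export
write_turnovers <- function(turnovers, path) {
  utils::write.table(as.data.frame(turnovers), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Select the catalytic enzyme of a reaction
#'
#' Secondary catalytic relationships are discarded; among several primary
#' isozymes the one with the highest measured abundance is chosen. With no
#' abundance data the tie is broken lexicographically when
#' `fallback_lexicographic = TRUE`, otherwise it is an error.
#'
#' @param graph a `knowledge_graph`.
#' @param reaction reaction node id.
#' @param abundance optional named numeric vector of protein abundances.
#' @param fallback_lexicographic logical tie-break flag.
#' @return a protein node id.
#' @export
select_catalytic_enzyme <- function(graph, reaction, abundance = NULL,
                                    fallback_lexicographic = TRUE) {
  cats <- catalysts_of(graph, reaction)
  prim <- cats$protein[cats$catalysis_class == "primary"]
  if (length(prim) == 0)
    stop("reaction '", reaction, "' has no primary catalysis edge")
  if (length(prim) == 1) return(prim)
  ab <- if (is.null(abundance)) rep(NA_real_, length(prim)) else abundance[prim]
  ab[is.na(ab)] <- -Inf
  if (all(!is.finite(ab))) {
    if (!fallback_lexicographic)
      stop("no abundance data to break isozyme tie for reaction '", reaction, "'")
    return(sort(prim)[1])
  }
  best <- prim[ab == max(ab)]
  sort(best)[1]
}

#' Enzyme cost per unit flux
#'
#' `a = M / (kcat_s * n_subunits * 3600 * sigma)` in g h/mmol, with `M` in
#' kDa (numerically g/mmol) and `kcat_s` in s^-1 per polypeptide. The
#' subunit multiplier converts a per-polypeptide turnover into a per-enzyme
#' one; `sigma` is the condition-specific average saturation.
#'
#' @param M molecular mass (kDa).
#' @param kcat_s turnover number (s^-1).
#' @param sigma saturation scalar in (0, 1].
#' @param n_subunits number of polypeptide subunits (>= 1).
#' @return cost in g h/mmol.
#' @export
compute_enzyme_cost <- function(M, kcat_s, sigma = 1, n_subunits = 1) {
  if (any(M <= 0) || any(kcat_s <= 0) || any(sigma <= 0) || any(n_subunits < 1))
    stop("M, kcat_s, sigma must be positive and n_subunits >= 1")
  M / (kcat_s * n_subunits * 3600 * sigma)
}

ENZYME_POOL_MET <- "enzyme_pool"
ENZYME_SUPPLY_RXN <- "ENZ_SUPPLY"

#' Build an enzyme-constrained (sMOMENT) model
#'
#' Reversible reactions are duplicated into irreversible `<id>_fwd` /
#' `<id>_rev` copies; a pool pseudometabolite is consumed by each enzymatic
#' reaction with stoichiometry `a_i` (its enzyme cost per unit flux) and
#' produced by a supply pseudoreaction upper-bounded by `etot`, enforcing
#' `sum_i a_i v_i <= etot`. Exchanges, the biomass reaction, maintenance and
#' reactions without a catalysing enzyme carry zero cost. Transporters
#' lacking a measured turnover receive the conventional default of 65 s^-1.
#'
#' @param model a `metabolic_model`.
#' @param graph a `knowledge_graph` covering the enzymatic reactions.
#' @param turnovers a `turnover_set`.
#' @param etot total enzyme budget (g/gDW).
#' @param sigma average saturation scalar.
#' @param abundance optional protein abundances for isozyme selection.
#' @param masses optional named protein masses (kDa); defaults to
#'   [protein_mass()] on the graph.
#' @param transporters reaction ids treated as transporters for the default
#'   turnover rule.
#' @param default_transporter_kcat default transporter turnover (s^-1).
#' @param uncosted_whitelist reactions allowed to stay uncosted when no
#'   turnover is available.
#' @return an object of class `ec_model`: list with the augmented `model`,
#'   `cost` (per split reaction, at the given `sigma`), `enzyme_of`,
#'   `split_map`, `etot`, `sigma`, `biomass`, and a `report` of applied
#'   defaults/misses.
#' @export
build_ec_model <- function(model, graph, turnovers, etot, sigma = 1,
                           abundance = NULL, masses = NULL,
                           transporters = character(0),
                           default_transporter_kcat = 65,
                           uncosted_whitelist = character(0)) {
  exch <- exchange_reactions(model)
  biomass <- names(model$objective)[1]
  # direction-split model
  ids <- model$reaction_ids
  split_cols <- list(); split_map <- list()
  lb <- model$lower_bound; ub <- model$upper_bound
  for (k in seq_along(ids)) {
    id <- ids[k]
    fwd_ok <- ub[k] > 0
    rev_ok <- lb[k] < 0
    entries <- list()
    if (fwd_ok) {
      nm <- if (rev_ok) paste0(id, "_fwd") else id
      entries[[nm]] <- list(col = model$S[, k], lb = max(lb[k], 0), ub = ub[k],
                            dir = "fwd", base = id)
    }
    if (rev_ok) {
      nm <- if (fwd_ok) paste0(id, "_rev") else id
      entries[[nm]] <- list(col = -model$S[, k], lb = max(-ub[k], 0), ub = -lb[k],
                            dir = "rev", base = id)
    }
    split_cols <- c(split_cols, entries)
    split_map[[id]] <- names(entries)
  }
  sn <- names(split_cols)
  S2 <- do.call(cbind, lapply(split_cols, function(e) e$col))
  dimnames(S2) <- list(model$metabolite_ids, sn)
  lb2 <- vapply(split_cols, function(e) e$lb, 0)
  ub2 <- vapply(split_cols, function(e) e$ub, 0)

  # cost assignment per split reaction
  cost <- stats::setNames(rep(0, length(sn)), sn)
  enzyme_of <- stats::setNames(rep(NA_character_, length(sn)), sn)
  report <- list(default_transporter = character(0), missing_kcat = character(0))
  rxn_nodes <- graph$nodes$id[graph$nodes$type == "reaction"]
  for (nm in sn) {
    e <- split_cols[[nm]]
    base <- e$base
    if (base %in% exch || base == biomass || !base %in% rxn_nodes) next
    cats <- catalysts_of(graph, base)
    if (nrow(cats) == 0) next                      # spontaneous
    enz <- select_catalytic_enzyme(graph, base, abundance)
    M <- if (!is.null(masses) && enz %in% names(masses)) masses[[enz]]
         else protein_mass(graph, enz)
    kc <- lookup_kcat(turnovers, base, e$dir)
    nsub <- if (isTRUE(attr(turnovers, "subunit_applied"))) 1L
            else n_subunits(graph, enz)
    if (is.na(kc)) {
      if (base %in% transporters) {
        kc <- default_transporter_kcat
        report$default_transporter <- c(report$default_transporter, nm)
      } else if (base %in% uncosted_whitelist) {
        report$missing_kcat <- c(report$missing_kcat, nm)
        next
      } else {
        stop("no turnover number for reaction '", base, "' (", e$dir,
             ") and no default applies")
      }
    }
    cost[nm] <- compute_enzyme_cost(M, kc, sigma, nsub)
    enzyme_of[nm] <- enz
  }

  # pool row + supply pseudoreaction
  S3 <- rbind(S2, -cost)
  rownames(S3)[nrow(S3)] <- ENZYME_POOL_MET
  S3 <- cbind(S3, supply = c(rep(0, nrow(S2)), 1))
  colnames(S3)[ncol(S3)] <- ENZYME_SUPPLY_RXN
  lb3 <- c(lb2, 0); ub3 <- c(ub2, etot)
  obj_rxn <- split_map[[biomass]][1]
  aug <- metabolic_model(S3, lb3, ub3, stats::setNames(1, obj_rxn))
  structure(list(model = aug, cost = cost, enzyme_of = enzyme_of,
                 split_map = split_map, etot = etot, sigma = sigma,
                 biomass = obj_rxn, base_biomass = biomass),
            class = "ec_model")
}

#' @export
print.ec_model <- function(x, ...) {
  cat("ec_model:", length(x$cost), "split reactions,",
      sum(x$cost > 0), "costed; etot =", x$etot, "g/gDW; sigma =", x$sigma, "\n")
  invisible(x)
}

#' Change the total enzyme budget of an EC model
#'
#' @param ec an `ec_model`.
#' @param etot new budget (g/gDW); `Inf` removes the pool limit.
#' @return modified `ec_model`.
#' @export
set_enzyme_budget <- function(ec, etot) {
  ec$etot <- etot
  ec$model$upper_bound[ENZYME_SUPPLY_RXN] <- etot
  ec
}

#' Set bounds of a base reaction inside an EC model
#'
#' Maps bounds on the original (possibly reversible) reaction onto its
#' direction-split copies.
#'
#' @param ec an `ec_model`.
#' @param rxn base reaction id.
#' @param lb,ub new bounds on the base reaction.
#' @return modified `ec_model`.
#' @export
ec_set_bounds <- function(ec, rxn, lb, ub) {
  parts <- ec$split_map[[rxn]]
  if (is.null(parts)) stop("unknown base reaction: ", rxn)
  for (nm in parts) {
    dir_fwd <- !endsWith(nm, "_rev")
    if (dir_fwd) {
      ec$model$lower_bound[nm] <- max(lb, 0)
      ec$model$upper_bound[nm] <- max(ub, 0)
    } else {
      ec$model$lower_bound[nm] <- max(-ub, 0)
      ec$model$upper_bound[nm] <- max(-lb, 0)
    }
  }
  ec
}

#' Apply a growth condition to an EC model
#'
#' Enzyme-constrained analogue of [set_condition()].
#'
#' @inheritParams set_condition
#' @param ec an `ec_model`.
#' @return modified `ec_model`.
#' @export
ec_set_condition <- function(ec, carbon_exchange, uptake_bound = 10,
                             aerobic = TRUE, maintenance_bound = 0,
                             oxygen_exchange = NULL,
                             oxygen_uptake_bound = NULL,
                             maintenance_reaction = NULL) {
  ec <- ec_set_bounds(ec, carbon_exchange, -uptake_bound, 0)
  if (!is.null(oxygen_exchange)) {
    if (!aerobic) {
      ec <- ec_set_bounds(ec, oxygen_exchange, 0, 0)
    } else if (!is.null(oxygen_uptake_bound)) {
      ec <- ec_set_bounds(ec, oxygen_exchange, -oxygen_uptake_bound, 0)
    }
  }
  if (!is.null(maintenance_reaction)) {
    parts <- ec$split_map[[maintenance_reaction]]
    ec$model$lower_bound[parts[1]] <- maintenance_bound
  }
  ec
}

#' Net (direction-merged) fluxes of an EC solution
#'
#' @param ec an `ec_model`.
#' @param flux a `flux_distribution` on the split model.
#' @return named vector of net fluxes on the base reaction ids.
#' @export
net_fluxes <- function(ec, flux) {
  v <- flux$values
  out <- vapply(names(ec$split_map), function(id) {
    parts <- ec$split_map[[id]]
    s <- 0
    for (nm in parts) s <- s + if (endsWith(nm, "_rev")) -v[[nm]] else v[[nm]]
    s
  }, 0)
  out
}

#' Predict enzyme allocation at a fixed growth rate
#'
#' Fixes the biomass flux and minimises total enzyme cost
#' `sum_i a_i v_i` (the enzyme supply flux); per-enzyme abundances are the
#' costs `a_i v_i` aggregated over the reactions each enzyme catalyses.
#'
#' @param ec an `ec_model`.
#' @param growth_rate target growth rate (1/h).
#' @return list with `enzyme_abundance` (named g/gDW), `flux`
#'   (a `flux_distribution`), and `total_cost`.
#' @export
predict_allocation <- function(ec, growth_rate) {
  gmax <- solve_fba(ec$model)
  if (gmax$status != "optimal")
    stop("EC model infeasible (status ", gmax$status, ")")
  if (growth_rate > gmax$objective_value + 1e-9)
    stop("growth rate ", growth_rate, " infeasible; maximum feasible is ",
         format(gmax$objective_value))
  mod <- with_bounds(ec$model, ec$biomass, lb = growth_rate, ub = growth_rate)
  mod$objective <- stats::setNames(1, ENZYME_SUPPLY_RXN)
  sol <- solve_fba(mod, "min")
  if (sol$status != "optimal")
    stop("allocation LP returned status ", sol$status)
  contrib <- ec$cost * sol$values[names(ec$cost)]
  keep <- !is.na(ec$enzyme_of)
  ab <- tapply(contrib[keep], ec$enzyme_of[keep], sum)
  list(enzyme_abundance = stats::setNames(as.numeric(ab), names(ab)),
       flux = sol, total_cost = sol$objective_value)
}

#' Enzyme costs per unit flux on the base reaction ids
#'
#' Collapses the direction-split cost vector of an EC model back onto the
#' base reactions (taking the forward-direction cost where both exist), for
#' use with net-flux analyses such as elementary-mode scoring.
#'
#' @param ec an `ec_model`.
#' @return named numeric vector over base reactions with nonzero cost.
#' @export
enzyme_costs <- function(ec) {
  out <- numeric(0)
  for (id in names(ec$split_map)) {
    parts <- ec$split_map[[id]]
    fwd <- parts[!endsWith(parts, "_rev")]
    a <- if (length(fwd)) ec$cost[[fwd[1]]] else ec$cost[[parts[1]]]
    if (a > 0) out[id] <- a
  }
  out
}

#' Estimate the average saturation coefficient from data
#'
#' `sigma = sum(predicted over measured enzymes) / total measured abundance`;
#' dividing the predictions by `sigma` makes their sum match the measured
#' total.
#'
#' @param predicted named numeric vector of predicted abundances (g/gDW).
#' @param measured named numeric vector of measured abundances (g/gDW).
#' @return scalar `sigma`.
#' @export
fit_saturation <- function(predicted, measured) {
  common <- intersect(names(predicted), names(measured))
  if (length(common) == 0) stop("no overlap between predicted and measured enzymes")
  tot <- sum(measured)
  if (tot <= 0) stop("measured total abundance is zero")
  sum(predicted[common]) / tot
}

#' Root-mean-square error of log10 abundances
#'
#' Enzymes with zero (or missing) predicted abundance are excluded.
#'
#' @param predicted,measured named numeric vectors (g/gDW).
#' @return list with `rmse` (log10 units) and `n_used`.
#' @export
rmse_log10 <- function(predicted, measured) {
  common <- intersect(names(predicted), names(measured))
  p <- predicted[common]; m <- measured[common]
  keep <- p > 0 & m > 0
  if (!any(keep)) return(list(rmse = NA_real_, n_used = 0L))
  list(rmse = sqrt(mean((log10(p[keep]) - log10(m[keep]))^2)),
       n_used = sum(keep))
}
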