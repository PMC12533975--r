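#' Construct a metabolic model
#'
#' A `metabolic_model` holds a stoichiometric matrix (metabolites x
#' reactions), per-reaction flux bounds in mmol/gDW/h (the biomass reaction
#' is in 1/h by the usual convention), an objective, and annotations.
#' Exchange reactions are recognised as columns with exactly one nonzero
#' stoichiometric entry; uptake is a negative exchange flux.
#'
#' @param S numeric matrix, metabolites in rows, reactions in columns.
#'   Row and column names are used as metabolite and reaction identifiers.
#' @param lower_bound,upper_bound numeric vectors of per-reaction bounds.
#' @param objective named numeric vector of objective coefficients
#'   (typically `c(biomass_reaction = 1)`).
#' @param reversible optional logical vector; defaults to `lower_bound < 0`.
#' @param annotations optional named list of external-database references.
#' @return an object of class `metabolic_model`.
#' @export
metabolic_model <- function(S, lower_bound, upper_bound, objective,
                            reversible = NULL, annotations = list()) {
  S <- as.matrix(S)
  if (is.null(rownames(S)) || is.null(colnames(S)))
    stop("S must have metabolite row names and reaction column names")
  n <- ncol(S)
  stopifnot(length(lower_bound) == n, length(upper_bound) == n)
  if (any(lower_bound > upper_bound))
    stop("lower_bound must be <= upper_bound for every reaction")
  zero_cols <- colSums(abs(S)) == 0
  if (any(zero_cols))
    stop("reaction(s) with all-zero stoichiometry: ",
         paste(colnames(S)[zero_cols], collapse = ", "))
  if (is.null(names(objective)) || !all(names(objective) %in% colnames(S)))
    stop("objective must be named with reaction ids present in the model")
  m <- structure(list(
    S = S,
    metabolite_ids = rownames(S),
    reaction_ids = colnames(S),
    lower_bound = stats::setNames(as.numeric(lower_bound), colnames(S)),
    upper_bound = stats::setNames(as.numeric(upper_bound), colnames(S)),
    objective = objective,
    annotations = annotations
  ), class = "metabolic_model")
  m
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("metabolic_model:", length(x$metabolite_ids), "metabolites x",
      length(x$reaction_ids), "reactions\n")
  cat("  exchanges:", length(exchange_reactions(x)),
      " objective:", paste(names(x$objective), collapse = "+"), "\n")
  invisible(x)
}

#' Identifiers of exchange reactions
#'
#' Exchange (boundary) reactions are columns of the stoichiometric matrix
#' with exactly one nonzero entry.
#'
#' @param model a `metabolic_model`.
#' @return character vector of reaction ids.
#' @export
exchange_reactions <- function(model) {
  model$reaction_ids[colSums(model$S != 0) == 1]
}

#' Read a metabolic model from file
#'
#' Supports COBRA-style JSON (keys `metabolites`, `reactions` with
#' `lower_bound`/`upper_bound`/`metabolites` maps and `objective_coefficient`)
#' and SBML Level 3 with the FBC flux-bounds extension.
#'
#' @param path file path.
#' @param format `"json"` or `"sbml"`; default guessed from the extension.
#' @return a `metabolic_model`.
#' @export
read_model <- function(path, format = c("guess", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "guess") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  }
  if (!file.exists(path)) stop("no such file: ", path)
  switch(format, json = read_model_json(path), sbml = read_model_sbml(path))
}

read_model_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$reactions) || is.null(doc$metabolites))
    stop("JSON model parse failure: missing 'reactions' or 'metabolites' element")
  met_ids <- vapply(doc$metabolites, function(m) m$id, "")
  rxn_ids <- vapply(doc$reactions, function(r) r$id, "")
  S <- matrix(0, length(met_ids), length(rxn_ids),
              dimnames = list(met_ids, rxn_ids))
  lb <- ub <- numeric(length(rxn_ids))
  objective <- numeric(0)
  for (k in seq_along(doc$reactions)) {
    r <- doc$reactions[[k]]
    coefs <- unlist(r$metabolites)
    if (length(coefs) == 0 || all(coefs == 0))
      stop("JSON model validation error: reaction '", r$id,
           "' has empty or all-zero stoichiometry")
    bad <- setdiff(names(coefs), met_ids)
    if (length(bad))
      stop("JSON model parse failure: reaction '", r$id,
           "' references unknown metabolite(s): ", paste(bad, collapse = ", "))
    S[names(coefs), k] <- coefs
    lb[k] <- if (is.null(r$lower_bound)) -1000 else r$lower_bound
    ub[k] <- if (is.null(r$upper_bound)) 1000 else r$upper_bound
    oc <- r$objective_coefficient
    if (!is.null(oc) && oc != 0) objective[r$id] <- oc
  }
  if (length(objective) == 0) objective <- stats::setNames(numeric(0), character(0))
  ann <- if (!is.null(doc$id)) list(model_id = doc$id) else list()
  metabolic_model(S, lb, ub, objective, annotations = ann)
}

#' Write a metabolic model to file
#'
#' @param model a `metabolic_model`.
#' @param path output path.
#' @param format `"json"` or `"sbml"`.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = c("json", "sbml")) {
  format <- match.arg(format)
  if (format == "json") write_model_json(model, path) else write_model_sbml(model, path)
  invisible(path)
}

write_model_json <- function(model, path) {
  mets <- lapply(model$metabolite_ids, function(id) list(id = id))
  rxns <- lapply(seq_along(model$reaction_ids), function(k) {
    id <- model$reaction_ids[k]
    coefs <- model$S[, k]
    coefs <- coefs[coefs != 0]
    out <- list(id = id,
                metabolites = as.list(coefs),
                lower_bound = unname(model$lower_bound[k]),
                upper_bound = unname(model$upper_bound[k]))
    if (id %in% names(model$objective))
      out$objective_coefficient <- unname(model$objective[[id]])
    out
  })
  doc <- list(id = model$annotations$model_id %||% "model",
              metabolites = mets, reactions = rxns, genes = list())
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sbml_sid <- function(x) {
  # SBML SIds must match [A-Za-z_][A-Za-z0-9_]*
  x <- gsub("[^A-Za-z0-9_]", "__", x)
  ifelse(grepl("^[A-Za-z_]", x), x, paste0("_", x))
}

read_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")
  species <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  if (length(species) == 0) stop("SBML parse failure: no species found")
  met_ids <- xml2::xml_attr(species, "id")
  params <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))
  rxns <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  if (length(rxns) == 0) stop("SBML parse failure: no reactions found")
  rxn_ids <- xml2::xml_attr(rxns, "id")
  S <- matrix(0, length(met_ids), length(rxn_ids),
              dimnames = list(met_ids, rxn_ids))
  lb <- ub <- numeric(length(rxn_ids))
  for (k in seq_along(rxns)) {
    r <- rxns[[k]]
    for (sr in xml2::xml_find_all(r, "./s:listOfReactants/s:speciesReference", ns)) {
      sp <- xml2::xml_attr(sr, "species")
      S[sp, k] <- S[sp, k] - as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    for (sr in xml2::xml_find_all(r, "./s:listOfProducts/s:speciesReference", ns)) {
      sp <- xml2::xml_attr(sr, "species")
      S[sp, k] <- S[sp, k] + as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    if (all(S[, k] == 0))
      stop("SBML validation error: reaction '", rxn_ids[k],
           "' has empty or all-zero stoichiometry")
    lbid <- xml2::xml_attr(r, "fbc:lowerFluxBound", ns)
    ubid <- xml2::xml_attr(r, "fbc:upperFluxBound", ns)
    lb[k] <- if (!is.na(lbid)) pval[[lbid]] else -1000
    ub[k] <- if (!is.na(ubid)) pval[[ubid]] else 1000
  }
  objective <- numeric(0)
  fobj <- xml2::xml_find_all(doc, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective", ns)
  for (fo in fobj) {
    objective[xml2::xml_attr(fo, "fbc:reaction", ns)] <-
      as.numeric(xml2::xml_attr(fo, "fbc:coefficient", ns))
  }
  metabolic_model(S, lb, ub, objective)
}

write_model_sbml <- function(model, path) {
  rid <- sbml_sid(model$reaction_ids)
  mid <- sbml_sid(model$metabolite_ids)
  esc <- function(x) x # ids already sanitised
  con <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" level="3" version="1" fbc:required="false">',
    '<model id="model" fbc:strict="true">',
    '<listOfCompartments><compartment id="c" constant="true"/></listOfCompartments>',
    '<listOfSpecies>',
    sprintf('<species id="%s" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>', esc(mid)),
    '</listOfSpecies>',
    '<listOfParameters>',
    sprintf('<parameter id="lb_%s" value="%.17g" constant="true"/>', esc(rid), model$lower_bound),
    sprintf('<parameter id="ub_%s" value="%.17g" constant="true"/>', esc(rid), model$upper_bound),
    '</listOfParameters>'
  )
  rxn_xml <- vapply(seq_along(rid), function(k) {
    coefs <- model$S[, k]
    reac <- which(coefs < 0); prod <- which(coefs > 0)
    body <- character(0)
    if (length(reac))
      body <- c(body, "<listOfReactants>",
                sprintf('<speciesReference species="%s" stoichiometry="%.17g" constant="true"/>',
                        mid[reac], -coefs[reac]),
                "</listOfReactants>")
    if (length(prod))
      body <- c(body, "<listOfProducts>",
                sprintf('<speciesReference species="%s" stoichiometry="%.17g" constant="true"/>',
                        mid[prod], coefs[prod]),
                "</listOfProducts>")
    paste0(sprintf('<reaction id="%s" reversible="%s" fast="false" fbc:lowerFluxBound="lb_%s" fbc:upperFluxBound="ub_%s">',
                   rid[k], tolower(model$lower_bound[k] < 0), rid[k], rid[k]),
           paste(body, collapse = ""), "</reaction>")
  }, "")
  obj_idx <- match(names(model$objective), model$reaction_ids)
  con <- c(con, "<listOfReactions>", rxn_xml, "</listOfReactions>",
           '<fbc:listOfObjectives fbc:activeObjective="obj">',
           '<fbc:objective fbc:id="obj" fbc:type="maximize">',
           "<fbc:listOfFluxObjectives>",
           sprintf('<fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="%.17g"/>',
                   rid[obj_idx], unlist(model$objective)),
           "</fbc:listOfFluxObjectives>", "</fbc:objective>",
           "</fbc:listOfObjectives>", "</model>", "</sbml>")
  writeLines(con, path)
}

#' Flux balance analysis
#'
#' Maximises (or minimises) the model objective `c'v` subject to steady-state
#' mass balance `S v = 0` and the flux bounds.
#'
#' @param model a `metabolic_model` with a nonempty objective.
#' @param sense `"max"` (default) or `"min"`.
#' @return a `flux_distribution`: list with `values` (named fluxes),
#'   `objective_value` and `status`.
#' @export
solve_fba <- function(model, sense = c("max", "min")) {
  sense <- match.arg(sense)
  if (length(model$objective) == 0) stop("model has an empty objective")
  obj <- numeric(length(model$reaction_ids))
  names(obj) <- model$reaction_ids
  obj[names(model$objective)] <- unlist(model$objective)
  res <- solve_lp(obj, model$S, rep(0, nrow(model$S)),
                  model$lower_bound, model$upper_bound,
                  maximize = (sense == "max"))
  flux_distribution(model, res)
}

flux_distribution <- function(model, res) {
  structure(list(
    values = stats::setNames(res$x, model$reaction_ids),
    objective_value = res$objective,
    status = res$status
  ), class = "flux_distribution")
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat("flux_distribution: status =", x$status,
      " objective =", format(x$objective_value), "\n")
  invisible(x)
}

#' Parsimonious flux balance analysis
#'
#' Two-stage LP: first the FBA optimum is computed, then, with the objective
#' flux fixed at that optimum (within a small slack), the total absolute flux
#' `sum(|v|)` is minimised by variable splitting.
#'
#' @param model a `metabolic_model`.
#' @param slack numeric slack on the fixed optimum (default `1e-9`).
#' @return a `flux_distribution`; the attribute `"total_flux"` carries
#'   `sum(|v|)`.
#' @export
solve_pfba <- function(model, slack = 1e-9) {
  fba <- solve_fba(model)
  if (fba$status != "optimal") return(fba)
  n <- length(model$reaction_ids)
  obj_row <- numeric(n)
  obj_row[match(names(model$objective), model$reaction_ids)] <- unlist(model$objective)
  # v = p - q, p,q >= 0; min sum(p+q) s.t. S(p-q)=0, c'(p-q) = opt - slack
  S2 <- cbind(model$S, -model$S)
  A <- rbind(S2, c(obj_row, -obj_row))
  b <- c(rep(0, nrow(model$S)), fba$objective_value - slack)
  lb2 <- c(pmax(model$lower_bound, 0), pmax(-model$upper_bound, 0))
  ub2 <- c(pmax(model$upper_bound, 0), pmax(-model$lower_bound, 0))
  res <- solve_lp(rep(1, 2 * n), A, b, lb2, ub2, maximize = FALSE)
  if (res$status != "optimal")
    stop("pFBA stage-2 LP returned status ", res$status)
  v <- res$x[seq_len(n)] - res$x[n + seq_len(n)]
  out <- flux_distribution(model, list(x = v, objective = sum(obj_row * v),
                                       status = "optimal"))
  attr(out, "total_flux") <- sum(abs(v))
  out
}

with_bounds <- function(model, rxn, lb = NULL, ub = NULL) {
  if (!all(rxn %in% model$reaction_ids)) {
    stop("unknown reaction id(s): ",
         paste(setdiff(rxn, model$reaction_ids), collapse = ", "))
  }
  if (!is.null(lb)) model$lower_bound[rxn] <- lb
  if (!is.null(ub)) model$upper_bound[rxn] <- ub
  model
}

#' Production envelope
#'
#' Discretises the achievable flux range of a target reaction into
#' `n_points` equally spaced values; at each value the target flux is fixed
#' and growth is minimised and maximised.
#'
#' @param model a `metabolic_model`.
#' @param target reaction id whose flux spans the envelope.
#' @param n_points number of grid points (>= 2).
#' @return a data frame of class `production_envelope` with columns
#'   `target_flux`, `growth_min`, `growth_max` (NA at infeasible interior
#'   points).
#' @export
production_envelope <- function(model, target, n_points = 20) {
  stopifnot(n_points >= 2)
  if (!target %in% model$reaction_ids) stop("unknown target reaction: ", target)
  tmod <- model
  tmod$objective <- stats::setNames(1, target)
  pmin_ <- solve_fba(tmod, "min")
  pmax_ <- solve_fba(tmod, "max")
  if (pmin_$status != "optimal" || pmax_$status != "optimal")
    stop("target flux range infeasible: min status ", pmin_$status,
         ", max status ", pmax_$status)
  grid <- seq(pmin_$objective_value, pmax_$objective_value, length.out = n_points)
  rows <- lapply(grid, function(p) {
    fixed <- with_bounds(model, target, lb = p, ub = p)
    lo <- solve_fba(fixed, "min")
    hi <- solve_fba(fixed, "max")
    data.frame(target_flux = p,
               growth_min = if (lo$status == "optimal") lo$objective_value else NA_real_,
               growth_max = if (hi$status == "optimal") hi$objective_value else NA_real_)
  })
  out <- do.call(rbind, rows)
  attr(out, "target") <- target
  class(out) <- c("production_envelope", class(out))
  out
}

#' Write a production envelope as TSV
#'
#' @param envelope result of [production_envelope()].
#' @param path output path.
#' @export
write_envelope <- function(envelope, path) {
  utils::write.table(as.data.frame(envelope), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Apply a growth condition to a model
#'
#' Bounds carbon uptake (uptake is a negative exchange flux, so the exchange
#' lower bound is set to `-uptake_bound`), closes oxygen uptake for the
#' anaerobic scenario, and sets the non-growth-associated maintenance lower
#' bound (6.86 mmol/gDW/h by convention, inherited from the parent
#' genome-scale model).
#'
#' @param model a `metabolic_model`.
#' @param carbon_exchange exchange reaction id of the carbon source.
#' @param uptake_bound maximal uptake in mmol/gDW/h (default 10).
#' @param aerobic logical; `FALSE` closes the oxygen exchange.
#' @param maintenance_bound lower bound on the maintenance reaction
#'   (mmol/gDW/h).
#' @param oxygen_exchange,maintenance_reaction reaction ids (may be `NULL`
#'   if the model has no such reaction).
#' @return a modified copy of `model`.
#' @export
set_condition <- function(model, carbon_exchange, uptake_bound = 10,
                          aerobic = TRUE, maintenance_bound = 6.86,
                          oxygen_exchange = "EX_o2_e",
                          maintenance_reaction = "ATPM") {
  model <- with_bounds(model, carbon_exchange, lb = -uptake_bound)
  if (!is.null(oxygen_exchange) && oxygen_exchange %in% model$reaction_ids) {
    if (!aerobic) {
      model <- with_bounds(model, oxygen_exchange, lb = 0)
    }
  } else if (!aerobic && !is.null(oxygen_exchange)) {
    stop("unknown oxygen exchange reaction: ", oxygen_exchange)
  }
  if (!is.null(maintenance_reaction) &&
      maintenance_reaction %in% model$reaction_ids) {
    model <- with_bounds(model, maintenance_reaction, lb = maintenance_bound)
  }
  model
}

#' Lump a subnetwork into an equivalent biomass reaction
#'
#' Given an extended model, a reference flux distribution on it, and a set of
#' retained metabolites, returns a single reaction whose stoichiometry is the
#' net consumption/production of each retained metabolite by the lumped
#' subnetwork (the biomass reaction plus every reaction touching a
#' non-retained metabolite) at the reference flux, scaled to unit biomass
#' flux.
#'
#' @param extended_model a `metabolic_model`.
#' @param reference_flux a `flux_distribution`, optimal on `extended_model`.
#' @param retained_metabolites character vector of metabolite ids to keep.
#' @param biomass reaction id of the biomass reaction (default: first
#'   objective reaction).
#' @param tol mass-balance tolerance.
#' @return named numeric vector: stoichiometric coefficients of the lumped
#'   reaction over the retained metabolites (zero entries dropped), with
#'   attribute `"lumped_reactions"`.
#' @export
lump_equivalent_biomass <- function(extended_model, reference_flux,
                                    retained_metabolites,
                                    biomass = names(extended_model$objective)[1],
                                    tol = 1e-6) {
  stopifnot(all(retained_metabolites %in% extended_model$metabolite_ids))
  v <- reference_flux$values[extended_model$reaction_ids]
  if (max(abs(extended_model$S %*% v)) > tol)
    stop("reference flux violates mass balance")
  v_bm <- v[[biomass]]
  if (abs(v_bm) < tol)
    stop("biomass flux is zero in the reference distribution; cannot scale")
  dropped <- setdiff(extended_model$metabolite_ids, retained_metabolites)
  touches_dropped <- colSums(extended_model$S[dropped, , drop = FALSE] != 0) > 0
  lumped <- extended_model$reaction_ids[touches_dropped]
  lumped <- union(lumped, biomass)
  coef <- as.vector(extended_model$S[retained_metabolites, lumped, drop = FALSE] %*%
                      v[lumped]) / v_bm
  names(coef) <- retained_metabolites
  coef <- coef[abs(coef) > 1e-12]
  attr(coef, "lumped_reactions") <- lumped
  coef
}
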