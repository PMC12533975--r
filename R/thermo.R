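R_GAS_KJ <- 8.314e-3   # kJ/mol/K
T_DEFAULT <- 310.15    # K

#' Factor a covariance matrix into a rectangular square root
#'
#' Eigendecomposition-based factor `Q` with `Q %*% t(Q)` reconstructing the
#' covariance; eigenvalues below `1e-9 * lambda_max` are treated as zero, so
#' `ncol(Q)` is the numerical rank. A significantly negative eigenvalue
#' (below `-1e-6 * lambda_max`) is an error.
#'
#' @param covariance symmetric positive semidefinite matrix.
#' @return list with `Q` (N x q) and `q` (rank).
#' @export
factor_covariance <- function(covariance) {
  covariance <- as.matrix(covariance)
  if (max(abs(covariance - t(covariance))) > 1e-8)
    stop("covariance matrix is not symmetric")
  if (all(covariance == 0))
    return(list(Q = matrix(0, nrow(covariance), 0), q = 0L))
  eg <- eigen((covariance + t(covariance)) / 2, symmetric = TRUE)
  lmax <- max(eg$values)
  if (any(eg$values < -1e-6 * lmax))
    stop("covariance matrix is not positive semidefinite")
  keep <- eg$values > 1e-9 * lmax
  q <- sum(keep)
  Q <- eg$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(eg$values[keep]), q)
  list(Q = Q, q = as.integer(q))
}

#' Thermodynamic parameter set
#'
#' Mean standard transformed reaction Gibbs energies with a covariance
#' matrix describing (possibly correlated) estimation uncertainty. Only
#' balanced metabolic reactions belong here; exchanges and pseudoreactions
#' are excluded by construction of the input.
#'
#' @param reaction_index ordered character vector of reaction ids.
#' @param mean mean dGr'0 vector (kJ/mol), same length.
#' @param covariance covariance matrix (kJ^2/mol^2).
#' @return object of class `thermo_parameter_set` with `Q` and rank `q`.
#' @export
thermo_parameter_set <- function(reaction_index, mean, covariance) {
  stopifnot(length(reaction_index) == length(mean),
            nrow(covariance) == length(mean),
            ncol(covariance) == length(mean))
  f <- factor_covariance(covariance)
  structure(list(reaction_index = reaction_index,
                 mean = stats::setNames(as.numeric(mean), reaction_index),
                 covariance = as.matrix(covariance),
                 Q = f$Q, q = f$q),
            class = "thermo_parameter_set")
}

#' @export
print.thermo_parameter_set <- function(x, ...) {
  cat("thermo_parameter_set:", length(x$reaction_index),
      "reactions, covariance rank", x$q, "\n")
  invisible(x)
}

#' Probabilistic max-min driving force
#'
#' Maximises the minimum driving force `b` over realised standard Gibbs
#' energies within the `alpha`-level confidence region of the (correlated)
#' estimate and over log metabolite concentrations within bounds:
#' maximise `b` subject to
#' `dGr'0 = mean + Q m`, `dGr' = dGr'0 + RT S' c`,
#' `-sign(v_i) dGr'_i >= b` for every nonzero-flux reaction covered by the
#' parameter set, `||m||^2 <= chi2(q, alpha)` and
#' `ln(cmin) <= c <= ln(cmax)`. The single ball constraint is handled by
#' cutting planes on top of the package LP solver, which converges to the
#' QCP optimum.
#'
#' @param model a `metabolic_model`.
#' @param flux a `flux_distribution` whose signs define reaction
#'   directions.
#' @param params a `thermo_parameter_set`.
#' @param alpha confidence level (default 0.9).
#' @param conc_bounds either `c(min, max)` molar bounds for all metabolites
#'   (default `c(1e-6, 1e-2)`, i.e. 1 uM to 10 mM) or a 2-column matrix with
#'   metabolite row names for per-metabolite overrides.
#' @param temperature Kelvin (default 310.15).
#' @param flux_tol relative threshold deciding which fluxes are nonzero.
#' @return object of class `thermodynamic_state`: `b` (the MDF, kJ/mol),
#'   `log_concentration`, `m`, `drG_prime` (all covered reactions),
#'   `drG0_realised`, `alpha`, `status`, `active_reactions`.
#' @export
solve_probabilistic_mdf <- function(model, flux, params, alpha = 0.9,
                                    conc_bounds = c(1e-6, 1e-2),
                                    temperature = T_DEFAULT,
                                    flux_tol = 1e-9) {
  RT <- R_GAS_KJ * temperature
  v <- flux$values
  vmax <- max(abs(v), 1e-12)
  active <- names(v)[abs(v) > flux_tol * vmax]
  uncovered <- setdiff(intersect(active, model$reaction_ids[
    !model$reaction_ids %in% exchange_reactions(model)]),
    params$reaction_index)
  covered_active <- intersect(active, params$reaction_index)
  if (length(uncovered))
    warning("nonzero-flux reaction(s) without thermodynamic parameters ",
            "exempted from driving-force constraints: ",
            paste(uncovered, collapse = ", "))
  if (length(covered_active) == 0)
    stop("no active reaction is covered by the thermodynamic parameter set")

  mets <- model$metabolite_ids[
    rowSums(model$S[, params$reaction_index, drop = FALSE] != 0) > 0]
  nm <- length(mets)
  if (is.matrix(conc_bounds)) {
    cmin <- log(conc_bounds[mets, 1]); cmax <- log(conc_bounds[mets, 2])
  } else {
    cmin <- rep(log(conc_bounds[1]), nm); cmax <- rep(log(conc_bounds[2]), nm)
  }
  q <- params$q
  r2 <- if (q > 0) stats::qchisq(alpha, df = q) else 0
  r <- sqrt(r2)

  # variables: m (q), c (nm), b (1), slacks (one per driving-force row,
  # then one per added cut)
  sgn <- sign(v[covered_active])
  idx <- match(covered_active, params$reaction_index)
  Qa <- if (q > 0) params$Q[idx, , drop = FALSE] else matrix(0, length(idx), 0)
  Sa <- t(model$S[mets, covered_active, drop = FALSE])   # reactions x mets
  nr <- length(covered_active)
  # -sgn*(mean + Qa m + RT Sa c) - b - slack = sgn*... rearranged:
  # (-sgn*Qa) m + (-sgn*RT*Sa) c - b - slack = sgn * mean
  A0 <- cbind(-sgn * Qa, -sgn * RT * Sa, -1, -diag(nr))
  b0 <- sgn * params$mean[covered_active]
  lb <- c(rep(-r, q), cmin, -Inf, rep(0, nr))
  ub <- c(rep(r, q), cmax, Inf, rep(Inf, nr))
  obj <- c(rep(0, q + nm), 1, rep(0, nr))
  A <- A0; bb <- b0

  sol <- NULL
  for (iter in seq_len(200)) {
    res <- solve_lp(obj, A, bb, lb, ub, maximize = TRUE)
    if (res$status != "optimal") {
      return(structure(list(b = NA_real_, status = res$status,
                            active_reactions = covered_active,
                            alpha = alpha),
                       class = "thermodynamic_state"))
    }
    sol <- res
    if (q == 0) break
    m <- res$x[seq_len(q)]
    nrm <- sqrt(sum(m^2))
    if (nrm <= r + 1e-9) break
    # supporting hyperplane of the ball at m/||m||: u'm <= r
    u <- m / nrm
    A <- rbind(cbind(A, 0), c(u, rep(0, nm), 0, rep(0, ncol(A) - q - nm - 1), 1))
    bb <- c(bb, r)
    lb <- c(lb, 0); ub <- c(ub, Inf)
    obj <- c(obj, 0)
  }
  m <- if (q > 0) sol$x[seq_len(q)] else numeric(0)
  cc <- sol$x[q + seq_len(nm)]
  names(cc) <- mets
  bopt <- unname(sol$x[q + nm + 1])
  drg0 <- params$mean + if (q > 0) as.vector(params$Q %*% m) else 0
  drg <- drg0 + RT * as.vector(t(model$S[mets, params$reaction_index,
                                         drop = FALSE]) %*% cc)
  names(drg) <- params$reaction_index
  structure(list(b = bopt, log_concentration = cc, m = m,
                 drG_prime = drg, drG0_realised = drg0, alpha = alpha,
                 status = "optimal", active_reactions = covered_active,
                 temperature = temperature),
            class = "thermodynamic_state")
}

#' @export
print.thermodynamic_state <- function(x, ...) {
  cat("thermodynamic_state: status =", x$status,
      " MDF b =", format(x$b), "kJ/mol at alpha =", x$alpha, "\n")
  invisible(x)
}

#' Flux-force efficacy
#'
#' `eta = tanh(-dGr' / (2 RT))`, the ratio of net to total flux of a
#' reaction; `eta = 0.5` corresponds to `dGr' ~ -1.1 RT` (about -2.8 kJ/mol
#' at 310.15 K).
#'
#' @param drG_prime reaction Gibbs energy (kJ/mol); vectorised.
#' @param temperature Kelvin.
#' @return efficacy in (-1, 1).
#' @export
flux_force_efficacy <- function(drG_prime, temperature = T_DEFAULT) {
  if (any(temperature <= 0)) stop("temperature must be positive")
  tanh(-drG_prime / (2 * R_GAS_KJ * temperature))
}

#' Split high-flux reactions into low/high flux-force efficacy groups
#'
#' Selects reactions carrying at least `flux_fraction` of the reference
#' uptake flux (default 2.5%), optionally excluding transport/spontaneous
#' reactions, and pools them by efficacy relative to `eta_threshold`
#' (default 0.5).
#'
#' @param state a `thermodynamic_state` (supplies `drG_prime`).
#' @param flux a `flux_distribution`.
#' @param reference_uptake reaction id of the reference (substrate uptake)
#'   flux; must be nonzero.
#' @param flux_fraction minimum |flux| as a fraction of the reference.
#' @param eta_threshold efficacy split point.
#' @param exclude reaction ids excluded from grouping.
#' @param temperature Kelvin.
#' @return list with `low` and `high` character vectors and `eta` (named
#'   efficacies of the selected reactions).
#' @export
group_by_efficacy <- function(state, flux, reference_uptake,
                              flux_fraction = 0.025, eta_threshold = 0.5,
                              exclude = character(0),
                              temperature = T_DEFAULT) {
  vref <- abs(flux$values[[reference_uptake]])
  if (vref == 0) stop("reference uptake flux is zero")
  cand <- setdiff(names(state$drG_prime), exclude)
  vc <- abs(flux$values[cand])
  cand <- cand[vc >= flux_fraction * vref & vc > 0]
  eta <- flux_force_efficacy(state$drG_prime[cand], temperature)
  list(low = cand[eta < eta_threshold],
       high = cand[eta >= eta_threshold],
       eta = eta)
}

#' Read / write thermodynamic parameters as TSV
#'
#' `path` holds columns `reaction`, `drG0_prime_kJ_mol`; `cov_path` a dense
#' covariance matrix with matching header.
#'
#' @param path TSV of means.
#' @param cov_path TSV of the covariance matrix (row/col order as `path`).
#' @return a `thermo_parameter_set`.
#' @export
read_thermo_params <- function(path, cov_path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  S <- as.matrix(utils::read.delim(cov_path, row.names = 1))
  thermo_parameter_set(d$reaction, d$drG0_prime_kJ_mol,
                       S[d$reaction, d$reaction])
}

#' @rdname read_thermo_params
#' @param params a `thermo_parameter_set`.
#' @export
write_thermo_params <- function(params, path, cov_path) {
  utils::write.table(
    data.frame(reaction = params$reaction_index,
               drG0_prime_kJ_mol = unname(params$mean)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  cov <- params$covariance
  dimnames(cov) <- list(params$reaction_index, params$reaction_index)
  utils::write.table(cov, cov_path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}
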