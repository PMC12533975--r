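#' Reference flux distributions for turnover-number fitting
#'
#' For each condition the measured growth rate is fixed and the total enzyme
#' cost is minimised on the enzyme-constrained model parameterised with the
#' original (unadjusted) turnover numbers. Infeasible conditions are excluded
#' with a warning reporting the maximum feasible growth.
#'
#' @param ec an `ec_model` built with the original turnover numbers.
#' @param conditions named list; each element a list with `growth` (1/h) and
#'   optionally arguments for [ec_set_condition()] (`carbon_exchange`,
#'   `uptake_bound`, `aerobic`, ...).
#' @return named list of `flux_distribution`s on the split model.
#' @export
compute_reference_fluxes <- function(ec, conditions) {
  out <- list()
  for (cn in names(conditions)) {
    spec_c <- conditions[[cn]]
    ecc <- ec
    cond_args <- spec_c[setdiff(names(spec_c), "growth")]
    if (length(cond_args) > 0)
      ecc <- do.call(ec_set_condition, c(list(ecc), cond_args))
    sol <- tryCatch(predict_allocation(ecc, spec_c$growth), error = identity)
    if (inherits(sol, "error")) {
      warning("condition '", cn, "' excluded: ", conditionMessage(sol))
      next
    }
    out[[cn]] <- sol$flux
  }
  out
}

#' Define a turnover-adjustment problem
#'
#' @param ec `ec_model` built with the original turnover numbers at
#'   `sigma = 1`.
#' @param reference_flux named list of `flux_distribution`s (one per
#'   condition) from [compute_reference_fluxes()].
#' @param measured_abundance data frame with columns `condition`, `enzyme`,
#'   `abundance` (g/gDW).
#' @param u_bounds log10 adjustment bounds, default `c(-2, 2)` (at most a
#'   100-fold change in either direction).
#' @param rho ridge regularisation weight (default 1).
#' @return object of class `fit_problem`.
#' @export
fit_problem <- function(ec, reference_flux, measured_abundance,
                        u_bounds = c(-2, 2), rho = 1) {
  stopifnot(u_bounds[1] <= 0, u_bounds[2] >= 0, rho >= 0)
  stopifnot(all(c("condition", "enzyme", "abundance") %in%
                  names(measured_abundance)))
  measured_abundance <- measured_abundance[
    measured_abundance$condition %in% names(reference_flux), , drop = FALSE]
  n_zero <- sum(measured_abundance$abundance <= 0)
  if (n_zero > 0) {
    message(n_zero, " zero measured abundances dropped from the loss")
    measured_abundance <- measured_abundance[measured_abundance$abundance > 0, ,
                                             drop = FALSE]
  }
  structure(list(ec = ec, reference_flux = reference_flux,
                 measured = measured_abundance,
                 u_bounds = u_bounds, rho = rho),
            class = "fit_problem")
}

# design tables: per (condition, enzyme) datum, the split reactions feeding
# it with weights w = a_i * v_i^ref (sigma = 1, u = 0)
fit_design <- function(problem) {
  ec <- problem$ec
  conds <- names(problem$reference_flux)
  keep <- !is.na(ec$enzyme_of) & ec$cost > 0
  rxn_split <- names(ec$cost)[keep]
  base_of <- vapply(rxn_split, function(nm) {
    for (id in names(ec$split_map)) if (nm %in% ec$split_map[[id]]) return(id)
    NA_character_
  }, "")
  enz_of <- ec$enzyme_of[keep]
  data_rows <- list()
  support <- character(0)
  for (cn in conds) {
    v <- problem$reference_flux[[cn]]$values
    w <- ec$cost[keep] * ec$sigma * v[rxn_split]   # cost at sigma = 1
    active <- w > 0
    support <- union(support, base_of[active])
    meas <- problem$measured[problem$measured$condition == cn, , drop = FALSE]
    for (r in seq_len(nrow(meas))) {
      en <- meas$enzyme[r]
      sel <- which(enz_of == en & active)
      if (length(sel) == 0) next                   # zero predicted: dropped
      data_rows[[length(data_rows) + 1]] <- list(
        condition = cn, enzyme = en, w = w[sel], base = base_of[sel],
        y = log10(meas$abundance[r]))
    }
  }
  list(rows = data_rows, support = sort(support), conditions = conds)
}

#' Adjust turnover numbers against measured enzyme abundances
#'
#' Minimises, over per-reaction log10 adjustments `u` (within `u_bounds`) and
#' per-condition scalings `sigma_c`, the loss
#' `sum_(c,i) (log10 e_hat - log10 e_meas)^2 + rho * ||u||^2`, where
#' `e_hat(i,c) = sum_j a_j 10^(-u_j) v_jc^ref / sigma_c` over the split
#' reactions `j` of enzyme `i`, with the reference fluxes held fixed.
#' Turnover numbers of reactions with zero flux in every reference
#' distribution cannot be adjusted and keep `u = 0`.
#'
#' @param problem a `fit_problem`.
#' @return object of class `fit_result`: `u` (named, all base reactions),
#'   `condition_scaling` (`sigma_c`), `adjusted_kcat_factor` (`10^u`),
#'   `objective`, `rmse` per condition (log10), `convergence`.
#' @export
adjust_turnover_numbers <- function(problem) {
  des <- fit_design(problem)
  if (length(des$rows) == 0)
    stop("no overlap between measured enzymes and the reference flux support")
  u_ids <- des$support
  conds <- des$conditions
  nu <- length(u_ids); nc <- length(conds)
  rho <- problem$rho

  affine <- all(vapply(des$rows, function(r) length(unique(r$base)) == 1, TRUE))
  if (affine) {
    # each datum reads log10(sum w) - u_b - s_c = y: an exact
    # box-constrained ridge least-squares problem, solved as a QP
    N <- length(des$rows)
    X <- matrix(0, N, nu + nc)
    t0 <- numeric(N)
    for (i in seq_len(N)) {
      row <- des$rows[[i]]
      X[i, match(row$base[1], u_ids)] <- 1
      X[i, nu + match(row$condition, conds)] <- 1
      t0[i] <- log10(sum(row$w)) - row$y
    }
    # minimise ||t0 - X z||^2 + rho ||u||^2 with z = (u, s); the ridge on u
    # makes H positive definite whenever every condition has data and the
    # enzyme-condition incidence graph is connected
    H <- crossprod(X) + diag(c(rep(rho, nu), rep(0, nc)), nu + nc)
    d <- crossprod(X, t0)
    Amat <- cbind(rbind(diag(nu), matrix(0, nc, nu)),
                  rbind(-diag(nu), matrix(0, nc, nu)))
    bvec <- c(rep(problem$u_bounds[1], nu), rep(-problem$u_bounds[2], nu))
    qp <- tryCatch(quadprog::solve.QP(H, d, Amat, bvec),
                   error = function(e) quadprog::solve.QP(
                     H + diag(1e-10 * max(diag(H)), nu + nc), d, Amat, bvec))
    z <- qp$solution
    opt <- list(par = z, value = sum((t0 - X %*% z)^2) +
                  rho * sum(z[seq_len(nu)]^2), convergence = 0L)
  } else {
    opt <- fit_smooth(problem, des, u_ids, conds, nu, nc, rho)
  }

  u_fit <- stats::setNames(opt$par[seq_len(nu)], u_ids)
  s_fit <- stats::setNames(opt$par[nu + seq_len(nc)], conds)
  all_base <- names(problem$ec$split_map)
  u_all <- stats::setNames(rep(0, length(all_base)), all_base)
  u_all[u_ids] <- u_fit

  # per-condition RMSE at the optimum
  rmse <- stats::setNames(rep(NA_real_, nc), conds)
  for (cn in conds) {
    res2 <- vapply(Filter(function(r) r$condition == cn, des$rows), function(row) {
      tot <- sum(row$w * 10^(-u_all[row$base]))
      (log10(tot) - s_fit[[cn]] - row$y)^2
    }, 0)
    if (length(res2)) rmse[cn] <- sqrt(mean(res2))
  }
  structure(list(u = u_all, support = u_ids,
                 condition_scaling = 10^s_fit,
                 adjusted_kcat_factor = 10^u_all,
                 objective = opt$value, rmse = rmse,
                 convergence = opt$convergence),
            class = "fit_result")
}

# smooth fallback when an enzyme pools several base reactions: the loss is
# no longer affine in u, so minimise it directly with analytic gradients
fit_smooth <- function(problem, des, u_ids, conds, nu, nc, rho) {
  fg <- function(par) {
    u <- par[seq_len(nu)]; s <- par[nu + seq_len(nc)]
    names(u) <- u_ids; names(s) <- conds
    loss <- rho * sum(u^2)
    gu <- 2 * rho * u; gs <- stats::setNames(rep(0, nc), conds)
    for (row in des$rows) {
      uu <- u[row$base]
      terms <- row$w * 10^(-uu)
      tot <- sum(terms)
      res <- log10(tot) - s[[row$condition]] - row$y
      loss <- loss + res^2
      # d log10(tot) / d u_b = -(sum of terms with base b) / tot
      gcontrib <- -2 * res * terms / tot
      for (k in seq_along(row$base))
        gu[row$base[k]] <- gu[row$base[k]] + gcontrib[k]
      gs[[row$condition]] <- gs[[row$condition]] - 2 * res
    }
    list(value = loss, grad = c(gu, gs))
  }

  opt <- stats::optim(
    par = rep(0, nu + nc),
    fn = function(p) fg(p)$value,
    gr = function(p) fg(p)$grad,
    method = "L-BFGS-B",
    lower = c(rep(problem$u_bounds[1], nu), rep(-20, nc)),
    upper = c(rep(problem$u_bounds[2], nu), rep(20, nc)),
    control = list(maxit = 10000, factr = 1, pgtol = 1e-12))
  opt
}

#' @export
print.fit_result <- function(x, ...) {
  cat("fit_result: ", length(x$support), "adjusted reactions; objective =",
      format(x$objective), "\n")
  cat("  sigma_c:", paste(sprintf("%s=%.3g", names(x$condition_scaling),
                                  x$condition_scaling), collapse = ", "), "\n")
  invisible(x)
}

#' Apply a fitted adjustment to a turnover set
#'
#' @param turnovers a `turnover_set`.
#' @param fit a `fit_result`.
#' @return a `turnover_set` with `kcat_s * 10^u` and provenance `adjusted`
#'   where `u != 0`.
#' @export
apply_adjustment <- function(turnovers, fit) {
  u <- fit$u[turnovers$reaction]
  u[is.na(u)] <- 0
  turnovers$kcat_s <- turnovers$kcat_s * 10^u
  turnovers$provenance[u != 0] <- "adjusted"
  turnovers
}

# predicted per-enzyme abundances for one condition at sigma_c = 1
predict_from_reference <- function(ec, flux, u) {
  keep <- !is.na(ec$enzyme_of) & ec$cost > 0
  rxn_split <- names(ec$cost)[keep]
  base_of <- vapply(rxn_split, function(nm) {
    for (id in names(ec$split_map)) if (nm %in% ec$split_map[[id]]) return(id)
    NA_character_
  }, "")
  w <- ec$cost[keep] * ec$sigma * flux$values[rxn_split] * 10^(-u[base_of])
  ab <- tapply(w, ec$enzyme_of[keep], sum)
  stats::setNames(as.numeric(ab), names(ab))
}

#' Leave-one-out cross-validation of the turnover adjustment
#'
#' Each condition is held out in turn, the adjustment is fitted on the
#' remaining conditions, abundances for the held-out condition are predicted
#' with the fitted turnover numbers (its scaling obtained by matching totals
#' as in [fit_saturation()]), and the held-out log10 RMSE is reported
#' (zero-prediction enzymes excluded).
#'
#' @param problem a `fit_problem` with at least two conditions.
#' @return data frame with columns `condition`, `rmse_heldout`, `n_used`.
#' @export
cross_validate_loo <- function(problem) {
  conds <- names(problem$reference_flux)
  if (length(conds) < 2) stop("leave-one-out requires at least 2 conditions")
  rows <- lapply(conds, function(cn) {
    train <- problem
    train$measured <- problem$measured[problem$measured$condition != cn, ,
                                       drop = FALSE]
    fit <- adjust_turnover_numbers(train)
    pred <- predict_from_reference(problem$ec, problem$reference_flux[[cn]],
                                   fit$u)
    meas <- problem$measured[problem$measured$condition == cn, , drop = FALSE]
    mv <- stats::setNames(meas$abundance, meas$enzyme)
    sig <- fit_saturation(pred, mv)
    err <- rmse_log10(pred / sig, mv)
    data.frame(condition = cn, rmse_heldout = err$rmse, n_used = err$n_used)
  })
  do.call(rbind, rows)
}

#' Regularisation path of the turnover adjustment
#'
#' @param problem a `fit_problem`.
#' @param rhos numeric vector of ridge weights.
#' @return data frame with `rho`, `objective`, `u_norm`, `rmse_mean`.
#' @export
regularisation_path <- function(problem, rhos) {
  rows <- lapply(rhos, function(r) {
    p <- problem; p$rho <- r
    fit <- adjust_turnover_numbers(p)
    data.frame(rho = r, objective = fit$objective,
               u_norm = sqrt(sum(fit$u^2)),
               rmse_mean = mean(fit$rmse, na.rm = TRUE))
  })
  do.call(rbind, rows)
}
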