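#' Transporter saturation under irreversible Michaelis-Menten kinetics
#'
#' `sigma_up = c / (Km + c)`, the fractional saturation of the substrate
#' transporter at external substrate concentration `c`.
#'
#' @param c external substrate concentration (mM), nonnegative.
#' @param Km Michaelis constant (mM), positive; the package default for the
#'   glucose PTS transporter is 0.116 mM.
#' @return saturation in `[0, 1)`.
#' @export
transporter_saturation <- function(c, Km = 0.116) {
  if (any(c < 0)) stop("concentration must be nonnegative")
  if (any(Km <= 0)) stop("Km must be positive")
  c / (Km + c)
}

#' Saturation FBA at one external substrate concentration
#'
#' Growth is maximised on the enzyme-constrained model with every enzyme
#' cost frozen at the model's saturation except the designated transporter,
#' whose cost is rescaled to `a_up / sigma_up(c)` (its cost at full
#' saturation divided by the Michaelis-Menten saturation at concentration
#' `c`).
#'
#' @param ec an `ec_model` whose `sigma` is the fitted condition saturation.
#' @param transporter base reaction id of the substrate transporter (must be
#'   costed).
#' @param conc external substrate concentration (mM).
#' @param Km Michaelis constant (mM).
#' @param tol support threshold relative to the largest flux.
#' @return object of class `satfba_result`: `concentration`, `sigma_up`,
#'   `growth`, `flux` (net fluxes on base reactions), `yield` (gDW/mmol),
#'   `support` and `support_signature`.
#' @export
solve_satfba <- function(ec, transporter, conc, Km = 0.116, tol = 1e-9) {
  parts <- ec$split_map[[transporter]]
  if (is.null(parts) || all(ec$cost[parts] == 0))
    stop("transporter '", transporter, "' is not a costed reaction")
  s_up <- transporter_saturation(conc, Km)
  if (s_up == 0) {
    return(structure(list(concentration = conc, sigma_up = 0, growth = 0,
                          flux = NULL, yield = NA_real_,
                          support = character(0), support_signature = ""),
                     class = "satfba_result"))
  }
  mod <- ec$model
  # cost at full transporter saturation: a * sigma_model; rescale by sigma_up
  for (nm in parts) {
    if (ec$cost[[nm]] > 0) {
      a_full <- ec$cost[[nm]] * ec$sigma
      mod$S[ENZYME_POOL_MET, nm] <- -a_full / s_up
    }
  }
  sol <- solve_fba(mod)
  if (sol$status != "optimal") {
    # e.g. a maintenance demand that cannot be met at low saturation
    return(structure(list(concentration = conc, sigma_up = s_up,
                          growth = NA_real_, flux = NULL, yield = NA_real_,
                          support = character(0), support_signature = "",
                          status = sol$status),
                     class = "satfba_result"))
  }
  vnet <- net_fluxes(ec, sol)
  growth <- sol$objective_value
  v_up <- abs(vnet[[transporter]])
  yld <- if (v_up > 0) growth / v_up else NA_real_
  vmax <- max(abs(vnet), 1e-12)
  supp <- names(vnet)[abs(vnet) > tol * vmax]
  structure(list(concentration = conc, sigma_up = s_up, growth = growth,
                 flux = vnet, yield = yld, support = supp,
                 support_signature = paste(sort(supp), collapse = "|"),
                 status = "optimal"),
            class = "satfba_result")
}

#' @export
print.satfba_result <- function(x, ...) {
  cat(sprintf("satfba_result: c = %g mM, sigma_up = %.4f, growth = %.6g, yield = %.6g\n",
              x$concentration, x$sigma_up, x$growth, x$yield))
  invisible(x)
}

#' Test whether a support is elementary
#'
#' A flux support is elementary iff the null space of the stoichiometric
#' matrix restricted to the support columns is one-dimensional (the rank
#' equals support size minus one).
#'
#' @param model a `metabolic_model` (the unsplit base model).
#' @param support character vector of reaction ids.
#' @return logical.
#' @export
is_elementary_support <- function(model, support) {
  support <- intersect(support, model$reaction_ids)
  if (length(support) == 0) return(FALSE)
  A <- model$S[, support, drop = FALSE]
  qr(A)$rank == length(support) - 1
}

#' Screen saturation FBA over a grid of substrate concentrations
#'
#' @param ec an `ec_model`.
#' @param transporter transporter base reaction id.
#' @param grid ascending positive concentrations (mM).
#' @param Km Michaelis constant (mM).
#' @return data frame of class `satfba_screen` with columns
#'   `concentration`, `sigma_up`, `growth`, `yield`, `switch` (support
#'   change vs the previous grid point); the per-point results are attached
#'   as attribute `"results"`.
#' @export
screen_concentrations <- function(ec, transporter, grid, Km = 0.116) {
  stopifnot(all(diff(grid) > 0), all(grid > 0))
  res <- lapply(grid, function(cc) solve_satfba(ec, transporter, cc, Km))
  sig <- vapply(res, function(r) r$support_signature, "")
  out <- data.frame(
    concentration = grid,
    sigma_up = vapply(res, function(r) r$sigma_up, 0),
    growth = vapply(res, function(r) r$growth, 0),
    yield = vapply(res, function(r) r$yield, 0),
    switch = c(FALSE, sig[-1] != sig[-length(sig)]))
  attr(out, "results") <- res
  class(out) <- c("satfba_screen", class(out))
  out
}
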