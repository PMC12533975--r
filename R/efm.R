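#' Elementary flux mode enumeration
#'
#' Enumerates the complete set of elementary flux modes of
#' `{v : S v = 0, v_j >= 0 for irreversible j}` by direction splitting
#' followed by double description on the splitted cone, with the
#' combinatorial adjacency test on zero-pattern bit sets. Futile
#' forward+backward two-cycles created by the splitting are removed and the
#' remaining rays are mapped back to signed net fluxes. Each mode is
#' canonically normalised to `max |v| = 1`.
#'
#' A reversible mode (one whose support uses only reversible reactions) is
#' reported twice, once per direction, matching the convention that the two
#' orientations are distinct modes.
#'
#' @param model a `metabolic_model`.
#' @param max_reactions guard on problem size (default 40); exceeding it is
#'   an error unless `allow_large = TRUE`.
#' @param allow_large override the size guard.
#' @param tol zero threshold on normalised flux values.
#' @return list of `flux_mode` objects (fields `flux`, `support`).
#' @export
enumerate_efms <- function(model, max_reactions = 40, allow_large = FALSE,
                           tol = 1e-9) {
  n <- length(model$reaction_ids)
  if (n > max_reactions && !allow_large)
    stop("model has ", n, " reactions (> ", max_reactions,
         "); set allow_large = TRUE to override")
  rev <- model$lower_bound < 0
  # split: columns = fwd copies for all, rev copies for reversible
  S <- model$S
  Ssplit <- cbind(S, -S[, rev, drop = FALSE])
  owner <- c(seq_len(n), which(rev))           # base reaction of each column
  sign_of <- c(rep(1, n), rep(-1, sum(rev)))
  ns <- ncol(Ssplit)

  # double description on {w >= 0, Ssplit w = 0}
  R <- diag(ns)
  for (k in seq_len(nrow(Ssplit))) {
    s <- as.vector(Ssplit[k, ] %*% R)
    s[abs(s) < 1e-12] <- 0
    Z <- which(s == 0); P <- which(s > 0); N <- which(s < 0)
    newrays <- list()
    if (length(P) && length(N)) {
      zero_pat <- abs(R) < tol                  # ns x nrays logical
      for (p in P) for (q in N) {
        common <- zero_pat[, p] & zero_pat[, q]
        # adjacency: no third ray's zero set contains the intersection
        others <- setdiff(seq_len(ncol(R)), c(p, q))
        adjacent <- TRUE
        if (length(others)) {
          cnt <- colSums(zero_pat[common, others, drop = FALSE])
          if (any(cnt == sum(common))) adjacent <- FALSE
        }
        if (adjacent) {
          r <- s[p] * R[, q] - s[q] * R[, p]
          r <- r / max(abs(r))
          r[abs(r) < tol] <- 0
          newrays[[length(newrays) + 1]] <- r
        }
      }
    }
    R <- cbind(R[, Z, drop = FALSE],
               if (length(newrays)) do.call(cbind, newrays))
    if (is.null(R) || ncol(R) == 0) break
  }
  if (is.null(R) || ncol(R) == 0) return(list())

  # map back to net fluxes, drop futile two-cycles and duplicates
  modes <- list()
  seen <- character(0)
  for (j in seq_len(ncol(R))) {
    w <- R[, j]
    v <- numeric(n)
    for (kk in seq_len(ns)) v[owner[kk]] <- v[owner[kk]] + sign_of[kk] * w[kk]
    if (max(abs(v)) < tol) next                 # pure futile cycle
    v <- v / max(abs(v))
    v[abs(v) < tol] <- 0
    key <- paste(round(v, 8), collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    names(v) <- model$reaction_ids
    modes[[length(modes) + 1]] <- new_flux_mode(v)
  }
  modes
}

new_flux_mode <- function(v) {
  structure(list(flux = v, support = names(v)[v != 0]), class = "flux_mode")
}

#' @export
print.flux_mode <- function(x, ...) {
  cat("flux_mode over {", paste(x$support, collapse = ", "), "}\n")
  if (!is.null(x$yield)) cat("  yield =", format(x$yield),
                             " mu =", format(x$growth_estimate), "\n")
  invisible(x)
}

nullspace <- function(A, tol = 1e-10) {
  if (ncol(A) == 0) return(matrix(0, 0, 0))
  sv <- svd(A, nu = 0, nv = ncol(A))
  r <- sum(sv$d > tol * max(sv$d, 1))
  if (r == ncol(A)) return(matrix(0, ncol(A), 0))
  sv$v[, (r + 1):ncol(A), drop = FALSE]
}

#' Brute-force elementary flux modes (test oracle)
#'
#' Enumerates all support subsets (guarded at 15 reactions), keeping those
#' whose restricted null space is one-dimensional, nonzero on the whole
#' support, sign-feasible for the irreversible reactions, and
#' inclusion-minimal. Normalisation is identical to [enumerate_efms()].
#'
#' @param model a `metabolic_model` with at most `max_reactions` reactions.
#' @param max_reactions hard guard (default 15).
#' @return list of `flux_mode` objects.
#' @export
brute_force_efms <- function(model, max_reactions = 15) {
  n <- length(model$reaction_ids)
  if (n > max_reactions)
    stop("brute-force enumeration refused beyond ", max_reactions, " reactions")
  irrev <- model$lower_bound >= 0
  cand <- list()
  for (mask in seq_len(2^n - 1)) {
    supp <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    K <- nullspace(model$S[, supp, drop = FALSE])
    if (ncol(K) != 1) next
    v0 <- K[, 1]
    if (any(abs(v0) < 1e-9)) next               # support not exact
    for (sgn in c(1, -1)) {
      v <- sgn * v0
      if (any(v[irrev[supp]] < 0)) next
      full <- numeric(n); full[supp] <- v
      full <- full / max(abs(full))
      names(full) <- model$reaction_ids
      cand[[length(cand) + 1]] <- full
    }
  }
  # inclusion-minimal supports only
  supps <- lapply(cand, function(v) which(v != 0))
  keep <- vapply(seq_along(cand), function(i) {
    !any(vapply(seq_along(cand), function(j) {
      i != j && length(supps[[j]]) < length(supps[[i]]) &&
        all(supps[[j]] %in% supps[[i]])
    }, TRUE))
  }, TRUE)
  cand <- cand[keep]
  # dedupe
  keys <- vapply(cand, function(v) paste(round(v, 8), collapse = ","), "")
  cand <- cand[!duplicated(keys)]
  lapply(cand, new_flux_mode)
}

#' Filter elementary flux modes physiologically
#'
#' Retains modes with nonzero biomass flux; in the aerobic case additionally
#' requires nonzero oxygen uptake and zero flux in each excluded
#' (anaerobic-only) reaction. The exclusion list is ignored in the anaerobic
#' case.
#'
#' @param modes list of `flux_mode`s.
#' @param aerobic logical.
#' @param biomass biomass reaction id.
#' @param oxygen_uptake oxygen uptake/transport reaction id (required if
#'   `aerobic`).
#' @param excluded_reactions reaction ids that must carry zero flux in
#'   aerobic modes.
#' @param tol zero threshold.
#' @return filtered list of modes.
#' @export
filter_modes <- function(modes, aerobic, biomass, oxygen_uptake = NULL,
                         excluded_reactions = character(0), tol = 1e-9) {
  Filter(function(m) {
    if (abs(m$flux[[biomass]]) <= tol) return(FALSE)
    if (aerobic) {
      if (!is.null(oxygen_uptake) && abs(m$flux[[oxygen_uptake]]) <= tol)
        return(FALSE)
      for (r in excluded_reactions)
        if (r %in% names(m$flux) && abs(m$flux[[r]]) > tol) return(FALSE)
    }
    TRUE
  }, modes)
}

#' Score a flux mode: biomass yield and achievable growth rate
#'
#' `yield = v_BM / |v_uptake|` (gDW/mmol) and
#' `mu = f_enz * v_BM / c_enz` with `c_enz = sum_i a_i |v_i|`; both are
#' invariant to the arbitrary scaling of the mode.
#'
#' @param mode a `flux_mode`.
#' @param cost named enzyme costs per unit flux (g h/mmol) on base reaction
#'   ids; reactions absent from `cost` are free.
#' @param biomass biomass reaction id.
#' @param substrate_uptake substrate uptake reaction id.
#' @param f_enz total enzyme budget for the mode (g/gDW; default 0.285).
#' @return the mode with fields `yield_biomass`, `enzyme_cost` (at the
#'   stored scale), `growth_estimate` added.
#' @export
score_mode <- function(mode, cost, biomass, substrate_uptake, f_enz = 0.285) {
  v_bm <- mode$flux[[biomass]]
  v_up <- abs(mode$flux[[substrate_uptake]])
  if (v_up == 0) stop("mode has zero substrate uptake; yield undefined")
  common <- intersect(names(cost), names(mode$flux))
  c_enz <- sum(cost[common] * abs(mode$flux[common]))
  mu <- if (c_enz == 0) {
    if (v_bm > 0) {
      warning("zero enzyme cost with nonzero biomass flux; mu set to Inf")
      Inf
    } else 0
  } else f_enz * v_bm / c_enz
  mode$yield_biomass <- v_bm / v_up
  mode$enzyme_cost <- c_enz
  mode$growth_estimate <- mu
  mode
}

#' Pareto front of scored modes in (yield, growth)
#'
#' @param scored_modes list of modes from [score_mode()].
#' @return the non-dominated modes, sorted by yield descending.
#' @export
pareto_front <- function(scored_modes) {
  if (length(scored_modes) == 0) return(scored_modes)
  y <- vapply(scored_modes, function(m) m$yield_biomass, 0)
  g <- vapply(scored_modes, function(m) m$growth_estimate, 0)
  dominated <- vapply(seq_along(scored_modes), function(i) {
    any(y >= y[i] & g >= g[i] & (y > y[i] | g > g[i]))
  }, TRUE)
  keep <- which(!dominated)
  scored_modes[keep[order(y[keep], decreasing = TRUE)]]
}

#' Scale the enzyme cost of oxygen-consuming reactions
#'
#' Emulates a low-oxygen environment in which oxygen-dependent respiratory
#' reactions operate at low saturation: their cost per unit flux is
#' multiplied by `factor` (1000-fold for the low-oxygen scenario).
#'
#' @param cost named cost vector.
#' @param oxygen_reactions reaction ids to scale.
#' @param factor positive multiplier.
#' @return modified cost vector.
#' @export
scale_oxygen_cost <- function(cost, oxygen_reactions, factor) {
  stopifnot(factor > 0)
  missing <- setdiff(oxygen_reactions, names(cost))
  if (length(missing))
    stop("unknown reaction id(s): ", paste(missing, collapse = ", "))
  cost[oxygen_reactions] <- cost[oxygen_reactions] * factor
  cost
}
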