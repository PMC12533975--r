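# shared fixture builders and small oracles

# linear chain with unit stoichiometry: uptake (<= cap) -> A -> biomass
chain_model <- function(cap = 10) {
  S <- matrix(c(1, -1, 0,
                0, 1, -1), nrow = 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("U", "R1", "BM")))
  metabolic_model(S, lower_bound = c(0, 0, 0), upper_bound = c(cap, 1000, 1000),
                  objective = c(BM = 1))
}

# two redundant parallel paths of equal stoichiometry (for pFBA)
parallel_model <- function(cap = 10) {
  S <- matrix(0, 2, 4, dimnames = list(c("A", "B"), c("U", "P1", "P2", "BM")))
  S["A", "U"] <- 1
  S["A", "P1"] <- -1; S["B", "P1"] <- 1
  S["A", "P2"] <- -1; S["B", "P2"] <- 1
  S["B", "BM"] <- -1
  metabolic_model(S, rep(0, 4), c(cap, 1000, 1000, 1000), c(BM = 1))
}

# random small network with integer stoichiometry; guaranteed nonzero
# columns, mixed reversibility; used for EFM oracle-equivalence checks
random_network <- function(n_mets, n_rxns, seed) {
  set.seed(seed)
  repeat {
    S <- matrix(sample(c(-1, 0, 0, 1, -2, 2), n_mets * n_rxns,
                       replace = TRUE, prob = c(.25, .3, .1, .25, .05, .05)),
                n_mets, n_rxns)
    if (all(colSums(abs(S)) > 0)) break
  }
  dimnames(S) <- list(paste0("m", seq_len(n_mets)), paste0("r", seq_len(n_rxns)))
  rev <- stats::runif(n_rxns) < 0.3
  metabolic_model(S, ifelse(rev, -1000, 0), rep(1000, n_rxns),
                  stats::setNames(1, colnames(S)[1]))
}

# compare two EFM sets: same size and a 1-1 match on support + values
expect_same_modes <- function(a, b, tol = 1e-8) {
  expect_equal(length(a), length(b))
  used <- logical(length(b))
  for (m in a) {
    hit <- FALSE
    for (j in seq_along(b)) {
      if (used[j]) next
      if (setequal(m$support, b[[j]]$support) &&
          max(abs(m$flux - b[[j]]$flux[names(m$flux)])) < tol) {
        used[j] <- TRUE; hit <- TRUE; break
      }
    }
    expect_true(hit, label = paste("mode over {",
                                   paste(m$support, collapse = ","),
                                   "} matched in other set"))
  }
}

# exhaustive vertex-enumeration LP oracle for small problems:
# optimises obj over {A x = b, lb <= x <= ub} by checking all basic points
brute_lp <- function(obj, A, b, lb, ub, maximize = FALSE) {
  n <- ncol(A); m <- nrow(A)
  best <- if (maximize) -Inf else Inf
  idx <- utils::combn(n, n - m)
  for (k in seq_len(ncol(idx))) {
    fixset <- idx[, k]; freeset <- setdiff(seq_len(n), fixset)
    Af <- A[, freeset, drop = FALSE]
    if (qr(Af)$rank < length(freeset)) next
    for (mask in 0:(2^length(fixset) - 1)) {
      vals <- ifelse(bitwAnd(mask, 2^(seq_along(fixset) - 1)) > 0,
                     ub[fixset], lb[fixset])
      if (any(!is.finite(vals))) next
      xf <- tryCatch(solve(Af, b - A[, fixset, drop = FALSE] %*% vals),
                     error = function(e) NULL)
      if (is.null(xf)) next
      x <- numeric(n); x[fixset] <- vals; x[freeset] <- xf
      if (any(x < lb - 1e-7) || any(x > ub + 1e-7)) next
      v <- sum(obj * x)
      best <- if (maximize) max(best, v) else min(best, v)
    }
  }
  best
}
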