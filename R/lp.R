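#' Solve a linear program with equality constraints and variable bounds
#'
#' Solves `min/max obj' x` subject to `A x = b` and `lb <= x <= ub` with a
#' dense bounded-variable two-phase primal simplex. This is the optimisation
#' core behind all flux balance computations in the package; it is written
#' for the small, dense models this toolkit targets (up to a few hundred
#' variables), not for genome-scale work.
#'
#' @param obj numeric objective coefficient vector (length n).
#' @param A numeric constraint matrix (m x n).
#' @param b numeric right-hand side (length m).
#' @param lb,ub numeric variable bounds; `-Inf`/`Inf` allowed.
#' @param maximize logical; maximise instead of minimise.
#' @param tol numeric feasibility/optimality tolerance.
#' @param maxit iteration cap per phase.
#' @return list with `x` (primal solution), `objective`, and `status`
#'   (one of `"optimal"`, `"infeasible"`, `"unbounded"`).
#' @keywords internal
solve_lp <- function(obj, A, b, lb, ub, maximize = FALSE,
                     tol = 1e-9, maxit = 20000L) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(b) == m, length(lb) == n, length(ub) == n)
  if (any(lb > ub + tol)) {
    return(list(x = rep(NA_real_, n), objective = NA_real_, status = "infeasible"))
  }
  sense <- if (maximize) -1 else 1
  cost <- sense * obj

  if (m == 0L) {
    # pure box problem
    x <- ifelse(cost > 0, lb, ifelse(cost < 0, ub, ifelse(is.finite(lb), lb, pmin(ub, 0))))
    x[!is.finite(x) & cost == 0] <- 0
    if (any(!is.finite(x) & cost != 0)) {
      return(list(x = rep(NA_real_, n), objective = NA_real_, status = "unbounded"))
    }
    return(list(x = x, objective = sum(obj * x), status = "optimal"))
  }

  # initial nonbasic point: finite lower bound preferred, then upper, else 0
  x0 <- ifelse(is.finite(lb), lb, ifelse(is.finite(ub), ub, 0))
  nb_state <- ifelse(is.finite(lb), 1L, ifelse(is.finite(ub), 2L, 3L))

  r <- b - as.vector(A %*% x0)
  sgn <- ifelse(r >= 0, 1, -1)
  AA <- cbind(A, diag(sgn, nrow = m))
  ntot <- n + m
  LB <- c(lb, rep(0, m))
  UB <- c(ub, rep(Inf, m))
  x <- c(x0, abs(r))
  state <- c(nb_state, rep(0L, m))      # 0 = basic
  basis <- (n + 1L):ntot

  run_phase <- function(cvec, x, basis, state, maxit) {
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > maxit) return(list(x = x, basis = basis, state = state, status = "maxit"))
      bland <- it > maxit %/% 2L
      B <- AA[, basis, drop = FALSE]
      y <- tryCatch(solve(t(B), cvec[basis]), error = function(e) NULL)
      if (is.null(y)) return(list(x = x, basis = basis, state = state, status = "singular"))
      nonbasic <- which(state != 0L)
      dvec <- cvec[nonbasic] - as.vector(crossprod(AA[, nonbasic, drop = FALSE], y))
      st <- state[nonbasic]
      # candidate improving directions
      can_up <- (st == 1L | st == 3L) & dvec < -tol
      can_dn <- (st == 2L | st == 3L) & dvec > tol
      cand <- which(can_up | can_dn)
      if (length(cand) == 0L) {
        return(list(x = x, basis = basis, state = state, status = "optimal"))
      }
      if (bland) {
        k <- cand[which.min(nonbasic[cand])]
      } else {
        k <- cand[which.max(abs(dvec[cand]))]
      }
      j <- nonbasic[k]
      delta <- if (can_up[k]) 1 else -1
      w <- solve(B, AA[, j])
      # ratio test
      xB <- x[basis]
      dw <- delta * w
      t_best <- UB[j] - LB[j]          # own-bound flip span (Inf if open)
      if (!is.finite(t_best)) t_best <- Inf
      leave <- 0L
      for (i in seq_len(m)) {
        if (dw[i] > tol) {
          li <- LB[basis[i]]
          ti <- if (is.finite(li)) (xB[i] - li) / dw[i] else Inf
        } else if (dw[i] < -tol) {
          ui <- UB[basis[i]]
          ti <- if (is.finite(ui)) (ui - xB[i]) / (-dw[i]) else Inf
        } else next
        if (ti < t_best - 1e-12 ||
            (ti < t_best + 1e-12 && leave != 0L &&
             (if (bland) basis[i] < basis[leave] else abs(dw[i]) > abs(dw[leave])))) {
          t_best <- ti
          leave <- i
        }
      }
      if (!is.finite(t_best)) {
        return(list(x = x, basis = basis, state = state, status = "unbounded"))
      }
      t_best <- max(t_best, 0)
      # update values
      x[j] <- x[j] + delta * t_best
      x[basis] <- xB - t_best * dw
      if (leave == 0L) {
        # bound flip of the entering variable
        state[j] <- if (delta > 0) 2L else 1L
      } else {
        lv <- basis[leave]
        # snap leaving variable to its bound
        if (dw[leave] > 0) { x[lv] <- LB[lv]; state[lv] <- 1L }
        else { x[lv] <- UB[lv]; state[lv] <- 2L }
        basis[leave] <- j
        state[j] <- 0L
      }
    }
  }

  # Phase 1: drive artificials to zero
  c1 <- c(rep(0, n), rep(1, m))
  ph1 <- run_phase(c1, x, basis, state, maxit)
  if (ph1$status %in% c("singular", "maxit")) {
    stop("LP solver failed in phase 1 (", ph1$status, ")")
  }
  art_sum <- sum(ph1$x[(n + 1L):ntot])
  if (art_sum > 1e-7) {
    return(list(x = rep(NA_real_, n), objective = NA_real_, status = "infeasible"))
  }
  # lock artificials at zero for phase 2
  UB[(n + 1L):ntot] <- 0
  x <- ph1$x
  x[(n + 1L):ntot] <- pmax(0, pmin(x[(n + 1L):ntot], 0))
  c2 <- c(cost, rep(0, m))
  ph2 <- run_phase(c2, x, ph1$basis, ph1$state, maxit)
  if (ph2$status %in% c("singular", "maxit")) {
    stop("LP solver failed in phase 2 (", ph2$status, ")")
  }
  if (ph2$status == "unbounded") {
    return(list(x = rep(NA_real_, n), objective = NA_real_, status = "unbounded"))
  }
  xx <- ph2$x[seq_len(n)]
  list(x = xx, objective = sum(obj * xx), status = "optimal")
}
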