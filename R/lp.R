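## Dense bounded-variable linear programming
##
## Solves  max/min c'x  subject to  A x = b,  lb <= x <= ub  with all bounds
## finite, via a two-phase primal simplex with explicit variable bounds.
## Bland's rule is used throughout, so the pivot sequence -- and hence the
## returned vertex under degenerate optima -- is a deterministic function of
## the input alone. Problem sizes here are genome-toy scale (tens of
## variables), so a dense implementation with a fresh basis solve per
## iteration is both simple and fast.
##
## This solver exists because no LP package is available in the dependency
## set; it is validated against exhaustive vertex enumeration in the tests.

.LP_TOL_DJ <- 1e-9     # reduced-cost optimality tolerance
.LP_TOL_PIV <- 1e-10   # pivot magnitude threshold
.LP_TOL_FEAS <- 1e-7   # phase-1 residual deemed infeasible above this

#' Solve a bounded linear program
#'
#' @param obj Objective coefficient vector (length n).
#' @param A Constraint matrix (m x n), dense or sparse; rows are equalities.
#' @param b Right-hand side (length m).
#' @param lb,ub Finite variable bounds.
#' @param direction `"max"` or `"min"`.
#' @param maxiter Iteration cap (Bland's rule guarantees finite termination;
#'   this is a safety net).
#' @return A list with `status` (`"optimal"`, `"infeasible"`, or
#'   `"unbounded"`), `value` (objective at the optimum, `NA` otherwise), and
#'   `x` (primal solution).
#' @keywords internal
solve_lp <- function(obj, A, b, lb, ub, direction = c("max", "min"),
                     maxiter = 20000L) {
  direction <- match.arg(direction)
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(b) == m, length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub))) {
    stop("solve_lp() requires finite variable bounds")
  }
  if (any(lb > ub + 1e-12)) {
    return(list(status = "infeasible", value = NA_real_, x = rep(NA_real_, n)))
  }

  cmin <- if (direction == "max") -obj else obj

  ## Extended problem: n structural + m artificial columns.
  x0 <- lb
  r <- b - as.vector(A %*% x0)
  s <- ifelse(r >= 0, 1, -1)
  Aext <- cbind(A, diag(s, nrow = m))
  lext <- c(lb, rep(0, m))
  uext <- c(ub, rep(Inf, m))
  N <- n + m

  x <- c(x0, abs(r))
  basis <- (n + 1L):N
  ## at_upper[j]: nonbasic variable j currently sits at its upper bound
  at_upper <- rep(FALSE, N)
  in_basis <- rep(FALSE, N)
  in_basis[basis] <- TRUE

  run_simplex <- function(cost) {
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > maxiter) stop("simplex iteration limit reached")
      AB <- Aext[, basis, drop = FALSE]
      qrAB <- qr(AB)
      nonbasic <- which(!in_basis)
      ## refresh basic values from the nonbasic ones (numerical hygiene)
      rhs <- b - as.vector(Aext[, nonbasic, drop = FALSE] %*% x[nonbasic])
      x[basis] <<- qr.coef(qrAB, rhs)

      y <- qr.solve(t(AB), cost[basis])
      dj <- cost[nonbasic] - as.vector(y %*% Aext[, nonbasic, drop = FALSE])

      free_var <- uext[nonbasic] - lext[nonbasic] > .LP_TOL_PIV
      enter_mask <- free_var &
                    ((!at_upper[nonbasic] & dj < -.LP_TOL_DJ) |
                     (at_upper[nonbasic] & dj > .LP_TOL_DJ))
      if (!any(enter_mask)) return("optimal")
      ## Dantzig pricing early for speed; Bland's least-index rule after a
      ## fixed iteration count for guaranteed termination. Both choices are
      ## deterministic functions of the input.
      cand <- nonbasic[enter_mask]
      if (it <= 500L) {
        gain <- abs(dj[enter_mask])
        j <- cand[which.max(gain)]   # which.max: first (lowest-index) maximum
      } else {
        j <- min(cand)
      }
      dirj <- if (at_upper[j]) -1 else 1

      d <- qr.coef(qrAB, Aext[, j])
      delta <- -dirj * d                           # xB changes by t * delta

      tmax <- uext[j] - lext[j]                    # bound flip distance
      leave_local <- 0L                            # 0 => bound flip
      for (i in seq_len(m)) {
        di <- delta[i]
        if (di < -.LP_TOL_PIV) {
          ti <- (x[basis[i]] - lext[basis[i]]) / (-di)
        } else if (di > .LP_TOL_PIV) {
          ti <- (uext[basis[i]] - x[basis[i]]) / di
        } else next
        ti <- max(ti, 0)
        ## Bland tie-break: strictly smaller ratio, or equal ratio with a
        ## smaller variable index, wins.
        if (ti < tmax - 1e-12 ||
            (ti < tmax + 1e-12 && leave_local > 0L &&
             basis[i] < basis[leave_local])) {
          tmax <- ti
          leave_local <- i
        }
      }
      if (!is.finite(tmax)) return("unbounded")

      x[j] <<- x[j] + dirj * tmax
      x[basis] <<- x[basis] + tmax * delta
      if (leave_local == 0L) {
        at_upper[j] <<- !at_upper[j]               # flipped to other bound
        x[j] <<- if (at_upper[j]) uext[j] else lext[j]
      } else {
        leaving <- basis[leave_local]
        hit_upper <- delta[leave_local] > 0
        x[leaving] <<- if (hit_upper) uext[leaving] else lext[leaving]
        at_upper[leaving] <<- hit_upper
        in_basis[leaving] <<- FALSE
        basis[leave_local] <<- j
        in_basis[j] <<- TRUE
        at_upper[j] <<- FALSE
      }
    }
  }

  ## Phase 1: drive artificials to zero.
  c1 <- c(rep(0, n), rep(1, m))
  st <- run_simplex(c1)
  if (st != "optimal" || sum(x[(n + 1L):N]) > .LP_TOL_FEAS) {
    return(list(status = "infeasible", value = NA_real_, x = rep(NA_real_, n)))
  }

  ## Pivot basic artificials out where possible; freeze all artificials at 0.
  art_rows <- which(basis > n)
  for (i in art_rows) {
    AB <- Aext[, basis, drop = FALSE]
    Binv_row <- tryCatch(solve(t(AB), diag(m)[, i]),
                         error = function(e) qr.solve(t(AB), diag(m)[, i]))
    piv <- as.vector(Binv_row %*% Aext[, seq_len(n), drop = FALSE])
    cand <- which(!in_basis[seq_len(n)] & abs(piv) > 1e-8)
    if (length(cand) > 0L) {
      j <- min(cand)
      leaving <- basis[i]
      in_basis[leaving] <- FALSE
      at_upper[leaving] <- FALSE
      x[leaving] <- 0
      basis[i] <- j
      in_basis[j] <- TRUE
      at_upper[j] <- FALSE
    }
    ## else: redundant row, the artificial stays basic at value 0
  }
  uext[(n + 1L):N] <- 0

  ## Phase 2.
  c2 <- c(cmin, rep(0, m))
  st <- run_simplex(c2)
  if (st == "unbounded") {
    return(list(status = "unbounded", value = NA_real_, x = rep(NA_real_, n)))
  }
  xs <- x[seq_len(n)]
  ## clamp roundoff outside the box
  xs <- pmin(pmax(xs, lb), ub)
  list(status = "optimal", value = sum(obj * xs), x = xs)
}
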