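## Dense bounded-variable two-phase simplex.
##
## Written in-package because the constraint-based layer needs a reliable,
## deterministic LP core: Bland's smallest-index rule guarantees both finite
## termination and bit-reproducible solutions (the pFBA degeneracy
## tie-break), and the problems are small (tens of variables), so dense
## basis solves are appropriate. Verified against brute-force vertex
## enumeration in the test suite.

#' Solve a bounded linear program
#'
#' Optimizes \code{obj \%*\% x} subject to \code{Aeq \%*\% x == beq} and
#' \code{lb <= x <= ub}, via a two-phase primal simplex on bounded
#' variables. Deterministic: identical inputs give identical solutions,
#' including among degenerate alternative optima.
#'
#' Infinite bounds are capped at \code{big} (fluxes in constraint-based
#' models are conventionally bounded at 1000 anyway).
#'
#' @param obj numeric objective coefficients.
#' @param Aeq equality constraint matrix (dense or sparse).
#' @param beq equality right-hand side.
#' @param lb,ub variable bounds, recycled to \code{length(obj)}.
#' @param maximize maximize (default) or minimize.
#' @param big cap applied to infinite bounds.
#' @param tol feasibility/optimality tolerance.
#' @return list with \code{status} ("optimal" or "infeasible"), \code{x}
#'   and \code{value}.
#' @keywords internal
lpSolveBounded <- function(obj, Aeq, beq, lb, ub, maximize = TRUE,
                           big = 1e6, tol = 1e-9) {
  n <- length(obj)
  lb <- rep_len(as.numeric(lb), n)
  ub <- rep_len(as.numeric(ub), n)
  lb[lb < -big] <- -big
  ub[ub > big] <- big
  if (any(lb > ub)) stop("inconsistent bounds: lb > ub")
  A <- as.matrix(Aeq)
  if (ncol(A) != n) stop("Aeq has ", ncol(A), " columns, expected ", n)
  m <- nrow(A)

  ## phase 1: artificial basis. Nonbasic structurals start at their lower
  ## bound; one signed artificial per row absorbs the residual.
  r <- as.numeric(beq - A %*% lb)
  sgn <- ifelse(r >= 0, 1, -1)
  Afull <- cbind(A, diag(sgn, m, m))
  N <- n + m
  lbf <- c(lb, rep(0, m))
  ubf <- c(ub, rep(sum(abs(r)) + 1, m))
  xval <- c(lb, abs(r))
  basis <- n + seq_len(m)
  atUpper <- rep(FALSE, N)

  res <- simplexCore(Afull, c(rep(0, n), rep(1, m)), basis, xval, atUpper,
                     lbf, ubf, tol)
  if (sum(res$xval[n + seq_len(m)]) > tol * (1 + sum(abs(beq))))
    return(list(status = "infeasible", x = rep(NA_real_, n),
                value = NA_real_))

  ## phase 2: pin artificials at zero, optimize the real objective
  lbf[n + seq_len(m)] <- 0
  ubf[n + seq_len(m)] <- 0
  res$xval[n + seq_len(m)][res$xval[n + seq_len(m)] < tol] <- 0
  cvec <- c(if (maximize) -obj else obj, rep(0, m))
  res <- simplexCore(Afull, cvec, res$basis, res$xval, res$atUpper,
                     lbf, ubf, tol)
  x <- res$xval[seq_len(n)]
  list(status = "optimal", x = x, value = sum(obj * x))
}

## primal simplex on bounded variables, Bland's rule; minimizes cvec'x
simplexCore <- function(Afull, cvec, basis, xval, atUpper, lbf, ubf, tol) {
  N <- ncol(Afull)
  repeat {
    B <- Afull[, basis, drop = FALSE]
    y <- solve(t(B), cvec[basis])
    nonbasic <- setdiff(seq_len(N), basis)
    d <- cvec[nonbasic] - as.numeric(crossprod(Afull[, nonbasic,
                                                     drop = FALSE], y))
    free <- ubf[nonbasic] - lbf[nonbasic] > 0
    improving <- free & ((!atUpper[nonbasic] & d < -tol) |
                           (atUpper[nonbasic] & d > tol))
    if (!any(improving)) break
    j <- min(nonbasic[improving])  # Bland: smallest index enters
    sigma <- if (atUpper[j]) -1 else 1
    w <- solve(B, Afull[, j])
    deltaB <- -sigma * w
    ## ratio test against basic bounds and the entering variable's own span
    tmax <- ubf[j] - lbf[j]
    leave <- 0L
    for (i in seq_along(basis)) {
      bi <- basis[i]
      ti <- if (deltaB[i] < -tol) (xval[bi] - lbf[bi]) / (-deltaB[i])
            else if (deltaB[i] > tol) (ubf[bi] - xval[bi]) / deltaB[i]
            else next
      if (ti < tmax - tol ||
          (ti < tmax + tol && (leave == 0L || basis[i] < basis[leave]))) {
        tmax <- min(tmax, ti)
        leave <- i
      }
    }
    if (!is.finite(tmax)) stop("LP unbounded despite finite bounds")
    tmax <- max(tmax, 0)
    xval[j] <- xval[j] + sigma * tmax
    xval[basis] <- xval[basis] + deltaB * tmax
    if (leave == 0L) {
      atUpper[j] <- !atUpper[j]  # bound flip, basis unchanged
    } else {
      out <- basis[leave]
      ## snap the leaving variable to the bound it reached
      atUpper[out] <- deltaB[leave] > 0
      xval[out] <- if (atUpper[out]) ubf[out] else lbf[out]
      basis[leave] <- j
      atUpper[j] <- FALSE
    }
  }
  list(basis = basis, xval = xval, atUpper = atUpper)
}
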