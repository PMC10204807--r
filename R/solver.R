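#' Solve a bounded-variable linear program
#'
#' Dense two-phase primal simplex for problems of the form
#' \deqn{\max\ c^T x \quad \mathrm{s.t.}\quad A x = b,\ \ l \le x \le u.}
#' This is the numerical core behind [solve_fba()], [canonicalize()] and
#' [flux_variability()]. The implementation keeps nonbasic variables at
#' either bound, performs bound flips, and switches from Dantzig to Bland
#' pivoting after a run of degenerate steps so that it terminates on the
#' highly degenerate equality systems that stoichiometric models produce.
#'
#' Every variable must have at least one finite bound; metabolic problems
#' always do (flux bounds default to +/- 1000).
#'
#' @param obj objective coefficient vector, length `n`.
#' @param A dense constraint matrix, `m x n`, read as `A x = b`.
#' @param b right-hand side, length `m`.
#' @param lb,ub variable bounds, length `n` (may contain `-Inf`/`Inf`, but
#'   not both for the same variable).
#' @param sense `"max"` or `"min"`.
#' @param tol pivot tolerance on reduced costs and ratio tests.
#' @param max_iter pivot limit; hitting it surfaces as status `"maxiter"`
#'   rather than a silently wrong answer.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`,
#'   `"maxiter"`), `x` (primal solution, length `n`) and `objval` (in the
#'   requested sense); `x` and `objval` are `NULL` unless optimal.
#' @keywords internal
lp_solve_bounded <- function(obj, A, b, lb, ub, sense = c("max", "min"),
                             tol = 1e-9, max_iter = 50000L) {
  sense <- match.arg(sense)
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(b) == m, length(lb) == n, length(ub) == n)
  if (any(lb > ub + 1e-12)) return(list(status = "infeasible", x = NULL, objval = NULL))
  if (any(!is.finite(lb) & !is.finite(ub)))
    stop("every variable needs at least one finite bound")
  cvec <- if (sense == "min") -obj else obj

  nE <- n + m
  lbE <- c(lb, rep(0, m))
  ubE <- c(ub, rep(Inf, m))

  ## nonbasic structural variables start at the finite bound nearer zero
  x <- numeric(nE)
  at_lower <- rep(TRUE, nE)
  for (j in seq_len(n)) {
    lo <- lb[j]; hi <- ub[j]
    if (!is.finite(lo)) { x[j] <- hi; at_lower[j] <- FALSE }
    else if (!is.finite(hi)) x[j] <- lo
    else if (abs(hi) < abs(lo)) { x[j] <- hi; at_lower[j] <- FALSE }
    else x[j] <- lo
  }
  resid <- as.numeric(b - A %*% x[seq_len(n)])
  Aext <- cbind(A, diag(ifelse(resid >= 0, 1, -1), m))
  x[n + seq_len(m)] <- abs(resid)
  basis <- n + seq_len(m)
  in_basis <- logical(nE); in_basis[basis] <- TRUE

  run_phase <- function(cE, basis, in_basis, x, at_lower, allow_enter) {
    degen_run <- 0L
    for (iter in seq_len(max_iter)) {
      Bmat <- Aext[, basis, drop = FALSE]
      y <- tryCatch(solve(t(Bmat), cE[basis]), error = function(e) NULL)
      if (is.null(y)) return(list(status = "singular"))
      nonbasic <- which(!in_basis & allow_enter & (ubE - lbE) > tol)
      if (length(nonbasic)) {
        d <- cE[nonbasic] - as.numeric(crossprod(Aext[, nonbasic, drop = FALSE], y))
        eligible <- (at_lower[nonbasic] & d > tol) | (!at_lower[nonbasic] & d < -tol)
      } else eligible <- logical(0)
      if (!any(eligible))
        return(list(status = "optimal", basis = basis, in_basis = in_basis,
                    x = x, at_lower = at_lower))
      cand <- nonbasic[eligible]
      e <- if (degen_run > 60L) min(cand) else cand[which.max(abs(d[eligible]))]
      dir <- if (at_lower[e]) 1 else -1
      step <- dir * as.numeric(solve(Bmat, Aext[, e]))
      xB <- x[basis]
      t_best <- ubE[e] - lbE[e]              # bound-flip distance (may be Inf)
      leave <- 0L; leave_to_lower <- TRUE
      for (i in seq_len(m)) {
        si <- step[i]
        if (si > tol) {
          lim <- (xB[i] - lbE[basis[i]]) / si
          if (lim < t_best) { t_best <- lim; leave <- i; leave_to_lower <- TRUE }
        } else if (si < -tol) {
          lim <- (ubE[basis[i]] - xB[i]) / (-si)
          if (lim < t_best) { t_best <- lim; leave <- i; leave_to_lower <- FALSE }
        }
      }
      if (!is.finite(t_best)) return(list(status = "unbounded"))
      t_best <- max(t_best, 0)
      degen_run <- if (t_best <= tol) degen_run + 1L else 0L
      x[basis] <- xB - t_best * step
      x[e] <- x[e] + dir * t_best
      if (leave == 0L) {
        at_lower[e] <- !at_lower[e]          # bound flip, basis unchanged
      } else {
        lv <- basis[leave]
        in_basis[lv] <- FALSE
        at_lower[lv] <- leave_to_lower
        x[lv] <- if (leave_to_lower) lbE[lv] else ubE[lv]
        basis[leave] <- e
        in_basis[e] <- TRUE
      }
    }
    list(status = "maxiter")
  }

  ## phase 1: drive artificial variables to zero
  r1 <- run_phase(c(rep(0, n), rep(-1, m)), basis, in_basis, x, at_lower,
                  rep(TRUE, nE))
  if (!identical(r1$status, "optimal"))
    return(list(status = r1$status, x = NULL, objval = NULL))
  if (sum(r1$x[n + seq_len(m)]) > 1e-7)
    return(list(status = "infeasible", x = NULL, objval = NULL))

  ## phase 2: artificials pinned at zero, optimize the real objective
  ubE <- c(ub, rep(0, m))
  x2 <- r1$x; x2[n + seq_len(m)] <- 0
  r2 <- run_phase(c(cvec, rep(0, m)), r1$basis, r1$in_basis, x2, r1$at_lower,
                  c(rep(TRUE, n), rep(FALSE, m)))
  if (!identical(r2$status, "optimal"))
    return(list(status = r2$status, x = NULL, objval = NULL))
  xs <- r2$x[seq_len(n)]
  list(status = "optimal", x = xs, objval = sum(obj * xs))
}
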