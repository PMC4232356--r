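# Internal linear-programming layer.
#
# All solvers in this package reduce to one primitive:
#   min/max  c'x  s.t.  A_eq x = b_eq,  A_ub x <= b_ub,  lower <= x <= upper
# with bounds allowed to be infinite. A dense two-phase simplex with Bland's
# rule does the pivoting; problems here have at most a few dozen columns, so
# robust status classification (optimal / infeasible / unbounded) matters far
# more than speed.

#' Solve a small linear program
#'
#' Minimizes (or maximizes) `objective %*% x` subject to equality rows,
#' inequality (`<=`) rows and variable bounds. Infinite bounds are handled
#' natively: free variables are split internally and never require a big-M
#' box.
#'
#' @param objective numeric cost vector, one entry per variable.
#' @param A_eq,b_eq equality constraints `A_eq x = b_eq` (may be `NULL`).
#' @param A_ub,b_ub inequality constraints `A_ub x <= b_ub` (may be `NULL`).
#' @param lower,upper variable bounds, recycled to the number of variables;
#'   `-Inf`/`Inf` allowed.
#' @param maximize maximize instead of minimize.
#' @param tol pivot / feasibility tolerance.
#'
#' @return A list with `x` (primal solution, `NA` unless optimal),
#'   `objective` (optimal value on the original min/max scale) and
#'   `status`, one of `"optimal"`, `"infeasible"`, `"unbounded"`.
#' @keywords internal
lp_solve <- function(objective, A_eq = NULL, b_eq = NULL,
                     A_ub = NULL, b_ub = NULL,
                     lower = 0, upper = Inf,
                     maximize = FALSE, tol = 1e-9) {
  n <- length(objective)
  lower <- rep_len(lower, n)
  upper <- rep_len(upper, n)
  if (any(lower > upper)) stop("lp_solve: lower bound exceeds upper bound")
  cc <- if (maximize) -objective else objective

  A <- rbind(
    if (!is.null(A_eq)) matrix(A_eq, ncol = n) else NULL,
    if (!is.null(A_ub)) matrix(A_ub, ncol = n) else NULL
  )
  if (is.null(A)) A <- matrix(0, 0, n)
  b <- c(b_eq, b_ub)
  n_eq <- if (is.null(A_eq)) 0L else length(b_eq)
  is_eq <- seq_len(nrow(A)) <= n_eq

  # --- reduce to standard form: min c'y, By = d, y >= 0 -------------------
  # Each original variable becomes one or two nonnegative columns; `recover`
  # records how to map a standard-form solution back.
  cols <- list()    # per original variable: list(idx, sign, shift)
  B <- matrix(0, nrow(A), 0)
  cstd <- numeric(0)
  d <- b
  extra_ub <- list() # rows y_j <= u - l for doubly bounded variables
  for (j in seq_len(n)) {
    lj <- lower[j]; uj <- upper[j]
    if (is.finite(lj)) {
      # x_j = lj + y
      d <- d - A[, j] * lj
      B <- cbind(B, A[, j]); cstd <- c(cstd, cc[j])
      idx <- ncol(B)
      if (is.finite(uj)) extra_ub[[length(extra_ub) + 1L]] <- c(idx, uj - lj)
      cols[[j]] <- list(idx = idx, sign = 1, shift = lj)
    } else if (is.finite(uj)) {
      # x_j = uj - y
      d <- d - A[, j] * uj
      B <- cbind(B, -A[, j]); cstd <- c(cstd, -cc[j])
      cols[[j]] <- list(idx = ncol(B), sign = -1, shift = uj)
    } else {
      # free: x_j = y+ - y-
      B <- cbind(B, A[, j], -A[, j]); cstd <- c(cstd, cc[j], -cc[j])
      cols[[j]] <- list(idx = c(ncol(B) - 1L, ncol(B)), sign = c(1, -1),
                        shift = 0)
    }
  }
  # upper-bound rows for doubly bounded variables
  for (e in extra_ub) {
    row <- numeric(ncol(B)); row[e[1]] <- 1
    B <- rbind(B, row); d <- c(d, e[2]); is_eq <- c(is_eq, FALSE)
  }
  # slack columns on inequality rows
  for (i in which(!is_eq)) {
    s <- numeric(nrow(B)); s[i] <- 1
    B <- cbind(B, s); cstd <- c(cstd, 0)
  }
  # nonnegative right-hand side
  neg <- d < 0
  if (any(neg)) { B[neg, ] <- -B[neg, , drop = FALSE]; d[neg] <- -d[neg] }

  res <- simplex_two_phase(cstd, B, d, tol = tol)
  if (res$status != "optimal") {
    return(list(x = rep(NA_real_, n), objective = NA_real_,
                status = res$status))
  }
  x <- numeric(n)
  for (j in seq_len(n)) {
    cj <- cols[[j]]
    x[j] <- sum(cj$sign * res$x[cj$idx]) + cj$shift[1]
  }
  obj <- sum(objective * x)
  list(x = x, objective = obj, status = "optimal")
}

# Two-phase tableau simplex for min c'x, Ax = b (b >= 0), x >= 0.
# Bland's rule throughout: slow but cycle-free, fine at this scale.
simplex_two_phase <- function(cc, A, b, tol = 1e-9) {
  m <- nrow(A); n <- ncol(A)
  if (m == 0L) {
    # no constraints: optimum is 0 at origin unless some cost is negative
    if (any(cc < -tol)) return(list(status = "unbounded"))
    return(list(status = "optimal", x = numeric(n)))
  }
  # phase 1: artificial basis
  Tab <- cbind(A, diag(m), b)
  basis <- n + seq_len(m)
  cost1 <- c(numeric(n), rep(1, m))
  out <- simplex_iterate(Tab, basis, cost1, ncol(Tab) - 1L, tol)
  Tab <- out$Tab; basis <- out$basis
  phase1_val <- sum(cost1[basis] * Tab[, ncol(Tab)])
  if (phase1_val > sqrt(tol)) return(list(status = "infeasible"))
  # drive remaining artificials out of the basis or drop redundant rows
  keep <- rep(TRUE, m)
  for (i in seq_len(m)) {
    if (basis[i] > n) {
      piv <- which(abs(Tab[i, seq_len(n)]) > tol)
      if (length(piv) == 0L) { keep[i] <- FALSE; next }
      Tab <- pivot(Tab, i, piv[1]); basis[i] <- piv[1]
    }
  }
  Tab <- Tab[keep, , drop = FALSE]; basis <- basis[keep]
  Tab <- Tab[, c(seq_len(n), ncol(Tab)), drop = FALSE]
  # phase 2
  out <- simplex_iterate(Tab, basis, cc, n, tol)
  if (out$status == "unbounded") return(list(status = "unbounded"))
  x <- numeric(n)
  x[out$basis] <- out$Tab[, ncol(out$Tab)]
  list(status = "optimal", x = x)
}

simplex_iterate <- function(Tab, basis, cost, n_struct, tol) {
  repeat {
    m <- nrow(Tab)
    rhs_col <- ncol(Tab)
    # reduced costs over admissible columns
    cb <- cost[basis]
    red <- cost[seq_len(n_struct)] -
      as.vector(crossprod(Tab[, seq_len(n_struct), drop = FALSE], cb))
    enter_cands <- which(red < -tol)
    if (length(enter_cands) == 0L)
      return(list(Tab = Tab, basis = basis, status = "optimal"))
    enter <- min(enter_cands)  # Bland
    col <- Tab[, enter]
    pos <- which(col > tol)
    if (length(pos) == 0L)
      return(list(Tab = Tab, basis = basis, status = "unbounded"))
    ratio <- Tab[pos, rhs_col] / col[pos]
    rmin <- min(ratio)
    leave_cands <- pos[ratio <= rmin + tol]
    leave <- leave_cands[which.min(basis[leave_cands])]  # Bland
    Tab <- pivot(Tab, leave, enter)
    basis[leave] <- enter
  }
}

pivot <- function(Tab, i, j) {
  Tab[i, ] <- Tab[i, ] / Tab[i, j]
  other <- setdiff(seq_len(nrow(Tab)), i)
  if (length(other))
    Tab[other, ] <- Tab[other, , drop = FALSE] -
      outer(Tab[other, j], Tab[i, ])
  Tab
}
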