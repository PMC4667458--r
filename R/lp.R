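# Dense two-phase tableau simplex with Bland's anti-cycling rule.
# Problems here are small (toy metabolic networks, parsimonious-FBA splits),
# so a dense tableau is simple, deterministic and robust; phase 1 drives
# artificial variables out, redundant rows are dropped, and Bland's rule
# guarantees termination on degenerate vertices.

# min cost.x  s.t.  A x = b (b >= 0), x >= 0
# returns list(status, x, value); status in optimal/infeasible/unbounded
simplex_core <- function(A, b, cost, tol = 1e-9) {
  m <- nrow(A)
  n <- ncol(A)
  tab <- cbind(A, diag(m), b, deparse.level = 0)
  basis <- n + seq_len(m)
  rhs_col <- ncol(tab)

  run_phase <- function(obj) {
    # obj covers all structural + artificial columns
    repeat {
      cb <- obj[basis]
      red <- obj[seq_len(rhs_col - 1L)] -
        as.numeric(cb %*% tab[, seq_len(rhs_col - 1L), drop = FALSE])
      entering <- which(red < -tol)
      if (!length(entering)) return("optimal")
      j <- entering[1L]                              # Bland: lowest index
      col <- tab[, j]
      rows <- which(col > tol)
      if (!length(rows)) return("unbounded")
      ratios <- tab[rows, rhs_col] / col[rows]
      rmin <- min(ratios)
      cand <- rows[ratios <= rmin + tol]
      i <- cand[which.min(basis[cand])]              # Bland on the leaving var
      piv <- tab[i, j]
      tab[i, ] <<- tab[i, ] / piv
      upd <- which(abs(tab[, j]) > 0 & seq_len(m) != i)
      for (r in upd) tab[r, ] <<- tab[r, ] - tab[r, j] * tab[i, ]
      basis[i] <<- j
    }
  }

  # phase 1: minimize the artificial sum
  st <- run_phase(c(rep(0, n), rep(1, m)))
  if (st != "optimal") return(list(status = "infeasible"))
  if (sum(tab[, rhs_col][basis > n]) > 1e-7) return(list(status = "infeasible"))
  # pivot remaining (degenerate) artificials out; drop redundant rows
  keep <- rep(TRUE, m)
  for (i in which(basis > n)) {
    piv_col <- which(abs(tab[i, seq_len(n)]) > tol)
    if (length(piv_col)) {
      j <- piv_col[1L]
      tab[i, ] <- tab[i, ] / tab[i, j]
      for (r in seq_len(m)) {
        if (r != i && abs(tab[r, j]) > 0) tab[r, ] <- tab[r, ] - tab[r, j] * tab[i, ]
      }
      basis[i] <- j
    } else {
      keep[i] <- FALSE                               # redundant constraint
    }
  }
  if (!all(keep)) {
    tab <- tab[keep, , drop = FALSE]
    basis <- basis[keep]
    m <- nrow(tab)
  }
  # phase 2 on the structural columns only (artificials barred by +Inf cost
  # equivalent: zero their columns so they can never price in)
  tab[, n + seq_len(length(keep))] <- 0
  st <- run_phase(c(cost, rep(Inf, rhs_col - 1L - n)))
  if (st == "unbounded") return(list(status = "unbounded"))
  x <- numeric(n)
  x[basis[basis <= n]] <- tab[basis <= n, rhs_col]
  list(status = "optimal", x = x, value = sum(cost * x))
}

#' Solve a bounded linear program
#'
#' Deterministic dense-simplex solver for problems of the form: optimize
#' `obj . x` subject to `Aeq x = beq`, `Age x >= bge`, `lb <= x <= ub`.
#' Variables are shifted to `x - lb >= 0`, finite upper bounds become slack
#' rows, and a two-phase tableau simplex with Bland's rule solves the
#' standard form. Infinite bounds are capped at +/- 1e6 (flux bounds in
#' constraint-based models are conventionally finite).
#'
#' @param obj objective coefficients.
#' @param Aeq,beq equality constraints (may be NULL).
#' @param Age,bge greater-or-equal constraints (may be NULL).
#' @param lb,ub variable bounds.
#' @param maximize logical (default TRUE).
#' @return list with `status` (`"optimal"`, `"infeasible"` or
#'   `"unbounded"`), `objective`, and `x` on the original scale.
#' @keywords internal
solve_lp <- function(obj, Aeq = NULL, beq = NULL, Age = NULL, bge = NULL,
                     lb, ub, maximize = TRUE) {
  n <- length(obj)
  big <- 1e6
  lb <- pmax(lb, -big)
  ub <- pmin(ub, big)
  if (any(lb > ub)) return(list(status = "infeasible", objective = NA_real_, x = NULL))
  # assemble standard form in the shifted variable w = x - lb, plus one
  # surplus column per >= row and one slack column per upper bound
  n_ge <- if (is.null(Age)) 0L else length(bge)
  rows <- list(); rhs <- c()
  add_row <- function(a_struct, a_extra, b) {
    rows[[length(rows) + 1L]] <<- c(a_struct, a_extra)
    rhs <<- c(rhs, b)
  }
  extra <- n_ge + n                       # surplus cols then ub-slack cols
  if (!is.null(Aeq)) {
    Aeq <- matrix(Aeq, ncol = n)
    b2 <- beq - as.numeric(Aeq %*% lb)
    for (i in seq_along(b2)) add_row(Aeq[i, ], numeric(extra), b2[i])
  }
  if (n_ge > 0L) {
    Age <- matrix(Age, ncol = n)
    b2 <- bge - as.numeric(Age %*% lb)
    for (i in seq_along(b2)) {
      surplus <- numeric(extra)
      surplus[i] <- -1
      add_row(Age[i, ], surplus, b2[i])
    }
  }
  d <- ub - lb
  for (j in seq_len(n)) {
    slack <- numeric(extra)
    slack[n_ge + j] <- 1
    a <- numeric(n)
    a[j] <- 1
    add_row(a, slack, d[j])
  }
  A <- do.call(rbind, rows)
  neg <- rhs < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  rhs[neg] <- -rhs[neg]
  cost <- c(if (maximize) -obj else obj, numeric(extra))
  sol <- simplex_core(A, rhs, cost)
  if (sol$status != "optimal") {
    return(list(status = sol$status, objective = NA_real_, x = NULL))
  }
  x <- sol$x[seq_len(n)] + lb
  list(status = "optimal", objective = sum(obj * x), x = x)
}
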