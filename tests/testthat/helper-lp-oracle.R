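# Independent LP oracle: brute-force vertex enumeration for
#   optimize obj.v  s.t.  S v = 0,  lb <= v <= ub  (all bounds finite).
# Every vertex of the polytope fixes at least n - rank(S) variables at a
# bound; enumerate all such choices, solve the remaining square system, and
# keep the feasible ones. Entirely independent of the simplex code path.
lp_vertex_oracle <- function(obj, S, lb, ub, maximize = TRUE) {
  n <- ncol(S)
  r <- qr(S)$rank
  free <- n - r
  best <- NULL
  consider <- function(v) {
    if (max(abs(S %*% v)) > 1e-7) return()
    if (any(v < lb - 1e-7) || any(v > ub + 1e-7)) return()
    val <- sum(obj * v)
    if (is.null(best) || (maximize && val > best) || (!maximize && val < best)) {
      best <<- val
    }
  }
  if (free == 0L) {
    consider(numeric(n))
    return(best)
  }
  combs <- utils::combn(n, free)
  for (ci in seq_len(ncol(combs))) {
    Fx <- combs[, ci]
    K <- setdiff(seq_len(n), Fx)
    SK <- S[, K, drop = FALSE]
    if (qr(SK)$rank < r) next
    for (mask in 0:(2^free - 1)) {
      take_ub <- bitwAnd(mask, 2^(seq_len(free) - 1L)) > 0
      vF <- ifelse(take_ub, ub[Fx], lb[Fx])
      rhs <- -S[, Fx, drop = FALSE] %*% vF
      vK <- tryCatch(qr.solve(SK, rhs), error = function(e) NULL)
      if (is.null(vK)) next
      v <- numeric(n)
      v[Fx] <- vF
      v[K] <- vK
      consider(v)
    }
  }
  best
}

# Random small feasible bounded network: one source, one sink (objective),
# random internal conversions. Zero flux is always feasible; all bounds are
# finite so the LP is bounded.
random_network <- function(n_rxns = 8, n_mets = 4) {
  mets <- sprintf("m%d", seq_len(n_mets))
  rxns <- list(list(id = "SRC", stoich = setNames(1, mets[1]), lb = 0, ub = 10))
  for (j in seq_len(n_rxns - 2L)) {
    from <- sample(mets, 1)
    to <- sample(setdiff(mets, from), 1)
    coef <- sample(1:2, 2, replace = TRUE)
    rev <- runif(1) < 0.3
    rxns[[length(rxns) + 1L]] <-
      list(id = sprintf("R%d", j),
           stoich = setNames(c(-coef[1], coef[2]), c(from, to)),
           lb = if (rev) -10 else 0, ub = sample(c(5, 10, 20), 1))
  }
  rxns[[length(rxns) + 1L]] <-
    list(id = "SINK", stoich = setNames(-1, mets[n_mets]), lb = 0, ub = 50)
  metabolic_model(rxns, id = "random")
}
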