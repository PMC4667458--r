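#' Flux balance analysis
#'
#' Maximizes the flux through `objective_id` subject to steady-state mass
#' balance `S v = 0` and the model's flux bounds.
#'
#' @param model a [metabolic_model()].
#' @param objective_id reaction id to optimize.
#' @param maximize logical (default TRUE).
#' @return a `flux_distribution`: list with `fluxes` (named vector),
#'   `objective_id`, `objective_value` and `status`. An infeasible model
#'   yields `status = "infeasible"` and NA objective rather than an error,
#'   so knockdown screens can record inviability.
#' @export
fba <- function(model, objective_id, maximize = TRUE) {
  if (!(objective_id %in% model$rxns)) stop("unknown objective reaction: ", objective_id)
  obj <- as.numeric(model$rxns == objective_id)
  sol <- solve_lp(obj, Aeq = model$S, beq = numeric(nrow(model$S)),
                  lb = model$lb, ub = model$ub, maximize = maximize)
  fluxes <- if (sol$status == "optimal") setNames(sol$x, model$rxns) else NULL
  structure(list(fluxes = fluxes, objective_id = objective_id,
                 objective_value = sol$objective, status = sol$status),
            class = "flux_distribution")
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat(sprintf("FBA (%s): %s, objective %s\n", x$objective_id, x$status,
              format(x$objective_value)))
  invisible(x)
}

#' Parsimonious flux balance analysis
#'
#' FBA followed by minimization of the total absolute flux at the fixed
#' optimal objective value. The wild-type flux distribution of an FBA
#' optimum is generally non-unique; the parsimonious solution is the
#' conventional deterministic representative and is used to derive
#' knockdown bounds.
#'
#' @inheritParams fba
#' @return a `flux_distribution` (objective value of the primary FBA).
#' @export
pfba <- function(model, objective_id) {
  first <- fba(model, objective_id)
  if (first$status != "optimal") return(first)
  n <- length(model$rxns)
  S <- model$S
  obj_row <- as.numeric(model$rxns == objective_id)
  # v = p - q, p,q >= 0; minimize 1'p + 1'q at fixed objective flux
  Aeq <- rbind(cbind(S, -S), c(obj_row, -obj_row))
  beq <- c(numeric(nrow(S)), first$objective_value)
  lb2 <- numeric(2 * n)
  ub2 <- c(pmax(model$ub, 0), pmax(-model$lb, 0))
  Age <- NULL; bge <- NULL
  pos_lb <- which(model$lb > 0)
  for (j in pos_lb) {
    row <- numeric(2 * n); row[j] <- 1; row[n + j] <- -1
    Age <- rbind(Age, row); bge <- c(bge, model$lb[j])
  }
  neg_ub <- which(model$ub < 0)
  for (j in neg_ub) {
    row <- numeric(2 * n); row[j] <- -1; row[n + j] <- 1
    Age <- rbind(Age, row); bge <- c(bge, -model$ub[j])
  }
  sol <- solve_lp(rep(1, 2 * n), Aeq = Aeq, beq = beq, Age = Age, bge = bge,
                  lb = lb2, ub = ub2, maximize = FALSE)
  if (sol$status != "optimal") return(first)  # keep the plain FBA solution
  v <- sol$x[seq_len(n)] - sol$x[n + seq_len(n)]
  structure(list(fluxes = setNames(v, model$rxns), objective_id = objective_id,
                 objective_value = first$objective_value, status = "optimal"),
            class = "flux_distribution")
}

#' Flux variability analysis at a fixed objective level
#'
#' For each requested reaction, the minimum and maximum flux compatible with
#' holding `objective_id` at `fraction` of its optimal value.
#'
#' @inheritParams fba
#' @param reactions reaction ids to scan (default: all).
#' @param fraction fraction of the optimum enforced as a lower bound on the
#'   objective (default 1, i.e. at the optimum).
#' @return data frame with `rxn`, `min`, `max`.
#' @export
fva <- function(model, objective_id, reactions = model$rxns, fraction = 1) {
  opt <- fba(model, objective_id)
  if (opt$status != "optimal") stop("FVA requires a feasible model")
  fixed <- set_bounds(model, objective_id,
                      lb = fraction * opt$objective_value,
                      ub = model$ub[objective_id])
  res <- lapply(reactions, function(r) {
    lo <- fba(fixed, r, maximize = FALSE)
    hi <- fba(fixed, r, maximize = TRUE)
    data.frame(rxn = r, min = lo$objective_value, max = hi$objective_value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
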