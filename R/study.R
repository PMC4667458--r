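#' Filter-recovery benchmark on a seeded synthetic bundle
#'
#' Simulates a time course, applies the retention rules, and compares the
#' decisions with the planted truth. The false-positive rate is estimated
#' over the flat decoy transcripts (unassigned decoys plus members of flat
#' modules and non-differentially-expressed regulators).
#'
#' @param seed RNG seed.
#' @param sigma log2-ratio noise (default 0.1).
#' @param n_decoys number of unassigned flat decoy transcripts.
#' @return list with `agreement` (fraction of transcripts whose kept/rule
#'   decision matches the plant), `rule_agreement`, `fpr` (false-positive
#'   rate over planted-null transcripts), `n_null`, `n` (total transcripts).
#' @export
filter_recovery_study <- function(seed, sigma = 0.1, n_decoys = 2000L) {
  sim <- simulate_expression(simulation_spec(sigma = sigma,
                                             n_decoys = n_decoys, seed = seed))
  rep <- filter_transcripts(compute_log_ratios(sim$expr))
  m <- merge(rep, sim$truth$transcripts, by = "transcript_id")
  null_tx <- !m$kept.y
  list(agreement = mean(m$kept.x == m$kept.y),
       rule_agreement = mean(m$rule.x == m$rule.y),
       fpr = mean(m$kept.x[null_tx]),
       n_null = sum(null_tx),
       n = nrow(m))
}

#' Wave-recovery benchmark on a noiseless seeded bundle
#'
#' Runs the wave stage on a noiseless simulation and compares dynamics
#' classes and twofold-crossing timestamps with the planted analytic values.
#'
#' @param seed RNG seed.
#' @return list with `class_accuracy`, `direction_accuracy`,
#'   `max_timestamp_err` (minutes), `timestamp_errs` per module, `n_waves`,
#'   and the module comparison table.
#' @export
wave_recovery_study <- function(seed) {
  sim <- simulate_expression(simulation_spec(sigma = 0, n_decoys = 0,
                                             seed = seed))
  ratios <- compute_log_ratios(sim$expr)
  kept <- kept_transcripts(filter_transcripts(ratios))
  res <- build_waves(subset_ratios(ratios, kept), sim$modules)
  m <- merge(res$modules, sim$truth$modules, by = "module_id")
  dyn <- m$dynamics.y != "flat"
  errs <- m$timestamp.x[dyn] - m$timestamp.y[dyn]
  names(errs) <- m$module_id[dyn]
  list(class_accuracy = mean(m$dynamics.x[dyn] == m$dynamics.y[dyn]),
       direction_accuracy = mean(m$direction.x[dyn] == m$direction.y[dyn]),
       max_timestamp_err = max(abs(errs)),
       timestamp_errs = errs,
       n_waves = nrow(res$waves),
       modules = m)
}

#' Influence-recovery benchmark over seeded replicates
#'
#' For each seed: simulate the default bundle (10 planted regulator-module
#' influences with 15-90 min lags and mixed signs among flat decoy
#' regulators and modules), run filtering, module classification and
#' influence inference with default settings, and score the recovered edge
#' set against the plant.
#'
#' @param seeds integer vector of replicate seeds (default 1:10).
#' @param sigma log2-ratio noise (default 0.1).
#' @param n_decoys unassigned decoy transcripts per replicate (default 500).
#' @param window,percentile,lag_step,trn_horizon_min inference settings
#'   (defaults as in [pipeline_config()]).
#' @return list with `per_seed` (data frame: seed, edges, precision, recall,
#'   sign accuracy, max lag error), `lag_errors` (recovered minus planted
#'   lag for every true positive across replicates), and the means
#'   `precision`, `recall`, `sign_accuracy`.
#' @export
trn_recovery_study <- function(seeds = 1:10, sigma = 0.1, n_decoys = 500L,
                               window = lag_window(), percentile = 5,
                               lag_step = 15, trn_horizon_min = 1440) {
  per_seed <- list()
  lag_errors <- c()
  for (seed in seeds) {
    sim <- simulate_expression(simulation_spec(sigma = sigma,
                                               n_decoys = n_decoys,
                                               seed = seed))
    ratios <- compute_log_ratios(sim$expr)
    kept <- kept_transcripts(filter_transcripts(ratios))
    res <- build_waves(subset_ratios(ratios, kept), sim$modules)
    nonflat <- res$modules$module_id[res$modules$dynamics != "flat"]
    times <- expr_times(ratios)
    horizon <- which(res$profiles[[1L]]$time <= trn_horizon_min)
    tr_kept <- intersect(sim$regulators, kept)
    tr_profiles <- lapply(tr_kept, function(id)
      smooth_profile(times, as.numeric(ratios[id, ]))$value[horizon])
    names(tr_profiles) <- tr_kept
    mod_profiles <- lapply(res$profiles[nonflat], function(p) p$value[horizon])
    edges <- infer_influences(tr_profiles, mod_profiles, window = window,
                              percentile = percentile, lag_step = lag_step,
                              eval_times = times[times <= trn_horizon_min])
    truth <- sim$truth$edges
    key <- function(d) paste(d$tr_id, d$module_id)
    tp <- sum(key(edges) %in% key(truth))
    hits <- merge(edges, truth, by = c("tr_id", "module_id"))
    lag_errors <- c(lag_errors, hits$lag_min.x - hits$lag_min.y)
    per_seed[[length(per_seed) + 1L]] <- data.frame(
      seed = seed, n_edges = nrow(edges),
      precision = tp / max(nrow(edges), 1L),
      recall = tp / nrow(truth),
      sign_accuracy = if (nrow(hits)) mean(hits$sign.x == hits$sign.y) else NA,
      max_lag_err = if (nrow(hits)) max(abs(hits$lag_min.x - hits$lag_min.y)) else NA)
  }
  per_seed <- do.call(rbind, per_seed)
  list(per_seed = per_seed,
       lag_errors = lag_errors,
       precision = mean(per_seed$precision),
       recall = mean(per_seed$recall),
       sign_accuracy = mean(per_seed$sign_accuracy))
}

# classed subsetting helper used by the study and pipeline code
subset_ratios <- function(ratios, ids) {
  out <- ratios[rownames(ratios) %in% ids, , drop = FALSE]
  attr(out, "times") <- attr(ratios, "times")
  class(out) <- class(ratios)
  out
}
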