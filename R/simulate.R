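#' Default sampling grid for the simulated starvation time course
#'
#' Minutes since starvation onset: 2-min steps through the first 12 min so
#' that early-stage crossings (12-18 min scale) are resolvable, then
#' progressively sparser sampling out to 48 h, with the four
#' lipid-accumulation timepoints (8, 12, 24, 48 h) at the end.
#'
#' @return numeric vector of times in minutes.
#' @export
default_time_grid <- function() {
  c(0, 2, 4, 6, 8, 10, 12, 18, 24, 30, 45, 60, 120, 240, 480, 720, 1440, 2880)
}

# -- planted profile shapes ---------------------------------------------------

# Monotonic shift to a new steady level: scaled logistic anchored at r(0) = 0,
# with plateau `direction * amplitude` and first threshold crossing at t_cross.
make_monotonic_curve <- function(t_cross, amplitude, direction, thr = 1) {
  if (amplitude <= thr) stop("planted amplitude must exceed the fold threshold")
  s <- max(2, t_cross / 5)
  shape <- function(t, t0) {
    l0 <- 1 / (1 + exp(t0 / s))
    (1 / (1 + exp(-(t - t0) / s)) - l0) / (1 - l0)
  }
  g <- function(t0) amplitude * shape(t_cross, t0) - thr
  t0 <- stats::uniroot(g, lower = 0, upper = t_cross + 40 * s, tol = 1e-10)$root
  function(t) direction * amplitude * shape(t, t0)
}

# Transient pulse returning to baseline: rise times decay, peak scaled to
# `direction * amplitude`, first crossing at t_cross, effectively over well
# before the final sampled time.
make_transient_curve <- function(t_cross, amplitude, direction, thr = 1,
                                 width = NULL) {
  if (amplitude <= thr) stop("planted amplitude must exceed the fold threshold")
  width <- width %||% min(max(150, 4 * t_cross), 1200)
  s1 <- max(2, t_cross / 5)
  s2 <- width / 6
  base <- function(t, t1) {
    (1 / (1 + exp(-(t - t1) / s1))) * (1 / (1 + exp((t - (t1 + width)) / s2)))
  }
  scaled <- function(t, t1) {
    peak <- stats::optimize(function(u) base(u, t1), c(0, t1 + 2 * width),
                            maximum = TRUE)$objective
    amplitude * (base(t, t1) - base(0, t1)) / (peak - base(0, t1))
  }
  g <- function(t1) scaled(t_cross, t1) - thr
  t1 <- stats::uniroot(g, lower = t_cross, upper = t_cross + 30 * s1,
                       tol = 1e-10, extendInt = "downX")$root
  function(t) direction * scaled(t, t1)
}

flat_curve <- function() function(t) rep(0, length(t))

# Exact first |curve| > thr crossing of a planted curve (bracketed root).
true_crossing <- function(curve, thr = 1, t_max = 2880) {
  tt <- seq(0, t_max, by = 0.5)
  v <- abs(curve(tt))
  i <- which(v > thr)[1L]
  if (is.na(i)) stop("planted curve never crosses the threshold")
  if (i == 1L) return(tt[1L])
  stats::uniroot(function(t) abs(curve(t)) - thr, c(tt[i - 1L], tt[i]),
                 tol = 1e-9)$root
}

# -- simulation spec ----------------------------------------------------------

default_module_plan <- function() {
  # planted crossings sit in the densely sampled first hour or at/near
  # sampled timepoints, where a minute-resolution timestamp is identifiable;
  # transitions between 4-h-spaced samples are not resolvable on this grid
  # Influence matching is sign-blind (activation and repression both score)
  # and the lag scan can slide crossings by 15-90 min, so two same-dynamics
  # modules are only separable when no admissible lag aligns their
  # crossings. Four driven modules therefore carry the planted influences
  # (several regulators per module, as in real regulatory programs), and
  # the dynamic decoys sit at the temporal extremes, outside the
  # lag-shiftable band of every driver: the earliest waves precede any
  # regulator effect and the latest changes lack matched regulators.
  plan <- rbind(
    # driven modules (targets of the planted regulator influences)
    data.frame(module_id = sprintf("M%02d", 1:4),
               dynamics = c("monotonic", "transient", "monotonic", "transient"),
               direction = c(1, -1, -1, 1),
               t_cross = c(45, 50, 240, 240),
               amplitude = c(2, 2.5, 2.6, 2.4),
               stringsAsFactors = FALSE),
    # dynamic decoy modules (differentially expressed, not driven)
    data.frame(module_id = sprintf("M%02d", 5:20),
               dynamics = c("monotonic", "transient", "monotonic", "transient",
                            "monotonic", "monotonic", "transient", "transient",
                            "monotonic", "monotonic", "transient", "monotonic",
                            "transient", "monotonic", "transient", "monotonic"),
               direction = c(1, -1, -1, 1, -1, 1, 1, -1, 1, -1, 1, 1,
                             -1, -1, 1, 1),
               t_cross = c(12, 18, 15, 480, 480, 480, 20, 480, 15, 20,
                           18, 12, 480, 480, 20, 480),
               amplitude = c(2.4, 2, 2.6, 2.2, 2, 2.4, 2.8, 2, 2.2, 2.6,
                             2.2, 2, 2.4, 2.8, 2, 2.2),
               stringsAsFactors = FALSE))
  flat <- data.frame(module_id = sprintf("M%02d", 21:60),
                     dynamics = "flat", direction = 0, t_cross = NA_real_,
                     amplitude = 0, stringsAsFactors = FALSE)
  out <- rbind(plan, flat)
  out$n_transcripts <- 10L
  out
}

default_regulator_plan <- function() {
  # ten planted influences over the four driven modules; lags span the full
  # 15-90 min window and each driven module keeps t_cross >= 2.5 * lag so
  # the advanced regulator profile is still quiescent at time zero
  drivers <- data.frame(
    tr_id = sprintf("TR%02d", 1:10),
    module_id = c("M01", "M02", "M03", "M03", "M03", "M03",
                  "M04", "M04", "M04", "M04"),
    lag = c(15, 15, 15, 30, 60, 90, 15, 30, 60, 90),
    sign = c("activation", "repression", "activation", "repression",
             "activation", "repression", "activation", "activation",
             "repression", "activation"),
    stringsAsFactors = FALSE)
  decoys <- data.frame(tr_id = sprintf("TR%02d", 11:20),
                       module_id = NA_character_, lag = NA_real_,
                       sign = NA_character_, stringsAsFactors = FALSE)
  rbind(drivers, decoys)
}

#' Specification of a synthetic starvation time course
#'
#' Defines the planted structure: module dynamics (logistic plateaus for
#' monotonic waves, logistic pulses for transient ones, with exact
#' threshold-crossing times), regulator transcripts leading their driven
#' module by a planted lag (negated for repression), flat decoy modules and
#' regulators emulating the non-differentially-expressed majority, and
#' unassigned flat decoy transcripts. Noise is Gaussian on the log2-ratio
#' scale (multiplicative on FPKM); baselines are drawn log-normally with a
#' floor that keeps the +1 pseudocount and zero-clipping from distorting
#' planted amplitudes.
#'
#' @param times sampling grid in minutes (default [default_time_grid()]).
#' @param modules module plan: data frame with `module_id`, `dynamics`
#'   (`"monotonic"`, `"transient"`, `"flat"`), `direction` (1/-1),
#'   `t_cross` (minutes), `amplitude` (log2 units), `n_transcripts`.
#' @param regulators regulator plan: data frame with `tr_id`, `module_id`
#'   (NA for non-differentially-expressed decoy regulators), `lag` (minutes),
#'   `sign` (`"activation"`/`"repression"`).
#' @param n_decoys number of unassigned flat decoy transcripts (default 500).
#' @param sigma noise standard deviation on the log2-ratio scale (default 0.1).
#' @param baseline_meanlog,baseline_sdlog log-normal baseline FPKM parameters
#'   (default meanlog log(20), sdlog 1).
#' @param fold_threshold log2 threshold the plants are calibrated against
#'   (default 1).
#' @param seed mandatory RNG seed.
#' @return a `simulation_spec` list.
#' @export
simulation_spec <- function(times = default_time_grid(),
                            modules = default_module_plan(),
                            regulators = default_regulator_plan(),
                            n_decoys = 500L, sigma = 0.1,
                            baseline_meanlog = log(20), baseline_sdlog = 1,
                            fold_threshold = 1, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (sigma < 0) stop("sigma must be >= 0")
  dyn <- modules$dynamics != "flat"
  if (any(dyn & modules$amplitude <= fold_threshold)) {
    stop("planted dynamic modules need amplitude > fold_threshold")
  }
  if (any(dyn & (modules$t_cross <= 0 | modules$t_cross >= max(times)))) {
    stop("planted crossing times must lie inside the sampled span")
  }
  drv <- !is.na(regulators$module_id)
  if (!all(regulators$module_id[drv] %in% modules$module_id)) {
    stop("regulator plan references unknown modules")
  }
  structure(list(times = times, modules = modules, regulators = regulators,
                 n_decoys = as.integer(n_decoys), sigma = sigma,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 fold_threshold = fold_threshold, seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Simulate an FPKM time course with planted waves and lagged regulators
#'
#' Builds the noiseless planted log2-ratio curves, reconstructs FPKM as
#' `x_t = (x_0 + 1) * 2^(r + eps) - 1` (clipped at 0) with
#' `eps ~ Normal(0, sigma)` and `eps = 0` at the reference sample, and
#' returns the expression matrix together with module membership, the
#' regulator list and the full ground truth.
#'
#' @param spec a [simulation_spec()].
#' @return list with `expr` ([expression_matrix()]), `modules` (named list
#'   module id -> transcript ids), `regulators` (character vector of
#'   regulator transcript ids), and `truth` (list of data frames:
#'   `transcripts` with expected filter outcome, `modules` with planted
#'   class/direction/exact crossing time, `edges` with the planted
#'   regulator-module influences).
#' @export
simulate_expression <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  times <- spec$times
  thr <- spec$fold_threshold
  mods <- spec$modules
  regs <- spec$regulators

  curves <- vector("list", nrow(mods))
  names(curves) <- mods$module_id
  t_true <- rep(NA_real_, nrow(mods))
  for (i in seq_len(nrow(mods))) {
    curves[[i]] <- switch(mods$dynamics[i],
      flat = flat_curve(),
      monotonic = make_monotonic_curve(mods$t_cross[i], mods$amplitude[i],
                                       mods$direction[i], thr),
      transient = make_transient_curve(mods$t_cross[i], mods$amplitude[i],
                                       mods$direction[i], thr),
      stop("unknown dynamics class: ", mods$dynamics[i]))
    if (mods$dynamics[i] != "flat") {
      t_true[i] <- true_crossing(curves[[i]], thr, max(times))
    }
  }

  ids <- character(0); curve_rows <- list(); row_module <- character(0)
  modules_out <- list()
  for (i in seq_len(nrow(mods))) {
    tid <- sprintf("%s_T%02d", mods$module_id[i], seq_len(mods$n_transcripts[i]))
    modules_out[[mods$module_id[i]]] <- tid
    for (id in tid) {
      ids <- c(ids, id)
      curve_rows[[id]] <- curves[[i]](times)
      row_module <- c(row_module, mods$module_id[i])
    }
  }
  # regulator transcripts: driven module's curve advanced by the lag,
  # negated for repression, re-anchored so r(0) = 0
  for (k in seq_len(nrow(regs))) {
    id <- regs$tr_id[k]
    ids <- c(ids, id)
    row_module <- c(row_module, NA_character_)
    if (is.na(regs$module_id[k])) {
      curve_rows[[id]] <- rep(0, length(times))
    } else {
      cm <- curves[[regs$module_id[k]]]
      sgn <- if (regs$sign[k] == "repression") -1 else 1
      curve_rows[[id]] <- sgn * (cm(times + regs$lag[k]) - cm(regs$lag[k]))
    }
  }
  if (spec$n_decoys > 0L) {
    did <- sprintf("DECOY%04d", seq_len(spec$n_decoys))
    ids <- c(ids, did)
    row_module <- c(row_module, rep(NA_character_, spec$n_decoys))
    for (id in did) curve_rows[[id]] <- rep(0, length(times))
  }

  r <- do.call(rbind, curve_rows[ids])
  rownames(r) <- ids
  # baseline floor keeps downregulated trajectories clear of the zero clip
  min_r <- pmin(0, apply(r, 1L, min))
  x0 <- 2^(-min_r + 1) + stats::rlnorm(length(ids), spec$baseline_meanlog,
                                       spec$baseline_sdlog)
  eps <- matrix(stats::rnorm(length(r), 0, spec$sigma), nrow(r), ncol(r))
  eps[, times == 0] <- 0
  x <- pmax((x0 + 1) * 2^(r + eps) - 1, 0)
  rownames(x) <- ids
  expr <- expression_matrix(x, times)

  # expected filter outcome from the analytic plants: every dynamic plant
  # holds |r| > thr over a same-sign sampled run spanning >= 30 min (rule 2);
  # rule 1 additionally requires strict exceedance at all lipid timepoints
  dyn <- mods$dynamics != "flat"
  lipid_tp <- c(480, 720, 1440, 2880)
  rule_of_curve <- function(curve) {
    if (all(abs(curve(lipid_tp)) > thr)) "both" else "2"
  }
  expected_rule <- rep("none", nrow(mods))
  expected_rule[dyn] <- vapply(curves[dyn], rule_of_curve, character(1L))
  drv <- !is.na(regs$module_id)
  tr_rule <- setNames(rep("none", nrow(regs)), regs$tr_id)
  tr_rule[drv] <- vapply(which(drv), function(k) {
    cm <- curves[[regs$module_id[k]]]
    rule_of_curve(function(t) cm(t + regs$lag[k]) - cm(regs$lag[k]))
  }, character(1L))
  rule_all <- c(rep(expected_rule, mods$n_transcripts),   # module members, in id order
                unname(tr_rule),                           # regulator transcripts
                rep("none", spec$n_decoys))                # unassigned decoys
  truth_tx <- data.frame(
    transcript_id = ids,
    module_id = row_module,
    kept = rule_all != "none",
    rule = rule_all,
    stringsAsFactors = FALSE, row.names = NULL)
  truth_modules <- data.frame(
    module_id = mods$module_id,
    dynamics = mods$dynamics,
    direction = ifelse(dyn, ifelse(mods$direction > 0, "up", "down"), NA),
    timestamp = t_true,
    amplitude = mods$amplitude,
    stringsAsFactors = FALSE, row.names = NULL)
  truth_edges <- data.frame(
    tr_id = regs$tr_id[drv], module_id = regs$module_id[drv],
    lag_min = regs$lag[drv], sign = regs$sign[drv],
    stringsAsFactors = FALSE, row.names = NULL)

  list(expr = expr, modules = modules_out, regulators = regs$tr_id,
       truth = list(transcripts = truth_tx, modules = truth_modules,
                    edges = truth_edges),
       spec = spec)
}

#' Hand-solvable toy metabolic models for the knockdown screen
#'
#' Three fixture topologies whose knockdown outcomes are solvable by hand:
#' \describe{
#'   \item{chain}{`SRC -> A -> B`, with both `BM_TAG` and `EX_TAG` consuming
#'     B. Knocking down either gene caps both objectives at `1/kd_factor`
#'     of wild type, so the biomass ratio is 1/16 under the default factor —
#'     below the 10 % viability floor (rho undefined, ratio of ratios 1).}
#'   \item{branch}{Biomass requires B and C, TAG only B. Ground truth uses
#'     `kd_factor = 2`: knocking down the sole C-producing gene halves
#'     biomass while TAG is untouched, so rho = 2 and the cell stays viable;
#'     the B-branch gene gives rho = 0.5, the shared source gene rho = 1.}
#'   \item{isozyme}{One step carries GPR `"g1 or g2"`: a single-gene
#'     knockdown is rescued under boolean GPR evaluation, so rho = 1.}
#' }
#'
#' @param kind `"chain"`, `"branch"` or `"isozyme"`.
#' @return list with `model` (a [metabolic_model()]), `cfg` (the
#'   [knockdown_config()] the ground truth is solved for) and `truth`
#'   (data frame: `gene`, `rho`, `bm_ratio`, `tag_ratio`, `viable`).
#' @export
toy_metabolic_model <- function(kind = c("chain", "branch", "isozyme")) {
  kind <- match.arg(kind)
  if (kind == "chain") {
    model <- metabolic_model(list(
      list(id = "SRC", stoich = c(A = 1), lb = 0, ub = 10, gpr = "gS"),
      list(id = "R1", stoich = c(A = -1, B = 1), gpr = "g1"),
      list(id = "BM_TAG", stoich = c(B = -1)),
      list(id = "EX_TAG", stoich = c(B = -1))),
      id = "toy_chain", bm_tag = "BM_TAG", ex_tag = "EX_TAG")
    cfg <- knockdown_config(kd_factor = 16)
    truth <- data.frame(gene = c("g1", "gS"), rho = NA_real_,
                        bm_ratio = 1 / 16, tag_ratio = 1 / 16, viable = FALSE,
                        stringsAsFactors = FALSE)
  } else if (kind == "branch") {
    model <- metabolic_model(list(
      list(id = "SRC", stoich = c(A = 1), lb = 0, ub = 10, gpr = "gS"),
      list(id = "RB", stoich = c(A = -1, B = 1), gpr = "gB"),
      list(id = "RC", stoich = c(A = -1, C = 1), gpr = "gC"),
      list(id = "BM_TAG", stoich = c(B = -1, C = -1)),
      list(id = "EX_TAG", stoich = c(B = -1))),
      id = "toy_branch", bm_tag = "BM_TAG", ex_tag = "EX_TAG")
    cfg <- knockdown_config(kd_factor = 2)
    truth <- data.frame(gene = c("gB", "gC", "gS"), rho = c(0.5, 2, 1),
                        bm_ratio = 0.5, tag_ratio = c(0.25, 1, 0.5),
                        viable = TRUE, stringsAsFactors = FALSE)
  } else {
    model <- metabolic_model(list(
      list(id = "SRC", stoich = c(A = 1), lb = 0, ub = 10),
      list(id = "R1", stoich = c(A = -1, B = 1), gpr = "g1 or g2"),
      list(id = "BM_TAG", stoich = c(B = -1)),
      list(id = "EX_TAG", stoich = c(B = -1))),
      id = "toy_isozyme", bm_tag = "BM_TAG", ex_tag = "EX_TAG")
    cfg <- knockdown_config(kd_factor = 16)
    truth <- data.frame(gene = c("g1", "g2"), rho = 1, bm_ratio = 1,
                        tag_ratio = 1, viable = TRUE, stringsAsFactors = FALSE)
  }
  list(model = model, cfg = cfg, truth = truth)
}
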