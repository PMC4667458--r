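#' Read a module membership table
#'
#' Two-column TSV (`module_id`, `transcript_id`), one row per membership;
#' transcripts may belong to several modules.
#'
#' @param path file path.
#' @return named list: module id -> character vector of transcript ids.
#' @export
read_module_tsv <- function(path) {
  d <- read_tsv_body(path)
  if (!all(c("module_id", "transcript_id") %in% names(d))) {
    stop("module table needs columns module_id, transcript_id")
  }
  split(d$transcript_id, d$module_id)
}

#' Read a one- or two-column gene/transcript list
#' @param path TSV path; first column is the id, further columns are ignored.
#' @return character vector of unique ids.
#' @export
read_id_list <- function(path) {
  d <- read_tsv_body(path)
  unique(as.character(d[[1L]]))
}

#' Pipeline configuration
#'
#' Bundles every stage's inputs and settings. Inputs may be given as file
#' paths (read with the package readers) or as in-memory objects; stages
#' whose inputs are absent are skipped.
#'
#' @param expr expression matrix (path or [expression_matrix()]); required.
#' @param modules module membership (path or named list); enables the wave
#'   and regulator stages.
#' @param regulators regulator transcript ids (path or character vector);
#'   enables the influence stage.
#' @param model metabolic model (path to JSON/SBML or [metabolic_model()]);
#'   enables the knockdown stage.
#' @param candidate_genes genes to screen (path or character vector;
#'   default: all model genes).
#' @param s_down,p_down genes downregulated under sulfur / phosphorus
#'   starvation (path or character vector), for overlap classification.
#' @param filter a [filter_config()].
#' @param fold_threshold log2 crossing threshold for waves (default 1).
#' @param grid_step dense grid step in minutes (default 1).
#' @param smooth_p smoothing weight (default NULL = GCV).
#' @param window a [lag_window()].
#' @param percentile influence acceptance percentile (default 5).
#' @param lag_step lag scan resolution in minutes (default 15).
#' @param trn_horizon_min influence distances are computed on the dense grid
#'   restricted to `[0, trn_horizon_min]` (default 1440: transient pulses
#'   have returned to baseline by 24 h, so the window spans the full
#'   dynamics; beyond it all profiles sit at their final levels and the
#'   shared saturated tail carries no discriminating signal).
#' @param kd a [knockdown_config()].
#' @param outdir output directory (created if missing).
#' @param seed RNG seed recorded in the manifest (the pipeline itself is
#'   deterministic given its inputs).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(expr, modules = NULL, regulators = NULL,
                            model = NULL, candidate_genes = NULL,
                            s_down = NULL, p_down = NULL,
                            filter = filter_config(), fold_threshold = 1,
                            grid_step = 1, smooth_p = NULL,
                            window = lag_window(), percentile = 5,
                            lag_step = 15, trn_horizon_min = 1440,
                            kd = knockdown_config(), outdir, seed = 1L) {
  if (missing(outdir)) stop("outdir is required")
  structure(list(expr = expr, modules = modules, regulators = regulators,
                 model = model, candidate_genes = candidate_genes,
                 s_down = s_down, p_down = p_down, filter = filter,
                 fold_threshold = fold_threshold, grid_step = grid_step,
                 smooth_p = smooth_p, window = window, percentile = percentile,
                 lag_step = lag_step, trn_horizon_min = trn_horizon_min, kd = kd,
                 outdir = outdir, seed = as.integer(seed)),
            class = "pipeline_config")
}

resolve_input <- function(x, reader) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1L && file.exists(x)) reader(x) else x
}

#' Run the full analysis pipeline
#'
#' Executes filtering -> waves -> regulator influences -> knockdown screen,
#' writing every intermediate table under `cfg$outdir` with parameter header
#' comments, plus a `manifest.json` recording package version, parameters,
#' completed stages and MD5 hashes of every output. Outputs are
#' deterministic: identical inputs, configuration and seed give
#' byte-identical files.
#'
#' @param cfg a [pipeline_config()].
#' @param quiet suppress per-stage progress messages (default FALSE; messages
#'   go to stderr).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  t_start <- proc.time()[["elapsed"]]
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)
  out <- function(f) file.path(cfg$outdir, f)
  stages <- character(0)
  files <- character(0)

  expr <- resolve_input(cfg$expr, read_expression_tsv)
  if (!inherits(expr, "expr_matrix")) expr <- expression_matrix(expr)
  times <- expr_times(expr)

  # -- stage 1: log ratios and differential-expression filter
  ratios <- compute_log_ratios(expr)
  write_matrix_tsv(ratios, out("log_ratios.tsv"),
                   list(stage = "log_ratios", pseudocount = 1))
  report <- filter_transcripts(ratios, cfg$filter)
  write_tsv_with_header(report, out("filter_report.tsv"),
                        list(stage = "filter",
                             fold_threshold = cfg$filter$fold_threshold,
                             lipid_timepoints = cfg$filter$lipid_timepoints,
                             min_period = cfg$filter$min_period,
                             lipid_rule_mode = cfg$filter$lipid_rule_mode))
  kept <- kept_transcripts(report)
  stages <- c(stages, "filter")
  files <- c(files, "log_ratios.tsv", "filter_report.tsv")
  say("filter: kept %d / %d transcripts", length(kept), nrow(ratios))

  # -- stage 2: waves
  modules <- resolve_input(cfg$modules, read_module_tsv)
  waves_res <- NULL
  if (!is.null(modules)) {
    waves_res <- build_waves(subset_ratios(ratios, kept), modules,
                             fold_threshold = cfg$fold_threshold,
                             grid_step = cfg$grid_step, p = cfg$smooth_p)
    write_tsv_with_header(waves_res$modules, out("module_classes.tsv"),
                          list(stage = "waves", fold_threshold = cfg$fold_threshold,
                               grid_step = cfg$grid_step,
                               smoothing = cfg$smooth_p %||% "gcv"))
    write_tsv_with_header(waves_res$waves, out("waves.tsv"),
                          list(stage = "waves", fold_threshold = cfg$fold_threshold))
    stages <- c(stages, "waves")
    files <- c(files, "module_classes.tsv", "waves.tsv")
    say("waves: %d waves from %d non-flat modules", nrow(waves_res$waves),
        sum(waves_res$modules$dynamics != "flat"))
  } else say("waves: skipped (no module membership)")

  # -- stage 3: regulator influences
  regulators <- resolve_input(cfg$regulators, read_id_list)
  edges <- NULL
  if (!is.null(regulators) && !is.null(waves_res)) {
    tr_kept <- intersect(regulators, kept)
    nonflat <- waves_res$modules$module_id[waves_res$modules$dynamics != "flat"]
    horizon <- which(waves_res$profiles[[1L]]$time <= cfg$trn_horizon_min)
    tr_profiles <- lapply(tr_kept, function(id) {
      smooth_profile(times, as.numeric(ratios[id, ]),
                     grid_step = cfg$grid_step, p = cfg$smooth_p,
                     id = id)$value[horizon]
    })
    names(tr_profiles) <- tr_kept
    mod_profiles <- lapply(waves_res$profiles[nonflat],
                           function(p) p$value[horizon])
    if (length(tr_profiles) && length(mod_profiles)) {
      edges <- infer_influences(tr_profiles, mod_profiles,
                                window = cfg$window,
                                percentile = cfg$percentile,
                                lag_step = cfg$lag_step,
                                grid_step = cfg$grid_step,
                                eval_times = times[times <= cfg$trn_horizon_min])
      write_tsv_with_header(edges, out("influences.tsv"),
                            list(stage = "trn", window = c(cfg$window$min_lag,
                                                           cfg$window$max_lag),
                                 percentile = cfg$percentile,
                                 horizon_min = cfg$trn_horizon_min,
                                 n_regulators = length(tr_profiles),
                                 n_modules = length(mod_profiles)))
      stages <- c(stages, "trn")
      files <- c(files, "influences.tsv")
      say("trn: %d influences from %d regulators x %d modules",
          nrow(edges), length(tr_profiles), length(mod_profiles))
    } else say("trn: skipped (no differentially expressed regulator or module)")
  } else say("trn: skipped (needs regulators and modules)")

  # -- stage 4: knockdown screen
  model <- resolve_input(cfg$model, function(p) {
    if (grepl("\\.xml$|\\.sbml$", p, ignore.case = TRUE)) read_sbml_model(p)
    else load_model_json(p)
  })
  if (!is.null(model)) {
    candidates <- resolve_input(cfg$candidate_genes, read_id_list) %||% model$genes
    screen <- screen_targets(model, candidates, cfg$kd)
    write_tsv_with_header(screen, out("knockdown_screen.tsv"),
                          list(stage = "knockdown", kd_factor = cfg$kd$kd_factor,
                               viability_fraction = cfg$kd$viability_fraction,
                               gpr_mode = cfg$kd$gpr_mode,
                               unmapped = length(attr(screen, "unmapped"))))
    stages <- c(stages, "knockdown")
    files <- c(files, "knockdown_screen.tsv")
    say("knockdown: %d targets (rho > 1) of %d screened genes",
        sum(screen$target), nrow(screen))
    s_down <- resolve_input(cfg$s_down, read_id_list)
    p_down <- resolve_input(cfg$p_down, read_id_list)
    if (!is.null(s_down) || !is.null(p_down)) {
      overlap <- classify_condition_overlap(screen$gene[screen$target],
                                            s_down %||% character(0),
                                            p_down %||% character(0))
      write_tsv_with_header(overlap, out("condition_overlap.tsv"),
                            list(stage = "overlap"))
      stages <- c(stages, "overlap")
      files <- c(files, "condition_overlap.tsv")
    }
  } else say("knockdown: skipped (no metabolic model)")

  manifest <- list(
    package = "tagwave",
    version = as.character(utils::packageVersion("tagwave")),
    seed = cfg$seed,
    parameters = list(
      fold_threshold = cfg$filter$fold_threshold,
      lipid_timepoints = cfg$filter$lipid_timepoints,
      min_period = cfg$filter$min_period,
      lipid_rule_mode = cfg$filter$lipid_rule_mode,
      grid_step = cfg$grid_step,
      smoothing = cfg$smooth_p %||% "gcv",
      lag_window = c(cfg$window$min_lag, cfg$window$max_lag),
      percentile = cfg$percentile,
      lag_step = cfg$lag_step,
      trn_horizon_min = cfg$trn_horizon_min,
      kd_factor = cfg$kd$kd_factor,
      viability_fraction = cfg$kd$viability_fraction,
      gpr_mode = cfg$kd$gpr_mode),
    stages = stages,
    files = as.list(setNames(unname(tools::md5sum(file.path(cfg$outdir, files))),
                             files)))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  say("pipeline: %d stages complete in %.1f s", length(stages),
      proc.time()[["elapsed"]] - t_start)
  invisible(manifest)
}
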