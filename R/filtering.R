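#' Differential-expression filter settings
#'
#' Two retention rules operate on the log2-ratio matrix. Rule 1 keeps a
#' transcript whose absolute log2 ratio exceeds `fold_threshold` at the
#' lipid-accumulation timepoints (8, 12, 24 and 48 h by default); under the
#' default `lipid_rule_mode = "all"` the threshold must be exceeded at all of
#' them, under `"any"` at one or more. Signs need not agree across those
#' timepoints. Rule 2 keeps a transcript whose ratio exceeds the threshold
#' with constant sign over a run of consecutive sampled timepoints spanning at
#' least `min_period` minutes; a single isolated timepoint never qualifies.
#'
#' @param fold_threshold log2 units, strictly exceeded; default 1 (twofold).
#' @param lipid_timepoints minutes; default `c(480, 720, 1440, 2880)`.
#' @param min_period minimum span (last minus first sampled time of the run)
#'   in minutes; default 30.
#' @param lipid_rule_mode `"all"` (default) or `"any"`.
#' @return a `filter_config` list.
#' @export
filter_config <- function(fold_threshold = 1,
                          lipid_timepoints = c(480, 720, 1440, 2880),
                          min_period = 30,
                          lipid_rule_mode = c("all", "any")) {
  lipid_rule_mode <- match.arg(lipid_rule_mode)
  if (fold_threshold <= 0) stop("fold_threshold must be > 0")
  if (min_period <= 0) stop("min_period must be > 0")
  structure(list(fold_threshold = fold_threshold,
                 lipid_timepoints = sort(lipid_timepoints),
                 min_period = min_period,
                 lipid_rule_mode = lipid_rule_mode),
            class = "filter_config")
}

# First sampled time of the earliest same-sign run with |r| > thr spanning
# >= min_period minutes, or NA if no run qualifies.
first_qualifying_run <- function(r, times, thr, min_period) {
  best <- NA_real_
  for (s in c(1, -1)) {
    above <- if (s > 0) r > thr else r < -thr
    if (!any(above)) next
    runs <- rle(above)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    ok <- runs$values & (times[ends] - times[starts]) >= min_period
    if (any(ok)) {
      cand <- times[starts[which(ok)[1L]]]
      if (is.na(best) || cand < best) best <- cand
    }
  }
  best
}

#' Apply the two differential-expression retention rules
#'
#' @param ratios a `log_ratio_matrix` from [compute_log_ratios()].
#' @param cfg a [filter_config()].
#' @return a data frame (one row per transcript) with columns
#'   `transcript_id`, `kept`, `rule` (`"1"`, `"2"`, `"both"` or `"none"`) and
#'   `first_pass_time_min` (earliest timepoint anchoring a firing rule, NA if
#'   none fired). The kept transcript ids are also available via
#'   `attr(, "kept")`.
#' @export
filter_transcripts <- function(ratios, cfg = filter_config()) {
  if (!inherits(ratios, "log_ratio_matrix")) stop("ratios must be a log_ratio_matrix")
  if (nrow(ratios) == 0L) stop("empty log-ratio matrix")
  times <- expr_times(ratios)
  if (!all(cfg$lipid_timepoints %in% times)) {
    stop("lipid_timepoints must all be present in the sampled times")
  }
  thr <- cfg$fold_threshold
  lip <- match(cfg$lipid_timepoints, times)
  lip_above <- abs(ratios[, lip, drop = FALSE]) > thr
  rule1 <- if (cfg$lipid_rule_mode == "all") {
    rowSums(lip_above) == length(lip)
  } else {
    rowSums(lip_above) > 0L
  }
  rule1_first <- apply(ratios[, lip, drop = FALSE], 1L, function(r) {
    i <- which(abs(r) > thr)
    if (length(i)) cfg$lipid_timepoints[i[1L]] else NA_real_
  })
  rule2_first <- apply(unclass(ratios), 1L, first_qualifying_run,
                       times = times, thr = thr, min_period = cfg$min_period)
  rule2 <- !is.na(rule2_first)
  rule <- ifelse(rule1 & rule2, "both",
                 ifelse(rule1, "1", ifelse(rule2, "2", "none")))
  first_pass <- pmin(ifelse(rule1, rule1_first, NA_real_),
                     rule2_first, na.rm = TRUE)
  first_pass[rule == "none"] <- NA_real_
  rep <- data.frame(transcript_id = rownames(ratios),
                    kept = rule != "none",
                    rule = rule,
                    first_pass_time_min = as.numeric(first_pass),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(rep, "kept") <- rep$transcript_id[rep$kept]
  attr(rep, "config") <- cfg
  rep
}

#' Transcript ids retained by a filter report
#' @param report a report from [filter_transcripts()].
#' @return character vector of kept transcript ids.
#' @export
kept_transcripts <- function(report) attr(report, "kept")
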