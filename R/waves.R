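#' Mean log2-ratio profile of a transcript module
#'
#' Unweighted arithmetic mean over the module's member transcripts at each
#' sampled timepoint. Members absent from the matrix are ignored; an empty
#' intersection is an error.
#'
#' @param ratios a `log_ratio_matrix`.
#' @param members character vector of member transcript ids.
#' @return numeric vector of per-timepoint means, named by time.
#' @export
module_mean_profile <- function(ratios, members) {
  hit <- intersect(members, rownames(ratios))
  if (!length(hit)) stop("no module member found in the log-ratio matrix")
  colMeans(ratios[hit, , drop = FALSE])
}

#' Cubic smoothing spline on a dense minute grid
#'
#' Two-step smoothing of a sampled log2-ratio profile: a cubic smoothing
#' spline denoises the profile at the sampled times, and a shape-preserving
#' monotone Hermite interpolant carries the denoised values onto a dense
#' grid covering `[0, max(times)]`. The shape-preserving resampling step
#' avoids the over- and undershoot a global cubic produces between sparsely
#' sampled late timepoints, which would otherwise distort threshold
#' crossings and lag estimates.
#'
#' The smoothing weight `p` follows the csaps convention: `p = 1` is the
#' interpolation limit (the curve passes through the samples), smaller
#' values smooth harder (internally `lambda = (1 - p) / p`). With
#' `p = NULL` (default) the penalty is picked automatically by generalized
#' cross-validation; when GCV degenerates (noise-free data drives the
#' optimal penalty below the representable range) the fit falls back to the
#' interpolation limit, which is the GCV limit for noiseless samples.
#'
#' @param times sampled times in minutes, strictly increasing, >= 4 points.
#' @param values log2 ratios at `times`.
#' @param grid_step dense grid step in minutes (default 1).
#' @param p smoothing weight in (0, 1], or NULL for automatic selection.
#' @param id optional profile identifier carried through to outputs.
#' @return a `smooth_profile`: list with `time`, `value`, `p` (the setting
#'   used: a number or `"gcv"`/`"interpolate"`), `id`.
#' @export
smooth_profile <- function(times, values, grid_step = 1, p = NULL, id = NULL) {
  if (length(times) < 4L) stop("need at least 4 timepoints to smooth")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (length(values) != length(times)) stop("times and values differ in length")
  grid <- seq(min(times), max(times), by = grid_step)
  if (grid[length(grid)] < max(times)) grid <- c(grid, max(times))
  denoised <- if (is.null(p)) {
    tryCatch(list(y = stats::predict(stats::smooth.spline(times, values,
                                                          cv = FALSE),
                                     times)$y, p = "gcv"),
             error = function(e) list(y = values, p = "interpolate"))
  } else if (p >= 1) {
    list(y = values, p = "interpolate")
  } else {
    if (p <= 0) stop("p must be in (0, 1]")
    list(y = stats::predict(stats::smooth.spline(times, values,
                                                 lambda = (1 - p) / p),
                            times)$y, p = p)
  }
  f <- stats::splinefun(times, denoised$y, method = "monoH.FC")
  structure(list(time = grid, value = f(grid), p = denoised$p, id = id),
            class = "smooth_profile")
}

#' @export
print.smooth_profile <- function(x, ...) {
  cat(sprintf("smooth profile%s: %d grid points over [%g, %g] min (p = %s)\n",
              if (is.null(x$id)) "" else paste0(" ", x$id),
              length(x$time), min(x$time), max(x$time), format(x$p)))
  invisible(x)
}

#' Classify the dynamics of a smoothed module profile
#'
#' A profile whose absolute smoothed ratio never exceeds `fold_threshold` is
#' `flat`. Otherwise the direction (`up`/`down`) is the sign at the first
#' threshold crossing, and the profile is `transient` if it has returned to
#' within the threshold band by the final grid point, `monotonic` if it holds
#' a new level beyond the threshold.
#'
#' @param sp a [smooth_profile()].
#' @param fold_threshold log2 threshold (default 1, i.e. twofold).
#' @return list with `dynamics` (`"monotonic"`, `"transient"` or `"flat"`)
#'   and `direction` (`"up"`, `"down"` or NA for flat profiles).
#' @export
classify_dynamics <- function(sp, fold_threshold = 1) {
  v <- sp$value
  i <- which(abs(v) > fold_threshold)
  if (!length(i)) return(list(dynamics = "flat", direction = NA_character_))
  direction <- if (v[i[1L]] > 0) "up" else "down"
  dynamics <- if (abs(v[length(v)]) < fold_threshold) "transient" else "monotonic"
  list(dynamics = dynamics, direction = direction)
}

#' Twofold-crossing timestamp of a smoothed profile
#'
#' Earliest time at which the absolute smoothed log2 ratio exceeds
#' `fold_threshold`, refined linearly between the bracketing grid points.
#'
#' @inheritParams classify_dynamics
#' @return crossing time in minutes.
#' @export
crossing_timestamp <- function(sp, fold_threshold = 1) {
  a <- abs(sp$value)
  i <- which(a > fold_threshold)
  if (!length(i)) stop("profile never crosses the threshold (flat)")
  i <- i[1L]
  if (i == 1L) return(sp$time[1L])
  t0 <- sp$time[i - 1L]; t1 <- sp$time[i]
  a0 <- a[i - 1L]; a1 <- a[i]
  t0 + (fold_threshold - a0) / (a1 - a0) * (t1 - t0)
}

#' Stage scheme for the starvation response timeline
#'
#' Early/mid/late boundaries in minutes. Boundaries are closed on the upper
#' side: a crossing at exactly 18 min is early, at exactly 60 min mid.
#' Timestamps beyond `late_max` are still labelled late.
#'
#' @param early_max upper bound of the early stage (default 18 min).
#' @param mid_max upper bound of the mid stage (default 60 min).
#' @param late_max nominal upper bound of the late stage (default 480 min).
#' @return a `stage_scheme` list.
#' @export
stage_scheme <- function(early_max = 18, mid_max = 60, late_max = 480) {
  if (!(0 < early_max && early_max < mid_max && mid_max < late_max)) {
    stop("stage boundaries must be increasing and positive")
  }
  structure(list(early_max = early_max, mid_max = mid_max, late_max = late_max),
            class = "stage_scheme")
}

#' Assign a stage label to a crossing timestamp
#'
#' @param timestamp crossing time in minutes (vectorized), >= 0.
#' @param scheme a [stage_scheme()].
#' @return character vector of `"early"`, `"mid"` or `"late"`.
#' @export
assign_stage <- function(timestamp, scheme = stage_scheme()) {
  if (any(timestamp < 0)) stop("timestamps must be non-negative")
  ifelse(timestamp <= scheme$early_max, "early",
         ifelse(timestamp <= scheme$mid_max, "mid", "late"))
}

#' Group classified modules into transcriptional waves
#'
#' Modules sharing dynamics class, direction, and twofold-crossing timestamp
#' (quantized to the sampled timepoint at or before the crossing) form one
#' wave. Waves are ordered by quantized timestamp, then dynamics, then
#' direction.
#'
#' @param module_table data frame with columns `module_id`, `dynamics`,
#'   `direction`, `timestamp` (minutes); flat modules must be excluded
#'   beforehand.
#' @param sampled_times the original sampling grid in minutes.
#' @return the table with added columns `quantized_time` and `wave_id`.
#' @export
group_into_waves <- function(module_table, sampled_times) {
  if (nrow(module_table) == 0L) {
    module_table$quantized_time <- numeric(0)
    module_table$wave_id <- character(0)
    return(module_table)
  }
  sampled_times <- sort(sampled_times)
  q <- vapply(module_table$timestamp, function(ts) {
    at_or_before <- sampled_times[sampled_times <= ts]
    if (!length(at_or_before)) sampled_times[1L] else max(at_or_before)
  }, numeric(1L))
  module_table$quantized_time <- q
  key <- paste(module_table$dynamics, module_table$direction, q, sep = "|")
  ord_key <- unique(key[order(q, module_table$dynamics, module_table$direction)])
  module_table$wave_id <- sprintf("W%02d", match(key, ord_key))
  module_table[order(module_table$wave_id, module_table$module_id), , drop = FALSE]
}

#' Build the full wave table from log ratios and module membership
#'
#' Convenience stage runner: computes each module's mean profile, smooths it,
#' classifies its dynamics, timestamps the twofold crossing, groups non-flat
#' modules into waves, recomputes each wave's mean profile over the union of
#' member transcripts, and assigns stage labels from the wave timestamp.
#'
#' @param ratios a `log_ratio_matrix` (typically restricted to filtered
#'   transcripts).
#' @param modules named list: module id -> character vector of transcript ids.
#' @param fold_threshold log2 crossing threshold (default 1).
#' @param grid_step dense grid step in minutes (default 1).
#' @param p smoothing weight passed to [smooth_profile()] (default NULL, GCV).
#' @param scheme a [stage_scheme()].
#' @return list with `modules` (per-module classification table), `waves`
#'   (per-wave table: `wave_id`, `dynamics`, `direction`, `timestamp_min`,
#'   `stage`, `module_ids`, `n_transcripts`) and `profiles` (named list of
#'   smoothed module profiles).
#' @export
build_waves <- function(ratios, modules, fold_threshold = 1, grid_step = 1,
                        p = NULL, scheme = stage_scheme()) {
  times <- expr_times(ratios)
  modules <- modules[vapply(modules, function(m) any(m %in% rownames(ratios)),
                            logical(1L))]
  if (!length(modules)) stop("no module has members in the log-ratio matrix")
  profs <- lapply(names(modules), function(id) {
    smooth_profile(times, module_mean_profile(ratios, modules[[id]]),
                   grid_step = grid_step, p = p, id = id)
  })
  names(profs) <- names(modules)
  cls <- lapply(profs, classify_dynamics, fold_threshold = fold_threshold)
  mt <- data.frame(module_id = names(modules),
                   dynamics = vapply(cls, `[[`, character(1L), "dynamics"),
                   direction = vapply(cls, `[[`, character(1L), "direction"),
                   n_transcripts = vapply(modules, function(m)
                     sum(m %in% rownames(ratios)), integer(1L)),
                   stringsAsFactors = FALSE, row.names = NULL)
  mt$timestamp <- NA_real_
  nonflat <- mt$dynamics != "flat"
  mt$timestamp[nonflat] <- vapply(profs[mt$module_id[nonflat]],
                                  crossing_timestamp,
                                  numeric(1L), fold_threshold = fold_threshold)
  grouped <- group_into_waves(mt[nonflat, , drop = FALSE], times)
  waves <- do.call(rbind, lapply(split(grouped, grouped$wave_id), function(g) {
    members <- unique(unlist(modules[g$module_id], use.names = FALSE))
    wp <- smooth_profile(times, module_mean_profile(ratios, members),
                         grid_step = grid_step, p = p, id = g$wave_id[1L])
    ts <- tryCatch(crossing_timestamp(wp, fold_threshold),
                   error = function(e) min(g$timestamp))
    data.frame(wave_id = g$wave_id[1L],
               dynamics = g$dynamics[1L],
               direction = g$direction[1L],
               timestamp_min = ts,
               stage = assign_stage(ts, scheme),
               module_ids = paste(sort(g$module_id), collapse = ","),
               n_modules = nrow(g),
               n_transcripts = length(intersect(members, rownames(ratios))),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  waves <- waves[order(waves$timestamp_min, waves$wave_id), , drop = FALSE]
  rownames(waves) <- NULL
  list(modules = merge(mt, grouped[, c("module_id", "quantized_time", "wave_id")],
                       by = "module_id", all.x = TRUE, sort = TRUE),
       waves = waves, profiles = profs)
}
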