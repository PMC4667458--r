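#' Expression time-course matrix
#'
#' Container for a transcripts-by-timepoints FPKM matrix with a minute-valued
#' time axis. The first column is the pre-starvation reference sample and must
#' be at time 0. FPKM values are non-negative; transcript ids are unique.
#'
#' @param values numeric matrix, transcripts in rows (rownames are transcript
#'   ids), timepoints in columns.
#' @param times numeric vector of times in minutes, one per column, strictly
#'   increasing, starting at exactly 0. Defaults to `as.numeric(colnames(values))`.
#' @return an `expr_matrix`: the matrix with a `times` attribute.
#' @export
expression_matrix <- function(values, times = as.numeric(colnames(values))) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || anyNA(rownames(values))) {
    stop("expression matrix must have transcript ids as rownames")
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate transcript ids in expression matrix")
  }
  if (anyNA(times) || length(times) != ncol(values)) {
    stop("times must be one finite value per column")
  }
  if (ncol(values) < 3L) stop("need at least 3 timepoints")
  if (times[1L] != 0) stop("reference sample missing: first time must be exactly 0")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (anyNA(values) || any(values < 0)) stop("FPKM values must be non-negative and finite")
  colnames(values) <- format(times, trim = TRUE, scientific = FALSE)
  structure(values, times = as.numeric(times), class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expression matrix: %d transcripts x %d timepoints (%s..%s min)\n",
              nrow(x), ncol(x), min(expr_times(x)), max(expr_times(x))))
  invisible(x)
}

#' Time axis of an expression or log-ratio matrix
#' @param x an `expr_matrix` or `log_ratio_matrix`.
#' @return numeric vector of times in minutes.
#' @export
expr_times <- function(x) attr(x, "times")

#' Log2 expression ratios against the pre-starvation reference
#'
#' For each transcript i and time t computes
#' `r = log2((x_t + 1) / (x_0 + 1))` with a +1 pseudocount on the FPKM scale,
#' so the ratio is finite even when a transcript drops to 0 FPKM. The column
#' at t = 0 is identically 0.
#'
#' @param expr an [expression_matrix()].
#' @return a `log_ratio_matrix` with the same axes, log2 units.
#' @export
compute_log_ratios <- function(expr) {
  if (!inherits(expr, "expr_matrix")) expr <- expression_matrix(expr)
  times <- expr_times(expr)
  r <- log2((unclass(expr) + 1) / (expr[, 1L] + 1))
  structure(r, times = times, class = c("log_ratio_matrix", "matrix", "array"))
}

#' @export
print.log_ratio_matrix <- function(x, ...) {
  cat(sprintf("log2-ratio matrix: %d transcripts x %d timepoints\n", nrow(x), ncol(x)))
  invisible(x)
}

log_ratio_matrix <- function(values, times = as.numeric(colnames(values))) {
  values <- as.matrix(values)
  if (times[1L] != 0) stop("first time must be 0")
  if (any(abs(values[, 1L]) > 1e-12)) stop("column at t = 0 must be identically 0")
  if (anyNA(values) || any(!is.finite(values))) stop("log ratios must be finite")
  colnames(values) <- format(times, trim = TRUE, scientific = FALSE)
  structure(values, times = as.numeric(times),
            class = c("log_ratio_matrix", "matrix", "array"))
}

#' Read an FPKM time-course matrix from TSV
#'
#' Wide format: first column `transcript_id`, remaining columns headed by the
#' time in minutes. Long format (`long = TRUE`): columns
#' `transcript_id`, `time_min`, `fpkm`.
#'
#' @param path file path.
#' @param long logical, read the long format instead of the wide one.
#' @return an [expression_matrix()].
#' @export
read_expression_tsv <- function(path, long = FALSE) {
  if (long) {
    d <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
    need <- c("transcript_id", "time_min", "fpkm")
    if (!all(need %in% names(d))) stop("long format needs columns: ", paste(need, collapse = ", "))
    times <- sort(unique(d$time_min))
    ids <- unique(d$transcript_id)
    m <- matrix(NA_real_, length(ids), length(times), dimnames = list(ids, NULL))
    m[cbind(match(d$transcript_id, ids), match(d$time_min, times))] <- d$fpkm
    if (anyNA(m)) stop("long-format table is not a complete transcript x time grid")
    return(expression_matrix(m, times))
  }
  d <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                         check.names = FALSE, stringsAsFactors = FALSE)
  if (names(d)[1L] != "transcript_id") stop("first column must be transcript_id")
  m <- as.matrix(d[, -1L, drop = FALSE])
  rownames(m) <- d$transcript_id
  expression_matrix(m, as.numeric(colnames(m)))
}

#' Write an expression or log-ratio matrix as TSV (wide layout)
#'
#' @param x matrix with a `times` attribute.
#' @param path output file path.
#' @param header_params optional named list written as `# key: value` comment
#'   lines before the table.
#' @export
write_matrix_tsv <- function(x, path, header_params = NULL) {
  d <- data.frame(transcript_id = rownames(x), unclass(x),
                  check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_with_header(d, path, header_params)
}

# Subsetting preserves the time axis and class when the result is a matrix
# (base drop semantics, so single-row/column selections still give vectors).
subset_timed_matrix <- function(x, i, j, drop) {
  y <- unclass(x)
  out <- if (missing(i) && missing(j)) y
  else if (missing(j)) y[i, , drop = drop]
  else if (missing(i)) y[, j, drop = drop]
  else y[i, j, drop = drop]
  if (is.matrix(out)) {
    times <- attr(x, "times")
    attr(out, "times") <- if (missing(j)) times else times[j]
    class(out) <- class(x)
  }
  out
}

#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = TRUE) {
  subset_timed_matrix(x, i, j, drop)
}

#' @export
`[.log_ratio_matrix` <- function(x, i, j, ..., drop = TRUE) {
  subset_timed_matrix(x, i, j, drop)
}
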