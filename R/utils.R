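#' @keywords internal
"_PACKAGE"

#' @importFrom stats predict quantile rnorm rlnorm runif setNames smooth.spline
#'   splinefun uniroot
#' @importFrom utils read.table write.table
NULL

# Write a data frame as TSV preceded by `# key: value` comment lines, with
# fixed numeric formatting so identical inputs give byte-identical files.
write_tsv_with_header <- function(d, path, header_params = NULL, digits = 15) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(header_params)) {
    for (k in names(header_params)) {
      v <- header_params[[k]]
      writeLines(sprintf("# %s: %s", k, paste(format(v, trim = TRUE, digits = 15,
                                                     scientific = FALSE), collapse = ",")), con)
    }
  }
  num <- vapply(d, is.numeric, logical(1L))
  d[num] <- lapply(d[num], function(col) {
    out <- formatC(col, digits = digits, format = "g")
    out[is.na(col)] <- "NA"
    out
  })
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Read a TSV written by write_tsv_with_header, skipping comment lines.
read_tsv_body <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
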