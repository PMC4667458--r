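#' Parse a gene-protein-reaction (GPR) boolean rule
#'
#' Accepts the conventional syntax, e.g. `"(g1 and g2) or g3"`, with
#' `and`/`or` case-insensitive (also `&`, `&&`, `|`, `||`) and arbitrary
#' parenthesization. Returns a boolean tree: a gene id leaf (character), or
#' a list `list(op = "and"|"or", args = list(...))`. An empty or NA rule
#' returns NULL (no gene association).
#'
#' @param rule GPR string.
#' @return parse tree or NULL.
#' @export
parse_gpr <- function(rule) {
  if (is.null(rule) || length(rule) == 0L || is.na(rule) || !nzchar(trimws(rule))) {
    return(NULL)
  }
  s <- gsub("([()])", " \\1 ", rule)
  toks <- strsplit(trimws(s), "[[:space:]]+")[[1L]]
  norm <- function(tok) {
    low <- tolower(tok)
    if (low %in% c("and", "&", "&&")) "and"
    else if (low %in% c("or", "|", "||")) "or"
    else tok
  }
  toks <- vapply(toks, norm, character(1L), USE.NAMES = FALSE)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  parse_expr <- function() {
    node <- parse_term()
    args <- list(node)
    while (identical(peek(), "or")) {
      take()
      args[[length(args) + 1L]] <- parse_term()
    }
    if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
  }
  parse_term <- function() {
    node <- parse_factor()
    args <- list(node)
    while (identical(peek(), "and")) {
      take()
      args[[length(args) + 1L]] <- parse_factor()
    }
    if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
  }
  parse_factor <- function() {
    t <- take()
    if (is.na(t)) stop("unexpected end of GPR rule: ", rule)
    if (t == "(") {
      node <- parse_expr()
      if (!identical(take(), ")")) stop("unbalanced parentheses in GPR rule: ", rule)
      return(node)
    }
    if (t %in% c(")", "and", "or")) stop("malformed GPR rule: ", rule)
    t
  }
  tree <- parse_expr()
  if (pos <= length(toks)) stop("trailing tokens in GPR rule: ", rule)
  tree
}

#' Genes referenced by a GPR tree
#' @param tree a tree from [parse_gpr()].
#' @return character vector of unique gene ids (empty for NULL).
#' @export
gpr_genes <- function(tree) {
  if (is.null(tree)) return(character(0))
  if (is.character(tree)) return(tree)
  unique(unlist(lapply(tree$args, gpr_genes), use.names = FALSE))
}

#' Evaluate a GPR tree with a set of inactivated genes
#'
#' @param tree a tree from [parse_gpr()].
#' @param inactive character vector of knocked genes.
#' @return TRUE if the reaction remains catalyzed. A NULL tree (no gene
#'   association) always evaluates TRUE.
#' @export
eval_gpr <- function(tree, inactive = character(0)) {
  if (is.null(tree)) return(TRUE)
  if (is.character(tree)) return(!(tree %in% inactive))
  vals <- vapply(tree$args, eval_gpr, logical(1L), inactive = inactive)
  if (tree$op == "and") all(vals) else any(vals)
}

# Is a reaction disabled by the loss of `gene`?
# boolean mode: GPR evaluates FALSE without the gene (isozymes rescue).
# any mode: the gene merely appears in the GPR.
reaction_disabled_by <- function(tree, gene, gpr_mode = c("boolean", "any")) {
  gpr_mode <- match.arg(gpr_mode)
  if (is.null(tree)) return(FALSE)
  if (gpr_mode == "any") gene %in% gpr_genes(tree) else !eval_gpr(tree, gene)
}
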