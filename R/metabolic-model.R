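#' Construct a constraint-based metabolic model
#'
#' @param reactions list of reactions, each a list with `id`, `stoich`
#'   (named numeric: metabolite -> coefficient, negative = consumed),
#'   `lb`, `ub` (flux bounds; default `c(0, 1000)`), and optional `gpr`
#'   (boolean rule string over gene ids).
#' @param id model identifier.
#' @param bm_tag,ex_tag reaction ids designated as the TAG-free biomass
#'   objective and the TAG exchange (optional; required by the knockdown
#'   screen).
#' @return a `metabolic_model`: list with the stoichiometric matrix `S`
#'   (metabolites x reactions), `rxns`, `mets`, `lb`, `ub`, `gpr` (strings),
#'   `gpr_tree` (parsed), `genes`, `bm_tag`, `ex_tag`.
#' @export
metabolic_model <- function(reactions, id = "model", bm_tag = NA_character_,
                            ex_tag = NA_character_) {
  if (!length(reactions)) stop("model needs at least one reaction")
  rxns <- vapply(reactions, `[[`, character(1L), "id")
  if (anyDuplicated(rxns)) stop("duplicate reaction ids")
  mets <- sort(unique(unlist(lapply(reactions, function(r) names(r$stoich)),
                             use.names = FALSE)))
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  for (j in seq_along(reactions)) {
    st <- reactions[[j]]$stoich
    if (length(st)) {
      if (is.null(names(st)) || any(!nzchar(names(st)))) {
        stop("unnamed stoichiometry in reaction ", rxns[j])
      }
      S[names(st), j] <- as.numeric(st)
    }
  }
  lb <- vapply(reactions, function(r) as.numeric(r$lb %||% 0), numeric(1L))
  ub <- vapply(reactions, function(r) as.numeric(r$ub %||% 1000), numeric(1L))
  if (any(lb > ub)) stop("lower bound exceeds upper bound for: ",
                         paste(rxns[lb > ub], collapse = ", "))
  gpr <- vapply(reactions, function(r) as.character(r$gpr %||% ""), character(1L))
  gpr_tree <- lapply(gpr, parse_gpr)
  names(lb) <- names(ub) <- names(gpr) <- names(gpr_tree) <- rxns
  m <- structure(list(id = id, S = S, mets = mets, rxns = rxns, lb = lb,
                      ub = ub, gpr = gpr, gpr_tree = gpr_tree,
                      genes = sort(unique(unlist(lapply(gpr_tree, gpr_genes)))),
                      bm_tag = bm_tag, ex_tag = ex_tag),
                 class = "metabolic_model")
  validate_model(m)
}

validate_model <- function(m, require_designated = FALSE) {
  for (r in c(bm_tag = m$bm_tag, ex_tag = m$ex_tag)) {
    if (!is.na(r) && !(r %in% m$rxns)) stop("designated reaction not in model: ", r)
  }
  if (!is.na(m$bm_tag) && !is.na(m$ex_tag) && m$bm_tag == m$ex_tag) {
    stop("BM_TAG and EX_TAG must be distinct reactions")
  }
  if (require_designated && (is.na(m$bm_tag) || is.na(m$ex_tag))) {
    stop("model lacks designated BM_TAG/EX_TAG reactions")
  }
  m
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("metabolic model '%s': %d reactions, %d metabolites, %d genes\n",
              x$id, length(x$rxns), length(x$mets), length(x$genes)))
  if (!is.na(x$bm_tag)) cat("  biomass (BM_TAG):", x$bm_tag, "\n")
  if (!is.na(x$ex_tag)) cat("  TAG exchange (EX_TAG):", x$ex_tag, "\n")
  invisible(x)
}

# Update one reaction's bounds, returning the modified model.
set_bounds <- function(model, rxn, lb = NULL, ub = NULL) {
  if (!(rxn %in% model$rxns)) stop("unknown reaction: ", rxn)
  if (!is.null(lb)) model$lb[rxn] <- lb
  if (!is.null(ub)) model$ub[rxn] <- ub
  if (model$lb[rxn] > model$ub[rxn]) stop("lb > ub for ", rxn)
  model
}

# Append a reaction (used for demand reactions in the precursor search).
add_reaction <- function(model, id, stoich, lb = 0, ub = 1000, gpr = "") {
  if (id %in% model$rxns) stop("reaction id already present: ", id)
  new_mets <- setdiff(names(stoich), model$mets)
  if (length(new_mets)) {
    model$S <- rbind(model$S, matrix(0, length(new_mets), ncol(model$S),
                                     dimnames = list(new_mets, NULL)))
    model$mets <- rownames(model$S)
  }
  col <- numeric(nrow(model$S))
  names(col) <- rownames(model$S)
  col[names(stoich)] <- stoich
  model$S <- cbind(model$S, col)
  colnames(model$S)[ncol(model$S)] <- id
  model$rxns <- colnames(model$S)
  model$lb <- c(model$lb, setNames(lb, id))
  model$ub <- c(model$ub, setNames(ub, id))
  model$gpr <- c(model$gpr, setNames(gpr, id))
  model$gpr_tree <- c(model$gpr_tree, setNames(list(parse_gpr(gpr)), id))
  model
}

#' Load a metabolic model from the JSON dialect
#'
#' The dialect mirrors COBRA JSON: top level `id`, `metabolites`
#' (list of `{id}`), `reactions` (list of `{id, metabolites: {met: coef},
#' lower_bound, upper_bound, gene_reaction_rule}`), plus `bm_tag` / `ex_tag`
#' naming the designated reactions (falling back to reactions literally named
#' `BM_TAG` / `EX_TAG`).
#'
#' @param path JSON file path.
#' @param require_designated error if BM_TAG/EX_TAG cannot be identified
#'   (default TRUE; the knockdown screen needs them).
#' @return a [metabolic_model()].
#' @export
load_model_json <- function(path, require_designated = TRUE) {
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(j$reactions)) stop("no reactions in model file")
  declared <- vapply(j$metabolites %||% list(), `[[`, character(1L), "id")
  reactions <- lapply(j$reactions, function(r) {
    st <- unlist(r$metabolites)
    if (length(declared) && length(st) && !all(names(st) %in% declared)) {
      stop("reaction ", r$id, " references undeclared metabolite(s): ",
           paste(setdiff(names(st), declared), collapse = ", "))
    }
    list(id = r$id, stoich = st,
         lb = r$lower_bound %||% 0, ub = r$upper_bound %||% 1000,
         gpr = r$gene_reaction_rule %||% "")
  })
  rxn_ids <- vapply(reactions, `[[`, character(1L), "id")
  pick <- function(key, fallback) {
    v <- j[[key]] %||% (if (fallback %in% rxn_ids) fallback else NA_character_)
    as.character(v)
  }
  m <- metabolic_model(reactions, id = j$id %||% basename(path),
                       bm_tag = pick("bm_tag", "BM_TAG"),
                       ex_tag = pick("ex_tag", "EX_TAG"))
  validate_model(m, require_designated = require_designated)
}

#' Write a metabolic model in the JSON dialect
#' @param model a [metabolic_model()].
#' @param path output path.
#' @export
write_model_json <- function(model, path) {
  reactions <- lapply(model$rxns, function(r) {
    st <- model$S[, r]
    st <- st[st != 0]
    list(id = r, metabolites = as.list(st),
         lower_bound = unname(model$lb[r]), upper_bound = unname(model$ub[r]),
         gene_reaction_rule = unname(model$gpr[r]))
  })
  j <- list(id = model$id,
            metabolites = lapply(model$mets, function(m) list(id = m)),
            reactions = reactions)
  if (!is.na(model$bm_tag)) j$bm_tag <- model$bm_tag
  if (!is.na(model$ex_tag)) j$ex_tag <- model$ex_tag
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an SBML metabolic model
#'
#' Compact reader for SBML Level 2 (GENE_ASSOCIATION in reaction notes) and
#' Level 3 with the fbc extension (flux-bound parameters and
#' geneProductAssociation trees). Reactions without fbc bounds fall back to
#' `(-1000, 1000)` when reversible, `(0, 1000)` otherwise.
#'
#' @inheritParams load_model_json
#' @return a [metabolic_model()].
#' @export
read_sbml_model <- function(path, require_designated = TRUE) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  model_node <- xml2::xml_find_first(doc, ".//model")
  params <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  pval <- setNames(as.numeric(xml2::xml_attr(params, "value")),
                   xml2::xml_attr(params, "id"))
  gp <- xml2::xml_find_all(doc, ".//*[local-name()='listOfGeneProducts']/*")
  glab <- setNames(
    ifelse(is.na(xml2::xml_attr(gp, "label")),
           xml2::xml_attr(gp, "fbc:label"), xml2::xml_attr(gp, "label")),
    ifelse(is.na(xml2::xml_attr(gp, "id")),
           xml2::xml_attr(gp, "fbc:id"), xml2::xml_attr(gp, "id")))
  fbc_attr <- function(node, name) {
    v <- xml2::xml_attr(node, name)
    if (is.na(v)) v <- xml2::xml_attr(node, paste0("fbc:", name))
    v
  }
  gpa_to_rule <- function(node) {
    nm <- sub(".*:", "", xml2::xml_name(node))
    if (nm == "geneProductRef") {
      ref <- fbc_attr(node, "geneProduct")
      lab <- glab[ref]
      return(if (!is.na(lab) && nzchar(lab)) lab else ref)
    }
    kids <- xml2::xml_children(node)
    parts <- vapply(kids, gpa_to_rule, character(1L))
    op <- if (nm == "and") " and " else " or "
    paste0("(", paste(parts, collapse = op), ")")
  }
  rxn_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  if (!length(rxn_nodes)) stop("no reactions in SBML file")
  reactions <- lapply(rxn_nodes, function(rn) {
    id <- xml2::xml_attr(rn, "id")
    sto <- c()
    for (side in c(-1, 1)) {
      sel <- if (side < 0) "./listOfReactants/speciesReference" else "./listOfProducts/speciesReference"
      for (sr in xml2::xml_find_all(rn, sel)) {
        coef <- as.numeric(xml2::xml_attr(sr, "stoichiometry"))
        if (is.na(coef)) coef <- 1
        sp <- xml2::xml_attr(sr, "species")
        cur <- if (sp %in% names(sto)) sto[[sp]] else 0
        sto[sp] <- cur + side * coef
      }
    }
    rev <- !identical(xml2::xml_attr(rn, "reversible"), "false")
    lb_ref <- fbc_attr(rn, "lowerFluxBound")
    ub_ref <- fbc_attr(rn, "upperFluxBound")
    lb <- if (!is.na(lb_ref) && lb_ref %in% names(pval)) pval[lb_ref] else if (rev) -1000 else 0
    ub <- if (!is.na(ub_ref) && ub_ref %in% names(pval)) pval[ub_ref] else 1000
    gpa <- xml2::xml_find_first(rn, "./*[local-name()='geneProductAssociation']/*")
    gpr <- if (!inherits(gpa, "xml_missing")) {
      gpa_to_rule(gpa)
    } else {
      notes <- xml2::xml_text(xml2::xml_find_first(rn, "./notes"))
      ga <- regmatches(notes, regexpr("GENE_ASSOCIATION:[^<\n]*", notes))
      if (length(ga)) trimws(sub("GENE_ASSOCIATION:", "", ga)) else ""
    }
    list(id = id, stoich = sto, lb = unname(lb), ub = unname(ub), gpr = gpr)
  })
  rxn_ids <- vapply(reactions, `[[`, character(1L), "id")
  m <- metabolic_model(reactions,
                       id = xml2::xml_attr(model_node, "id") %||% basename(path),
                       bm_tag = if ("BM_TAG" %in% rxn_ids) "BM_TAG" else NA_character_,
                       ex_tag = if ("EX_TAG" %in% rxn_ids) "EX_TAG" else NA_character_)
  validate_model(m, require_designated = require_designated)
}

#' Split the TAG species out of the biomass reaction
#'
#' Removes the TAG-class species from the biomass definition (giving the
#' TAG-free biomass reaction `BM_TAG`) and creates a separate exchange
#' reaction `EX_TAG` consuming the stripped species with their original
#' biomass coefficients, so TAG output can be optimized independently of
#' growth. The original biomass reaction is closed (bounds 0) so it cannot
#' shadow the split objectives.
#'
#' @param model a [metabolic_model()].
#' @param tag_species metabolite ids of the TAG compounds in the biomass
#'   reaction (must all be consumed by it).
#' @param biomass_id id of the original biomass reaction.
#' @param bm_tag_id,ex_tag_id ids for the two new reactions.
#' @return the modified model with `bm_tag`/`ex_tag` set.
#' @export
split_tag_from_biomass <- function(model, tag_species, biomass_id,
                                   bm_tag_id = "BM_TAG", ex_tag_id = "EX_TAG") {
  if (!length(tag_species)) stop("tag_species must be non-empty")
  if (!(biomass_id %in% model$rxns)) stop("unknown biomass reaction: ", biomass_id)
  if (bm_tag_id %in% model$rxns || ex_tag_id %in% model$rxns) {
    stop("TAG already split from biomass (", bm_tag_id, "/", ex_tag_id,
         " present): refusing to apply twice")
  }
  bio <- model$S[, biomass_id]
  consumed <- names(bio)[bio < 0]
  missing <- setdiff(tag_species, consumed)
  if (length(missing)) {
    stop("tag_species not consumed by the biomass reaction: ",
         paste(missing, collapse = ", "))
  }
  bm_st <- bio[bio != 0 & !(names(bio) %in% tag_species)]
  ex_st <- bio[names(bio) %in% tag_species]     # negative = consumed, kept as-is
  model <- add_reaction(model, bm_tag_id, bm_st,
                        lb = unname(model$lb[biomass_id]),
                        ub = unname(model$ub[biomass_id]),
                        gpr = unname(model$gpr[biomass_id]))
  model <- add_reaction(model, ex_tag_id, ex_st, lb = 0,
                        ub = unname(model$ub[biomass_id]))
  model <- set_bounds(model, biomass_id, lb = 0, ub = 0)
  model$bm_tag <- bm_tag_id
  model$ex_tag <- ex_tag_id
  validate_model(model)
}
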