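#' Knockdown screen settings
#'
#' A knockdown caps the magnitude of every flux disabled by the gene's loss
#' at `1/kd_factor` of its wild-type value (flux direction preserved; a
#' reaction carrying no wild-type flux is closed). A perturbed model is
#' viable only if it retains at least `viability_fraction` of the wild-type
#' biomass flux. Under `gpr_mode = "boolean"` isozymes rescue a knockdown
#' (the GPR must evaluate false without the gene); under `"any"` every
#' reaction whose GPR mentions the gene is constrained.
#'
#' @param kd_factor flux reduction factor, > 1 (default 16).
#' @param viability_fraction minimum retained biomass fraction in (0, 1)
#'   (default 0.10).
#' @param gpr_mode `"boolean"` (default) or `"any"`.
#' @return a `knockdown_config` list.
#' @export
knockdown_config <- function(kd_factor = 16, viability_fraction = 0.10,
                             gpr_mode = c("boolean", "any")) {
  gpr_mode <- match.arg(gpr_mode)
  if (kd_factor <= 1) stop("kd_factor must be > 1")
  if (viability_fraction <= 0 || viability_fraction >= 1) {
    stop("viability_fraction must be in (0, 1)")
  }
  structure(list(kd_factor = kd_factor, viability_fraction = viability_fraction,
                 gpr_mode = gpr_mode), class = "knockdown_config")
}

#' Apply knockdown flux bounds for one gene
#'
#' @param model a [metabolic_model()].
#' @param wt_flux wild-type `flux_distribution` (from [pfba()] on the
#'   biomass objective) supplying the reference fluxes.
#' @param gene gene id to knock down.
#' @param cfg a [knockdown_config()].
#' @param tol fluxes with `|v| <= tol` are treated as zero and closed.
#' @return the model with tightened bounds; the affected reaction ids are
#'   attached as `attr(, "affected")`. A gene absent from every GPR is a
#'   no-op with a warning.
#' @export
gene_knockdown_bounds <- function(model, wt_flux, gene, cfg = knockdown_config(),
                                  tol = 1e-9) {
  hit <- model$rxns[vapply(model$gpr_tree, reaction_disabled_by, logical(1L),
                           gene = gene, gpr_mode = cfg$gpr_mode)]
  if (!length(hit)) {
    if (!(gene %in% model$genes)) {
      warning("gene absent from every GPR: ", gene, " (no-op)")
    }
    attr(model, "affected") <- character(0)
    return(model)
  }
  if (is.null(wt_flux$fluxes)) stop("wild-type flux distribution is not optimal")
  for (r in hit) {
    v <- unname(wt_flux$fluxes[r])
    cap <- abs(v) / cfg$kd_factor
    if (abs(v) <= tol) {
      model <- set_bounds(model, r, lb = 0, ub = 0)
    } else if (v > 0) {
      model <- set_bounds(model, r, lb = max(model$lb[r], 0), ub = cap)
    } else {
      model <- set_bounds(model, r, lb = -cap, ub = min(model$ub[r], 0))
    }
  }
  attr(model, "affected") <- hit
  model
}

# Wild-type reference fluxes/objectives needed by the screen; computed once.
wildtype_state <- function(model) {
  validate_model(model, require_designated = TRUE)
  bm <- pfba(model, model$bm_tag)
  if (bm$status != "optimal") stop("wild-type model infeasible for BM_TAG")
  tag <- fba(model, model$ex_tag)
  if (tag$status != "optimal") stop("wild-type model infeasible for EX_TAG")
  list(bm = bm, tag = tag)
}

#' TAG-per-biomass knockdown score for one gene
#'
#' Computes the dimensionless ratio
#' `rho = (TAG_pert / TAG_WT) / (BM_TAG_pert / BM_TAG_WT)`:
#' the wild-type biomass flux (BM_TAG objective) is derived by parsimonious
#' FBA, knockdown bounds are applied from its flux distribution, and the
#' perturbed biomass and TAG exchange maxima are recomputed. `rho > 1`
#' predicts more TAG per unit biomass under the knockdown. A perturbation
#' retaining less than the viability fraction of wild-type biomass is
#' recorded as inviable and its rho is NA.
#'
#' @inheritParams gene_knockdown_bounds
#' @param wt optional precomputed wild-type state (internal reuse by
#'   [screen_targets()]).
#' @return one-row data frame: `gene`, `bm_wt`, `bm_pert`, `tag_wt`,
#'   `tag_pert`, `bm_ratio`, `tag_ratio`, `rho`, `viable`,
#'   `affected_reactions`.
#' @export
knockdown_rho <- function(model, gene, cfg = knockdown_config(), wt = NULL) {
  wt <- wt %||% wildtype_state(model)
  bm_wt <- wt$bm$objective_value
  tag_wt <- wt$tag$objective_value
  pert <- gene_knockdown_bounds(model, wt$bm, gene, cfg)
  affected <- attr(pert, "affected")
  bm_p <- fba(pert, model$bm_tag)
  tag_p <- fba(pert, model$ex_tag)
  bm_pert <- if (bm_p$status == "optimal") bm_p$objective_value else 0
  tag_pert <- if (tag_p$status == "optimal") tag_p$objective_value else 0
  viable <- bm_pert >= cfg$viability_fraction * bm_wt
  bm_ratio <- if (bm_wt > 0) bm_pert / bm_wt else NA_real_
  tag_ratio <- if (tag_wt > 0) tag_pert / tag_wt else NA_real_
  rho <- if (viable && !is.na(bm_ratio) && !is.na(tag_ratio) &&
             bm_wt > 0 && tag_wt > 0 && bm_pert > 0) {
    tag_ratio / bm_ratio
  } else NA_real_
  data.frame(gene = gene, bm_wt = bm_wt, bm_pert = bm_pert,
             tag_wt = tag_wt, tag_pert = tag_pert,
             bm_ratio = bm_ratio, tag_ratio = tag_ratio,
             rho = rho, viable = viable,
             affected_reactions = paste(affected, collapse = ","),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Rank candidate genes by predicted TAG-per-biomass gain
#'
#' Runs [knockdown_rho()] for every candidate gene present in the model's
#' GPRs, flags viable genes with `rho > 1` as targets, and sorts by
#' descending rho (ties by gene id). Candidates absent from the model are
#' reported in `attr(, "unmapped")`, never silently dropped.
#'
#' @inheritParams knockdown_rho
#' @param candidate_genes character vector of gene ids to screen.
#' @return data frame of per-gene results with an added logical `target`
#'   column.
#' @export
screen_targets <- function(model, candidate_genes, cfg = knockdown_config()) {
  if (!length(candidate_genes)) stop("candidate_genes must be non-empty")
  candidate_genes <- unique(candidate_genes)
  mapped <- intersect(sort(candidate_genes), model$genes)
  unmapped <- setdiff(candidate_genes, model$genes)
  if (!length(mapped)) {
    out <- data.frame(gene = character(0), bm_wt = numeric(0), bm_pert = numeric(0),
                      tag_wt = numeric(0), tag_pert = numeric(0),
                      bm_ratio = numeric(0), tag_ratio = numeric(0),
                      rho = numeric(0), viable = logical(0),
                      affected_reactions = character(0), target = logical(0),
                      stringsAsFactors = FALSE)
    attr(out, "unmapped") <- unmapped
    return(out)
  }
  wt <- wildtype_state(model)
  res <- do.call(rbind, lapply(mapped, knockdown_rho, model = model,
                               cfg = cfg, wt = wt))
  res$target <- res$viable & !is.na(res$rho) & res$rho > 1
  ord <- order(-ifelse(is.na(res$rho), -Inf, res$rho), res$gene)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "unmapped") <- unmapped
  res
}

#' Genes able to supply a set of precursor metabolites
#'
#' For each precursor a temporary demand reaction is added and maximized;
#' flux variability analysis at that optimum then identifies every reaction
#' able to carry nonzero flux while the demand is held at its maximum, and
#' the genes of their GPRs are returned. A precursor whose maximal demand is
#' zero contributes nothing (with a warning).
#'
#' @param model a [metabolic_model()].
#' @param precursor_mets metabolite ids (e.g. acetyl-CoA, malonyl-CoA,
#'   glycerol 3-phosphate).
#' @param tol flux magnitude below which a reaction is considered unable to
#'   carry flux.
#' @return sorted character vector of gene ids.
#' @export
precursor_genes <- function(model, precursor_mets, tol = 1e-6) {
  missing <- setdiff(precursor_mets, model$mets)
  if (length(missing)) stop("metabolite(s) not in model: ", paste(missing, collapse = ", "))
  genes <- character(0)
  for (met in precursor_mets) {
    dm_id <- paste0("DM_", met)
    dm <- add_reaction(model, dm_id, setNames(-1, met), lb = 0, ub = 1000)
    opt <- fba(dm, dm_id)
    if (opt$status != "optimal" || opt$objective_value <= tol) {
      warning("no producible flux toward ", met, "; skipping")
      next
    }
    ranges <- fva(dm, dm_id, reactions = model$rxns)
    able <- ranges$rxn[pmax(abs(ranges$min), abs(ranges$max)) > tol]
    genes <- c(genes, unlist(lapply(model$gpr_tree[able], gpr_genes),
                             use.names = FALSE))
  }
  sort(unique(genes))
}

#' Classify screen targets by starvation-condition overlap
#'
#' Targets come from the nitrogen-starvation screen by construction; the
#' class records whether each is also downregulated under sulfur and/or
#' phosphorus starvation.
#'
#' @param targets gene ids downregulated under N starvation.
#' @param s_down gene ids downregulated under S starvation.
#' @param p_down gene ids downregulated under P starvation.
#' @return data frame with `gene`, `in_s`, `in_p` and
#'   `class` in `{"N-only", "N+S", "N+P", "N+S+P"}`.
#' @export
classify_condition_overlap <- function(targets, s_down = character(0),
                                       p_down = character(0)) {
  in_s <- targets %in% s_down
  in_p <- targets %in% p_down
  cls <- ifelse(in_s & in_p, "N+S+P",
                ifelse(in_s, "N+S", ifelse(in_p, "N+P", "N-only")))
  data.frame(gene = targets, in_s = in_s, in_p = in_p, class = cls,
             stringsAsFactors = FALSE, row.names = NULL)
}
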