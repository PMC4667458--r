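# Shared fixture builders; everything is generated in code.

default_times <- tagwave::default_time_grid()

# log-ratio matrix from a named list of per-transcript value vectors
make_ratios <- function(rows, times = default_times) {
  m <- do.call(rbind, rows)
  rownames(m) <- names(rows)
  colnames(m) <- format(times, trim = TRUE, scientific = FALSE)
  structure(m, times = times, class = c("log_ratio_matrix", "matrix", "array"))
}

# vector of zeros with named time positions set
at_times <- function(times, ...) {
  v <- setNames(numeric(length(times)), format(times, trim = TRUE, scientific = FALSE))
  spec <- list(...)
  for (k in names(spec)) v[k] <- spec[[k]]
  unname(v)
}

# subset a classed ratio matrix without losing attributes
ratios_subset <- function(ratios, ids) {
  out <- ratios[rownames(ratios) %in% ids, , drop = FALSE]
  attr(out, "times") <- attr(ratios, "times")
  class(out) <- class(ratios)
  out
}

# random FPKM matrix for oracle checks
random_expr <- function(n = 20, times = default_times) {
  m <- matrix(rlnorm(n * length(times), log(50), 1.5), n, length(times))
  rownames(m) <- sprintf("T%03d", seq_len(n))
  expression_matrix(m, times)
}

# tiny SBML (level 3 + fbc) document for the reader test: the chain model
sbml_chain_text <- function() {
  paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
'<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" level="3" version="1">\n',
'<model id="sbml_chain">\n',
'<listOfParameters>\n',
'<parameter id="lb_zero" value="0" constant="true"/>\n',
'<parameter id="ub_src" value="10" constant="true"/>\n',
'<parameter id="ub_big" value="1000" constant="true"/>\n',
'</listOfParameters>\n',
'<listOfSpecies>\n',
'<species id="A" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>\n',
'<species id="B" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>\n',
'</listOfSpecies>\n',
'<fbc:listOfGeneProducts>\n',
'<fbc:geneProduct fbc:id="gp1" fbc:label="gS"/>\n',
'<fbc:geneProduct fbc:id="gp2" fbc:label="g1"/>\n',
'<fbc:geneProduct fbc:id="gp3" fbc:label="g2"/>\n',
'</fbc:listOfGeneProducts>\n',
'<listOfReactions>\n',
'<reaction id="SRC" reversible="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_src">\n',
'<listOfProducts><speciesReference species="A" stoichiometry="1" constant="true"/></listOfProducts>\n',
'<fbc:geneProductAssociation><fbc:geneProductRef fbc:geneProduct="gp1"/></fbc:geneProductAssociation>\n',
'</reaction>\n',
'<reaction id="R1" reversible="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_big">\n',
'<listOfReactants><speciesReference species="A" stoichiometry="1" constant="true"/></listOfReactants>\n',
'<listOfProducts><speciesReference species="B" stoichiometry="1" constant="true"/></listOfProducts>\n',
'<fbc:geneProductAssociation><fbc:or>',
'<fbc:geneProductRef fbc:geneProduct="gp2"/>',
'<fbc:geneProductRef fbc:geneProduct="gp3"/>',
'</fbc:or></fbc:geneProductAssociation>\n',
'</reaction>\n',
'<reaction id="BM_TAG" reversible="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_big">\n',
'<listOfReactants><speciesReference species="B" stoichiometry="1" constant="true"/></listOfReactants>\n',
'</reaction>\n',
'<reaction id="EX_TAG" reversible="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_big">\n',
'<listOfReactants><speciesReference species="B" stoichiometry="1" constant="true"/></listOfReactants>\n',
'</reaction>\n',
'</listOfReactions>\n',
'</model>\n</sbml>\n')
}
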