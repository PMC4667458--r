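#!/usr/bin/env Rscript
# Generate the canonical synthetic study inputs: an FPKM time course with
# planted transcriptional waves and lagged regulator drivers, the module
# membership, the regulator list, the planted ground truth, and the
# hand-solvable toy metabolic models. Everything downstream (02-05) reads
# from results/data/.

suppressPackageStartupMessages(library(tagwave))

seed <- 1L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

spec <- simulation_spec(sigma = 0.1, n_decoys = 500, seed = seed)
sim <- simulate_expression(spec)

write_matrix_tsv(sim$expr, file.path(out, "expression_fpkm.tsv"),
                 list(stage = "simulate", sigma = spec$sigma, seed = seed))
membership <- data.frame(
  module_id = rep(names(sim$modules), lengths(sim$modules)),
  transcript_id = unlist(sim$modules, use.names = FALSE))
write.table(membership, file.path(out, "module_membership.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(tr_id = sim$regulators),
            file.path(out, "regulators.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(sim$truth$transcripts, file.path(out, "truth_transcripts.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(sim$truth$modules, file.path(out, "truth_modules.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(sim$truth$edges, file.path(out, "truth_edges.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
for (kind in c("chain", "branch", "isozyme")) {
  toy <- toy_metabolic_model(kind)
  write_model_json(toy$model, file.path(out, sprintf("toy_%s.json", kind)))
  write.table(toy$truth, file.path(out, sprintf("toy_%s_truth.tsv", kind)),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

message(sprintf(
  "simulated %d transcripts x %d timepoints: %d modules (%d dynamic), %d regulators (%d drivers), %d planted influences",
  nrow(sim$expr), ncol(sim$expr), length(sim$modules),
  sum(sim$truth$modules$dynamics != "flat"), length(sim$regulators),
  nrow(sim$truth$edges), nrow(sim$truth$edges)))
message("inputs written under ", out)
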