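#!/usr/bin/env Rscript
# Differential-expression filtering of the simulated N-starvation time
# course: log2 ratios against the pre-starvation sample (with +1
# pseudocount), then the two retention rules (twofold at the lipid
# timepoints, or a sustained >= 30 min twofold run).

suppressPackageStartupMessages(library(tagwave))

expr <- read_expression_tsv("results/data/expression_fpkm.tsv")
ratios <- compute_log_ratios(expr)
report <- filter_transcripts(ratios)

dir.create("results", showWarnings = FALSE)
write_matrix_tsv(ratios, "results/log_ratios.tsv",
                 list(stage = "log_ratios", pseudocount = 1))
write.table(report, "results/filter_report.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

truth <- read.table("results/data/truth_transcripts.tsv", header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
m <- merge(report, truth, by = "transcript_id")
message(sprintf("kept %d / %d transcripts (rules: %s)",
                sum(report$kept), nrow(report),
                paste(names(table(report$rule)), table(report$rule),
                      sep = "=", collapse = ", ")))
message(sprintf("agreement with planted truth: %.1f%% (rules %.1f%%)",
                100 * mean(m$kept.x == m$kept.y),
                100 * mean(m$rule.x == m$rule.y)))
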