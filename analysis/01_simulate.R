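#!/usr/bin/env Rscript
# Build the preset synthetic cohort (494 samples, 60 recurrence events,
# three omics blocks with a planted two-subgroup structure) and write it in
# the TSV dialect used by the rest of the workflow.

suppressPackageStartupMessages(library(omisurv))

out_dir <- "results/cohort"
cohort <- prad_preset()
write_cohort(cohort, out_dir)

cat("cohort written to", out_dir, "\n")
cat(sprintf("samples: %d, recurrence events: %d (%.1f%%)\n",
            nrow(cohort$clinical), sum(cohort$survival$event),
            100 * mean(cohort$survival$event)))
cat(sprintf("block widths: expression %d, methylation %d, miRNA %d\n",
            ncol(cohort$omics$expression), ncol(cohort$omics$methylation),
            ncol(cohort$omics$mirna)))
cat(sprintf("planted high-risk prevalence: %.2f; informative features: %s\n",
            mean(cohort$truth),
            paste(lengths(cohort$truth_features), collapse = "/")))
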