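#!/usr/bin/env Rscript
# Filter (missing / all-zero / zero-variance features), z-score per feature,
# align samples across blocks and report what was dropped.

suppressPackageStartupMessages(library(omisurv))

cohort <- prad_preset()
prep <- preprocess_cohort(cohort)

dir.create("results", showWarnings = FALSE)
drop_log <- do.call(rbind, lapply(names(prep$drop_logs), function(k) {
  log <- prep$drop_logs[[k]]
  if (nrow(log) == 0) return(NULL)
  cbind(kind = k, log)
}))
if (is.null(drop_log)) drop_log <- data.frame(kind = character(0))
jsonlite::write_json(drop_log, "results/feature_drop_log.json",
                     auto_unbox = TRUE, pretty = TRUE)

cat("surviving feature counts:\n")
print(vapply(prep$blocks, ncol, integer(1)))
cat("dropped features:", nrow(drop_log), "(results/feature_drop_log.json)\n")
stacked <- stack_omics(prep$blocks)
cat(sprintf("stacked matrix: %d samples x %d features\n",
            nrow(stacked), ncol(stacked)))
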