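#!/usr/bin/env Rscript
# Label-transfer robustness: repeated stratified 5-fold SVM cross-validation
# of the autoencoder-arm subgroup labels over the documented feature-set
# combinations (bottleneck nodes, 250 multiomics features, multiomics +
# clinical variants).

suppressPackageStartupMessages(library(omisurv))

if (!file.exists("results/subtyping.rds"))
  stop("run analysis/03_subtyping.R first")
st <- readRDS("results/subtyping.rds")
sub <- st$sub

latent_sel <- sub$arms$ae$latent[, sub$arms$ae$selected_nodes, drop = FALSE]
top <- sub$arms$ae$top_features
multi <- do.call(cbind, lapply(names(sub$prep$blocks), function(k)
  sub$prep$blocks[[k]][, top$feature_id[top$kind == k], drop = FALSE]))
lab <- sub$arms$ae$high_risk
clin <- sub$prep$clinical

sets <- c("nodes", "multiomics", "multiomics+all_clinical",
          "multiomics+stage", "multiomics+age", "multiomics+gleason")
rows <- lapply(seq_along(sets), function(i) {
  s <- sets[i]
  x <- build_feature_table(s, latent = latent_sel, multiomics = multi,
                           clinical = clin)
  cv <- crossvalidate_svm(x, lab, folds = 5, reps = 10,
                          seed = 300 + i)
  data.frame(feature_set = s, n_features = ncol(x),
             accuracy = cv$mean[["accuracy"]],
             sensitivity = cv$mean[["sensitivity"]],
             specificity = cv$mean[["specificity"]],
             accuracy_sd = cv$sd[["accuracy"]])
})
tab <- do.call(rbind, rows)
data.table::fwrite(tab, "results/svm_cv.tsv", sep = "\t")
cat("5-fold x 10-rep stratified CV (high-risk = positive class):\n")
print(tab, digits = 3, row.names = FALSE)
cat("written to results/svm_cv.tsv\n")
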