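#' Assemble a named feature set for classification
#'
#' Feature-set combinations mirror the label-transfer experiment: latent
#' bottleneck nodes alone, the 250-feature multiomics table, and the
#' multiomics table with clinical variables appended. Clinical encoding: age
#' numeric, Gleason score numeric, TNM stage ordinal (I..IV -> 1..4).
#'
#' @param set_name one of `"nodes"`, `"multiomics"`,
#'   `"multiomics+all_clinical"`, `"multiomics+stage"`, `"multiomics+age"`,
#'   `"multiomics+gleason"`.
#' @param latent samples-by-nodes matrix of (Cox-selected) bottleneck nodes.
#' @param multiomics samples-by-features matrix of the selected top
#'   differential features.
#' @param clinical data.frame with `age`, `gleason`, `stage` columns, rows
#'   aligned to the matrices.
#' @return numeric matrix; column provenance in attribute `"provenance"`.
#' @export
build_feature_table <- function(set_name, latent = NULL, multiomics = NULL,
                                clinical = NULL) {
  valid <- c("nodes", "multiomics", "multiomics+all_clinical",
             "multiomics+stage", "multiomics+age", "multiomics+gleason")
  if (!set_name %in% valid)
    stop("unknown feature set '", set_name, "'; valid names: ",
         paste(valid, collapse = ", "))
  encode_clinical <- function(vars) {
    cols <- list()
    if ("age" %in% vars) cols$age <- as.numeric(clinical$age)
    if ("gleason" %in% vars) cols$gleason <- as.numeric(clinical$gleason)
    if ("stage" %in% vars)
      cols$stage <- as.numeric(factor(clinical$stage,
                                      levels = c("I", "II", "III", "IV")))
    do.call(cbind, cols)
  }
  parts <- list(); prov <- character(0)
  if (set_name == "nodes") {
    parts$nodes <- latent
    prov <- rep("latent_node", ncol(latent))
  } else {
    parts$multiomics <- multiomics
    prov <- rep("multiomics", ncol(multiomics))
    clin_vars <- switch(set_name,
      "multiomics" = character(0),
      "multiomics+all_clinical" = c("age", "gleason", "stage"),
      "multiomics+stage" = "stage",
      "multiomics+age" = "age",
      "multiomics+gleason" = "gleason")
    if (length(clin_vars) > 0) {
      parts$clinical <- encode_clinical(clin_vars)
      prov <- c(prov, rep("clinical", length(clin_vars)))
    }
  }
  x <- do.call(cbind, parts)
  attr(x, "provenance") <- data.frame(column = colnames(x), source = prov,
                                      stringsAsFactors = FALSE)
  x
}

# stratified fold ids: within each class, shuffle and deal round-robin
stratified_folds <- function(labels, folds) {
  ids <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    ids[idx] <- rep_len(seq_len(folds), length(idx))
  }
  ids
}

#' Repeated stratified cross-validation of an SVM label classifier
#'
#' RBF-kernel SVM (cost 1, kernel width `1/(n_features * var)` via the e1071
#' default) trained on 4/5 of the samples per fold; feature standardization
#' parameters are fitted on the training folds only. Sensitivity treats the
#' high-risk subgroup (label 1) as the positive class.
#'
#' @param x samples-by-features numeric matrix.
#' @param labels 0/1 subgroup labels (1 = high-risk).
#' @param folds,reps folds per repetition and number of repetitions
#'   (defaults 5 and 10).
#' @param seed seed controlling fold assignment.
#' @return list of class `cv_report`: `per_fold` data.frame (rep, fold,
#'   accuracy, sensitivity, specificity), `mean` and `sd` summaries,
#'   `fold_ids` matrix, `seed`.
#' @export
crossvalidate_svm <- function(x, labels, folds = 5L, reps = 10L, seed = 1L) {
  stopifnot(is.matrix(x), nrow(x) == length(labels), nrow(x) >= folds)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("both classes must be present")
  n <- nrow(x)
  per_fold <- list(); fold_ids <- matrix(0L, n, reps)
  for (r in seq_len(reps)) {
    set.seed(derive_seed(seed, r))
    fid <- stratified_folds(labels, folds)
    # a training fold missing a class can only happen for tiny classes; refold
    tries <- 0
    while (any(vapply(seq_len(folds), function(f)
      length(unique(labels[fid != f])) < 2, logical(1)))) {
      warning("class absent from a training fold; refolding")
      fid <- stratified_folds(labels, folds)
      tries <- tries + 1
      if (tries > 10) stop("cannot build folds with both classes present")
    }
    fold_ids[, r] <- fid
    for (f in seq_len(folds)) {
      tr <- fid != f; te <- !tr
      mu <- colMeans(x[tr, , drop = FALSE])
      sdv <- apply(x[tr, , drop = FALSE], 2, stats::sd)
      sdv[sdv == 0] <- 1
      xt <- sweep(sweep(x[tr, , drop = FALSE], 2, mu), 2, sdv, "/")
      xv <- sweep(sweep(x[te, , drop = FALSE], 2, mu), 2, sdv, "/")
      fit <- e1071::svm(xt, factor(labels[tr], levels = c(0, 1)),
                        kernel = "radial", cost = 1, scale = FALSE)
      pred <- as.integer(as.character(predict(fit, xv)))
      truth <- labels[te]
      tp <- sum(pred == 1 & truth == 1); tn <- sum(pred == 0 & truth == 0)
      fp <- sum(pred == 1 & truth == 0); fn <- sum(pred == 0 & truth == 1)
      per_fold[[length(per_fold) + 1]] <- data.frame(
        rep = r, fold = f,
        accuracy = (tp + tn) / length(truth),
        sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
        specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
    }
  }
  per_fold <- do.call(rbind, per_fold)
  metrics <- c("accuracy", "sensitivity", "specificity")
  structure(list(
    per_fold = per_fold,
    mean = vapply(per_fold[metrics], mean, numeric(1), na.rm = TRUE),
    sd = vapply(per_fold[metrics], stats::sd, numeric(1), na.rm = TRUE),
    fold_ids = fold_ids, folds = folds, reps = reps, seed = seed
  ), class = "cv_report")
}
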