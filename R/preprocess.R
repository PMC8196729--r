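#' Drop unusable features from an omics block
#'
#' Removes any feature (column) that contains a missing value, is identically
#' zero, or has zero variance, and records the dropped IDs with reasons.
#' All-zero rather than any-zero removal is used so count-like data are not
#' annihilated; zero-variance removal makes later per-feature standardization
#' well defined.
#'
#' @param m samples-by-features numeric matrix with dimnames.
#' @return the filtered matrix; the drop log (data.frame `feature_id`,
#'   `reason`) is attached as attribute `"drop_log"`.
#' @export
filter_features <- function(m) {
  stopifnot(is.matrix(m), !is.null(colnames(m)))
  has_na <- apply(m, 2, function(x) any(!is.finite(x)))
  all_zero <- apply(m, 2, function(x) all(!is.na(x) & x == 0))
  zero_var <- apply(m, 2, function(x) {
    x <- x[is.finite(x)]
    length(x) < 2 || stats::var(x) == 0
  })
  drop <- has_na | all_zero | zero_var
  reason <- ifelse(has_na, "missing",
                   ifelse(all_zero, "all_zero", "zero_variance"))
  if (all(drop)) stop("all features dropped by filtering; nothing left to analyze")
  out <- m[, !drop, drop = FALSE]
  attr(out, "kind") <- attr(m, "kind")
  attr(out, "drop_log") <- data.frame(
    feature_id = colnames(m)[drop],
    reason = reason[drop],
    row.names = NULL, stringsAsFactors = FALSE
  )
  out
}

#' Standardize each feature to mean 0, SD 1
#'
#' Per-feature z-scoring (the reference semantics of the standard
#' normalization used by similarity-network tooling). Constant columns are an
#' error: filter first.
#'
#' @param m samples-by-features numeric matrix.
#' @return matrix of the same shape with unit-variance, zero-mean columns.
#' @export
normalize_features <- function(m) {
  stopifnot(is.matrix(m))
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0 | !is.finite(sds)))
    stop("constant or non-finite feature columns present; run filter_features() first")
  out <- scale(m)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  attr(out, "kind") <- attr(m, "kind")
  out
}

#' Align omics blocks and the clinical table on shared samples
#'
#' Keeps only samples present in every block and in the clinical table, in the
#' clinical table's order.
#'
#' @param blocks named list of samples-by-features matrices with row names.
#' @param clinical data.frame with a `sample_id` column (order defines output
#'   order); optional.
#' @return list of row-subset blocks, all with identical sample ordering.
#' @export
align_samples <- function(blocks, clinical = NULL) {
  ids <- Reduce(intersect, lapply(blocks, rownames))
  if (!is.null(clinical)) ids <- clinical$sample_id[clinical$sample_id %in% ids]
  if (length(ids) == 0) stop("no samples shared across all blocks")
  lapply(blocks, function(b) {
    out <- b[ids, , drop = FALSE]
    attr(out, "kind") <- attr(b, "kind")
    out
  })
}

#' Stack aligned omics blocks column-wise
#'
#' @param blocks named list of sample-aligned, filtered, normalized matrices.
#' @return matrix of width `sum(ncol)` with a `provenance` attribute mapping
#'   each stacked column to `(kind, feature_id)`; the map is invertible.
#' @export
stack_omics <- function(blocks) {
  stopifnot(length(blocks) >= 2)
  ref <- rownames(blocks[[1]])
  for (k in names(blocks)) {
    if (!identical(rownames(blocks[[k]]), ref)) {
      offenders <- union(setdiff(rownames(blocks[[k]]), ref),
                         setdiff(ref, rownames(blocks[[k]])))
      stop("sample IDs not aligned across blocks (block '", k, "'): ",
           paste(utils::head(offenders, 5), collapse = ", "),
           if (length(offenders) > 5) ", ..." else "")
    }
  }
  stacked <- do.call(cbind, lapply(blocks, unclass))
  prov <- do.call(rbind, lapply(names(blocks), function(k) {
    data.frame(kind = k, feature_id = colnames(blocks[[k]]),
               stringsAsFactors = FALSE)
  }))
  prov$column <- seq_len(nrow(prov))
  # stacked column names stay the original feature IDs; uniqueness across
  # blocks is guaranteed by the per-kind ID alphabets
  colnames(stacked) <- prov$feature_id
  if (anyDuplicated(colnames(stacked)))
    stop("duplicate feature IDs across blocks; cannot build an invertible provenance map")
  attr(stacked, "provenance") <- prov
  stacked
}

#' Filter, normalize and align a cohort's omics blocks
#'
#' Convenience wrapper running [filter_features()], [normalize_features()] and
#' [align_samples()] over the three blocks of a cohort.
#'
#' @param cohort a `cohort` (see [generate_cohort()]).
#' @return list with `blocks` (processed matrices), `drop_logs` and the
#'   aligned `survival` / `clinical` tables.
#' @export
preprocess_cohort <- function(cohort) {
  filtered <- lapply(cohort$omics, filter_features)
  drop_logs <- lapply(filtered, attr, "drop_log")
  normed <- lapply(filtered, normalize_features)
  blocks <- align_samples(normed, cohort$clinical)
  ids <- rownames(blocks[[1]])
  surv <- cohort$survival[match(ids, cohort$survival$sample_id), , drop = FALSE]
  clin <- cohort$clinical[match(ids, cohort$clinical$sample_id), , drop = FALSE]
  rownames(surv) <- rownames(clin) <- NULL
  list(blocks = blocks, drop_logs = drop_logs, survival = surv, clinical = clin)
}
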