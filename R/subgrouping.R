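#' K-means subtyping with silhouette-based model selection
#'
#' Runs seeded k-means (20 restarts) for each candidate k; the mean silhouette
#' width decides k (the elbow trace of within-cluster sums of squares is
#' reported as a diagnostic only). A silhouette below 0.25 everywhere triggers
#' a low-confidence warning.
#'
#' @param latent samples-by-features matrix (e.g. Cox-selected bottleneck
#'   nodes).
#' @param k_range candidate cluster counts (default 2:10).
#' @param seed seed for the k-means restarts.
#' @return list with `k`, `labels` (named integer vector), `silhouette` and
#'   `wss` traces indexed by k.
#' @export
kmeans_select_k <- function(latent, k_range = 2:10, seed = 1L) {
  stopifnot(is.matrix(latent), ncol(latent) >= 1)
  n <- nrow(latent)
  if (max(k_range) > n - 1) {
    warning("k_range truncated: fewer samples than largest candidate k")
    k_range <- k_range[k_range <= n - 1]
  }
  d <- stats::dist(latent)
  sil <- numeric(length(k_range)); wss <- numeric(length(k_range))
  fits <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    set.seed(derive_seed(seed, k_range[i]))
    km <- stats::kmeans(latent, centers = k_range[i], nstart = 20, iter.max = 100)
    fits[[i]] <- km
    wss[i] <- km$tot.withinss
    sil[i] <- mean(cluster::silhouette(km$cluster, d)[, "sil_width"])
  }
  best <- which.max(sil)
  if (max(sil) < 0.25)
    warning("low silhouette across all k; cluster structure is weak")
  labels <- stats::setNames(fits[[best]]$cluster, rownames(latent))
  list(k = k_range[best], labels = labels,
       silhouette = stats::setNames(sil, k_range),
       wss = stats::setNames(wss, k_range))
}

#' Tag two subgroups as high- or low-risk from their survival
#'
#' The subgroup with the shorter Kaplan-Meier median survival is tagged
#' high-risk; when a median is undefined (curve never drops below 0.5) or the
#' medians tie, the subgroup with the higher event rate is high-risk, with a
#' warning when even that ties.
#'
#' @param labels two-group integer labels.
#' @param surv [surv_data()] aligned to labels.
#' @return list with `risk_order` (named map label -> "high"/"low") and
#'   `high_risk` (per-sample 0/1 indicator, 1 = high-risk subgroup).
#' @export
assign_risk_order <- function(labels, surv) {
  lv <- sort(unique(labels))
  if (length(lv) != 2) stop("risk ordering requires exactly 2 subgroups")
  med <- vapply(lv, function(g) {
    sel <- labels == g
    fit <- survival::survfit(survival::Surv(surv$time[sel], surv$event[sel]) ~ 1)
    mt <- summary(fit)$table["median"]
    if (is.na(mt)) Inf else as.numeric(mt)
  }, numeric(1))
  if (med[1] != med[2]) {
    high <- lv[which.min(med)]   # an undefined median counts as Inf (longer)
  } else {
    rate <- vapply(lv, function(g) mean(surv$event[labels == g]), numeric(1))
    if (rate[1] == rate[2])
      warning("subgroups have identical median survival and event rate; arbitrary risk order")
    high <- lv[which.max(rate)]
  }
  risk_order <- stats::setNames(ifelse(lv == high, "high", "low"), lv)
  list(risk_order = risk_order,
       high_risk = as.integer(labels == high))
}

#' Wilcoxon rank-sum differential table between two subgroups
#'
#' Two-sided rank-sum test per feature (exact for small tie-free groups,
#' tie-corrected normal approximation otherwise, as implemented by
#' `stats::wilcox.test`); direction is the sign of (high-risk mean - low-risk
#' mean). Degenerate features (identical values) get p = 1 and direction 0.
#'
#' @param block samples-by-features matrix (one omics block).
#' @param high_risk 0/1 per-sample high-risk indicator from
#'   [assign_risk_order()].
#' @return data.frame `de_table`: `kind`, `feature_id`, `statistic`, `p`,
#'   `mean_high`, `mean_low`, `direction` (+1/-1/0).
#' @export
wilcoxon_de <- function(block, high_risk) {
  stopifnot(is.matrix(block), nrow(block) == length(high_risk))
  if (!any(high_risk == 1) || !any(high_risk == 0))
    stop("both subgroups must be nonempty")
  hi <- high_risk == 1
  res <- apply(block, 2, function(x) {
    mh <- mean(x[hi]); ml <- mean(x[!hi])
    if (stats::sd(x) == 0)
      return(c(statistic = NA_real_, p = 1, mean_high = mh, mean_low = ml,
               direction = 0))
    wt <- suppressWarnings(stats::wilcox.test(x[hi], x[!hi]))
    c(statistic = unname(wt$statistic), p = wt$p.value,
      mean_high = mh, mean_low = ml, direction = sign(mh - ml))
  })
  out <- as.data.frame(t(res))
  data.frame(kind = attr(block, "kind") %||% NA_character_,
             feature_id = colnames(block), out,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Top-N differential features per omics, concatenated
#'
#' Features are ranked by ascending p; ties broken by larger absolute
#' subgroup mean difference, then lexicographic feature ID, so the output is
#' deterministic.
#'
#' @param tables named list of `de_table`s (one per omics kind).
#' @param quotas named per-omics selection counts; defaults 100 expression,
#'   100 methylation, 50 miRNA.
#' @return data.frame of the selected rows in rank order, per-omics blocks
#'   concatenated in the order of `tables`.
#' @export
select_top_features <- function(tables,
                                quotas = c(expression = 100L, methylation = 100L,
                                           mirna = 50L)) {
  out <- lapply(names(tables), function(k) {
    tab <- tables[[k]]
    q <- quotas[[k]] %||% stop("no quota for omics kind: ", k)
    ord <- order(tab$p, -abs(tab$mean_high - tab$mean_low), tab$feature_id)
    tab <- tab[ord, , drop = FALSE]
    if (q > nrow(tab)) {
      warning(sprintf("quota %d exceeds available %d features for %s; taking all",
                      q, nrow(tab), k))
      q <- nrow(tab)
    }
    tab[seq_len(q), , drop = FALSE]
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Intersect the top feature lists of two subtyping arms
#'
#' Per-omics intersection of the two arms' top lists; for every shared
#' feature the differential directions of both arms (computed after high/low
#' risk alignment in each arm) are compared and flagged concordant or
#' discordant.
#'
#' @param top_a,top_b selected-feature data.frames from
#'   [select_top_features()] for the two arms.
#' @return data.frame with `kind`, `feature_id`, `p_a`, `p_b`, `direction_a`,
#'   `direction_b`, `concordant`.
#' @export
intersect_models <- function(top_a, top_b) {
  merged <- merge(top_a[, c("kind", "feature_id", "p", "direction")],
                  top_b[, c("kind", "feature_id", "p", "direction")],
                  by = c("kind", "feature_id"), suffixes = c("_a", "_b"))
  if (nrow(merged) == 0)
    return(data.frame(kind = character(0), feature_id = character(0),
                      p_a = numeric(0), p_b = numeric(0),
                      direction_a = numeric(0), direction_b = numeric(0),
                      concordant = logical(0)))
  merged$concordant <- merged$direction_a == merged$direction_b
  merged[order(merged$kind, merged$feature_id), ]
}
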