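#' Pick panel features from a cross-arm intersection
#'
#' Per omics kind, the `per_omics_count` intersected features with the
#' smallest differential p-value are taken; when the two arms assign a shared
#' feature different p-values, their mean decides the rank (ties: feature ID).
#'
#' @param intersection data.frame from [intersect_models()].
#' @param per_omics_count features to take per omics (default 2, giving the
#'   2 genes + 2 miRNAs + 2 methylation probes panel shape).
#' @return data.frame of picked rows, with a `p_rank` column (the mean p used
#'   for ranking). Omics kinds with fewer intersected features than requested
#'   contribute what they have, with a warning.
#' @export
pick_panel_features <- function(intersection, per_omics_count = 2L) {
  if (nrow(intersection) == 0) stop("empty intersection; nothing to pick from")
  intersection$p_rank <- (intersection$p_a + intersection$p_b) / 2
  out <- lapply(split(intersection, intersection$kind), function(tab) {
    tab <- tab[order(tab$p_rank, tab$feature_id), , drop = FALSE]
    if (nrow(tab) < per_omics_count)
      warning(sprintf("only %d intersected feature(s) for %s (wanted %d)",
                      nrow(tab), tab$kind[1], per_omics_count))
    tab[seq_len(min(per_omics_count, nrow(tab))), , drop = FALSE]
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fit a multivariate-Cox risk panel
#'
#' Optional univariate pre-screen (p < `screen_alpha`) of the candidate
#' features, then a joint Cox fit whose coefficients define the linear risk
#' score `sum(beta_i * x_i)`.
#'
#' @param x samples-by-features matrix containing the candidate features.
#' @param feature_ids candidate panel feature IDs (columns of `x`).
#' @param surv [surv_data()] aligned to rows of `x`.
#' @param screen_alpha univariate screen threshold; `NULL` disables the
#'   screen.
#' @return list of class `risk_panel`: `features`, `coefficients`, `cox`
#'   (the `cox_fit`), `cutoff` (NA until [find_cutoff()] is applied).
#' @export
fit_risk_panel <- function(x, feature_ids, surv, screen_alpha = 0.05) {
  missing_cols <- setdiff(feature_ids, colnames(x))
  if (length(missing_cols) > 0)
    stop("features not in matrix: ", paste(missing_cols, collapse = ", "))
  keep <- feature_ids
  if (!is.null(screen_alpha)) {
    scr <- univariate_cox_screen(x[, feature_ids, drop = FALSE], surv,
                                 alpha = screen_alpha)
    keep <- scr$selected
    if (length(keep) == 0)
      stop("no candidate feature passes the univariate screen; relax screen_alpha")
  }
  fit <- multivariate_cox(x[, keep, drop = FALSE], surv)
  structure(list(features = keep, coefficients = fit$coefficients,
                 cox = fit, cutoff = NA_real_,
                 clinical_coefficients = NULL),
            class = "risk_panel")
}

#' Linear risk scores of a panel
#'
#' `score_i = sum_j beta_j x_ij` over the panel features.
#'
#' @param panel a `risk_panel` (or any list with `features` and
#'   `coefficients`).
#' @param x samples-by-features matrix containing all panel features.
#' @return numeric per-sample scores, named by row names of `x`.
#' @export
compute_risk_scores <- function(panel, x) {
  missing_cols <- setdiff(panel$features, colnames(x))
  if (length(missing_cols) > 0)
    stop("features not in matrix: ", paste(missing_cols, collapse = ", "))
  drop(x[, panel$features, drop = FALSE] %*% panel$coefficients[panel$features])
}

#' Maximally selected log-rank cutpoint for a risk score
#'
#' Scans candidate cutoffs at the midpoints of consecutive sorted unique
#' scores restricted to the 10th-90th percentile window and returns the one
#' maximizing the log-rank statistic of the induced two-group split. The
#' resulting log-rank p at the chosen cutoff is optimistically biased by the
#' search; report it as such.
#'
#' @param scores per-sample risk scores.
#' @param surv [surv_data()] aligned to scores.
#' @return list with `cutoff`, `statistic` and the scanned `candidates`
#'   data.frame.
#' @export
find_cutoff <- function(scores, surv) {
  stopifnot(length(scores) == nrow(surv))
  if (length(scores) < 10) stop("need at least 10 samples for a cutpoint search")
  if (sum(surv$event) < 2) stop("need at least 2 events")
  u <- sort(unique(scores))
  if (length(u) < 2) stop("all scores equal; no cutpoint exists")
  mid <- (u[-1] + u[-length(u)]) / 2
  qs <- stats::quantile(scores, c(0.1, 0.9))
  cand <- mid[mid >= qs[1] & mid <= qs[2]]
  if (length(cand) == 0) cand <- mid
  stat <- vapply(cand, function(cc) {
    grp <- scores > cc
    if (all(grp) || !any(grp)) return(-Inf)
    tryCatch(logrank_test(as.integer(grp), surv)$statistic,
             error = function(e) -Inf)
  }, numeric(1))
  best <- which.max(stat)
  list(cutoff = cand[best], statistic = stat[best],
       candidates = data.frame(cutoff = cand, statistic = stat))
}

#' Evaluate a fitted risk panel
#'
#' Dichotomizes the score at the panel cutoff (computing it via
#' [find_cutoff()] if unset) and reports Kaplan-Meier curves per risk group,
#' the log-rank test of the split, Harrell's C-index of the continuous score,
#' and the cumulative/dynamic AUC at `horizon`. With `clinical` given, the
#' panel is refitted jointly with age, Gleason and ordinal stage and the same
#' metrics are reported for the combined score.
#'
#' @param panel a `risk_panel`.
#' @param x samples-by-features matrix with the panel features.
#' @param surv [surv_data()] aligned to rows.
#' @param clinical optional data.frame with `age`, `gleason`, `stage`.
#' @param horizon AUC horizon in months (default 60 = 5 years).
#' @return list with `scores`, `cutoff`, `groups` ("high"/"low"), `km`,
#'   `logrank`, `cindex`, `auc`, and (if clinical given) `clinical` holding
#'   the combined model's coefficients and metrics.
#' @export
evaluate_panel <- function(panel, x, surv, clinical = NULL, horizon = 60) {
  scores <- compute_risk_scores(panel, x)
  cutoff <- panel$cutoff
  if (is.na(cutoff)) cutoff <- find_cutoff(scores, surv)$cutoff
  grp <- ifelse(scores > cutoff, "high", "low")
  if (length(unique(grp)) < 2)
    stop("degenerate split: one risk group is empty at the chosen cutoff")
  res <- list(
    scores = scores, cutoff = cutoff, groups = grp,
    km = km_curve(surv, grp),
    logrank = logrank_test(grp, surv),
    cindex = concordance_index(scores, surv),
    auc = time_dependent_auc(scores, surv, horizon)$auc
  )
  if (!is.null(clinical)) {
    clin <- cbind(age = as.numeric(clinical$age),
                  gleason = as.numeric(clinical$gleason),
                  stage = as.numeric(factor(clinical$stage,
                                            levels = c("I", "II", "III", "IV"))))
    xc <- cbind(x[, panel$features, drop = FALSE], clin)
    fit <- multivariate_cox(xc, surv)
    sc <- drop(xc %*% fit$coefficients)
    cut2 <- find_cutoff(sc, surv)$cutoff
    grp2 <- ifelse(sc > cut2, "high", "low")
    res$clinical <- list(
      coefficients = fit$coefficients,
      scores = sc, cutoff = cut2,
      logrank = if (length(unique(grp2)) > 1) logrank_test(grp2, surv) else NULL,
      cindex = concordance_index(sc, surv),
      auc = time_dependent_auc(sc, surv, horizon)$auc
    )
  }
  res
}
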