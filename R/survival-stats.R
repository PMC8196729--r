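#' Assemble a survival data.frame
#'
#' @param time positive follow-up times (months).
#' @param event 0/1 event indicator (1 = recurrence observed).
#' @param sample_id optional IDs.
#' @return data.frame with `sample_id`, `time`, `event`.
#' @export
surv_data <- function(time, event, sample_id = NULL) {
  stopifnot(length(time) == length(event))
  if (any(time <= 0)) stop("survival times must be positive")
  if (!all(event %in% c(0, 1))) stop("event indicator must be 0/1")
  if (is.null(sample_id)) sample_id <- sprintf("SAMP_%04d", seq_along(time))
  data.frame(sample_id = sample_id, time = as.numeric(time),
             event = as.integer(event), stringsAsFactors = FALSE)
}

#' Univariate Cox screen over feature columns
#'
#' One single-covariate Cox proportional-hazards fit (Efron ties) per feature;
#' features whose Wald p-value is below `alpha` are retained in input order.
#' Raw p-values are used, matching the screening rule of the reproduced study;
#' set `fdr = TRUE` for a Benjamini-Hochberg variant.
#'
#' @param features samples-by-features numeric matrix with column names.
#' @param surv [surv_data()] aligned to the rows of `features`.
#' @param alpha selection threshold on the Wald p-value (default 0.05).
#' @param fdr apply Benjamini-Hochberg adjustment before thresholding.
#' @return list with `selected` (feature IDs), and `fits`: a data.frame of
#'   per-feature coefficient, SE, Wald p and convergence flag. Constant or
#'   non-convergent features are skipped with a warning, never selected.
#' @export
univariate_cox_screen <- function(features, surv, alpha = 0.05, fdr = FALSE) {
  stopifnot(is.matrix(features), nrow(features) == nrow(surv))
  if (sum(surv$event) < 2) stop("need at least 2 events to screen")
  y <- survival::Surv(surv$time, surv$event)
  res <- lapply(seq_len(ncol(features)), function(j) {
    x <- features[, j]
    if (stats::sd(x) == 0)
      return(list(coef = NA_real_, se = NA_real_, p = NA_real_, ok = FALSE))
    fit <- tryCatch(
      survival::coxph(y ~ x, ties = "efron",
                      control = survival::coxph.control(eps = 1e-9, iter.max = 100)),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit) || !is.finite(fit$coefficients[1]))
      return(list(coef = NA_real_, se = NA_real_, p = NA_real_, ok = FALSE))
    se <- sqrt(diag(fit$var))[1]
    z <- fit$coefficients[1] / se
    list(coef = unname(fit$coefficients[1]), se = se,
         p = 2 * stats::pnorm(-abs(z)), ok = TRUE)
  })
  fits <- data.frame(
    feature_id = colnames(features),
    coef = vapply(res, `[[`, numeric(1), "coef"),
    se = vapply(res, `[[`, numeric(1), "se"),
    p = vapply(res, `[[`, numeric(1), "p"),
    converged = vapply(res, `[[`, logical(1), "ok"),
    stringsAsFactors = FALSE
  )
  if (any(!fits$converged))
    warning(sprintf("%d feature(s) skipped (constant or non-convergent Cox fit)",
                    sum(!fits$converged)))
  p_use <- if (fdr) stats::p.adjust(fits$p, "BH") else fits$p
  selected <- fits$feature_id[fits$converged & !is.na(p_use) & p_use < alpha]
  list(selected = selected, fits = fits)
}

#' Multivariate Cox proportional-hazards fit
#'
#' @param features samples-by-covariates matrix (column names = covariates).
#' @param surv [surv_data()] aligned to rows.
#' @return list of class `cox_fit`: `coefficients`, `se`, `p` (Wald), `loglik`
#'   (partial log-likelihood at the solution), `converged`, and the underlying
#'   `coxph` fit.
#' @export
multivariate_cox <- function(features, surv) {
  stopifnot(is.matrix(features), nrow(features) == nrow(surv))
  if (nrow(features) <= ncol(features))
    stop("need more samples than covariates")
  qr_x <- qr(cbind(features))
  if (qr_x$rank < ncol(features)) {
    dep <- colnames(features)[qr_x$pivot[(qr_x$rank + 1):ncol(features)]]
    stop("singular design; collinear columns: ", paste(dep, collapse = ", "))
  }
  df <- data.frame(features, check.names = FALSE)
  df$.time <- surv$time; df$.event <- surv$event
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", colnames(features)), collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = "efron",
                         control = survival::coxph.control(eps = 1e-9, iter.max = 100))
  se <- sqrt(diag(fit$var))
  z <- fit$coefficients / se
  structure(list(
    coefficients = stats::setNames(as.numeric(fit$coefficients), colnames(features)),
    se = stats::setNames(se, colnames(features)),
    p = stats::setNames(2 * stats::pnorm(-abs(z)), colnames(features)),
    loglik = fit$loglik[2],
    converged = all(is.finite(fit$coefficients)),
    fit = fit
  ), class = "cox_fit")
}

#' Harrell's concordance index
#'
#' A pair is comparable iff the smaller observed time belongs to an event; a
#' comparable pair is concordant when the higher risk score has the shorter
#' time; tied scores count 1/2. Tied times with both events are not
#' comparable.
#'
#' @param risk finite per-sample risk scores (higher = worse prognosis).
#' @param surv [surv_data()] aligned to `risk`.
#' @return concordance in `[0,1]`.
#' @export
concordance_index <- function(risk, surv) {
  stopifnot(length(risk) == nrow(surv))
  if (any(!is.finite(risk))) stop("non-finite risk scores")
  time <- surv$time; event <- surv$event
  n <- length(risk)
  conc <- 0; comp <- 0
  for (i in seq_len(n)) {
    if (event[i] != 1) next
    # pairs where i has the strictly smaller time and an event
    j <- which(time > time[i] | (time == time[i] & event == 0))
    j <- j[j != i]
    if (length(j) == 0) next
    comp <- comp + length(j)
    conc <- conc + sum(risk[i] > risk[j]) + 0.5 * sum(risk[i] == risk[j])
  }
  if (comp == 0) stop("no comparable pairs; concordance undefined")
  conc / comp
}

#' Log-rank test between survival groups
#'
#' @param labels per-sample group labels (>= 2 nonempty groups).
#' @param surv [surv_data()] aligned to `labels`.
#' @return list with `statistic` (chi-square), `df`, `p`.
#' @export
logrank_test <- function(labels, surv) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2) stop("need at least 2 nonempty groups")
  if (sum(surv$event) < 1) stop("need at least 1 event")
  sd <- survival::survdiff(survival::Surv(surv$time, surv$event) ~ labels)
  df <- length(sd$n) - 1
  list(statistic = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Kaplan-Meier survival curve
#'
#' @param surv [surv_data()].
#' @param labels optional group labels; one curve per group if given.
#' @return data.frame with `time`, `surv`, `n_risk`, `n_event` (and `group`
#'   when labels are given); the product-limit estimate starts at 1 and is
#'   right-continuous.
#' @export
km_curve <- function(surv, labels = NULL) {
  y <- survival::Surv(surv$time, surv$event)
  if (is.null(labels)) {
    fit <- survival::survfit(y ~ 1)
    data.frame(time = fit$time, surv = fit$surv,
               n_risk = fit$n.risk, n_event = fit$n.event)
  } else {
    g <- as.factor(labels)
    fit <- survival::survfit(y ~ g)
    grp <- rep(sub("^g=", "", names(fit$strata)), fit$strata)
    data.frame(group = grp, time = fit$time, surv = fit$surv,
               n_risk = fit$n.risk, n_event = fit$n.event)
  }
}

# Kaplan-Meier estimate of the censoring distribution G(t); returns a step
# function evaluator using left limits G(t-)
censoring_km <- function(surv) {
  fit <- survival::survfit(survival::Surv(surv$time, 1 - surv$event) ~ 1)
  times <- fit$time; s <- fit$surv
  function(t, left = FALSE) {
    vapply(t, function(tt) {
      idx <- if (left) which(times < tt) else which(times <= tt)
      if (length(idx) == 0) 1 else s[max(idx)]
    }, numeric(1))
  }
}

#' Time-dependent cumulative/dynamic AUC at a horizon
#'
#' Discrimination of a risk score for events occurring by `horizon`, under
#' right censoring, using inverse-probability-of-censoring weights from a
#' Kaplan-Meier estimate of the censoring distribution: cases (event by the
#' horizon) are weighted by `1/G(T_i-)`, controls (still at risk past the
#' horizon) by `1/G(horizon)`. Without censoring this reduces to the ordinary
#' binary AUC of "event by horizon".
#'
#' @param risk per-sample risk scores (higher = earlier event expected).
#' @param surv [surv_data()].
#' @param horizon evaluation horizon in the time unit of `surv` (e.g. 60
#'   months for 5 years).
#' @return list with `auc` and `roc`, a data.frame of (fpr, tpr) points over
#'   score thresholds.
#' @export
time_dependent_auc <- function(risk, surv, horizon) {
  stopifnot(length(risk) == nrow(surv))
  if (horizon <= 0 || horizon > max(surv$time))
    stop("horizon outside the observed time range")
  is_case <- surv$time <= horizon & surv$event == 1
  is_ctrl <- surv$time > horizon
  if (!any(is_case) || !any(is_ctrl))
    stop("no cases or no controls at the requested horizon")
  g <- censoring_km(surv)
  w <- numeric(length(risk))
  w[is_case] <- 1 / pmax(g(surv$time[is_case], left = TRUE), 1e-10)
  w[is_ctrl] <- 1 / pmax(g(horizon), 1e-10)
  cases <- which(is_case); ctrls <- which(is_ctrl)
  num <- 0
  for (i in cases) {
    num <- num + w[i] * sum(w[ctrls] * ((risk[i] > risk[ctrls]) +
                                          0.5 * (risk[i] == risk[ctrls])))
  }
  auc <- num / (sum(w[cases]) * sum(w[ctrls]))
  thr <- sort(unique(risk), decreasing = TRUE)
  roc <- data.frame(
    fpr = vapply(thr, function(c) sum(w[ctrls] * (risk[ctrls] >= c)) / sum(w[ctrls]), numeric(1)),
    tpr = vapply(thr, function(c) sum(w[cases] * (risk[cases] >= c)) / sum(w[cases]), numeric(1))
  )
  roc <- rbind(data.frame(fpr = 0, tpr = 0), roc)
  list(auc = auc, roc = roc)
}
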