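#' Configuration for an end-to-end run
#'
#' One global seed fans out deterministically to every stochastic stage
#' (autoencoder initialization/batching, k-means restarts, CV folds).
#'
#' @param snf an [snf_config()].
#' @param ae an [ae_config()].
#' @param screen_alpha univariate Cox screen threshold for latent nodes and
#'   panel candidates.
#' @param quotas per-omics top-N selection counts.
#' @param k_range candidate cluster numbers for both arms.
#' @param cv_folds,cv_reps cross-validation settings.
#' @param panel_per_omics panel features per omics kind.
#' @param horizon evaluation horizon in months.
#' @param seed global seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(snf = snf_config(), ae = ae_config("tuned"),
                       screen_alpha = 0.05,
                       quotas = c(expression = 100L, methylation = 100L, mirna = 50L),
                       k_range = 2:10, cv_folds = 5L, cv_reps = 10L,
                       panel_per_omics = 2L, horizon = 60, seed = 1L) {
  structure(list(snf = snf, ae = ae, screen_alpha = screen_alpha,
                 quotas = quotas, k_range = k_range, cv_folds = cv_folds,
                 cv_reps = cv_reps, panel_per_omics = panel_per_omics,
                 horizon = horizon, seed = seed),
            class = "run_config")
}

# polynomial rolling hash (mod 2^31 - 1, exact in doubles) over the JSON
# rendering of an object; manifest identity marker only
config_hash <- function(obj) {
  s <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, force = TRUE)
  h <- 0
  for (b in utf8ToInt(as.character(s))) {
    h <- (h * 131 + b) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

# shared two-subgroup machinery for one arm: risk order + survival metrics
arm_two_group_summary <- function(labels, surv) {
  ro <- assign_risk_order(labels, surv)
  list(
    risk_order = ro$risk_order,
    high_risk = ro$high_risk,
    logrank = logrank_test(ro$high_risk, surv),
    cindex = concordance_index(ro$high_risk, surv)
  )
}

#' Run the two-arm subtyping workflow on a cohort
#'
#' Preprocesses the three omics blocks, derives two-subgroup labels with both
#' arms (similarity network fusion + spectral clustering; stacked autoencoder
#' + Cox-screened bottleneck nodes + k-means), aligns each arm's labels to
#' high/low recurrence risk, computes per-arm log-rank and C-index, ranks
#' differential features per omics per arm, selects the top-N lists and
#' intersects them across arms. Cluster-number estimates are reported; the
#' recurrence-risk machinery itself is two-group, so when an arm's estimate
#' is not 2 the arm is reclustered at k = 2 with a warning.
#'
#' @param cohort a `cohort` (see [generate_cohort()], [prad_preset()]).
#' @param cfg a [run_config()].
#' @return list with `prep`, per-arm results under `arms$snf` / `arms$ae`,
#'   `intersection`, and a `manifest`.
#' @export
run_subtyping <- function(cohort, cfg = run_config()) {
  prep <- preprocess_cohort(cohort)
  surv <- surv_data(prep$survival$time, prep$survival$event,
                    prep$survival$sample_id)

  # --- SNF arm ---------------------------------------------------------------
  snf_cfg <- cfg$snf
  snf_cfg$k_range <- intersect(cfg$k_range, snf_cfg$k_range)
  affinities <- lapply(prep$blocks, function(b)
    affinity_matrix(pairwise_distance(b), snf_cfg))
  fused <- fuse_networks(affinities, snf_cfg)
  k_est <- estimate_num_clusters(fused, snf_cfg)
  k_snf <- k_est$k_eigengap
  if (k_snf != 2) {
    warning(sprintf("SNF eigen-gap estimate k = %d; reclustering at k = 2 for the recurrence-risk analysis", k_snf))
  }
  snf_labels <- spectral_cluster(fused, 2L, seed = derive_seed(cfg$seed, 11))
  snf_arm <- c(list(labels = snf_labels, k_estimates = k_est, fused = fused),
               arm_two_group_summary(snf_labels, surv))

  # --- autoencoder arm -------------------------------------------------------
  stacked <- stack_omics(prep$blocks)
  ae_cfg <- cfg$ae
  ae_cfg$seed <- derive_seed(cfg$seed, 21)
  model <- train_autoencoder(stacked, ae_cfg)
  latent <- encode(model, stacked)
  screen <- univariate_cox_screen(latent, surv, alpha = cfg$screen_alpha)
  sel_nodes <- screen$selected
  if (length(sel_nodes) < 2) {
    warning("fewer than 2 Cox-selected bottleneck nodes; using all nodes")
    sel_nodes <- colnames(latent)
  }
  km <- kmeans_select_k(latent[, sel_nodes, drop = FALSE],
                        k_range = cfg$k_range, seed = derive_seed(cfg$seed, 22))
  ae_labels <- km$labels
  if (km$k != 2) {
    warning(sprintf("silhouette-optimal k = %d; reclustering at k = 2 for the recurrence-risk analysis", km$k))
    set.seed(derive_seed(cfg$seed, 23))
    ae_labels <- stats::setNames(
      stats::kmeans(latent[, sel_nodes, drop = FALSE], centers = 2,
                    nstart = 20, iter.max = 100)$cluster,
      rownames(latent))
  }
  ae_arm <- c(list(labels = ae_labels, k_selection = km, model = model,
                   latent = latent, selected_nodes = sel_nodes,
                   node_screen = screen$fits),
              arm_two_group_summary(ae_labels, surv))

  # --- differential features + intersection ---------------------------------
  de_for <- function(high_risk) lapply(prep$blocks, wilcoxon_de, high_risk = high_risk)
  snf_arm$de_tables <- de_for(snf_arm$high_risk)
  ae_arm$de_tables <- de_for(ae_arm$high_risk)
  snf_arm$top_features <- select_top_features(snf_arm$de_tables, cfg$quotas)
  ae_arm$top_features <- select_top_features(ae_arm$de_tables, cfg$quotas)
  intersection <- intersect_models(ae_arm$top_features, snf_arm$top_features)

  list(
    prep = prep, survival = surv,
    arms = list(snf = snf_arm, ae = ae_arm),
    intersection = intersection,
    manifest = list(
      config_hash = config_hash(cfg[setdiff(names(cfg), "seed")]),
      seed = cfg$seed,
      n_samples = nrow(stacked),
      artifacts = c("arms$snf$labels", "arms$snf$de_tables", "arms$snf$top_features",
                    "arms$ae$labels", "arms$ae$de_tables", "arms$ae$top_features",
                    "intersection")
    )
  )
}

#' Build and evaluate the multiomics risk panel from subtyping outputs
#'
#' Picks the per-omics most significant intersected features, pre-screens them
#' by univariate Cox, fits the multivariate-Cox risk score, locates the
#' maximally selected log-rank cutoff and evaluates the panel with and
#' (optionally) without clinical covariates.
#'
#' @param subtyping output of [run_subtyping()].
#' @param cfg the same [run_config()].
#' @param with_clinical also fit/evaluate the panel + clinical model.
#' @return list with `panel`, `picked`, `evaluation`.
#' @export
run_panel <- function(subtyping, cfg = run_config(), with_clinical = TRUE) {
  if (nrow(subtyping$intersection) == 0)
    stop("empty cross-arm intersection; increase the top-N quotas and rerun")
  picked <- pick_panel_features(subtyping$intersection, cfg$panel_per_omics)
  x <- do.call(cbind, lapply(subtyping$prep$blocks, unclass))
  surv <- subtyping$survival
  panel <- fit_risk_panel(x, picked$feature_id, surv,
                          screen_alpha = cfg$screen_alpha)
  scores <- compute_risk_scores(panel, x)
  panel$cutoff <- find_cutoff(scores, surv)$cutoff
  evaluation <- evaluate_panel(
    panel, x, surv,
    clinical = if (with_clinical) subtyping$prep$clinical else NULL,
    horizon = cfg$horizon)
  list(panel = panel, picked = picked, evaluation = evaluation)
}

#' Serialize a risk panel to JSON
#'
#' @param panel a `risk_panel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel_json <- function(panel, path) {
  obj <- list(features = panel$features,
              coefficients = as.list(panel$coefficients),
              cutoff = panel$cutoff)
  if (!is.null(panel$clinical_coefficients))
    obj$clinical_coefficients <- as.list(panel$clinical_coefficients)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
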