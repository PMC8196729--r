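test_that("silhouette-driven k-means finds well-separated planted blobs", {
  set.seed(1)
  x <- rbind(matrix(rnorm(40 * 3, 0), ncol = 3),
             matrix(rnorm(40 * 3, 6), ncol = 3))
  rownames(x) <- sprintf("S%03d", 1:80)
  res <- kmeans_select_k(x, k_range = 2:6, seed = 2)
  expect_equal(res$k, 2)
  expect_equal(ari(res$labels, rep(1:2, each = 40)), 1)

  hits <- vapply(1:10, function(s) {
    set.seed(s)
    y <- rbind(matrix(rnorm(25 * 2, 0), ncol = 2),
               matrix(rnorm(25 * 2, 6), ncol = 2),
               matrix(c(rnorm(25, 12), rnorm(25, 0)), ncol = 2))
    rownames(y) <- sprintf("S%03d", 1:75)
    kmeans_select_k(y, k_range = 2:6, seed = s)$k == 3
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("structureless data yields a low-confidence warning; oversized k range truncates", {
  set.seed(9)
  x <- matrix(rnorm(60 * 4), 60, 4, dimnames = list(sprintf("S%d", 1:60), NULL))
  expect_warning(kmeans_select_k(x, k_range = 2:5, seed = 1), "low silhouette")
  small <- x[1:4, ]
  expect_warning(res <- suppressWarnings(kmeans_select_k(small, k_range = 2:10, seed = 1)) ,
                 NA)
  expect_lte(res$k, 3)
})

test_that("risk ordering tags the planted high-hazard subgroup and ignores label names", {
  sim <- sim_surv(300, hr = 4, seed = 14)
  labels <- sim$group + 1L
  ro <- assign_risk_order(labels, sim$surv)
  expect_identical(unname(ro$risk_order[as.character(2)]), "high")
  expect_identical(ro$high_risk, as.integer(sim$group == 1))
  ro_swap <- assign_risk_order(3L - labels, sim$surv)
  expect_identical(ro_swap$high_risk, ro$high_risk)
})

test_that("identical survival in both subgroups triggers the tie warning", {
  base <- surv_data(rep(c(3, 6, 9, 12), 2), rep(c(1, 0, 1, 0), 2))
  expect_warning(assign_risk_order(rep(1:2, each = 4), base), "identical")
})

test_that("rank-sum table matches an exact enumeration oracle on a small toy", {
  x <- c(1.2, 3.4, 2.2, 5.1, 0.7, 4.4, 2.9, 3.8)
  grp <- c(1, 1, 1, 1, 0, 0, 0, 0)
  block <- cbind(f1 = x)
  rownames(block) <- sprintf("S%d", 1:8)
  de <- wilcoxon_de(block, grp)

  # exact two-sided rank-sum p by complete enumeration of group assignments
  ranks <- rank(x)
  w_obs <- sum(ranks[grp == 1]) - 4 * 5 / 2   # Mann-Whitney U
  combs <- combn(8, 4)
  u_all <- apply(combs, 2, function(idx) sum(ranks[idx]) - 10)
  # U is centered at n1*n2/2 = 8 under the null
  p_exact <- mean(abs(u_all - 8) >= abs(w_obs - 8))
  expect_equal(de$p, p_exact, tolerance = 1e-12)
  expect_equal(unname(de$statistic), w_obs)
})

test_that("rank-sum direction flips under label swap, p and degenerate cases behave", {
  set.seed(6)
  block <- matrix(rnorm(60 * 4), 60, 4,
                  dimnames = list(sprintf("S%d", 1:60), paste0("f", 1:4)))
  block[, 1] <- block[, 1] + rep(c(2, 0), each = 30)
  block[, 4] <- 7   # degenerate
  grp <- rep(c(1, 0), each = 30)
  de <- wilcoxon_de(block, grp)
  de_sw <- wilcoxon_de(block, 1 - grp)
  expect_equal(de$p, de_sw$p, tolerance = 1e-12)
  expect_equal(de$direction[1:3], -de_sw$direction[1:3])
  expect_equal(de$p[4], 1)
  expect_equal(de$direction[4], 0)

  same <- cbind(g = rep(1:5, 2))
  rownames(same) <- sprintf("S%d", 1:10)
  expect_equal(wilcoxon_de(same, rep(c(1, 0), each = 5))$p, 1)
})

test_that("top-N selection honors quotas, ordering and deterministic ties", {
  tab <- function(p, md, ids, kind) {
    data.frame(kind = kind, feature_id = ids, statistic = NA, p = p,
               mean_high = md, mean_low = 0, direction = sign(md))
  }
  tables <- list(
    expression = tab(c(0.5, 0.001, 0.02), c(1, 2, 3), c("g1", "g2", "g3"), "expression"),
    methylation = tab(c(0.2, 0.2, 0.2), c(1, 3, 2), c("m1", "m2", "m3"), "methylation"),
    mirna = tab(c(0.9, 0.1), c(1, 1), c("r1", "r2"), "mirna")
  )
  out <- select_top_features(tables, c(expression = 2L, methylation = 2L, mirna = 1L))
  expect_identical(out$feature_id, c("g2", "g3", "m2", "m3", "r2"))
  # all-tied p: ordering by |mean diff| then ID, reproducible
  out2 <- select_top_features(tables["methylation"], c(methylation = 3L))
  expect_identical(out2$feature_id, c("m2", "m3", "m1"))
  expect_warning(select_top_features(tables["mirna"], c(mirna = 5L)), "quota")
})

test_that("default quotas produce the 250-feature combined list", {
  coh <- small_cohort(n = 60, seed = 4)
  blocks <- lapply(coh$omics, function(b) {
    b <- b[, 1:min(ncol(b), 120), drop = FALSE]; b
  })
  # widen blocks enough for the full default quotas
  set.seed(1)
  blocks$expression <- cbind(blocks$expression,
    matrix(rnorm(60 * 60), 60, dimnames = list(NULL, sprintf("extra_%d", 1:60))))
  attr(blocks$expression, "kind") <- "expression"
  blocks$methylation <- cbind(blocks$methylation,
    matrix(rnorm(60 * 60), 60, dimnames = list(NULL, sprintf("xm_%d", 1:60))))
  attr(blocks$methylation, "kind") <- "methylation"
  blocks$mirna <- cbind(blocks$mirna,
    matrix(rnorm(60 * 30), 60, dimnames = list(NULL, sprintf("xr_%d", 1:30))))
  attr(blocks$mirna, "kind") <- "mirna"
  grp <- unname(coh$truth)
  tables <- lapply(blocks, wilcoxon_de, high_risk = grp)
  out <- select_top_features(tables)
  expect_equal(nrow(out), 250)
  expect_equal(as.vector(table(factor(out$kind, c("expression", "methylation", "mirna")))),
               c(100, 100, 50))
})

test_that("intersection reports shared features and direction concordance", {
  a <- data.frame(kind = "expression", feature_id = c("g1", "g2", "g3"),
                  p = c(0.01, 0.02, 0.03), direction = c(1, -1, 1))
  b <- data.frame(kind = "expression", feature_id = c("g2", "g3", "g4"),
                  p = c(0.05, 0.01, 0.2), direction = c(-1, -1, 1))
  res <- intersect_models(a, b)
  expect_setequal(res$feature_id, c("g2", "g3"))
  expect_true(res$concordant[res$feature_id == "g2"])
  expect_false(res$concordant[res$feature_id == "g3"])

  expect_equal(nrow(intersect_models(a, a)), 3)
  expect_true(all(intersect_models(a, a)$concordant))
  b2 <- b; b2$feature_id <- c("x1", "x2", "x3")
  expect_equal(nrow(intersect_models(a, b2)), 0)
})
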