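test_that("pairwise distances are squared Euclidean: toys and brute force", {
  m <- rbind(a = c(0, 0), b = c(3, 4))
  d <- pairwise_distance(m)
  expect_equal(d["a", "b"], 25)
  expect_equal(diag(d), c(a = 0, b = 0))

  m2 <- toy_matrix(10, 5, seed = 2)
  d2 <- pairwise_distance(m2)
  oracle <- matrix(0, 10, 10)
  for (i in 1:10) for (j in 1:10) oracle[i, j] <- sum((m2[i, ] - m2[j, ])^2)
  expect_equal(unname(d2), oracle, tolerance = 1e-10)

  m3 <- m2; m3[3, ] <- m3[7, ]
  expect_equal(pairwise_distance(m3)[3, 7], 0)
  m4 <- m2; m4[1, 1] <- NA
  expect_error(pairwise_distance(m4), "non-finite")
})

test_that("affinity kernel matches a hand computation on a 4-point toy", {
  m <- cbind(x = c(0, 1, 4, 9))
  rownames(m) <- letters[1:4]
  cfg <- snf_config(K = 1, sigma = 0.5, t = 1)
  w <- affinity_matrix(pairwise_distance(m), cfg)
  # hand oracle: d = squared distances; eps_ij = (nn_i + nn_j + d_ij)/3 with
  # nn_i the single nearest-neighbor squared distance
  d <- as.matrix(dist(m))^2
  nn <- apply(d + diag(Inf, 4), 1, min)
  w_hand <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    eps <- (nn[i] + nn[j] + d[i, j]) / 3
    w_hand[i, j] <- exp(-d[i, j] / (0.5 * eps))
  }
  w_hand <- (w_hand + t(w_hand)) / 2
  expect_equal(unname(w), w_hand, tolerance = 1e-12)
  expect_true(all(diag(w) >= apply(w, 1, max) - 1e-12))
})

test_that("affinity on (near-)zero distances hits the guarded floor", {
  m <- matrix(1, 5, 3, dimnames = list(sprintf("S%d", 1:5), c("a", "b", "c")))
  expect_warning(w <- affinity_matrix(pairwise_distance(m), snf_config(K = 2)),
                 "degenerate")
  expect_equal(unname(w), matrix(1, 5, 5))
})

test_that("affinity construction is permutation-equivariant", {
  m <- toy_matrix(12, 4, seed = 9)
  cfg <- snf_config(K = 3)
  w <- affinity_matrix(pairwise_distance(m), cfg)
  perm <- sample(12)
  wp <- affinity_matrix(pairwise_distance(m[perm, ]), cfg)
  expect_equal(unname(wp), unname(w[perm, perm]), tolerance = 1e-12)
})

test_that("one fusion step equals the hand-executed cross-diffusion update", {
  set.seed(4)
  w1 <- planted_affinity(2, 2, seed = 1)  # 4 nodes
  w2 <- planted_affinity(2, 2, seed = 2)
  dimnames(w2) <- dimnames(w1)
  cfg <- snf_config(K = 1, t = 1)

  # independent oracle: explicit matrix products with the status/kernel
  # normalizations written out
  status <- function(w) {
    n <- nrow(w); p <- matrix(0, n, n)
    for (i in 1:n) {
      srow <- sum(w[i, -i])
      for (j in setdiff(1:n, i)) p[i, j] <- w[i, j] / (2 * srow)
      p[i, i] <- 0.5
    }
    p
  }
  kern <- function(w, K) {
    n <- nrow(w); s <- matrix(0, n, n)
    for (i in 1:n) {
      nb <- order(w[i, ], decreasing = TRUE)[1:(K + 1)]
      s[i, nb] <- w[i, nb] / sum(w[i, nb])
    }
    s
  }
  p1 <- status(w1); p1 <- (p1 + t(p1)) / 2
  p2 <- status(w2); p2 <- (p2 + t(p2)) / 2
  s1 <- kern(w1, 1); s2 <- kern(w2, 1)
  q1 <- status(s1 %*% p2 %*% t(s1)); q1 <- (q1 + t(q1)) / 2
  q2 <- status(s2 %*% p1 %*% t(s2)); q2 <- (q2 + t(q2)) / 2
  oracle <- (q1 + q2) / 2
  oracle <- (oracle + t(oracle)) / 2

  fused <- fuse_networks(list(w1, w2), cfg)
  expect_equal(unname(fused), unname(oracle), tolerance = 1e-10)
})

test_that("fused output is symmetric, nonnegative, finite; ids must align", {
  ws <- lapply(1:3, function(s)
    affinity_matrix(pairwise_distance(toy_matrix(15, 6, seed = s)),
                    snf_config(K = 4)))
  fused <- fuse_networks(ws, snf_config(K = 4, t = 5))
  expect_true(isSymmetric(fused, tol = 1e-10))
  expect_true(all(fused >= 0) && all(is.finite(fused)))
  w_bad <- ws[[2]]
  rownames(w_bad)[1] <- "ZZZ"
  expect_error(fuse_networks(list(ws[[1]], w_bad), snf_config(K = 4)),
               "align")
})

test_that("fusing identical views preserves the induced clustering", {
  w <- planted_affinity(2, 15, within = 0.8, between = 0.1, noise = 0.1,
                        seed = 6)
  base <- spectral_cluster(w, 2, seed = 1)
  fused <- fuse_networks(list(w, w, w), snf_config(K = 5, t = 10))
  lab <- spectral_cluster(fused, 2, seed = 1)
  expect_equal(ari(lab, base), 1)
})

test_that("spectral clustering recovers exact and noisy planted blocks", {
  w <- planted_affinity(2, 10, within = 1, between = 0, noise = 0, seed = 1)
  lab <- spectral_cluster(w, 2, seed = 3)
  expect_equal(ari(lab, attr(w, "truth")), 1)

  aris <- vapply(1:20, function(s) {
    wn <- planted_affinity(3, 12, within = 0.85, between = 0.1, noise = 0.07,
                           seed = s)
    ari(spectral_cluster(wn, 3, seed = s), attr(wn, "truth"))
  }, numeric(1))
  expect_gte(mean(aris), 0.95)
})

test_that("spectral labels are equivariant to sample permutation", {
  w <- planted_affinity(2, 8, noise = 0.05, seed = 3)
  lab <- spectral_cluster(w, 2, seed = 1)
  perm <- sample(16)
  lab_p <- spectral_cluster(w[perm, perm], 2, seed = 1)
  expect_equal(ari(lab_p, lab[perm]), 1)
})

test_that("eigen-gap finds exact block multiplicity; degenerate input warns", {
  w <- planted_affinity(2, 10, within = 1, between = 0, noise = 0, seed = 1)
  est <- estimate_num_clusters(w, snf_config(K = 3, k_range = 2:6))
  expect_equal(est$k_eigengap, 2)

  flat <- matrix(1, 12, 12)
  expect_warning(est2 <- estimate_num_clusters(flat, snf_config(K = 3, k_range = 2:6)),
                 "no eigen-gap")
  expect_equal(est2$k_eigengap, 2)
})

test_that("rotation cost is reported alongside the eigen-gap", {
  w <- planted_affinity(3, 12, within = 0.9, between = 0.05, noise = 0.03,
                        seed = 2)
  est <- estimate_num_clusters(w, snf_config(K = 4, k_range = 2:6))
  expect_equal(est$k_eigengap, 3)
  expect_equal(est$k_rotation, 3)
  expect_length(est$rotation_cost, 5)
})
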