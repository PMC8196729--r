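#' SNF hyperparameters
#'
#' @param K neighborhood size used both for the self-tuning kernel bandwidth
#'   and the sparse diffusion kernel (default 20).
#' @param sigma kernel bandwidth multiplier (default 0.5).
#' @param t number of cross-diffusion iterations (default 20).
#' @param k_range candidate cluster numbers (default 2:10).
#' @param seed seed for the spectral-clustering k-means step.
#' @return validated list of class `snf_config`.
#' @export
snf_config <- function(K = 20L, sigma = 0.5, t = 20L, k_range = 2:10, seed = 1L) {
  stopifnot(K >= 1, sigma > 0, t >= 1, all(k_range >= 2))
  structure(list(K = as.integer(K), sigma = sigma, t = as.integer(t),
                 k_range = as.integer(k_range), seed = as.integer(seed)),
            class = "snf_config")
}

#' Squared Euclidean distance matrix between samples
#'
#' @param m samples-by-features numeric matrix (normalized features).
#' @return symmetric n-by-n matrix of squared Euclidean distances, zero
#'   diagonal, sample IDs as dimnames.
#' @export
pairwise_distance <- function(m) {
  stopifnot(is.matrix(m), nrow(m) >= 2)
  if (any(!is.finite(m))) stop("non-finite values in feature matrix")
  sq <- rowSums(m^2)
  d <- outer(sq, sq, "+") - 2 * tcrossprod(m)
  d[d < 0] <- 0
  d <- (d + t(d)) / 2
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

#' Self-tuning Gaussian affinity from a squared-distance matrix
#'
#' `W(i,j) = exp(-d(i,j) / (sigma * eps_ij))` with the local scale
#' `eps_ij = (mean_i + mean_j + d(i,j)) / 3`, where `mean_i` is the average
#' squared distance from `i` to its `K` nearest neighbors (self excluded).
#' A small floor keeps `eps` positive on duplicate-heavy inputs.
#'
#' @param d squared-distance matrix from [pairwise_distance()].
#' @param cfg an [snf_config()].
#' @return symmetric positive affinity matrix with unit diagonal.
#' @export
affinity_matrix <- function(d, cfg = snf_config()) {
  n <- nrow(d)
  if (cfg$K >= n) stop("K must be smaller than the number of samples")
  knn_mean <- apply(d, 1, function(x) mean(sort(x)[2:(cfg$K + 1)]))
  eps <- (outer(knn_mean, knn_mean, "+") + d) / 3
  if (any(eps < 1e-12)) {
    warning("degenerate local scales (duplicate-heavy input); applying floor")
    eps[eps < 1e-12] <- 1e-12
  }
  w <- exp(-d / (cfg$sigma * eps))
  w <- (w + t(w)) / 2
  dimnames(w) <- dimnames(d)
  w
}

# full-graph status matrix: P(i,j) = W(i,j) / (2 sum_{k != i} W(i,k)) off the
# diagonal, P(i,i) = 1/2; rows sum to 1
snf_status_matrix <- function(w) {
  off <- w
  diag(off) <- 0
  rs <- rowSums(off)
  rs[rs == 0] <- .Machine$double.eps
  p <- off / (2 * rs)
  diag(p) <- 0.5
  p
}

# sparse local kernel: keep each row's K largest affinities (self included,
# since W(i,i) is maximal), zero the rest, row-normalize
snf_kernel_matrix <- function(w, K) {
  n <- nrow(w)
  s <- matrix(0, n, n, dimnames = dimnames(w))
  for (i in seq_len(n)) {
    keep <- order(w[i, ], decreasing = TRUE)[seq_len(min(K + 1L, n))]
    s[i, keep] <- w[i, keep]
  }
  s / rowSums(s)
}

#' Fuse per-omics affinity graphs by cross-network diffusion
#'
#' Runs `t` iterations of the similarity-network-fusion update: each view's
#' status matrix is diffused through its own sparse local kernel against the
#' average of the other views' status matrices,
#' `P_v <- S_v (sum_{u != v} P_u / (m-1)) S_v^T`, then renormalized and
#' symmetrized. Returns the symmetrized average of the final status matrices.
#'
#' @param ws list of >= 2 affinity matrices over identical samples.
#' @param cfg an [snf_config()].
#' @return fused symmetric nonnegative n-by-n matrix.
#' @export
fuse_networks <- function(ws, cfg = snf_config()) {
  stopifnot(length(ws) >= 2)
  ref <- rownames(ws[[1]])
  for (w in ws) {
    if (!is.null(ref) && !identical(rownames(w), ref))
      stop("sample IDs differ across views; align before fusing")
    if (nrow(w) != nrow(ws[[1]])) stop("views have different sample counts")
  }
  m <- length(ws)
  p <- lapply(ws, function(w) {
    q <- snf_status_matrix(w)
    (q + t(q)) / 2
  })
  s <- lapply(ws, snf_kernel_matrix, K = cfg$K)
  for (iter in seq_len(cfg$t)) {
    p_new <- vector("list", m)
    for (v in seq_len(m)) {
      others <- Reduce(`+`, p[-v]) / (m - 1)
      q <- s[[v]] %*% others %*% t(s[[v]])
      q <- snf_status_matrix(q)
      p_new[[v]] <- (q + t(q)) / 2
    }
    p <- p_new
  }
  fused <- Reduce(`+`, p) / m
  fused <- (fused + t(fused)) / 2
  dimnames(fused) <- dimnames(ws[[1]])
  fused
}

# symmetric normalized graph Laplacian eigen-decomposition (ascending values)
normalized_laplacian_eigen <- function(w) {
  w <- (w + t(w)) / 2
  deg <- rowSums(w)
  deg[deg <= 0] <- .Machine$double.eps
  dhalf <- 1 / sqrt(deg)
  l <- diag(nrow(w)) - (dhalf * w) %*% diag(dhalf)
  l <- (l + t(l)) / 2
  eigen(l, symmetric = TRUE)
}

#' Spectral clustering of an affinity graph
#'
#' Symmetric-normalized Laplacian, eigenvectors of the `k` smallest
#' eigenvalues, row-normalized, clustered by seeded k-means with 20 restarts.
#'
#' @param w symmetric nonnegative affinity matrix.
#' @param k number of clusters (>= 2).
#' @param seed seed for k-means.
#' @return integer labels in `1..k`, named by sample ID.
#' @export
spectral_cluster <- function(w, k, seed = 1L) {
  stopifnot(k >= 2, nrow(w) == ncol(w))
  eig <- normalized_laplacian_eigen(w)
  n_comp <- sum(eig$values < 1e-8)
  if (n_comp > k)
    warning(sprintf("graph has %d connected components but k = %d", n_comp, k))
  idx <- order(eig$values)[seq_len(k)]
  u <- eig$vectors[, idx, drop = FALSE]
  norms <- sqrt(rowSums(u^2))
  norms[norms == 0] <- 1
  u <- u / norms
  set.seed(seed)
  km <- stats::kmeans(u, centers = k, nstart = 20, iter.max = 100)
  stats::setNames(km$cluster, rownames(w))
}

#' Estimate the number of clusters in an affinity graph
#'
#' Two heuristics over `cfg$k_range`: the eigen-gap of the normalized
#' Laplacian spectrum (primary) and a rotation cost, the residual of aligning
#' the top-k spectral embedding with a discrete cluster indicator matrix via
#' alternating rotation/discretisation. Ties and disagreements resolve toward
#' the eigen-gap estimate; within each heuristic ties go to the smaller k.
#'
#' @param w symmetric nonnegative affinity matrix.
#' @param cfg an [snf_config()].
#' @return list with `k_eigengap`, `k_rotation`, and the per-k diagnostics
#'   `eigengap` and `rotation_cost`.
#' @export
estimate_num_clusters <- function(w, cfg = snf_config()) {
  n <- nrow(w)
  k_range <- cfg$k_range[cfg$k_range <= n - 1]
  if (length(k_range) == 0) stop("k_range has no admissible values")
  eig <- normalized_laplacian_eigen(w)
  lambda <- sort(eig$values)
  gaps <- diff(lambda)[k_range]           # lambda_{k+1} - lambda_k
  if (max(gaps) < 1e-10)
    warning("no eigen-gap structure detected; returning smallest candidate k")
  k_eigengap <- k_range[which.max(gaps)]

  ord <- order(eig$values)
  cost <- vapply(k_range, function(k) {
    u <- eig$vectors[, ord[seq_len(k)], drop = FALSE]
    norms <- sqrt(rowSums(u^2)); norms[norms == 0] <- 1
    rotation_cost(u / norms)
  }, numeric(1))
  k_rotation <- k_range[which.min(cost)]

  list(k_eigengap = k_eigengap, k_rotation = k_rotation,
       eigengap = stats::setNames(gaps, k_range),
       rotation_cost = stats::setNames(cost, k_range))
}

# alternating discretisation (indicator snap + orthogonal Procrustes rotation);
# returns the normalized residual ||X_discrete - X R||_F^2 / n
rotation_cost <- function(u) {
  n <- nrow(u); k <- ncol(u)
  if (k == 1) return(0)
  # deterministic init: greedily pick maximally uncorrelated rows as axes
  r <- matrix(0, k, k)
  r[, 1] <- u[1, ]
  c_acc <- rep(0, n)
  for (j in 2:k) {
    c_acc <- c_acc + abs(u %*% r[, j - 1])
    r[, j] <- u[which.min(c_acc), ]
  }
  last <- Inf
  for (iter in 1:30) {
    m <- u %*% r
    lab <- max.col(m, ties.method = "first")
    xd <- matrix(0, n, k)
    xd[cbind(seq_len(n), lab)] <- 1
    sv <- svd(crossprod(xd, u))
    obj <- sum(sv$d)
    r <- sv$v %*% t(sv$u)
    if (abs(obj - last) < 1e-10) break
    last <- obj
  }
  (2 * n - 2 * obj) / n
}
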