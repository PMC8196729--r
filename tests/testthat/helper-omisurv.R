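# shared fixtures and oracles, all built in code at test time

# adjusted Rand index between two labelings
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  si <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  e <- sa * sb / choose(n, 2)
  denom <- (sa + sb) / 2 - e
  if (denom == 0) return(0)
  (si - e) / denom
}

# small labeled matrix with dimnames for preprocess/SNF tests
toy_matrix <- function(n = 10, p = 5, seed = 1, kind = "expression") {
  set.seed(seed)
  m <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("S%03d", 1:n), sprintf("f%03d", 1:p)))
  attr(m, "kind") <- kind
  m
}

# noisy block-diagonal affinity with k planted blocks
planted_affinity <- function(k, block_size = 20, within = 0.9, between = 0.1,
                             noise = 0.05, seed = 1) {
  set.seed(seed)
  n <- k * block_size
  truth <- rep(seq_len(k), each = block_size)
  w <- matrix(between, n, n) + matrix(abs(rnorm(n * n, 0, noise)), n, n)
  for (g in seq_len(k)) {
    idx <- which(truth == g)
    w[idx, idx] <- within + abs(rnorm(length(idx)^2, 0, noise))
  }
  w <- (w + t(w)) / 2
  diag(w) <- 1
  dimnames(w) <- list(sprintf("S%03d", 1:n), sprintf("S%03d", 1:n))
  attr(w, "truth") <- truth
  w
}

# uncensored/censored survival fixture with optional group hazard ratio
sim_surv <- function(n, hr = 1, p_high = 0.5, scale = 100, censor = 80,
                     seed = 1) {
  set.seed(seed)
  z <- rbinom(n, 1, p_high)
  t_ev <- rexp(n, (1 / scale) * hr^z)
  t_cn <- rexp(n, 1 / censor)
  list(surv = surv_data(pmin(t_ev, t_cn), as.integer(t_ev <= t_cn)), group = z)
}

# exhaustive pair-enumeration oracle for Harrell's C (independent of the
# package implementation): loops every ordered pair, comparable iff the
# smaller observed time is an event
cindex_oracle <- function(risk, time, event) {
  n <- length(risk)
  conc <- 0; comp <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (time[i] == time[j]) {
        if (event[i] == event[j]) next
        a <- if (event[i] == 1) i else j   # event precedes same-time censoring
        b <- if (a == i) j else i
      } else {
        a <- if (time[i] < time[j]) i else j
        b <- if (a == i) j else i
        if (event[a] != 1) next
      }
      comp <- comp + 1
      if (risk[a] > risk[b]) conc <- conc + 1
      else if (risk[a] == risk[b]) conc <- conc + 0.5
    }
  }
  if (comp == 0) stop("no comparable pairs")
  conc / comp
}

# tiny planted two-subgroup cohort for pipeline-level tests
small_cohort <- function(n = 150, seed = 11, hr = 4, delta = 1.5) {
  generate_cohort(sim_config(
    n_samples = n,
    n_features = c(expression = 60L, methylation = 60L, mirna = 30L),
    informative_fraction = c(0.2, 0.2, 0.2),
    effect_size = delta, subgroup_prob = 0.35, hazard_ratio = hr,
    baseline_scale = 120, censor_scale = 60, seed = seed))
}
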