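# Independent brute-force oracles used across tests. These deliberately do
# not share code paths with the package implementation.

# ZINB pmf by direct evaluation of the mixture in ordinary (non-log) space
oracle_zinb_pmf <- function(x, mu, theta, pi) {
  nb <- exp(lgamma(x + theta) - lgamma(theta) - lgamma(x + 1)) *
    (theta / (theta + mu))^theta * (mu / (theta + mu))^x
  pi * (x == 0) + (1 - pi) * nb
}

# scalar InfoNCE by direct formula on already-normalised vectors
oracle_info_nce <- function(q, kp, kn, tau) {
  q <- q / sqrt(sum(q^2))
  kp <- kp / sqrt(sum(kp^2))
  num <- exp(sum(q * kp) / tau)
  den <- num
  if (NROW(kn) > 0) {
    for (i in seq_len(nrow(kn))) {
      v <- kn[i, ] / sqrt(sum(kn[i, ]^2))
      den <- den + exp(sum(q * v) / tau)
    }
  }
  -log(num / den)
}

# scalar hybrid loss by direct formula (positives included in denominator)
oracle_hybrid <- function(q, ki, kic, kn, tau, lam, include_pos = TRUE) {
  q <- q / sqrt(sum(q^2))
  ki <- ki / sqrt(sum(ki^2))
  sims <- apply(kic, 1L, function(v) sum(q * v / sqrt(sum(v^2))))
  s_ic <- mean(sims)
  a1 <- exp((1 - lam) * sum(q * ki) / tau)
  a2 <- exp(lam * s_ic / tau)
  den <- if (include_pos) a1 + a2 else 0
  if (NROW(kn) > 0) {
    for (i in seq_len(nrow(kn))) {
      v <- kn[i, ] / sqrt(sum(kn[i, ]^2))
      den <- den + exp(sum(q * v) / tau)
    }
  }
  -log((a1 + a2) / den)
}

# pair-counting ARI by explicit enumeration of all element pairs
oracle_ari_pairs <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]
    sb <- b[i] == b[j]
    if (sa && sb) n11 <- n11 + 1
    else if (!sa && !sb) n00 <- n00 + 1
    else if (sa) n10 <- n10 + 1
    else n01 <- n01 + 1
  }
  tot <- choose(n, 2)
  exp_idx <- (n11 + n10) * (n11 + n01) / tot
  max_idx <- ((n11 + n10) + (n11 + n01)) / 2
  if (abs(max_idx - exp_idx) < 1e-12) return(0)
  (n11 - exp_idx) / (max_idx - exp_idx)
}

# MI / entropies directly from joint frequencies
oracle_mi <- function(a, b) {
  n <- length(a)
  mi <- 0
  for (ua in unique(a)) for (ub in unique(b)) {
    pij <- sum(a == ua & b == ub) / n
    if (pij > 0) mi <- mi + pij * log(pij / (sum(a == ua) / n * sum(b == ub) / n))
  }
  mi
}

oracle_entropy <- function(a) {
  p <- table(a) / length(a)
  -sum(p * log(p))
}

# minimal-cost assignment by exhaustive permutation search (square matrices)
oracle_assignment_cost <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  min(vapply(perms(seq_len(n)),
             function(p) sum(cost[cbind(seq_len(n), p)]), numeric(1)))
}

# all set partitions of 1..n as label vectors
all_partitions <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_partitions(n - 1)) {
    k <- max(p)
    for (c in seq_len(k + 1)) out[[length(out) + 1]] <- c(p, c)
  }
  out
}

# small labelled simulation + preprocessing for model tests
tiny_expr <- function(n_cells = 240L, n_genes = 80L, K = 3L, seed = 1L,
                      lfc = 3, dropout = 0.1) {
  cfg <- sim_config(n_cells = n_cells, n_genes = n_genes,
                    cluster_proportions = rep(1 / K, K),
                    n_marker_genes = max(5L, n_genes %/% (2L * K)),
                    lfc = lfc, base_mean = 1, theta_sim = 2,
                    dropout_pi = dropout, depth_variation = 0.2, seed = seed)
  preprocess_counts(simulate_counts(cfg))
}

# fast encoder settings for unit tests
tiny_enc <- function(K = 3L) {
  encoder_config(layer_sizes = c(64L, 32L), bottleneck_dim = 16L,
                 n_clusters = K, lr = 3e-3, batch_size = 32L)
}

.as_dense_test <- function(x) as.matrix(x)
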