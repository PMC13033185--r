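test_that("zinb_nll matches the direct-evaluation pmf oracle", {
  for (mu in c(0.1, 1, 10)) for (theta in c(0.5, 2, 100)) for (pi in c(0, 0.3, 0.9)) {
    x <- 0:20
    expected <- -log(oracle_zinb_pmf(x, mu, theta, pi))
    got <- zinb_nll(x, rep(mu, 21), rep(theta, 21), rep(pi, 21), reduce = "none")
    expect_equal(got, expected, tolerance = 1e-10)
  }
})

test_that("zinb_nll handles the degenerate and limiting cases", {
  expect_equal(zinb_nll(0, 1, 1, 1), 0)                       # pure dropout
  expect_equal(zinb_nll(0, 1, 1, 0), log(2))                  # (theta/(theta+mu))^theta = 1/2
  # NB -> Poisson as theta grows
  expect_lt(abs(zinb_nll(7, 2, 1e6, 0) - (-dpois(7, 2, log = TRUE))), 1e-3)
  expect_error(zinb_nll(-1, 1, 1, 0), "non-negative")
  expect_error(zinb_nll(1.5, 1, 1, 0), "non-negative integer")
  expect_error(zinb_nll(1, -1, 1, 0), "positive")
})

test_that("analytic ZINB gradients agree with finite differences", {
  set.seed(42)
  x <- matrix(c(0, 1, 5, 0, 12, 3), 2, 3)
  mu <- matrix(runif(6, 0.5, 5), 2, 3)
  th <- matrix(runif(6, 0.5, 3), 2, 3)
  pi <- matrix(runif(6, 0.05, 0.8), 2, 3)
  g <- scDistill:::.zinb_nll_grad(x, mu, th, pi)
  expect_equal(g$nll, zinb_nll(x, mu, th, pi, reduce = "none"), tolerance = 1e-12)
  eps <- 1e-6
  num <- function(which_par) {
    d <- array(0, dim(mu))
    for (i in seq_along(mu)) {
      pp <- list(mu = mu, th = th, pi = pi)
      pm <- pp
      pp[[which_par]][i] <- pp[[which_par]][i] + eps
      pm[[which_par]][i] <- pm[[which_par]][i] - eps
      d[i] <- (sum(zinb_nll(x, pp$mu, pp$th, pp$pi, reduce = "none")) -
                 sum(zinb_nll(x, pm$mu, pm$th, pm$pi, reduce = "none"))) / (2 * eps)
    }
    d
  }
  expect_equal(g$dmu, num("mu"), tolerance = 1e-5)
  expect_equal(g$dtheta, num("th"), tolerance = 1e-5)
  expect_equal(g$dpi, num("pi"), tolerance = 1e-5)
})

test_that("corrupt is a seeded additive Gaussian", {
  X <- matrix(0, 200, 500)
  expect_identical(corrupt(X, 0), X)
  a <- corrupt(X, 1, seed = 9)
  b <- corrupt(X, 1, seed = 9)
  expect_identical(a, b)
  # moments at n = 1e5: mean within 3 sd/sqrt(n), variance near 1
  expect_lt(abs(mean(a)), 3 / sqrt(length(a)))
  expect_lt(abs(var(as.vector(a)) - 1), 0.02)
})

test_that("soft_assign implements the Student-t kernel", {
  Z <- matrix(c(0, 0), 1, 2)
  one <- soft_assign(Z, matrix(c(5, 5), 1, 2))
  expect_equal(one$Q[1, 1], 1)

  # cell at center 1, second center at distance d
  d <- 2
  sa <- soft_assign(Z, rbind(c(0, 0), c(d, 0)))
  w1 <- 1
  w2 <- 1 / (1 + d^2)
  expect_equal(sa$Q[1, ], c(w1, w2) / (w1 + w2))

  set.seed(1)
  Zr <- matrix(rnorm(40), 10, 4)
  Cr <- matrix(rnorm(12), 3, 4)
  expect_equal(rowSums(soft_assign(Zr, Cr)$Q), rep(1, 10))
})

test_that("target_distribution sharpens and fixes one-hot rows", {
  onehot <- diag(3)[c(1, 2, 3, 1), ]
  expect_equal(target_distribution(onehot), onehot)

  unif <- matrix(0.5, 4, 2)
  expect_equal(target_distribution(unif), unif)

  set.seed(2)
  for (i in 1:20) {
    # balanced cluster frequencies: rows are cyclic shifts of one profile,
    # so every column sum is equal and squaring can only sharpen
    base <- rexp(4)
    base <- base / sum(base)
    Q <- t(sapply(0:3, function(s) base[(seq_len(4) + s - 1) %% 4 + 1]))
    P <- target_distribution(Q)
    expect_equal(rowSums(P), rep(1, 4))
    expect_true(all(apply(P, 1, max) >= apply(Q, 1, max) - 1e-12))
  }
})

test_that("clustering_kl is a KL divergence", {
  Q <- matrix(c(0.3, 0.7, 0.5, 0.5), 2, 2, byrow = TRUE)
  expect_equal(clustering_kl(Q, Q), 0)
  expect_equal(clustering_kl(matrix(c(1, 0), 1), matrix(c(0.5, 0.5), 1)), log(2))
  set.seed(3)
  for (i in 1:20) {
    P <- matrix(rexp(8), 2, 4)
    P <- P / rowSums(P)
    Q <- matrix(rexp(8), 2, 4)
    Q <- Q / rowSums(Q)
    expect_gte(clustering_kl(P, Q), 0)
  }
})

test_that("pretraining reduces the ZINB loss and is seed-reproducible", {
  pp <- tiny_expr(seed = 21L)
  cfg <- tiny_enc()
  ae1 <- pretrain_autoencoder(pp$expr, pp$raw, cfg, epochs = 1L, seed = 5L)
  ae <- pretrain_autoencoder(pp$expr, pp$raw, cfg, epochs = 15L, seed = 5L)
  expect_true(all(is.finite(ae$loss_log)))
  expect_lt(tail(ae$loss_log, 1), ae1$loss_log[1])
  ae_b <- pretrain_autoencoder(pp$expr, pp$raw, cfg, epochs = 15L, seed = 5L)
  expect_identical(ae$loss_log, ae_b$loss_log)
  expect_equal(ae$params, ae_b$params)
})

test_that("clustering self-training recovers well-separated clusters", {
  pp <- tiny_expr(n_cells = 300L, seed = 31L)
  cfg <- tiny_enc(K = 3L)
  ae <- pretrain_autoencoder(pp$expr, pp$raw, cfg, epochs = 40L, seed = 2L)
  dec <- train_cluster(ae, pp$expr, pp$raw, epochs = 10L, seed = 2L)
  expect_true(all(is.finite(dec$embedding)))
  expect_equal(rowSums(dec$assignment$Q), rep(1, 300), tolerance = 1e-6)
  km <- kmeans(dec$embedding, 3, nstart = 10)
  ari <- evaluate_clustering(km$cluster, pp$expr$labels)$ari
  expect_gte(ari, 0.9)

  # gamma = 0 reduces to continued autoencoder training
  cfg0 <- cfg
  cfg0$gamma <- 0
  ae0 <- ae
  ae0$cfg <- cfg0
  dec0 <- train_cluster(ae0, pp$expr, pp$raw, epochs = 2L, seed = 2L)
  expect_true(all(is.finite(dec0$embedding)))

  cfg_big <- cfg
  cfg_big$n_clusters <- 1000L
  ae_big <- ae
  ae_big$cfg <- cfg_big
  expect_error(train_cluster(ae_big, pp$expr, pp$raw, epochs = 1L, seed = 2L),
               "exceeds")
})

test_that("ZINB pmf is properly normalised for moderate parameters", {
  for (mu in c(0.5, 5)) for (theta in c(1, 20)) for (pi in c(0, 0.4)) {
    x <- 0:2000
    total <- sum(exp(-zinb_nll(x, rep(mu, length(x)), rep(theta, length(x)),
                               rep(pi, length(x)), reduce = "none")))
    expect_equal(total, 1, tolerance = 1e-6)
  }
})
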