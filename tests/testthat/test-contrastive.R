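test_that("momentum_update obeys its limiting and geometric contracts", {
  set.seed(1)
  pp <- tiny_expr(n_cells = 120L, seed = 41L)
  ctr <- train_contrastive(pp$expr, cfg = contrastive_config(
    seed = 1L, epochs = 1L, batch_size = 40L, queue_size = 60L),
    layer_sizes = c(16L), bottleneck_dim = 4L)
  st <- ctr$state

  frozen <- momentum_update(st, m = 1)
  expect_equal(frozen$key, st$key)
  copied <- momentum_update(st, m = 0)
  expect_equal(copied$key, st$query)

  # iterating with frozen query converges to query at rate m
  m <- 0.9
  s <- st
  s$momentum_m <- m
  d0 <- abs(s$key$enc$W[[1]][1] - s$query$enc$W[[1]][1])
  for (i in 1:100) s <- momentum_update(s)
  d100 <- abs(s$key$enc$W[[1]][1] - s$query$enc$W[[1]][1])
  expect_equal(d100, d0 * m^100, tolerance = 1e-8)
  # shapes preserved
  expect_identical(lapply(s$key$enc$W, dim), lapply(st$key$enc$W, dim))
})

test_that("exact KNN search honours metric and self-exclusion contracts", {
  # collinear points: middle point's 1-NN is the nearer endpoint
  X <- matrix(c(0, 4, 10), 3, 1)
  nn <- build_knn(X, 1)
  expect_equal(nn$neighbor_ids[2, 1], 1L)

  set.seed(5)
  Y <- matrix(rnorm(40), 10, 4)
  nn2 <- build_knn(Y, 3)
  for (i in 1:10) expect_false(i %in% nn2$neighbor_ids[i, ])

  # duplicated cell is its duplicate's 1-NN at distance 0
  Z <- rbind(Y, Y[1, ])
  nn3 <- build_knn(Z, 1)
  expect_equal(nn3$neighbor_ids[11, 1], 1L)
  expect_lt(nn3$distances[11, 1], 1e-6)

  # exactness against dist()
  D <- as.matrix(dist(Y))
  diag(D) <- Inf
  for (i in 1:10) {
    expect_equal(sort(nn2$neighbor_ids[i, ]), sort(order(D[i, ])[1:3]))
  }

  expect_error(build_knn(Y, 10), "smaller")
})

test_that("info_nce matches its closed form and the scalar oracle", {
  d <- 8
  q <- c(1, rep(0, d - 1))
  negs <- diag(d)[2:5, ]
  for (M in c(1, 3, 4)) {
    got <- info_nce(q, q, negs[seq_len(M), , drop = FALSE], tau = 1)
    expect_equal(got, -log(exp(1) / (exp(1) + M * exp(0))), tolerance = 1e-12)
  }
  # no negatives: denominator reduces to the positive alone
  expect_equal(info_nce(q, q, NULL, tau = 0.3), 0)

  set.seed(6)
  for (i in 1:25) {
    q <- rnorm(4); kp <- rnorm(4); kn <- matrix(rnorm(5 * 4), 5)
    tau <- runif(1, 0.1, 1)
    expect_equal(info_nce(q, kp, kn, tau), oracle_info_nce(q, kp, kn, tau),
                 tolerance = 1e-8)
  }
  expect_error(info_nce(rep(0, 4), kp, kn, 1), "zero-norm")
})

test_that("hybrid loss matches the brute-force oracle and its symmetries", {
  set.seed(7)
  for (i in 1:25) {
    q <- rnorm(4); ki <- rnorm(4)
    kic <- matrix(rnorm(3 * 4), 3)
    kn <- matrix(rnorm(6 * 4), 6)
    for (lam in c(0, 0.3, 1)) {
      cfg <- contrastive_config(tau = 0.25, lambda_mix = lam)
      expect_equal(hybrid_info_nce(q, ki, kic, kn, cfg),
                   oracle_hybrid(q, ki, kic, kn, 0.25, lam),
                   tolerance = 1e-8)
      cfg$positives_in_denominator <- FALSE
      expect_equal(hybrid_info_nce(q, ki, kic, kn, cfg),
                   oracle_hybrid(q, ki, kic, kn, 0.25, lam, include_pos = FALSE),
                   tolerance = 1e-8)
    }
  }

  # lambda = 0.5 with neighbour key equal to self key: both positives equal
  q <- c(1, 0, 0, 0); ki <- c(0.6, 0.8, 0, 0)
  cfg <- contrastive_config(lambda_mix = 0.5, tau = 0.2)
  got <- hybrid_info_nce(q, ki, matrix(ki, 1), matrix(c(0, 0, 1, 0), 1), cfg)
  expect_equal(got, oracle_hybrid(q, ki, matrix(ki, 1), matrix(c(0, 0, 1, 0), 1),
                                  0.2, 0.5), tolerance = 1e-10)

  # monotone decreasing in the self similarity
  kn <- matrix(rnorm(8), 2)
  vals <- sapply(c(0, 0.5, 0.9), function(s) {
    hybrid_info_nce(c(1, 0, 0, 0), c(s, sqrt(1 - s^2), 0, 0),
                    matrix(c(0, 1, 0, 0), 1), kn, cfg)
  })
  expect_true(all(diff(vals) < 0))

  expect_warning(hybrid_info_nce(q, ki, NULL, kn, cfg), "empty neighbour")
})

test_that("contrastive_step_loss adds exactly the L1 penalty", {
  set.seed(8)
  q <- rnorm(4); ki <- rnorm(4)
  kic <- matrix(rnorm(8), 2)
  kn <- matrix(rnorm(12), 3)
  cfg0 <- contrastive_config(alpha_l1 = 0)
  cfg1 <- contrastive_config(alpha_l1 = 0.05)
  base <- hybrid_info_nce(q, ki, kic, kn, cfg0)
  expect_equal(contrastive_step_loss(q, ki, kic, kn, cfg0), base)
  expect_equal(contrastive_step_loss(q, ki, kic, kn, cfg1),
               base + 0.05 * sum(abs(q)), tolerance = 1e-12)
})

test_that("contrastive training separates clusters and is reproducible", {
  pp <- tiny_expr(n_cells = 200L, seed = 51L)
  cfg <- contrastive_config(seed = 3L, epochs = 8L, batch_size = 50L,
                            queue_size = 100L)
  ctr <- train_contrastive(pp$expr, cfg = cfg,
                           layer_sizes = c(32L), bottleneck_dim = 8L)
  expect_true(all(is.finite(ctr$embedding)))
  expect_true(all(is.finite(ctr$loss_log)))

  # same seed, same embeddings
  ctr2 <- train_contrastive(pp$expr, cfg = cfg,
                            layer_sizes = c(32L), bottleneck_dim = 8L)
  expect_identical(ctr$embedding, ctr2$embedding)

  # mean within-cluster cosine similarity exceeds between-cluster
  Z <- ctr$embedding / sqrt(rowSums(ctr$embedding^2))
  S <- tcrossprod(Z)
  lab <- pp$expr$labels
  same <- outer(lab, lab, "==")
  diag(same) <- NA
  expect_gt(mean(S[which(same)]), mean(S[which(!same)]))

  expect_error(
    train_contrastive(pp$expr, cfg = contrastive_config(
      batch_size = 300L, queue_size = 1024L)),
    "queue_size")
})
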