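test_that("cross_entropy matches its closed forms and the Gibbs bound", {
  # perfect one-hot prediction
  logits <- matrix(c(50, 0, 0), 1)
  expect_equal(cross_entropy(matrix(c(1, 0, 0), 1), logits), 0, tolerance = 1e-10)

  # uniform prediction against a one-hot target: log C
  for (C in c(2, 5, 9)) {
    expect_equal(cross_entropy(matrix(diag(C)[1, ], 1), matrix(0, 1, C)), log(C))
  }

  # H(p, q) >= H(p) for soft targets
  set.seed(21)
  for (i in 1:10) {
    p <- rexp(4); p <- matrix(p / sum(p), 1)
    logits <- matrix(rnorm(4), 1)
    expect_gte(cross_entropy(p, logits), -sum(p * log(p)) - 1e-10)
  }

  expect_error(cross_entropy(matrix(c(0.4, 0.4), 1), matrix(0, 1, 2)),
               "row-stochastic")
})

test_that("kd_loss reduces to its limits and matches a hand-computed case", {
  set.seed(22)
  hard <- diag(3)[c(1, 2, 3, 1), ]
  tl <- matrix(rnorm(12), 4, 3)
  sl <- matrix(rnorm(12), 4, 3)

  # alpha = 1: exactly the temperature-tau1 cross-entropy
  cfg1 <- kd_config(alpha_kd = 1, tau1 = 2, tau2 = 4)
  expect_equal(kd_loss(hard, tl, sl, cfg1), cross_entropy(hard, sl / 2))

  # teacher == student: KL term vanishes
  cfg0 <- kd_config(alpha_kd = 0.3, tau1 = 1, tau2 = 4)
  expect_equal(kd_loss(hard, sl, sl, cfg0),
               0.3 * cross_entropy(hard, sl), tolerance = 1e-12)

  # 2-class scalar case, alpha = 0.5, tau1 = 1, tau2 = 2, evaluated by hand
  h <- matrix(c(1, 0), 1)
  tlog <- matrix(c(1, -1), 1)
  slog <- matrix(c(0.5, -0.5), 1)
  ps1 <- exp(slog) / sum(exp(slog))
  ce <- -log(ps1[1])
  pt <- exp(tlog / 2) / sum(exp(tlog / 2))
  ps2 <- exp(slog / 2) / sum(exp(slog / 2))
  kl <- sum(pt * (log(pt) - log(ps2)))
  want <- 0.5 * ce + 0.5 * 4 * kl
  expect_equal(kd_loss(h, tlog, slog, kd_config(alpha_kd = 0.5, tau1 = 1, tau2 = 2)),
               want, tolerance = 1e-10)

  # continuity in alpha and temperatures (small perturbations, small change)
  base <- kd_loss(hard, tl, sl, kd_config(alpha_kd = 0.5, tau1 = 1, tau2 = 4))
  for (eps in c(1e-4, -1e-4)) {
    expect_lt(abs(kd_loss(hard, tl, sl,
                          kd_config(alpha_kd = 0.5 + eps, tau1 = 1, tau2 = 4)) - base), 0.01)
    expect_lt(abs(kd_loss(hard, tl, sl,
                          kd_config(alpha_kd = 0.5, tau1 = 1 + eps, tau2 = 4)) - base), 0.01)
  }
})

test_that("teacher trains on anchors and dimensions its head by class count", {
  pp <- tiny_expr(n_cells = 200L, seed = 61L)
  cfg <- tiny_enc()
  ae <- pretrain_autoencoder(pp$expr, pp$raw, cfg, epochs = 20L, seed = 6L)
  dec <- train_cluster(ae, pp$expr, pp$raw, epochs = 5L, seed = 6L)
  pseudo <- leiden_cluster(dec$embedding, n_neighbors = 10L, seed = 6L)
  dens <- compute_density(dec$embedding, 5L)
  anc <- select_anchors(pseudo, dens, 0.4, pp$expr$cell_ids)

  kcfg <- kd_config(seed = 6L, epochs_teacher = 100L)
  tea <- train_teacher(dec$state, anc, pp$expr, kcfg)
  expect_equal(length(tea$classes), length(unique(pseudo)))
  expect_equal(ncol(predict(tea, pp$expr)), length(unique(pseudo)))
  # training accuracy improves over the epoch-1 baseline
  expect_gt(tail(tea$acc_log, 1), tea$acc_log[1])

  tea2 <- train_teacher(dec$state, anc, pp$expr, kcfg)
  expect_equal(tea$params, tea2$params)
})

test_that("student refines the teacher and keeps row-stochastic outputs", {
  pp <- tiny_expr(n_cells = 200L, seed = 61L)
  cfg <- tiny_enc()
  ae <- pretrain_autoencoder(pp$expr, pp$raw, cfg, epochs = 20L, seed = 6L)
  dec <- train_cluster(ae, pp$expr, pp$raw, epochs = 5L, seed = 6L)
  pseudo <- leiden_cluster(dec$embedding, n_neighbors = 10L, seed = 6L)
  dens <- compute_density(dec$embedding, 5L)
  anc <- select_anchors(pseudo, dens, 0.4, pp$expr$cell_ids)
  kcfg <- kd_config(seed = 6L, epochs_teacher = 100L)
  tea <- train_teacher(dec$state, anc, pp$expr, kcfg)

  # 0 student epochs: assignments equal the teacher's argmax
  k0 <- kcfg
  k0$epochs_student <- 0L
  stu0 <- train_student(tea, anc, pp$expr, k0, encoder_state = dec$state)
  tl <- predict(tea, pp$expr)
  expect_equal(stu0$hard_labels,
               tea$classes[max.col(tl, ties.method = "first")])

  stu <- train_student(tea, anc, pp$expr, kcfg, encoder_state = dec$state)
  expect_equal(rowSums(stu$soft_probs), rep(1, 200), tolerance = 1e-9)
  # hard labels are the argmax of the soft rows
  expect_equal(stu$hard_labels,
               tea$classes[max.col(stu$soft_probs, ties.method = "first")])
  # teacher and student architectures are identical (self-distillation)
  expect_identical(lapply(stu$student$params$enc$W, dim),
                   lapply(tea$params$enc$W, dim))
  expect_identical(lapply(stu$student$params$head$W, dim),
                   lapply(tea$params$head$W, dim))
})

test_that("distillation does not degrade separable clusterings (median over seeds)", {
  deltas <- sapply(1:10, function(s) {
    pp <- tiny_expr(n_cells = 180L, n_genes = 60L, seed = 100L + s)
    cfg <- tiny_enc()
    ae <- pretrain_autoencoder(pp$expr, pp$raw, cfg, epochs = 25L, seed = s)
    dec <- train_cluster(ae, pp$expr, pp$raw, epochs = 5L, seed = s)
    pseudo <- leiden_cluster(dec$embedding, n_neighbors = 10L, seed = s,
                             n_clusters = 3L)
    dens <- compute_density(dec$embedding, 5L)
    anc <- suppressWarnings(select_anchors(pseudo, dens, 0.4))
    kcfg <- kd_config(seed = s, epochs_student = 10L)
    tea <- train_teacher(dec$state, anc, pp$expr, kcfg)
    stu <- train_student(tea, anc, pp$expr, kcfg, encoder_state = dec$state)
    truth <- pp$expr$labels
    evaluate_clustering(stu$hard_labels, truth)$ari -
      evaluate_clustering(pseudo, truth)$ari
  })
  expect_gte(median(deltas), -0.02)
})
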