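test_that("Leiden finds two far-separated blobs and is deterministic", {
  set.seed(11)
  # bottleneck-like dimensionality; low-d Gaussian KNN graphs have strong
  # internal communities that modularity happily splits
  Z <- rbind(matrix(rnorm(100 * 16, 0), 100, 16),
             matrix(rnorm(100 * 16, 8), 100, 16))
  lab <- leiden_cluster(Z, n_neighbors = 15, seed = 4L)
  expect_length(unique(lab), 2L)
  expect_equal(length(lab), 200L)
  expect_true(all(lab %in% c(0L, 1L)))
  # partition agrees with the construction
  expect_equal(evaluate_clustering(lab, rep(c("a", "b"), each = 100))$ari, 1)

  lab2 <- leiden_cluster(Z, n_neighbors = 15, seed = 4L)
  expect_identical(lab, lab2)

  expect_warning(one <- leiden_cluster(matrix(1, 30, 3), seed = 1L), "identical")
  expect_equal(one, rep(0L, 30))
  expect_error(leiden_cluster(Z, n_neighbors = 200), "below")
})

test_that("resolution search reaches a requested community count", {
  set.seed(12)
  Z <- do.call(rbind, lapply(1:4, function(k) matrix(rnorm(50 * 3, 7 * k), 50, 3)))
  lab <- leiden_cluster(Z, n_neighbors = 10, seed = 2L, n_clusters = 4L)
  expect_length(unique(lab), 4L)
})

test_that("compute_density equals the exhaustive cosine oracle", {
  # all-identical embeddings: density 1
  expect_equal(compute_density(matrix(1, 8, 3), k = 2), rep(1, 8))

  # orthogonal neighbours: density 0
  Z <- rbind(c(1, 0), c(0, 1), c(0, 1.0001))
  expect_equal(compute_density(Z, k = 2)[1], 0, tolerance = 1e-6)

  set.seed(13)
  for (rep in 1:10) {
    Z <- matrix(rnorm(10 * 3), 10, 3)
    k <- 2
    got <- compute_density(Z, k)
    U <- Z / sqrt(rowSums(Z^2))
    S <- tcrossprod(U)
    diag(S) <- -Inf
    want <- sapply(1:10, function(i) {
      nb <- order(-S[i, ])[1:k]
      mean(U[nb, , drop = FALSE] %*% U[i, ])
    })
    expect_equal(got, want, tolerance = 1e-10)
  }

  # invariant to positive rescaling of any embedding vector
  Z <- matrix(rnorm(30), 10, 3)
  Zs <- Z * runif(10, 0.5, 2)
  expect_equal(compute_density(Z, 3), compute_density(Zs, 3), tolerance = 1e-10)

  expect_error(compute_density(rbind(c(0, 0), c(1, 1), c(2, 2)), 1), "zero-norm")
})

test_that("anchor selection takes the ceil-fraction densest cells per cluster", {
  set.seed(14)
  labels <- rep(c(0L, 1L), c(10L, 7L))
  density <- c(seq(1, 0.1, length.out = 10), seq(0.9, 0.3, length.out = 7))
  anc <- select_anchors(labels, density, anchor_fraction = 0.4)
  expect_s3_class(anc, "anchor_split")
  expect_equal(sum(anc$is_anchor[anc$pseudo_label == 0]), 4L)   # ceil(0.4*10)
  expect_equal(sum(anc$is_anchor[anc$pseudo_label == 1]), 3L)   # ceil(0.4*7)
  # the densest cells are the anchors
  expect_true(all(which(anc$is_anchor[1:10]) == 1:4))

  # ties at the boundary break by cell index; counts unchanged
  dens_tie <- c(rep(1, 10), rep(0.5, 7))
  anc_t <- select_anchors(labels, dens_tie, 0.4)
  expect_equal(which(anc_t$is_anchor[1:10]), 1:4)
  expect_equal(which(anc_t$is_anchor[11:17]), 1:3)

  # nesting: anchors(0.2) subset of anchors(0.4), per cluster
  a2 <- select_anchors(labels, density, 0.2)
  expect_true(all(which(a2$is_anchor) %in% which(anc$is_anchor)))

  # singleton cluster keeps its cell, with a warning
  expect_warning(a1 <- select_anchors(c(0L, 0L, 1L), c(1, 2, 3), 0.4), "single")
  expect_true(a1$is_anchor[3])

  expect_error(select_anchors(labels, density[1:5]), "lengths differ")
  expect_error(select_anchors(labels, density, 0), "anchor_fraction")
})

test_that("anchor counts follow the ceil rule on random partitions", {
  set.seed(15)
  for (rep in 1:20) {
    k <- sample(2:6, 1)
    sizes <- sample(1:1000, k, replace = TRUE)
    labels <- rep(seq_len(k) - 1L, sizes)
    density <- rnorm(sum(sizes))
    anc <- suppressWarnings(select_anchors(labels, density, 0.4))
    counts <- tapply(anc$is_anchor, anc$pseudo_label, sum)
    expect_equal(as.numeric(counts), as.numeric(ceiling(0.4 * sizes)))
    # no cell is both anchor and non-anchor; totals add up
    expect_equal(sum(counts), sum(anc$is_anchor))
  }
})
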