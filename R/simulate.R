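#' Configuration for the ZINB count simulator
#'
#' Describes a labelled synthetic scRNA-seq count matrix: clusters are
#' defined by blocks of marker genes whose negative-binomial mean is
#' up-shifted by a log2 fold change; sequencing-depth variation is
#' log-normal per cell; dropout zeroes entries independently with
#' probability `dropout_pi` (zero inflation).
#'
#' @param n_cells,n_genes matrix dimensions.
#' @param cluster_proportions numeric vector summing to 1; may contain rare
#'   fractions down to 0.001.
#' @param n_marker_genes markers per cluster (disjoint blocks).
#' @param lfc log2 fold change of marker genes over `base_mean`.
#' @param base_mean NB mean of non-marker genes (before depth scaling).
#' @param theta_sim NB dispersion (size) parameter; larger is closer to Poisson.
#' @param dropout_pi probability in `[0, 1)` of zeroing any entry.
#' @param depth_variation standard deviation (log scale) of per-cell depth
#'   factors; 0 gives equal depths.
#' @param seed integer RNG seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_cells = 1000L, n_genes = 500L,
                       cluster_proportions = c(1 / 3, 1 / 3, 1 / 3),
                       n_marker_genes = 30L, lfc = 3, base_mean = 1,
                       theta_sim = 2, dropout_pi = 0.1,
                       depth_variation = 0.2, seed = 1L) {
  p <- cluster_proportions
  if (abs(sum(p) - 1) > 1e-9) .stopf("cluster_proportions must sum to 1 (got %.12f)", sum(p))
  if (any(p <= 0)) .stopf("cluster_proportions must be positive")
  if (any(n_cells * p < 1)) .stopf("every cluster must expect at least one cell")
  if (dropout_pi < 0 || dropout_pi >= 1) .stopf("dropout_pi must be in [0, 1)")
  stopifnot(n_cells >= 1, n_genes >= 1, n_marker_genes >= 0,
            lfc > 0, base_mean > 0, theta_sim > 0, depth_variation >= 0)
  structure(list(
    n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
    cluster_proportions = p, n_marker_genes = as.integer(n_marker_genes),
    lfc = lfc, base_mean = base_mean, theta_sim = theta_sim,
    dropout_pi = dropout_pi, depth_variation = depth_variation,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Named simulation presets
#'
#' Fixed, documented configurations used throughout the test substrate:
#' * `easy3` - 1,000 cells, 3 balanced clusters, strong markers.
#' * `rare5` - 3,000 cells, 5 clusters with proportions
#'   (0.40, 0.30, 0.20, 0.09, 0.01); the 1 % cluster exercises rare
#'   subpopulation detection.
#' * `hard_overlap` - weak markers, high dropout, overdispersed counts.
#'
#' @param name one of `"easy3"`, `"rare5"`, `"hard_overlap"`.
#' @param seed RNG seed stored in the returned config.
#' @return A [sim_config()] object.
#' @export
sim_preset <- function(name, seed = 1L) {
  switch(name,
    easy3 = sim_config(
      n_cells = 1000L, n_genes = 500L,
      cluster_proportions = c(1 / 3, 1 / 3, 1 / 3),
      n_marker_genes = 30L, lfc = 3, base_mean = 1, theta_sim = 2,
      dropout_pi = 0.1, depth_variation = 0.2, seed = seed),
    rare5 = sim_config(
      n_cells = 3000L, n_genes = 300L,
      cluster_proportions = c(0.40, 0.30, 0.20, 0.09, 0.01),
      n_marker_genes = 25L, lfc = 3, base_mean = 1, theta_sim = 2,
      dropout_pi = 0.15, depth_variation = 0.2, seed = seed),
    hard_overlap = sim_config(
      n_cells = 1000L, n_genes = 400L,
      cluster_proportions = c(0.4, 0.3, 0.2, 0.1),
      n_marker_genes = 25L, lfc = 2, base_mean = 1, theta_sim = 1,
      dropout_pi = 0.3, depth_variation = 0.3, seed = seed),
    .stopf("unknown preset '%s'; available: easy3, rare5, hard_overlap", name)
  )
}

#' Simulate a labelled ZINB count matrix
#'
#' Draws cluster labels from a multinomial (deterministically topped up so
#' every cluster receives at least one cell), builds per-cluster mean
#' profiles (`base_mean`, markers shifted by `2^lfc`), scales by per-cell
#' log-normal depth factors, samples NB counts and applies independent
#' dropout zeroing with probability `dropout_pi`.
#'
#' @param cfg a [sim_config()].
#' @return A [count_matrix()] with per-cell `labels` (`"c1"`, `"c2"`, ...).
#' @export
simulate_counts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  K <- length(cfg$cluster_proportions)
  n <- cfg$n_cells
  G <- cfg$n_genes

  sizes <- as.integer(stats::rmultinom(1, n, cfg$cluster_proportions))
  # guarantee >= 1 cell per cluster: move cells from the largest clusters
  while (any(sizes == 0L)) {
    i <- which.min(sizes)
    j <- which.max(sizes)
    sizes[i] <- sizes[i] + 1L
    sizes[j] <- sizes[j] - 1L
  }
  labels_int <- sample(rep.int(seq_len(K), sizes))

  # disjoint marker blocks; silently truncated if n_genes is small
  mean_mat <- matrix(cfg$base_mean, K, G)
  fc <- 2^cfg$lfc
  for (k in seq_len(K)) {
    lo <- (k - 1L) * cfg$n_marker_genes + 1L
    hi <- min(k * cfg$n_marker_genes, G)
    if (lo <= hi) mean_mat[k, lo:hi] <- cfg$base_mean * fc
  }

  depth <- exp(stats::rnorm(n, 0, cfg$depth_variation))
  mu <- mean_mat[labels_int, , drop = FALSE] * depth

  counts <- matrix(
    stats::rnbinom(n * G, size = cfg$theta_sim, mu = as.vector(mu)),
    n, G
  )
  if (cfg$dropout_pi > 0) {
    drop <- matrix(stats::runif(n * G) < cfg$dropout_pi, n, G)
    counts[drop] <- 0L
  }

  count_matrix(
    counts,
    cell_ids = sprintf("cell%0*d", nchar(n), seq_len(n)),
    gene_ids = sprintf("gene%0*d", nchar(G), seq_len(G)),
    labels = paste0("c", labels_int)
  )
}

#' Write a simulated count matrix as MatrixMarket + metadata files
#'
#' Emits `matrix.mtx` (genes x cells, the conventional orientation),
#' `barcodes.tsv`, `features.tsv` and, when labels are present,
#' `labels.csv`. The layout round-trips through [load_counts()].
#'
#' @param cm a [count_matrix()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
export_counts <- function(cm, dir) {
  stopifnot(inherits(cm, "count_matrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- methods::as(methods::as(Matrix::Matrix(t(.counts_of(cm)), sparse = TRUE), "generalMatrix"), "TsparseMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(cm$cell_ids, file.path(dir, "barcodes.tsv"))
  writeLines(cm$gene_ids, file.path(dir, "features.tsv"))
  if (!is.null(cm$labels)) {
    utils::write.csv(
      data.frame(cell_id = cm$cell_ids, label = cm$labels),
      file.path(dir, "labels.csv"), row.names = FALSE
    )
  }
  invisible(dir)
}
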