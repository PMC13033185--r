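#' Leiden community detection on a KNN graph of embeddings
#'
#' Builds an exact K-nearest-neighbour graph (undirected, unweighted) of
#' the embedding rows and partitions it with the Leiden algorithm
#' (modularity objective). Labels are 0-based consecutive integers ordered
#' by decreasing community size.
#'
#' @param Z embedding matrix, cells x dims.
#' @param n_neighbors graph degree (default 15).
#' @param resolution Leiden resolution (default 1).
#' @param seed RNG seed (Leiden refinement is stochastic).
#' @param n_clusters optional target community count; when supplied the
#'   resolution is tuned by bisection to reach it (the given `resolution`
#'   is the starting point) and the closest achieved partition is
#'   returned.
#' @return Integer vector of community labels, one per cell.
#' @export
leiden_cluster <- function(Z, n_neighbors = 15L, resolution = 1,
                           seed = 1L, n_clusters = NULL) {
  Z <- .as_dense(Z)
  n <- nrow(Z)
  if (n_neighbors >= n) .stopf("n_neighbors (%d) must be below n_cells (%d)", n_neighbors, n)
  if (stats::sd(as.vector(Z)) < .EPS) {
    .warnf("all embeddings identical; returning a single cluster")
    return(rep(0L, n))
  }
  knn <- build_knn(Z, n_neighbors)
  el <- cbind(rep(seq_len(n), n_neighbors), as.vector(knn$neighbor_ids))
  g <- igraph::simplify(igraph::graph_from_edgelist(el, directed = FALSE))

  run <- function(res) {
    set.seed(.stage_seed(seed, 41L))
    igraph::membership(igraph::cluster_leiden(
      g, objective_function = "modularity", resolution = res, n_iterations = 3L))
  }
  memb <- run(resolution)
  if (!is.null(n_clusters)) {
    k <- length(unique(memb))
    if (k != n_clusters) {
      # community count grows ~monotonically with resolution: geometric bisection
      lo <- resolution / 64
      hi <- resolution * 64
      best <- memb
      best_gap <- abs(k - n_clusters)
      for (i in 1:30) {
        mid <- sqrt(lo * hi)
        m2 <- run(mid)
        k2 <- length(unique(m2))
        if (abs(k2 - n_clusters) < best_gap) {
          best <- m2
          best_gap <- abs(k2 - n_clusters)
        }
        if (k2 == n_clusters) break
        if (k2 < n_clusters) lo <- mid else hi <- mid
      }
      memb <- best
    }
  }
  sizes <- sort(table(memb), decreasing = TRUE)
  relab <- stats::setNames(seq_along(sizes) - 1L, names(sizes))
  unname(relab[as.character(memb)])
}

#' Cosine-similarity density of each cell in the latent space
#'
#' `Dens_i = (1/k) * sum_{j in KNN(i)} cos(z_i, z_j)`, with neighbour sets
#' recomputed in the embedding space under the same cosine geometry the
#' density averages (KNN on the L2-normalised embeddings). Values lie in
#' `[-1, 1]`; exactly invariant to positive rescaling of any embedding
#' vector.
#'
#' @param Z embedding matrix, cells x dims.
#' @param k neighbours per cell (default 5); must be `< n_cells`.
#' @return Numeric vector of densities, one per cell.
#' @export
compute_density <- function(Z, k = 5L) {
  Z <- .as_dense(Z)
  n <- nrow(Z)
  if (k >= n) .stopf("k (%d) must be below n_cells (%d)", k, n)
  nrm <- sqrt(rowSums(Z^2))
  if (any(nrm < .EPS)) {
    .stopf("zero-norm embedding for cell(s): %s",
           paste(which(nrm < .EPS), collapse = ", "))
  }
  U <- Z / nrm
  knn <- build_knn(U, k)   # on the unit sphere: Euclidean order = cosine order
  dens <- numeric(n)
  for (j in seq_len(k)) {
    dens <- dens + rowSums(U * U[knn$neighbor_ids[, j], , drop = FALSE])
  }
  dens / k
}

#' Split cells into anchors and non-anchors by per-cluster density
#'
#' Within each pseudo-label class, cells are ranked by density
#' (descending, ties broken by cell index) and the top
#' `ceiling(anchor_fraction * class size)` become anchors — the trusted
#' training set for distillation; the remainder form the
#' evaluation/refinement set. A singleton cluster keeps its single cell as
#' anchor (with a warning).
#'
#' @param labels integer pseudo-labels per cell.
#' @param density numeric densities per cell (see [compute_density()]).
#' @param anchor_fraction fraction in `(0, 1]` (default 0.4).
#' @param cell_ids optional identifiers carried into the output.
#' @return An `anchor_split` data.frame with columns `cell_id`,
#'   `pseudo_label`, `density`, `is_anchor`.
#' @export
select_anchors <- function(labels, density, anchor_fraction = 0.4, cell_ids = NULL) {
  if (length(labels) != length(density)) .stopf("labels and density lengths differ")
  if (anchor_fraction <= 0 || anchor_fraction > 1) .stopf("anchor_fraction must be in (0, 1]")
  if (!all(is.finite(density))) .stopf("densities must be finite")
  n <- length(labels)
  cell_ids <- cell_ids %||% sprintf("cell%d", seq_len(n))
  is_anchor <- logical(n)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) == 1L) {
      .warnf("cluster %s has a single cell; keeping it as anchor", cl)
      is_anchor[idx] <- TRUE
      next
    }
    ord <- idx[order(-density[idx], idx)]
    n_anchor <- ceiling(anchor_fraction * length(idx))
    is_anchor[ord[seq_len(n_anchor)]] <- TRUE
  }
  structure(
    data.frame(cell_id = cell_ids, pseudo_label = as.integer(labels),
               density = density, is_anchor = is_anchor,
               stringsAsFactors = FALSE),
    anchor_fraction = anchor_fraction,
    class = c("anchor_split", "data.frame")
  )
}
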