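#' Configuration for the end-to-end clustering pipeline
#'
#' Nests the per-stage configurations and the ablation switches. Any
#' stage config left `NULL` uses that stage's defaults with sizes adapted
#' to the data.
#'
#' @param n_clusters number of clusters for the self-training stage and
#'   the Leiden resolution search; `NULL` lets Leiden decide at the given
#'   resolution.
#' @param use_contrastive,use_mlp_head,use_self_kd ablation switches:
#'   disable the contrastive stage (pseudo-labels then come from the
#'   stage-1 embeddings), drop the MLP projection head, or skip the
#'   teacher/student distillation (final labels are the Leiden
#'   pseudo-labels).
#' @param encoder an [encoder_config()] or `NULL`.
#' @param contrastive a [contrastive_config()] or `NULL`.
#' @param kd a [kd_config()] or `NULL`.
#' @param pretrain_epochs,cluster_epochs stage-1 epoch counts.
#' @param leiden_neighbors,leiden_resolution pseudo-labelling graph
#'   settings.
#' @param anchor_fraction per-cluster anchor fraction (default 0.4).
#' @param density_k neighbours for the density metric (default the
#'   contrastive `k_neighbors`).
#' @param min_cells,norm_scale,n_top preprocessing settings.
#' @param seed global seed; stage seeds are derived from it.
#' @param outdir optional directory for per-stage artefacts and a JSON
#'   run manifest.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_clusters = NULL,
                            use_contrastive = TRUE, use_mlp_head = TRUE,
                            use_self_kd = TRUE,
                            encoder = NULL, contrastive = NULL, kd = NULL,
                            pretrain_epochs = 60L, cluster_epochs = 15L,
                            leiden_neighbors = 15L, leiden_resolution = 1,
                            anchor_fraction = 0.4, density_k = NULL,
                            min_cells = 3L, norm_scale = 1e4, n_top = 2000L,
                            seed = 1L, outdir = NULL) {
  structure(list(
    n_clusters = if (is.null(n_clusters)) NULL else as.integer(n_clusters),
    use_contrastive = isTRUE(use_contrastive),
    use_mlp_head = isTRUE(use_mlp_head),
    use_self_kd = isTRUE(use_self_kd),
    encoder = encoder, contrastive = contrastive, kd = kd,
    pretrain_epochs = as.integer(pretrain_epochs),
    cluster_epochs = as.integer(cluster_epochs),
    leiden_neighbors = as.integer(leiden_neighbors),
    leiden_resolution = leiden_resolution,
    anchor_fraction = anchor_fraction,
    density_k = if (is.null(density_k)) NULL else as.integer(density_k),
    min_cells = as.integer(min_cells), norm_scale = norm_scale,
    n_top = as.integer(n_top),
    seed = as.integer(seed), outdir = outdir
  ), class = "pipeline_config")
}

#' Run the full two-stage clustering pipeline
#'
#' Stages: preprocessing -> ZINB autoencoder pretraining -> clustering
#' self-training -> (contrastive refinement) -> Leiden pseudo-labelling +
#' density-based anchor selection -> (teacher/student self-distillation)
#' -> metrics against ground-truth labels when available. Bracketed
#' stages are governed by the ablation switches.
#'
#' @param counts a [count_matrix()], or a [sim_config()] to simulate from.
#' @param cfg a [pipeline_config()].
#' @return A list: `assignment` (`cluster_assignment` with final hard and
#'   soft labels), `report` (`eval_report`, `NULL` without truth labels),
#'   `anchors`, `pseudo_labels`, `embedding`, `expr`, `timings` (seconds
#'   per stage).
#' @export
run_pipeline <- function(counts, cfg = pipeline_config()) {
  t_all <- list()
  tick <- function(name, expr_) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr_)
    t_all[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  if (inherits(counts, "sim_config")) counts <- simulate_counts(counts)
  stopifnot(inherits(counts, "count_matrix"))
  seed <- cfg$seed

  pp <- tick("preprocess", preprocess_counts(counts, cfg$min_cells, cfg$norm_scale, cfg$n_top))
  expr <- pp$expr
  raw <- pp$raw
  n <- nrow(expr$values)
  n_genes <- ncol(expr$values)

  n_clusters_guess <- cfg$n_clusters %||% 8L
  enc_cfg <- cfg$encoder %||% encoder_config(
    layer_sizes = c(128L, 64L), bottleneck_dim = 32L,
    n_clusters = n_clusters_guess, lr = 3e-3, batch_size = 128L)
  enc_cfg$n_clusters <- min(enc_cfg$n_clusters, n)

  ae <- tick("pretrain", pretrain_autoencoder(expr, raw, enc_cfg,
                                              epochs = cfg$pretrain_epochs, seed = seed))
  dec <- tick("cluster_train", train_cluster(ae, expr, raw,
                                             epochs = cfg$cluster_epochs, seed = seed))

  if (cfg$use_contrastive) {
    ctr_cfg <- cfg$contrastive %||% contrastive_config(seed = seed)
    ctr_cfg$seed <- seed
    ctr_cfg$queue_size <- min(ctr_cfg$queue_size, n)
    ctr_cfg$batch_size <- min(ctr_cfg$batch_size, ctr_cfg$queue_size)
    ctr <- tick("contrastive", train_contrastive(expr, init = dec$state, cfg = ctr_cfg,
                                                 use_head = cfg$use_mlp_head))
    embedding <- ctr$embedding
    enc_state <- ctr$state
  } else {
    ctr_cfg <- cfg$contrastive %||% contrastive_config(seed = seed)
    ctr <- NULL
    embedding <- dec$embedding
    enc_state <- dec$state
  }

  pseudo <- tick("leiden", leiden_cluster(embedding,
                                          n_neighbors = min(cfg$leiden_neighbors, n - 1L),
                                          resolution = cfg$leiden_resolution,
                                          seed = seed, n_clusters = cfg$n_clusters))
  dens <- tick("density", compute_density(embedding, k = cfg$density_k %||% ctr_cfg$k_neighbors))
  anchors <- tick("anchors", select_anchors(pseudo, dens, cfg$anchor_fraction,
                                            cell_ids = expr$cell_ids))

  if (cfg$use_self_kd) {
    kd_cfg <- cfg$kd %||% kd_config(seed = seed)
    kd_cfg$seed <- seed
    teacher <- tick("teacher", train_teacher(enc_state, anchors, expr, kd_cfg))
    assignment <- tick("student", train_student(teacher, anchors, expr, kd_cfg,
                                                encoder_state = enc_state))
  } else {
    classes <- sort(unique(pseudo))
    soft <- matrix(0, n, length(classes))
    soft[cbind(seq_len(n), match(pseudo, classes))] <- 1
    assignment <- structure(
      list(hard_labels = pseudo, soft_probs = soft, student = NULL,
           loss_log = numeric(0)),
      class = "cluster_assignment")
  }

  report <- if (!is.null(expr$labels)) {
    evaluate_clustering(assignment$hard_labels, expr$labels)
  } else NULL

  out <- list(assignment = assignment, report = report, anchors = anchors,
              pseudo_labels = pseudo, embedding = embedding, expr = expr,
              timings = unlist(t_all))

  if (!is.null(cfg$outdir)) .write_artifacts(out, counts, cfg)
  out
}

# per-stage artefacts + run manifest under cfg$outdir
.write_artifacts <- function(out, counts, cfg) {
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(out$anchors),
                   file.path(cfg$outdir, "anchors.csv"), row.names = FALSE)
  soft <- out$assignment$soft_probs
  colnames(soft) <- sprintf("prob_cluster%d", seq_len(ncol(soft)) - 1L)
  utils::write.csv(
    data.frame(cell_id = out$expr$cell_ids,
               final_label = out$assignment$hard_labels,
               max_prob = apply(soft, 1L, max), soft,
               check.names = FALSE),
    file.path(cfg$outdir, "assignments.csv"), row.names = FALSE)
  if (!is.null(out$report)) {
    jsonlite::write_json(
      list(ari = out$report$ari, nmi = out$report$nmi, ami = out$report$ami,
           per_class_f1 = as.list(out$report$per_class_f1)),
      file.path(cfg$outdir, "metrics.json"), auto_unbox = TRUE, digits = NA)
    utils::write.csv(out$report$confusion,
                     file.path(cfg$outdir, "confusion.csv"))
  }
  manifest <- list(
    seed = cfg$seed, n_cells = nrow(out$expr$values),
    n_genes = ncol(out$expr$values),
    ablation = list(use_contrastive = cfg$use_contrastive,
                    use_mlp_head = cfg$use_mlp_head,
                    use_self_kd = cfg$use_self_kd),
    stage_seconds = as.list(out$timings))
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

#' Scatter plot of an embedding coloured by labels
#'
#' Plots the first two embedding dimensions (requires ggplot2).
#'
#' @param Z embedding matrix (>= 2 columns).
#' @param labels per-cell labels for colouring.
#' @return A ggplot object.
#' @export
plot_embedding <- function(Z, labels = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    .stopf("ggplot2 is required for plotting")
  }
  Z <- .as_dense(Z)
  df <- data.frame(dim1 = Z[, 1], dim2 = Z[, 2],
                   label = if (is.null(labels)) "cell" else as.character(labels))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dim1, y = .data$dim2, colour = .data$label)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "embedding 1", y = "embedding 2", colour = NULL)
}
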