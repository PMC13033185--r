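#' Construct a count matrix container
#'
#' Raw non-negative integer counts, cells x genes, with identifiers and
#' optional per-cell class labels. Matrices denser than 50 % are stored
#' dense, sparser ones as `dgCMatrix`.
#'
#' @param values numeric or sparse matrix of non-negative integers,
#'   cells in rows.
#' @param cell_ids,gene_ids character identifiers matching the dimensions.
#' @param labels optional per-cell class labels (character).
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(values, cell_ids = NULL, gene_ids = NULL, labels = NULL) {
  if (is.data.frame(values)) values <- as.matrix(values)
  n <- nrow(values)
  G <- ncol(values)
  cell_ids <- cell_ids %||% rownames(values) %||% sprintf("cell%d", seq_len(n))
  gene_ids <- gene_ids %||% colnames(values) %||% sprintf("gene%d", seq_len(G))
  if (length(cell_ids) != n) .stopf("cell_ids length %d != %d cells", length(cell_ids), n)
  if (length(gene_ids) != G) .stopf("gene_ids length %d != %d genes", length(gene_ids), G)
  if (!is.null(labels) && length(labels) != n) {
    .stopf("labels length %d != %d cells", length(labels), n)
  }
  .check_count_values(values)
  dens <- if (inherits(values, "sparseMatrix")) {
    Matrix::nnzero(values) / (as.numeric(n) * G)
  } else {
    mean(values != 0)
  }
  values <- if (dens < 0.5) {
    methods::as(Matrix::Matrix(values, sparse = TRUE), "CsparseMatrix")
  } else {
    .as_dense(values)
  }
  dimnames(values) <- NULL
  structure(
    list(counts = values, cell_ids = as.character(cell_ids),
         gene_ids = as.character(gene_ids),
         labels = if (is.null(labels)) NULL else as.character(labels)),
    class = "count_matrix"
  )
}

.counts_of <- function(cm) .as_dense(cm$counts)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d cells x %d genes (%s)%s\n",
              nrow(x$counts), ncol(x$counts),
              if (inherits(x$counts, "sparseMatrix")) "sparse" else "dense",
              if (is.null(x$labels)) "" else
                sprintf(", %d label classes", length(unique(x$labels)))))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Load raw counts from disk
#'
#' Supported formats:
#' * `mtx` - MatrixMarket file in the conventional genes x rows orientation
#'   (transposed on read), with barcode and feature files; defaults to
#'   `barcodes.tsv` / `features.tsv` next to the matrix.
#' * `csv` - header row of gene ids, first column of cell ids.
#' * `dense` - whitespace-separated numbers, no ids (generated on read).
#'
#' @param path file path (`.mtx` for `format = "mtx"`).
#' @param format one of `"mtx"`, `"csv"`, `"dense"`.
#' @param barcodes,features optional paths for the MTX id lists.
#' @return A [count_matrix()] in cells x genes orientation.
#' @export
load_counts <- function(path, format = c("mtx", "csv", "dense"),
                        barcodes = NULL, features = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) .stopf("file not found: %s", path)
  if (format == "mtx") {
    m <- tryCatch(Matrix::readMM(path),
                  error = function(e) .stopf("malformed MTX '%s': %s", path, conditionMessage(e)))
    barcodes <- barcodes %||% file.path(dirname(path), "barcodes.tsv")
    features <- features %||% file.path(dirname(path), "features.tsv")
    if (!file.exists(barcodes)) .stopf("barcode file not found: %s", barcodes)
    if (!file.exists(features)) .stopf("feature file not found: %s", features)
    cells <- readLines(barcodes)
    genes <- readLines(features)
    m <- Matrix::t(m)  # stored genes x cells; we want cells x genes
    if (nrow(m) != length(cells) || ncol(m) != length(genes)) {
      .stopf("MTX dimensions %d x %d do not match %d barcodes / %d features",
             ncol(m), nrow(m), length(cells), length(genes))
    }
    lab_file <- file.path(dirname(path), "labels.csv")
    labels <- NULL
    if (file.exists(lab_file)) {
      lab <- utils::read.csv(lab_file, stringsAsFactors = FALSE)
      labels <- lab$label[match(cells, lab$cell_id)]
    }
    return(count_matrix(m, cell_ids = cells, gene_ids = genes, labels = labels))
  }
  if (format == "csv") {
    df <- tryCatch(utils::read.csv(path, check.names = FALSE, row.names = 1L),
                   error = function(e) .stopf("malformed CSV '%s': %s", path, conditionMessage(e)))
    return(count_matrix(as.matrix(df),
                        cell_ids = rownames(df), gene_ids = colnames(df)))
  }
  m <- tryCatch(as.matrix(utils::read.table(path)),
                error = function(e) .stopf("malformed dense file '%s': %s", path, conditionMessage(e)))
  dimnames(m) <- NULL
  count_matrix(m)
}

#' Drop genes detected in too few cells
#'
#' Retains exactly the genes with a nonzero count in at least `min_cells`
#' cells; the cell set is unchanged. Idempotent.
#'
#' @param counts a [count_matrix()].
#' @param min_cells minimum number of cells a gene must be detected in
#'   (default 3).
#' @return A filtered [count_matrix()].
#' @export
filter_genes <- function(counts, min_cells = 3L) {
  stopifnot(inherits(counts, "count_matrix"), min_cells >= 1)
  prevalence <- Matrix::colSums(counts$counts > 0)
  keep <- prevalence >= min_cells
  if (!any(keep)) {
    .stopf("all %d genes are detected in fewer than %d cells; lower min_cells",
           length(keep), min_cells)
  }
  count_matrix(counts$counts[, keep, drop = FALSE],
               cell_ids = counts$cell_ids,
               gene_ids = counts$gene_ids[keep],
               labels = counts$labels)
}

#' Normalised, log-transformed expression container
#'
#' @param values dense real matrix, cells x selected genes.
#' @param size_factors positive per-cell factors (library size relative to
#'   the median library size) used to rescale decoder means.
#' @param hvg_index integer indices of the retained genes in the gene list
#'   the object was built from.
#' @param cell_ids,gene_ids identifiers.
#' @param labels optional per-cell labels carried along.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, size_factors, hvg_index,
                              cell_ids, gene_ids, labels = NULL) {
  values <- .as_dense(values)
  if (!all(is.finite(values))) .stopf("expression values must be finite")
  if (any(size_factors <= 0)) .stopf("size factors must be positive")
  stopifnot(length(size_factors) == nrow(values),
            length(hvg_index) == ncol(values),
            length(cell_ids) == nrow(values),
            length(gene_ids) == ncol(values))
  structure(
    list(values = values, size_factors = as.numeric(size_factors),
         hvg_index = as.integer(hvg_index),
         cell_ids = as.character(cell_ids), gene_ids = as.character(gene_ids),
         labels = labels),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d cells x %d genes\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Depth-normalise and log-transform counts
#'
#' Each cell's counts are divided by its library size, multiplied by
#' `scale` (counts-per-`scale`) and transformed with `log1p`. Size factors
#' (library size over median library size) are recorded for rescaling
#' decoder means.
#'
#' @param counts a [count_matrix()].
#' @param scale normalisation target (default 10,000, the usual single-cell
#'   convention).
#' @return An [expression_matrix()] over all genes of `counts`.
#' @export
normalize_log <- function(counts, scale = 1e4) {
  stopifnot(inherits(counts, "count_matrix"), scale > 0)
  lib <- Matrix::rowSums(counts$counts)
  if (any(lib == 0)) {
    .stopf("zero-depth cell(s): %s",
           paste(counts$cell_ids[lib == 0], collapse = ", "))
  }
  vals <- log1p(.counts_of(counts) / lib * scale)
  expression_matrix(
    vals,
    size_factors = lib / stats::median(lib),
    hvg_index = seq_along(counts$gene_ids),
    cell_ids = counts$cell_ids, gene_ids = counts$gene_ids,
    labels = counts$labels
  )
}

#' Select highly variable genes
#'
#' Ranks genes by mean-binned normalised dispersion: per-gene dispersion
#' (variance over mean of the depth-normalised counts) is z-scored within
#' 20 equal-frequency mean bins, and the `n_top` highest-scoring genes are
#' kept in their original order. Ties break by gene order. If fewer than
#' `n_top` genes exist the matrix is returned unchanged.
#'
#' @param expr an [expression_matrix()].
#' @param n_top number of genes to keep (default 2000).
#' @return An [expression_matrix()] restricted to the selection;
#'   `hvg_index` records the chosen columns.
#' @export
select_hvg <- function(expr, n_top = 2000L) {
  stopifnot(inherits(expr, "expression_matrix"), n_top >= 1)
  G <- ncol(expr$values)
  if (n_top >= G) return(expr)
  norm_counts <- expm1(expr$values)
  mu <- colMeans(norm_counts)
  v <- apply(norm_counts, 2L, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  n_bins <- min(20L, max(1L, G %/% 5L))
  bins <- if (n_bins < 2L) rep(1L, G) else {
    cut(rank(mu, ties.method = "first"), breaks = n_bins, labels = FALSE)
  }
  score <- numeric(G)
  for (b in unique(bins)) {
    idx <- which(bins == b)
    s <- stats::sd(disp[idx])
    score[idx] <- if (is.na(s) || s < .EPS) 0 else (disp[idx] - mean(disp[idx])) / s
  }
  ord <- order(-score, seq_len(G))   # ties broken by gene order
  keep <- sort(ord[seq_len(n_top)])
  expression_matrix(
    expr$values[, keep, drop = FALSE],
    size_factors = expr$size_factors,
    hvg_index = expr$hvg_index[keep],
    cell_ids = expr$cell_ids, gene_ids = expr$gene_ids[keep],
    labels = expr$labels
  )
}

#' Run the standard preprocessing recipe
#'
#' Convenience wrapper: [filter_genes()] (min 3 cells) then
#' [normalize_log()] then [select_hvg()].
#'
#' @param counts a [count_matrix()].
#' @param min_cells,scale,n_top see the individual steps.
#' @return A list with elements `expr` (the model input) and `raw`
#'   (the filtered counts restricted to the selected genes, used by the
#'   ZINB reconstruction loss).
#' @export
preprocess_counts <- function(counts, min_cells = 3L, scale = 1e4, n_top = 2000L) {
  filtered <- filter_genes(counts, min_cells)
  expr <- select_hvg(normalize_log(filtered, scale), n_top)
  sel <- match(expr$gene_ids, filtered$gene_ids)
  raw <- count_matrix(filtered$counts[, sel, drop = FALSE],
                      cell_ids = filtered$cell_ids,
                      gene_ids = filtered$gene_ids[sel],
                      labels = filtered$labels)
  list(expr = expr, raw = raw)
}
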