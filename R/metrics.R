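# Clustering agreement metrics: ARI, NMI, AMI (all chance-/information-
# based on the contingency table) and Hungarian-matched per-class F1.

.contingency <- function(pred, truth) {
  table(factor(pred), factor(truth))
}

.ari_from_table <- function(ct) {
  n <- sum(ct)
  sum_comb <- function(x) sum(choose(x, 2))
  a <- sum_comb(rowSums(ct))
  b <- sum_comb(colSums(ct))
  idx <- sum_comb(as.vector(ct))
  expected <- a * b / choose(n, 2)
  maxidx <- (a + b) / 2
  if (abs(maxidx - expected) < .EPS) return(0)
  (idx - expected) / (maxidx - expected)
}

.entropy <- function(counts) {
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log(p))
}

.mi_from_table <- function(ct) {
  n <- sum(ct)
  mi <- 0
  rs <- rowSums(ct)
  cs <- colSums(ct)
  for (i in seq_len(nrow(ct))) for (j in seq_len(ncol(ct))) {
    nij <- ct[i, j]
    if (nij > 0) mi <- mi + nij / n * log(nij * n / (rs[i] * cs[j]))
  }
  mi
}

# Expected mutual information under the hypergeometric null (the
# permutation model), used by AMI.
.emi_from_table <- function(ct) {
  n <- sum(ct)
  a <- rowSums(ct)
  b <- colSums(ct)
  emi <- 0
  for (i in seq_along(a)) for (j in seq_along(b)) {
    lo <- max(1, a[i] + b[j] - n)
    hi <- min(a[i], b[j])
    if (hi < lo) next
    for (nij in lo:hi) {
      term <- nij / n * log(n * nij / (a[i] * b[j]))
      lp <- lgamma(a[i] + 1) + lgamma(b[j] + 1) + lgamma(n - a[i] + 1) +
        lgamma(n - b[j] + 1) - lgamma(n + 1) - lgamma(nij + 1) -
        lgamma(a[i] - nij + 1) - lgamma(b[j] - nij + 1) -
        lgamma(n - a[i] - b[j] + nij + 1)
      emi <- emi + term * exp(lp)
    }
  }
  emi
}

#' Hungarian (optimal) assignment for a square or rectangular cost matrix
#'
#' Jonker-Volgenant style shortest-augmenting-path algorithm, minimising
#' total cost. Rectangular inputs are padded with zero-cost dummies.
#'
#' @param cost numeric cost matrix.
#' @return Integer vector: for each row, the assigned column (`NA` for
#'   rows matched to a dummy column).
#' @export
hungarian_assignment <- function(cost) {
  cost <- as.matrix(cost)
  nr <- nrow(cost)
  nc <- ncol(cost)
  n <- max(nr, nc)
  C <- matrix(0, n, n)
  C[seq_len(nr), seq_len(nc)] <- cost
  INF <- sum(abs(C)) + 1

  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1)      # p[j]: row assigned to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L              # columns are offset by 1 (index 1 = virtual col 0)
    minv <- rep(INF, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- INF
      j1 <- 0L
      for (j in 2:(n + 1)) {
        if (!used[j]) {
          cur <- C[i0, j - 1] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in 1:(n + 1)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  assign_col <- integer(n)
  for (j in 2:(n + 1)) if (p[j] > 0L) assign_col[p[j]] <- j - 1L
  out <- assign_col[seq_len(nr)]
  out[out > nc] <- NA_integer_
  out
}

#' Evaluate a clustering against ground-truth labels
#'
#' Computes the Adjusted Rand Index, Normalised Mutual Information
#' (arithmetic normalisation), Adjusted Mutual Information (hypergeometric
#' expected-MI correction, arithmetic normalisation) and per-class F1
#' scores after matching predicted clusters to truth classes by Hungarian
#' assignment on the contingency table (maximising the matched count).
#'
#' @param pred predicted cluster labels.
#' @param truth ground-truth class labels of the same length.
#' @return An `eval_report`: `ari`, `nmi`, `ami`, `per_class_f1` (named by
#'   truth class; 0 for unmatched classes), `confusion` (pred x truth
#'   integer matrix), `matching` (named map truth class -> matched
#'   predicted cluster).
#' @export
evaluate_clustering <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    .stopf("pred (%d) and truth (%d) have different lengths", length(pred), length(truth))
  }
  ct <- .contingency(pred, truth)
  n <- sum(ct)
  hu <- unname(.entropy(rowSums(ct)))
  hv <- unname(.entropy(colSums(ct)))
  mi <- unname(.mi_from_table(ct))
  mean_h <- (hu + hv) / 2
  nmi <- if (mean_h < .EPS) 1 else mi / mean_h
  emi <- unname(.emi_from_table(ct))
  denom <- mean_h - emi
  ami <- if (abs(denom) < .EPS) 1 else (mi - emi) / denom

  # Hungarian matching: maximise matched counts = minimise (max - count)
  cost <- max(ct) - ct
  match_col <- hungarian_assignment(cost)   # for each pred row, truth col
  truth_classes <- colnames(ct)
  f1 <- stats::setNames(numeric(length(truth_classes)), truth_classes)
  matching <- stats::setNames(rep(NA_character_, length(truth_classes)), truth_classes)
  for (r in seq_len(nrow(ct))) {
    j <- match_col[r]
    if (is.na(j)) next
    tp <- ct[r, j]
    prec <- if (sum(ct[r, ]) > 0) tp / sum(ct[r, ]) else 0
    rec <- if (sum(ct[, j]) > 0) tp / sum(ct[, j]) else 0
    f1[j] <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    matching[j] <- rownames(ct)[r]
  }

  structure(
    list(ari = .ari_from_table(ct), nmi = nmi, ami = ami,
         per_class_f1 = f1,
         confusion = unclass(ct), matching = matching),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: ARI %.4f | NMI %.4f | AMI %.4f\n", x$ari, x$nmi, x$ami))
  cat("per-class F1:\n")
  print(round(x$per_class_f1, 4))
  invisible(x)
}
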