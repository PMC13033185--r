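# Internal numeric helpers shared across modules.

.EPS <- 1e-10

`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

.as_dense <- function(x) {
  if (inherits(x, "Matrix")) as.matrix(x) else x
}

#' @noRd
.softmax_rows <- function(logits) {
  m <- apply(logits, 1L, max)
  e <- exp(logits - m)
  e / rowSums(e)
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

# softplus, stable for large |x|
.softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

# row-wise L2 normalisation; zero-norm rows are a caller error
.l2_normalize <- function(x, what = "representation") {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  nrm <- sqrt(rowSums(x^2))
  if (any(nrm < .EPS)) {
    .stopf("zero-norm %s at row(s): %s", what,
           paste(which(nrm < .EPS), collapse = ", "))
  }
  x / nrm
}

# elementwise log-sum-exp of two same-shape arrays (either may be -Inf)
.logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log(exp(a - m) + exp(b - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

# squared Euclidean distances between rows of A (n x d) and B (k x d)
.sqdist <- function(A, B) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  pmax(d2, 0)
}

# derive a stage seed from a user seed; keeps within 32-bit integer range
.stage_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 97 + offset) %% .Machine$integer.max)
}

.check_count_values <- function(x, context = "count matrix") {
  v <- if (inherits(x, "sparseMatrix")) x@x else x
  if (any(v < 0)) .stopf("%s contains negative entries", context)
  if (any(abs(v - round(v)) > 1e-8)) .stopf("%s contains non-integer entries", context)
  invisible(TRUE)
}
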