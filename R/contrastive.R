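#' Configuration for neighbourhood-enhanced momentum contrastive training
#'
#' @param tau softmax temperature of the InfoNCE objective.
#' @param lambda_mix weight in `[0, 1]` balancing the augmented-self
#'   positive against the neighbour positive.
#' @param alpha_l1 weight of the L1 sparsity penalty on the
#'   pre-normalisation query representation.
#' @param k_neighbors neighbours per cell used as additional positives.
#' @param momentum_m exponential-moving-average coefficient of the key
#'   encoder (`key <- m * key + (1 - m) * query`).
#' @param queue_size number of past key embeddings kept as negatives
#'   (clipped to the number of cells at train time).
#' @param noise_sigma Gaussian corruption used to create the two views.
#' @param head_hidden,head_dim projection-head hidden width and output
#'   dimension.
#' @param positives_in_denominator include the positive terms in the
#'   denominator so the loss is a proper `-log` probability (default);
#'   `FALSE` gives the negatives-only variant.
#' @param epochs,batch_size,lr,seed training settings.
#' @return A `contrastive_config` list.
#' @export
contrastive_config <- function(tau = 0.2, lambda_mix = 0.5, alpha_l1 = 1e-4,
                               k_neighbors = 5L, momentum_m = 0.999,
                               queue_size = 1024L, noise_sigma = 1.5,
                               head_hidden = 64L, head_dim = 32L,
                               positives_in_denominator = TRUE,
                               epochs = 100L, batch_size = 256L, lr = 1e-3,
                               seed = 1L) {
  stopifnot(tau > 0, lambda_mix >= 0, lambda_mix <= 1, alpha_l1 >= 0,
            k_neighbors >= 1, momentum_m >= 0, momentum_m <= 1,
            queue_size >= 1, noise_sigma >= 0, epochs >= 1, batch_size >= 1)
  structure(list(
    tau = tau, lambda_mix = lambda_mix, alpha_l1 = alpha_l1,
    k_neighbors = as.integer(k_neighbors), momentum_m = momentum_m,
    queue_size = as.integer(queue_size), noise_sigma = noise_sigma,
    head_hidden = as.integer(head_hidden), head_dim = as.integer(head_dim),
    positives_in_denominator = isTRUE(positives_in_denominator),
    epochs = as.integer(epochs), batch_size = as.integer(batch_size),
    lr = lr, seed = as.integer(seed)
  ), class = "contrastive_config")
}

#' Momentum update of the key encoder
#'
#' Replaces every key-side weight by `m * key + (1 - m) * query`; the query
#' side is untouched. `m = 1` freezes the keys, `m = 0` copies the query.
#'
#' @param state a `dynamic_encoder` (see [train_contrastive()]).
#' @param m optional momentum override; defaults to the state's value.
#' @return The updated state.
#' @export
momentum_update <- function(state, m = NULL) {
  stopifnot(inherits(state, "dynamic_encoder"))
  m <- m %||% state$momentum_m
  stopifnot(m >= 0, m <= 1)
  state$key <- .map2(state$key, state$query, function(k, q) m * k + (1 - m) * q)
  state
}

#' Exact K-nearest-neighbour index
#'
#' Euclidean nearest neighbours per cell, computed exactly by blocked
#' brute-force search (self excluded). The exact search trivially meets an
#' approximate-recall contract at the scales this package targets.
#'
#' @param X an [expression_matrix()] or a numeric matrix (rows = cells).
#' @param k neighbours per cell; must be `< n_cells`.
#' @return A `neighbor_index` list: `neighbor_ids` (cells x k) and
#'   `distances` (cells x k), both ordered nearest-first.
#' @export
build_knn <- function(X, k) {
  if (inherits(X, "expression_matrix")) X <- X$values
  X <- .as_dense(X)
  n <- nrow(X)
  if (k >= n) .stopf("k (%d) must be smaller than the number of cells (%d)", k, n)
  ids <- matrix(0L, n, k)
  dst <- matrix(0, n, k)
  block <- max(1L, min(n, as.integer(2e7 / max(1, n))))
  for (s in seq(1L, n, by = block)) {
    e <- min(s + block - 1L, n)
    d2 <- .sqdist(X[s:e, , drop = FALSE], X)
    for (r in seq_len(e - s + 1L)) {
      i <- s + r - 1L
      row <- d2[r, ]
      row[i] <- Inf
      o <- order(row)[seq_len(k)]
      ids[i, ] <- o
      dst[i, ] <- sqrt(row[o])
    }
  }
  structure(list(neighbor_ids = ids, distances = dst, k = as.integer(k)),
            class = "neighbor_index")
}

# ---- loss functions --------------------------------------------------------

.as_unit_rows <- function(x, what) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  .l2_normalize(x, what)
}

#' InfoNCE contrastive loss for a single query
#'
#' `-log( exp(q . k+ / tau) / (exp(q . k+ / tau) + sum_m exp(q . k-_m / tau)) )`.
#' Inputs are L2-normalised internally; zero-norm vectors are an error.
#'
#' @param q query representation (vector).
#' @param k_pos positive key (vector).
#' @param k_negs matrix of negative keys (rows), or `NULL`/0-row for none.
#' @param tau temperature (> 0).
#' @return Non-negative scalar loss.
#' @export
info_nce <- function(q, k_pos, k_negs = NULL, tau = 0.2) {
  stopifnot(tau > 0)
  q <- .as_unit_rows(q, "query")
  k_pos <- .as_unit_rows(k_pos, "positive key")
  s_pos <- sum(q * k_pos) / tau
  s_neg <- if (is.null(k_negs) || NROW(k_negs) == 0L) numeric(0) else {
    kn <- .as_unit_rows(k_negs, "negative key")
    as.vector(kn %*% t(q)) / tau
  }
  m <- max(s_pos, s_neg)
  -(s_pos - (m + log(sum(exp(c(s_pos, s_neg) - m)))))
}

#' Hybrid neighbourhood-enhanced InfoNCE loss for a single query
#'
#' Two positive terms share the numerator: the augmented self (weight
#' `1 - lambda`) and the neighbourhood key (weight `lambda`), where the
#' neighbour similarity is the mean of `q . k_ij` over the supplied
#' neighbour keys:
#' `-log( (exp((1-l) q.k_i / tau) + exp(l q.k_ic / tau)) / D )`.
#' By default `D` also contains the two positive exponentials (proper
#' probability, loss >= 0); `cfg$positives_in_denominator = FALSE` gives
#' the negatives-only denominator.
#' With no neighbours the loss falls back to [info_nce()] with a warning.
#'
#' @param q query representation (vector).
#' @param k_i augmented-self key (vector).
#' @param k_ic matrix of neighbour keys (rows), may be `NULL`.
#' @param k_negs matrix of negative keys (rows).
#' @param cfg a [contrastive_config()].
#' @return Scalar loss.
#' @export
hybrid_info_nce <- function(q, k_i, k_ic, k_negs = NULL, cfg = contrastive_config()) {
  if (is.null(k_ic) || NROW(k_ic) == 0L) {
    .warnf("empty neighbour set; falling back to info_nce")
    return(info_nce(q, k_i, k_negs, cfg$tau))
  }
  q <- .as_unit_rows(q, "query")
  k_i <- .as_unit_rows(k_i, "self key")
  kn <- .as_unit_rows(k_ic, "neighbour key")
  tau <- cfg$tau
  lam <- cfg$lambda_mix
  s_i <- sum(q * k_i)
  s_ic <- mean(as.vector(kn %*% t(q)))
  e_pos <- c((1 - lam) * s_i / tau, lam * s_ic / tau)
  s_neg <- if (is.null(k_negs) || NROW(k_negs) == 0L) numeric(0) else {
    as.vector(.as_unit_rows(k_negs, "negative key") %*% t(q)) / tau
  }
  den <- if (cfg$positives_in_denominator) c(e_pos, s_neg) else s_neg
  if (length(den) == 0L) .stopf("denominator is empty: no negatives and positives excluded")
  lse <- function(v) { m <- max(v); m + log(sum(exp(v - m))) }
  -(lse(e_pos) - lse(den))
}

#' Full contrastive step loss with L1 sparsity
#'
#' [hybrid_info_nce()] plus `alpha_l1 * ||q||_1` on the pre-normalisation
#' query representation.
#'
#' @inheritParams hybrid_info_nce
#' @return Scalar loss.
#' @export
contrastive_step_loss <- function(q, k_i, k_ic, k_negs = NULL, cfg = contrastive_config()) {
  hybrid_info_nce(q, k_i, k_ic, k_negs, cfg) + cfg$alpha_l1 * sum(abs(q))
}

# ---- training --------------------------------------------------------------

# forward a batch through encoder (+ optional head), returning caches and
# the L2-normalised output plus pre-normalisation representation
.ctr_forward <- function(arch, par, X, use_head) {
  ec <- nn_forward(arch$enc, par$enc, X)
  z <- ec$h[[length(ec$h)]]
  if (use_head) {
    hc <- nn_forward(arch$head, par$head, z)
    u <- hc$h[[length(hc$h)]]
  } else {
    hc <- NULL
    u <- z
  }
  nrm <- sqrt(rowSums(u^2))
  nrm <- pmax(nrm, .EPS)
  list(ec = ec, hc = hc, u = u, nrm = nrm, q = u / nrm)
}

#' Train the dynamic query/key encoder pair
#'
#' MoCo-style training: the query encoder (optionally initialised from a
#' stage-1 `zinb_ae`) plus an MLP projection head is trained by the hybrid
#' neighbourhood InfoNCE loss with L1 sparsity; the key side is updated
#' only by [momentum_update()]; negatives come from a FIFO queue of past
#' key embeddings; the two views of a cell are independent Gaussian
#' corruptions; neighbour positives are key-encoder embeddings of each
#' cell's K nearest neighbours in the input space.
#'
#' @param expr an [expression_matrix()].
#' @param init optional `zinb_ae` whose encoder initialises the query side;
#'   `NULL` trains from scratch.
#' @param cfg a [contrastive_config()].
#' @param use_head attach the MLP projection head (default `TRUE`); when
#'   `FALSE` the contrastive loss acts directly on the bottleneck.
#' @param layer_sizes,bottleneck_dim architecture when `init` is `NULL`.
#' @return A list: `embedding` (bottleneck embeddings of the clean input
#'   under the query encoder), `state` (a `dynamic_encoder`), `loss_log`.
#' @export
train_contrastive <- function(expr, init = NULL, cfg = contrastive_config(),
                              use_head = TRUE,
                              layer_sizes = c(256L, 64L), bottleneck_dim = 32L) {
  stopifnot(inherits(expr, "expression_matrix"))
  scaler <- if (!is.null(init)) init$scaler else .make_scaler(expr$values)
  X <- .apply_scaler(expr$values, scaler)
  n <- nrow(X)
  queue_size <- min(cfg$queue_size, n)
  if (queue_size < cfg$batch_size) {
    .stopf("queue_size (%d) must be at least batch_size (%d)", queue_size, cfg$batch_size)
  }
  set.seed(.stage_seed(cfg$seed, 37L))

  if (!is.null(init)) {
    stopifnot(inherits(init, "zinb_ae"))
    enc_stack <- init$arch$enc
    enc_par <- init$params$enc
    bdim <- init$cfg$bottleneck_dim
  } else {
    enc_stack <- nn_stack(c(ncol(X), layer_sizes, bottleneck_dim),
                          c(rep("relu", length(layer_sizes)), "linear"))
    enc_par <- nn_init(enc_stack)
    bdim <- bottleneck_dim
  }
  arch <- list(enc = enc_stack)
  par <- list(enc = enc_par)
  if (use_head) {
    arch$head <- nn_stack(c(bdim, cfg$head_hidden, cfg$head_dim), c("relu", "linear"))
    par$head <- nn_init(arch$head)
  }

  state <- structure(
    list(arch = arch, query = par, key = .copy_params(par),
         momentum_m = cfg$momentum_m, use_head = use_head, scaler = scaler),
    class = "dynamic_encoder")

  knn <- build_knn(X, cfg$k_neighbors)
  nb_ids <- knn$neighbor_ids

  # queue warm start: key embeddings of a random subset, oldest slot first
  init_idx <- sample.int(n, queue_size)
  queue <- .ctr_forward(arch, state$key, corrupt(X[init_idx, , drop = FALSE], cfg$noise_sigma),
                        use_head)$q
  qpos <- 1L  # next slot to overwrite (FIFO ring)

  opt <- opt_new(state$query)
  tau <- cfg$tau
  lam <- cfg$lambda_mix
  loss_log <- numeric(cfg$epochs)

  for (ep in seq_len(cfg$epochs)) {
    idx <- sample.int(n)
    tot <- 0
    for (b in split(idx, ceiling(seq_along(idx) / cfg$batch_size))) {
      B <- length(b)
      Xb <- X[b, , drop = FALSE]
      fq <- .ctr_forward(arch, state$query, corrupt(Xb, cfg$noise_sigma), use_head)
      fk <- .ctr_forward(arch, state$key, corrupt(Xb, cfg$noise_sigma), use_head)
      k_self <- fk$q

      # neighbour keys on the clean profiles, mean per cell
      nb_b <- nb_ids[b, , drop = FALSE]
      uids <- unique(as.vector(nb_b))
      k_nb <- .ctr_forward(arch, state$key, X[uids, , drop = FALSE], use_head)$q
      pos <- match(as.vector(nb_b), uids)
      kbar <- matrix(0, B, ncol(k_nb))
      for (j in seq_len(cfg$k_neighbors)) {
        kbar <- kbar + k_nb[pos[(j - 1L) * B + seq_len(B)], , drop = FALSE]
      }
      kbar <- kbar / cfg$k_neighbors

      q <- fq$q
      s_i <- rowSums(q * k_self)
      s_ic <- rowSums(q * kbar)
      S_neg <- tcrossprod(q, queue) / tau           # B x M
      a1 <- exp((1 - lam) * s_i / tau)
      a2 <- exp(lam * s_ic / tau)
      num <- a1 + a2
      e_neg <- exp(S_neg)
      den <- rowSums(e_neg) + if (cfg$positives_in_denominator) num else 0
      loss <- mean(-log(num / den)) + cfg$alpha_l1 * sum(abs(fq$u)) / B
      if (!is.finite(loss)) .stopf("contrastive training diverged at epoch %d", ep)

      inv_den <- 1 / den
      d_si <- (1 - lam) / tau * a1 *
        (if (cfg$positives_in_denominator) inv_den else 0) - (1 - lam) / tau * a1 / num
      d_sic <- lam / tau * a2 *
        (if (cfg$positives_in_denominator) inv_den else 0) - lam / tau * a2 / num
      d_Sneg <- e_neg * inv_den / tau               # B x M
      G <- d_si * k_self + d_sic * kbar + d_Sneg %*% queue
      G <- G / B
      # through row normalisation q = u / ||u||, plus L1 subgradient
      du <- (G - q * rowSums(G * q)) / fq$nrm
      du <- du + cfg$alpha_l1 * sign(fq$u) / B

      if (use_head) {
        bh <- nn_backward(arch$head, state$query$head, fq$hc, du)
        be <- nn_backward(arch$enc, state$query$enc, fq$ec, bh$dX)
        grads <- list(enc = be$grad, head = bh$grad)
      } else {
        be <- nn_backward(arch$enc, state$query$enc, fq$ec, du)
        grads <- list(enc = be$grad)
      }
      st <- opt_step(opt, state$query, grads, cfg$lr)
      opt <- st$opt
      state$query <- st$params
      state <- momentum_update(state)

      # enqueue this batch's self keys (FIFO)
      slots <- ((qpos - 1L + seq_len(B) - 1L) %% queue_size) + 1L
      queue[slots, ] <- k_self
      qpos <- ((qpos - 1L + B) %% queue_size) + 1L

      tot <- tot + loss * B
    }
    loss_log[ep] <- tot / n
  }

  Z <- nn_forward(arch$enc, state$query$enc, X)
  Z <- Z$h[[length(Z$h)]]
  list(embedding = Z, state = state, loss_log = loss_log)
}

#' @export
print.dynamic_encoder <- function(x, ...) {
  cat(sprintf("dynamic_encoder: momentum %.4g, %s projection head\n",
              x$momentum_m, if (x$use_head) "with" else "no"))
  invisible(x)
}
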