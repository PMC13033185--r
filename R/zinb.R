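#' Encoder/decoder configuration for the ZINB autoencoder
#'
#' @param layer_sizes hidden layer widths of the encoder (the decoder is the
#'   mirror image).
#' @param bottleneck_dim embedding dimension (>= 2).
#' @param noise_sigma standard deviation of the Gaussian input corruption.
#' @param cascade_noise also inject noise at every hidden encoder layer
#'   (cascaded denoising).
#' @param gamma weight of the clustering KL loss relative to the ZINB
#'   reconstruction loss.
#' @param n_clusters number of clusters for the self-training stage.
#' @param standardize_input z-score each gene of the encoder input
#'   (default `TRUE`); the reconstruction targets stay raw counts. Greatly
#'   speeds and stabilises optimisation, as in other ZINB-autoencoder
#'   tools.
#' @param lr,batch_size optimiser settings.
#' @return An `encoder_config` list.
#' @export
encoder_config <- function(layer_sizes = c(256L, 64L), bottleneck_dim = 32L,
                           noise_sigma = 1.5, cascade_noise = FALSE,
                           gamma = 1, n_clusters = 3L, standardize_input = TRUE,
                           lr = 1e-3, batch_size = 256L) {
  stopifnot(bottleneck_dim >= 2, gamma >= 0, noise_sigma >= 0,
            n_clusters >= 1, lr > 0, batch_size >= 1)
  structure(list(
    layer_sizes = as.integer(layer_sizes),
    bottleneck_dim = as.integer(bottleneck_dim),
    noise_sigma = noise_sigma, cascade_noise = isTRUE(cascade_noise),
    gamma = gamma, n_clusters = as.integer(n_clusters),
    standardize_input = isTRUE(standardize_input),
    lr = lr, batch_size = as.integer(batch_size)
  ), class = "encoder_config")
}

# per-gene z-score transform of the model input; zero-variance genes pass
# through centred only
.make_scaler <- function(X, enabled = TRUE) {
  if (!enabled) return(NULL)
  ctr <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  sdv[sdv < 1e-8] <- 1
  list(center = ctr, scale = sdv)
}

.apply_scaler <- function(X, scaler) {
  if (is.null(scaler)) return(X)
  X <- sweep(X, 2L, scaler$center, "-")
  sweep(X, 2L, scaler$scale, "/")
}

#' Corrupt a matrix with additive Gaussian noise
#'
#' @param X numeric matrix.
#' @param sigma noise standard deviation (>= 0; 0 returns `X` unchanged).
#' @param seed optional seed; if `NULL` the current RNG stream is used.
#' @return `X + e` with `e ~ N(0, sigma^2)` i.i.d.
#' @export
corrupt <- function(X, sigma, seed = NULL) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(X)
  if (!is.null(seed)) set.seed(seed)
  X + matrix(stats::rnorm(length(X), 0, sigma), nrow(X), ncol(X))
}

# ---- ZINB likelihood -------------------------------------------------------

.check_zinb_params <- function(mu, theta, pi) {
  if (any(mu <= 0)) .stopf("ZINB mean mu must be positive")
  if (any(theta <= 0)) .stopf("ZINB dispersion theta must be positive")
  if (any(pi < 0 | pi > 1)) .stopf("ZINB dropout pi must be in [0, 1]")
}

# log NB pmf in log-gamma form
.nb_logpmf <- function(x, mu, theta) {
  lgamma(x + theta) - lgamma(theta) - lgamma(x + 1) +
    theta * (log(theta) - log(theta + mu)) +
    x * (log(pmax(mu, .EPS)) - log(theta + mu))
}

#' Zero-inflated negative binomial negative log-likelihood
#'
#' Computed in log space: the NB term via log-gamma, the zero mixture via
#' log-sum-exp of `log(pi)` and `log(1 - pi) + theta * log(theta/(theta + mu))`.
#'
#' @param x non-negative integer counts (vector or matrix).
#' @param mu,theta,pi ZINB parameters, recycled to the shape of `x`;
#'   `mu > 0`, `theta > 0`, `pi` in `[0, 1]`.
#' @param reduce `"mean"` (default) or `"none"` for per-entry values.
#' @return Mean NLL, or a per-entry array when `reduce = "none"`.
#' @export
zinb_nll <- function(x, mu, theta, pi, reduce = c("mean", "none")) {
  reduce <- match.arg(reduce)
  if (any(x < 0) || any(abs(x - round(x)) > 1e-8)) {
    .stopf("counts must be non-negative integers")
  }
  .check_zinb_params(mu, theta, pi)
  nb_ll <- .nb_logpmf(x, mu, theta)
  # log P(x=0) = logsumexp(log pi, log(1-pi) + theta*log(theta/(theta+mu)))
  log_p0 <- .logsumexp2(log(pi), log1p(-pi) + theta * (log(theta) - log(theta + mu)))
  ll <- ifelse(x == 0, log_p0, log(pmax(1 - pi, .EPS)) + nb_ll)
  nll <- -ll
  if (reduce == "mean") mean(nll) else nll
}

# NLL plus analytic gradients wrt (mu, theta, pi); elementwise, with the
# zero and positive entries handled on disjoint index sets (zeros are
# typically half the matrix, so branching by subset beats ifelse).
.zinb_nll_grad <- function(x, mu, theta, pi) {
  dm <- dim(x)
  nll <- dmu <- dth <- dpi <- numeric(length(x))
  iz <- which(x == 0)
  ip <- which(x > 0)
  if (length(iz)) {
    muz <- mu[iz]; thz <- theta[iz]; piz <- pi[iz]
    r <- thz + muz
    p0 <- exp(thz * (log(thz) - log(r)))
    L0 <- pmax(piz + (1 - piz) * p0, .EPS)
    w <- (1 - piz) * p0 / L0
    nll[iz] <- -log(L0)
    dmu[iz] <- w * thz / r
    dth[iz] <- -w * (log(thz / r) + muz / r)
    dpi[iz] <- -(1 - p0) / L0
  }
  if (length(ip)) {
    xp <- x[ip]; mup <- mu[ip]; thp <- theta[ip]; pip <- pi[ip]
    r <- thp + mup
    lthr <- log(thp) - log(r)
    nll[ip] <- -(log(pmax(1 - pip, .EPS)) +
                   lgamma(xp + thp) - lgamma(thp) - lgamma(xp + 1) +
                   thp * lthr + xp * (log(mup) - log(r)))
    dmu[ip] <- (xp + thp) / r - xp / mup
    dth[ip] <- -(digamma(xp + thp) - digamma(thp) + lthr + 1 - (xp + thp) / r)
    dpi[ip] <- 1 / pmax(1 - pip, .EPS)
  }
  dim(nll) <- dim(dmu) <- dim(dth) <- dim(dpi) <- dm
  list(nll = nll, dmu = dmu, dtheta = dth, dpi = dpi)
}

# ---- DEC algebra -----------------------------------------------------------

#' Student-t soft cluster assignment
#'
#' `q_ij = (1 + ||z_i - c_j||^2)^-1`, normalised over clusters (Student-t
#' kernel with one degree of freedom).
#'
#' @param Z embeddings, cells x dims.
#' @param centers cluster centres, clusters x dims.
#' @return A `soft_assignment` list with row-stochastic `Q` and `centers`.
#' @export
soft_assign <- function(Z, centers) {
  Z <- .as_dense(Z)
  centers <- matrix(centers, ncol = ncol(Z))
  if (nrow(centers) < 1) .stopf("need at least one cluster centre")
  w <- 1 / (1 + .sqdist(Z, centers))
  structure(list(Q = w / rowSums(w), centers = centers), class = "soft_assignment")
}

#' DEC target distribution
#'
#' Squares the soft assignment and renormalises by cluster frequency:
#' `p_ij = (q_ij^2 / f_j) / sum_j' (q_ij'^2 / f_j')` with
#' `f_j = sum_i q_ij`. Sharpens each row while down-weighting large
#' clusters; one-hot rows are fixed points.
#'
#' @param Q row-stochastic matrix (or a `soft_assignment`).
#' @return Row-stochastic matrix `P` of the same shape.
#' @export
target_distribution <- function(Q) {
  if (inherits(Q, "soft_assignment")) Q <- Q$Q
  f <- colSums(Q)
  if (any(f < .EPS)) {
    .warnf("empty cluster(s) in target distribution; epsilon-guarded")
    f <- pmax(f, .EPS)
  }
  num <- sweep(Q^2, 2L, f, "/")
  num / rowSums(num)
}

#' Kullback-Leibler clustering loss
#'
#' `KL(P || Q) = sum_ij p_ij log(p_ij / q_ij)` with `0 log 0 = 0` and an
#' epsilon guard on `q`.
#'
#' @param P,Q row-stochastic matrices of equal shape.
#' @return A non-negative scalar.
#' @export
clustering_kl <- function(P, Q) {
  stopifnot(all(dim(P) == dim(Q)))
  if (any(Q < .EPS & P > .EPS)) .warnf("q == 0 where p > 0; epsilon-guarded")
  term <- ifelse(P > 0, P * (log(pmax(P, .EPS)) - log(pmax(Q, .EPS))), 0)
  sum(term)
}

# ---- autoencoder model -----------------------------------------------------

# architecture: enc D -> layer_sizes -> bottleneck (linear output);
# dec bottleneck -> rev(layer_sizes) (relu); three linear heads H -> D.
.ae_arch <- function(D, cfg) {
  hidden <- cfg$layer_sizes
  list(
    enc = nn_stack(c(D, hidden, cfg$bottleneck_dim),
                   c(rep("relu", length(hidden)), "linear")),
    dec = nn_stack(c(cfg$bottleneck_dim, rev(hidden)),
                   rep("relu", length(hidden))),
    head = nn_stack(c(hidden[1L], D), "linear")  # shape shared by mu/theta/pi heads
  )
}

.ae_init <- function(arch) {
  list(enc = nn_init(arch$enc), dec = nn_init(arch$dec),
       mu = nn_init(arch$head), th = nn_init(arch$head), pi = nn_init(arch$head))
}

.THETA_MIN <- 1e-4
.THETA_MAX <- 1e4

# forward through decoder heads; sf = per-cell size factors
.ae_decode <- function(arch, par, z, sf) {
  dc <- nn_forward(arch$dec, par$dec, z)
  H <- dc$h[[length(dc$h)]]
  mu_pre <- nn_forward(arch$head, par$mu, H)$a[[1L]]
  th_pre <- nn_forward(arch$head, par$th, H)$a[[1L]]
  pi_pre <- nn_forward(arch$head, par$pi, H)$a[[1L]]
  mu_pre <- pmin(pmax(mu_pre, -15), 15)
  list(
    dc = dc, H = H, mu_pre = mu_pre, th_pre = th_pre, pi_pre = pi_pre,
    mu = sf * exp(mu_pre),
    theta = pmin(pmax(.softplus(th_pre), .THETA_MIN), .THETA_MAX),
    pi = .sigmoid(pi_pre)
  )
}

# full forward + backward for the ZINB reconstruction loss (mean over
# entries); dz_extra is an optional additional gradient at the bottleneck
# (the clustering loss). Returns loss, grads (same shape as par), z.
.ae_loss_grad <- function(arch, par, X_in, x_count, sf, dz_extra = NULL,
                          cascade_sigma = 0) {
  ec <- nn_forward(arch$enc, par$enc, X_in, hidden_noise = cascade_sigma)
  z <- ec$h[[length(ec$h)]]
  dec <- .ae_decode(arch, par, z, sf)
  g <- .zinb_nll_grad(x_count, dec$mu, dec$theta, dec$pi)
  nent <- length(x_count)
  loss <- sum(g$nll) / nent

  dmu_pre <- g$dmu * dec$mu / nent
  dth_pre <- g$dtheta * .sigmoid(dec$th_pre) *
    (dec$theta > .THETA_MIN & dec$theta < .THETA_MAX) / nent
  dpi_pre <- g$dpi * dec$pi * (1 - dec$pi) / nent

  head_cache <- list(h = list(dec$H), a = list(NULL))
  bmu <- nn_backward(arch$head, par$mu, head_cache, dmu_pre)
  bth <- nn_backward(arch$head, par$th, head_cache, dth_pre)
  bpi <- nn_backward(arch$head, par$pi, head_cache, dpi_pre)
  dH <- bmu$dX + bth$dX + bpi$dX
  bdec <- nn_backward(arch$dec, par$dec, dec$dc, dH)
  dz <- bdec$dX
  if (!is.null(dz_extra)) {
    if (is.function(dz_extra)) dz_extra <- dz_extra(z)
    dz <- dz + dz_extra
  }
  benc <- nn_backward(arch$enc, par$enc, ec, dz)

  list(loss = loss,
       grads = list(enc = benc$grad, dec = bdec$grad,
                    mu = bmu$grad, th = bth$grad, pi = bpi$grad),
       z = z)
}

.ae_embed <- function(arch, par, X) {
  ec <- nn_forward(arch$enc, par$enc, X)
  ec$h[[length(ec$h)]]
}

# corrupted encoder input, optionally cascading noise into hidden layers
.ae_corrupt_input <- function(X, cfg) {
  corrupt(X, cfg$noise_sigma)
}

#' Pre-train the denoising ZINB autoencoder
#'
#' Minimises the mean ZINB negative log-likelihood of the raw counts given
#' the decoder heads (mean scaled by size factors, dispersion via softplus,
#' dropout via sigmoid), with Gaussian-corrupted input (denoising). Adam,
#' mini-batched, reproducible per seed.
#'
#' @param expr an [expression_matrix()] (model input).
#' @param raw a [count_matrix()] aligned with `expr` (same cells, the
#'   selected genes) supplying the reconstruction targets.
#' @param cfg an [encoder_config()].
#' @param epochs number of passes over the data.
#' @param seed RNG seed.
#' @return A `zinb_ae` state: architecture, parameters, config, loss log.
#' @export
pretrain_autoencoder <- function(expr, raw, cfg = encoder_config(), epochs = 40L, seed = 1L) {
  stopifnot(inherits(expr, "expression_matrix"), inherits(raw, "count_matrix"))
  X <- expr$values
  C <- .counts_of(raw)
  if (!all(dim(X) == dim(C))) .stopf("expr and raw must align on cells and genes")
  n <- nrow(X)
  scaler <- .make_scaler(X, cfg$standardize_input)
  X <- .apply_scaler(X, scaler)
  set.seed(.stage_seed(seed, 11L))
  arch <- .ae_arch(ncol(X), cfg)
  par <- .ae_init(arch)
  opt <- opt_new(par)
  sf <- expr$size_factors
  log_df <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    idx <- sample.int(n)
    tot <- 0
    for (b in split(idx, ceiling(seq_along(idx) / cfg$batch_size))) {
      Xb <- .ae_corrupt_input(X[b, , drop = FALSE], cfg)
      res <- .ae_loss_grad(arch, par, Xb, C[b, , drop = FALSE], sf[b],
                           cascade_sigma = if (cfg$cascade_noise) cfg$noise_sigma else 0)
      if (!is.finite(res$loss)) .stopf("ZINB pretraining diverged (non-finite loss) at epoch %d", ep)
      st <- opt_step(opt, par, res$grads, cfg$lr)
      opt <- st$opt
      par <- st$params
      tot <- tot + res$loss * length(b)
    }
    log_df[ep] <- tot / n
  }
  structure(list(arch = arch, params = par, cfg = cfg, opt = opt,
                 scaler = scaler, loss_log = log_df, input_dim = ncol(X)),
            class = "zinb_ae")
}

#' @export
print.zinb_ae <- function(x, ...) {
  cat(sprintf("zinb_ae: %d -> %s -> %d; final pretrain loss %.4f\n",
              x$input_dim, paste(x$cfg$layer_sizes, collapse = "-"),
              x$cfg$bottleneck_dim, utils::tail(x$loss_log, 1)))
  invisible(x)
}

#' Bottleneck embeddings of cells under a trained encoder
#'
#' Applies the model's input standardisation (if any) and returns the
#' bottleneck representation of the clean expression values.
#'
#' @param state a `zinb_ae` (from [pretrain_autoencoder()] /
#'   [train_cluster()]) or a `dynamic_encoder` (from
#'   [train_contrastive()]; its query encoder is used).
#' @param expr an [expression_matrix()] or numeric matrix.
#' @return Numeric matrix, cells x bottleneck dimensions.
#' @export
embed_cells <- function(state, expr) {
  X <- if (inherits(expr, "expression_matrix")) expr$values else .as_dense(expr)
  X <- .apply_scaler(X, state$scaler)
  enc <- .extract_encoder(state)
  out <- nn_forward(enc$stack, enc$params, X)
  out$h[[length(out$h)]]
}

#' Clustering self-training on the pretrained autoencoder
#'
#' Initialises cluster centres by K-means on the bottleneck embeddings of
#' the clean input, then alternates per mini-batch: recompute the Student-t
#' soft assignment `Q` and target distribution `P`, and take a gradient
#' step on `L_ZINB + gamma * KL(P || Q)` (embeddings and centres both
#' updated).
#'
#' @param state a `zinb_ae` from [pretrain_autoencoder()].
#' @param expr,raw as in [pretrain_autoencoder()].
#' @param epochs training epochs.
#' @param seed RNG seed.
#' @param denoise keep corrupting the input during self-training
#'   (default `TRUE`).
#' @return A list: `state` (updated `zinb_ae`), `embedding` (cells x
#'   bottleneck), `assignment` (a `soft_assignment` on the full data),
#'   `loss_log`.
#' @export
train_cluster <- function(state, expr, raw, epochs = 15L, seed = 1L, denoise = TRUE) {
  stopifnot(inherits(state, "zinb_ae"))
  cfg <- state$cfg
  X <- .apply_scaler(expr$values, state$scaler)
  C <- .counts_of(raw)
  n <- nrow(X)
  if (cfg$n_clusters > n) .stopf("n_clusters (%d) exceeds n_cells (%d)", cfg$n_clusters, n)
  set.seed(.stage_seed(seed, 23L))
  arch <- state$arch
  par <- state$params
  sf <- expr$size_factors

  Z0 <- .ae_embed(arch, par, X)
  km <- stats::kmeans(Z0, centers = cfg$n_clusters, nstart = 10L, iter.max = 100L)
  centers <- km$centers

  par$centers <- centers
  opt <- opt_new(par)
  log_df <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    idx <- sample.int(n)
    tot <- 0
    for (b in split(idx, ceiling(seq_along(idx) / cfg$batch_size))) {
      Xb <- X[b, , drop = FALSE]
      X_in <- if (denoise) .ae_corrupt_input(Xb, cfg) else Xb
      nb <- length(b)
      # P and Q are recomputed for each batch at the batch's current z;
      # the callback also yields the centre gradient and the KL value.
      aux <- new.env(parent = emptyenv())
      dz_fn <- function(z) {
        sa <- soft_assign(z, par$centers)
        P <- target_distribution(sa$Q)
        w <- 1 / (1 + .sqdist(z, par$centers))
        A <- w * (P - sa$Q)
        aux$dcent <- -cfg$gamma * 2 * (crossprod(A, z) - colSums(A) * par$centers) / nb
        aux$kl <- clustering_kl(P, sa$Q) / nb
        cfg$gamma * 2 * (rowSums(A) * z - A %*% par$centers) / nb
      }
      res <- .ae_loss_grad(arch, par, X_in, C[b, , drop = FALSE], sf[b],
                           dz_extra = dz_fn,
                           cascade_sigma = if (cfg$cascade_noise) cfg$noise_sigma else 0)
      if (!is.finite(res$loss)) .stopf("clustering training diverged at epoch %d", ep)
      grads <- res$grads
      grads$centers <- aux$dcent
      st <- opt_step(opt, par, grads, cfg$lr)
      opt <- st$opt
      par <- st$params
      tot <- tot + (res$loss + cfg$gamma * aux$kl) * nb
    }
    log_df[ep] <- tot / n
  }
  state$params <- par
  state$loss_log <- c(state$loss_log, log_df)
  Z <- .ae_embed(arch, par, X)
  list(state = state, embedding = Z,
       assignment = soft_assign(Z, par$centers), loss_log = log_df)
}
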