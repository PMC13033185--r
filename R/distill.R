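#' Configuration for the self-knowledge-distillation stage
#'
#' @param alpha_kd weight in `[0, 1]` on the hard-label cross-entropy term
#'   (the soft teacher term gets `1 - alpha_kd`).
#' @param tau1 softmax temperature of the hard cross-entropy term.
#' @param tau2 softmax temperature of the teacher/student KL term; the KL
#'   is scaled by `tau2^2` so gradients stay comparable across
#'   temperatures.
#' @param epochs_teacher,epochs_student training epochs.
#' @param lr_teacher learning rate for the head-only teacher fit (higher
#'   than the student's since it trains a single linear layer from
#'   scratch).
#' @param train_encoder also fine-tune the teacher's encoder (default the
#'   classification head alone is trained, on frozen embeddings).
#' @param lr,batch_size optimiser settings.
#' @param seed RNG seed.
#' @return A `kd_config` list.
#' @export
kd_config <- function(alpha_kd = 0.5, tau1 = 1, tau2 = 4,
                      epochs_teacher = 300L, epochs_student = 30L,
                      train_encoder = FALSE, lr = 1e-3, lr_teacher = 1e-2,
                      batch_size = 256L, seed = 1L) {
  stopifnot(alpha_kd >= 0, alpha_kd <= 1, tau1 > 0, tau2 > 0,
            epochs_teacher >= 1, epochs_student >= 0, lr > 0, lr_teacher > 0)
  structure(list(
    alpha_kd = alpha_kd, tau1 = tau1, tau2 = tau2,
    epochs_teacher = as.integer(epochs_teacher),
    epochs_student = as.integer(epochs_student),
    train_encoder = isTRUE(train_encoder), lr = lr, lr_teacher = lr_teacher,
    batch_size = as.integer(batch_size), seed = as.integer(seed)
  ), class = "kd_config")
}

#' Cross-entropy between target distributions and logits
#'
#' `-mean_i sum_c p_ic log softmax(logits_i)_c`, epsilon-guarded.
#'
#' @param p row-stochastic targets (one-hot or soft), cells x classes.
#' @param logits real matrix of the same shape.
#' @return Non-negative scalar (mean over cells).
#' @export
cross_entropy <- function(p, logits) {
  p <- as.matrix(p)
  logits <- as.matrix(logits)
  stopifnot(all(dim(p) == dim(logits)))
  if (any(abs(rowSums(p) - 1) > 1e-6)) .stopf("targets must be row-stochastic")
  q <- .softmax_rows(logits)
  -mean(rowSums(p * log(pmax(q, .EPS))))
}

#' Self-knowledge-distillation loss
#'
#' `alpha * H(p, softmax(student / tau1)) +
#'  (1 - alpha) * tau2^2 * KL(softmax(teacher / tau2) || softmax(student / tau2))`,
#' mean over cells. At `alpha = 1` this is exactly the temperature-`tau1`
#' cross-entropy; when teacher and student logits agree the KL term is 0.
#'
#' @param hard row-stochastic hard targets (one-hot pseudo-labels).
#' @param teacher_logits,student_logits real matrices, cells x classes.
#' @param cfg a [kd_config()].
#' @return Non-negative scalar loss.
#' @export
kd_loss <- function(hard, teacher_logits, student_logits, cfg = kd_config()) {
  hard <- as.matrix(hard)
  teacher_logits <- as.matrix(teacher_logits)
  student_logits <- as.matrix(student_logits)
  stopifnot(all(dim(hard) == dim(student_logits)),
            all(dim(teacher_logits) == dim(student_logits)))
  ce <- cross_entropy(hard, student_logits / cfg$tau1)
  pt <- .softmax_rows(teacher_logits / cfg$tau2)
  ps <- .softmax_rows(student_logits / cfg$tau2)
  kl <- mean(rowSums(pt * (log(pmax(pt, .EPS)) - log(pmax(ps, .EPS)))))
  cfg$alpha_kd * ce + (1 - cfg$alpha_kd) * cfg$tau2^2 * kl
}

# ---- classifier model (encoder + linear head) ------------------------------

.clf_forward <- function(clf, X) {
  ec <- nn_forward(clf$arch$enc, clf$params$enc, X)
  z <- ec$h[[length(ec$h)]]
  hc <- nn_forward(clf$arch$head, clf$params$head, z)
  list(ec = ec, hc = hc, logits = hc$h[[length(hc$h)]])
}

#' Predicted logits of a teacher/student classifier
#'
#' @param object a `distill_classifier` from [train_teacher()] or the
#'   student inside [train_student()]'s result.
#' @param newdata an [expression_matrix()] or numeric matrix.
#' @param ... unused.
#' @return Logit matrix, cells x classes.
#' @export
predict.distill_classifier <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "expression_matrix")) newdata$values else .as_dense(newdata)
  .clf_forward(object, .apply_scaler(X, object$scaler))$logits
}

#' Train the teacher classifier on anchor cells
#'
#' Reloads the contrastive-pretrained encoder, attaches a linear
#' classification head with one output per distinct pseudo-label, and
#' trains it by cross-entropy against the pseudo-labels of the anchor
#' cells only. By default the encoder stays frozen and only the head is
#' fitted (on the frozen bottleneck embeddings); `cfg$train_encoder = TRUE`
#' fine-tunes both.
#'
#' @param encoder_state a `dynamic_encoder` (from [train_contrastive()])
#'   or a `zinb_ae`; its encoder becomes the teacher's backbone.
#' @param anchors an `anchor_split` (see [select_anchors()]).
#' @param expr the [expression_matrix()] the anchors refer to.
#' @param cfg a [kd_config()].
#' @return A `distill_classifier`: architecture, parameters, class ids,
#'   training-accuracy log.
#' @export
train_teacher <- function(encoder_state, anchors, expr, cfg = kd_config()) {
  stopifnot(inherits(anchors, "anchor_split"), inherits(expr, "expression_matrix"))
  enc <- .extract_encoder(encoder_state)
  X <- .apply_scaler(expr$values, encoder_state$scaler)
  set.seed(.stage_seed(cfg$seed, 53L))

  classes <- sort(unique(anchors$pseudo_label))
  C <- length(classes)
  a_idx <- which(anchors$is_anchor)
  if (length(a_idx) == 0L) .stopf("no anchor cells")
  y <- match(anchors$pseudo_label[a_idx], classes)
  Y <- matrix(0, length(a_idx), C)
  Y[cbind(seq_along(a_idx), y)] <- 1

  bdim <- enc$stack$sizes[length(enc$stack$sizes)]
  head_stack <- nn_stack(c(bdim, C), "linear")
  clf <- structure(
    list(arch = list(enc = enc$stack, head = head_stack),
         params = list(enc = enc$params, head = nn_init(head_stack)),
         classes = classes, scaler = encoder_state$scaler),
    class = "distill_classifier")

  Xa <- X[a_idx, , drop = FALSE]
  acc_log <- numeric(cfg$epochs_teacher)
  if (!cfg$train_encoder) {
    # frozen encoder: fit the linear head full-batch on cached embeddings
    Z <- nn_forward(enc$stack, enc$params, Xa)
    Z <- Z$h[[length(Z$h)]]
    opt <- opt_new(clf$params$head)
    for (ep in seq_len(cfg$epochs_teacher)) {
      hc <- nn_forward(head_stack, clf$params$head, Z)
      logits <- hc$h[[length(hc$h)]]
      q <- .softmax_rows(logits)
      dlog <- (q - Y) / nrow(Y)
      bk <- nn_backward(head_stack, clf$params$head, hc, dlog)
      st <- opt_step(opt, clf$params$head, bk$grad, cfg$lr_teacher)
      opt <- st$opt
      clf$params$head <- st$params
      acc_log[ep] <- mean(max.col(logits, ties.method = "first") == y)
    }
  } else {
    opt <- opt_new(clf$params)
    n <- nrow(Xa)
    for (ep in seq_len(cfg$epochs_teacher)) {
      idx <- sample.int(n)
      correct <- 0
      for (b in split(idx, ceiling(seq_along(idx) / cfg$batch_size))) {
        fw <- .clf_forward(clf, Xa[b, , drop = FALSE])
        q <- .softmax_rows(fw$logits)
        dlog <- (q - Y[b, , drop = FALSE]) / length(b)
        bh <- nn_backward(head_stack, clf$params$head, fw$hc, dlog)
        be <- nn_backward(enc$stack, clf$params$enc, fw$ec, bh$dX)
        st <- opt_step(opt, clf$params, list(enc = be$grad, head = bh$grad), cfg$lr)
        opt <- st$opt
        clf$params <- st$params
        correct <- correct + sum(max.col(fw$logits, ties.method = "first") == y[b])
      }
      acc_log[ep] <- correct / n
    }
  }
  clf$acc_log <- acc_log
  clf
}

.extract_encoder <- function(state) {
  if (inherits(state, "dynamic_encoder")) {
    list(stack = state$arch$enc, params = state$query$enc)
  } else if (inherits(state, "zinb_ae")) {
    list(stack = state$arch$enc, params = state$params$enc)
  } else {
    .stopf("expected a dynamic_encoder or zinb_ae state")
  }
}

#' Train the student by self-distillation and assign final labels
#'
#' The student shares the teacher's architecture; its encoder is
#' re-initialised from the same contrastive encoder and its head afresh.
#' It is trained on all cells with [kd_loss()]: anchors contribute the
#' hard cross-entropy term (their pseudo-labels) and every cell
#' contributes the softened-teacher KL term. Returns probabilistic and
#' hard assignments for every cell.
#'
#' @param teacher a `distill_classifier` from [train_teacher()].
#' @param anchors the `anchor_split` used for the teacher.
#' @param expr the [expression_matrix()].
#' @param cfg a [kd_config()].
#' @param encoder_state optional encoder for the student's initialisation;
#'   defaults to the teacher's encoder weights.
#' @return A `cluster_assignment`: `hard_labels` (pseudo-label ids, one
#'   per cell; argmax of the soft rows, ties to the lowest index),
#'   `soft_probs` (row-stochastic), `student` (the trained classifier),
#'   `loss_log`.
#' @export
train_student <- function(teacher, anchors, expr, cfg = kd_config(),
                          encoder_state = NULL) {
  stopifnot(inherits(teacher, "distill_classifier"),
            inherits(anchors, "anchor_split"),
            inherits(expr, "expression_matrix"))
  X <- .apply_scaler(expr$values, teacher$scaler)
  n <- nrow(X)
  C <- length(teacher$classes)
  set.seed(.stage_seed(cfg$seed, 67L))

  enc_par <- if (is.null(encoder_state)) teacher$params$enc else .extract_encoder(encoder_state)$params
  # self-distillation: the student starts as the teacher (same architecture,
  # encoder from the contrastive stage, head copied) and is refined by the
  # hard + softened objectives
  student <- structure(
    list(arch = teacher$arch,
         params = list(enc = .copy_params(enc_par),
                       head = .copy_params(teacher$params$head)),
         classes = teacher$classes, scaler = teacher$scaler),
    class = "distill_classifier")

  teacher_logits <- .clf_forward(teacher, X)$logits
  pt <- .softmax_rows(teacher_logits / cfg$tau2)

  hard_row <- match(anchors$pseudo_label, teacher$classes)
  is_anchor <- anchors$is_anchor

  opt <- opt_new(student$params)
  loss_log <- numeric(cfg$epochs_student)
  for (ep in seq_len(cfg$epochs_student)) {
    idx <- sample.int(n)
    tot <- 0
    for (b in split(idx, ceiling(seq_along(idx) / cfg$batch_size))) {
      fw <- .clf_forward(student, X[b, , drop = FALSE])
      logits <- fw$logits
      nb <- length(b)

      ps2 <- .softmax_rows(logits / cfg$tau2)
      dlog <- (1 - cfg$alpha_kd) * cfg$tau2 * (ps2 - pt[b, , drop = FALSE]) / nb
      kl <- mean(rowSums(pt[b, , drop = FALSE] *
                           (log(pmax(pt[b, , drop = FALSE], .EPS)) - log(pmax(ps2, .EPS)))))
      loss <- (1 - cfg$alpha_kd) * cfg$tau2^2 * kl

      ab <- which(is_anchor[b])
      if (length(ab) > 0L && cfg$alpha_kd > 0) {
        ps1 <- .softmax_rows(logits[ab, , drop = FALSE] / cfg$tau1)
        Yb <- matrix(0, length(ab), C)
        Yb[cbind(seq_along(ab), hard_row[b][ab])] <- 1
        dlog[ab, ] <- dlog[ab, ] +
          cfg$alpha_kd * (ps1 - Yb) / (cfg$tau1 * length(ab))
        loss <- loss + cfg$alpha_kd *
          (-mean(rowSums(Yb * log(pmax(ps1, .EPS)))))
      }
      if (!is.finite(loss)) .stopf("distillation diverged at epoch %d", ep)

      bh <- nn_backward(student$arch$head, student$params$head, fw$hc, dlog)
      be <- nn_backward(student$arch$enc, student$params$enc, fw$ec, bh$dX)
      st <- opt_step(opt, student$params, list(enc = be$grad, head = bh$grad), cfg$lr)
      opt <- st$opt
      student$params <- st$params
      tot <- tot + loss * nb
    }
    loss_log[ep] <- tot / n
  }

  logits <- if (cfg$epochs_student > 0) .clf_forward(student, X)$logits else teacher_logits
  soft <- .softmax_rows(logits)
  hard <- teacher$classes[max.col(soft, ties.method = "first")]
  structure(
    list(hard_labels = hard, soft_probs = soft,
         student = student, loss_log = loss_log),
    class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: %d cells, %d clusters\n",
              length(x$hard_labels), ncol(x$soft_probs)))
  invisible(x)
}
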