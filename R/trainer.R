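# Pair classifier head, multi-task binary cross-entropy, micro-F1, Adam, and
# the training loop (plateau learning-rate schedule + early stopping).

#' Training configuration
#'
#' Defaults follow the reference protocol: Adam with learning rate 0.001 and
#' weight decay 5e-4, batch size 512, up to 300 epochs, learning rate reduced
#' on plateau (patience 20), early stop after 20 consecutive epochs without
#' a training-loss improvement.
#'
#' @param learning_rate Initial Adam learning rate.
#' @param weight_decay L2 coefficient added to gradients.
#' @param batch_size Pairs per optimization step (`Inf` = full batch).
#' @param max_epochs Epoch cap.
#' @param plateau_patience Epochs without improvement before the learning
#'   rate is multiplied by `plateau_factor`.
#' @param plateau_factor Learning-rate reduction factor.
#' @param early_stop_patience Epochs without improvement before stopping.
#' @param seed Seed for initialization-independent training randomness
#'   (batch shuffling, negative split).
#' @param verbose Print per-epoch log lines.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.001, weight_decay = 5e-4,
                         batch_size = 512L, max_epochs = 300L,
                         plateau_patience = 20L, plateau_factor = 0.1,
                         early_stop_patience = 20L, seed = 1L,
                         verbose = FALSE) {
  stopifnot(learning_rate > 0, weight_decay >= 0, batch_size >= 1,
            max_epochs >= 1, plateau_patience >= 1, early_stop_patience >= 1)
  if (plateau_patience > max_epochs || early_stop_patience > max_epochs) {
    stop_validation("patience must not exceed max_epochs")
  }
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = batch_size, max_epochs = as.integer(max_epochs),
                 plateau_patience = as.integer(plateau_patience),
                 plateau_factor = plateau_factor,
                 early_stop_patience = as.integer(early_stop_patience),
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Predict interaction-type probabilities for one protein pair
#'
#' Combines the two embeddings by element-wise product and applies the fully
#' connected head followed by an element-wise sigmoid.  Symmetric in its
#' arguments.
#'
#' @param e_i,e_j Embedding vectors of equal width.
#' @param head List with `W` (`d_emb x 7`) and `b` (`1 x 7`).
#' @return Length-7 probability vector.
#' @export
predict_pair <- function(e_i, e_j, head) {
  if (length(e_i) != length(e_j)) stop_validation("embedding widths disagree")
  z <- matrix(e_i * e_j, 1L)
  as.vector(1 / (1 + exp(-(z %*% head$W + head$b))))
}

#' Multi-task binary cross-entropy loss
#'
#' Sum over the 7 classes of the per-class binary cross-entropy, averaged
#' over pairs; probabilities are clamped to `[1e-7, 1 - 1e-7]` before the
#' logarithm.
#'
#' @param y `m x 7` binary label matrix.
#' @param yhat `m x 7` probability matrix.
#' @param clamp Clamping bound for the probabilities.
#' @return Non-negative scalar.
#' @export
bce_loss <- function(y, yhat, clamp = 1e-7) {
  y <- as.matrix(y); yhat <- as.matrix(yhat)
  if (!all(dim(y) == dim(yhat))) stop_validation("label/probability shapes disagree")
  pc <- pmin(pmax(yhat, clamp), 1 - clamp)
  sum(-y * log(pc) - (1 - y) * log(1 - pc)) / nrow(y)
}

#' Micro-averaged F1 over the 7 interaction classes
#'
#' Pools true/false positives and false negatives across all classes before
#' forming precision and recall:
#' `Recall_m = sum(TP_i) / (sum(TP_i) + sum(FN_i))`,
#' `Precision_m = sum(TP_i) / (sum(TP_i) + sum(FP_i))`,
#' `F1 = 2 * Recall_m * Precision_m / (Recall_m + Precision_m)`
#' (0 when the denominator is 0).
#'
#' @param y_true,y_pred `m x 7` binary matrices.
#' @return A `metric_report`: per-class `tp`, `fp`, `fn`, `tn`, pooled
#'   `recall_m`, `precision_m`, `micro_f1`.
#' @export
micro_f1 <- function(y_true, y_pred) {
  y_true <- as.matrix(y_true); y_pred <- as.matrix(y_pred)
  if (!all(dim(y_true) == dim(y_pred))) stop_validation("shapes disagree")
  assert_binary_matrix(y_true, "y_true")
  assert_binary_matrix(y_pred, "y_pred")
  tp <- colSums(y_true == 1 & y_pred == 1)
  fp <- colSums(y_true == 0 & y_pred == 1)
  fn <- colSums(y_true == 1 & y_pred == 0)
  tn <- colSums(y_true == 0 & y_pred == 0)
  recall <- if (sum(tp) + sum(fn) > 0) sum(tp) / (sum(tp) + sum(fn)) else 0
  precision <- if (sum(tp) + sum(fp) > 0) sum(tp) / (sum(tp) + sum(fp)) else 0
  f1 <- if (recall + precision > 0) 2 * recall * precision / (recall + precision) else 0
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 recall_m = recall, precision_m = precision, micro_f1 = f1),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> micro-F1 %.4f (precision %.4f, recall %.4f)\n",
              x$micro_f1, x$precision_m, x$recall_m))
  invisible(x)
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  zero <- lapply(params, function(p) p * 0)
  list(m = zero, v = zero, t = 0L)
}

adam_step <- function(params, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8, skip = character()) {
  state$t <- state$t + 1L
  b1t <- 1 - beta1^state$t
  b2t <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g) || nm %in% skip) next
    if (weight_decay > 0) g <- g + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / b1t) / (sqrt(state$v[[nm]] / b2t) + eps)
  }
  list(params = params, state = state)
}

# ---- training loop ---------------------------------------------------------

#' Train a model
#'
#' Adam with the configured hyperparameters, learning rate reduced on a
#' training-loss plateau, early stopping after `early_stop_patience`
#' non-improving epochs.  Training pairs are the split's training edges plus
#' all sampled negatives (all-zero labels); held-out micro-F1 is measured on
#' the split's test edges, i.e. it quantifies recovery of interaction types
#' on true interactions.  Evaluation binarizes probabilities at 0.5.
#'
#' The per-epoch `micro_f1` history column is an on-the-fly estimate from the
#' embeddings of the epoch's last batch (before that batch's update); the
#' returned `final` report is a fresh forward pass with the final parameters.
#'
#' @param model A [ppihop_model()].
#' @param dataset The [ppihop_dataset()] the model was initialized on.
#' @param split A `ppi_partition` over the dataset's positive edges.
#' @param cfg A [train_config()].
#' @return List with `model` (trained), `history` (data.frame: epoch, lr,
#'   loss, micro_f1), `final` (`metric_report` on the test pairs), and
#'   `test_pairs` / `test_labels`.
#' @export
ppihop_train <- function(model, dataset, split, cfg = train_config()) {
  if (nrow(split$train) < 1L) stop_validation("empty training edge set")
  both <- intersect(pair_key(split$train$protein_i, split$train$protein_j),
                    pair_key(split$test$protein_i, split$test$protein_j))
  if (length(both)) stop_validation("train/test splits overlap")

  train_edges <- split$train[, c("protein_i", "protein_j")]
  if (!is.null(dataset$negatives) && nrow(dataset$negatives)) {
    train_edges <- rbind(train_edges,
                         dataset$negatives[, c("protein_i", "protein_j")])
  }
  test_edges <- split$test[, c("protein_i", "protein_j")]
  train_idx <- pair_index(dataset, train_edges)
  test_idx <- pair_index(dataset, test_edges)
  y_train <- pair_labels(dataset, train_edges)
  y_test <- pair_labels(dataset, test_edges)

  params <- model$params
  state <- adam_init(params)
  skip <- if (!model$cfg$gin$eps_learnable) grep("\\.eps$", names(params), value = TRUE)
          else character()
  lr <- cfg$learning_rate
  best <- Inf
  bad_plateau <- 0L
  bad_stop <- 0L
  n_train <- nrow(train_idx)
  history <- data.frame(epoch = integer(), lr = double(), loss = double(),
                        micro_f1 = double())

  with_seed(derive_seed(cfg$seed, 1L), {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(n_train)
      bs <- min(cfg$batch_size, n_train)
      starts <- seq(1L, n_train, by = bs)
      ep_loss <- 0
      f1_est <- NA_real_
      for (s in starts) {
        bidx <- ord[s:min(s + bs - 1L, n_train)]
        tape <- ad_tape()
        fw <- model_forward(tape, params, model, dataset,
                            train_idx[bidx, , drop = FALSE])
        loss <- ad_bce(tape, fw$prob, y_train[bidx, , drop = FALSE])
        ad_backward(tape, loss)
        grads <- lapply(fw$P, function(nd) nd$grad)
        ep_loss <- ep_loss + loss$value[1L, 1L] * length(bidx)
        if (s == starts[length(starts)]) {
          # cheap test-set estimate from this batch's (pre-update) embeddings
          pr <- head_predict(fw$E$value, test_idx, params)
          f1_est <- micro_f1(y_test, (pr >= 0.5) + 0L)$micro_f1
        }
        st <- adam_step(params, grads, state, lr, cfg$weight_decay, skip = skip)
        params <- st$params
        state <- st$state
      }
      ep_loss <- ep_loss / n_train
      history <- rbind(history, data.frame(epoch = epoch, lr = lr,
                                           loss = ep_loss, micro_f1 = f1_est))
      if (cfg$verbose) {
        message(sprintf("epoch %3d  lr %.2e  loss %.4f  micro-F1 %.4f",
                        epoch, lr, ep_loss, f1_est))
      }
      if (ep_loss < best - 1e-8) {
        best <- ep_loss
        bad_plateau <- 0L
        bad_stop <- 0L
      } else {
        bad_plateau <- bad_plateau + 1L
        bad_stop <- bad_stop + 1L
      }
      if (bad_plateau >= cfg$plateau_patience) {
        lr <- lr * cfg$plateau_factor
        bad_plateau <- 0L
      }
      if (bad_stop >= cfg$early_stop_patience) break
    }
  })

  model$params <- params
  final <- ppihop_evaluate(model, dataset, test_idx, y_test)
  list(model = model, history = history, final = final,
       test_pairs = test_edges, test_labels = y_test)
}

# pair probabilities from a fixed embedding matrix and current head params
head_predict <- function(E, pairs_idx, params) {
  z <- E[pairs_idx[, 1L], , drop = FALSE] * E[pairs_idx[, 2L], , drop = FALSE]
  1 / (1 + exp(-(z %*% params[["head.W"]] +
                   bcast_rows(params[["head.b"]], nrow(z)))))
}

#' Evaluate a model on a set of pairs
#'
#' Forward pass (no gradients) followed by binarization at 0.5 and
#' [micro_f1()].
#'
#' @param model A trained `ppihop_model`.
#' @param dataset The matching `ppihop_dataset`.
#' @param pairs_idx `m x 2` integer matrix of protein indices (or an edge
#'   data.frame with `protein_i`/`protein_j`).
#' @param labels `m x 7` binary label matrix.
#' @return A `metric_report` with the probability matrix attached as
#'   attribute `"prob"`.
#' @export
ppihop_evaluate <- function(model, dataset, pairs_idx, labels) {
  if (is.data.frame(pairs_idx)) pairs_idx <- pair_index(dataset, pairs_idx)
  tape <- ad_tape()
  fw <- model_forward(tape, model$params, model, dataset, pairs_idx)
  prob <- fw$prob$value
  report <- micro_f1(labels, (prob >= 0.5) + 0L)
  attr(report, "prob") <- prob
  report
}
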