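#' Training protocol settings
#'
#' Defaults follow the optimization protocol used for the full network:
#' Adam with learning rate 0.001, mini-batches of 16, categorical
#' cross-entropy, at most 100 epochs with early stopping after 20 epochs
#' without validation-loss improvement (best-validation weights restored).
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size mini-batch size.
#' @param max_epochs maximum number of epochs.
#' @param patience epochs without validation-loss improvement before
#'   stopping.
#' @param seed seed for shuffling, dropout and any resampling inside the
#'   training loop.
#' @return A list of class `train_control`.
#' @export
train_control <- function(learning_rate = 0.001, batch_size = 16L,
                          max_epochs = 100L, patience = 20L, seed = 1L) {
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 1,
            patience >= 1, patience <= max_epochs)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "train_control")
}

#' Class-rebalancing resampling plan
#'
#' Target per-class training-set sizes: undersample normal to 4000 and
#' oversample AF, other and noisy to 2500, 3000 and 1000 respectively.
#'
#' @param N,A,O,P target counts per class.
#' @return Named integer vector.
#' @export
resampling_plan <- function(N = 4000L, A = 2500L, O = 3000L, P = 1000L) {
  plan <- c(N = as.integer(N), A = as.integer(A), O = as.integer(O),
            P = as.integer(P))
  if (any(plan < 1)) stop("resampling targets must be >= 1")
  plan
}

#' Stratified k-fold splits with train/validation subdivision
#'
#' Each fold preserves the global class proportions; the k test folds
#' partition the dataset.  Within each fold the remaining records are
#' split 90/10 (stratified) into training and validation.  Splitting is by
#' record id, so multiple CS-ECM chunks of one recording never straddle
#' sets.  Deterministic for a fixed seed.
#'
#' @param labels data frame with `record_id` and `label` columns.
#' @param k number of folds.
#' @param seed seed.
#' @param val_frac validation fraction of the non-test pool.
#' @return List of `k` folds, each a list with `fold_id`, `test`, `train`,
#'   `validation` (character vectors of record ids).
#' @export
make_folds <- function(labels, k = 5L, seed = 1L, val_frac = 0.1) {
  stopifnot(is.data.frame(labels), all(c("record_id", "label") %in% names(labels)))
  cls_n <- table(factor(labels$label, levels = ecg_classes()))
  if (any(cls_n < k))
    stop("every class needs at least k = ", k, " records; got ",
         paste(names(cls_n)[cls_n < k], collapse = ", "))
  set.seed(seed)
  assign_fold <- integer(nrow(labels))
  for (cl in ecg_classes()) {
    idx <- which(labels$label == cl)
    idx <- sample(idx)
    assign_fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  lapply(seq_len(k), function(f) {
    test <- labels$record_id[assign_fold == f]
    pool <- labels[assign_fold != f, , drop = FALSE]
    val <- character()
    for (cl in ecg_classes()) {
      ids <- pool$record_id[pool$label == cl]
      nv <- round(val_frac * length(ids))
      if (nv > 0) val <- c(val, sample(ids, nv))
    }
    list(fold_id = f, test = test,
         train = setdiff(pool$record_id, val), validation = val)
  })
}

#' Resample a training pool to the plan's class counts
#'
#' Undersampling draws without replacement; oversampling duplicates each
#' record `floor(target/n)` times and tops up by seeded sampling without
#' replacement, so the class counts match the plan exactly.
#'
#' @param labels data frame with `record_id` and `label` for the pool.
#' @param plan a [resampling_plan()].
#' @param seed seed.
#' @return Character vector of record ids (with duplicates for oversampled
#'   classes), in class order.
#' @export
resample_training_set <- function(labels, plan = resampling_plan(), seed = 1L) {
  set.seed(seed)
  out <- character()
  for (cl in ecg_classes()) {
    ids <- labels$record_id[labels$label == cl]
    n <- length(ids)
    if (n == 0) stop("class ", cl, " is empty in the training pool")
    target <- plan[[cl]]
    sel <- if (n == target) {
      ids
    } else if (n > target) {
      sample(ids, target)
    } else {
      c(rep(ids, target %/% n), sample(ids, target %% n))
    }
    out <- c(out, sel)
  }
  out
}

.one_hot <- function(labels, classes = ecg_classes()) {
  y <- matrix(0, length(labels), length(classes))
  idx <- match(labels, classes)
  if (anyNA(idx)) stop("invalid class code in labels")
  y[cbind(seq_along(labels), idx)] <- 1
  y
}

.eval_loss <- function(model, X, y_onehot, batch_size = 32L) {
  n <- dim(X)[3]
  loss <- 0; correct <- 0
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(n, start + batch_size - 1L)
    out <- cpp_forward(unclass(model$config), model$par,
                       X[, , idx, drop = FALSE], FALSE, 0, FALSE)
    p <- pmax(out$probs, 1e-12)
    loss <- loss - sum(log(p[y_onehot[idx, , drop = FALSE] == 1]))
    correct <- correct +
      sum(max.col(out$probs, ties.method = "first") ==
            max.col(y_onehot[idx, , drop = FALSE], ties.method = "first"))
  }
  list(loss = loss / n, acc = correct / n)
}

#' Train a BIT-CNN by mini-batch Adam with early stopping
#'
#' Categorical cross-entropy is minimized with Adam; per-epoch shuffling
#' and dropout masks are seeded from the control seed.  Training stops
#' when the validation loss fails to improve for `patience` epochs and the
#' best-validation weights are restored.
#'
#' @param model an untrained (or previously trained) [bitcnn()].
#' @param x training inputs: list of `csecm`/matrices or an H x W x n
#'   array.
#' @param y training class codes (length n).
#' @param x_val,y_val validation inputs and class codes.
#' @param control a [train_control()].
#' @param verbose print per-epoch progress.
#' @return The trained `bitcnn`, with `history` (data frame of per-epoch
#'   train/validation loss and validation accuracy) and `trained = TRUE`.
#' @export
train_bitcnn <- function(model, x, y, x_val, y_val,
                         control = train_control(), verbose = FALSE) {
  stopifnot(inherits(model, "bitcnn"), inherits(control, "train_control"))
  cfg <- unclass(model$config)
  X <- .as_input_array(x, model$config)
  n <- dim(X)[3]
  if (n == 0 || length(y) != n) stop("training set empty or label mismatch")
  Y <- .one_hot(y, model$classes)
  Xv <- .as_input_array(x_val, model$config)
  Yv <- .one_hot(y_val, model$classes)

  lay <- model$layout
  sz <- lay$nrow * lay$ncol
  ends <- cumsum(sz)
  tr_idx <- unlist(mapply(function(e, s, tr) if (tr) (e - s + 1L):e else NULL,
                          ends, sz, lay$trainable))
  par <- model$par
  m1 <- numeric(length(tr_idx)); m2 <- numeric(length(tr_idx))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-7; t <- 0L
  best_loss <- Inf; best_par <- par; best_epoch <- 0L
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric(), val_acc = numeric())
  set.seed(control$seed)
  for (epoch in seq_len(control$max_epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0L
    for (start in seq(1L, n, by = control$batch_size)) {
      idx <- ord[start:min(n, start + control$batch_size - 1L)]
      drop_seed <- sample.int(.Machine$integer.max, 1L)
      res <- cpp_loss_grad(cfg, par, X[, , idx, drop = FALSE],
                           Y[idx, , drop = FALSE], drop_seed)
      par <- res$par_new                       # carries BN running stats
      g <- res$grad[tr_idx]
      t <- t + 1L
      m1 <- b1 * m1 + (1 - b1) * g
      m2 <- b2 * m2 + (1 - b2) * g^2
      mhat <- m1 / (1 - b1^t)
      vhat <- m2 / (1 - b2^t)
      par[tr_idx] <- par[tr_idx] - control$learning_rate * mhat / (sqrt(vhat) + eps)
      ep_loss <- ep_loss + res$loss; nb <- nb + 1L
    }
    model$par <- par
    ev <- .eval_loss(model, Xv, Yv)
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = ep_loss / nb,
                                   val_loss = ev$loss, val_acc = ev$acc))
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f  acc %.3f",
                      epoch, ep_loss / nb, ev$loss, ev$acc))
    if (ev$loss < best_loss - 1e-9) {
      best_loss <- ev$loss; best_par <- par; best_epoch <- epoch
    } else if (epoch - best_epoch >= control$patience) {
      break
    }
  }
  model$par <- best_par
  model$trained <- TRUE
  model$history <- hist
  model
}

#' @export
plot.bitcnn <- function(x, ...) {
  if (is.null(x$history)) stop("model has no training history")
  h <- x$history
  graphics::plot(h$epoch, h$train_loss, type = "l", col = "steelblue",
                 ylim = range(c(h$train_loss, h$val_loss)),
                 xlab = "epoch", ylab = "cross-entropy loss", ...)
  graphics::lines(h$epoch, h$val_loss, col = "firebrick")
  graphics::legend("topright", c("train", "validation"),
                   col = c("steelblue", "firebrick"), lty = 1, bty = "n")
  invisible(x)
}

#' Aggregate per-chunk probabilities into one record-level class
#'
#' A recording longer than one minute contributes several CS-ECMs; its
#' label is the argmax of the arithmetic mean of the chunk probability
#' vectors, ties broken by class order (N, A, O, P).
#'
#' @param probs matrix of chunk probability vectors (chunks x 4) or a
#'   single probability vector.
#' @return A single class code.
#' @export
aggregate_record_prediction <- function(probs) {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
  if (nrow(probs) == 0) stop("no chunk predictions to aggregate")
  ecg_classes()[which.max(colMeans(probs))]
}
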