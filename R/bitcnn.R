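#' BIT-CNN architecture configuration
#'
#' Hyperparameters of the beat-interval-texture CNN.  The default values
#' give the full-size network: shaped-convolution kernel extent `K = 5`;
#' 32/64/128 B-type filters in low-level blocks 1-3; 64/128/256 filters per
#' path (B, I, T) in super-blocks 4-6; 1x1-convolution widths 3, 6, 12, 18,
#' 24, 30 (each a multiple of 3, one weight group per clinically meaningful
#' region of the segment: before the first R-peak, after it, and around the
#' second R-peak); a 3x3 spatial-attention convolution whose weights are
#' shared across the three paths of a super-block; and a channel-attention
#' perceptron with hidden width 180.  Under these defaults the network has
#' 2,015,043 parameters (2,011,907 trainable) and 1,568 shaped convolution
#' filters.
#'
#' @param K odd kernel extent of the B (1 x K), I (K x 1) and T (K x K)
#'   convolution filters.
#' @param lb_filters filter counts of low-level blocks 1-3.
#' @param hb_filters per-path filter counts of super-blocks 4-6.
#' @param one_by_one 1x1-convolution widths for blocks 1-6; each must be
#'   divisible by 3.
#' @param dropout_rate dropout fraction applied after each super-block
#'   concatenation.
#' @param spatial_attention_kernel odd kernel extent of the spatial
#'   attention convolution.
#' @param fa_hidden hidden width of the channel-attention perceptron.
#' @param n_classes number of output classes.
#' @param height,width input CS-ECM shape.
#' @return A list of class `bitcnn_config`.
#' @export
bitcnn_config <- function(K = 5, lb_filters = c(32, 64, 128),
                          hb_filters = c(64, 128, 256),
                          one_by_one = c(3, 6, 12, 18, 24, 30),
                          dropout_rate = 0.3, spatial_attention_kernel = 3,
                          fa_hidden = 180, n_classes = 4,
                          height = 180, width = 240) {
  if (K %% 2 != 1) stop("`K` must be odd")
  if (spatial_attention_kernel %% 2 != 1)
    stop("`spatial_attention_kernel` must be odd")
  if (length(lb_filters) != 3 || any(lb_filters <= 0))
    stop("`lb_filters` must be 3 positive counts")
  if (length(hb_filters) != 3 || any(hb_filters <= 0))
    stop("`hb_filters` must be 3 positive counts")
  if (length(one_by_one) != 6 || any(one_by_one <= 0))
    stop("`one_by_one` must be 6 positive counts")
  if (any(one_by_one %% 3 != 0))
    stop("`one_by_one` entries must each be divisible by 3")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("`dropout_rate` must be in [0, 1)")
  structure(list(
    K = as.integer(K), lb_filters = as.integer(lb_filters),
    hb_filters = as.integer(hb_filters), one_by_one = as.integer(one_by_one),
    dropout_rate = dropout_rate,
    spatial_attention_kernel = as.integer(spatial_attention_kernel),
    fa_hidden = as.integer(fa_hidden), n_classes = as.integer(n_classes),
    height = as.integer(height), width = as.integer(width)
  ), class = "bitcnn_config")
}

#' Reduced BIT-CNN configuration for CPU-scale experiments
#'
#' Same topology as [bitcnn_config()] with filter counts divided by four
#' (8/16/32 and 16/32/64 per path) and narrower 1x1 widths
#' (3, 3, 6, 6, 6, 6), sized so that full training runs complete in
#' minutes on a single CPU.
#'
#' @param ... overrides passed to [bitcnn_config()].
#' @return A `bitcnn_config`.
#' @export
bitcnn_config_small <- function(...) {
  bitcnn_config(lb_filters = c(8, 16, 32), hb_filters = c(16, 32, 64),
                one_by_one = c(3, 3, 6, 6, 6, 6), ...)
}

#' Construct an (untrained) BIT-CNN model
#'
#' Assembles the network and initializes its weights (Glorot-uniform for
#' convolution and dense weights, zeros for biases, unit batch-norm).
#' The architecture: three low-level blocks (B-type 1xK convolution,
#' batch-norm, ReLU, 1x1 convolution, width-only dual max/average pooling);
#' three super-blocks, each with parallel B (1xK), I (Kx1) and T (KxK)
#' paths (convolution, batch-norm, ReLU, 1x1 convolution, spatial
#' attention, 2x2 dual pooling), channel-concatenated `[B || I || T]` and
#' followed by dropout; a feature-attention layer (global average + max
#' pooling concatenated, perceptron-learned sigmoid channel scores); and a
#' softmax head.
#'
#' @param config a [bitcnn_config()].
#' @param seed seed for the weight initialization.
#' @return An object of class `bitcnn`: list with `config`, `par` (flat
#'   parameter vector), `layout` (parameter table), `trained` flag and
#'   `history`.
#' @export
bitcnn <- function(config = bitcnn_config(), seed = 1L) {
  stopifnot(inherits(config, "bitcnn_config"))
  lay <- cpp_param_layout(unclass(config))
  n <- sum(lay$nrow * lay$ncol)
  par <- numeric(n)
  set.seed(seed)
  off <- 0L
  for (i in seq_len(nrow(lay))) {
    sz <- lay$nrow[i] * lay$ncol[i]
    nm <- lay$name[i]
    vals <-
      if (grepl("_w$|_w[0-9]$", nm) || grepl("_conv_w$|_one_w$|_sa_w$", nm) ||
          nm %in% c("fa_w1", "fa_w2", "fc_w")) {
        lim <- sqrt(6 / (lay$fan_in[i] + lay$fan_out[i]))
        stats::runif(sz, -lim, lim)
      } else if (grepl("_gamma$|_rvar$", nm)) {
        rep(1, sz)
      } else {
        rep(0, sz)
      }
    par[off + seq_len(sz)] <- vals
    off <- off + sz
  }
  structure(list(config = config, par = par, layout = lay,
                 trained = FALSE, history = NULL, classes = ecg_classes()),
            class = "bitcnn")
}

#' Parameter audit of a BIT-CNN
#'
#' @param model a [bitcnn()] model.
#' @return A list with `total`, `trainable`, `non_trainable` and
#'   `shaped_filters` (the number of B/I/T convolution filters over all
#'   blocks).
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "bitcnn"))
  lay <- model$layout
  sz <- lay$nrow * lay$ncol
  cfg <- model$config
  list(total = sum(sz), trainable = sum(sz[lay$trainable]),
       non_trainable = sum(sz[!lay$trainable]),
       shaped_filters = sum(cfg$lb_filters) + 3L * sum(cfg$hb_filters))
}

#' Per-block output shapes of a BIT-CNN
#'
#' Pure shape arithmetic: low-level pooling halves the width only, the
#' super-block pooling halves both dimensions (ceiling on odd extents).
#'
#' @param config a [bitcnn_config()].
#' @return Data frame with block, height, width, channels.
#' @export
bitcnn_shapes <- function(config = bitcnn_config()) {
  h <- config$height; w <- config$width
  out <- data.frame(block = character(), height = integer(),
                    width = integer(), channels = integer())
  for (b in 1:3) {
    w <- ceiling(w / 2)
    out <- rbind(out, data.frame(block = paste0("block", b), height = h,
                                 width = w, channels = 2L * config$one_by_one[b]))
  }
  for (b in 4:6) {
    h <- ceiling(h / 2); w <- ceiling(w / 2)
    out <- rbind(out, data.frame(block = paste0("block", b), height = h,
                                 width = w, channels = 6L * config$one_by_one[b]))
  }
  embedding <- 2L * out$channels[6]
  attr(out, "embedding_length") <- embedding
  out
}

#' @export
print.bitcnn <- function(x, ...) {
  pc <- count_parameters(x)
  cat(sprintf(
    "BIT-CNN (%s): input %dx%d, %s classes\n  parameters: %s total (%s trainable), %d shaped filters\n",
    if (x$trained) "trained" else "untrained",
    x$config$height, x$config$width, x$config$n_classes,
    format(pc$total, big.mark = ","), format(pc$trainable, big.mark = ","),
    pc$shaped_filters))
  invisible(x)
}

#' @export
summary.bitcnn <- function(object, ...) {
  print(object)
  shp <- bitcnn_shapes(object$config)
  cat("\nPer-block output shapes (height, width, channels):\n")
  print(shp, row.names = FALSE)
  cat(sprintf("\nFeature embedding length: %d\n",
              attr(shp, "embedding_length")))
  invisible(list(shapes = shp, parameters = count_parameters(object)))
}

#' @export
coef.bitcnn <- function(object, ...) {
  lay <- object$layout
  out <- list()
  off <- 0L
  for (i in seq_len(nrow(lay))) {
    sz <- lay$nrow[i] * lay$ncol[i]
    out[[lay$name[i]]] <- matrix(object$par[off + seq_len(sz)],
                                 lay$nrow[i], lay$ncol[i])
    off <- off + sz
  }
  out
}

# stack a list of csecm objects / matrices into an H x W x N array
.as_input_array <- function(x, cfg) {
  if (inherits(x, "csecm")) x <- list(x)
  if (is.matrix(x)) x <- list(x)
  mats <- lapply(x, function(m) if (inherits(m, "csecm")) m$matrix else m)
  if (!length(mats)) stop("empty input: no matrices supplied")
  for (m in mats)
    if (!all(dim(m) == c(cfg$height, cfg$width)))
      stop("input matrix shape ", paste(dim(m), collapse = "x"),
           " does not match model input ", cfg$height, "x", cfg$width)
  array(unlist(mats), dim = c(cfg$height, cfg$width, length(mats)))
}

#' Predict class probabilities for CS-ECM inputs
#'
#' Runs the network in evaluation mode (dropout inactive, batch-norm using
#' running statistics); deterministic for fixed weights.
#'
#' @param object a [bitcnn()] model.
#' @param newdata a `csecm`, a matrix, or a list of either.
#' @param type `"prob"` for class probabilities, `"class"` for predicted
#'   class codes, `"embedding"` for the 2C-length feature embeddings.
#' @param batch_size internal evaluation batch size.
#' @param ... unused.
#' @return Probability matrix (n x 4, columns N, A, O, P), character vector
#'   of class codes, or embedding matrix.
#' @export
predict.bitcnn <- function(object, newdata, type = c("prob", "class", "embedding"),
                           batch_size = 16L, ...) {
  type <- match.arg(type)
  X <- .as_input_array(newdata, object$config)
  n <- dim(X)[3]
  probs <- matrix(NA_real_, n, object$config$n_classes)
  emb <- NULL
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(n, start + batch_size - 1L)
    out <- cpp_forward(unclass(object$config), object$par,
                       X[, , idx, drop = FALSE], FALSE, 0, FALSE)
    probs[idx, ] <- out$probs
    if (type == "embedding") {
      if (is.null(emb)) emb <- matrix(NA_real_, n, ncol(out$embedding))
      emb[idx, ] <- out$embedding
    }
  }
  colnames(probs) <- object$classes
  switch(type,
         prob = probs,
         class = object$classes[max.col(probs, ties.method = "first")],
         embedding = emb)
}

#' Per-block feature maps for a batch of inputs
#'
#' Evaluation-mode forward pass returning each block's output feature map
#' (post-concatenation for low-level blocks, post-dropout position -- i.e.
#' the concatenated map, dropout being inactive in evaluation -- for
#' super-blocks).  Used by the embedding and Grad-CAM tools.
#'
#' @param model a [bitcnn()].
#' @param newdata input as in [predict.bitcnn()].
#' @return List with `blocks` (list of 6 lists of H x W x C arrays) and
#'   `probs`.
#' @export
bitcnn_features <- function(model, newdata) {
  X <- .as_input_array(newdata, model$config)
  out <- cpp_forward(unclass(model$config), model$par, X, FALSE, 0, TRUE)
  list(blocks = out$blocks, probs = out$probs, embedding = out$embedding)
}

## ---- single layer operations (exposed for verification) -------------------

#' Shaped convolutions: beat, interval and texture filters
#'
#' Same-padding 2D convolutions with the three BIT kernel shapes: B-type
#' `1 x K` (beat morphology along a segment row), I-type `K x 1`
#' (inter-beat consistency at one timestep) and T-type `K x K` (texture
#' over both axes).  Output spatial shape equals input shape; channel count
#' equals the number of filters.
#'
#' @param x input array (H x W x C).
#' @param weights matrix `(kh*kw*C) x n_filters` (column-major kernel
#'   order: offsets within a column run y fastest, then x, then channel).
#' @param bias numeric vector of length `n_filters`.
#' @param K kernel extent.
#' @return Array H x W x n_filters.
#' @export
b_conv <- function(x, weights, bias, K = 5) {
  if (NCOL(weights) <= 0) stop("n_filters must be positive")
  cpp_conv2d_same(.as_cube(x), weights, bias, 1L, as.integer(K))
}

#' @rdname b_conv
#' @export
i_conv <- function(x, weights, bias, K = 5) {
  if (NCOL(weights) <= 0) stop("n_filters must be positive")
  cpp_conv2d_same(.as_cube(x), weights, bias, as.integer(K), 1L)
}

#' @rdname b_conv
#' @export
t_conv <- function(x, weights, bias, K = 5) {
  if (NCOL(weights) <= 0) stop("n_filters must be positive")
  cpp_conv2d_same(.as_cube(x), weights, bias, as.integer(K), as.integer(K))
}

.as_cube <- function(x) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  x
}

#' Dual max/average pooling
#'
#' Pools the feature map with max- and average-pooling in parallel and
#' channel-concatenates the results `[max || average]`, doubling the
#' channel count.  `mode = "low"` uses window and stride (1, 2) (width
#' halved, height untouched); `mode = "high"` uses (2, 2) (both halved,
#' ceiling on odd extents, averages taken over the clipped window).
#'
#' @param x input array (H x W x C).
#' @param mode `"low"` or `"high"`.
#' @return Pooled array with 2C channels.
#' @export
dual_pool <- function(x, mode = c("low", "high")) {
  mode <- match.arg(mode)
  x <- .as_cube(x)
  if (mode == "low" && dim(x)[2] < 2)
    stop("input is too narrow for low-level pooling")
  cpp_dual_pool(x, if (mode == "low") 0L else 1L)
}

#' Spatial attention
#'
#' Channel-wise mean and max maps are stacked (2 channels), convolved with
#' a single k x k filter (no bias) to one channel, passed through a
#' sigmoid, and the resulting score grid in `[0, 1]` multiplies every input
#' channel.  Output shape equals input shape.
#'
#' @param x input array (H x W x C).
#' @param weights matrix `(2*k*k) x 1`.
#' @param k odd kernel extent.
#' @return List with `output` (same shape as `x`) and `scores` (H x W).
#' @export
spatial_attention <- function(x, weights, k = 3) {
  cpp_spatial_attention(.as_cube(x), as.matrix(weights), as.integer(k))
}

#' Feature (channel) attention
#'
#' Global average and global max pooling vectors of the feature map are
#' concatenated into a representation of length 2C; a one-hidden-layer
#' perceptron maps it to 2C sigmoid scores, and the embedding is the
#' elementwise product of representation and scores.
#'
#' @param x input array (H x W x C).
#' @param w1,b1 hidden layer weights `(2C x h)` and bias (length h).
#' @param w2,b2 output layer weights `(h x 2C)` and bias (length 2C).
#' @return List with `representation`, `scores`, `embedding` (each length
#'   2C).
#' @export
feature_attention <- function(x, w1, b1, w2, b2) {
  cpp_feature_attention(.as_cube(x), as.matrix(w1), as.numeric(b1),
                        as.matrix(w2), as.numeric(b2))
}
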