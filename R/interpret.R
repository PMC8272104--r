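# bilinear upsampling of a low-resolution map onto the input grid
.bilinear_upsample <- function(m, H, W) {
  h <- nrow(m); w <- ncol(m)
  if (h == H && w == W) return(m)
  ys <- pmin(pmax((seq_len(H) - 0.5) * h / H - 0.5, 0), h - 1)
  xs <- pmin(pmax((seq_len(W) - 0.5) * w / W - 0.5, 0), w - 1)
  y0 <- pmin(floor(ys), h - 1); y1 <- pmin(y0 + 1, h - 1)
  x0 <- pmin(floor(xs), w - 1); x1 <- pmin(x0 + 1, w - 1)
  fy <- ys - y0; fx <- xs - x0
  a <- m[cbind(rep(y0 + 1, W), rep(x0 + 1, each = H))]
  b <- m[cbind(rep(y1 + 1, W), rep(x0 + 1, each = H))]
  cc <- m[cbind(rep(y0 + 1, W), rep(x1 + 1, each = H))]
  d <- m[cbind(rep(y1 + 1, W), rep(x1 + 1, each = H))]
  fyr <- rep(fy, W); fxr <- rep(fx, each = H)
  matrix(a * (1 - fyr) * (1 - fxr) + b * fyr * (1 - fxr) +
           cc * (1 - fyr) * fxr + d * fyr * fxr, H, W)
}

.cam_from <- function(act, grad, channels, H, W) {
  alpha <- apply(grad[, , channels, drop = FALSE], 3, mean)
  pre <- matrix(0, dim(act)[1], dim(act)[2])
  for (j in seq_along(channels))
    pre <- pre + alpha[j] * act[, , channels[j]]
  heat <- .bilinear_upsample(pmax(pre, 0), H, W)
  rng <- range(heat)
  norm <- if (diff(rng) > 0) (heat - rng[1]) / diff(rng) else heat * 0
  list(pre_relu = pre, heatmap = heat, normalized = norm)
}

#' Grad-CAM heatmap for one block
#'
#' Gradient-weighted class activation mapping: the gradient of the
#' pre-softmax class score with respect to a block's output feature map is
#' spatially averaged per channel to give channel weights; the
#' weighted channel sum is rectified (ReLU) and bilinearly upsampled to
#' the input CS-ECM grid.  Raw values are retained alongside a min-max
#' normalized copy for rendering.
#'
#' @param model a [bitcnn()].
#' @param input one CS-ECM (a `csecm` or a matrix of the model's input
#'   shape).
#' @param target_class class code whose score is explained.
#' @param block_id block 1-6.
#' @return An object of class `gradcam_map`: list with `heatmap`
#'   (nonnegative, input-shaped), `normalized` (in `[0, 1]`), `pre_relu`
#'   (low-resolution signed map), `block_id`, `target_class`,
#'   `filter_type` (`NULL` here).
#' @export
grad_cam <- function(model, input, target_class, block_id) {
  stopifnot(inherits(model, "bitcnn"))
  if (!target_class %in% model$classes) stop("invalid class code")
  if (!block_id %in% 1:6) stop("`block_id` must be in 1..6")
  X <- .as_input_array(input, model$config)[, , 1, drop = FALSE]
  res <- cpp_gradcam(unclass(model$config), model$par, X,
                     match(target_class, model$classes))
  act <- res$activations[[block_id]]
  grad <- res$gradients[[block_id]]
  cam <- .cam_from(act, grad, seq_len(dim(act)[3]),
                   model$config$height, model$config$width)
  structure(c(cam, list(block_id = block_id, target_class = target_class,
                        filter_type = NULL)),
            class = "gradcam_map")
}

#' Grad-CAM restricted to one filter type of a super-block
#'
#' Identical to [grad_cam()] but the weighted channel sum runs only over
#' the channels contributed by the named path under the fixed
#' `[B || I || T]` concatenation convention.  Only super-blocks (4-6)
#' have per-type paths.
#'
#' @inheritParams grad_cam
#' @param filter_type one of `"B"`, `"I"`, `"T"`.
#' @return A `gradcam_map` with `filter_type` set.
#' @export
grad_cam_by_filter_type <- function(model, input, target_class, block_id,
                                    filter_type = c("B", "I", "T")) {
  filter_type <- match.arg(filter_type)
  if (!block_id %in% 4:6)
    stop("block ", block_id, " is not a super-block; filter types exist ",
         "only for blocks 4-6")
  stopifnot(inherits(model, "bitcnn"))
  X <- .as_input_array(input, model$config)[, , 1, drop = FALSE]
  res <- cpp_gradcam(unclass(model$config), model$par, X,
                     match(target_class, model$classes))
  act <- res$activations[[block_id]]
  grad <- res$gradients[[block_id]]
  per_path <- dim(act)[3] %/% 3L
  p <- match(filter_type, c("B", "I", "T"))
  channels <- ((p - 1L) * per_path + 1L):(p * per_path)
  cam <- .cam_from(act, grad, channels,
                   model$config$height, model$config$width)
  structure(c(cam, list(block_id = block_id, target_class = target_class,
                        filter_type = filter_type)),
            class = "gradcam_map")
}

#' @export
print.gradcam_map <- function(x, ...) {
  cat(sprintf("Grad-CAM map: block %d, class %s%s, %dx%d, max %.4g\n",
              x$block_id, x$target_class,
              if (is.null(x$filter_type)) ""
              else paste0(", ", x$filter_type, "-type filters"),
              nrow(x$heatmap), ncol(x$heatmap), max(x$heatmap)))
  invisible(x)
}

#' @export
plot.gradcam_map <- function(x, ...) {
  graphics::image(t(x$normalized[rev(seq_len(nrow(x$normalized))), ]),
                  col = grDevices::hcl.colors(64, "Blue-Red"),
                  axes = FALSE, ...)
  invisible(x)
}

#' 2D embedding map of feature vectors (PCA then t-SNE)
#'
#' Feature vectors are first reduced with PCA to at most 50 principal
#' components (fewer if the dimension or sample count limits it), then
#' embedded in 2D with t-SNE.  Both stages are seeded, so the output is
#' deterministic for a fixed seed.
#'
#' @param features numeric matrix, one row per sample (e.g. flattened
#'   block outputs or feature embeddings).
#' @param labels class codes per sample (kept alongside the coordinates).
#' @param seed seed.
#' @param n_components PCA dimension cap.
#' @param perplexity t-SNE perplexity (reduced automatically for small n).
#' @return An object of class `embedding_map`: data frame with `x`, `y`,
#'   `label`.
#' @export
embed_2d <- function(features, labels = NULL, seed = 1L, n_components = 50L,
                     perplexity = 30) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 3) stop("need at least 3 samples to embed")
  if (ncol(features) < 2) stop("feature dimension must be >= 2")
  if (!is.null(labels) && length(labels) != n)
    stop("`labels` length must match rows of `features`")
  k <- min(n_components, ncol(features), n - 1L)
  set.seed(seed)
  pc <- stats::prcomp(features, center = TRUE, scale. = FALSE, rank. = k)
  z <- pc$x
  perp <- min(perplexity, (n - 2) / 3)
  ts <- Rtsne::Rtsne(z, dims = 2, perplexity = perp, pca = FALSE,
                     check_duplicates = FALSE, verbose = FALSE)
  out <- data.frame(x = ts$Y[, 1], y = ts$Y[, 2],
                    label = if (is.null(labels)) NA_character_ else labels)
  class(out) <- c("embedding_map", "data.frame")
  out
}

#' @export
plot.embedding_map <- function(x, ...) {
  cls <- ecg_classes()
  col <- c(N = "#4477AA", A = "#EE6677", O = "#228833", P = "#BBBBBB")
  ci <- if (all(is.na(x$label))) "black" else col[x$label]
  graphics::plot(x$x, x$y, col = ci, pch = 19, xlab = "t-SNE 1",
                 ylab = "t-SNE 2", ...)
  if (!all(is.na(x$label)))
    graphics::legend("topright", legend = cls, col = col[cls], pch = 19,
                     bty = "n")
  invisible(x)
}
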