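make_probe_model <- function(seed = 21) {
  m <- bitcnn(tiny_config(), seed = seed)
  set.seed(seed + 100)
  m$par <- m$par + rnorm(length(m$par), 0, 0.05)
  lay <- m$layout; sz <- lay$nrow * lay$ncol; ends <- cumsum(sz)
  for (i in grep("_rvar$", lay$name)) m$par[(ends[i] - sz[i] + 1):ends[i]] <- 1
  for (i in grep("_rmean$", lay$name)) m$par[(ends[i] - sz[i] + 1):ends[i]] <- 0
  m
}

test_that("Grad-CAM maps are nonnegative, input-shaped and class-aware", {
  m <- make_probe_model()
  set.seed(22)
  x <- matrix(rnorm(12 * 16), 12, 16)
  for (b in c(1L, 4L, 6L)) {
    g <- grad_cam(m, x, "A", b)
    expect_s3_class(g, "gradcam_map")
    expect_true(all(g$heatmap >= 0))
    expect_equal(dim(g$heatmap), c(12L, 16L))
    expect_true(all(g$normalized >= 0 & g$normalized <= 1))
  }
})

test_that("block-6 gradient agrees with a numeric head-only oracle", {
  # independent oracle: re-implement the FA + FC head in R from the
  # coefficient list and differentiate the class score numerically with
  # respect to the block-6 feature map
  m <- make_probe_model(31)
  set.seed(32)
  x <- matrix(rnorm(12 * 16), 12, 16)
  res <- bitecg:::cpp_gradcam(unclass(m$config), m$par,
                              array(x, dim = c(12, 16, 1)), 2L)
  A <- res$activations[[6]]
  G <- res$gradients[[6]]
  cf <- coef(m)
  head_score <- function(A) {
    C <- dim(A)[3]
    gap <- apply(A, 3, mean); gmp <- apply(A, 3, max)
    rep_v <- c(gap, gmp)
    h1 <- pmax(drop(t(cf$fa_w1) %*% rep_v) + drop(cf$fa_b1), 0)
    sc <- 1 / (1 + exp(-(drop(t(cf$fa_w2) %*% h1) + drop(cf$fa_b2))))
    emb <- rep_v * sc
    (drop(t(cf$fc_w) %*% emb) + drop(cf$fc_b))[2]
  }
  set.seed(33)
  idx <- sample(length(A), 25)
  num <- vapply(idx, function(j) {
    e <- 1e-5
    a1 <- A; a1[j] <- a1[j] + e
    a2 <- A; a2[j] <- a2[j] - e
    (head_score(a1) - head_score(a2)) / (2 * e)
  }, numeric(1))
  # global-max pooling puts kinks at near-tied spatial maxima, where the
  # two-sided numeric derivative straddles the subgradient; a slightly
  # relaxed tolerance absorbs the one or two affected coordinates
  expect_equal(num, G[idx], tolerance = 5e-3)
})

test_that("Grad-CAM is invariant to shifting all logits by a constant", {
  m <- make_probe_model(41)
  set.seed(42)
  x <- matrix(rnorm(12 * 16), 12, 16)
  g1 <- grad_cam(m, x, "O", 4)
  m2 <- m
  lay <- m2$layout; sz <- lay$nrow * lay$ncol; ends <- cumsum(sz)
  i <- which(lay$name == "fc_b")
  m2$par[(ends[i] - sz[i] + 1):ends[i]] <-
    m2$par[(ends[i] - sz[i] + 1):ends[i]] + 7.5
  g2 <- grad_cam(m2, x, "O", 4)
  expect_equal(g1$heatmap, g2$heatmap, tolerance = 1e-10)
})

test_that("filter-type maps partition the full pre-ReLU super-block map", {
  m <- make_probe_model(51)
  set.seed(52)
  x <- matrix(rnorm(12 * 16), 12, 16)
  for (b in 4:6) {
    full <- grad_cam(m, x, "N", b)
    parts <- lapply(c("B", "I", "T"), function(ft)
      grad_cam_by_filter_type(m, x, "N", b, ft))
    # linearity of the weighted channel sum over the channel partition
    expect_equal(Reduce(`+`, lapply(parts, `[[`, "pre_relu")),
                 full$pre_relu, tolerance = 1e-10)
    for (p in parts) {
      expect_true(all(p$heatmap >= 0))
      expect_equal(dim(p$heatmap), c(12L, 16L))
    }
  }
  expect_error(grad_cam_by_filter_type(m, x, "N", 2, "B"), "super-block")
})

test_that("an all-zero network yields all-zero heatmaps", {
  m <- bitcnn(tiny_config(), seed = 61)
  m$par[] <- 0
  lay <- m$layout; sz <- lay$nrow * lay$ncol; ends <- cumsum(sz)
  for (i in grep("_rvar$", lay$name)) m$par[(ends[i] - sz[i] + 1):ends[i]] <- 1
  x <- matrix(rnorm(12 * 16), 12, 16)
  # zero gamma kills every feature map, so probabilities are uniform and
  # every Grad-CAM heatmap is a weighted sum of zeros
  expect_equal(unname(predict(m, x)[1, ]), rep(0.25, 4), tolerance = 1e-12)
  g <- grad_cam(m, x, "N", 6)
  expect_true(all(g$heatmap == 0))
})

test_that("PCA + t-SNE embedding is seeded and separates clear clusters", {
  set.seed(71)
  n <- 60
  a <- matrix(rnorm(n / 2 * 360), n / 2, 360)
  b <- matrix(rnorm(n / 2 * 360), n / 2, 360)
  b[, 1:40] <- b[, 1:40] + 6
  feats <- rbind(a, b)
  labs <- rep(c("N", "A"), each = n / 2)
  e1 <- embed_2d(feats, labs, seed = 5)
  e2 <- embed_2d(feats, labs, seed = 5)
  expect_identical(e1, e2)
  expect_equal(nrow(e1), n)
  expect_gt(mean_silhouette(cbind(e1$x, e1$y), labs), 0.5)
  # degenerate dimensions still run
  e3 <- embed_2d(matrix(rnorm(20 * 2), 20, 2), seed = 1)
  expect_equal(nrow(e3), 20L)
  expect_error(embed_2d(matrix(rnorm(4), 2, 2)), "at least 3")
})
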