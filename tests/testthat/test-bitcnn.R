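test_that("configuration invariants are enforced", {
  expect_error(bitcnn_config(one_by_one = c(4, 6, 12, 18, 24, 30)),
               "divisible by 3")
  expect_error(bitcnn_config(K = 4), "odd")
  expect_error(bitcnn_config(spatial_attention_kernel = 2), "odd")
  expect_error(bitcnn_config(lb_filters = c(0, 64, 128)), "positive")
})

test_that("default network matches the published parameter audit", {
  m <- bitcnn(bitcnn_config(), seed = 1)
  pc <- count_parameters(m)
  expect_equal(pc$total, 2015043L)
  expect_equal(pc$trainable, 2011907L)
  expect_equal(pc$non_trainable, 3136L)          # 2 x 1568 BN running stats
  expect_equal(pc$shaped_filters, 1568L)
})

test_that("closed-form parameter counts of individual pieces agree", {
  m <- bitcnn(bitcnn_config(), seed = 1)
  lay <- m$layout
  sz <- setNames(lay$nrow * lay$ncol, lay$name)
  expect_equal(unname(sz["fc_w"] + sz["fc_b"]), 360L * 4L + 4L)  # 1444
  expect_equal(unname(sz["lb1_conv_w"] + sz["lb1_conv_b"]),
               32L * (5L * 1L * 1L + 1L))                        # 192
  # channel bookkeeping: LB outputs 6/12/24 channels, HB 108/144/180
  shp <- bitcnn_shapes(bitcnn_config())
  expect_equal(shp$channels, c(6L, 12L, 24L, 108L, 144L, 180L))
  expect_equal(attr(shp, "embedding_length"), 360L)
  # LB output spatial shape: height untouched, width halved three times
  expect_equal(shp$height[1:3], rep(180L, 3))
  expect_equal(shp$width[1:3], c(120L, 60L, 30L))
})

test_that("shaped convolutions preserve spatial shape and set channels", {
  set.seed(2)
  x <- array(rnorm(10 * 14), dim = c(10, 14, 1))
  w <- matrix(rnorm(5 * 4), 5, 4)
  y <- b_conv(x, w, rep(0, 4), K = 5)
  expect_equal(dim(y), c(10L, 14L, 4L))
  # I-type on an input constant along the row (time) axis stays constant
  # along that axis: the K x 1 kernel only mixes across segments, applied
  # identically at every timestep
  xc <- array(rep(rnorm(10), times = 14), dim = c(10, 14, 1))
  yi <- i_conv(xc, matrix(rnorm(5 * 2), 5, 2), c(0.3, -0.1), K = 5)
  expect_equal(dim(yi), c(10L, 14L, 2L))
  for (c in 1:2) expect_lt(max(apply(yi[, , c], 1, sd)), 1e-12)
  # T-type with zero kernel and bias is identically zero
  yt <- t_conv(x, matrix(0, 25, 3), rep(0, 3), K = 5)
  expect_true(all(yt == 0))
  expect_error(b_conv(x, matrix(rnorm(0), 5, 0), numeric(0)), "positive")
  # B-type convolution against a direct R computation (same padding)
  x1 <- array(rnorm(6 * 9), dim = c(6, 9, 1))
  w1 <- matrix(rnorm(3), 3, 1)
  y1 <- b_conv(x1, w1, 0.7, K = 3)
  ref <- matrix(0.7, 6, 9)
  xp <- cbind(0, x1[, , 1], 0)
  for (j in 1:9)
    ref[, j] <- ref[, j] + xp[, j:(j + 2)] %*% w1
  expect_equal(y1[, , 1], ref, tolerance = 1e-12)
})

test_that("dual pooling arithmetic and max/average branches", {
  set.seed(3)
  x <- array(rnorm(180 * 240 * 3), dim = c(180, 240, 3))
  lo <- dual_pool(x, "low")
  expect_equal(dim(lo), c(180L, 120L, 6L))
  # max branch >= average branch everywhere, equal on constant input
  expect_true(all(lo[, , 1:3] >= lo[, , 4:6]))
  const <- array(2.2, dim = c(8, 8, 2))
  hc <- dual_pool(const, "high")
  expect_equal(hc[, , 1:2], hc[, , 3:4])
  expect_true(all(hc == 2.2))
  # high-level pooling on odd extents uses ceiling
  hi <- dual_pool(array(rnorm(45 * 8 * 24), dim = c(45, 8, 24)), "high")
  expect_equal(dim(hi), c(23L, 4L, 48L))
  # hand-checked 2x2 window
  m <- array(c(1, 3, 2, 4), dim = c(2, 2, 1))
  h <- dual_pool(m, "high")
  expect_equal(as.numeric(h), c(4, 2.5))
  expect_error(dual_pool(array(1, dim = c(4, 1, 1)), "low"), "narrow")
})

test_that("spatial attention bounds, saturation and shape contract", {
  set.seed(4)
  x <- array(rnorm(12 * 9 * 5), dim = c(12, 9, 5))
  w <- matrix(rnorm(18, sd = 0.3), 18, 1)
  sa <- spatial_attention(x, w, k = 3)
  expect_equal(dim(sa$output), dim(x))
  expect_true(all(sa$scores >= 0 & sa$scores <= 1))
  expect_true(all(abs(sa$output) <= abs(x) + 1e-12))
  # zero weights: sigmoid(0) = 0.5 exactly
  sa0 <- spatial_attention(x, matrix(0, 18, 1), k = 3)
  expect_equal(sa0$output, x * 0.5, tolerance = 1e-12)
  expect_true(all(sa0$scores == 0.5))
  # direct oracle: scores from an explicit R loop over the 2-channel stack
  cmean <- apply(x, c(1, 2), mean)
  cmax <- apply(x, c(1, 2), max)
  stacked <- array(c(cmean, cmax), dim = c(12, 9, 2))
  pre <- t_conv(stacked, w, 0, K = 3)
  expect_equal(sa$scores, 1 / (1 + exp(-pre[, , 1])), tolerance = 1e-12)
})

test_that("feature attention produces a 2C-length gated embedding", {
  set.seed(5)
  C <- 90
  x <- array(rnorm(6 * 4 * C), dim = c(6, 4, C))
  h <- 7
  w1 <- matrix(rnorm(2 * C * h, sd = 0.1), 2 * C, h)
  w2 <- matrix(rnorm(h * 2 * C, sd = 0.1), h, 2 * C)
  fa <- feature_attention(x, w1, rnorm(h), w2, rnorm(2 * C))
  expect_length(fa$representation, 180L)
  expect_length(fa$embedding, 180L)
  expect_true(all(fa$scores > 0 & fa$scores < 1))
  # constant map: GAP equals GMP per channel
  xc <- array(rep(rnorm(C), each = 24), dim = c(6, 4, C))
  fac <- feature_attention(xc, w1, rnorm(h), w2, rnorm(2 * C))
  expect_equal(fac$representation[1:C], fac$representation[C + 1:C],
               tolerance = 1e-12)
  # scores forced to one: embedding equals the representation
  fa1 <- feature_attention(x, matrix(0, 2 * C, h), rep(0, h),
                           matrix(0, h, 2 * C), rep(1e3, 2 * C))
  expect_equal(fa1$embedding, fa1$representation, tolerance = 1e-12)
})

test_that("prediction is a deterministic probability simplex", {
  cfg <- tiny_config()
  m <- bitcnn(cfg, seed = 6)
  set.seed(7)
  xs <- lapply(1:4, function(i) matrix(rnorm(12 * 16), 12, 16))
  p <- predict(m, xs)
  expect_equal(dim(p), c(4L, 4L))
  expect_true(all(p >= 0))
  expect_equal(rowSums(p), rep(1, 4), tolerance = 1e-6)
  # identical inputs give identical outputs in evaluation mode
  p2 <- predict(m, list(xs[[1]], xs[[1]]))
  expect_equal(p2[1, ], p2[2, ], tolerance = 1e-12)
  expect_identical(predict(m, xs), p)
  # zeroed final layer: exactly uniform probabilities
  m0 <- m
  lay <- m0$layout; sz <- lay$nrow * lay$ncol; ends <- cumsum(sz)
  for (nm in c("fc_w", "fc_b")) {
    i <- which(lay$name == nm)
    m0$par[(ends[i] - sz[i] + 1):ends[i]] <- 0
  }
  expect_equal(unname(predict(m0, xs[[1]])[1, ]), rep(0.25, 4),
               tolerance = 1e-12)
  expect_error(predict(m, matrix(0, 5, 5)), "shape")
})

test_that("row permutations commute with the low-level B-path blocks", {
  # 1xK kernels never mix rows before block 4, so permuting input rows
  # permutes every LB block output by the same row permutation
  cfg <- tiny_config()
  m <- bitcnn(cfg, seed = 8)
  set.seed(9)
  x <- matrix(rnorm(12 * 16), 12, 16)
  perm <- sample(12)
  f1 <- bitcnn_features(m, x)
  f2 <- bitcnn_features(m, x[perm, ])
  for (b in 1:3)
    expect_equal(f2$blocks[[b]][[1]], f1$blocks[[b]][[1]][perm, , ],
                 tolerance = 1e-12)
})

test_that("back-propagation matches finite differences on a tiny network", {
  cfg <- tiny_config()
  m <- bitcnn(cfg, seed = 3)
  # nudge all parameters off their ties (zero biases give exactly tied
  # channel maxima, where the subgradient and the two-sided numeric
  # derivative legitimately differ)
  set.seed(99)
  m$par <- m$par + rnorm(length(m$par), 0, 0.05)
  lay <- m$layout; sz <- lay$nrow * lay$ncol; ends <- cumsum(sz)
  for (i in grep("_rvar$", lay$name)) m$par[(ends[i] - sz[i] + 1):ends[i]] <- 1
  for (i in grep("_rmean$", lay$name)) m$par[(ends[i] - sz[i] + 1):ends[i]] <- 0
  set.seed(4)
  X <- array(rnorm(12 * 16 * 2), dim = c(12, 16, 2))
  Y <- rbind(c(1, 0, 0, 0), c(0, 0, 1, 0))
  cl <- unclass(cfg)
  res <- bitecg:::cpp_loss_grad(cl, m$par, X, Y, 7)
  set.seed(5)
  idx <- unlist(lapply(which(lay$trainable), function(i) {
    s <- ends[i] - sz[i] + 1
    sample(s:ends[i], min(2L, sz[i]))
  }))
  f <- function(par) bitecg:::cpp_loss_grad(cl, par, X, Y, 7)$loss
  num <- vapply(idx, function(j) {
    e <- 1e-5
    p1 <- m$par; p1[j] <- p1[j] + e
    p2 <- m$par; p2[j] <- p2[j] - e
    (f(p1) - f(p2)) / (2 * e)
  }, numeric(1))
  ana <- res$grad[idx]
  rel <- abs(num - ana) / pmax(1e-6, abs(num) + abs(ana))
  expect_lt(max(rel), 1e-3)
})
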