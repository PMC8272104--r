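test_that("stratified folds preserve class proportions exactly when exact", {
  labels <- data.frame(
    record_id = sprintf("r%03d", 1:400),
    label = rep(ecg_classes(), each = 100))
  folds <- make_folds(labels, k = 5, seed = 11)
  expect_length(folds, 5L)
  all_test <- unlist(lapply(folds, `[[`, "test"))
  expect_setequal(all_test, labels$record_id)    # test folds partition
  expect_equal(anyDuplicated(all_test), 0L)
  for (f in folds) {
    expect_setequal(c(f$test, f$train, f$validation), labels$record_id)
    expect_length(intersect(f$test, c(f$train, f$validation)), 0L)
    expect_length(intersect(f$train, f$validation), 0L)
    tl <- labels$label[labels$record_id %in% f$test]
    expect_equal(unname(table(factor(tl, ecg_classes()))), rep(20L, 4),
                 ignore_attr = TRUE)
  }
})

test_that("folds on CinC-like class sizes match the stated fold makeup", {
  counts <- c(N = 5076L, A = 758L, O = 2415L, P = 279L)
  labels <- data.frame(
    record_id = sprintf("x%04d", seq_len(sum(counts))),
    label = rep(names(counts), counts))
  folds <- make_folds(labels, k = 5, seed = 2)
  for (f in folds) {
    tl <- table(factor(labels$label[labels$record_id %in% f$test],
                       ecg_classes()))
    expect_equal(unname(tl["N"]), 1015, tolerance = 0.002)
    expect_equal(unname(tl["A"]), 151, tolerance = 0.01)
    expect_equal(unname(tl["O"]), 483, tolerance = 0.005)
    expect_equal(unname(tl["P"]), 56, tolerance = 0.02)
    # validation is about 10% of the remaining 80%
    expect_equal(length(f$validation),
                 round(0.1 * (nrow(labels) - length(f$test))), tolerance = 0.01)
  }
  expect_identical(make_folds(labels, 5, seed = 2), folds)  # deterministic
  few <- data.frame(record_id = c("a", "b", "c", "d"),
                    label = c("N", "A", "O", "P"))
  expect_error(make_folds(few, k = 5), "at least k")
})

test_that("resampling hits the plan exactly for over- and undersampling", {
  labels <- data.frame(
    record_id = sprintf("r%03d", 1:70),
    label = rep(c("N", "A", "O", "P"), c(40, 10, 15, 5)))
  plan <- resampling_plan(N = 25, A = 25, O = 15, P = 12)
  out <- resample_training_set(labels, plan, seed = 3)
  tab <- table(labels$label[match(out, labels$record_id)])
  expect_equal(unname(tab[ecg_classes()]), c(25L, 25L, 15L, 12L),
               ignore_attr = TRUE)
  # class of 10 oversampled to 25: each record appears 2 or 3 times
  a_counts <- table(out[out %in% labels$record_id[labels$label == "A"]])
  expect_true(all(a_counts %in% c(2L, 3L)))
  expect_equal(sum(a_counts), 25L)
  # undersampled class: distinct records, subset of the pool
  n_sel <- out[out %in% labels$record_id[labels$label == "N"]]
  expect_equal(anyDuplicated(n_sel), 0L)
  # class already at target is unchanged in content
  o_sel <- out[out %in% labels$record_id[labels$label == "O"]]
  expect_setequal(o_sel, labels$record_id[labels$label == "O"])
  # deterministic under a fixed seed, for any seed the counts hold
  expect_identical(resample_training_set(labels, plan, seed = 3), out)
  for (s in 4:6) {
    out_s <- resample_training_set(labels, plan, seed = s)
    expect_equal(length(out_s), sum(plan))
  }
  expect_error(resample_training_set(labels[labels$label != "P", ], plan),
               "empty")
})

test_that("training loop: improvement, patience rule and history bounds", {
  cfg <- tiny_config()
  m <- bitcnn(cfg, seed = 12)
  set.seed(13)
  mk <- function(n, cl) lapply(seq_len(n), function(i) {
    base <- matrix(rnorm(12 * 16, sd = 0.3), 12, 16)
    if (cl %in% c("A", "O")) base[, 1:8] <- base[, 1:8] + 2.5
    if (cl %in% c("O", "P")) base[5:8, ] <- base[5:8, ] - 2.5
    base
  })
  xs <- c(mk(6, "N"), mk(6, "A"), mk(6, "O"), mk(6, "P"))
  ys <- rep(ecg_classes(), each = 6)
  fit <- train_bitcnn(m, xs, ys, xs[seq(1, 24, 3)], ys[seq(1, 24, 3)],
                      control = train_control(max_epochs = 8, patience = 8,
                                              batch_size = 8, seed = 5))
  expect_true(fit$trained)
  expect_lte(nrow(fit$history), 8L)
  expect_lt(fit$history$train_loss[nrow(fit$history)],
            fit$history$train_loss[1])
  # patience semantics: training either runs to max_epochs or halts exactly
  # `patience` epochs after the best validation loss, restoring the best
  # weights (so re-evaluating the returned model reproduces that best loss)
  m2 <- bitcnn(cfg, seed = 14)
  ctrl <- train_control(learning_rate = 0.05, max_epochs = 12, patience = 2,
                        batch_size = 8, seed = 5)
  fit2 <- train_bitcnn(m2, xs, ys, xs[1:8], ys[1:8], control = ctrl)
  h <- fit2$history
  expect_lte(nrow(h), ctrl$max_epochs)
  best <- which.min(h$val_loss)
  if (nrow(h) < ctrl$max_epochs)
    expect_equal(nrow(h), best + ctrl$patience)
  ev <- bitecg:::.eval_loss(fit2, bitecg:::.as_input_array(xs[1:8], cfg),
                            bitecg:::.one_hot(ys[1:8]))
  expect_equal(ev$loss, min(h$val_loss), tolerance = 1e-10)
  expect_error(train_bitcnn(m, list(), character(), xs[1:2], ys[1:2]),
               "empty")
})

test_that("record-level aggregation averages chunks with class-order ties", {
  expect_equal(aggregate_record_prediction(c(0.1, 0.2, 0.6, 0.1)), "O")
  # two chunks tie N and A at 0.4: class order picks N
  p <- rbind(c(0.6, 0.2, 0.1, 0.1), c(0.2, 0.6, 0.1, 0.1))
  expect_equal(aggregate_record_prediction(p), "N")
  p3 <- rbind(c(0.2, 0.2, 0.5, 0.1), c(0.1, 0.3, 0.5, 0.1),
              c(0.3, 0.1, 0.5, 0.1))
  expect_equal(aggregate_record_prediction(p3), "O")
  expect_error(aggregate_record_prediction(matrix(0, 0, 4)), "no chunk")
})
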