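test_that("segment windows cover 480 source samples decimated to 240", {
  cfg <- ecm_config()
  expect_equal(cfg$width, 240L)
  expect_equal(cfg$fiducial_col, 60L)
  # impulse at index 3000: window [2880, 3360), fiducial at column 60 (0-based)
  rec <- impulse_recording(9000, peaks = c(3000L))
  segs <- extract_segments(rec, rpeak_list(3000L, 300), cfg)
  expect_length(segs, 1L)
  expect_length(segs[[1]]$values, 240L)
  expect_equal(which.max(segs[[1]]$values) - 1L, 60L)
  # nothing outside the window leaks in: an impulse at 2879 (one sample
  # before the window) contributes nothing beyond filter edge effects
  rec2 <- impulse_recording(9000, peaks = c(3000L, 2879L))
  segs2 <- extract_segments(rec2, rpeak_list(3000L, 300), cfg)
  expect_equal(which.max(segs2[[1]]$values) - 1L, 60L)
})

test_that("boundary peaks are dropped, not padded", {
  cfg <- ecm_config()
  # peak at 50: window would start at -70
  rec <- impulse_recording(9000, peaks = c(50L, 3000L))
  segs <- extract_segments(rec, rpeak_list(c(50L, 3000L), 300), cfg)
  expect_length(segs, 1L)
  # peak too close to the end (window end exceeds the signal)
  segs <- extract_segments(rec, rpeak_list(c(3000L, 8800L), 300), cfg)
  expect_length(segs, 1L)
  expect_length(extract_segments(rec, rpeak_list(integer(), 300), cfg), 0L)
  expect_error(extract_segments(ecg_recording(rnorm(100), 150), rpeak_list(10L, 150),
                                cfg), "source_fs")
})

test_that("interior impulse beats all peak at the fiducial column", {
  cfg <- ecm_config()
  peaks <- as.integer(seq(300, 8600, by = 240))   # 0.8 s spacing at 300 Hz
  rec <- impulse_recording(9000, peaks = peaks)
  segs <- extract_segments(rec, rpeak_list(peaks, 300), cfg)
  expect_length(segs, length(peaks))
  expect_true(all(vapply(segs, function(s) which.max(s$values), 0L) == 61L))
})

test_that("wrap padding fills 180 rows by repeating the segment series", {
  cfg <- ecm_config()
  mk_segs <- function(k) lapply(seq_len(k), function(i)
    list(values = rep(i, cfg$width), fiducial_col = 60L))
  # 37 segments: row r equals segment r mod 37
  e <- size_adapt(mk_segs(37), cfg, record_id = "w")
  expect_equal(dim(e$matrix), c(180L, 240L))
  expect_equal(e$n_source_segments, 37L)
  for (r in c(0L, 36L, 37L, 100L, 179L))
    expect_equal(e$matrix[r + 1L, 1L], (r %% 37L) + 1)
  # exactly 180 segments: rows are the segments verbatim
  e180 <- size_adapt(mk_segs(180), cfg)
  expect_equal(e180$matrix[, 1], as.numeric(1:180))
  # single segment: every row identical
  e1 <- size_adapt(mk_segs(1), cfg)
  expect_true(all(e1$matrix == 1))
  # wrap conservation: the set of distinct rows equals the source segments
  expect_equal(sort(unique(e$matrix[, 1])), as.numeric(1:37))
  expect_error(size_adapt(list(), cfg), "no segments")
  expect_error(size_adapt(mk_segs(181), cfg), "chunk")
})

test_that("long recordings split into equal chunks of at most 60 s", {
  cfg <- ecm_config()
  r30 <- ecg_recording(rnorm(30 * 300), 300, "r30")
  expect_length(chunk_long_recording(r30, cfg), 1L)
  r150 <- ecg_recording(rnorm(150 * 300), 300, "r150", label = "O")
  ch <- chunk_long_recording(r150, cfg)
  expect_length(ch, 3L)
  expect_true(all(vapply(ch, function(x) length(x$samples), 0L) == 50L * 300L))
  expect_equal(vapply(ch, function(x) x$chunk_index, 0L), 0:2)
  expect_true(all(vapply(ch, function(x) x$label, "") == "O"))
  r61 <- ecg_recording(rnorm(61 * 300), 300, "r61")
  ch61 <- chunk_long_recording(r61, cfg)
  expect_length(ch61, 2L)
  expect_equal(vapply(ch61, function(x) length(x$samples), 0L),
               c(9150L, 9150L))                      # 30.5 s each
  # chunks tile the original signal exactly
  expect_equal(unlist(lapply(ch, function(x) x$samples)), r150$samples)
})

test_that("build_csecms produces 180x240 for any duration in 9-61 s", {
  for (d in c(9, 20, 37.5, 61)) {
    g <- generate_recording("N", d, seed = round(100 + d))
    ecms <- suppressWarnings(build_csecms(g$recording))
    for (e in ecms) expect_equal(dim(e$matrix), c(180L, 240L))
  }
  # a 150 s recording gives three chunks sharing the record id
  g <- generate_recording("N", 50, seed = 7)
  long <- ecg_recording(rep(g$recording$samples, 3), 300, "L1", label = "N")
  ecms <- build_csecms(long)
  expect_length(ecms, 3L)
  expect_equal(vapply(ecms, function(e) e$chunk_index, 0L), 0:2)
  expect_true(all(vapply(ecms, function(e) e$record_id, "") == "L1"))
  suppressWarnings(
    expect_error(build_csecms(ecg_recording(numeric(9000), 300, "flat")),
                 "no usable beats"))
})

test_that("decimation halves segment length exactly and preserves peaks", {
  taps <- bitecg:::.decim_taps(2)
  x <- numeric(480); x[121] <- 1                  # 0-based offset 120
  y <- bitecg:::.decimate_vec(x, 2, taps)
  expect_length(y, 240L)
  expect_equal(which.max(y) - 1L, 60L)
  # a constant signal stays constant (the FIR has unit DC gain to ~2e-4)
  expect_equal(bitecg:::.decimate_vec(rep(2.5, 480), 2, taps),
               rep(2.5, 240), tolerance = 1e-3)
})
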