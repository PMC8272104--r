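#' CS-ECM construction settings
#'
#' Geometry of the consistent-sized electrocardiomatrix: each detected
#' R-peak anchors a 1.6 s segment (0.4 s before to 1.2 s after the
#' fiducial), sampled at 300 Hz (480 samples) and decimated to 150 Hz
#' (240 columns); 180 segment rows form one matrix; recordings longer than
#' 60 s are chunked first.
#'
#' @param pre_s seconds before the fiducial point.
#' @param post_s seconds after the fiducial point.
#' @param source_fs source sampling rate in Hz.
#' @param target_fs rate after decimation; must divide `source_fs`.
#' @param height matrix rows (the maximum segment count a recording may
#'   contribute).
#' @param chunk_threshold_s recordings longer than this are chunked.
#' @param normalize amplitude normalization applied per chunk before
#'   segment extraction: `"robust"` (subtract median, divide by IQR) or
#'   `"none"`.
#' @return A list of class `ecm_config`; `width` is derived as
#'   `round((pre_s + post_s) * target_fs)` (240 under defaults) and
#'   `fiducial_col` as `pre_s * target_fs` (0-based column 60).
#' @export
ecm_config <- function(pre_s = 0.4, post_s = 1.2, source_fs = 300,
                       target_fs = 150, height = 180,
                       chunk_threshold_s = 60, normalize = c("robust", "none")) {
  normalize <- match.arg(normalize)
  stopifnot(pre_s >= 0, post_s > 0, source_fs > 0, target_fs > 0, height >= 1)
  if (source_fs %% target_fs != 0)
    stop("`target_fs` must divide `source_fs`")
  structure(list(
    pre_s = pre_s, post_s = post_s, source_fs = source_fs,
    target_fs = target_fs, height = as.integer(height),
    width = as.integer(round((pre_s + post_s) * target_fs)),
    fiducial_col = as.integer(round(pre_s * target_fs)),
    chunk_threshold_s = chunk_threshold_s, normalize = normalize
  ), class = "ecm_config")
}

# symmetric FIR low-pass taps for decimation by q (zero-phase by symmetry)
.decim_taps <- function(q, order = 30L) {
  as.numeric(signal::fir1(order, 1 / q))
}

# anti-alias filter then keep every q-th sample (edge-replicated padding)
.decimate_vec <- function(x, q, taps) {
  if (q == 1) return(x)
  h <- (length(taps) - 1L) %/% 2L
  xp <- c(rep(x[1], h), x, rep(x[length(x)], h))
  y <- stats::filter(xp, taps, sides = 2)
  y <- as.numeric(y[(h + 1L):(h + length(x))])
  y[seq(1L, length(x), by = q)]
}

#' Extract beat-anchored segments from a recording
#'
#' The i-th segment spans `[peak - pre_s * fs, peak + post_s * fs)` at the
#' source rate (480 samples under defaults) and is decimated to the target
#' rate (240 columns).  Peaks whose raw window crosses either signal
#' boundary are dropped, so every emitted row is genuine signal.
#'
#' @param rec an [ecg_recording()] at `cfg$source_fs`.
#' @param peaks an `rpeak_list` for `rec`.
#' @param cfg an [ecm_config()].
#' @return A list of segments, each a list with `values` (length
#'   `cfg$width`) and `fiducial_col`; empty if no peak is retainable.
#' @export
extract_segments <- function(rec, peaks, cfg = ecm_config()) {
  stopifnot(inherits(rec, "ecg_recording"), inherits(peaks, "rpeak_list"))
  if (rec$fs != cfg$source_fs)
    stop("recording rate ", rec$fs, " does not match config source_fs ",
         cfg$source_fs)
  if (peaks$fs != rec$fs) stop("peak list rate does not match recording")
  q <- cfg$source_fs %/% cfg$target_fs
  pre <- round(cfg$pre_s * cfg$source_fs)
  post <- round(cfg$post_s * cfg$source_fs)
  n <- length(rec$samples)
  taps <- .decim_taps(q)
  out <- list()
  for (p in peaks$indices) {              # p is 0-based
    start <- p - pre
    end <- p + post                       # exclusive
    if (start < 0 || end > n) next
    raw <- rec$samples[(start + 1L):end]
    vals <- .decimate_vec(raw, q, taps)
    stopifnot(length(vals) == cfg$width)
    out[[length(out) + 1L]] <-
      list(values = vals, fiducial_col = cfg$fiducial_col)
  }
  out
}

#' Wrap-pad segments into one fixed-size CS-ECM
#'
#' Row *r* (0-based) of the matrix is segment *r* mod *n_segments*, repeating
#' the segment series until all `cfg$height` rows are filled.  With exactly
#' `height` segments the rows are the segments verbatim.
#'
#' @param segments list of segments from [extract_segments()]
#'   (1 to `cfg$height` of them).
#' @param cfg an [ecm_config()].
#' @param record_id,chunk_index,label provenance carried on the result.
#' @return An object of class `csecm`: list with `matrix`
#'   (`height x width`), `record_id`, `chunk_index`, `n_source_segments`,
#'   `label`.
#' @export
size_adapt <- function(segments, cfg = ecm_config(), record_id = "rec",
                       chunk_index = 0L, label = NULL) {
  k <- length(segments)
  if (k == 0) stop("no segments")
  if (k > cfg$height)
    stop("more segments (", k, ") than rows (", cfg$height,
         "); chunk the recording first")
  m <- matrix(0, cfg$height, cfg$width)
  for (r in seq_len(cfg$height))
    m[r, ] <- segments[[((r - 1L) %% k) + 1L]]$values
  structure(list(matrix = m, record_id = record_id,
                 chunk_index = as.integer(chunk_index),
                 n_source_segments = k, label = label),
            class = "csecm")
}

#' @export
print.csecm <- function(x, ...) {
  cat(sprintf(
    "CS-ECM %dx%d from '%s' (chunk %d, %d source segment%s%s)\n",
    nrow(x$matrix), ncol(x$matrix), x$record_id, x$chunk_index,
    x$n_source_segments, if (x$n_source_segments == 1) "" else "s",
    if (is.null(x$label)) "" else paste0(", label ", x$label)))
  invisible(x)
}

#' Split a long recording into chunks of at most the threshold length
#'
#' Recordings no longer than `cfg$chunk_threshold_s` are returned as a
#' singleton.  Longer recordings are cut into
#' `ceiling(duration / threshold)` contiguous, non-overlapping chunks of
#' equal length (within one sample), which avoids degenerate short tails.
#'
#' @param rec an [ecg_recording()].
#' @param cfg an [ecm_config()].
#' @return List of [ecg_recording()]s, each with a `chunk_index` field
#'   (0-based) and the parent's `record_id` and `label`.
#' @export
chunk_long_recording <- function(rec, cfg = ecm_config()) {
  stopifnot(inherits(rec, "ecg_recording"))
  n <- length(rec$samples)
  thr <- cfg$chunk_threshold_s * rec$fs
  if (n <= thr) {
    rec$chunk_index <- 0L
    return(list(rec))
  }
  k <- ceiling(n / thr)
  bounds <- round(seq(0, n, length.out = k + 1))
  lapply(seq_len(k), function(i) {
    chunk <- ecg_recording(rec$samples[(bounds[i] + 1L):bounds[i + 1L]],
                           fs = rec$fs, record_id = rec$record_id,
                           label = rec$label)
    chunk$chunk_index <- i - 1L
    chunk
  })
}

#' Build all CS-ECMs for one recording
#'
#' Composition of the pipeline: chunk the recording, and per chunk
#' normalize amplitude, detect R-peaks, extract beat-anchored segments and
#' wrap-pad them into a fixed-size matrix.  Chunks without a retainable
#' beat are skipped with a warning; if a chunk yields more segments than
#' rows, the first `cfg$height` are kept with a warning.
#'
#' @param rec an [ecg_recording()] at `cfg$source_fs`.
#' @param cfg an [ecm_config()].
#' @param peaks optional `rpeak_list` for the *whole* recording (e.g.
#'   external annotations); by default peaks are detected per chunk with
#'   [detect_r_peaks()].
#' @return List of `csecm` objects in chunk order.
#' @export
build_csecms <- function(rec, cfg = ecm_config(), peaks = NULL) {
  chunks <- chunk_long_recording(rec, cfg)
  offset <- 0L
  out <- list()
  for (ch in chunks) {
    x <- ch$samples
    if (cfg$normalize == "robust") {
      med <- stats::median(x)
      iqr <- stats::IQR(x)
      scale <- if (iqr > 0) iqr else if (stats::sd(x) > 0) stats::sd(x) else 1
      ch$samples <- (x - med) / scale
    }
    pk <- if (is.null(peaks)) {
      detect_r_peaks(ch)
    } else {
      idx <- peaks$indices[peaks$indices >= offset &
                           peaks$indices < offset + length(x)] - offset
      rpeak_list(idx, fs = ch$fs)
    }
    segs <- extract_segments(ch, pk, cfg)
    if (length(segs) == 0) {
      warning("chunk ", ch$chunk_index, " of '", rec$record_id,
              "' has no usable beats; skipped")
    } else {
      if (length(segs) > cfg$height) {
        warning("chunk ", ch$chunk_index, " of '", rec$record_id, "' has ",
                length(segs), " segments; keeping the first ", cfg$height)
        segs <- segs[seq_len(cfg$height)]
      }
      out[[length(out) + 1L]] <-
        size_adapt(segs, cfg, record_id = rec$record_id,
                   chunk_index = ch$chunk_index, label = rec$label)
    }
    offset <- offset + length(x)
  }
  if (!length(out)) stop("no usable beats in recording '", rec$record_id, "'")
  out
}
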