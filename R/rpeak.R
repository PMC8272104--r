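#' Detect R-peaks in a single-lead ECG recording
#'
#' A Pan-Tompkins style detector: zero-phase Butterworth band-pass
#' (5-15 Hz), differentiation, squaring, centred moving-window integration
#' over 150 ms, adaptive dual-threshold peak picking with search-back, and
#' refinement of each detection to the extremum of largest absolute
#' band-passed amplitude within +/- 50 ms (so inverted QRS complexes still
#' anchor on the R wave).  The output is deterministic, invariant to adding
#' a constant offset and to positive amplitude rescaling, and enforces a
#' 0.2 s refractory gap between reported peaks.
#'
#' @param rec an [ecg_recording()] of at least 2 s.
#' @param refine logical; refine detections to the local band-passed
#'   extremum (default `TRUE`).
#' @return An object of class `rpeak_list`: list with `indices` (0-based,
#'   strictly increasing sample positions) and `fs`.  A zero-variance
#'   signal yields an empty peak list.
#' @export
detect_r_peaks <- function(rec, refine = TRUE) {
  stopifnot(inherits(rec, "ecg_recording"))
  fs <- rec$fs
  x <- rec$samples
  if (length(x) < 2 * fs) stop("signal shorter than 2 s")
  if (stats::sd(x) == 0)
    return(structure(list(indices = integer(), fs = fs), class = "rpeak_list"))

  ## band-pass 5-15 Hz, zero phase
  bf <- signal::butter(3, c(5, 15) / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bf, x - mean(x))

  ## derivative, square, centred moving-window integral (150 ms)
  d <- c(0, diff(xf))
  sq <- d^2
  win <- max(3L, as.integer(round(0.15 * fs)))
  mwi <- stats::filter(sq, rep(1 / win, win), sides = 2)
  mwi[is.na(mwi)] <- 0
  mwi <- as.numeric(mwi)
  if (max(mwi) <= 0)
    return(structure(list(indices = integer(), fs = fs), class = "rpeak_list"))

  ## candidate local maxima with 0.2 s refractory merge
  n <- length(mwi)
  is_max <- c(FALSE, mwi[2:(n - 1)] > mwi[1:(n - 2)] &
                     mwi[2:(n - 1)] >= mwi[3:n], FALSE)
  cand <- which(is_max & mwi > 1e-12 * max(mwi))
  refr <- round(0.2 * fs)
  cand <- .merge_close(cand, mwi[cand], refr)
  if (!length(cand))
    return(structure(list(indices = integer(), fs = fs), class = "rpeak_list"))

  ## adaptive dual threshold with search-back
  init <- mwi[seq_len(min(n, 2 * fs))]
  spki <- max(init); npki <- mean(init) / 2
  thr1 <- npki + 0.25 * (spki - npki)
  accepted <- integer(); rr_hist <- numeric()
  last_q <- -Inf
  for (i in seq_along(cand)) {
    p <- cand[i]; v <- mwi[p]
    if (v > thr1) {
      accepted <- c(accepted, p)
      if (is.finite(last_q)) rr_hist <- c(rr_hist, p - last_q)
      last_q <- p
      spki <- 0.125 * v + 0.875 * spki
    } else {
      npki <- 0.125 * v + 0.875 * npki
      ## search-back: missed beat if the gap exceeds 1.66 x mean RR
      rrm <- if (length(rr_hist)) mean(utils::tail(rr_hist, 8)) else NA
      if (!is.na(rrm) && is.finite(last_q) && (p - last_q) > 1.66 * rrm &&
          v > thr1 / 2) {
        accepted <- c(accepted, p)
        rr_hist <- c(rr_hist, p - last_q)
        last_q <- p
        spki <- 0.25 * v + 0.75 * spki
      }
    }
    thr1 <- npki + 0.25 * (spki - npki)
  }
  if (!length(accepted))
    return(structure(list(indices = integer(), fs = fs), class = "rpeak_list"))

  ## refine to extremum of largest |band-passed| amplitude within +/- 50 ms
  if (refine) {
    half <- as.integer(round(0.05 * fs)) + win %/% 2L
    accepted <- vapply(accepted, function(p) {
      lo <- max(1L, as.integer(p) - half)
      hi <- min(length(xf), as.integer(p) + half)
      lo + which.max(abs(xf[lo:hi])) - 1L
    }, integer(1))
  }
  accepted <- sort(unique(accepted))
  accepted <- .merge_close(accepted, abs(xf[accepted]), refr)
  structure(list(indices = as.integer(accepted - 1L), fs = fs),
            class = "rpeak_list")
}

# keep only peaks separated by >= gap samples, preferring larger scores
.merge_close <- function(pos, score, gap) {
  if (length(pos) <= 1) return(pos)
  keep <- rep(TRUE, length(pos))
  i <- 1L
  while (i < length(pos)) {
    j <- i + 1L
    while (j <= length(pos) && !keep[j]) j <- j + 1L
    if (j > length(pos)) break
    if (pos[j] - pos[i] < gap) {
      if (score[j] > score[i]) { keep[i] <- FALSE; i <- j }
      else keep[j] <- FALSE
    } else i <- j
  }
  pos[keep]
}

#' @export
print.rpeak_list <- function(x, ...) {
  cat(sprintf("R-peak list: %d peaks @ %g Hz\n", length(x$indices), x$fs))
  invisible(x)
}

#' Construct an R-peak list from known indices
#'
#' Lets callers substitute external annotations for the built-in detector.
#'
#' @param indices 0-based, strictly increasing sample indices.
#' @param fs sampling rate the indices refer to.
#' @return An `rpeak_list`.
#' @export
rpeak_list <- function(indices, fs) {
  indices <- as.integer(indices)
  if (is.unsorted(indices, strictly = TRUE))
    stop("`indices` must be strictly increasing")
  structure(list(indices = indices, fs = fs), class = "rpeak_list")
}

#' Write peak indices as a plain-text sidecar (one index per line)
#' @param peaks an `rpeak_list`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rpeaks <- function(peaks, path) {
  writeLines(as.character(peaks$indices), path)
  invisible(path)
}
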