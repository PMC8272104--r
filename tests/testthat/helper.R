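# shared fixtures and small oracles, all built in code

# impulse-train recording: unit spikes at given 0-based indices
impulse_recording <- function(n, peaks, fs = 300, record_id = "imp") {
  x <- numeric(n)
  x[peaks + 1L] <- 1
  ecg_recording(x, fs = fs, record_id = record_id)
}

# tiny network configuration used by gradient / layer tests
tiny_config <- function(...) {
  bitcnn_config(K = 3, lb_filters = c(2, 3, 2), hb_filters = c(2, 2, 3),
                one_by_one = c(3, 3, 3, 3, 3, 3),
                spatial_attention_kernel = 3, fa_hidden = 5,
                height = 12, width = 16, dropout_rate = 0, ...)
}

# fraction of truth fiducials matched by a detection within +/- tol samples
fiducial_recall <- function(truth, detected, tol = 10) {
  if (!length(truth)) return(NA_real_)
  mean(vapply(truth, function(f) any(abs(detected - f) <= tol), logical(1)))
}

# mean silhouette coefficient (euclidean), small-n oracle
mean_silhouette <- function(xy, labels) {
  d <- as.matrix(stats::dist(xy))
  n <- nrow(xy)
  s <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(d[i, labels == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

# Table of printed per-class scores for the published confusion matrix
published_confusion <- function() {
  as_confusion_matrix(rbind(
    c(4611, 23, 354, 88),
    c(29, 610, 97, 22),
    c(524, 103, 1712, 76),
    c(37, 11, 21, 210)
  ))
}
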