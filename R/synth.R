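#' Synthetic ECG generator settings
#'
#' Parameters of the four-class synthetic single-lead ECG model.  Each beat
#' is a sum of Gaussian bumps (P, Q, R, S, T) placed at rhythm-driven
#' fiducial times; classes differ in rhythm statistics, P-wave amplitude,
#' ectopic beats and noise:
#'
#' * `N` (normal): mean R-R interval 0.8 s with slow sinusoidal heart-rate
#'   variability, full P-QRS-T morphology, mild noise.
#' * `A` (atrial fibrillation): P amplitude exactly 0, per-beat R-R drawn
#'   independently from a Gamma distribution with coefficient of variation
#'   `af_rr_cov` (>= 0.15), plus a low-amplitude 4-9 Hz fibrillatory
#'   baseline oscillation.
#' * `O` (other arrhythmia): normal backbone interrupted by ectopic beats
#'   (premature, widened and inverted QRS, compensatory pause).
#' * `P` (noisy): beats remain placed, but broadband noise is overlaid at a
#'   signal-to-noise ratio `noisy_snr_db` (<= 0 dB), so the ground truth
#'   stays meaningful.
#'
#' @param fs sampling rate in Hz.
#' @param duration_mean,duration_sd mean and sd (s) of the duration sampler,
#'   truncated to `duration_range`.
#' @param duration_range allowed duration range in seconds.
#' @param mean_rr mean R-R interval (s) of the normal rhythm.
#' @param hrv_amp,hrv_freq amplitude (s) and frequency (Hz) of the sinusoidal
#'   heart-rate-variability modulation of the normal rhythm.
#' @param rr_jitter_sd per-beat Gaussian R-R jitter (s) for the normal rhythm.
#' @param af_mean_rr mean R-R interval (s) for atrial fibrillation.
#' @param af_rr_cov coefficient of variation of the AF R-R distribution.
#' @param f_wave_amp amplitude of the AF fibrillatory baseline oscillation.
#' @param ectopic_prob per-beat ectopic probability in the other class.
#' @param noisy_snr_db signal-to-noise ratio (dB) of the noisy class.
#' @param base_noise_sd background white-noise sd for non-noisy classes.
#' @param wander_amp amplitude of the slow (0.25 Hz) baseline wander.
#' @param p_amp,t_amp P- and T-wave amplitudes for classes that have them.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(fs = 300, duration_mean = 30, duration_sd = 10,
                       duration_range = c(9, 61), mean_rr = 0.8,
                       hrv_amp = 0.05, hrv_freq = 0.1, rr_jitter_sd = 0.01,
                       af_mean_rr = 0.7, af_rr_cov = 0.25, f_wave_amp = 0.06,
                       ectopic_prob = 0.15, noisy_snr_db = -3,
                       base_noise_sd = 0.02, wander_amp = 0.05,
                       p_amp = 0.15, t_amp = 0.3) {
  spec <- as.list(environment())
  stopifnot(fs > 0, duration_mean > 0, mean_rr > 0, af_mean_rr > 0,
            af_rr_cov >= 0.15, noisy_snr_db <= 0,
            duration_range[1] < duration_range[2])
  structure(spec, class = "synth_spec")
}

# Gaussian bump helper: amplitude, center (s relative to R), width (s)
.wave_table <- function(spec, ectopic = FALSE) {
  if (ectopic) {
    # premature ventricular morphology: wide inverted QRS, no P wave
    rbind(
      c(0,      -0.170, 0.025),                 # no P
      c(-0.80,   0.000, 0.040),                 # wide inverted R
      c(0.35,    0.090, 0.050),                 # discordant T
      c(0.10,   -0.060, 0.030)
    )
  } else {
    rbind(
      c(spec$p_amp, -0.170, 0.025),             # P
      c(-0.10,      -0.035, 0.010),             # Q
      c(1.00,        0.000, 0.012),             # R
      c(-0.15,       0.035, 0.010),             # S
      c(spec$t_amp,  0.250, 0.060)              # T
    )
  }
}

# derive a per-record seed from a master seed (kept well below 2^31)
.derive_seed <- function(master, index) {
  as.integer((as.numeric(master) * 48271 + as.numeric(index) * 16807) %%
               2147483587)
}

#' Generate one labeled synthetic ECG recording
#'
#' Deterministic for identical arguments and seed.  Returns both the signal
#' and the generator's ground truth (beat fiducial sample indices, per-beat
#' type and the R-R series), which the detector and classifier tests use as
#' their oracle.
#'
#' @param class_code one of N, A, O, P.
#' @param duration_s duration in seconds, within `spec$duration_range`.
#' @param seed integer seed.
#' @param spec a [synth_spec()].
#' @return A list with `recording` (an [ecg_recording()]) and `truth`
#'   (list with `fiducials` (0-based sample indices), `beat_type`,
#'   `rr` (s), `class`).
#' @export
generate_recording <- function(class_code, duration_s, seed = 1L,
                               spec = synth_spec()) {
  if (!class_code %in% ecg_classes()) stop("invalid class code: ", class_code)
  if (duration_s < spec$duration_range[1] || duration_s > spec$duration_range[2])
    stop("duration out of range [", spec$duration_range[1], ", ",
         spec$duration_range[2], "] s")
  old <- .Random.seed_exists()
  set.seed(seed)
  fs <- spec$fs
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs

  ## rhythm: beat onset times
  beat_t <- c(); rr <- c(); beat_type <- c()
  cur <- stats::runif(1, 0.3, 0.5)
  rhythm_af <- class_code == "A"
  phase <- stats::runif(1, 0, 2 * pi)
  pending_pause <- FALSE
  while (cur < duration_s - 0.05) {
    beat_t <- c(beat_t, cur)
    if (rhythm_af) {
      shape <- 1 / spec$af_rr_cov^2
      step <- stats::rgamma(1, shape = shape, rate = shape / spec$af_mean_rr)
      step <- max(step, 0.25)
      beat_type <- c(beat_type, "normal")
    } else {
      step <- spec$mean_rr +
        spec$hrv_amp * sin(2 * pi * spec$hrv_freq * cur + phase) +
        stats::rnorm(1, 0, spec$rr_jitter_sd)
      type <- "normal"
      if (pending_pause) {
        step <- step * 1.4                     # compensatory pause
        pending_pause <- FALSE
      } else if (class_code == "O" && stats::runif(1) < spec$ectopic_prob) {
        step <- step * 0.6                     # premature ectopic next
        pending_pause <- TRUE
        type <- "ectopic_next"
      }
      beat_type <- c(beat_type, type)
      step <- max(step, 0.3)
    }
    rr <- c(rr, step)
    cur <- cur + step
  }
  ## mark the premature beat itself (the one after an "ectopic_next" step)
  types <- rep("normal", length(beat_t))
  idx_ect <- which(beat_type == "ectopic_next") + 1L
  idx_ect <- idx_ect[idx_ect <= length(types)]
  types[idx_ect] <- "ectopic"

  ## morphology: sum of Gaussian bumps
  x <- numeric(n)
  for (i in seq_along(beat_t)) {
    tab <- .wave_table(spec, ectopic = types[i] == "ectopic")
    if (class_code == "A") tab <- tab[tab[, 2] != -0.170, , drop = FALSE]
    for (k in seq_len(nrow(tab))) {
      amp <- tab[k, 1]; mu <- beat_t[i] + tab[k, 2]; sd <- tab[k, 3]
      if (amp == 0) next
      lo <- max(1L, floor((mu - 5 * sd) * fs)); hi <- min(n, ceiling((mu + 5 * sd) * fs))
      if (lo > hi) next
      seg <- lo:hi
      x[seg] <- x[seg] + amp * exp(-0.5 * ((t[seg] - mu) / sd)^2)
    }
  }

  ## class noise
  if (class_code == "A") {
    fr <- stats::runif(3, 4, 9)
    ph <- stats::runif(3, 0, 2 * pi)
    fwave <- rowSums(sapply(seq_len(3), function(j)
      sin(2 * pi * fr[j] * t + ph[j])))
    x <- x + spec$f_wave_amp * fwave / 3
  }
  x <- x + spec$wander_amp *
    sin(2 * pi * 0.25 * t + stats::runif(1, 0, 2 * pi))        # baseline wander
  x <- x + stats::rnorm(n, 0, spec$base_noise_sd)
  if (class_code == "P") {
    sig_rms <- sqrt(mean(x^2))
    noise_sd <- sig_rms * 10^(-spec$noisy_snr_db / 20)
    x <- x + stats::rnorm(n, 0, noise_sd)
  }
  .Random.seed_restore(old)

  fid <- round(beat_t * fs)                     # 0-based sample indices
  keep <- fid >= 0 & fid < n
  list(
    recording = ecg_recording(x, fs = fs, record_id = sprintf("S%05d", seed %% 100000L),
                              label = class_code),
    truth = list(fiducials = fid[keep], beat_type = types[keep],
                 rr = rr, class = class_code)
  )
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate a labeled synthetic dataset
#'
#' `n_per_class` recordings per class, with per-record seeds derived from a
#' single master seed and durations drawn from the truncated normal
#' duration sampler in `spec`.
#'
#' @param n_per_class recordings per class (>= 1).
#' @param seed master seed.
#' @param spec a [synth_spec()].
#' @param classes class codes to generate (default all four).
#' @return A list with `recordings` (list of [ecg_recording()]),
#'   `truths` (parallel list of ground truths), and `reference`
#'   (data frame record_id/label).
#' @export
generate_dataset <- function(n_per_class, seed = 1L, spec = synth_spec(),
                             classes = ecg_classes()) {
  stopifnot(n_per_class >= 1)
  recs <- list(); truths <- list()
  idx <- 0L
  set.seed(.derive_seed(seed, 0L))
  for (cl in classes) {
    for (i in seq_len(n_per_class)) {
      idx <- idx + 1L
      rs <- .derive_seed(seed, idx)
      set.seed(rs)
      d <- stats::rnorm(1, spec$duration_mean, spec$duration_sd)
      d <- min(max(d, spec$duration_range[1]), spec$duration_range[2])
      out <- generate_recording(cl, d, seed = rs, spec = spec)
      out$recording$record_id <- sprintf("S%s%04d", cl, i)
      recs[[idx]] <- out$recording
      truths[[idx]] <- out$truth
    }
  }
  ids <- vapply(recs, function(r) r$record_id, "")
  labs <- vapply(recs, function(r) r$label, "")
  list(recordings = recs, truths = truths,
       reference = data.frame(record_id = ids, label = labs))
}
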