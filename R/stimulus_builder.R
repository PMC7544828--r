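# Centered moving average with edge padding (cumsum-based).
smooth_moving_avg <- function(x, w) {
  if (w <= 1L) return(x)
  padded <- c(rep(x[1], w), x, rep(x[length(x)], w))
  cs <- cumsum(padded)
  half <- floor(w / 2)
  idx <- seq_along(x) + w
  (cs[idx + half] - cs[idx - (w - half)]) / w
}

# Analytic signal via the FFT construction (positive frequencies doubled,
# negative zeroed); magnitude gives the Hilbert envelope.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Hilbert envelope of a waveform in dB re peak
#'
#' Extracts the analytic-signal magnitude, removes pitch-period ripple with
#' a 10-ms moving average, decimates onto 1-ms frames, and expresses the
#' result in dB relative to its peak, floored at -120 dB so silence stays
#' finite. The 10-ms smoothing window is longer than one glottal period for
#' any F0 above 100 Hz, so the series tracks the syllable-scale amplitude
#' contour that the stationarity criterion is about.
#'
#' @param wave Mono numeric waveform.
#' @param sample_rate Sample rate in Hz.
#' @return Numeric envelope series at 1 kHz frame rate (dB re peak) with
#'   attribute `frame_step` (seconds).
#' @export
envelope_db <- function(wave, sample_rate) {
  if (length(wave) == 0) stop("empty signal")
  env <- smooth_moving_avg(Mod(analytic_signal(wave)),
                           max(1L, round(0.01 * sample_rate)))
  per <- max(1L, round(sample_rate / 1000))
  nf <- floor(length(env) / per)
  frames <- colMeans(matrix(env[seq_len(nf * per)], nrow = per))
  peak <- max(frames)
  db <- if (peak <= 0) rep(-120, nf) else 20 * log10(pmax(frames / peak, 1e-6))
  db <- pmax(db, -120)
  attr(db, "frame_step") <- 0.001
  db
}

#' Voiced window of an envelope
#'
#' The first and last 1-ms frames at or above 10 dB below the envelope peak;
#' everything outside carries too little voicing to build a stimulus from.
#'
#' @param env Envelope in dB re peak from [envelope_db()].
#' @param drop_db Threshold below peak (default 10 dB).
#' @param min_duration Minimum usable window length in seconds.
#' @return List with `start` and `end` frame indices.
#' @export
voiced_window <- function(env, drop_db = 10, min_duration = 0.3) {
  above <- which(env >= max(env) - drop_db)
  if (length(above) == 0) {
    stop2_unusable("no frames within ", drop_db, " dB of the envelope peak")
  }
  start <- above[1]; end <- above[length(above)]
  if ((end - start + 1) * 0.001 < min_duration) {
    stop2_unusable("voiced window shorter than ", min_duration * 1000, " ms")
  }
  list(start = start, end = end)
}

stop2_unusable <- function(...) {
  stop(structure(class = c("unusable_recording", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Search for a pseudo-stationary 300-ms segment
#'
#' Draws random onsets uniformly within the voiced window and accepts the
#' first whose 300-ms envelope-level standard deviation does not exceed
#' 3 dB. After 10 failed draws the recording is declared unusable and the
#' caller should draw a new one.
#'
#' @param env Envelope in dB re peak from [envelope_db()].
#' @param window Segment duration in seconds.
#' @param criterion Maximum envelope-level SD in dB.
#' @param max_iter Maximum number of random onsets tried.
#' @return Onset time in seconds (relative to the start of `env`), or `NA`
#'   on failure; the number of onsets tried is attached as attribute
#'   `iterations`.
#' @export
find_stationary_segment <- function(env, window = 0.3, criterion = 3,
                                    max_iter = 10) {
  vw <- voiced_window(env, min_duration = window)
  wn <- round(window / 0.001)
  last_onset <- vw$end - wn + 1L
  if (last_onset < vw$start) stop2_unusable("voiced window shorter than segment")
  for (i in seq_len(max_iter)) {
    onset <- sample(vw$start:last_onset, 1L)
    if (stats::sd(env[onset:(onset + wn - 1L)]) <= criterion) {
      return(structure((onset - 1L) * 0.001, iterations = i))
    }
  }
  structure(NA_real_, iterations = max_iter)
}

# Resynthesize a segment's harmonic content at a constant F0, keeping its
# temporal (Hilbert) envelope: harmonic weights are sampled from the
# segment's smoothed spectral magnitude.
flatten_f0 <- function(segment, sample_rate, target_f0) {
  n <- length(segment)
  # slow amplitude contour only: the pitch-period ripple of the source must
  # not amplitude-modulate the resynthesized carrier
  env <- smooth_moving_avg(Mod(analytic_signal(segment)),
                           max(1L, round(0.01 * sample_rate)))
  spec <- Mod(stats::fft(segment))[1:floor(n / 2)]
  freq_res <- sample_rate / n
  half_bw <- max(1L, round(50 / freq_res))
  n_harm <- max(1L, floor(min(sample_rate / 2 - 1, 5000) / target_f0))
  weights <- vapply(seq_len(n_harm), function(h) {
    bin <- round(h * target_f0 / freq_res)
    lo <- max(1L, bin - half_bw); hi <- min(length(spec), bin + half_bw)
    mean(spec[lo:hi])
  }, numeric(1))
  weights <- weights / max(weights)
  t_idx <- seq_len(n)
  carrier <- rowSums(vapply(seq_len(n_harm), function(h) {
    weights[h] * sin(2 * pi * h * target_f0 * t_idx / sample_rate)
  }, numeric(n)))
  rms_c <- sqrt(mean(carrier^2))
  if (rms_c > 0) carrier <- carrier / rms_c
  out <- carrier * env
  peak <- max(abs(out))
  if (peak > 0) out / peak else out
}

# Scale a waveform to an RMS level in dB re the digital calibration
# reference (-26 dBFS RMS standing in for 65 dB SPL).
set_level <- function(wave, level_db_re_cal = 0, cal_dbfs = -26) {
  target <- 10^((cal_dbfs + level_db_re_cal) / 20)
  r <- sqrt(mean(wave^2))
  if (r == 0) return(wave)
  wave * target / r
}

#' Build one 3I-2AFC trial triplet
#'
#' Implements the stimulus algorithm of the own-voice pitch JND task: pick a
#' recording at random from the pool, locate a pseudo-stationary 300-ms
#' voiced segment (drawing a new recording when the search fails), gate it
#' with 30-ms cosine ramps, flatten its F0 to a reference roved uniformly
#' between 150 and 200 Hz, and present three intervals — two at the
#' reference F0 and one (the target, in interval 2 or 3 with equal
#' probability) shifted by `delta` semitones — each independently level-roved
#' within +/- 3 dB of the calibration level. The same segment fills all
#' three intervals of a trial.
#'
#' With `audio = FALSE` the acoustic path is bypassed: the triplet carries
#' the roves, target position and F0s only, which is all a simulated
#' observer needs.
#'
#' @param pool List of recordings, each a list with `wave` and
#'   `sample_rate`; ignored when `audio = FALSE`.
#' @param delta Signed pitch difference of the target in semitones, nonzero.
#' @param audio Build waveforms (TRUE) or a symbolic triplet (FALSE).
#' @param ref_range Reference-F0 roving range in Hz.
#' @param level_rove_db Half-width of the per-interval level roving in dB.
#' @return An object of class `trial_triplet`: `reference_f0`, `target_f0`,
#'   `target_interval` (2 or 3), `delta`, `level_roves` (length 3), and with
#'   audio, `segments` (list of 3 waveforms), `sample_rate`, `onset`,
#'   `source`.
#' @export
build_triplet <- function(pool = NULL, delta, audio = !is.null(pool),
                          ref_range = c(150, 200), level_rove_db = 3) {
  if (!is.numeric(delta) || delta == 0) stop("delta must be nonzero (semitones)")
  reference_f0 <- stats::runif(1, ref_range[1], ref_range[2])
  target_f0 <- reference_f0 * 2^(delta / 12)
  target_interval <- sample(2:3, 1)
  level_roves <- stats::runif(3, -level_rove_db, level_rove_db)
  out <- list(
    reference_f0 = reference_f0, target_f0 = target_f0,
    target_interval = target_interval, delta = delta,
    level_roves = level_roves
  )
  if (audio) {
    if (is.null(pool) || length(pool) == 0) stop("empty stimulus pool")
    remaining <- seq_along(pool)
    onset <- NA_real_
    src <- NA_integer_
    while (length(remaining) > 0) {
      k <- if (length(remaining) == 1) remaining else sample(remaining, 1)
      rec <- pool[[k]]
      onset <- tryCatch(
        find_stationary_segment(envelope_db(rec$wave, rec$sample_rate)),
        unusable_recording = function(e) NA_real_
      )
      if (!is.na(onset)) { src <- k; break }
      remaining <- setdiff(remaining, k)
    }
    if (is.na(onset)) stop("stimulus pool exhausted without a stationary segment")
    rec <- pool[[src]]
    i0 <- round(onset * rec$sample_rate) + 1L
    seg <- rec$wave[i0:(i0 + round(0.3 * rec$sample_rate) - 1L)]
    seg <- apply_cosine_gate(seg, rec$sample_rate, ramp = 0.03)
    f0s <- rep(reference_f0, 3)
    f0s[target_interval] <- target_f0
    out$segments <- lapply(seq_len(3), function(i) {
      set_level(flatten_f0(seg, rec$sample_rate, f0s[i]), level_roves[i])
    })
    out$sample_rate <- rec$sample_rate
    out$onset <- onset
    out$source <- src
  }
  structure(out, class = "trial_triplet")
}
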