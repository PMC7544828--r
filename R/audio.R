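# Vowel formant targets (Hz) and bandwidths for the harmonic-complex
# synthesizer. Values are generic adult-speech formants; the synthesizer is
# plumbing to exercise the pitch tracker and stimulus builder, not a vocal
# model.
.vowel_formants <- list(
  a = list(freq = c(800, 1200, 2500), bw = c(90, 110, 160)),
  e = list(freq = c(400, 2200, 2900), bw = c(70, 110, 160)),
  o = list(freq = c(450, 800, 2600), bw = c(70, 90, 160))
)

#' Synthesize a sustained vowel as a harmonic complex
#'
#' Builds a harmonic complex at the requested F0 with a vowel-dependent
#' spectral envelope (three formant resonances over a -6 dB/octave source
#' slope), optional cycle-to-cycle F0 jitter, and smooth 30-ms onset/offset
#' ramps. Peak amplitude is kept below full scale.
#'
#' @param vowel `"a"`, `"e"` or `"o"`.
#' @param f0 Fundamental in Hz (75-600).
#' @param duration Duration in seconds.
#' @param sample_rate Sample rate in Hz.
#' @param jitter Cycle-to-cycle F0 jitter as a percentage of `f0`.
#' @param seed Integer seed for the jitter stream.
#' @return Numeric waveform in `[-1, 1]` with attribute `sample_rate`.
#' @export
synthesize_vowel <- function(vowel = c("a", "e", "o"), f0 = 170,
                             duration = 1.5, sample_rate = 48000,
                             jitter = 0, seed = 1) {
  vowel <- match.arg(vowel)
  if (f0 < 75 || f0 > 600) stop("f0 outside the 75-600 Hz tracker range")
  n <- round(duration * sample_rate)
  t_idx <- seq_len(n)
  fm <- .vowel_formants[[vowel]]
  n_harm <- floor(min(sample_rate / 2 - 1, 5000) / f0)
  harm_f <- f0 * seq_len(n_harm)
  # formant gains over a gently sloping source spectrum
  gain <- (f0 / harm_f)^0.5 * Reduce(`+`, lapply(seq_along(fm$freq), function(k) {
    1 / sqrt(1 + ((harm_f - fm$freq[k]) / fm$bw[k])^2)
  }))

  if (jitter > 0) {
    # instantaneous F0 varies cycle to cycle; realized via cumulative phase
    n_cycles <- ceiling(duration * f0) + 2L
    cyc_f0 <- with_substream(seed, "jitter",
      f0 * (1 + stats::rnorm(n_cycles, 0, jitter / 100)))
    cyc_f0 <- pmax(cyc_f0, 0.5 * f0)
    inst_f0 <- rep(cyc_f0, times = ceiling(sample_rate / cyc_f0))[t_idx]
    phase <- 2 * pi * cumsum(inst_f0) / sample_rate
  } else {
    phase <- 2 * pi * f0 * t_idx / sample_rate
  }
  wave <- rowSums(vapply(seq_len(n_harm),
                         function(h) gain[h] * sin(h * phase),
                         numeric(n)))
  wave <- apply_cosine_gate(wave, sample_rate, ramp = 0.03)
  0.9 * wave / max(abs(wave))
}

#' Raised-cosine onset/offset gating
#'
#' Shapes the existing samples with raised-cosine ramps; the duration of the
#' signal is unchanged.
#'
#' @param wave Numeric waveform.
#' @param sample_rate Sample rate in Hz.
#' @param ramp Ramp duration in seconds (default 30 ms).
#' @return Gated waveform of identical length.
#' @export
apply_cosine_gate <- function(wave, sample_rate, ramp = 0.03) {
  nr <- min(round(ramp * sample_rate), floor(length(wave) / 2))
  if (nr < 1) return(wave)
  g <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
  wave[seq_len(nr)] <- wave[seq_len(nr)] * g
  wave[(length(wave) - nr + 1):length(wave)] <-
    wave[(length(wave) - nr + 1):length(wave)] * rev(g)
  wave
}

#' Autocorrelation pitch tracker
#'
#' Frame-wise (10-ms hop, 40-ms window) normalized-autocorrelation pitch
#' estimation with parabolic interpolation of the peak lag. Frames whose
#' peak autocorrelation falls below the voicing threshold, or whose energy is
#' negligible, are marked unvoiced (`NA`). Restricting `search_low` /
#' `search_high` around a previously identified characteristic pitch is what
#' suppresses octave errors on the second pass.
#'
#' @param wave Numeric waveform.
#' @param sample_rate Sample rate in Hz.
#' @param search_low,search_high F0 search range in Hz.
#' @param frame_step Hop in seconds.
#' @param voicing_threshold Minimum normalized autocorrelation peak.
#' @return Numeric F0 track (Hz, `NA` = unvoiced) with attribute `times`.
#' @export
estimate_f0_autocorr <- function(wave, sample_rate, search_low = 75,
                                 search_high = 600, frame_step = 0.01,
                                 voicing_threshold = 0.5) {
  if (sample_rate < 4 * search_high) {
    stop("sample rate too low for the requested search range")
  }
  win <- round(0.04 * sample_rate)
  hop <- round(frame_step * sample_rate)
  lag_min <- max(2L, floor(sample_rate / search_high))
  lag_max <- ceiling(sample_rate / search_low)
  starts <- seq(1L, max(1L, length(wave) - win + 1L), by = hop)
  peak_amp <- max(abs(wave), 0)
  f0 <- vapply(starts, function(s) {
    fr <- wave[s:(s + win - 1L)]
    fr <- fr - mean(fr)
    if (peak_amp == 0 || sqrt(mean(fr^2)) < 1e-3 * peak_amp) return(NA_real_)
    e0 <- sum(fr^2)
    lags <- lag_min:min(lag_max, win - 1L)
    ac <- vapply(lags, function(l) {
      a <- fr[1:(win - l)]
      b <- fr[(l + 1):win]
      sum(a * b) / sqrt(sum(a^2) * sum(b^2))
    }, numeric(1))
    k <- which.max(ac)
    if (ac[k] < voicing_threshold) return(NA_real_)
    lag <- lags[k]
    # parabolic interpolation around the peak for sub-sample lag accuracy
    if (k > 1 && k < length(ac)) {
      denom <- ac[k - 1] - 2 * ac[k] + ac[k + 1]
      if (abs(denom) > 1e-12) lag <- lag + 0.5 * (ac[k - 1] - ac[k + 1]) / denom
    }
    sample_rate / lag
  }, numeric(1))
  f0[!is.na(f0) & (f0 < search_low | f0 > search_high)] <- NA_real_
  attr(f0, "times") <- (starts - 1L) / sample_rate
  f0
}
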