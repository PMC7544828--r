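#' Longest contiguous voiced stretch of an F0 track
#'
#' @param track Numeric F0 track in Hz with `NA` at unvoiced frames.
#' @return List with `start`, `end` (frame indices) and `n` frames; `n = 0`
#'   for an empty or fully unvoiced track.
#' @export
longest_voiced_run <- function(track) {
  voiced <- !is.na(track)
  if (!any(voiced)) return(list(start = NA_integer_, end = NA_integer_, n = 0L))
  r <- rle(voiced)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- which(r$values)
  best <- k[which.max(r$lengths[k])]
  list(start = starts[best], end = ends[best], n = r$lengths[best])
}

#' Trial inclusion filter
#'
#' A trial is retained only when the stable (voiced) portion of the
#' vocalization lasts at least 400 ms; trials with no production at all are
#' excluded. The stable portion is operationalized as the longest contiguous
#' voiced stretch of the track.
#'
#' @inheritParams longest_voiced_run
#' @param min_duration Minimum voiced duration in seconds.
#' @param frame_step Frame step in seconds.
#' @return Logical flag.
#' @export
inclusion_filter <- function(track, min_duration = 0.4, frame_step = 0.01) {
  longest_voiced_run(track)$n * frame_step >= min_duration
}

#' Early and middle F0 of one vocalization
#'
#' Two summaries per trial: the mean F0 over the first 100 ms of voicing
#' (before any feedback-based correction can act, hence a clean read-out of
#' feedforward control) and the mean over the central 100 ms of the voiced
#' stretch (where compensatory corrections may mix with adaptation). The
#' middle window is centered on the midpoint of the longest voiced stretch.
#'
#' @inheritParams inclusion_filter
#' @param window Window length in seconds.
#' @return List with `early_f0`, `middle_f0` (Hz) and `voiced_duration` (s).
#' @export
extract_segments <- function(track, window = 0.1, frame_step = 0.01) {
  run <- longest_voiced_run(track)
  wn <- round(window / frame_step)
  if (run$n < wn) stop("voiced stretch shorter than the analysis window")
  early_idx <- run$start:(run$start + wn - 1L)
  mid_center <- run$start + (run$n - 1L) / 2
  mid_start <- max(run$start, floor(mid_center - wn / 2) + 1L)
  mid_idx <- mid_start:min(run$end, mid_start + wn - 1L)
  early <- track[early_idx]
  middle <- track[mid_idx]
  if (sum(!is.na(early)) < 5 || sum(!is.na(middle)) < 5) {
    stop("fewer than 5 voiced frames in an analysis window")
  }
  list(
    early_f0 = mean(early, na.rm = TRUE),
    middle_f0 = mean(middle, na.rm = TRUE),
    voiced_duration = run$n * frame_step
  )
}

# Per-trial segment F0 (Hz) for a whole session; NA where the trial is
# excluded or too short.
session_segment_f0 <- function(session, metric = c("early", "middle")) {
  metric <- match.arg(metric)
  vapply(seq_along(session$tracks), function(i) {
    if (!session$trials$included[i]) return(NA_real_)
    seg <- tryCatch(extract_segments(session$tracks[[i]]), error = function(e) NULL)
    if (is.null(seg)) NA_real_ else seg[[paste0(metric, "_f0")]]
  }, numeric(1))
}

#' Characteristic voice pitch from pooled F0 points
#'
#' Pools F0 points over time and trials, histograms them on a log-frequency
#' (cents) axis, and fits a Gaussian to the histogram by least squares. The
#' fitted mean defines the speaker's characteristic voice pitch and a
#' +/- 6 semitone window around it for a restricted second tracking pass
#' (which is what prevents octave errors).
#'
#' @param f0_points Numeric vector of F0 values in Hz (pooled over trials).
#' @param bin_width Histogram bin width in cents.
#' @param search_range First-pass search range in Hz; points outside are
#'   dropped before fitting.
#' @return List with `mean_f0`, `sd_cents`, `window_low`, `window_high`.
#' @export
characteristic_pitch <- function(f0_points, bin_width = 10,
                                 search_range = c(75, 600)) {
  f0_points <- f0_points[!is.na(f0_points) &
                           f0_points >= search_range[1] &
                           f0_points <= search_range[2]]
  if (length(f0_points) < 1000) {
    stop("need at least 1000 pooled F0 points to estimate characteristic pitch")
  }
  cents <- hz_to_cents(f0_points, ref = search_range[1])
  if (diff(range(cents)) < bin_width) {
    # effectively a point mass: the Gaussian fit is degenerate but the
    # characteristic pitch is unambiguous
    mean_f0 <- cents_to_hz(mean(cents), ref = search_range[1])
    return(list(mean_f0 = mean_f0, sd_cents = 0,
                window_low = mean_f0 * 2^(-0.5),
                window_high = mean_f0 * 2^(0.5)))
  }
  breaks <- seq(floor(min(cents) / bin_width) * bin_width - bin_width,
                ceiling(max(cents) / bin_width) * bin_width + bin_width,
                by = bin_width)
  if (length(breaks) < 4) stop("degenerate single-bin F0 histogram")
  h <- graphics::hist(cents, breaks = breaks, plot = FALSE)
  x <- h$mids
  y <- h$counts
  mu0 <- sum(x * y) / sum(y)
  sd0 <- max(bin_width, sqrt(sum(y * (x - mu0)^2) / sum(y)))
  fit <- tryCatch(
    stats::nls(y ~ a * exp(-(x - mu)^2 / (2 * s^2)),
               start = list(a = max(y), mu = mu0, s = sd0),
               control = stats::nls.control(warnOnly = TRUE)),
    error = function(e) NULL
  )
  est <- if (is.null(fit)) {
    c(mu = mu0, s = sd0)
  } else {
    stats::coef(fit)[c("mu", "s")]
  }
  mean_f0 <- cents_to_hz(unname(est["mu"]), ref = search_range[1])
  list(
    mean_f0 = mean_f0,
    sd_cents = abs(unname(est["s"])),
    window_low = mean_f0 * 2^(-0.5),
    window_high = mean_f0 * 2^(0.5)
  )
}

#' Within- and across-trial F0 variability of a session phase
#'
#' Two complementary variability summaries of the baseline vocalizations:
#' the SD of frame-wise F0 within a trial (in cents relative to the trial
#' mean), averaged over trials; and the SD across trials of the per-trial
#' mean F0 (in cents relative to the phase mean).
#'
#' @param session A `pitch_session`.
#' @param phase Phase to summarize (default baseline).
#' @return List with `within_trial_sd` and `across_trial_sd`, both in cents.
#' @export
variability_stats <- function(session, phase = "baseline") {
  idx <- phase_window(phase)
  idx <- idx[session$trials$included[idx]]
  if (length(idx) < 2) stop("need at least 2 included trials")
  per_trial <- lapply(session$tracks[idx], function(tr) {
    v <- tr[!is.na(tr)]
    m <- mean(v)
    list(mean_hz = m, sd_cents = stats::sd(hz_to_cents(v, m)))
  })
  means <- vapply(per_trial, `[[`, numeric(1), "mean_hz")
  grand <- mean(means)
  list(
    within_trial_sd = mean(vapply(per_trial, `[[`, numeric(1), "sd_cents")),
    across_trial_sd = stats::sd(hz_to_cents(means, grand))
  )
}
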