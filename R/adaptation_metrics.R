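#' Adaptation and after-effect summary of a normalized session
#'
#' Window means of the normalized (flipped) F0 series: the whole hold phase
#' and its two halves (trials 91-140 and 141-190), per-vowel hold means, and
#' the after-effect windows at the start of washout (first 30, first 8 and
#' first 5 trials). The session is labelled `"opposing"` when the hold-phase
#' mean is positive under the flip convention, `"following"` when negative;
#' an exactly zero mean is labelled opposing by convention.
#'
#' @param session A `pitch_session`.
#' @param cents Normalized series from [normalize_session()].
#' @return An object of class `adaptation_summary`.
#' @export
summarize_adaptation <- function(session, cents) {
  win_mean <- function(w) {
    idx <- phase_window(w)
    v <- cents[idx][session$trials$included[idx]]
    v <- v[!is.na(v)]
    if (length(v) == 0) stop("window '", w, "' is empty after exclusions")
    mean(v)
  }
  hold_idx <- phase_window("hold")
  per_vowel <- vapply(c("a", "e", "o"), function(vw) {
    idx <- hold_idx[session$trials$vowel[hold_idx] == vw &
                      session$trials$included[hold_idx]]
    mean(cents[idx], na.rm = TRUE)
  }, numeric(1))
  hold_mean <- win_mean("hold")
  structure(
    list(
      hold_mean = hold_mean,
      hold_first_half_mean = win_mean("hold_first_half"),
      hold_second_half_mean = win_mean("hold_second_half"),
      per_vowel_hold_means = per_vowel,
      washout30_mean = win_mean("washout30"),
      washout8_mean = win_mean("washout8"),
      washout5_mean = win_mean("washout5"),
      label = if (hold_mean >= 0) "opposing" else "following",
      metric = attr(cents, "metric")
    ),
    class = "adaptation_summary"
  )
}

#' Frame-wise mean F0 trace over a set of trials
#'
#' Aligns the selected trials at their first voiced frame and averages F0
#' frame by frame over the first `duration` seconds of voicing. With a
#' reference trace (typically the baseline mean trace of the same speaker),
#' the result is expressed in cents relative to that reference.
#'
#' @param session A `pitch_session`.
#' @param trial_set Integer trial indices to average.
#' @param duration Trace duration in seconds (default 500 ms).
#' @param ref_trace Optional reference trace in Hz of the same length.
#' @return Numeric trace (Hz, or cents when `ref_trace` is given) with
#'   attribute `times`.
#' @export
mean_trace <- function(session, trial_set, duration = 0.5, ref_trace = NULL) {
  trial_set <- trial_set[session$trials$included[trial_set]]
  if (length(trial_set) == 0) stop("no eligible trials")
  nf <- round(duration / session$frame_step)
  mat <- vapply(session$tracks[trial_set], function(tr) {
    run <- longest_voiced_run(tr)
    seg <- tr[run$start:min(run$end, run$start + nf - 1L)]
    length(seg) <- nf
    seg
  }, numeric(nf))
  trace <- rowMeans(mat, na.rm = TRUE)
  if (!is.null(ref_trace)) {
    stopifnot(length(ref_trace) == nf)
    trace <- 1200 * log2(trace / ref_trace)
  }
  attr(trace, "times") <- (seq_len(nf) - 1L) * session$frame_step
  trace
}

#' One-sample t statistic against zero
#'
#' `t = mean / (sd / sqrt(n))` with `n - 1` degrees of freedom and a
#' two-sided p value. A zero-variance sample with a nonzero mean yields an
#' infinite t (p = 0); an all-zero sample yields t = 0.
#'
#' @param values Numeric vector, length >= 2.
#' @return List with `t`, `df`, `p`, `mean`, `n`.
#' @export
one_sample_t <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) stop("need at least 2 values")
  m <- mean(values)
  s <- stats::sd(values)
  if (s == 0) {
    t <- if (m == 0) 0 else sign(m) * Inf
    p <- if (m == 0) 1 else 0
  } else {
    t <- m / (s / sqrt(n))
    p <- 2 * stats::pt(-abs(t), df = n - 1)
  }
  list(t = t, df = n - 1, p = p, mean = m, n = n)
}

#' Pearson correlation with r-squared
#'
#' Thin wrapper around [stats::cor.test()] reporting r, r-squared and the
#' two-sided t-based p value, with optional log transforms (JNDs are
#' log-transformed before correlation in this workflow).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param log_x,log_y Log-transform the corresponding input first.
#' @return List with `r`, `r2`, `p`, `n`.
#' @export
correlate <- function(x, y, log_x = FALSE, log_y = FALSE) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (log_x) x <- log(x)
  if (log_y) y <- log(y)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance in an input")
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), r2 = unname(ct$estimate)^2,
       p = ct$p.value, n = length(x))
}

#' Test/retest consistency quadrant
#'
#' Classifies a participant by the signs of the hold-phase means in the two
#' adaptation experiments (fixed-size shift, then JND-size shift): both
#' positive is consistently opposing, both negative consistently following,
#' and the two mixed quadrants capture inconsistent behaviour.
#'
#' @param summary_exp1,summary_exp3 [summarize_adaptation()] results (early
#'   metric).
#' @return One of `"opp/opp"`, `"opp/fol"`, `"fol/opp"`, `"fol/fol"`.
#' @export
consistency_quadrant <- function(summary_exp1, summary_exp3) {
  lab <- function(s) if (s$label == "opposing") "opp" else "fol"
  paste(lab(summary_exp1), lab(summary_exp3), sep = "/")
}
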