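#' Per-trial F0 reference from a cubic polynomial fit
#'
#' The traditional way of expressing adaptation data — cents relative to a
#' single baseline average — breaks down for speakers whose voice drifts over
#' the session: the drift masquerades as (or hides) adaptation. Instead, a
#' third-degree polynomial in trial index is fitted by ordinary least squares
#' to the segment F0 of the trials recorded with intact feedback: the 80
#' baseline trials and the last 50 washout trials. The fitted curve predicts,
#' for every one of the 270 trials, what F0 would have been had the feedback
#' always remained intact.
#'
#' Excluded trials are dropped from the fit but still receive predictions.
#' Trial index is centered at 135.5 before raising to powers, for numerical
#' conditioning; predictions are identical to the uncentered fit. Lower
#' polynomial degrees and shorter washout anchors are available for
#' sensitivity analyses; the cubic with the 50-trial anchor is the default.
#'
#' @param session A `pitch_session`.
#' @param metric Which per-trial F0 summary to fit: `"early"` (first 100 ms)
#'   or `"middle"` (central 100 ms).
#' @param degree Polynomial degree (default 3).
#' @param washout_anchor Number of final washout trials anchoring the fit
#'   (default 50).
#' @return An object of class `reference_curve`: `coeffs` (on the centered
#'   index), `fitted_indices`, `predicted_f0` (Hz, length 270) and `metric`.
#' @export
fit_reference <- function(session, metric = c("early", "middle"),
                          degree = 3, washout_anchor = 50) {
  metric <- match.arg(metric)
  stopifnot(degree >= 0, degree <= 3, washout_anchor >= 1, washout_anchor <= 80)
  seg <- session_segment_f0(session, metric)
  n <- nrow(session$trials)
  anchor <- c(phase_window("baseline"), (n - washout_anchor + 1L):n)
  fit_idx <- anchor[session$trials$included[anchor] & !is.na(seg[anchor])]
  if (length(fit_idx) < 20) stop("fewer than 20 usable trials in the fit set")
  xc <- fit_idx - 135.5
  X <- stats::model.matrix(~ stats::poly(xc, degree = max(degree, 1), raw = TRUE))
  if (degree == 0) X <- X[, 1, drop = FALSE]
  fit <- stats::lm.fit(X, seg[fit_idx])
  all_xc <- seq_len(n) - 135.5
  Xa <- cbind(1, stats::poly(all_xc, degree = max(degree, 1), raw = TRUE))
  if (degree == 0) Xa <- Xa[, 1, drop = FALSE]
  pred <- as.numeric(Xa %*% fit$coefficients)
  if (any(!is.finite(pred)) || any(pred <= 0)) {
    stop("reference curve predicts non-positive F0; fit is degenerate")
  }
  structure(
    list(coeffs = unname(fit$coefficients), fitted_indices = fit_idx,
         predicted_f0 = pred, metric = metric, degree = degree,
         washout_anchor = washout_anchor),
    class = "reference_curve"
  )
}

#' Single-value baseline reference
#'
#' The traditional normalization: one constant reference, the mean segment F0
#' of the included baseline trials, repeated for all 270 trials. Provided for
#' comparison with the polynomial reference, over which it is known to report
#' spurious adaptation for drifting speakers.
#'
#' @inheritParams fit_reference
#' @return A `reference_curve` with constant `predicted_f0`.
#' @export
single_value_reference <- function(session, metric = c("early", "middle")) {
  metric <- match.arg(metric)
  seg <- session_segment_f0(session, metric)
  idx <- phase_window("baseline")
  idx <- idx[session$trials$included[idx] & !is.na(seg[idx])]
  if (length(idx) < 2) stop("too few usable baseline trials")
  m <- mean(seg[idx])
  structure(
    list(coeffs = m, fitted_indices = idx,
         predicted_f0 = rep(m, nrow(session$trials)), metric = metric,
         degree = 0, washout_anchor = 0),
    class = "reference_curve"
  )
}

#' Normalize a session against a reference curve
#'
#' Expresses each trial's segment F0 in cents relative to the per-trial
#' reference prediction, and flips the sign for the upward-shift group so
#' that opposing responses are positive in both groups. Excluded trials
#' yield `NA`.
#'
#' @param session A `pitch_session`.
#' @param ref A [fit_reference()] curve (its `metric` determines the segment
#'   summary used).
#' @param direction Feedback shift direction; defaults to the session's own.
#' @return Numeric vector of normalized values in cents (length 270, `NA` for
#'   excluded trials), with attributes `metric` and `flipped`.
#' @export
normalize_session <- function(session, ref, direction = session$direction) {
  stopifnot(inherits(ref, "reference_curve"))
  if (length(ref$predicted_f0) != nrow(session$trials)) {
    stop("reference does not cover all trial indices")
  }
  seg <- session_segment_f0(session, ref$metric)
  cents <- 1200 * log2(seg / ref$predicted_f0)
  if (direction == "up") cents <- -cents
  attr(cents, "metric") <- ref$metric
  attr(cents, "flipped") <- direction == "up"
  cents
}
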