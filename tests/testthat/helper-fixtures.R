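# Shared fixtures for the suite. Everything is generated in code; no files.

# A speaker with no noise, no drift and no response: every track is constant.
silent_speaker <- function(f0 = 170) {
  speaker_params(
    baseline_f0 = f0, drift_coeffs = c(0, 0, 0, 0),
    across_trial_sd = 0, within_trial_sd = 0,
    adaptation_gain = 0, adaptation_tau = 1, aftereffect_tau = 1
  )
}

# A strongly drifting speaker (rising from 165 Hz through the session) with
# zero adaptation, for normalization tests. The drift is quadratic, i.e.
# within the cubic model class.
drifting_speaker <- function() {
  speaker_params(
    baseline_f0 = 165, drift_coeffs = c(0, 1.2, -0.0025, 0),
    across_trial_sd = 0, within_trial_sd = 0,
    adaptation_gain = 0, adaptation_tau = 1, aftereffect_tau = 1
  )
}

# Build a pitch_session directly from a list of tracks (for metric tests).
manual_session <- function(tracks, direction = "down", shift_magnitude = 100) {
  n <- length(tracks)
  stopifnot(n == 270)
  phase <- session_phases(n)
  sgn <- if (direction == "up") 1 else -1
  shift <- numeric(n)
  shift[phase_window("ramp")] <- sgn * shift_magnitude * (1:10) / 10
  shift[phase_window("hold")] <- sgn * shift_magnitude
  structure(
    list(
      trials = data.frame(
        index = seq_len(n), phase = phase,
        vowel = rep(c("a", "e", "o"), length.out = n),
        shift_cents = shift,
        included = vapply(tracks, inclusion_filter, logical(1)),
        stringsAsFactors = FALSE
      ),
      tracks = tracks, frame_step = 0.01,
      direction = direction, shift_magnitude = shift_magnitude,
      ground_truth = NULL
    ),
    class = "pitch_session"
  )
}

# Independent brute-force QUEST posterior: plain likelihood product over the
# grid, written against the Watson-Pelli Weibull formula directly.
brute_force_posterior <- function(grid, prior_mean, prior_sd, beta, gamma,
                                  delta_lapse, epsilon, x, correct) {
  lp <- stats::dnorm(grid, prior_mean, prior_sd, log = TRUE)
  for (i in seq_along(x)) {
    p <- delta_lapse * gamma + (1 - delta_lapse) *
      (1 - (1 - gamma) * exp(-10^(beta * (x[i] - grid + epsilon))))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    lp <- lp + if (correct[i]) log(p) else log1p(-p)
  }
  w <- exp(lp - max(lp))
  w / sum(w)
}
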