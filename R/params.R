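#' Parameters of a simulated speaker
#'
#' A speaker is described by a characteristic voice pitch, a slow cubic drift
#' of that pitch over the 270 trials of a session, trial-to-trial and
#' within-trial F0 variability (both in cents), per-vowel pitch offsets, and
#' a parametric response to pitch-shifted feedback: a fraction
#' `adaptation_gain` of the applied shift is opposed (negative gain means the
#' speaker follows the shift), with first-order exponential dynamics governed
#' by `adaptation_tau` while the perturbation is present and `aftereffect_tau`
#' once feedback is restored.
#'
#' @param baseline_f0 Characteristic F0 in Hz (within the 75-600 Hz tracker
#'   range).
#' @param drift_coeffs Numeric vector of up to 4 polynomial coefficients
#'   (Hz per trial-index power 0..3) describing slow drift across the session.
#' @param across_trial_sd SD of trial-to-trial F0 deviations, cents.
#' @param within_trial_sd SD of within-trial frame-to-frame F0 deviations,
#'   cents.
#' @param adaptation_gain Fraction of the feedback shift that is opposed;
#'   negative values produce following behaviour.
#' @param adaptation_tau Time constant (in trials) of the response rise while
#'   the shift is applied.
#' @param aftereffect_tau Time constant (in trials) of the response decay
#'   during washout.
#' @param vowel_offsets Named numeric vector of per-vowel F0 offsets in cents
#'   for vowels "a", "e", "o".
#' @param drift_sine Optional `c(amplitude_cents, period_trials)` adding a
#'   sinusoidal drift component that the cubic reference cannot represent;
#'   used to stress model mismatch.
#' @return An object of class `speaker_params`.
#' @export
speaker_params <- function(baseline_f0 = 170,
                           drift_coeffs = c(0, 0, 0, 0),
                           across_trial_sd = 30,
                           within_trial_sd = 40,
                           adaptation_gain = 0.2,
                           adaptation_tau = 5,
                           aftereffect_tau = 3,
                           vowel_offsets = c(a = 0, e = 0, o = 0),
                           drift_sine = NULL) {
  stopifnot(
    is.numeric(baseline_f0), length(baseline_f0) == 1,
    baseline_f0 >= 75, baseline_f0 <= 600,
    across_trial_sd >= 0, within_trial_sd >= 0,
    adaptation_tau > 0, aftereffect_tau > 0,
    length(drift_coeffs) <= 4
  )
  drift_coeffs <- c(drift_coeffs, rep(0, 4 - length(drift_coeffs)))
  vo <- c(a = 0, e = 0, o = 0)
  vo[names(vowel_offsets)] <- vowel_offsets
  structure(
    list(
      baseline_f0 = baseline_f0, drift_coeffs = drift_coeffs,
      across_trial_sd = across_trial_sd, within_trial_sd = within_trial_sd,
      adaptation_gain = adaptation_gain, adaptation_tau = adaptation_tau,
      aftereffect_tau = aftereffect_tau, vowel_offsets = vo,
      drift_sine = drift_sine
    ),
    class = "speaker_params"
  )
}

#' Parameters of a simulated 3I-2AFC observer
#'
#' The observer answers the odd-one-out pitch task through the same Weibull
#' psychometric family that the staircase assumes: chance floor at 50%
#' (`guess_rate`), threshold defined as the 70.707% correct point on the
#' interval-dB scale, slope `slope_beta`, and a lapse rate mixing responses
#' toward chance. `updown_offset` shifts the threshold for negative pitch
#' differences, reproducing the up/down asymmetry real listeners show, and
#' `vowel_bias_db` optionally penalizes specific vowels.
#'
#' @param true_threshold Threshold (70.707% point) in interval dB; e.g.
#'   47 cents is `cents_to_db(47)` = -3.28 dB.
#' @param slope_beta Weibull slope parameter, > 0.
#' @param lapse_rate Lapse probability in `[0, 0.05]`.
#' @param updown_offset dB added to the threshold when the target is lower
#'   than the reference (negative delta-F0).
#' @param vowel_bias_db Named numeric of per-vowel threshold offsets in dB.
#' @return An object of class `observer_params`.
#' @export
observer_params <- function(true_threshold = cents_to_db(47),
                            slope_beta = 3,
                            lapse_rate = 0.01,
                            updown_offset = 0,
                            vowel_bias_db = c(a = 0, e = 0, o = 0)) {
  stopifnot(
    slope_beta > 0,
    lapse_rate >= 0, lapse_rate <= 0.05
  )
  vb <- c(a = 0, e = 0, o = 0)
  vb[names(vowel_bias_db)] <- vowel_bias_db
  structure(
    list(
      true_threshold = true_threshold, slope_beta = slope_beta,
      lapse_rate = lapse_rate, updown_offset = updown_offset,
      guess_rate = 0.5, vowel_bias_db = vb
    ),
    class = "observer_params"
  )
}
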