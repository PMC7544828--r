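#' Phase labels of the 270-trial adaptation session
#'
#' Trials 1-80 are baseline (intact feedback), 81-90 ramp (the shift grows
#' linearly to its full magnitude), 91-190 hold (constant shift) and 191-270
#' washout (feedback intact again).
#'
#' @param n_trials Total trial count; only the canonical 270 layout is
#'   supported.
#' @return Character vector of phase labels.
#' @export
session_phases <- function(n_trials = 270) {
  stopifnot(n_trials == 270)
  rep(c("baseline", "ramp", "hold", "washout"), c(80, 10, 100, 80))
}

#' Trial indices belonging to a phase or analysis window
#'
#' @param window One of `"baseline"`, `"ramp"`, `"hold"`, `"washout"`,
#'   `"hold_first_half"`, `"hold_second_half"`, `"washout30"`, `"washout8"`,
#'   `"washout5"`, `"washout_last50"`.
#' @return Integer trial indices.
#' @export
phase_window <- function(window) {
  switch(window,
    baseline = 1:80,
    ramp = 81:90,
    hold = 91:190,
    washout = 191:270,
    hold_first_half = 91:140,
    hold_second_half = 141:190,
    washout30 = 191:220,
    washout8 = 191:198,
    washout5 = 191:195,
    washout_last50 = 221:270,
    stop("unknown window: ", window)
  )
}

#' Randomized vowel schedule with a per-block quota
#'
#' Draws a uniformly random vowel order subject to the constraint that every
#' consecutive block of 10 trials contains each of /a/, /e/, /o/ at least 3
#' times (so block counts are always a permutation of 3/3/4).
#'
#' @param n_trials Number of trials; must be a multiple of 10.
#' @param seed Integer seed.
#' @return Character vector of vowel labels (`"a"`, `"e"`, `"o"`).
#' @export
vowel_schedule <- function(n_trials = 270, seed = 1) {
  if (n_trials %% 10 != 0) stop("n_trials must be a multiple of 10")
  vowels <- c("a", "e", "o")
  with_substream(seed, "schedule", {
    unlist(lapply(seq_len(n_trials / 10), function(b) {
      extra <- sample(vowels, 1L)
      sample(c(rep(vowels, each = 3L), extra))
    }), use.names = FALSE)
  })
}

# Gaussian-smoothed unit-variance noise on the 10-ms frame grid; correlation
# length ~50 ms so that within-trial SD is controllable in cents.
smoothed_frame_noise <- function(n, corr_frames = 5) {
  pad <- 4L * corr_frames
  w <- stats::dnorm(seq(-pad, pad), sd = corr_frames)
  x <- stats::rnorm(n + 2L * pad)
  sm <- stats::filter(x, w / sqrt(sum(w^2)), sides = 2)
  as.numeric(sm[(pad + 1L):(pad + n)])
}

#' Generate a synthetic vocal adaptation session
#'
#' Simulates one 270-trial session (80 baseline / 10 ramp / 100 hold / 80
#' washout). Each trial's F0 track on the 10-ms frame grid is built as
#' cubic drift + vowel offset + across-trial deviate + smoothed within-trial
#' deviates + a response term: the speaker opposes (or follows, for a
#' negative gain) the applied shift with first-order exponential dynamics
#' during ramp/hold and decays back with the after-effect time constant
#' during washout. Ground-truth parameters and the noise-free response series
#' are stored for recovery tests.
#'
#' @param speaker A [speaker_params()] object.
#' @param direction `"up"` or `"down"`: direction of the feedback shift.
#' @param shift_magnitude Full shift magnitude in cents, > 0.
#' @param seed Integer seed (all per-session randomness derives from it).
#' @param trial_duration Vocalization duration in seconds (frames every
#'   10 ms).
#' @return An object of class `pitch_session`: a list with a `trials` data
#'   frame (`index`, `phase`, `vowel`, `shift_cents`, `included`), a list of
#'   per-trial F0 tracks (`tracks`, Hz with `NA` for unvoiced frames), the
#'   frame step, and the generator's `ground_truth`.
#' @export
generate_session <- function(speaker, direction = c("down", "up"),
                             shift_magnitude = 100, seed = 1,
                             trial_duration = 1.5) {
  direction <- match.arg(direction)
  if (!is.numeric(shift_magnitude) || shift_magnitude <= 0) {
    stop("shift_magnitude must be positive (cents)")
  }
  stopifnot(inherits(speaker, "speaker_params"))

  n <- 270L
  phase <- session_phases(n)
  vowel <- vowel_schedule(n, seed = seed)
  sgn <- if (direction == "up") 1 else -1
  shift <- numeric(n)
  shift[phase_window("ramp")] <- sgn * shift_magnitude * (1:10) / 10
  shift[phase_window("hold")] <- sgn * shift_magnitude

  # First-order response dynamics in trial index (cents, produced F0).
  response <- numeric(n)
  r <- 0
  for (t in seq_len(n)) {
    tau <- if (phase[t] == "washout") speaker$aftereffect_tau else speaker$adaptation_tau
    target <- -speaker$adaptation_gain * shift[t]
    r <- r + (target - r) * (1 - exp(-1 / tau))
    response[t] <- r
  }

  idx <- seq_len(n)
  base_hz <- speaker$baseline_f0 +
    speaker$drift_coeffs[1] + speaker$drift_coeffs[2] * idx +
    speaker$drift_coeffs[3] * idx^2 + speaker$drift_coeffs[4] * idx^3
  drift_cents <- if (!is.null(speaker$drift_sine)) {
    speaker$drift_sine[1] * sin(2 * pi * idx / speaker$drift_sine[2])
  } else {
    numeric(n)
  }

  n_frames <- round(trial_duration / 0.01)
  across <- with_substream(seed, "noise-across",
    stats::rnorm(n, 0, speaker$across_trial_sd)
  )
  tracks <- with_substream(seed, "noise-within", {
    lapply(seq_len(n), function(t) {
      within <- if (speaker$within_trial_sd > 0) {
        speaker$within_trial_sd * smoothed_frame_noise(n_frames)
      } else {
        numeric(n_frames)
      }
      cents <- speaker$vowel_offsets[[vowel[t]]] + drift_cents[t] +
        across[t] + response[t] + within
      base_hz[t] * 2^(cents / 1200)
    })
  })

  trials <- data.frame(
    index = idx, phase = phase, vowel = vowel, shift_cents = shift,
    included = vapply(tracks, function(tr) inclusion_filter(tr), logical(1)),
    stringsAsFactors = FALSE
  )
  structure(
    list(
      trials = trials, tracks = tracks, frame_step = 0.01,
      direction = direction, shift_magnitude = shift_magnitude,
      ground_truth = list(
        speaker = speaker, direction = direction,
        shift_magnitude = shift_magnitude, seed = seed,
        response_cents = response, across_cents = across,
        shift_cents = shift
      )
    ),
    class = "pitch_session"
  )
}

#' @export
print.pitch_session <- function(x, ...) {
  cat("<pitch_session>", nrow(x$trials), "trials,",
      sum(x$trials$included), "included; direction:", x$direction,
      sprintf("; shift: %.1f cents\n", x$shift_magnitude))
  invisible(x)
}
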