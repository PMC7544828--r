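#' Draw a simulated study cohort
#'
#' Samples per-participant speaker and observer parameters from the cohort
#' distributions the pipeline assumes (documented in the methods vignette):
#' characteristic pitch log-normal around 170 Hz, slow random cubic drift,
#' within-/across-trial F0 variability of 40 and 30 cents, adaptation gains
#' Normal(0.18, 0.54) (so roughly 63% of speakers oppose), and own-voice
#' pitch thresholds log-normal around 40 cents with slopes in 2-4 and lapse
#' rates up to 3%. Shift-direction group assignment alternates
#' deterministically across the cohort and is held fixed across experiments
#' 1 and 3.
#'
#' @param n Cohort size.
#' @param seed Integer seed.
#' @param gain_threshold_coupling Optional function mapping the observer's
#'   true threshold (interval dB) to an adaptation gain, replacing the
#'   independent gain draw; used to plant a JND-adaptation dependence.
#' @return List of participant configurations (`id`, `direction`,
#'   `speaker`, `observer`).
#' @export
sample_cohort <- function(n = 59, seed = 1, gain_threshold_coupling = NULL) {
  with_substream(seed, "cohort", {
    lapply(seq_len(n), function(i) {
      thr_cents <- min(max(stats::rlnorm(1, log(40), 0.7), 5), 300)
      observer <- observer_params(
        true_threshold = cents_to_db(thr_cents),
        slope_beta = stats::runif(1, 2, 4),
        lapse_rate = stats::runif(1, 0, 0.03),
        updown_offset = max(0, stats::rnorm(1, 1, 0.5))
      )
      gain <- if (is.null(gain_threshold_coupling)) {
        stats::rnorm(1, 0.18, 0.54)
      } else {
        gain_threshold_coupling(observer$true_threshold)
      }
      speaker <- speaker_params(
        baseline_f0 = min(max(stats::rlnorm(1, log(170), 0.25), 90), 350),
        drift_coeffs = c(0, stats::rnorm(1, 0, 0.02),
                         stats::rnorm(1, 0, 2e-4), stats::rnorm(1, 0, 8e-7)),
        across_trial_sd = 30, within_trial_sd = 40,
        adaptation_gain = gain,
        adaptation_tau = stats::runif(1, 2, 10),
        aftereffect_tau = stats::runif(1, 1, 5),
        vowel_offsets = stats::rnorm(3, 0, 15)
      )
      list(id = i, direction = if (i %% 2 == 1) "down" else "up",
           speaker = speaker, observer = observer)
    })
  })
}

# Analyse one adaptation session: reference fits, normalization and
# summaries for both segment metrics.
analyze_session <- function(session) {
  out <- lapply(c(early = "early", middle = "middle"), function(m) {
    ref <- fit_reference(session, metric = m)
    cents <- normalize_session(session, ref)
    list(ref = ref, cents = cents,
         summary = summarize_adaptation(session, cents))
  })
  out
}

#' Run the full three-experiment study on a simulated cohort
#'
#' For each participant: a fixed-size adaptation session (100 cents),
#' normalization and summaries; the 210-trial staircase plus post-hoc d-prime
#' refit giving the own-voice F0 JND; then a second adaptation session whose
#' shift equals that participant's measured JND. Cohort-level outputs are
#' the test/retest consistency quadrants (early metric) and the
#' JND-adaptation correlations, with JNDs log-transformed.
#'
#' @param n Cohort size.
#' @param seed Integer seed; every participant derives named sub-streams
#'   from it.
#' @param shift_exp1 Shift magnitude of the first experiment in cents.
#' @param cohort Optionally a pre-built [sample_cohort()] list (then `n` is
#'   ignored).
#' @param min_shift Floor on the personalized shift in cents.
#' @return An object of class `study_result`: `participants` (one row per
#'   participant), `correlations`, `quadrants`, `mean_jnd_cents`,
#'   `mean_hold_exp1`.
#' @export
run_full_study <- function(n = 59, seed = 1, shift_exp1 = 100, cohort = NULL,
                           min_shift = 1) {
  if (is.null(cohort)) cohort <- sample_cohort(n, seed)
  rows <- lapply(cohort, function(p) {
    pseed <- substream_seed(seed, paste0("participant-", p$id))
    s1 <- generate_session(p$speaker, p$direction, shift_exp1,
                           seed = substream_seed(pseed, "exp1"))
    a1 <- analyze_session(s1)
    sc <- run_staircase(p$observer, seed = substream_seed(pseed, "exp2"))
    jnd <- analyze_jnd(sc)
    shift3 <- max(jnd$jnd_cents, min_shift, na.rm = TRUE)
    s3 <- generate_session(p$speaker, p$direction, shift3,
                           seed = substream_seed(pseed, "exp3"))
    a3 <- analyze_session(s3)
    data.frame(
      id = p$id, direction = p$direction,
      baseline_f0 = p$speaker$baseline_f0,
      adaptation_gain = p$speaker$adaptation_gain,
      true_threshold_db = p$observer$true_threshold,
      jnd_cents = jnd$jnd_cents, jnd_status = jnd$status,
      hold_mean_early_exp1 = a1$early$summary$hold_mean,
      hold_mean_middle_exp1 = a1$middle$summary$hold_mean,
      washout8_early_exp1 = a1$early$summary$washout8_mean,
      label_exp1 = a1$early$summary$label,
      shift_exp3 = shift3,
      hold_mean_early_exp3 = a3$early$summary$hold_mean,
      hold_mean_middle_exp3 = a3$middle$summary$hold_mean,
      washout8_early_exp3 = a3$early$summary$washout8_mean,
      label_exp3 = a3$early$summary$label,
      quadrant = consistency_quadrant(a1$early$summary, a3$early$summary),
      stringsAsFactors = FALSE
    )
  })
  participants <- do.call(rbind, rows)
  ok <- !is.na(participants$jnd_cents)
  correlations <- list(
    exp1 = correlate(participants$jnd_cents[ok],
                     participants$hold_mean_early_exp1[ok], log_x = TRUE),
    exp3 = correlate(participants$jnd_cents[ok],
                     participants$hold_mean_early_exp3[ok], log_x = TRUE)
  )
  quad <- table(factor(participants$quadrant,
                       levels = c("opp/opp", "opp/fol", "fol/opp", "fol/fol")))
  structure(
    list(participants = participants, correlations = correlations,
         quadrants = quad, quadrant_prop = as.numeric(quad) / nrow(participants),
         mean_jnd_cents = mean(participants$jnd_cents, na.rm = TRUE),
         mean_hold_exp1 = mean(participants$hold_mean_early_exp1),
         seed = seed, n = nrow(participants)),
    class = "study_result"
  )
}

#' @export
print.study_result <- function(x, ...) {
  cat("<study_result>", x$n, "participants\n")
  cat(sprintf("  mean JND: %.1f cents; mean hold (exp1, early): %.1f cents\n",
              x$mean_jnd_cents, x$mean_hold_exp1))
  cat(sprintf("  JND-adaptation r2: exp1 %.3f (p=%.3f), exp3 %.3f (p=%.3f)\n",
              x$correlations$exp1$r2, x$correlations$exp1$p,
              x$correlations$exp3$r2, x$correlations$exp3$p))
  cat("  quadrants:", paste(names(x$quadrants), x$quadrants, collapse = ", "),
      "\n")
  invisible(x)
}
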