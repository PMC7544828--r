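test_that("analysis windows partition the hold and washout phases", {
  expect_equal(sort(c(phase_window("hold_first_half"), phase_window("hold_second_half"))),
               phase_window("hold"))
  expect_length(intersect(phase_window("hold_first_half"),
                          phase_window("hold_second_half")), 0)
  expect_true(all(phase_window("washout5") %in% phase_window("washout8")))
  expect_true(all(phase_window("washout8") %in% phase_window("washout30")))
  expect_equal(phase_window("washout8"), 191:198)
  expect_equal(phase_window("washout5"), 191:195)
})

test_that("adaptation summaries recover the planted response", {
  sp <- speaker_params(across_trial_sd = 3, within_trial_sd = 5,
                       adaptation_gain = 0.2, adaptation_tau = 0.5,
                       aftereffect_tau = 3)
  s <- generate_session(sp, "down", 100, seed = 10)
  cents <- normalize_session(s, fit_reference(s, "early"))
  sm <- summarize_adaptation(s, cents)
  expect_equal(sm$hold_mean, 20, tolerance = 0.15)
  expect_equal(sm$label, "opposing")
  expect_equal(sort(names(sm$per_vowel_hold_means)), c("a", "e", "o"))
  # after-effect decays with tau = 3 trials from ~20 cents: the narrow early
  # washout windows catch more of it than the 30-trial window
  expect_gt(sm$washout5_mean, sm$washout30_mean)
  expect_gt(sm$washout30_mean, 0)
  # closed-form check of the washout window means (exponential approach to 0)
  r_true <- s$ground_truth$response_cents
  expect_lt(abs(sm$washout5_mean - mean(r_true[191:195])), 4)
})

test_that("window means are linear in the normalized series", {
  s <- generate_session(speaker_params(), "down", 100, seed = 11)
  cents <- normalize_session(s, fit_reference(s, "early"))
  sm0 <- summarize_adaptation(s, cents)
  cents_shift <- cents + 7
  attributes(cents_shift) <- attributes(cents)
  sm1 <- summarize_adaptation(s, cents_shift)
  expect_equal(sm1$hold_mean, sm0$hold_mean + 7, tolerance = 1e-9)
  expect_equal(sm1$washout8_mean, sm0$washout8_mean + 7, tolerance = 1e-9)
  expect_equal(unname(sm1$per_vowel_hold_means),
               unname(sm0$per_vowel_hold_means) + 7, tolerance = 1e-9)
})

test_that("an all-zero series is labelled opposing by the tie rule", {
  s <- generate_session(silent_speaker(), "down", 100, seed = 12)
  cents <- normalize_session(s, fit_reference(s, "early"))
  expect_lt(abs(summarize_adaptation(s, cents)$hold_mean), 1e-9)
  # an exactly zero series resolves the tie as opposing
  zero <- structure(rep(0, 270), metric = "early")
  expect_equal(summarize_adaptation(s, zero)$label, "opposing")
})

test_that("mean traces average aligned voiced frames", {
  s <- generate_session(silent_speaker(170), "down", 100, seed = 13)
  tr <- mean_trace(s, 1:80)
  expect_equal(as.numeric(tr), rep(170, 50))
  # baseline-referenced baseline trace is 0 cents everywhere
  ref <- mean_trace(s, 1:80)
  tr0 <- mean_trace(s, 1:80, ref_trace = as.numeric(ref))
  expect_equal(as.numeric(tr0), rep(0, 50), tolerance = 1e-9)
  # hold trials of an adapted noiseless speaker show the response in cents
  sp <- speaker_params(across_trial_sd = 0, within_trial_sd = 0,
                       adaptation_gain = 0.3, adaptation_tau = 0.2)
  s2 <- generate_session(sp, "down", 100, seed = 13)
  base2 <- mean_trace(s2, 1:80)
  hold2 <- mean_trace(s2, 150:190, ref_trace = as.numeric(base2))
  expect_equal(as.numeric(hold2), rep(30, 50), tolerance = 1e-4)
  expect_error(mean_trace(s, integer(0)), "eligible")
})

test_that("one-sample t handles regular and degenerate inputs", {
  expect_equal(one_sample_t(c(1, -1))$t, 0)
  tt <- one_sample_t(c(2, 2, 2, 2))
  expect_true(is.infinite(tt$t) && tt$t > 0)
  expect_equal(tt$p, 0)
  expect_equal(one_sample_t(c(0, 0, 0))$t, 0)
  set.seed(14)
  x <- rnorm(30, 1, 2)
  ref <- stats::t.test(x)
  ours <- one_sample_t(x)
  expect_equal(ours$t, unname(ref$statistic))
  expect_equal(ours$p, ref$p.value)
  expect_error(one_sample_t(3), "at least 2")
})

test_that("t-test rejection rate matches the analytic power", {
  set.seed(15)
  nsim <- 2000
  rej <- mean(replicate(nsim, one_sample_t(rnorm(59, 18.3, 54))$p < 0.05))
  pow <- stats::power.t.test(n = 59, delta = 18.3, sd = 54,
                             type = "one.sample")$power
  expect_equal(rej, pow, tolerance = 3 * sqrt(pow * (1 - pow) / nsim) / pow)
})

test_that("correlation wrapper reproduces Pearson machinery", {
  x <- 1:20
  perfect <- correlate(x, 2 * x)
  expect_equal(perfect$r2, 1)
  set.seed(16)
  a <- rnorm(59); b <- rnorm(59)
  ref <- stats::cor.test(a, b)
  ours <- correlate(a, b)
  expect_equal(ours$r, unname(ref$estimate))
  expect_equal(ours$p, ref$p.value)
  # log transform is applied before correlating
  j <- exp(rnorm(59))
  expect_equal(correlate(j, b, log_x = TRUE)$r,
               unname(stats::cor.test(log(j), b)$estimate))
  expect_error(correlate(rep(1, 10), rnorm(10)), "variance")
  # null false-positive rate stays near the nominal level
  fp <- mean(replicate(1500, correlate(rnorm(59), rnorm(59))$p < 0.05))
  expect_equal(fp, 0.05, tolerance = 0.4)
  # planted signal fraction appears as r-squared
  n <- 4000
  x2 <- rnorm(n)
  y2 <- x2 + rnorm(n, 0, sqrt(3))   # signal variance fraction = 1/4
  expect_equal(correlate(x2, y2)$r2, 0.25, tolerance = 0.15)
})

test_that("consistency quadrants follow the hold-mean signs", {
  mk <- function(h) structure(list(hold_mean = h,
                                   label = if (h >= 0) "opposing" else "following"),
                              class = "adaptation_summary")
  expect_equal(consistency_quadrant(mk(10), mk(5)), "opp/opp")
  expect_equal(consistency_quadrant(mk(10), mk(-5)), "opp/fol")
  expect_equal(consistency_quadrant(mk(-10), mk(5)), "fol/opp")
  expect_equal(consistency_quadrant(mk(-1), mk(-1)), "fol/fol")
})

test_that("quadrants match planted gain signs for stable low-noise speakers", {
  for (g in c(0.4, -0.4)) {
    sp <- speaker_params(across_trial_sd = 5, within_trial_sd = 8,
                         adaptation_gain = g, adaptation_tau = 1,
                         aftereffect_tau = 1)
    sums <- lapply(c(101, 202), function(seed) {
      s <- generate_session(sp, "up", 100, seed = seed)
      summarize_adaptation(s, normalize_session(s, fit_reference(s, "early")))
    })
    want <- if (g > 0) "opp/opp" else "fol/fol"
    expect_equal(consistency_quadrant(sums[[1]], sums[[2]]), want)
  }
})
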