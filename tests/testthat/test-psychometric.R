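# A directional fit built directly from known parameters, for curve tests.
manual_fit <- function(threshold, beta, delta, direction = "positive") {
  structure(
    list(direction = direction, best_delta = delta, best_beta = beta,
         threshold = threshold, peak = 1,
         epsilon = calibrate_epsilon(beta, 0.5, delta),
         gamma = 0.5, target_pc = 0.70707, n_trials = 0,
         candidates = NULL),
    class = "directional_fit"
  )
}

test_that("the refit grid is 25 pairs centered on the final slope", {
  obs <- observer_params(true_threshold = -5, slope_beta = 3,
                         lapse_rate = 0.02, updown_offset = 0)
  sc <- run_staircase(obs, seed = 9)
  fit <- refit_direction(sc$history, "positive", final_beta = 4.2)
  expect_equal(nrow(fit$candidates), 25)
  expect_equal(sort(unique(fit$candidates$beta)), c(3.8, 4.0, 4.2, 4.4, 4.6))
  expect_equal(sort(unique(fit$candidates$delta_lapse)),
               c(0.01, 0.02, 0.03, 0.04, 0.05))
  expect_true(fit$best_beta %in% fit$candidates$beta)
  expect_true(fit$best_delta %in% fit$candidates$delta_lapse)
})

test_that("the refit scan equals a brute-force posterior over the grid", {
  obs <- observer_params(true_threshold = -4, slope_beta = 3,
                         lapse_rate = 0.02, updown_offset = 0)
  sc <- run_staircase(obs, n_trials = 80, seed = 10)
  fit <- refit_direction(sc$history, "negative", final_beta = 3)
  rows <- sc$history[sc$history$delta_sign == -1L, ]
  st <- quest_init()
  for (k in sample(nrow(fit$candidates), 6)) {
    b <- fit$candidates$beta[k]
    d <- fit$candidates$delta_lapse[k]
    post <- brute_force_posterior(st$grid, 10.8, 80, b, 0.5, d,
                                  calibrate_epsilon(b, 0.5, d),
                                  rows$x_db, rows$correct)
    expect_equal(fit$candidates$peak[k], max(post), tolerance = 1e-8)
    expect_equal(fit$candidates$threshold[k], st$grid[which.max(post)])
  }
})

test_that("identical histories give identical directional fits", {
  obs <- observer_params(true_threshold = -5, slope_beta = 3,
                         lapse_rate = 0.02, updown_offset = 0)
  sc <- run_staircase(obs, n_trials = 60, seed = 11)
  h <- sc$history
  h$delta_sign <- 1L
  h_neg <- h
  h_neg$delta_sign <- -1L
  fp <- refit_direction(h, "positive", 3)
  fn <- refit_direction(h_neg, "negative", 3)
  expect_equal(fp$threshold, fn$threshold)
  expect_equal(fp$best_beta, fn$best_beta)
  expect_equal(fp$best_delta, fn$best_delta)
})

test_that("parameter recovery of a single direction is unbiased at the median", {
  obs <- observer_params(true_threshold = -5, slope_beta = 3,
                         lapse_rate = 0.02, updown_offset = 0)
  errs <- vapply(1:12, function(seed) {
    sc <- run_staircase(obs, seed = seed)
    fit <- refit_direction(sc$history, "positive", final_beta = 3)
    fit$threshold - (-5)
  }, numeric(1))
  expect_lt(abs(stats::median(errs)), 1.5)
})

test_that("the symmetric d-prime case follows the closed form", {
  f <- manual_fit(threshold = -5, beta = 3, delta = 0.02)
  cv <- dprime_curve(f, f)
  # with identical fits F = 1 - H, so d' = 2 z(H)
  i <- which(abs(cv$grid) >= 0)  # all points
  h <- cv$hit[i]
  expect_equal(cv$dprime[i], 2 * stats::qnorm(h), tolerance = 1e-9)
  # at the common threshold, d' = 2 z(0.70707) = 1.09 > 0.77, so the JND sits
  # below the 70.7% threshold
  at_t <- which.min(abs(cv$grid - (-5)))
  expect_equal(cv$dprime[at_t], 2 * stats::qnorm(0.70707), tolerance = 1e-3)
  j <- extract_jnd(cv)
  expect_equal(j$status, "ok")
  expect_lt(j$jnd_db, -5)
})

test_that("the d-prime curve is symmetric under swapping the two fits", {
  fp <- manual_fit(-6, 3.2, 0.03)
  fn <- manual_fit(-3, 2.8, 0.01, "negative")
  a <- dprime_curve(fp, fn)
  b <- dprime_curve(fn, fp)
  # z(H) - z(1-Fpc) = z(Hpc) + z(Fpc): swapping the roles leaves d' unchanged
  expect_equal(a$dprime, b$dprime, tolerance = 1e-9)
})

test_that("JND extraction interpolates, flags edges and unmeasurable curves", {
  grid <- seq(-20, 20, by = 0.01)
  lin <- structure(list(grid = grid, hit = NULL, fa = NULL,
                        dprime = 0.1 * (grid + 10)), class = "dprime_curve")
  j <- extract_jnd(lin, criterion = 0.77)
  expect_equal(j$jnd_db, -10 + 7.7, tolerance = 1e-6)
  expect_equal(j$jnd_cents, db_to_cents(-2.3), tolerance = 1e-6)
  high <- structure(list(grid = grid, dprime = rep(2, length(grid))),
                    class = "dprime_curve")
  expect_equal(extract_jnd(high)$status, "at_edge")
  flat <- structure(list(grid = grid, dprime = rep(0.1, length(grid))),
                    class = "dprime_curve")
  expect_equal(extract_jnd(flat)$status, "unmeasurable")
})

test_that("improving the hit-rate fit never increases the JND", {
  fn <- manual_fit(-3, 3, 0.01, "negative")
  jnds <- vapply(c(-2, -4, -6, -8), function(tp) {
    extract_jnd(dprime_curve(manual_fit(tp, 3, 0.02), fn))$jnd_db
  }, numeric(1))
  expect_true(all(diff(jnds) < 1e-9))
})

test_that("the documented example fits combine into a plausible d-prime curve", {
  # positive fit: 3% lapse, slope 4.2, 70.7% point at 27 cents;
  # negative fit: 1% lapse, slope 4.2, 70.7% point at 43 cents
  fp <- manual_fit(cents_to_db(27), 4.2, 0.03)
  fn <- manual_fit(cents_to_db(43), 4.2, 0.01, "negative")
  cv <- dprime_curve(fp, fn)
  mid <- cv$grid > -15 & cv$grid < 10
  expect_true(all(diff(cv$dprime[mid]) > -1e-9))
  j <- extract_jnd(cv)
  expect_equal(j$status, "ok")
  # the criterion crossing falls at or below the positive-fit threshold and
  # well above the floor
  expect_lte(j$jnd_cents, 43)
  expect_gt(j$jnd_cents, 10)
})

test_that("vowel-specific JNDs behave under null and planted vowel effects", {
  base <- observer_params(true_threshold = -4, slope_beta = 3,
                          lapse_rate = 0.02, updown_offset = 0)
  sc <- run_staircase(base, seed = 12)
  jnds <- vowel_specific_jnds(sc)
  expect_length(jnds, 3)
  expect_true(all(is.finite(jnds)))
  # no vowel effect: the three JNDs are mutually within a modest factor
  expect_lt(max(jnds) / min(jnds), 2.5)
  # identical subsets give identical JNDs
  h <- sc$history
  h$vowel <- "a"
  h2 <- h
  expect_equal(
    analyze_jnd(h, final_beta = sc$winning_beta)$jnd_cents,
    analyze_jnd(h2, final_beta = sc$winning_beta)$jnd_cents
  )
  expect_error(vowel_specific_jnds(h, final_beta = 3), "underrepresented")

  # a planted 2x threshold penalty on /a/ shows up as the largest JND
  pen <- observer_params(true_threshold = -6, slope_beta = 3,
                         lapse_rate = 0.01, updown_offset = 0,
                         vowel_bias_db = c(a = semitones_to_db(2)))
  hits <- vapply(1:5, function(seed) {
    v <- vowel_specific_jnds(run_staircase(pen, seed = seed))
    names(which.max(v)) == "a"
  }, logical(1))
  expect_gte(sum(hits), 4)
})
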