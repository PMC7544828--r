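test_that("the Weibull family has the right floor, ceiling and tracking point", {
  for (beta in 1:4) {
    eps <- calibrate_epsilon(beta, 0.5, 0.01)
    expect_equal(weibull_p(-1e6, 0, beta, 0.5, 0.01, eps), 0.5)
    expect_equal(weibull_p(1e6, 0, beta, 0.5, 0.01, eps), 0.995)
    expect_equal(weibull_p(0, 0, beta, 0.5, 0.01, eps), 0.70707,
                 tolerance = 1e-10)
    # monotone nondecreasing in the tested level
    x <- seq(-20, 20, by = 0.05)
    expect_true(all(diff(weibull_p(x, 0, beta, 0.5, 0.01, eps)) >= 0))
  }
  # epsilon scales as 1/beta
  e1 <- calibrate_epsilon(1, 0.5, 0.01)
  e2 <- calibrate_epsilon(2, 0.5, 0.01)
  expect_equal(e2, e1 / 2, tolerance = 1e-12)
  expect_error(calibrate_epsilon(2, 0.5, 0.01, target_pc = 0.5), "range")
  expect_error(calibrate_epsilon(2, 0.5, 0.01, target_pc = 0.999), "range")
})

test_that("the state starts from the documented grid and prior", {
  st <- quest_init()
  expect_length(st$grid, 4001)
  expect_equal(st$grid[1], -20)
  expect_equal(st$grid[4001], 20)
  expect_equal(st$grid[2] - st$grid[1], 0.01)
  # with no data the posterior is the prior and the best guess its mode
  for (b in 1:4) {
    expect_equal(quest_posterior(st, b),
                 exp(st$log_prior) / sum(exp(st$log_prior)), tolerance = 1e-12)
  }
  bg <- quest_best_guess(st)
  expect_equal(bg$x_star, 10.8)
})

test_that("posteriors stay normalized and updates are order-invariant", {
  st <- quest_init()
  set.seed(31)
  xs <- runif(15, -10, 5)
  corr <- runif(15) < 0.7
  for (i in 1:15) st <- quest_update(st, xs[i], corr[i])
  for (b in 1:4) expect_equal(sum(quest_posterior(st, b)), 1, tolerance = 1e-9)
  # permuted history gives the same posterior
  st2 <- quest_init()
  perm <- sample(15)
  for (i in perm) st2 <- quest_update(st2, xs[i], corr[i])
  expect_equal(st$log_posterior, st2$log_posterior, tolerance = 1e-9)
})

test_that("an easy correct trial far below threshold is uninformative", {
  st <- quest_init()
  st2 <- quest_update(st, -19.5, TRUE)
  for (b in 1:4) {
    p0 <- quest_posterior(st, b)
    p1 <- quest_posterior(st2, b)
    # likelihood is ~gamma everywhere on the grid above the tested level
    expect_lt(max(abs(p1 - p0)), 1e-3)
  }
})

test_that("outcomes at the tracked rate pull the posterior mode to the tested level", {
  # 70% correct at a level is (nearly) the tracked performance point, so the
  # threshold estimate should settle close to that level
  st <- quest_init()
  for (i in 1:40) st <- quest_update(st, -5, i %% 10 < 7)
  bg <- quest_best_guess(st)
  expect_lt(abs(bg$x_star - (-5)), 2)
})

test_that("best-guess ties break toward the lower threshold", {
  st <- quest_init()
  # two posteriors that are exact translates: equal peaks, different modes
  a <- rep(0, length(st$grid)); a[1500] <- 5
  b <- rep(0, length(st$grid)); b[2500] <- 5
  low <- rep(-10, length(st$grid))
  st$log_posterior[1, ] <- a
  st$log_posterior[2, ] <- b
  st$log_posterior[3, ] <- low
  st$log_posterior[4, ] <- low
  bg <- quest_best_guess(st)
  expect_equal(bg$x_star, st$grid[1500])
})

test_that("placement roves uniformly around the best guess and clips to the grid", {
  set.seed(32)
  draws <- replicate(3000, place_next(-10)$x_db)
  expect_gte(min(draws), -15)
  expect_lte(max(draws), -5)
  expect_lt(min(draws), -14.8)
  expect_gt(max(draws), -5.2)
  signs <- replicate(2000, place_next(0)$delta_sign)
  expect_equal(mean(signs == 1), 0.5, tolerance = 0.07)
  # clipping at the grid edge
  hi <- replicate(500, place_next(19)$x_db)
  expect_lte(max(hi), 20)
})

test_that("staircases are deterministic under a fixed seed and track thresholds", {
  obs <- observer_params(true_threshold = cents_to_db(47), slope_beta = 3.5,
                         lapse_rate = 0.02, updown_offset = 0)
  r1 <- run_staircase(obs, seed = 5)
  r2 <- run_staircase(obs, seed = 5)
  expect_identical(r1$history, r2$history)
  expect_equal(nrow(r1$history), 210)
  expect_true(r1$winning_beta %in% 1:4)

  # near-deterministic observer: the step is found quickly
  step_obs <- observer_params(true_threshold = -10, slope_beta = 25,
                              lapse_rate = 0, updown_offset = 0)
  r3 <- run_staircase(step_obs, n_trials = 60, seed = 6)
  expect_lt(abs(r3$final_best_guess - (-10)), 0.5)
})

test_that("posterior uncertainty shrinks as trials accumulate", {
  obs <- observer_params(true_threshold = -3, slope_beta = 3,
                         lapse_rate = 0.01, updown_offset = 0)
  sd_at <- function(state) {
    bg <- quest_best_guess(state)
    b <- which(state$betas == bg$beta)
    post <- quest_posterior(state, b)
    m <- sum(post * state$grid)
    sqrt(sum(post * (state$grid - m)^2))
  }
  sds <- vapply(1:6, function(seed) {
    early <- run_staircase(obs, n_trials = 15, seed = seed)
    late <- run_staircase(obs, n_trials = 150, seed = seed)
    c(sd_at(early$state), sd_at(late$state))
  }, numeric(2))
  expect_lt(mean(sds[2, ]), mean(sds[1, ]))
})

test_that("the practice gate passes able observers and rejects poor ones", {
  sharp <- observer_params(true_threshold = -15, slope_beta = 4,
                           lapse_rate = 0, updown_offset = 0)
  g <- practice_gate(sharp, seed = 7)
  expect_true(g$pass)
  expect_equal(g$percent_correct, 100)
  # threshold far above 4.8 semitones: performance is chance, gate fails
  deaf <- observer_params(true_threshold = 19, slope_beta = 4,
                          lapse_rate = 0, updown_offset = 0)
  fails <- vapply(1:30, function(s) practice_gate(deaf, seed = s)$pass,
                  logical(1))
  # binomial tail oracle: at chance, P(pass) = P(X >= 17), X ~ B(20, 1/2),
  # about 0.13% -- zero passes in 30 seeds is the overwhelmingly likely draw
  expect_lt(mean(fails), 2 * stats::pbinom(16, 20, 0.5, lower.tail = FALSE) + 0.05)
})
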