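#' Weibull psychometric function on the interval-dB scale
#'
#' The Watson-Pelli QUEST form of the Weibull function:
#' `p(x) = delta * gamma + (1 - delta) * (1 - (1 - gamma) *
#' exp(-10^(beta * (x - threshold + epsilon))))`.
#' With gamma = 0.5 (3I-2AFC chance) the floor is exactly 0.5 and the
#' ceiling `delta * gamma + (1 - delta)`. `epsilon` shifts the curve so that
#' `p(threshold)` equals a chosen tracking point (see
#' [calibrate_epsilon()]).
#'
#' @param x Tested pitch difference, interval dB. Vectorized over `x` and
#'   `threshold`.
#' @param threshold Threshold parameter in interval dB.
#' @param beta Slope parameter (> 0).
#' @param gamma Guess rate (0.5 for 2AFC).
#' @param delta_lapse Lapse rate.
#' @param epsilon Calibration offset in dB.
#' @return Probability of a correct response.
#' @export
weibull_p <- function(x, threshold, beta, gamma = 0.5, delta_lapse = 0.01,
                      epsilon = 0) {
  delta_lapse * gamma +
    (1 - delta_lapse) * (1 - (1 - gamma) * exp(-10^(beta * (x - threshold + epsilon))))
}

#' Calibrate the Weibull offset to a tracking point
#'
#' Solves `weibull_p(T, T, beta, gamma, delta, epsilon) = target_pc` in
#' closed form, so that the threshold parameter always denotes the same
#' percent-correct point (70.707% here) whatever the slope and lapse.
#'
#' @inheritParams weibull_p
#' @param target_pc Percent-correct point that threshold should denote.
#' @return The offset `epsilon` in dB.
#' @export
calibrate_epsilon <- function(beta, gamma = 0.5, delta_lapse = 0.01,
                              target_pc = 0.70707) {
  floor_p <- gamma
  ceiling_p <- delta_lapse * gamma + (1 - delta_lapse)
  if (target_pc <= floor_p || target_pc >= ceiling_p) {
    stop("target percent correct outside the achievable range")
  }
  a <- (target_pc - delta_lapse * gamma) / (1 - delta_lapse)
  log10(-log((1 - a) / (1 - gamma))) / beta
}

#' Initialize the multi-QUEST state
#'
#' A grid of candidate thresholds from -20 to +20 interval dB (1 cent to 100
#' semitones) at 0.01 dB granularity, a deliberately uninformed Gaussian
#' prior (mean 10.8 dB = one octave, SD 80 dB), and one posterior per slope
#' value beta = 1, 2, 3, 4, each with its own calibrated epsilon so that
#' threshold means 70.707% correct throughout.
#'
#' @param betas Candidate slope values.
#' @param gamma Guess rate.
#' @param delta_lapse Lapse rate assumed during the staircase.
#' @param prior_mean,prior_sd Gaussian prior on threshold, interval dB.
#' @param grid_range,grid_step Grid extent and step in interval dB.
#' @param target_pc Tracked percent-correct point.
#' @return An object of class `quest_state`.
#' @export
quest_init <- function(betas = 1:4, gamma = 0.5, delta_lapse = 0.01,
                       prior_mean = 10.8, prior_sd = 80,
                       grid_range = c(-20, 20), grid_step = 0.01,
                       target_pc = 0.70707) {
  grid <- seq(grid_range[1] / grid_step, grid_range[2] / grid_step) * grid_step
  log_prior <- stats::dnorm(grid, prior_mean, prior_sd, log = TRUE)
  log_prior <- log_prior - log(sum(exp(log_prior - max(log_prior)))) - max(log_prior)
  epsilon <- vapply(betas, calibrate_epsilon, numeric(1),
                    gamma = gamma, delta_lapse = delta_lapse,
                    target_pc = target_pc)
  structure(
    list(
      grid = grid, betas = betas, gamma = gamma, delta_lapse = delta_lapse,
      epsilon = epsilon, target_pc = target_pc, log_prior = log_prior,
      log_posterior = matrix(log_prior, nrow = length(betas),
                             ncol = length(grid), byrow = TRUE),
      history = data.frame(trial = integer(), x_db = numeric(),
                           delta_sign = integer(), vowel = character(),
                           correct = logical(), stringsAsFactors = FALSE)
    ),
    class = "quest_state"
  )
}

# Log-likelihood of one outcome over the whole (sorted, uniform) threshold
# grid, exploiting saturation of the Weibull curve: for thresholds far below
# the tested level the curve equals its ceiling exactly in double precision,
# far above it equals gamma exactly, so only a narrow window needs the
# transcendental evaluation. Identical to clamping and logging weibull_p on
# the full grid.
.weibull_grid_ll <- function(x, grid, beta, gamma, delta_lapse, epsilon,
                             correct) {
  n <- length(grid)
  step <- grid[2] - grid[1]
  xt <- x + epsilon
  clamp_log <- function(p) {
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    if (correct) log(p) else log1p(-p)
  }
  ia <- max(0L, min(n, as.integer(floor((xt - 3 / beta - grid[1]) / step))))
  ib <- max(1L, min(n + 1L,
                    as.integer(ceiling((xt + 18 / beta - grid[1]) / step)) + 2L))
  ll <- numeric(n)
  if (ia > 0) ll[seq_len(ia)] <- clamp_log(delta_lapse * gamma + (1 - delta_lapse))
  if (ib <= n) ll[ib:n] <- clamp_log(gamma)
  if (ia < ib - 1L) {
    idx <- (ia + 1L):(ib - 1L)
    ll[idx] <- clamp_log(weibull_p(x, grid[idx], beta, gamma, delta_lapse,
                                   epsilon))
  }
  ll
}

#' Bayesian update of all QUEST posteriors after one trial
#'
#' Multiplies every beta-specific posterior by the likelihood of the observed
#' outcome at the tested level, evaluated at every candidate threshold on the
#' grid; bookkeeping is done in log space.
#'
#' @param state A `quest_state`.
#' @param x_db Tested pitch difference magnitude, interval dB.
#' @param correct Logical outcome.
#' @param delta_sign +1 or -1, sign of the tested difference (recorded, not
#'   used by the shared-posterior update).
#' @param vowel Optional vowel label for the trial's stimulus.
#' @return The updated `quest_state`.
#' @export
quest_update <- function(state, x_db, correct, delta_sign = 1L, vowel = NA_character_) {
  for (b in seq_along(state$betas)) {
    state$log_posterior[b, ] <- state$log_posterior[b, ] +
      .weibull_grid_ll(x_db, state$grid, state$betas[b], state$gamma,
                       state$delta_lapse, state$epsilon[b], correct)
  }
  state$history <- rbind(state$history, data.frame(
    trial = nrow(state$history) + 1L, x_db = x_db,
    delta_sign = as.integer(delta_sign), vowel = vowel,
    correct = correct, stringsAsFactors = FALSE
  ))
  state
}

#' Normalized posterior of one QUEST function
#'
#' @param state A `quest_state`.
#' @param beta_index Row index into the beta set.
#' @return Probability vector over the threshold grid summing to 1.
#' @export
quest_posterior <- function(state, beta_index) {
  lp <- state$log_posterior[beta_index, ]
  w <- exp(lp - max(lp))
  w / sum(w)
}

#' Best threshold guess across the four QUEST functions
#'
#' Finds the posterior mode of each beta-specific QUEST function and returns
#' the mode whose (normalized) posterior peak is highest across the four.
#' All ties break toward the smaller threshold, a conservative convention.
#'
#' @param state A `quest_state`.
#' @return List with `x_star` (dB), `beta` (winning slope value) and
#'   `peak` (winning posterior peak density).
#' @export
quest_best_guess <- function(state) {
  modes <- numeric(length(state$betas))
  peaks <- numeric(length(state$betas))
  for (b in seq_along(state$betas)) {
    post <- quest_posterior(state, b)
    i <- which.max(post)        # first maximum = lowest threshold on ties
    modes[b] <- state$grid[i]
    peaks[b] <- post[i]
  }
  best <- which(peaks == max(peaks))
  if (length(best) > 1) best <- best[which.min(modes[best])]
  list(x_star = modes[best], beta = state$betas[best], peak = peaks[best])
}

#' Place the next trial around the best guess
#'
#' The raw best guess is too greedy and can get stuck in local minima, so
#' placement is roved uniformly within +/- 5 dB of the best guess (a factor
#' of about 3.2 in pitch difference either way), clipped to the grid. The
#' sign of the trial's pitch difference is drawn equiprobably.
#'
#' @param x_star Current best guess, interval dB.
#' @param rove Half-width of the placement roving in dB.
#' @param grid_range Clipping range.
#' @return List with `x_db` (magnitude, dB) and `delta_sign` (+1/-1).
#' @export
place_next <- function(x_star, rove = 5, grid_range = c(-20, 20)) {
  x <- x_star + stats::runif(1, -rove, rove)
  list(
    x_db = min(max(x, grid_range[1]), grid_range[2]),
    delta_sign = sample(c(1L, -1L), 1)
  )
}

#' Simulated observer response to one 3I-2AFC trial
#'
#' The observer is correct with the probability given by its own Weibull
#' psychometric function, evaluated at the tested magnitude with the
#' threshold shifted by the up/down asymmetry offset for negative pitch
#' differences and by any per-vowel bias. Draws from the current RNG stream.
#'
#' @param observer An [observer_params()] object.
#' @param x_db Tested magnitude, interval dB.
#' @param delta_sign +1 or -1.
#' @param vowel Optional vowel label of the trial's stimulus.
#' @return Logical: correct response.
#' @export
simulate_response <- function(observer, x_db, delta_sign = 1L, vowel = NULL) {
  thr <- observer$true_threshold +
    if (delta_sign < 0) observer$updown_offset else 0
  if (!is.null(vowel) && vowel %in% names(observer$vowel_bias_db)) {
    thr <- thr + observer$vowel_bias_db[[vowel]]
  }
  eps <- calibrate_epsilon(observer$slope_beta, observer$guess_rate,
                           observer$lapse_rate)
  p <- weibull_p(x_db, thr, observer$slope_beta, observer$guess_rate,
                 observer$lapse_rate, eps)
  stats::runif(1) < p
}

#' Run the full Bayesian staircase on a simulated observer
#'
#' 210 trials of place -> respond -> update. Each trial's stimulus carries a
#' vowel label drawn uniformly (standing in for the random draw among the 80
#' baseline recordings). Returns the complete trial history, the final best
#' guess and its winning slope.
#'
#' @param observer An [observer_params()] object.
#' @param n_trials Number of trials (default 210).
#' @param seed Integer seed.
#' @param state Optionally a pre-built `quest_state` (e.g. with non-default
#'   grid or prior).
#' @return An object of class `staircase_result`: `history`,
#'   `final_best_guess` (dB), `winning_beta`, and the final `state`.
#' @export
run_staircase <- function(observer, n_trials = 210, seed = 1, state = NULL) {
  if (is.null(state)) state <- quest_init()
  x_db <- numeric(n_trials)
  delta_sign <- integer(n_trials)
  vowel <- character(n_trials)
  correct <- logical(n_trials)
  obs_eps <- calibrate_epsilon(observer$slope_beta, observer$guess_rate,
                               observer$lapse_rate)
  gr <- range(state$grid)
  lp <- state$log_posterior  # local copy: avoids copy-on-modify per trial
  nb <- length(state$betas)
  with_substream(seed, "staircase", {
    for (i in seq_len(n_trials)) {
      # best guess across the beta-specific posteriors (ties to lower x)
      modes <- numeric(nb); peaks <- numeric(nb)
      for (b in seq_len(nb)) {
        row <- lp[b, ]
        k <- which.max(row)
        modes[b] <- state$grid[k]
        peaks[b] <- 1 / sum(exp(row - row[k]))
      }
      best <- which(peaks == max(peaks))
      if (length(best) > 1) best <- best[which.min(modes[best])]
      pl <- place_next(modes[best], grid_range = gr)
      vw <- sample(c("a", "e", "o"), 1)
      thr <- observer$true_threshold + observer$vowel_bias_db[[vw]] +
        if (pl$delta_sign < 0) observer$updown_offset else 0
      corr <- stats::runif(1) < weibull_p(pl$x_db, thr, observer$slope_beta,
                                          observer$guess_rate,
                                          observer$lapse_rate, obs_eps)
      for (b in seq_len(nb)) {
        lp[b, ] <- lp[b, ] +
          .weibull_grid_ll(pl$x_db, state$grid, state$betas[b], state$gamma,
                           state$delta_lapse, state$epsilon[b], corr)
      }
      x_db[i] <- pl$x_db
      delta_sign[i] <- pl$delta_sign
      vowel[i] <- vw
      correct[i] <- corr
    }
  })
  state$log_posterior <- lp
  state$history <- data.frame(trial = seq_len(n_trials), x_db = x_db,
                              delta_sign = delta_sign, vowel = vowel,
                              correct = correct, stringsAsFactors = FALSE)
  final <- quest_best_guess(state)
  structure(
    list(history = state$history, final_best_guess = final$x_star,
         winning_beta = final$beta, state = state),
    class = "staircase_result"
  )
}

#' Practice block gate
#'
#' 20 practice trials at a fixed, clearly audible pitch difference of 4.8
#' semitones (10 upward, 10 downward). The test proper is only run for
#' observers who exceed 80% correct over the block.
#'
#' @param observer An [observer_params()] object.
#' @param seed Integer seed.
#' @param delta_semitones Practice pitch difference (default 4.8 semitones).
#' @return List with `pass` (logical) and `percent_correct`.
#' @export
practice_gate <- function(observer, seed = 1, delta_semitones = 4.8) {
  x <- semitones_to_db(delta_semitones)
  signs <- rep(c(1L, -1L), each = 10)
  correct <- with_substream(seed, "practice", {
    vapply(signs, function(s) simulate_response(observer, x, s), logical(1))
  })
  pc <- mean(correct)
  list(pass = pc > 0.8, percent_correct = 100 * pc)
}
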