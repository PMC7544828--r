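#' Post-hoc refit of one response direction
#'
#' After the staircase, the history is re-analysed separately for positive
#' and negative pitch differences over a finer parameter grid: lapse rates
#' 1-5% crossed with five slope values at 0.2 steps centered on the
#' staircase's final slope estimate (25 pairs in all). For each pair the full
#' grid posterior is recomputed from the sign-restricted trials (reusing the
#' staircase prior), and the pair whose posterior peak is highest wins; its
#' posterior mode is the direction's threshold, still denoting the 70.707%
#' point via per-pair epsilon calibration.
#'
#' @param history Staircase history data frame (`x_db`, `delta_sign`,
#'   `correct`, optionally `vowel`).
#' @param direction `"positive"` or `"negative"`.
#' @param final_beta Final slope estimate from the staircase.
#' @param deltas Candidate lapse rates.
#' @param state Optional `quest_state` supplying grid, prior, gamma and
#'   tracking point (defaults to the canonical configuration).
#' @return An object of class `directional_fit`: `direction`, `best_delta`,
#'   `best_beta`, `threshold` (dB), `peak`, `epsilon`, `gamma`, and the
#'   25-row `candidates` table.
#' @export
refit_direction <- function(history, direction = c("positive", "negative"),
                            final_beta, deltas = c(0.01, 0.02, 0.03, 0.04, 0.05),
                            state = NULL) {
  direction <- match.arg(direction)
  if (is.null(state)) state <- quest_init()
  sgn <- if (direction == "positive") 1L else -1L
  rows <- history[history$delta_sign == sgn, , drop = FALSE]
  if (nrow(rows) == 0) stop("no trials with ", direction, " pitch differences")
  betas <- final_beta + seq(-0.4, 0.4, by = 0.2)
  stopifnot(all(betas > 0))
  grid <- state$grid
  candidates <- expand.grid(delta_lapse = deltas, beta = betas,
                            KEEP.OUT.ATTRS = FALSE)
  candidates$epsilon <- mapply(calibrate_epsilon, candidates$beta,
                               MoreArgs = list(gamma = state$gamma,
                                               target_pc = state$target_pc),
                               delta_lapse = candidates$delta_lapse)
  scan <- .refit_scan_cpp(grid, state$log_prior, rows$x_db, rows$correct,
                          candidates$beta, candidates$delta_lapse,
                          candidates$epsilon, state$gamma)
  candidates$peak <- scan$peak
  candidates$threshold <- grid[scan$argmax]
  k <- order(-candidates$peak, candidates$threshold)[1]
  best <- list(beta = candidates$beta[k], delta_lapse = candidates$delta_lapse[k],
               threshold = candidates$threshold[k], peak = candidates$peak[k])
  structure(
    list(direction = direction, best_delta = best$delta_lapse,
         best_beta = best$beta, threshold = best$threshold, peak = best$peak,
         epsilon = calibrate_epsilon(best$beta, state$gamma, best$delta_lapse,
                                     state$target_pc),
         gamma = state$gamma, target_pc = state$target_pc,
         n_trials = nrow(rows), candidates = candidates),
    class = "directional_fit"
  )
}

# Percent-correct curve of a directional fit over a grid of levels.
fit_pc <- function(fit, x) {
  weibull_p(x, fit$threshold, fit$best_beta, fit$gamma, fit$best_delta,
            fit$epsilon)
}

#' Reconstruct the d-prime curve from the two directional fits
#'
#' Hit rates are read from the positive-direction fit and false-alarm rates
#' as 100% minus the negative-direction fit; both are clamped away from 0
#' and 1 and combined as `d'(x) = z(H(x)) - z(F(x))` with `z` the
#' standard-normal quantile.
#'
#' @param fit_pos,fit_neg [refit_direction()] results for the two signs.
#' @param grid Level grid in interval dB (defaults to the staircase grid).
#' @param clamp Clamping bounds for the rates.
#' @return An object of class `dprime_curve`: `grid`, `hit`, `fa`,
#'   `dprime`.
#' @export
dprime_curve <- function(fit_pos, fit_neg,
                         grid = seq(-2000, 2000) / 100,
                         clamp = c(0.001, 0.999)) {
  h <- pmin(pmax(fit_pc(fit_pos, grid), clamp[1]), clamp[2])
  f <- pmin(pmax(1 - fit_pc(fit_neg, grid), clamp[1]), clamp[2])
  structure(
    list(grid = grid, hit = h, fa = f,
         dprime = stats::qnorm(h) - stats::qnorm(f)),
    class = "dprime_curve"
  )
}

#' Extract the JND from a d-prime curve
#'
#' The final threshold is the smallest level at which the reconstructed
#' d-prime reaches the criterion (0.77, the 2AFC equivalent of the 70.707%
#' tracking point), linearly interpolated between grid points and converted
#' to cents.
#'
#' @param curve A [dprime_curve()].
#' @param criterion d-prime criterion.
#' @return List with `jnd_cents`, `jnd_db` and `status`: `"ok"`,
#'   `"at_edge"` (criterion already met at the lowest level) or
#'   `"unmeasurable"` (criterion never reached on the grid).
#' @export
extract_jnd <- function(curve, criterion = 0.77) {
  i <- which(curve$dprime >= criterion)[1]
  if (is.na(i)) {
    return(list(jnd_cents = NA_real_, jnd_db = NA_real_,
                status = "unmeasurable"))
  }
  if (i == 1L) {
    return(list(jnd_cents = db_to_cents(curve$grid[1]),
                jnd_db = curve$grid[1], status = "at_edge"))
  }
  x0 <- curve$grid[i - 1]; x1 <- curve$grid[i]
  d0 <- curve$dprime[i - 1]; d1 <- curve$dprime[i]
  x <- x0 + (criterion - d0) / (d1 - d0) * (x1 - x0)
  list(jnd_cents = db_to_cents(x), jnd_db = x, status = "ok")
}

#' Full post-hoc JND analysis of a staircase history
#'
#' Runs the 25-pair refit for each sign, reconstructs the d-prime curve and
#' extracts the JND at the criterion.
#'
#' @param result A [run_staircase()] result, or a history data frame (then
#'   `final_beta` must be given).
#' @param final_beta Final slope estimate; taken from `result` when omitted.
#' @param criterion d-prime criterion for the JND.
#' @return List with `fit_pos`, `fit_neg`, `curve`, `jnd_cents`, `jnd_db`,
#'   `status`.
#' @export
analyze_jnd <- function(result, final_beta = NULL, criterion = 0.77) {
  if (inherits(result, "staircase_result")) {
    history <- result$history
    if (is.null(final_beta)) final_beta <- result$winning_beta
  } else {
    history <- result
    if (is.null(final_beta)) stop("final_beta required with a raw history")
  }
  fp <- refit_direction(history, "positive", final_beta)
  fn <- refit_direction(history, "negative", final_beta)
  cv <- dprime_curve(fp, fn)
  j <- extract_jnd(cv, criterion)
  list(fit_pos = fp, fit_neg = fn, curve = cv,
       jnd_cents = j$jnd_cents, jnd_db = j$jnd_db, status = j$status)
}

#' Vowel-specific JNDs
#'
#' Re-runs the complete refit / d-prime / extraction pipeline on each
#' vowel's subset of the history.
#'
#' @inheritParams analyze_jnd
#' @param min_trials Minimum trials per vowel.
#' @return Named numeric vector of JNDs in cents for vowels a, e, o.
#' @export
vowel_specific_jnds <- function(result, final_beta = NULL, criterion = 0.77,
                                min_trials = 20) {
  if (inherits(result, "staircase_result")) {
    history <- result$history
    if (is.null(final_beta)) final_beta <- result$winning_beta
  } else {
    history <- result
    if (is.null(final_beta)) stop("final_beta required with a raw history")
  }
  vapply(c(a = "a", e = "e", o = "o"), function(vw) {
    sub <- history[!is.na(history$vowel) & history$vowel == vw, , drop = FALSE]
    if (nrow(sub) < min_trials) stop("vowel '", vw, "' underrepresented")
    analyze_jnd(sub, final_beta = final_beta, criterion = criterion)$jnd_cents
  }, numeric(1))
}
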