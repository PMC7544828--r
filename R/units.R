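#' Pitch-interval unit conversions
#'
#' The adaptive JND procedure works on a logarithmic "interval dB" scale in
#' which a pitch difference of `delta` semitones is expressed as
#' `10 * log10(delta)` dB. This has nothing to do with sound intensity: it
#' simply compresses the enormous usable range of pitch differences (1 cent to
#' 100 semitones, i.e. -20 dB to +20 dB) onto a scale on which a Gaussian
#' prior and a fixed-step grid are sensible.
#'
#' @param delta Pitch difference in semitones; must be positive.
#' @param x Pitch difference on the interval-dB scale.
#' @return `semitones_to_db()` returns dB; `db_to_semitones()` returns
#'   semitones; `db_to_cents()` returns cents (1 semitone = 100 cents).
#' @examples
#' semitones_to_db(12)   # 10.79 dB, one octave
#' db_to_semitones(-20)  # 0.01 semitones = 1 cent
#' @export
semitones_to_db <- function(delta) {
  if (any(!is.finite(delta)) || any(delta <= 0)) {
    stop("pitch differences must be positive and finite on the semitone scale")
  }
  10 * log10(delta)
}

#' @rdname semitones_to_db
#' @export
db_to_semitones <- function(x) 10^(x / 10)

#' @rdname semitones_to_db
#' @export
db_to_cents <- function(x) 100 * 10^(x / 10)

#' @rdname semitones_to_db
#' @export
cents_to_db <- function(cents) semitones_to_db(cents / 100)

#' Frequency ratio in cents
#'
#' `hz_to_cents(f, ref)` is `1200 * log2(f / ref)`: the musical distance of
#' `f` from `ref`, positive when `f` is higher. Antisymmetric in its
#' arguments.
#'
#' @param f,ref Frequencies in Hz; both must be positive.
#' @return Signed distance in cents.
#' @export
hz_to_cents <- function(f, ref) {
  if (any(!is.finite(c(f, ref))) || any(f <= 0) || any(ref <= 0)) {
    stop("frequencies must be positive and finite")
  }
  1200 * log2(f / ref)
}

#' @rdname hz_to_cents
#' @param cents Signed interval in cents.
#' @export
cents_to_hz <- function(cents, ref) {
  if (any(ref <= 0)) stop("reference frequency must be positive")
  ref * 2^(cents / 1200)
}

#' The d-prime criterion equivalent to 70.7% correct in 2AFC
#'
#' Under the standard signal-detection reading of a two-alternative forced
#' choice, a proportion correct of `pc` corresponds to a sensitivity of
#' `sqrt(2) * qnorm(pc)`. At the 70.707% tracking point of the staircase this
#' gives 0.7706, which rounds to the 0.77 criterion used to extract final
#' JNDs from the reconstructed d-prime curve.
#'
#' @param pc Proportion correct (default the staircase tracking point).
#' @return A d-prime value.
#' @export
dprime_criterion <- function(pc = 0.70707) sqrt(2) * stats::qnorm(pc)
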