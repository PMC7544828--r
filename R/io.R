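# Format doubles so that read-back reproduces them bit-exactly.
.fmt_num <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))

#' Write / read a session as a long-format CSV
#'
#' One row per 10-ms frame: `trial`, `phase`, `vowel`, `shift_cents`,
#' `time_s`, `f0_hz` (empty for unvoiced frames). Numeric fields are written
#' with enough digits for an exact round trip. Ground-truth generator
#' parameters, when present, go to a JSON sidecar via
#' [write_ground_truth_json()].
#'
#' @param session A `pitch_session`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_session_csv <- function(session, path) {
  rows <- lapply(seq_len(nrow(session$trials)), function(i) {
    tr <- session$tracks[[i]]
    data.frame(
      trial = session$trials$index[i],
      phase = session$trials$phase[i],
      vowel = session$trials$vowel[i],
      shift_cents = .fmt_num(session$trials$shift_cents[i]),
      time_s = .fmt_num((seq_along(tr) - 1L) * session$frame_step),
      f0_hz = .fmt_num(as.numeric(tr)),
      stringsAsFactors = FALSE
    )
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(what, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
}

#' @rdname write_session_csv
#' @param direction Shift direction to attach to the reloaded session.
#' @export
read_session_csv <- function(path, direction = "down") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(vowel = "character"))
  .require_columns(df, c("trial", "phase", "vowel", "shift_cents", "time_s",
                         "f0_hz"), "session CSV")
  split_rows <- split(df, df$trial)
  order_idx <- order(as.integer(names(split_rows)))
  split_rows <- split_rows[order_idx]
  tracks <- lapply(split_rows, function(d) as.numeric(d$f0_hz[order(d$time_s)]))
  first <- do.call(rbind, lapply(split_rows, function(d) d[1, , drop = FALSE]))
  trials <- data.frame(
    index = as.integer(first$trial), phase = first$phase,
    vowel = first$vowel, shift_cents = as.numeric(first$shift_cents),
    included = vapply(tracks, inclusion_filter, logical(1)),
    stringsAsFactors = FALSE
  )
  rownames(trials) <- NULL
  shift_mag <- max(abs(trials$shift_cents), 1e-9)
  structure(
    list(trials = trials, tracks = unname(tracks), frame_step = 0.01,
         direction = direction, shift_magnitude = shift_mag,
         ground_truth = NULL),
    class = "pitch_session"
  )
}

#' Ground-truth sidecar JSON for a synthetic session
#'
#' @param session A generated `pitch_session`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_json <- function(session, path) {
  gt <- session$ground_truth
  if (is.null(gt)) stop("session carries no ground truth")
  payload <- list(
    direction = gt$direction, shift_magnitude = gt$shift_magnitude,
    seed = gt$seed, speaker = unclass(gt$speaker),
    response_cents = gt$response_cents
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read a staircase history CSV
#'
#' Columns: `trial`, `x_db`, `delta_sign`, `vowel`, `correct`.
#'
#' @param history Staircase history data frame.
#' @param path CSV path.
#' @return `path` (write) or the history data frame (read).
#' @export
write_history_csv <- function(history, path) {
  .require_columns(history, c("trial", "x_db", "delta_sign", "vowel",
                              "correct"), "history")
  out <- history
  out$x_db <- .fmt_num(out$x_db)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_history_csv
#' @export
read_history_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(vowel = "character"))
  .require_columns(df, c("trial", "x_db", "delta_sign", "vowel", "correct"),
                   "history CSV")
  df$x_db <- as.numeric(df$x_db)
  df$delta_sign <- as.integer(df$delta_sign)
  df$correct <- as.logical(df$correct)
  df
}

#' Write / read structured results as JSON
#'
#' Reading accepts unknown extra keys with a warning, for forward
#' compatibility.
#'
#' @param x A list of results.
#' @param path JSON path.
#' @param expected Optional character vector of known keys for the reader.
#' @return `path` (write) or the parsed list (read).
#' @export
write_results_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_results_json
#' @export
read_results_json <- function(path, expected = NULL) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(expected)) {
    extra <- setdiff(names(x), expected)
    if (length(extra) > 0) {
      warning("ignoring unknown key(s): ", paste(extra, collapse = ", "))
    }
  }
  x
}
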