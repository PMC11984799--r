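# Device synchronization: TTL pulse schedules, dropped-frame detection and
# post hoc alignment of behavioral events to recorded frame pulses.

#' Generate a TTL pulse schedule
#'
#' Timestamps 0, 1/rate, 2/rate, ... strictly below `duration`; e.g. the
#' continuous 30 Hz camera-trigger signal.
#'
#' @param rate pulse rate in Hz (> 0).
#' @param duration schedule duration in seconds (>= 0).
#' @return object of class `pulse_schedule` with fields `rate`, `timestamps`.
#' @export
generate_schedule <- function(rate, duration) {
  assert_that(is_scalar_number(rate) && rate > 0, "rate must be > 0")
  assert_that(is_scalar_number(duration) && duration >= 0,
              "duration must be >= 0")
  x <- round(duration * rate, 9)
  n <- if (x == floor(x)) as.integer(x) else ceiling(x) # pulses in [0, duration)
  structure(list(rate = rate, timestamps = (seq_len(n) - 1L) / rate),
            class = "pulse_schedule")
}

#' Construct a pulse log from received timestamps
#'
#' @param timestamps non-decreasing seconds.
#' @param nominal_rate expected pulse rate in Hz.
#' @return object of class `pulse_log`.
#' @export
pulse_log <- function(timestamps, nominal_rate) {
  assert_that(length(timestamps) == 0L || all(diff(timestamps) >= 0),
              "pulse timestamps must be non-decreasing")
  assert_that(is_scalar_number(nominal_rate) && nominal_rate > 0,
              "nominal_rate must be > 0")
  structure(list(timestamps = as.numeric(timestamps),
                 nominal_rate = nominal_rate),
            class = "pulse_log")
}

#' Read a pulse log from a single-column text/CSV file of seconds
#'
#' @param path file path; one timestamp (seconds) per line, optional header.
#' @param nominal_rate expected rate in Hz.
#' @return a [pulse_log()].
#' @export
read_pulse_log <- function(path, nominal_rate) {
  assert_that(file.exists(path), "no such file: ", path)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  vals <- suppressWarnings(as.numeric(lines))
  if (length(vals) && is.na(vals[1L])) vals <- vals[-1L] # header
  assert_that(!anyNA(vals), "non-numeric pulse timestamps in ", path)
  pulse_log(vals, nominal_rate)
}

#' Detect dropped frames in a pulse log
#'
#' A gap g between consecutive pulses longer than 1.5 nominal intervals
#' implies `round(g * nominal_rate) - 1` missing frames at that position.
#' Jitter within +/-20% of nominal never triggers.
#'
#' @param log a [pulse_log()].
#' @return data.frame with columns `index` (gap follows this pulse),
#'   `gap` (s), `n_missing`; zero rows when nothing was dropped or the log
#'   has fewer than 2 timestamps.
#' @export
detect_dropped <- function(log) {
  stopifnot(inherits(log, "pulse_log"))
  empty <- data.frame(index = integer(0), gap = numeric(0),
                      n_missing = integer(0))
  if (length(log$timestamps) < 2L) return(empty)
  gaps <- diff(log$timestamps)
  bad <- which(gaps > 1.5 / log$nominal_rate)
  if (!length(bad)) return(empty)
  data.frame(index = bad, gap = gaps[bad],
             n_missing = as.integer(round(gaps[bad] * log$nominal_rate) - 1))
}

#' Align event times to recorded frame pulses
#'
#' Maps each event to the index (1-based) of the nearest pulse timestamp;
#' exact midpoints take the earlier index. Events outside the log's span
#' (before the first or after the last pulse by more than one nominal
#' interval) are flagged.
#'
#' @param event_times event times in seconds.
#' @param log a non-empty [pulse_log()].
#' @return data.frame with columns `time`, `frame`, `offset` (event minus
#'   pulse time) and `in_span`.
#' @export
align_events <- function(event_times, log) {
  stopifnot(inherits(log, "pulse_log"))
  ts <- log$timestamps
  assert_that(length(ts) > 0, "empty pulse log")
  lo <- findInterval(event_times, ts)
  frame <- integer(length(event_times))
  for (i in seq_along(event_times)) {
    if (lo[i] == 0L) {
      frame[i] <- 1L
    } else if (lo[i] >= length(ts)) {
      frame[i] <- length(ts)
    } else {
      d_lo <- event_times[i] - ts[lo[i]]
      d_hi <- ts[lo[i] + 1L] - event_times[i]
      frame[i] <- if (d_lo <= d_hi) lo[i] else lo[i] + 1L # tie -> earlier
    }
  }
  offset <- event_times - ts[frame]
  in_span <- event_times >= ts[1L] - 1 / log$nominal_rate &
    event_times <= ts[length(ts)] + 1 / log$nominal_rate
  data.frame(time = event_times, frame = frame, offset = offset,
             in_span = in_span)
}
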