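# Quadrature encoder decoding and wheel-trace geometry.
#
# The steering wheel position is read by a rotary encoder (1,024 pulses per
# revolution). Decoding uses x1 counting - one count per full quadrature pulse
# period, registered on the rising edge of channel A with direction taken from
# the level of channel B - so one revolution is exactly 1,024 counts and the
# angular quantum is 360/PPR degrees. Positions are event-driven step
# functions; traces are resampled to a uniform 100 Hz grid by
# last-observation-carried-forward.

WHEEL_DT <- 0.01 # 100 Hz grid

#' Construct a quadrature encoder stream
#'
#' @param time edge timestamps in seconds (non-decreasing).
#' @param channel `"A"` or `"B"` per edge.
#' @param level logic level 0/1 after the edge.
#' @param ppr pulses per revolution (default 1024).
#' @return object of class `encoder_stream`.
#' @export
encoder_stream <- function(time = numeric(0), channel = character(0),
                           level = integer(0), ppr = 1024) {
  assert_that(length(time) == length(channel) && length(time) == length(level),
              "time, channel, level must have equal length")
  if (length(time) > 1L && any(diff(time) < 0)) {
    stop_input("encoder timestamps must be non-decreasing")
  }
  assert_that(all(channel %in% c("A", "B")), "channel must be 'A' or 'B'")
  assert_that(all(level %in% c(0L, 1L)), "level must be 0 or 1")
  structure(list(time = as.numeric(time), channel = as.character(channel),
                 level = as.integer(level), ppr = ppr),
            class = "encoder_stream")
}

#' Construct a 100 Hz wheel trace
#'
#' Angle is cumulative (unwrapped) signed degrees: positive = rightward turn.
#'
#' @param time uniform 100 Hz timestamps in seconds.
#' @param angle signed cumulative angle in degrees.
#' @return object of class `wheel_trace`.
#' @export
wheel_trace <- function(time, angle) {
  assert_that(length(time) == length(angle), "time and angle lengths differ")
  if (length(time) > 1L) {
    assert_that(max(abs(diff(time) - WHEEL_DT)) < 1e-6,
                "wheel_trace requires a uniform 100 Hz grid")
  }
  structure(list(time = as.numeric(time), angle = as.numeric(angle)),
            class = "wheel_trace")
}

#' @export
print.wheel_trace <- function(x, ...) {
  cat(sprintf("<wheel_trace: %d samples @ 100 Hz, span [%.2f, %.2f] s>\n",
              length(x$time),
              if (length(x$time)) min(x$time) else NA_real_,
              if (length(x$time)) max(x$time) else NA_real_))
  invisible(x)
}

#' Decode a quadrature stream into a wheel trace
#'
#' x1 counting: on each rising edge of channel A the count moves +1 if B is
#' low (A leads B, rightward) and -1 if B is high. Angle per count is
#' `360/ppr` degrees. The step-function position is resampled to the 100 Hz
#' grid by last-observation-carried-forward, starting at 0 degrees at t = 0.
#'
#' @param stream an [encoder_stream()].
#' @param duration trace duration in seconds; defaults to the last edge time.
#' @return a [wheel_trace()].
#' @export
decode_quadrature <- function(stream, duration = NULL) {
  stopifnot(inherits(stream, "encoder_stream"))
  if (is.null(duration)) {
    duration <- if (length(stream$time)) max(stream$time) else 0
  }
  grid <- seq(0, duration + 1e-9, by = WHEEL_DT)
  n_edges <- length(stream$time)
  if (n_edges == 0L) return(wheel_trace(grid, numeric(length(grid))))
  quantum <- 360 / stream$ppr
  b_level <- 0L
  count_t <- numeric(n_edges)
  count_v <- numeric(n_edges)
  k <- 0L
  count <- 0
  for (i in seq_len(n_edges)) {
    if (stream$channel[i] == "B") {
      b_level <- stream$level[i]
    } else if (stream$level[i] == 1L) { # rising edge of A
      count <- count + if (b_level == 0L) 1 else -1
      k <- k + 1L
      count_t[k] <- stream$time[i]
      count_v[k] <- count
    }
  }
  angle_steps <- c(0, count_v[seq_len(k)] * quantum)
  step_times <- count_t[seq_len(k)]
  idx <- findInterval(grid + 1e-12, step_times) + 1L
  wheel_trace(grid, angle_steps[idx])
}

#' Synthesize a quadrature stream from an angle profile
#'
#' Inverse of [decode_quadrature()] up to one angular quantum: quantizes the
#' profile to quarter-pulse positions and emits the Gray-code edge sequence a
#' real encoder would produce.
#'
#' @param time sample times of the profile (seconds, increasing).
#' @param angle cumulative angle in degrees at those times.
#' @param ppr pulses per revolution.
#' @return an [encoder_stream()].
#' @export
encode_quadrature <- function(time, angle, ppr = 1024) {
  assert_that(length(time) == length(angle) && length(time) >= 1L,
              "time and angle must be equal-length, non-empty")
  qstep <- 360 / (4 * ppr)
  pos <- round(angle / qstep)
  # Gray states per quarter position (forward): (A,B) = 00,10,11,01
  a_of <- c(0L, 1L, 1L, 0L)
  b_of <- c(0L, 0L, 1L, 1L)
  times <- list(); chans <- list(); levels <- list()
  for (i in seq_len(length(pos) - 1L)) {
    d <- pos[i + 1L] - pos[i]
    if (d == 0) next
    steps <- seq(pos[i] + sign(d), pos[i + 1L], by = sign(d))
    frac <- (seq_along(steps)) / (length(steps) + 1)
    tt <- time[i] + frac * (time[i + 1L] - time[i])
    prev <- c(pos[i], head(steps, -1L))
    pm <- ((steps %% 4) + 4) %% 4 + 1L
    qm <- ((prev %% 4) + 4) %% 4 + 1L
    a_new <- a_of[pm]; b_new <- b_of[pm]
    a_old <- a_of[qm]; b_old <- b_of[qm]
    ch <- ifelse(a_new != a_old, "A", "B")
    lv <- ifelse(a_new != a_old, a_new, b_new)
    times[[length(times) + 1L]] <- tt
    chans[[length(chans) + 1L]] <- ch
    levels[[length(levels) + 1L]] <- lv
  }
  encoder_stream(unlist(times) %||% numeric(0),
                 unlist(chans) %||% character(0),
                 unlist(levels) %||% integer(0), ppr = ppr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Angular velocity of a wheel trace
#'
#' Central differences on the 100 Hz grid, one-sided at the boundaries.
#'
#' @param trace a [wheel_trace()] with at least 2 samples.
#' @return numeric vector of velocities in degrees/s on the same grid.
#' @export
angular_velocity <- function(trace) {
  stopifnot(inherits(trace, "wheel_trace"))
  n <- length(trace$angle)
  assert_that(n >= 2L, "angular_velocity needs at least 2 samples")
  a <- trace$angle
  v <- numeric(n)
  v[1L] <- (a[2L] - a[1L]) / WHEEL_DT
  v[n] <- (a[n] - a[n - 1L]) / WHEEL_DT
  if (n > 2L) {
    v[2:(n - 1L)] <- (a[3:n] - a[1:(n - 2L)]) / (2 * WHEEL_DT)
  }
  v
}

#' Detect satisfaction of the pre-stimulus quiescence requirement
#'
#' The animal must refrain from turning for `required_duration` seconds
#' (drawn by the caller, uniform on \[1.0, 1.5\] s in the tasks), allowing a
#' positional jitter of `jitter_tolerance` degrees relative to the angle at
#' the start of the running window. An excursion beyond tolerance restarts
#' the window at the excursion sample.
#'
#' @param trace a [wheel_trace()].
#' @param start_time earliest window start in seconds.
#' @param required_duration quiet duration required, seconds.
#' @param jitter_tolerance degrees of allowed jitter (default 2).
#' @return the earliest satisfaction time in seconds, or `NA_real_` if the
#'   trace ends before the requirement is met ("pending").
#' @export
detect_quiescence <- function(trace, start_time, required_duration,
                              jitter_tolerance = 2) {
  stopifnot(inherits(trace, "wheel_trace"))
  assert_that(is_scalar_number(required_duration) && required_duration > 0,
              "required_duration must be > 0")
  i0 <- which(trace$time >= start_time - 1e-9)[1L]
  if (is.na(i0)) return(NA_real_)
  n <- length(trace$time)
  a <- trace$angle
  anchor <- i0
  i <- i0
  while (i < n) {
    i <- i + 1L
    if (abs(a[i] - a[anchor]) > jitter_tolerance) {
      anchor <- i
    } else if (trace$time[i] - trace$time[anchor] >= required_duration - 1e-9) {
      return(trace$time[i])
    }
  }
  NA_real_
}

#' Detect a turning-goal crossing
#'
#' Finds the earliest time in `[origin_time, deadline]` at which the absolute
#' displacement from the angle at `origin_time` reaches `goal` degrees.
#'
#' @param trace a [wheel_trace()].
#' @param origin_time reference time (stimulus onset), seconds.
#' @param goal turning goal in degrees (> 0).
#' @param deadline end of the response window, seconds.
#' @return `NULL` if no crossing, else `list(time=, direction=)` with
#'   direction `"right"` (positive displacement) or `"left"`.
#' @export
detect_goal_crossing <- function(trace, origin_time, goal, deadline) {
  stopifnot(inherits(trace, "wheel_trace"))
  assert_that(is_scalar_number(goal) && goal > 0, "goal must be > 0")
  i0 <- which(trace$time >= origin_time - 1e-9)[1L]
  if (is.na(i0)) return(NULL)
  sel <- i0:length(trace$time)
  sel <- sel[trace$time[sel] <= deadline + 1e-9]
  if (!length(sel)) return(NULL)
  disp <- trace$angle[sel] - trace$angle[i0]
  hit <- which(abs(disp) >= goal - 1e-9)
  if (!length(hit)) return(NULL)
  j <- hit[1L]
  list(time = trace$time[sel[j]],
       direction = if (disp[j] > 0) "right" else "left")
}

#' Accumulated (path-length) wheel turning
#'
#' Sum of absolute per-sample angle increments over `[t0, t1]` - total path
#' length in both directions, not net displacement. Used to quantify
#' pre-stimulus turning (a putative impulsivity measure).
#'
#' @param trace a [wheel_trace()].
#' @param t0,t1 interval bounds in seconds, `t0 <= t1`.
#' @return accumulated turning in degrees.
#' @export
accumulated_turning <- function(trace, t0, t1) {
  stopifnot(inherits(trace, "wheel_trace"))
  assert_that(t1 >= t0, "t1 must be >= t0")
  sel <- which(trace$time >= t0 - 1e-9 & trace$time <= t1 + 1e-9)
  if (length(sel) < 2L) return(0)
  sum(abs(diff(trace$angle[sel])))
}
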