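# Synthetic mouse agents.
#
# An agent is a stationary stochastic policy with psychometric ground truth:
# its probability of choosing "right" at signed stimulus strength x follows
# the same error-function model the analysis module fits,
#   P(x) = lapse1 + (1 - lapse1 - lapse2) * (erf((x - bias)/slope) + 1) / 2,
# so psychometric fits on engine output can be validated against known
# parameters (parameter recovery). Motor behavior (reaction times, turn
# amplitude, impulsive pre-stimulus bursts, quiescence compliance,
# disengagement) is parameterized separately.

AGENT_FIELDS <- c("bias", "slope", "lapse1", "lapse2", "rt_median", "rt_sigma",
                  "response_prob", "amp_mean", "amp_sd", "turn_speed",
                  "impulsivity", "impulsivity_cv", "burst_peak", "burst_dur",
                  "quiescence_compliance",
                  "disengage_after_min", "disengage_rt_scale")

agent_defaults <- function() {
  list(
    bias = 0,            # psychometric bias, stimulus-strength %
    slope = 10,          # psychometric slope (width), stimulus-strength %
    lapse1 = 0,          # P(right) floor as x -> -Inf
    lapse2 = 0,          # 1 - P(right) ceiling as x -> +Inf
    rt_median = 0.35,    # s, log-normal reaction time median
    rt_sigma = 0.2,      # log-normal sigma
    response_prob = 1,   # probability of producing any response
    amp_mean = 60,       # deg, mean deliberate turn amplitude
    amp_sd = 8,          # deg
    turn_speed = 400,    # deg/s during a deliberate turn
    impulsivity = 0,     # spontaneous burst rate, bursts/s (0 = none)
    impulsivity_cv = 0.5,    # log-sd of the per-trial impulsivity gain
    burst_peak = c(20, 60),  # deg/s, uniform range of burst peak velocity
    burst_dur = c(0.1, 0.3), # s, uniform range of burst duration
    quiescence_compliance = 1, # probability a trial has no spontaneous bursts
    disengage_after_min = Inf, # session minute after which RTs slow down
    disengage_rt_scale = 5     # RT median multiplier once disengaged
  )
}

AGENT_PROFILES <- list(
  ideal = list(slope = 5),
  lapsing = list(lapse1 = 0.1, lapse2 = 0.1, slope = 15),
  biased = list(bias = 30, slope = 15, lapse1 = 0.05, lapse2 = 0.05),
  impulsive = list(slope = 15, impulsivity = 1.5, impulsivity_cv = 0.6,
                   burst_peak = c(60, 140), burst_dur = c(0.2, 0.4),
                   quiescence_compliance = 0.4),
  disengaging = list(slope = 5, disengage_after_min = 40),
  never_responding = list(response_prob = 0)
)

#' Construct an agent policy from a named profile
#'
#' Profiles: `ideal` (no lapses, steep psychometric curve, always responds),
#' `lapsing` (10% lapses each side), `biased` (rightward psychometric bias),
#' `impulsive` (no lapses, but spontaneous pre-stimulus wheel bursts and
#' partial quiescence compliance, so errors arise from impulsivity alone), `disengaging` (reaction times slow 5-fold after 40 min,
#' tripping the 2AFC disengagement rule), `never_responding`.
#'
#' @param profile profile name.
#' @param overrides named list of fields to override (see
#'   [agent_policy()] field list).
#' @return object of class `agent_policy`.
#' @export
make_agent <- function(profile = "ideal", overrides = list()) {
  assert_that(is.character(profile) && length(profile) == 1L &&
                profile %in% names(AGENT_PROFILES),
              "unknown agent profile: ", profile)
  pol <- modifyList(agent_defaults(), AGENT_PROFILES[[profile]])
  do.call(agent_policy, modifyList(pol, as.list(overrides)))
}

#' Construct an agent policy from explicit parameters
#'
#' @param ... fields overriding the defaults; see the source of
#'   `agent_defaults()` for the complete list and units.
#' @return object of class `agent_policy`.
#' @export
agent_policy <- function(...) {
  pol <- modifyList(agent_defaults(), list(...))
  extra <- setdiff(names(pol), AGENT_FIELDS)
  assert_that(length(extra) == 0L,
              "unknown agent fields: ", paste(extra, collapse = ", "))
  assert_that(pol$slope > 0, "slope must be > 0")
  assert_that(pol$lapse1 >= 0 && pol$lapse1 <= 0.5 &&
                pol$lapse2 >= 0 && pol$lapse2 <= 0.5,
              "lapse rates must be in [0, 0.5]")
  assert_that(pol$response_prob >= 0 && pol$response_prob <= 1,
              "response_prob must be in [0, 1]")
  assert_that(pol$quiescence_compliance >= 0 && pol$quiescence_compliance <= 1,
              "quiescence_compliance must be in [0, 1]")
  structure(pol, class = "agent_policy")
}

#' Ground-truth choice probability of an agent
#'
#' @param policy an `agent_policy`.
#' @param x signed stimulus strength in \[-100, 100\] (negative = left-rewarded).
#' @return probability of a rightward choice under the policy's true
#'   psychometric parameters.
#' @export
agent_p_right <- function(policy, x) {
  stopifnot(inherits(policy, "agent_policy"))
  psychometric_value(list(lapse1 = policy$lapse1, lapse2 = policy$lapse2,
                          bias = policy$bias, slope = policy$slope), x)
}

#' Draw an agent's choice and reaction time for one trial
#'
#' The agent responds at all with probability `response_prob`; a response is
#' rightward with probability P(x) under the policy's true parameters, and
#' its reaction time is log-normal. For Go/NoGo and detection the engine
#' passes a Go-evidence value for `x` (+100 Go / -100 NoGo) and reads
#' `"right"` as "respond". `signed_strength = NA` draws an unbiased coin for
#' the direction (pure detection).
#'
#' @param policy an `agent_policy`.
#' @param signed_strength signed stimulus strength in \[-100, 100\], or NA.
#' @param now_min current session time in minutes (drives disengagement).
#' @return `list(direction=, rt=)`; `direction` is `"right"`, `"left"` or
#'   `NA_character_` (no response, rt also NA).
#' @export
choose_response <- function(policy, signed_strength, now_min = 0) {
  stopifnot(inherits(policy, "agent_policy"))
  if (stats::runif(1) >= policy$response_prob) {
    return(list(direction = NA_character_, rt = NA_real_))
  }
  p_right <- if (is.na(signed_strength)) 0.5 else {
    assert_that(signed_strength >= -100 && signed_strength <= 100,
                "signed_strength must be in [-100, 100]")
    agent_p_right(policy, signed_strength)
  }
  direction <- if (stats::runif(1) < p_right) "right" else "left"
  scale <- if (now_min > policy$disengage_after_min) policy$disengage_rt_scale else 1
  rt <- stats::rlnorm(1, meanlog = log(policy$rt_median * scale),
                      sdlog = policy$rt_sigma)
  list(direction = direction, rt = rt)
}

# Spontaneous (stimulus-independent) burst velocity over [0, horizon].
# A per-trial impulsivity gain g (log-normal) scales both the burst rate and
# burst vigor; this trait/state variability is what couples accumulated
# pre-stimulus turning to post-onset crossing latency on false-alarm trials.
impulsive_velocity <- function(policy, horizon, dt = WHEEL_DT) {
  n <- ceiling(horizon / dt) + 1L
  v <- numeric(n)
  g <- stats::rlnorm(1, 0, policy$impulsivity_cv)
  rate <- policy$impulsivity * g
  t <- stats::rexp(1, rate)
  while (t < horizon) {
    dur <- stats::runif(1, policy$burst_dur[1], policy$burst_dur[2])
    peak <- stats::runif(1, policy$burst_peak[1], policy$burst_peak[2]) *
      g * sample(c(-1, 1), 1)
    i0 <- floor(t / dt) + 1L
    len <- max(2L, round(dur / dt))
    idx <- i0:min(n, i0 + len - 1L)
    kernel <- sin(pi * seq_along(idx) / (len + 1)) * peak
    v[idx] <- v[idx] + kernel
    t <- t + dur + stats::rexp(1, rate)
  }
  v
}

#' Render an agent's wheel trace for one trial
#'
#' Produces a causal 100 Hz trace covering the pre-stimulus (quiescence) epoch
#' and the response window. Spontaneous bursts are generated without knowledge
#' of the stimulus; the engine determines stimulus onset by running the
#' quiescence detector on this trace. A deliberate turn (if the decision has a
#' direction) is a constant-velocity ramp timed so the turning goal is crossed
#' at `onset + rt`, holding at an amplitude drawn above the goal.
#'
#' @param policy an `agent_policy`.
#' @param decision output of [choose_response()].
#' @param quiescence_duration required quiet window, seconds.
#' @param response_window response window after onset, seconds.
#' @param goal turning goal in degrees.
#' @param turn_direction physical turn direction, `"right"`/`"left"`/NA. For
#'   2AFC this equals `decision$direction`; for detection/Go-NoGo the engine
#'   draws it uniformly when the agent responds.
#' @param max_prestim cap on the pre-stimulus epoch, seconds.
#' @return `list(trace=, onset=)`: trial-local [wheel_trace()] starting at
#'   t = 0 and the stimulus onset time (quiescence satisfaction), or onset NA
#'   if quiescence was never achieved within `max_prestim`.
#' @export
render_trace <- function(policy, decision, quiescence_duration,
                         response_window, goal, turn_direction = NULL,
                         max_prestim = 60) {
  stopifnot(inherits(policy, "agent_policy"))
  if (is.null(turn_direction)) turn_direction <- decision$direction
  dt <- WHEEL_DT
  # Spontaneous bursts are drawn before (and independently of) the stimulus,
  # keeping the pre-stimulus trace causal. Burst-free trials get a horizon
  # just covering quiescence + response window.
  bursty <- policy$impulsivity > 0 &&
    stats::runif(1) >= policy$quiescence_compliance
  horizon <- if (bursty) {
    max_prestim + response_window + 1
  } else {
    quiescence_duration + response_window + 1
  }
  v <- if (bursty) {
    impulsive_velocity(policy, horizon, dt)
  } else {
    numeric(ceiling(horizon / dt) + 1L)
  }
  angle <- cumsum(v) * dt
  time <- (seq_along(angle) - 1L) * dt
  pre <- wheel_trace(time, angle)
  onset <- detect_quiescence(pre, 0, quiescence_duration)
  if (is.na(onset) || onset > max_prestim) {
    return(list(trace = pre, onset = NA_real_))
  }
  if (!is.na(turn_direction) && !is.na(decision$rt)) {
    amp <- max(goal * 1.2, stats::rnorm(1, policy$amp_mean, policy$amp_sd))
    t_cross <- goal / policy$turn_speed # time from turn start to goal
    t_start <- onset + max(dt, decision$rt - t_cross)
    sgn <- if (turn_direction == "right") 1 else -1
    rel <- time - t_start
    turn <- pmin(pmax(rel, 0) * policy$turn_speed, amp) * sgn
    angle <- angle + turn
  }
  n_keep <- min(length(time), ceiling((onset + response_window + 0.5) / dt) + 1L)
  list(trace = wheel_trace(time[seq_len(n_keep)], angle[seq_len(n_keep)]),
       onset = onset)
}
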