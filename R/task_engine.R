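# Event-driven trial/session state machines for the four tasks.
#
# Sessions run on a simulated clock advanced by events, so a 90-minute session
# executes in seconds and every timestamp is exact. Phase transitions are
# separated by one 10 ms scheduler tick; configured durations (ITI, timeout,
# noise) appear in the event log exactly.

ENGINE_TICK <- 0.01

#' Task configuration
#'
#' Builds the per-task, per-stage parameter set: turning goal, reward size,
#' stimulus strengths, response window, and timing constants. Defaults follow
#' the staged training protocol: detection/Go-NoGo use a 1.02 s response
#' window (two 0.51 s cloud presentations) and a 60 min session cap; 2AFC
#' uses a 15 s window and a 90 min cap. All tasks share a 0.5 s ITI, 1.5 s
#' timeout, 0.5 s noise punishment and a 1.0--1.5 s quiescence requirement.
#'
#' @param task `"pretraining"`, `"detection"`, `"gonogo"` or `"2afc"`.
#' @param stage stage index (detection/gonogo: 0--1; 2afc: 0--4;
#'   pretraining: session index 1--3, setting the 15/30/45 min duration).
#' @param reward_size reward in microliters; default 5 (detection/gonogo,
#'   pretraining) or 3 (2afc).
#' @param go_stimulus Go/NoGo only: which octave (`"low"`/`"high"`) is the Go
#'   stimulus.
#' @param side_map 2AFC only: named character mapping
#'   `c(high = "right"/"left", low = ...)` from dominant octave to correct
#'   turn direction.
#' @param reward_multiplier named numeric `c(left=, right=)` applied to the
#'   reward for the corresponding turn direction (intersession debiasing).
#' @param ... overrides for timing fields (`response_window`, `iti`,
#'   `timeout`, `noise_punish_duration`, `quiescence_range`, `session_min`,
#'   `session_cap`, `stim_duration`, `turning_goal`, `strengths`,
#'   `jitter_tolerance`).
#' @return object of class `task_config`.
#' @export
task_config <- function(task = c("detection", "gonogo", "2afc", "pretraining"),
                        stage = 0, reward_size = NULL,
                        go_stimulus = "low",
                        side_map = c(high = "right", low = "left"),
                        reward_multiplier = c(left = 1, right = 1), ...) {
  task <- match.arg(task)
  is2afc <- task == "2afc"
  cfg <- list(
    task = task,
    stage = stage,
    stim_duration = if (task == "pretraining") 2.04 else 0.51,
    response_window = if (is2afc) 15 else if (task == "pretraining") 2.04 else 1.02,
    iti = 0.5,
    timeout = 1.5,
    noise_punish_duration = 0.5,
    quiescence_range = c(1.0, 1.5),
    jitter_tolerance = 2,
    session_min = 45,
    session_cap = if (is2afc) 90 else 60,
    turning_goal = if (stage == 0) 15 else 30,
    strengths = 100,
    reward_size = reward_size %||% if (is2afc) 3 else 5,
    reward_multiplier = reward_multiplier,
    go_stimulus = match.arg(go_stimulus, c("low", "high")),
    side_map = side_map
  )
  if (is2afc) {
    cfg$strengths <- switch(as.character(stage),
                            "0" = 100, "1" = 100, "2" = c(100, 85),
                            "3" = c(100, 85, 70), "4" = c(100, 85, 70, 60),
                            stop_input("unknown 2afc stage: ", stage))
  } else if (task %in% c("detection", "gonogo")) {
    assert_that(stage %in% 0:1, "unknown ", task, " stage: ", stage)
  } else { # pretraining
    assert_that(stage %in% 1:3, "pretraining session index must be 1..3")
    cfg$session_cap <- c(15, 30, 45)[stage]
    cfg$session_min <- cfg$session_cap
    cfg$turning_goal <- 30 # unused; wheel immobilized
  }
  cfg <- modifyList(cfg, list(...))
  assert_that(cfg$response_window >= cfg$stim_duration,
              "response_window must cover one stimulus presentation")
  assert_that(task == "pretraining" || cfg$session_cap > cfg$session_min,
              "session_cap must exceed session_min")
  assert_that(all(sort(names(cfg$side_map)) == c("high", "low")) &&
                all(cfg$side_map %in% c("left", "right")),
              "side_map must map high/low to left/right")
  structure(cfg, class = "task_config")
}

#' Create mutable within-session state
#'
#' @param config a [task_config()].
#' @return environment tracking the virtual clock, trial history and
#'   pseudorandomization state. Used by [run_trial()]/[run_session()].
#' @export
new_session_state <- function(config) {
  st <- new.env(parent = emptyenv())
  st$now <- 0
  st$n <- 0L
  st$trials <- list()
  st$events_time <- list()
  st$events_name <- list()
  st$events_trial <- list()
  st$total_reward <- 0
  st$block_side <- NULL # 2afc stage 0
  st$block_streak <- 0L
  st$last_types <- character(0) # gonogo repeat limiter
  st$last_stim <- NULL # 2afc repeat-on-error
  st$last_outcome <- NA_character_
  st$rt_hist <- numeric(0) # per-trial RT (NA = no goal crossing)
  st
}

#' Draw the next stimulus under the task's pseudorandomization rules
#'
#' Go/NoGo: uniform Go/NoGo with at most 3 identical consecutive trial types.
#' 2AFC stage 0: alternating high/low blocks, switching after 3 consecutive
#' correct trials. 2AFC stages 1--3: pseudorandom side with equal-proportion
#' strengths and repeat-after-error debiasing (an incorrect trial is followed
#' by the same stimulus). Stage 4: no repeat-after-error. Detection and
#' pretraining always present 100% middle-octave clouds.
#'
#' @param config a [task_config()].
#' @param state session state from [new_session_state()].
#' @return `list(strength=, dominant=, go=, side=)`; `go` is a logical for
#'   Go/NoGo, `side` the correct turn direction for 2AFC (else NA).
#' @export
next_stimulus <- function(config, state) {
  task <- config$task
  if (task %in% c("detection", "pretraining")) {
    return(list(strength = 100, dominant = "middle", go = NA, side = NA_character_))
  }
  if (task == "gonogo") {
    go <- stats::runif(1) < 0.5
    lt <- state$last_types
    if (length(lt) >= 3L) {
      l3 <- tail(lt, 3L)
      if (all(l3 == "go")) go <- FALSE
      if (all(l3 == "nogo")) go <- TRUE
    }
    dominant <- if (go) config$go_stimulus else setdiff(c("low", "high"), config$go_stimulus)
    return(list(strength = 100, dominant = dominant, go = go, side = NA_character_))
  }
  # 2afc
  if (config$stage == 0) {
    if (is.null(state$block_side)) {
      state$block_side <- sample(c("left", "right"), 1L)
    }
    side <- state$block_side
    strength <- 100
  } else if (config$stage < 4 && identical(state$last_outcome, "incorrect") &&
             !is.null(state$last_stim)) {
    side <- state$last_stim$side
    strength <- state$last_stim$strength
  } else {
    side <- sample(c("left", "right"), 1L)
    strength <- if (length(config$strengths) > 1L) {
      sample(config$strengths, 1L)
    } else {
      config$strengths
    }
  }
  dominant <- names(config$side_map)[match(side, config$side_map)]
  list(strength = strength, dominant = dominant, go = NA, side = side)
}

#' Classify a trial outcome
#'
#' @param task task name.
#' @param target Go flag (logical, Go/NoGo), correct side (`"left"`/`"right"`,
#'   2AFC), ignored for detection.
#' @param crossing `NULL` or `list(time=, direction=)` from
#'   [detect_goal_crossing()].
#' @return outcome string: detection `correct`/`incorrect`; Go/NoGo
#'   `hit`/`miss`/`correct_rejection`/`false_alarm`; 2AFC
#'   `correct`/`incorrect`/`omission`.
#' @export
classify_outcome <- function(task, target, crossing) {
  responded <- !is.null(crossing)
  switch(task,
    detection = if (responded) "correct" else "incorrect",
    gonogo = {
      assert_that(is.logical(target) && length(target) == 1L && !is.na(target),
                  "gonogo target must be TRUE (Go) or FALSE (NoGo)")
      if (target) {
        if (responded) "hit" else "miss"
      } else {
        if (responded) "false_alarm" else "correct_rejection"
      }
    },
    `2afc` = {
      assert_that(target %in% c("left", "right"), "2afc target must be a side")
      if (!responded) "omission"
      else if (crossing$direction == target) "correct" else "incorrect"
    },
    stop_input("unknown task: ", task))
}

# outcomes that trigger reward / timeout / white noise
outcome_flags <- function(task, outcome) {
  rewarded <- outcome %in% c("correct", "hit")
  timeout <- switch(task,
                    detection = outcome == "incorrect",
                    gonogo = outcome %in% c("miss", "false_alarm"),
                    `2afc` = outcome %in% c("incorrect", "omission"),
                    FALSE)
  noise <- (task == "gonogo" && outcome == "false_alarm") ||
    (task == "2afc" && outcome == "incorrect")
  list(rewarded = rewarded, timeout = timeout, noise = noise)
}

# Events are buffered per trial and pushed once, to avoid quadratic list
# growth over long sessions.
push_events <- function(state, trial, times, names) {
  k <- length(state$events_time) + 1L
  state$events_time[[k]] <- times
  state$events_name[[k]] <- names
  state$events_trial[[k]] <- rep.int(trial, length(times))
}

#' Run one trial of the state machine
#'
#' FSM sequence: draw the quiescence duration uniform on \[1.0, 1.5\] s; wait
#' until the agent's wheel trace satisfies it (2 degree jitter); present the
#' tone cloud, repeating it back to back until a goal crossing or the end of
#' the response window; classify the outcome; deliver the reward or apply the
#' timeout (plus white noise for false alarms / incorrect 2AFC choices); then
#' the 0.5 s ITI. All events are time-stamped on the session clock.
#'
#' @param config a [task_config()].
#' @param agent an `agent_policy`.
#' @param state session state environment (mutated).
#' @param seed per-trial seed, or NULL to use the ambient RNG stream.
#' @return the trial record as a named list (also appended to `state`).
#' @export
run_trial <- function(config, agent, state = new_session_state(config),
                      seed = NULL) {
  with_seed(seed, run_trial_impl(config, agent, state, seed))
}

run_trial_impl <- function(config, agent, state, seed) {
  t0 <- state$now
  idx <- state$n + 1L
  tick <- ENGINE_TICK
  qd <- stats::runif(1, config$quiescence_range[1], config$quiescence_range[2])
  stim <- next_stimulus(config, state)
  x <- switch(config$task,
              detection = 100,
              gonogo = if (stim$go) 100 else -100,
              `2afc` = if (stim$side == "right") stim$strength else -stim$strength,
              stop_input("run_trial does not handle task: ", config$task))
  dec <- choose_response(agent, x, now_min = t0 / 60)
  responded_intent <- !is.na(dec$direction) &&
    (config$task == "2afc" || dec$direction == "right")
  turn_dir <- if (config$task == "2afc") {
    dec$direction
  } else if (responded_intent) {
    sample(c("left", "right"), 1L)
  } else {
    NA_character_
  }
  tr <- render_trace(agent, dec, qd, config$response_window,
                     config$turning_goal, turn_direction = turn_dir)
  ev_t <- t0
  ev_n <- "trial_start"
  if (is.na(tr$onset)) { # quiescence never achieved; abort trial
    push_events(state, idx, ev_t, ev_n)
    state$rt_hist <- c(state$rt_hist, NA_real_)
    state$now <- t0 + max(tr$trace$time) + config$iti
    rec <- trial_record(idx, t0, qd, NA_real_, stim, "no_quiescence",
                        NA_character_, NA_real_,
                        accumulated_turning(tr$trace, 0, max(tr$trace$time)),
                        0, state$now, seed)
    state$trials[[idx]] <- rec
    state$n <- idx
    return(rec)
  }
  onset_abs <- t0 + tr$onset
  ev_t <- c(ev_t, onset_abs); ev_n <- c(ev_n, "stim_onset")
  crossing <- detect_goal_crossing(tr$trace, tr$onset, config$turning_goal,
                                   tr$onset + config$response_window)
  resp_rel <- if (is.null(crossing)) config$response_window else crossing$time - tr$onset
  n_rep <- max(0L, ceiling(round(resp_rel / config$stim_duration, 9)) - 1L)
  if (n_rep > 0L) {
    ev_t <- c(ev_t, onset_abs + seq_len(n_rep) * config$stim_duration)
    ev_n <- c(ev_n, rep.int("stim_repeat", n_rep))
  }
  outcome <- classify_outcome(config$task, if (config$task == "gonogo") stim$go else stim$side,
                              crossing)
  rt <- if (is.null(crossing)) NA_real_ else crossing$time - tr$onset
  direction <- if (is.null(crossing)) NA_character_ else crossing$direction
  if (!is.null(crossing)) {
    ev_t <- c(ev_t, onset_abs + rt); ev_n <- c(ev_n, "response")
  }
  t_resp <- onset_abs + resp_rel
  flags <- outcome_flags(config$task, outcome)
  reward <- 0
  t <- t_resp
  if (flags$rewarded) {
    reward <- config$reward_size * (if (is.na(direction)) 1 else
      unname(config$reward_multiplier[[direction]]))
    t <- t + tick
    ev_t <- c(ev_t, t); ev_n <- c(ev_n, "reward")
    state$total_reward <- state$total_reward + reward
  } else if (flags$timeout) {
    t <- t + tick
    ev_t <- c(ev_t, t); ev_n <- c(ev_n, "timeout_start")
    if (flags$noise) {
      ev_t <- c(ev_t, t + tick, t + tick + config$noise_punish_duration)
      ev_n <- c(ev_n, "noise_on", "noise_off")
    }
    t <- t + config$timeout
    ev_t <- c(ev_t, t); ev_n <- c(ev_n, "timeout_end")
  }
  iti_start <- t + tick
  t_end <- iti_start + config$iti
  ev_t <- c(ev_t, iti_start, t_end)
  ev_n <- c(ev_n, "iti_start", "iti_end")
  push_events(state, idx, ev_t, ev_n)
  state$rt_hist <- c(state$rt_hist, rt)
  state$now <- t_end
  prestim <- accumulated_turning(tr$trace, 0, tr$onset)
  rec <- trial_record(idx, t0, qd, onset_abs, stim, outcome, direction, rt,
                      prestim, reward, t_end, seed)
  state$trials[[idx]] <- rec
  state$n <- idx
  # update pseudorandomization state
  if (config$task == "gonogo") {
    state$last_types <- c(tail(state$last_types, 2L),
                          if (stim$go) "go" else "nogo")
  }
  if (config$task == "2afc") {
    state$last_stim <- stim
    state$last_outcome <- outcome
    if (config$stage == 0) {
      if (outcome == "correct") {
        state$block_streak <- state$block_streak + 1L
        if (state$block_streak >= 3L) {
          state$block_side <- setdiff(c("left", "right"), state$block_side)
          state$block_streak <- 0L
        }
      } else {
        state$block_streak <- 0L
      }
    }
  }
  rec
}

trial_record <- function(index, t_start, qd, stim_onset, stim, outcome,
                         direction, rt, prestim, reward, t_end, seed) {
  list(index = index, t_start = t_start, quiescence_duration = qd,
       stim_onset = stim_onset, strength = stim$strength,
       dominant = stim$dominant, go = stim$go, side = stim$side,
       outcome = outcome, turn_direction = direction, rt = rt,
       prestim_turning = prestim, reward = reward, t_end = t_end,
       seed = seed %||% NA_integer_)
}

#' Check the disengagement criterion
#'
#' Always FALSE before the 45 min session minimum. Detection/Go-NoGo: TRUE
#' iff fewer than 4 of the last 20 trials contain a goal crossing. 2AFC: TRUE
#' iff the median reaction time over the last 20 responded trials exceeds 4
#' times the median reaction time of all responded trials so far. Fewer than
#' 20 (responded) trials: FALSE.
#'
#' @param task task name.
#' @param trials data.frame of trials so far with columns `outcome` and `rt`
#'   (as produced by [session_trials()]), or a session state environment.
#' @param now session clock time in seconds.
#' @param session_min session minimum in seconds (default 45 min).
#' @return logical.
#' @export
check_disengagement <- function(task, trials, now, session_min = 45 * 60) {
  if (now < session_min) return(FALSE)
  rt <- if (is.environment(trials)) trials$rt_hist else trials$rt
  if (task %in% c("detection", "gonogo")) {
    if (length(rt) < 20L) return(FALSE)
    sum(!is.na(tail(rt, 20L))) < 4L
  } else if (task == "2afc") {
    rts <- rt[!is.na(rt)]
    if (length(rts) < 20L) return(FALSE)
    stats::median(tail(rts, 20L)) > 4 * stats::median(rts)
  } else {
    FALSE
  }
}

session_trials_from_list <- function(lst) {
  if (!length(lst)) {
    return(data.frame(index = integer(0), t_start = numeric(0),
                      quiescence_duration = numeric(0), stim_onset = numeric(0),
                      strength = numeric(0), dominant = character(0),
                      go = logical(0), side = character(0),
                      outcome = character(0), turn_direction = character(0),
                      rt = numeric(0), prestim_turning = numeric(0),
                      reward = numeric(0), t_end = numeric(0),
                      seed = integer(0), stringsAsFactors = FALSE))
  }
  cols <- names(lst[[1L]])
  out <- lapply(cols, function(cn) {
    vals <- lapply(lst, `[[`, cn)
    vals[vapply(vals, is.null, TRUE)] <- NA
    unlist(vals, use.names = FALSE)
  })
  names(out) <- cols
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Run one full session
#'
#' Loops [run_trial()] on the virtual clock until the disengagement criterion
#' fires (possible only after the 45 min session minimum) or the session time
#' cap is reached (60 min detection/Go-NoGo, 90 min 2AFC). Pretraining
#' sessions ignore the wheel entirely: 100% middle-octave 2.04 s clouds are
#' presented, each followed by a 5 ul reward, for 15/30/45 min by session
#' index.
#'
#' @param config a [task_config()].
#' @param agent an `agent_policy`.
#' @param seed session seed; per-trial seeds are derived from it by counter,
#'   so any single trial can be reproduced in isolation and replaying the
#'   seed reproduces the identical record.
#' @return object of class `session_record`: list with `task`, `stage`,
#'   `config`, `seed`, `trials` (data.frame), `events` (data.frame),
#'   `start`, `end`, `termination_reason`, `total_reward_ul`.
#' @export
run_session <- function(config, agent, seed = 1L) {
  stopifnot(inherits(config, "task_config"), inherits(agent, "agent_policy"))
  if (config$task == "pretraining") return(run_pretraining_session(config, seed))
  state <- new_session_state(config)
  cap <- config$session_cap * 60
  smin <- config$session_min * 60
  reason <- "time_cap"
  while (state$now < cap) {
    run_trial(config, agent, state, seed = derive_seed(seed, state$n + 1L))
    if (state$now >= smin &&
        check_disengagement(config$task, state, state$now, smin)) {
      reason <- "disengaged"
      break
    }
  }
  finish_session(config, state, seed, reason, cap)
}

run_pretraining_session <- function(config, seed) {
  state <- new_session_state(config)
  cap <- config$session_cap * 60
  while (state$now < cap) {
    idx <- state$n + 1L
    t0 <- state$now
    t_rew <- t0 + config$stim_duration + ENGINE_TICK
    t_end <- t_rew + ENGINE_TICK + config$iti
    push_events(state, idx, c(t0, t_rew, t_end),
                c("trial_start", "reward", "iti_end"))
    state$total_reward <- state$total_reward + config$reward_size
    state$trials[[idx]] <- trial_record(idx, t0, NA_real_, t0,
                                        list(strength = 100, dominant = "middle",
                                             go = NA, side = NA_character_),
                                        NA_character_, NA_character_, NA_real_,
                                        0, config$reward_size, t_end,
                                        derive_seed(seed, idx))
    state$n <- idx
    state$now <- t_end
  }
  finish_session(config, state, seed, "time_cap", cap)
}

finish_session <- function(config, state, seed, reason, cap) {
  structure(list(
    task = config$task,
    stage = config$stage,
    config = unclass(config),
    seed = seed,
    trials = session_trials_from_list(state$trials),
    events = data.frame(
      trial = as.integer(unlist(state$events_trial) %||% integer(0)),
      time = as.numeric(unlist(state$events_time) %||% numeric(0)),
      event = as.character(unlist(state$events_name) %||% character(0)),
      stringsAsFactors = FALSE),
    start = 0,
    end = min(state$now, cap),
    termination_reason = reason,
    total_reward_ul = state$total_reward
  ), class = "session_record")
}

#' Trial table of a session
#'
#' @param session a `session_record`.
#' @return the session's trials as a data.frame.
#' @export
session_trials <- function(session) {
  stopifnot(inherits(session, "session_record"))
  session$trials
}

#' @export
print.session_record <- function(x, ...) {
  cat(sprintf("<session_record: %s stage %s, %d trials, %.1f min, %s, %.0f ul>\n",
              x$task, x$stage, nrow(x$trials), x$end / 60,
              x$termination_reason, x$total_reward_ul))
  invisible(x)
}
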