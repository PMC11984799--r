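test_that("task_config encodes the staged protocol parameters", {
  d0 <- task_config("detection", 0)
  expect_equal(d0$turning_goal, 15)
  expect_equal(d0$response_window, 1.02)
  expect_equal(d0$session_cap, 60)
  expect_equal(task_config("detection", 1)$turning_goal, 30)
  a <- task_config("2afc", 4)
  expect_equal(a$response_window, 15)
  expect_equal(a$session_cap, 90)
  expect_setequal(a$strengths, c(100, 85, 70, 60))
  expect_setequal(task_config("2afc", 3)$strengths, c(100, 85, 70))
  expect_equal(task_config("2afc", 0)$turning_goal, 15)
  expect_error(task_config("2afc", 7), class = "tonewheel_input_error")
  expect_error(task_config("detection", response_window = 0.3),
               class = "tonewheel_input_error")
})

test_that("classify_outcome maps task x response to the printed outcome sets", {
  cr <- list(time = 1, direction = "right")
  cl <- list(time = 1, direction = "left")
  expect_equal(classify_outcome("detection", NA, cr), "correct")
  expect_equal(classify_outcome("detection", NA, NULL), "incorrect")
  expect_equal(classify_outcome("gonogo", TRUE, cr), "hit")
  expect_equal(classify_outcome("gonogo", TRUE, NULL), "miss")
  expect_equal(classify_outcome("gonogo", FALSE, cl), "false_alarm")
  expect_equal(classify_outcome("gonogo", FALSE, NULL), "correct_rejection")
  expect_equal(classify_outcome("2afc", "left", cl), "correct")
  expect_equal(classify_outcome("2afc", "left", cr), "incorrect")
  expect_equal(classify_outcome("2afc", "right", NULL), "omission")
  expect_error(classify_outcome("foraging", NA, NULL),
               class = "tonewheel_input_error")
})

test_that("Go/NoGo ordering never repeats a trial type more than 3 times", {
  ses <- fx_gonogo_session()
  types <- session_trials(ses)$go
  runs <- rle(types)
  expect_true(all(runs$lengths <= 3))
  # after three identical types the next is forced to the other type
  cfg <- task_config("gonogo", 1)
  st <- new_session_state(cfg)
  st$last_types <- c("go", "go", "go")
  set.seed(1)
  draws <- replicate(20, next_stimulus(cfg, st)$go)
  expect_true(all(!draws))
})

test_that("2AFC stage 0 blocks alternate after three consecutive corrects", {
  cfg <- task_config("2afc", 0, session_min = 4, session_cap = 5)
  ses <- run_session(cfg, make_agent("ideal"), seed = 5)
  tr <- session_trials(ses)
  runs <- rle(tr$side)
  # an always-correct agent switches blocks every 3 trials
  expect_true(all(runs$lengths[-length(runs$lengths)] == 3))
  expect_true(all(tr$strength == 100))
})

test_that("2AFC stages 1-3 repeat the stimulus after an incorrect trial", {
  ses <- fx_2afc_session()
  tr <- session_trials(ses)
  inc <- which(tr$outcome == "incorrect")
  inc <- inc[inc < nrow(tr)]
  expect_gt(length(inc), 5)
  expect_true(all(tr$side[inc + 1L] == tr$side[inc]))
  expect_true(all(tr$strength[inc + 1L] == tr$strength[inc]))
  # stage 4 does not repeat: simulate many errors and check both sides follow
  cfg4 <- task_config("2afc", 4, session_min = 4, session_cap = 5)
  ses4 <- run_session(cfg4, make_agent("lapsing", list(lapse1 = 0.4, lapse2 = 0.4)),
                      seed = 31)
  t4 <- session_trials(ses4)
  inc4 <- which(t4$outcome == "incorrect")
  inc4 <- inc4[inc4 < nrow(t4)]
  expect_false(all(t4$side[inc4 + 1L] == t4$side[inc4]))
})

test_that("strengths are presented in nearly equal proportion", {
  ses <- fx_2afc_session() # stage 2: strengths 100/85
  tr <- session_trials(ses)
  # repeats after errors perturb the split only mildly
  expect_equal(mean(tr$strength == 100), 0.5, tolerance = 0.1)
})

test_that("detection trials reward any-direction crossings and truncate the stimulus", {
  cfg <- task_config("detection", 1, session_min = 1, session_cap = 1.2)
  ses <- run_session(cfg, make_agent("ideal"), seed = 9)
  tr <- session_trials(ses)
  expect_true(all(tr$outcome == "correct"))
  expect_true(all(tr$reward == cfg$reward_size))
  expect_true(all(!is.na(tr$rt)))
  # responses before the 0.51 s first presentation end leave no repeat event
  ev <- ses$events
  fast <- tr$index[tr$rt < 0.5]
  expect_false(any(ev$event == "stim_repeat" & ev$trial %in% fast))
  # a response after 0.51 s implies exactly one repeat
  slow <- tr$index[tr$rt > 0.52]
  if (length(slow)) {
    expect_true(all(table(ev$trial[ev$event == "stim_repeat"])[as.character(slow)] == 1))
  }
})

test_that("event logs carry exact configured durations", {
  ses <- fx_gonogo_session()
  to <- event_durations(ses, "timeout_start", "timeout_end")
  expect_true(any(!is.na(to)))
  expect_true(all(abs(to[!is.na(to)] - 1.5) < 1e-9))
  no <- event_durations(ses, "noise_on", "noise_off")
  expect_true(any(!is.na(no)))
  expect_true(all(abs(no[!is.na(no)] - 0.5) < 1e-9))
  iti <- event_durations(ses, "iti_start", "iti_end")
  expect_true(all(abs(iti[!is.na(iti)] - 0.5) < 1e-9))
})

test_that("event timestamps are strictly increasing within each trial", {
  for (ses in list(fx_gonogo_session(), fx_2afc_session())) {
    for (e in split(ses$events, ses$events$trial)) {
      expect_true(all(diff(e$time) > 0))
    }
  }
})

test_that("Go/NoGo punishments follow the outcome contingencies", {
  ses <- fx_gonogo_session()
  tr <- session_trials(ses)
  ev <- ses$events
  noise_trials <- unique(ev$trial[ev$event == "noise_on"])
  expect_setequal(noise_trials, tr$index[tr$outcome == "false_alarm"])
  timeout_trials <- unique(ev$trial[ev$event == "timeout_start"])
  expect_setequal(timeout_trials,
                  tr$index[tr$outcome %in% c("false_alarm", "miss")])
  # correct rejections: neither rewarded nor punished
  crs <- tr$index[tr$outcome == "correct_rejection"]
  expect_false(any(ev$trial %in% crs & ev$event %in% c("reward", "timeout_start")))
  expect_true(all(tr$reward[tr$outcome == "hit"] > 0))
})

test_that("2AFC omissions get timeouts but never noise", {
  ses <- fx_2afc_session()
  tr <- session_trials(ses)
  ev <- ses$events
  om <- tr$index[tr$outcome == "omission"]
  expect_gt(length(om), 0)
  expect_true(all(om %in% ev$trial[ev$event == "timeout_start"]))
  expect_false(any(ev$trial %in% om & ev$event == "noise_on"))
  noise_trials <- unique(ev$trial[ev$event == "noise_on"])
  expect_setequal(noise_trials, tr$index[tr$outcome == "incorrect"])
})

test_that("disengagement rules respect the session minimum and the printed thresholds", {
  mk <- function(rts) data.frame(rt = rts, outcome = NA)
  # detection: <4 crossings in last 20 trials
  few <- mk(c(rep(NA_real_, 17), 0.3, 0.3, 0.3))
  expect_true(check_disengagement("detection", few, now = 50 * 60))
  expect_false(check_disengagement("detection", few, now = 40 * 60))
  four <- mk(c(rep(NA_real_, 16), 0.3, 0.3, 0.3, 0.3))
  expect_false(check_disengagement("detection", four, now = 50 * 60))
  expect_false(check_disengagement("detection", mk(rep(NA_real_, 10)), now = 50 * 60))
  # 2afc: rolling median RT > 4x session median RT
  slow <- mk(c(rep(0.4, 80), rep(4.1 * 0.4, 20)))
  expect_true(check_disengagement("2afc", slow, now = 50 * 60))
  borderline <- mk(c(rep(0.4, 80), rep(3.9 * 0.4, 20)))
  expect_false(check_disengagement("2afc", borderline, now = 50 * 60))
  expect_false(check_disengagement("2afc", mk(rep(0.4, 19)), now = 50 * 60))
})

test_that("sessions terminate and record the reason", {
  # never-responding agent, scaled-down session: disengaged just past the minimum
  cfg <- task_config("detection", 1, session_min = 3, session_cap = 10)
  ses <- run_session(cfg, make_agent("never_responding"), seed = 4)
  expect_equal(ses$termination_reason, "disengaged")
  expect_gte(ses$end, 3 * 60)
  expect_lt(ses$end, 5 * 60)
  expect_true(all(is.na(session_trials(ses)$rt)))
  # engaged agent: time cap
  ses2 <- fx_gonogo_session()
  expect_equal(ses2$termination_reason, "time_cap")
  expect_lte(ses2$end, ses2$config$session_cap * 60)
})

test_that("pretraining presents clouds and rewards without outcome classification", {
  cfg <- task_config("pretraining", stage = 1)
  ses <- run_session(cfg, make_agent("ideal"), seed = 6)
  tr <- session_trials(ses)
  expect_equal(ses$end, 15 * 60)
  expect_gt(nrow(tr), 200) # >200 clouds in all pretraining sessions
  expect_true(all(is.na(tr$outcome)))
  expect_true(all(tr$reward == 5))
  expect_equal(ses$total_reward_ul, 5 * nrow(tr))
  expect_equal(task_config("pretraining", stage = 3)$session_cap, 45)
})

test_that("replaying a session seed reproduces the identical record", {
  cfg <- task_config("2afc", 1, session_min = 2, session_cap = 3)
  a <- run_session(cfg, make_agent("impulsive"), seed = 77)
  b <- run_session(cfg, make_agent("impulsive"), seed = 77)
  expect_identical(a$trials, b$trials)
  expect_identical(a$events, b$events)
  c <- run_session(cfg, make_agent("impulsive"), seed = 78)
  expect_false(identical(a$trials, c$trials))
})

test_that("engine reaction times agree with the agent's requested rt", {
  cfg <- task_config("detection", 1, session_min = 4, session_cap = 5)
  ses <- run_session(cfg, make_agent("ideal"), seed = 13)
  tr <- session_trials(ses)
  # crossings land within ~one 100 Hz sample above the drawn log-normal rt
  expect_lt(abs(median(tr$rt) - 0.35), 0.02)
})
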