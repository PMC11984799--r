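# Automated multi-session training: stage advancement, intersession reward
# adjustment, intersession debiasing, proficiency evaluation.

REWARD_BOUNDS <- list(detection = c(3, 5), gonogo = c(3, 5), `2afc` = c(1.5, 3),
                      pretraining = c(5, 5))

#' Intersession reward-size adjustment
#'
#' If more than 1 ml was consumed in the previous session the reward shrinks
#' by 0.1 ul (clamped at the task minimum: 3 ul detection/Go-NoGo, 1.5 ul
#' 2AFC); under 1 ml it grows by 0.1 ul (clamped at the maximum: 5 / 3 ul);
#' exactly 1 ml leaves it unchanged.
#'
#' @param prev previous reward size in microliters.
#' @param consumed_ml volume consumed in the previous session, ml.
#' @param task task name.
#' @return new reward size in microliters.
#' @export
adjust_reward <- function(prev, consumed_ml, task) {
  bounds <- REWARD_BOUNDS[[task]]
  assert_that(!is.null(bounds), "unknown task: ", task)
  assert_that(is_scalar_number(prev) && prev >= 0, "prev must be >= 0")
  assert_that(is_scalar_number(consumed_ml) && consumed_ml >= 0,
              "consumed_ml must be >= 0")
  new <- if (consumed_ml > 1) prev - 0.1 else if (consumed_ml < 1) prev + 0.1 else prev
  min(max(new, bounds[1]), bounds[2])
}

#' Stage-advancement decision
#'
#' Strict-inequality thresholds per task and stage: detection/Go-NoGo stage 0
#' needs >150 correct responses (crossings / hits); 2AFC stage 0 needs >300 correct, stage 1 >80%
#' correct for both high and low 100% clouds, stage 2 >75% for both, stage 3
#' >350 correct. Final stages never advance (proficiency is evaluated
#' separately).
#'
#' @param task task name.
#' @param stage current stage index.
#' @param summary a [session_summary()] of the completed session.
#' @return logical: advance to the next stage?
#' @export
evaluate_stage_advance <- function(task, stage, summary) {
  both <- function(thr) {
    !is.na(summary$acc_high) && !is.na(summary$acc_low) &&
      summary$acc_high > thr && summary$acc_low > thr
  }
  if (task %in% c("detection", "gonogo")) {
    # stage 0 shapes wheel turning, so its >150-correct bar counts rewarded
    # responses: any crossing for detection, hits for Go/NoGo (correct
    # rejections alone must not advance an animal that never turns)
    if (stage == 0) {
      n <- if (task == "gonogo") summary$n_hit else summary$n_correct
      return(n > 150)
    }
    if (stage == 1) return(FALSE)
    stop_input("unknown ", task, " stage: ", stage)
  }
  if (task == "2afc") {
    return(switch(as.character(stage),
                  "0" = summary$n_correct > 300,
                  "1" = both(0.80),
                  "2" = both(0.75),
                  "3" = summary$n_correct > 350,
                  "4" = FALSE,
                  stop_input("unknown 2afc stage: ", stage)))
  }
  stop_input("unknown task: ", task)
}

#' Intersession debiasing multipliers
#'
#' If more than 85% of the previous session's responded trials went to one
#' side, the reward for turning in the neglected direction is doubled on the
#' next session; otherwise both multipliers are 1.
#'
#' @param summary a [session_summary()] (uses `frac_right`).
#' @return named numeric `c(left=, right=)`.
#' @export
intersession_debias <- function(summary) {
  fr <- summary$frac_right
  if (is.na(fr)) return(c(left = 1, right = 1))
  if (fr > 0.85) c(left = 2, right = 1)
  else if (fr < 0.15) c(left = 1, right = 2)
  else c(left = 1, right = 1)
}

#' Task-proficiency evaluation
#'
#' Go/NoGo: d' > 1.8 on three consecutive sessions. 2AFC (stage 4): in each
#' of the last three sessions >300 trials and >80% correct on 100% clouds for
#' both sides, and the psychometric fit of the three sessions' cumulative
#' data has |bias| < 16, slope (threshold) < 19 (stimulus-strength %) and
#' both lapse rates < 0.2. Fewer than three qualifying sessions: FALSE.
#'
#' @param task task name.
#' @param summaries list of [session_summary()] for consecutive stage-final
#'   sessions, oldest first.
#' @param cumulative_data for 2AFC, per-level data (`x`, `n`, `k`) pooled
#'   over the last three sessions (see [psychometric_data()]).
#' @return logical, with the fitted curve as attribute `fit` for 2AFC.
#' @export
evaluate_proficiency <- function(task, summaries, cumulative_data = NULL) {
  if (length(summaries) < 3L) return(FALSE)
  last3 <- tail(summaries, 3L)
  if (task == "gonogo") {
    dps <- vapply(last3, `[[`, numeric(1), "dprime")
    return(all(!is.na(dps) & dps > 1.8))
  }
  if (task == "2afc") {
    ok <- all(vapply(last3, function(s) {
      s$n_trials > 300 && !is.na(s$acc_high) && !is.na(s$acc_low) &&
        s$acc_high > 0.80 && s$acc_low > 0.80
    }, logical(1)))
    if (!ok || is.null(cumulative_data)) return(FALSE)
    fit <- fit_psychometric(cumulative_data)
    out <- abs(fit$bias) < 16 && fit$slope < 19 &&
      fit$lapse1 < 0.2 && fit$lapse2 < 0.2
    attr(out, "fit") <- fit
    return(out)
  }
  if (task == "detection") return(FALSE) # no printed proficiency criterion
  stop_input("unknown task: ", task)
}

#' Run a full automated training program
#'
#' Simulates an animal through pretraining (3 sessions of 15/30/45 min) and
#' the staged protocol of one task, applying stage advancement, intersession
#' reward adjustment and (2AFC stages 0--3) intersession debiasing after each
#' session, and stopping when the proficiency criterion is met or
#' `max_sessions` is exhausted. The Go stimulus (Go/NoGo) and the
#' octave-to-side map (2AFC) are drawn once at the start, as they would be
#' per animal.
#'
#' @param task `"detection"`, `"gonogo"` or `"2afc"`.
#' @param agent an `agent_policy`.
#' @param seed integer seed; session seeds are derived by counter.
#' @param max_sessions cap on main-task sessions.
#' @param pretraining include the 3 pretraining sessions first?
#' @param keep_sessions keep the full `session_record`s (memory-heavy)?
#' @return object of class `training_record`: `progression` data.frame (one
#'   row per session), `proficient`, `final_stage`, `stage_state`, and
#'   optionally `sessions`.
#' @export
run_training <- function(task = c("detection", "gonogo", "2afc"), agent,
                         seed = 1L, max_sessions = 20L, pretraining = TRUE,
                         keep_sessions = FALSE) {
  task <- match.arg(task)
  stopifnot(inherits(agent, "agent_policy"))
  go_stim <- with_seed(derive_seed(seed, 777L),
                       sample(c("low", "high"), 2L))
  side_map <- stats::setNames(with_seed(derive_seed(seed, 778L),
                                        sample(c("left", "right"), 2L)),
                              c("high", "low"))
  state <- list(task = task, stage = 0L,
                reward_size = if (task == "2afc") 3 else 5,
                reward_multiplier = c(left = 1, right = 1))
  rows <- list()
  sessions <- list()
  final_summaries <- list() # summaries at the final stage, for proficiency
  final_trials <- list()
  proficient <- FALSE
  s_idx <- 0L
  if (pretraining) {
    for (i in 1:3) {
      cfg <- task_config("pretraining", stage = i)
      ses <- run_session(cfg, agent, seed = derive_seed(seed, 100L + i))
      s_idx <- s_idx + 1L
      rows[[s_idx]] <- data.frame(session = s_idx, task = "pretraining",
                                  stage = i, n_trials = nrow(ses$trials),
                                  n_correct = NA_integer_, dprime = NA_real_,
                                  reward_size = cfg$reward_size,
                                  consumed_ml = ses$total_reward_ul / 1000,
                                  termination = ses$termination_reason,
                                  advanced = FALSE, proficient = FALSE)
      if (keep_sessions) sessions[[s_idx]] <- ses
    }
  }
  final_stage <- switch(task, detection = 1L, gonogo = 1L, `2afc` = 4L)
  for (i in seq_len(max_sessions)) {
    cfg <- task_config(task, stage = state$stage,
                       reward_size = state$reward_size,
                       go_stimulus = go_stim[1L], side_map = side_map,
                       reward_multiplier = state$reward_multiplier)
    ses <- run_session(cfg, agent, seed = derive_seed(seed, 1000L + i))
    summ <- session_summary(ses)
    advanced <- evaluate_stage_advance(task, state$stage, summ)
    at_final <- state$stage == final_stage
    if (at_final) {
      final_summaries[[length(final_summaries) + 1L]] <- summ
      final_trials[[length(final_trials) + 1L]] <- ses$trials
    }
    cum_data <- if (task == "2afc" && length(final_trials) >= 3L) {
      psychometric_data(do.call(rbind, tail(final_trials, 3L)))
    }
    prof <- evaluate_proficiency(task, final_summaries, cum_data)
    proficient <- isTRUE(as.logical(prof))
    s_idx <- s_idx + 1L
    rows[[s_idx]] <- data.frame(session = s_idx, task = task,
                                stage = state$stage, n_trials = summ$n_trials,
                                n_correct = summ$n_correct,
                                dprime = summ$dprime,
                                reward_size = state$reward_size,
                                consumed_ml = summ$consumed_ml,
                                termination = summ$termination,
                                advanced = advanced, proficient = proficient)
    if (keep_sessions) sessions[[s_idx]] <- ses
    # intersession updates for the next session
    state$reward_size <- adjust_reward(state$reward_size, summ$consumed_ml, task)
    state$reward_multiplier <- if (task == "2afc" && state$stage < 4) {
      intersession_debias(summ)
    } else {
      c(left = 1, right = 1)
    }
    if (advanced) state$stage <- state$stage + 1L
    if (proficient) break
    # Detection defines no proficiency criterion; training is operationally
    # complete once stage 1 (final stage) has been run.
    if (task == "detection" && at_final) break
  }
  structure(list(progression = do.call(rbind, rows), proficient = proficient,
                 final_stage = state$stage, stage_state = state,
                 sessions = if (keep_sessions) sessions),
            class = "training_record")
}

#' @export
print.training_record <- function(x, ...) {
  cat(sprintf("<training_record: %d sessions, final stage %d, proficient: %s>\n",
              nrow(x$progression), x$final_stage, x$proficient))
  invisible(x)
}
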