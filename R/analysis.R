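# Behavioral statistics: signal detection, psychometric fitting, reaction
# times, pre-stimulus turning and session summaries.

#' Go/NoGo outcome counts
#'
#' @param n_hit,n_miss,n_cr,n_fa non-negative trial counts.
#' @return object of class `outcome_counts`.
#' @export
outcome_counts <- function(n_hit, n_miss, n_cr, n_fa) {
  counts <- c(n_hit = n_hit, n_miss = n_miss, n_cr = n_cr, n_fa = n_fa)
  assert_that(all(counts >= 0) && all(counts == round(counts)),
              "counts must be non-negative integers")
  structure(as.list(counts), class = "outcome_counts")
}

#' Tally Go/NoGo outcomes from a trial table
#'
#' @param trials trial data.frame with an `outcome` column.
#' @return an [outcome_counts()].
#' @export
count_outcomes <- function(trials) {
  outcome_counts(sum(trials$outcome == "hit"),
                 sum(trials$outcome == "miss"),
                 sum(trials$outcome == "correct_rejection"),
                 sum(trials$outcome == "false_alarm"))
}

#' Hit and false-alarm rates
#'
#' H = hits / (hits + misses); F = false alarms / (false alarms + correct
#' rejections).
#'
#' @param counts an [outcome_counts()].
#' @return named numeric `c(H=, F=)`.
#' @export
rates <- function(counts) {
  stopifnot(inherits(counts, "outcome_counts"))
  n_go <- counts$n_hit + counts$n_miss
  n_nogo <- counts$n_fa + counts$n_cr
  assert_that(n_go > 0 && n_nogo > 0,
              "need at least one Go and one NoGo trial")
  c(H = counts$n_hit / n_go, F = counts$n_fa / n_nogo)
}

#' Discriminability index d'
#'
#' d' = z(H) - z(F), with H and F clamped to \[1/(2N), 1 - 1/(2N)\] (N the
#' respective trial count) so that perfect rates stay finite.
#'
#' @param counts an [outcome_counts()].
#' @return d' (dimensionless).
#' @export
dprime <- function(counts) {
  r <- rates(counts)
  n_go <- counts$n_hit + counts$n_miss
  n_nogo <- counts$n_fa + counts$n_cr
  h <- min(max(r[["H"]], 1 / (2 * n_go)), 1 - 1 / (2 * n_go))
  f <- min(max(r[["F"]], 1 / (2 * n_nogo)), 1 - 1 / (2 * n_nogo))
  stats::qnorm(h) - stats::qnorm(f)
}

#' Psychometric function
#'
#' P(x) = lapse1 + (1 - lapse1 - lapse2) * (erf((x - bias)/slope) + 1) / 2,
#' the probability of a rightward choice at signed stimulus strength x
#' (negative = left-rewarded, |x| = strength in percent). `lapse1` is the
#' left asymptote, `1 - lapse2` the right asymptote, `bias` the horizontal
#' displacement and `slope` the width (both in stimulus-strength %).
#'
#' @param fit a `psychometric_fit` or any list with elements `lapse1`,
#'   `lapse2`, `bias`, `slope`.
#' @param x signed stimulus strengths.
#' @return probabilities in \[lapse1, 1 - lapse2\].
#' @export
psychometric_value <- function(fit, x) {
  fit$lapse1 + (1 - fit$lapse1 - fit$lapse2) *
    (erf((x - fit$bias) / fit$slope) + 1) / 2
}

#' Maximum-likelihood psychometric fit
#'
#' Maximizes the binomial log-likelihood of per-level rightward-choice counts
#' under the error-function model (see [psychometric_value()]), with bounded
#' parameters (lapses in \[0, 0.5\], slope in \[`slope_min`, `slope_max`\],
#' bias in \[-100, 100\]) and a deterministic multi-start grid; the best
#' negative log-likelihood is retained, so the fit is reproducible for given
#' data.
#'
#' @param data data.frame with columns `x` (signed strength), `n` (trials)
#'   and `k` (rightward choices), one row per level; at least 2 distinct
#'   levels.
#' @param slope_min,slope_max slope bounds in strength-% units.
#' @return object of class `psychometric_fit`: `lapse1`, `lapse2`, `bias`,
#'   `slope`, `nll`, `data`, and `boundary` flags naming parameters that sit
#'   on a bound (degenerate or uninformative data are flagged, not errors).
#' @export
fit_psychometric <- function(data, slope_min = 0.5, slope_max = 200) {
  assert_that(is.data.frame(data) && all(c("x", "n", "k") %in% names(data)),
              "data must have columns x, n, k")
  data <- data[data$n > 0, , drop = FALSE]
  assert_that(length(unique(data$x)) >= 2L, "need >= 2 distinct strengths")
  assert_that(all(data$k >= 0 & data$k <= data$n), "need 0 <= k <= n")
  x <- data$x; n <- data$n; k <- data$k
  nll <- function(p) {
    pr <- psychometric_value(list(lapse1 = p[1], lapse2 = p[2],
                                  bias = p[3], slope = p[4]), x)
    pr <- pmin(pmax(pr, 1e-9), 1 - 1e-9)
    -sum(k * log(pr) + (n - k) * log(1 - pr))
  }
  lower <- c(0, 0, -100, slope_min)
  upper <- c(0.5, 0.5, 100, slope_max)
  starts <- expand.grid(l1 = c(0.01, 0.1), l2 = c(0.01, 0.1),
                        bias = c(-20, 0, 20), slope = c(5, 15, 40, 100))
  # On likelihood ties (flat ridges arise with perfectly separable or
  # uninformative data) prefer the solution with smaller |bias|, then
  # smaller slope: the least-extreme curve consistent with the data.
  better <- function(a, b) {
    if (is.null(b)) return(TRUE)
    if (a$value < b$value - 1e-6) return(TRUE)
    if (a$value > b$value + 1e-6) return(FALSE)
    if (abs(a$par[3]) < abs(b$par[3]) - 1e-9) return(TRUE)
    if (abs(a$par[3]) > abs(b$par[3]) + 1e-9) return(FALSE)
    a$par[4] < b$par[4] - 1e-9
  }
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    p0 <- as.numeric(starts[i, ])
    res <- tryCatch(
      stats::optim(p0, nll, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(res) && better(res, best)) best <- res
  }
  p <- best$par
  tol <- 1e-6
  boundary <- c("lapse1", "lapse2", "bias", "slope")[
    p <= lower + tol | p >= upper - tol]
  structure(list(lapse1 = p[1], lapse2 = p[2], bias = p[3], slope = p[4],
                 nll = best$value, data = data, boundary = boundary,
                 convergence = best$convergence),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(paste0("<psychometric_fit: lapse1=%.3f lapse2=%.3f bias=%.2f ",
                     "slope=%.2f, NLL=%.2f%s>\n"),
              x$lapse1, x$lapse2, x$bias, x$slope, x$nll,
              if (length(x$boundary)) {
                paste0(", at bound: ", paste(x$boundary, collapse = ","))
              } else ""))
  invisible(x)
}

#' Aggregate 2AFC trials into per-level psychometric data
#'
#' Responded trials only; x is the signed strength (positive when the correct
#' side is right), k counts rightward turns.
#'
#' @param trials trial data.frame (see [session_trials()]).
#' @return data.frame with columns `x`, `n`, `k`.
#' @export
psychometric_data <- function(trials) {
  t <- trials[!is.na(trials$turn_direction) & !is.na(trials$side), , drop = FALSE]
  x <- ifelse(t$side == "right", t$strength, -t$strength)
  agg <- stats::aggregate(cbind(n = rep(1L, length(x)),
                                k = as.integer(t$turn_direction == "right")),
                          by = list(x = x), FUN = sum)
  agg[order(agg$x), , drop = FALSE]
}

#' Rolling fraction of correct trials
#'
#' Trailing (causal) mean of the correct indicator over `window` trials;
#' NA for the first `window - 1` trials.
#'
#' @param trials trial data.frame, or a logical vector of correct indicators.
#' @param window window length in trials (default 10).
#' @return numeric vector, one value per trial.
#' @export
rolling_performance <- function(trials, window = 10) {
  correct <- if (is.data.frame(trials)) {
    trials$outcome %in% c("correct", "hit", "correct_rejection")
  } else {
    as.logical(trials)
  }
  n <- length(correct)
  out <- rep(NA_real_, n)
  if (n >= window) {
    cs <- cumsum(correct)
    out[window:n] <- (cs[window:n] - c(0, cs)[(window:n) - window + 1L]) / window
  }
  out
}

#' Reaction time of a trial
#'
#' Time from tone-cloud onset until the wheel turn exceeds the turning goal;
#' NA when no goal crossing occurred.
#'
#' @param trial a trial record (list or one-row data.frame) with `rt`, or a
#'   crossing time and onset as two numbers.
#' @return seconds or NA.
#' @export
reaction_time <- function(trial) {
  if (is.numeric(trial) && length(trial) == 2L) {
    return(trial[1L] - trial[2L])
  }
  trial$rt
}

#' OLS regression of reaction time on pre-stimulus turning
#'
#' Ordinary least squares of RT against accumulated pre-stimulus wheel
#' turning, over trials that have both quantities. Used to test whether an
#' impulsive pre-stimulus state predicts faster goal crossings.
#'
#' @param trials trial data.frame with `rt` and `prestim_turning`, or a
#'   data.frame with columns `x` and `y`.
#' @return `list(slope=, intercept=, r_squared=, n=)`.
#' @export
prestim_rt_regression <- function(trials) {
  if (all(c("x", "y") %in% names(trials))) {
    x <- trials$x; y <- trials$y
  } else {
    keep <- !is.na(trials$rt) & !is.na(trials$prestim_turning)
    x <- trials$prestim_turning[keep]; y <- trials$rt[keep]
  }
  assert_that(length(x) >= 3L, "need >= 3 trials with RT and turning")
  fit <- stats::lm(y ~ x)
  list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
       r_squared = summary(fit)$r.squared, n = length(x))
}

#' Turning bias of a session
#'
#' @param trials trial data.frame.
#' @return percent of responded trials with a rightward turn.
#' @export
session_bias <- function(trials) {
  resp <- trials$turn_direction[!is.na(trials$turn_direction)]
  assert_that(length(resp) > 0, "no responded trials")
  100 * mean(resp == "right")
}

#' Restrict a session to its first minutes
#'
#' @param session a `session_record` or trial data.frame.
#' @param minutes cutoff from session start (default 20).
#' @return trials whose start time is before the cutoff.
#' @export
filter_first_minutes <- function(session, minutes = 20) {
  trials <- if (inherits(session, "session_record")) session$trials else session
  start <- if (inherits(session, "session_record")) session$start else 0
  trials[trials$t_start - start < minutes * 60, , drop = FALSE]
}

#' Summarize a session for training decisions
#'
#' @param session a `session_record`.
#' @return list with trial/correct/hit counts, per-side accuracies on 100%
#'   clouds, d' (Go/NoGo), turn-direction fractions, consumed volume and
#'   median RT.
#' @export
session_summary <- function(session) {
  stopifnot(inherits(session, "session_record"))
  t <- session$trials
  correct <- t$outcome %in% c("correct", "hit", "correct_rejection")
  responded <- !is.na(t$turn_direction)
  side_acc <- function(dominant) {
    sel <- !is.na(t$side) & t$dominant == dominant & t$strength == 100
    if (!any(sel)) return(NA_real_)
    mean(t$outcome[sel] == "correct")
  }
  dp <- if (session$task == "gonogo" &&
            any(t$outcome %in% c("hit", "miss")) &&
            any(t$outcome %in% c("false_alarm", "correct_rejection"))) {
    dprime(count_outcomes(t))
  } else {
    NA_real_
  }
  list(task = session$task, stage = session$stage,
       n_trials = nrow(t), n_correct = sum(correct),
       n_hit = sum(t$outcome == "hit"),
       acc_high = side_acc("high"), acc_low = side_acc("low"),
       dprime = dp,
       frac_right = if (any(responded)) {
         mean(t$turn_direction[responded] == "right")
       } else NA_real_,
       consumed_ml = session$total_reward_ul / 1000,
       median_rt = stats::median(t$rt, na.rm = TRUE),
       termination = session$termination_reason)
}
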