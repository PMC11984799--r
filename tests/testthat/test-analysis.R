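# frozen independent oracle values (computed with scipy.stats.norm.ppf /
# scipy.special.erf before implementation; see the package vignette)
DPRIME_PRINTED_COUNTS <- 1.957385944425005 # counts 514/333/832/40
DPRIME_CLAMPED_100 <- 5.151658607097801    # 2 * qnorm(1 - 1/200)

test_that("rates reproduce the printed-count ratios and reject empty cells", {
  r <- rates(outcome_counts(514, 333, 832, 40))
  expect_equal(unname(r["H"]), 514 / 847, tolerance = 1e-12)
  expect_equal(unname(r["F"]), 40 / 872, tolerance = 1e-12)
  expect_equal(unname(rates(outcome_counts(10, 0, 10, 0))), c(1, 0))
  expect_equal(unname(rates(outcome_counts(5, 5, 5, 5))), c(0.5, 0.5))
  expect_error(rates(outcome_counts(0, 0, 5, 5)),
               class = "tonewheel_input_error")
  expect_error(outcome_counts(-1, 2, 3, 4), class = "tonewheel_input_error")
})

test_that("dprime matches the high-precision inverse-normal oracle", {
  expect_equal(dprime(outcome_counts(514, 333, 832, 40)),
               DPRIME_PRINTED_COUNTS, tolerance = 1e-6)
  # H = F -> 0 exactly
  expect_equal(dprime(outcome_counts(5, 5, 5, 5)), 0)
  expect_equal(dprime(outcome_counts(30, 10, 10, 30)), 0)
  # perfect performance is clamped to 1/(2N)
  expect_equal(dprime(outcome_counts(100, 0, 100, 0)), DPRIME_CLAMPED_100,
               tolerance = 1e-9)
})

test_that("dprime is antisymmetric under outcome swap", {
  set.seed(12)
  for (i in 1:25) {
    n <- sample(1:200, 4, replace = TRUE)
    a <- dprime(outcome_counts(n[1], n[2], n[3], n[4]))
    b <- dprime(outcome_counts(n[4], n[3], n[2], n[1]))
    expect_equal(a, -b, tolerance = 1e-12)
  }
})

test_that("psychometric_value honors the erf model and its limits", {
  f <- list(lapse1 = 0.1, lapse2 = 0.2, bias = 5, slope = 15)
  expect_equal(psychometric_value(f, 5), 0.1 + 0.7 / 2) # x = bias
  expect_equal(psychometric_value(f, 1e6), 1 - 0.2, tolerance = 1e-12)
  expect_equal(psychometric_value(f, -1e6), 0.1, tolerance = 1e-12)
  # monotone non-decreasing for slope > 0
  x <- seq(-100, 100, by = 1)
  expect_true(all(diff(psychometric_value(f, x)) >= 0))
  # bounded by the lapse asymptotes
  p <- psychometric_value(f, x)
  expect_true(all(p >= 0.1 - 1e-12 & p <= 0.8 + 1e-12))
})

test_that("fits recover parameters on an identifiable stimulus design", {
  levels <- c(-40, -20, -10, 0, 10, 20, 40)
  errs <- t(sapply(1:8, function(s) {
    set.seed(s)
    true <- list(lapse1 = 0.1, lapse2 = 0.1,
                 bias = runif(1, 0, 10), slope = runif(1, 10, 20))
    k <- rbinom(length(levels), 500, psychometric_value(true, levels))
    f <- fit_psychometric(data.frame(x = levels, n = 500, k = k))
    c(abs(f$lapse1 - true$lapse1), abs(f$lapse2 - true$lapse2),
      abs(f$bias - true$bias), abs(f$slope - true$slope) / true$slope)
  }))
  med <- apply(errs, 2, median)
  expect_lt(med[1], 0.05)
  expect_lt(med[2], 0.05)
  expect_lt(med[3], 3)
  expect_lt(med[4], 0.20)
})

test_that("symmetric data yield near-zero bias; flat data are flagged", {
  x <- c(-100, -85, -70, -60, 60, 70, 85, 100)
  # mirror-symmetric right-choice counts: P(-x) = 1 - P(x)
  sym <- data.frame(x = x, n = 500, k = c(10, 25, 60, 100, 400, 440, 475, 490))
  fs <- fit_psychometric(sym)
  expect_lt(abs(fs$bias), 2)
  # uninformative data (right fraction 0.5 everywhere): flat likelihood is
  # resolved by boundary lapses and flagged, with the tie-break bias of 0
  flat <- data.frame(x = x, n = 500, k = 250)
  ff <- fit_psychometric(flat)
  expect_gt(length(ff$boundary), 0)
  expect_equal(ff$bias, 0)
  # degenerate one-sided data return boundary flags, not an error
  onesided <- data.frame(x = x, n = 500, k = 500)
  expect_s3_class(fit_psychometric(onesided), "psychometric_fit")
  expect_error(fit_psychometric(data.frame(x = 1, n = 10, k = 5)),
               class = "tonewheel_input_error")
})

test_that("rolling performance equals the brute-force trailing mean", {
  set.seed(5)
  for (i in 1:5) {
    v <- runif(40) < 0.6
    rp <- rolling_performance(v, window = 10)
    brute <- vapply(seq_along(v), function(j) {
      if (j < 10) NA_real_ else mean(v[(j - 9):j])
    }, numeric(1))
    expect_equal(rp, brute)
  }
  expect_equal(rolling_performance(rep(TRUE, 10))[10], 1)
  alt <- rolling_performance(rep(c(TRUE, FALSE), 10))
  expect_true(all(alt[10:20] == 0.5))
})

test_that("reaction_time reads the onset-to-crossing delay", {
  expect_equal(reaction_time(c(1.4, 1.0)), 0.4)
  expect_equal(reaction_time(list(rt = 0.25)), 0.25)
  expect_true(is.na(reaction_time(list(rt = NA_real_))))
})

test_that("prestim/RT regression matches OLS ground truth", {
  # collinear points: exact fit
  d <- data.frame(x = c(0, 10, 20, 40), y = -0.01 * c(0, 10, 20, 40) + 1)
  r <- suppressWarnings(prestim_rt_regression(d)) # "essentially perfect fit"
  expect_equal(r$slope, -0.01, tolerance = 1e-12)
  expect_equal(r$intercept, 1, tolerance = 1e-12)
  expect_equal(r$r_squared, 1)
  # independent variables: R^2 near zero
  set.seed(9)
  d2 <- data.frame(x = runif(300, 0, 50), y = rlnorm(300, log(0.4), 0.2))
  expect_lt(prestim_rt_regression(d2)$r_squared, 0.05)
  expect_error(prestim_rt_regression(data.frame(x = 1:2, y = 1:2)),
               class = "tonewheel_input_error")
})

test_that("session bias is the percentage of rightward responses", {
  tr <- data.frame(turn_direction = c(rep("right", 7), rep("left", 3), NA))
  expect_equal(session_bias(tr), 70)
  expect_equal(session_bias(data.frame(turn_direction = "right")), 100)
  expect_error(session_bias(data.frame(turn_direction = NA_character_)),
               class = "tonewheel_input_error")
})

test_that("first-minutes filter uses a strict start-time cutoff", {
  tr <- data.frame(t_start = c(0, 19 * 60 + 59, 20 * 60, 20 * 60 + 1),
                   outcome = "correct")
  kept <- filter_first_minutes(tr, minutes = 20)
  expect_equal(nrow(kept), 2L)
  ses <- fx_gonogo_session()
  k2 <- filter_first_minutes(ses, minutes = 2)
  expect_true(all(k2$t_start < 120))
  expect_equal(nrow(k2), sum(session_trials(ses)$t_start < 120))
})

test_that("closed-loop choice frequencies match agent ground truth", {
  ses <- fx_2afc_session()
  tr <- session_trials(ses)
  pol <- make_agent("lapsing", list(response_prob = 0.85))
  d <- psychometric_data(tr)
  for (i in seq_len(nrow(d))) {
    p <- agent_p_right(pol, d$x[i])
    expect_lt(abs(d$k[i] / d$n[i] - p),
              2.576 * sqrt(p * (1 - p) / d$n[i]) + 0.02)
  }
})

test_that("impulsive agents reproduce the false-alarm signatures", {
  ses <- fixture("gonogo_impulsive", {
    run_session(task_config("gonogo", 1), make_agent("impulsive"), seed = 314)
  })
  tr <- session_trials(ses)
  fa <- tr[tr$outcome == "false_alarm", ]
  hit <- tr[tr$outcome == "hit", ]
  expect_gt(nrow(fa), 20)
  # FA trials carry more pre-stimulus turning than hits (impulsive state)
  expect_gt(mean(fa$prestim_turning), mean(hit$prestim_turning))
  # accumulated pre-stimulus turning negatively predicts RT in FA trials
  r <- prestim_rt_regression(fa)
  expect_lt(r$slope, 0)
  expect_gt(r$r_squared, 0)
})
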