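# Shared, lazily computed simulation fixtures. Sessions used by several test
# files are run once per test process and memoized here.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# A short-but-real Go/NoGo session with a lapsing agent (has all 4 outcomes).
fx_gonogo_session <- function() {
  fixture("gonogo_lapsing", {
    cfg <- task_config("gonogo", stage = 1, session_min = 4, session_cap = 5)
    run_session(cfg, make_agent("lapsing"), seed = 2024)
  })
}

# A short 2AFC session with omissions (response_prob < 1) and incorrects.
fx_2afc_session <- function() {
  fixture("afc_lapsing", {
    cfg <- task_config("2afc", stage = 2, session_min = 7, session_cap = 8)
    run_session(cfg, make_agent("lapsing", list(response_prob = 0.85)),
                seed = 2025)
  })
}

# event-log durations between two named events, per trial
event_durations <- function(session, from, to) {
  ev <- session$events
  vapply(split(ev, ev$trial), function(e) {
    a <- e$time[e$event == from]
    b <- e$time[e$event == to]
    if (length(a) == 1L && length(b) == 1L) b - a else NA_real_
  }, numeric(1))
}
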