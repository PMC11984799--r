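# Session persistence.
#
# A session is stored as one versioned JSON document (config snapshot, seed,
# trials, events, termination metadata) written at full double precision so
# every timestamp round-trips bit-exactly, plus an optional flat CSV mirror
# of the trial table for spreadsheet users.

SESSION_STORE_VERSION <- "1.0"

#' Write a session record to disk
#'
#' @param session a `session_record`.
#' @param path output path for the JSON document.
#' @param csv_path optional path for a flat CSV trial table mirror.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path, csv_path = NULL) {
  stopifnot(inherits(session, "session_record"))
  cfg <- session$config
  # named atomic vectors serialize as bare arrays; convert to objects
  cfg$reward_multiplier <- as.list(cfg$reward_multiplier)
  cfg$side_map <- as.list(cfg$side_map)
  doc <- list(
    format = "tonewheel-session",
    version = SESSION_STORE_VERSION,
    task = session$task,
    stage = session$stage,
    seed = session$seed,
    start = session$start,
    end = session$end,
    termination_reason = session$termination_reason,
    total_reward_ul = session$total_reward_ul,
    config = cfg,
    trials = session$trials,
    events = session$events
  )
  # digits = I(17): 17 significant digits round-trip every double bit-exactly
  # (digits = NA collapses non-canonical values like 1.02 + 0.39 - 1.02)
  jsonlite::write_json(doc, path, digits = I(17), auto_unbox = TRUE,
                       dataframe = "columns", na = "null")
  if (!is.null(csv_path)) {
    utils::write.csv(session$trials, csv_path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a session record written by [write_session()]
#'
#' @param path JSON document path.
#' @return a `session_record`.
#' @export
read_session <- function(path) {
  assert_that(file.exists(path), "no such file: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "tonewheel-session")) {
    stop_input("not a tonewheel session file: ", path)
  }
  if (!identical(doc$version, SESSION_STORE_VERSION)) {
    stop(errorCondition(
      paste0("unsupported session-store version '", doc$version,
             "' (expected '", SESSION_STORE_VERSION, "')"),
      class = c("tonewheel_version_error", "error")))
  }
  trials <- as.data.frame(doc$trials, stringsAsFactors = FALSE)
  events <- as.data.frame(doc$events, stringsAsFactors = FALSE)
  # restore canonical column types (all-NA or integer-valued columns lose
  # their type through JSON)
  num_cols <- c("t_start", "quiescence_duration", "stim_onset", "strength",
                "rt", "prestim_turning", "reward", "t_end")
  chr_cols <- c("dominant", "side", "outcome", "turn_direction")
  for (cn in intersect(num_cols, names(trials))) {
    trials[[cn]] <- as.numeric(trials[[cn]])
  }
  for (cn in intersect(chr_cols, names(trials))) {
    trials[[cn]] <- as.character(trials[[cn]])
  }
  if ("index" %in% names(trials)) trials$index <- as.integer(trials$index)
  if ("seed" %in% names(trials)) trials$seed <- as.integer(trials$seed)
  if ("go" %in% names(trials)) trials$go <- as.logical(trials$go)
  if (nrow(events)) {
    events$trial <- as.integer(events$trial)
    events$time <- as.numeric(events$time)
    events$event <- as.character(events$event)
  }
  cfg <- doc$config
  for (f in c("quiescence_range", "strengths")) {
    cfg[[f]] <- as.numeric(unlist(cfg[[f]]))
  }
  cfg$reward_multiplier <- unlist(cfg$reward_multiplier)
  cfg$side_map <- unlist(cfg$side_map)
  structure(list(task = doc$task, stage = doc$stage, config = cfg,
                 seed = doc$seed, trials = trials, events = events,
                 start = doc$start, end = doc$end,
                 termination_reason = doc$termination_reason,
                 total_reward_ul = doc$total_reward_ul),
            class = "session_record")
}
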