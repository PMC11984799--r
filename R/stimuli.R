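# Tone-cloud and noise stimulus synthesis.
#
# A tone cloud is a rapid stream of brief, overlapping pure tones whose octave
# composition carries the perceptual evidence: a cloud of a given "stimulus
# strength" draws that percentage of its tones from one dominant octave and
# the remainder uniformly from the 24 pitches of the other two octaves.

PITCH_CLASSES <- c("C", "C#", "D", "D#", "E", "F", "F#", "G", "G#", "A", "A#", "B")

OCTAVE_NUMBER <- c(low = 7L, middle = 8L, high = 9L)

#' Frequency of a pitch in 12-tone equal temperament
#'
#' Frequencies follow 12-TET anchored at A4 = 440 Hz, so each octave doubles
#' the frequency. The three octaves used by the tasks are low (C7--B7,
#' 2,093--3,951 Hz), middle (C8--B8, 4,186--7,902 Hz) and high (C9--B9,
#' 8,372--15,804 Hz).
#'
#' @param pitch_name character vector of pitch names: note letter A--G, an
#'   optional sharp `#`, and an octave number, e.g. `"C7"`, `"A#8"`.
#' @return numeric vector of frequencies in Hz (full precision; round only
#'   for display).
#' @examples
#' pitch_frequency("A4") # 440
#' pitch_frequency("C7") # 2093.005
#' @export
pitch_frequency <- function(pitch_name) {
  assert_that(is.character(pitch_name) && length(pitch_name) >= 1L,
              "pitch_name must be a character vector")
  m <- regmatches(pitch_name,
                  regexec("^([A-G])(#?)(-?[0-9]+)$", pitch_name))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad)) {
    stop_input("malformed pitch name(s): ", paste(pitch_name[bad], collapse = ", "))
  }
  vapply(m, function(p) {
    idx <- match(paste0(p[2L], p[3L]), PITCH_CLASSES) - 1L
    octave <- as.integer(p[4L])
    semis <- (octave - 4L) * 12L + idx - 9L # semitones above A4
    440 * 2^(semis / 12)
  }, numeric(1))
}

#' Pitch table for the three task octaves
#'
#' @return named numeric vector mapping pitch names (C7..B9 plus the A4
#'   reference) to 12-TET frequencies in Hz; 12 pitches per octave.
#' @export
pitch_table <- function() {
  names <- c(as.vector(t(outer(7:9, PITCH_CLASSES,
                               function(o, n) paste0(n, o)))), "A4")
  stats::setNames(pitch_frequency(names), names)
}

#' Pitch names of one task octave
#'
#' @param octave one of `"low"` (C7--B7), `"middle"` (C8--B8), `"high"` (C9--B9).
#' @return character vector of 12 pitch names.
#' @export
octave_pitches <- function(octave) {
  octave <- match.arg(octave, names(OCTAVE_NUMBER))
  paste0(PITCH_CLASSES, OCTAVE_NUMBER[[octave]])
}

#' Parametric description of a tone cloud
#'
#' @param strength percent of tones drawn from the dominant octave, in
#'   \[50, 100\]. 100 is the easiest stimulus; lower strengths are harder.
#' @param dominant_octave `"low"`, `"middle"` or `"high"`.
#' @param duration cloud duration in seconds.
#' @param rate tone onsets per second (default 100, i.e. 10 ms inter-onset
#'   interval so consecutive 30 ms tones overlap by 20 ms).
#' @param tone_duration duration of each pure tone in seconds (default 0.030).
#' @param ramp_duration rise/decay ramp duration in seconds (default 0.003).
#' @param sample_rate audio sample rate in samples/s (default 44100).
#' @param seed integer seed making the pitch sampling reproducible, or NULL.
#' @return object of class `tone_cloud_spec`.
#' @export
tone_cloud_spec <- function(strength = 100, dominant_octave = "middle",
                            duration = 0.51, rate = 100,
                            tone_duration = 0.030, ramp_duration = 0.003,
                            sample_rate = 44100, seed = NULL) {
  dominant_octave <- match.arg(dominant_octave, names(OCTAVE_NUMBER))
  assert_that(is_scalar_number(strength) && strength >= 50 && strength <= 100,
              "strength must be in [50, 100]")
  assert_that(is_scalar_number(duration) && duration > 0, "duration must be > 0")
  assert_that(is_scalar_number(rate) && rate > 0, "rate must be > 0")
  assert_that(is_scalar_number(tone_duration) && tone_duration > 0,
              "tone_duration must be > 0")
  assert_that(is_scalar_number(ramp_duration) && ramp_duration >= 0 &&
                ramp_duration <= tone_duration / 2,
              "ramp_duration must be in [0, tone_duration/2]")
  assert_that(is_scalar_number(sample_rate) && sample_rate > 0,
              "sample_rate must be > 0")
  structure(list(strength = strength, dominant_octave = dominant_octave,
                 duration = duration, rate = rate,
                 tone_duration = tone_duration, ramp_duration = ramp_duration,
                 sample_rate = sample_rate, seed = seed),
            class = "tone_cloud_spec")
}

# Number of tone onsets in [0, duration) at fixed inter-onset interval 1/rate,
# robust to floating-point representation of duration * rate.
n_cloud_events <- function(duration, rate) {
  x <- round(duration * rate, 9)
  n <- ceiling(x)
  if (n == floor(x)) n <- as.integer(x) # exact multiple: onset at duration excluded
  as.integer(max(n, 1L))
}

#' Sample the tone events of a cloud
#'
#' Onsets sit on a fixed grid of 1/rate seconds starting at 0 and covering
#' \[0, duration). Each tone's pitch comes from the dominant octave with
#' probability `strength/100` and otherwise uniformly from the 24 pitches of
#' the other two octaves (equal probability of tones per octave).
#'
#' @param spec a [tone_cloud_spec()].
#' @return data.frame with columns `onset` (s), `pitch` (name),
#'   `frequency` (Hz), `dominant` (logical).
#' @export
sample_cloud_events <- function(spec) {
  stopifnot(inherits(spec, "tone_cloud_spec"))
  n <- n_cloud_events(spec$duration, spec$rate)
  with_seed(spec$seed, {
    onsets <- (seq_len(n) - 1L) / spec$rate
    dom <- stats::runif(n) < spec$strength / 100
    dom_pitches <- octave_pitches(spec$dominant_octave)
    other_pitches <- setdiff(paste0(rep(PITCH_CLASSES, 3), rep(7:9, each = 12)),
                             dom_pitches)
    pitch <- character(n)
    pitch[dom] <- sample(dom_pitches, sum(dom), replace = TRUE)
    pitch[!dom] <- sample(other_pitches, sum(!dom), replace = TRUE)
    data.frame(onset = onsets, pitch = pitch,
               frequency = pitch_frequency(pitch), dominant = dom,
               stringsAsFactors = FALSE)
  })
}

waveform <- function(samples, sample_rate) {
  structure(list(samples = as.numeric(samples), sample_rate = sample_rate),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform: %d samples @ %g Hz (%.3f s), peak %.3f>\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate,
              if (length(x$samples)) max(abs(x$samples)) else 0))
  invisible(x)
}

#' Apply raised-cosine onset/offset ramps
#'
#' Rise and decay ramps (Hann half-windows) avoid on-/offset clicks. The first
#' and last samples have amplitude 0 and the unramped middle is unchanged.
#'
#' @param tone a `waveform`.
#' @param ramp_duration ramp duration in seconds; must not exceed half the
#'   tone duration. 0 is the identity.
#' @return ramped `waveform`.
#' @export
apply_ramps <- function(tone, ramp_duration) {
  stopifnot(inherits(tone, "waveform"))
  assert_that(is_scalar_number(ramp_duration) && ramp_duration >= 0,
              "ramp_duration must be >= 0")
  n <- length(tone$samples)
  nr <- round(ramp_duration * tone$sample_rate)
  if (nr == 0L || n == 0L) return(tone)
  assert_that(nr <= floor(n / 2), "ramp longer than half the tone")
  env <- rep(1, n)
  ramp <- 0.5 * (1 - cos(pi * (seq_len(nr) - 1L) / nr))
  env[seq_len(nr)] <- ramp
  env[n + 1L - seq_len(nr)] <- ramp
  waveform(tone$samples * env, tone$sample_rate)
}

#' Synthesize a tone cloud waveform
#'
#' Superposes ramped pure tones at the sampled pitches and onsets. Tones whose
#' tail would exceed the nominal duration are truncated at the boundary (with
#' the decay ramp applied inside it), so the waveform length is exactly
#' `round(duration * sample_rate)` samples. The peak is normalized to
#' `amplitude`. Identical seeds give bit-identical output.
#'
#' @param spec a [tone_cloud_spec()].
#' @param amplitude peak amplitude after normalization, in (0, 1\].
#' @return a `waveform`.
#' @export
synthesize_cloud <- function(spec, amplitude = 0.9) {
  stopifnot(inherits(spec, "tone_cloud_spec"))
  assert_that(is_scalar_number(amplitude) && amplitude > 0 && amplitude <= 1,
              "amplitude must be in (0, 1]")
  events <- sample_cloud_events(spec)
  sr <- spec$sample_rate
  n_total <- round(spec$duration * sr)
  buf <- numeric(n_total)
  tone_n <- round(spec$tone_duration * sr)
  for (i in seq_len(nrow(events))) {
    s0 <- round(events$onset[i] * sr) + 1L
    len <- min(tone_n, n_total - s0 + 1L)
    if (len <= 0L) next
    t <- (seq_len(len) - 1L) / sr
    tone <- waveform(sin(2 * pi * events$frequency[i] * t), sr)
    rd <- min(spec$ramp_duration, (len / sr) / 2)
    tone <- apply_ramps(tone, rd)
    idx <- s0:(s0 + len - 1L)
    buf[idx] <- buf[idx] + tone$samples
  }
  peak <- max(abs(buf))
  if (peak > 0) buf <- buf * (amplitude / peak)
  waveform(buf, sr)
}

#' Gaussian white-noise burst
#'
#' Used as the punishment sound after false alarms (Go/NoGo) and incorrect
#' 2AFC choices. Zero-mean Gaussian noise, peak-normalized.
#'
#' @param duration seconds (>= 0; 0 gives an empty waveform).
#' @param sample_rate samples/s.
#' @param amplitude peak amplitude in (0, 1].
#' @param seed integer seed or NULL.
#' @return a `waveform`.
#' @export
white_noise <- function(duration, sample_rate = 44100, amplitude = 0.9,
                        seed = NULL) {
  assert_that(is_scalar_number(duration) && duration >= 0,
              "duration must be >= 0")
  n <- round(duration * sample_rate)
  if (n == 0L) return(waveform(numeric(0), sample_rate))
  with_seed(seed, {
    x <- stats::rnorm(n)
    waveform(x * (amplitude / max(abs(x))), sample_rate)
  })
}

#' Write a waveform to a RIFF/WAV file
#'
#' Standard single-channel RIFF/WAV, either 16-bit integer PCM (format 1) or
#' 32-bit IEEE float (format 3); round-trips losslessly at the declared depth.
#'
#' @param wave a `waveform`.
#' @param path output path.
#' @param bit_depth 16 (PCM) or 32 (float).
#' @return `path`, invisibly.
#' @seealso [read_wav()]
#' @export
write_wav <- function(wave, path, bit_depth = 16) {
  stopifnot(inherits(wave, "waveform"))
  assert_that(bit_depth %in% c(16, 32), "bit_depth must be 16 or 32")
  con <- tryCatch(file(path, "wb"), error = function(e) {
    stop_input("cannot open '", path, "' for writing: ", conditionMessage(e))
  })
  on.exit(close(con))
  n <- length(wave$samples)
  bytes_per <- bit_depth / 8
  data_size <- n * bytes_per
  fmt_code <- if (bit_depth == 16) 1L else 3L
  sr <- as.integer(round(wave$sample_rate))
  w_u32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w_u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  writeChar("RIFF", con, eos = NULL)
  w_u32(36 + data_size)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  w_u32(16)
  w_u16(fmt_code)
  w_u16(1) # mono
  w_u32(sr)
  w_u32(sr * bytes_per)
  w_u16(bytes_per)
  w_u16(bit_depth)
  writeChar("data", con, eos = NULL)
  w_u32(data_size)
  if (n > 0) {
    if (bit_depth == 16) {
      x <- pmin(pmax(wave$samples, -1), 1)
      writeBin(as.integer(round(x * 32767)), con, size = 2, endian = "little")
    } else {
      writeBin(as.numeric(wave$samples), con, size = 4, endian = "little")
    }
  }
  invisible(path)
}

#' Read a RIFF/WAV file written by [write_wav()]
#'
#' @param path WAV file path.
#' @return a `waveform` with attribute `bit_depth`.
#' @export
read_wav <- function(path) {
  assert_that(file.exists(path), "no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  r_u32 <- function() readBin(con, "integer", size = 4, endian = "little")
  r_u16 <- function() readBin(con, "integer", size = 2, endian = "little")
  tag <- readChar(con, 4, useBytes = TRUE)
  assert_that(identical(tag, "RIFF"), "not a RIFF file: ", path)
  r_u32()
  assert_that(identical(readChar(con, 4, useBytes = TRUE), "WAVE"),
              "not a WAVE file: ", path)
  fmt_code <- NULL; sr <- NULL; bit_depth <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- r_u32()
    if (id == "fmt ") {
      fmt_code <- r_u16(); r_u16()
      sr <- r_u32(); r_u32(); r_u16()
      bit_depth <- r_u16()
      if (size > 16) readBin(con, "raw", size - 16)
    } else if (id == "data") {
      if (bit_depth == 16) {
        samples <- readBin(con, "integer", n = size / 2, size = 2,
                           endian = "little") / 32767
      } else {
        samples <- readBin(con, "numeric", n = size / 4, size = 4,
                           endian = "little")
      }
      break
    } else {
      readBin(con, "raw", size)
    }
  }
  assert_that(!is.null(sr) && !is.null(samples), "malformed WAV: ", path)
  out <- waveform(samples, sr)
  attr(out, "bit_depth") <- bit_depth
  out
}
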