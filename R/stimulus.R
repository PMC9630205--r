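## Schematic audio rendering: an isochronous click grid outside the
## beat-drop window, a non-rhythmic drone through it, and the probe click at
## its planned sample. The psychometric layer never inspects audio; items
## are fully described by their spec, so a schematic realization (clicks +
## drone) carries the same timing information as produced music.

#' Audio rendering settings
#'
#' @param sample_rate Samples per second (default 44100).
#' @param bit_depth Bits per sample for WAV output (16).
#' @param channels Output channels; both carry identical content (2).
#' @param probe_freq Probe click pitch in Hz. Default 87.31 Hz, the
#'   equal-tempered F2 (A4 = 440 Hz), the nominal pitch of the woodblock
#'   probe.
#' @param probe_duration Probe click length in seconds (0.120, a 16th note
#'   at 125 bpm).
#' @param probe_level Peak amplitude of the probe click (linear, 0-1).
#' @param beat_freq,beat_duration,beat_level Frequency, length and peak
#'   amplitude of the grid clicks marking each beat outside the drop window.
#' @param drone_freq,drone_level Frequency and constant amplitude of the
#'   drone filling the beat-drop window. The drone is a plain sinusoid:
#'   constant envelope, hence no amplitude periodicity at the beat rate.
#' @return An object of class `bdat_audio_spec`.
#' @export
audio_render_spec <- function(sample_rate = 44100, bit_depth = 16,
                              channels = 2,
                              probe_freq = 87.31, probe_duration = 0.120,
                              probe_level = 0.8,
                              beat_freq = 660, beat_duration = 0.060,
                              beat_level = 0.6,
                              drone_freq = 110, drone_level = 0.15) {
  stopifnot(sample_rate > 0, probe_duration > 0, beat_duration > 0,
            probe_level + drone_level <= 1, beat_level <= 1)
  structure(list(sample_rate = sample_rate, bit_depth = bit_depth,
                 channels = channels,
                 probe_freq = probe_freq, probe_duration = probe_duration,
                 probe_level = probe_level,
                 beat_freq = beat_freq, beat_duration = beat_duration,
                 beat_level = beat_level,
                 drone_freq = drone_freq, drone_level = drone_level),
            class = "bdat_audio_spec")
}

## Percussive click: exponentially decaying cosine burst. The cosine phase
## puts full amplitude on the first sample, so the onset is sample-sharp.
click_burst <- function(freq, duration, level, sample_rate) {
  n <- round(duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  level * cos(2 * pi * freq * t) * exp(-t / (duration / 5))
}

#' Render one stimulus
#'
#' Produces the audio realization of an item: grid clicks on every beat of
#' bars 1-3, bar 4 beat 1, and bars 5-6; a drone from bar 4 beat 2 until the
#' re-entry at bar 5 beat 1; and the probe click at its planned onset
#' sample `round(probe_onset * sample_rate)`. Rendering is deterministic.
#'
#' @param item A single item (one row of an item bank, or an equivalent
#'   list).
#' @param spec An [audio_render_spec()].
#' @return An object of class `bdat_stimulus`: list with `samples` (numeric
#'   matrix, one column per channel, identical columns), `sample_rate`,
#'   `planned_onsets` (data frame of `label`, `time`), `timing` (the
#'   [probe_timing()] plan) and `item_id`.
#' @export
render_stimulus <- function(item, spec = audio_render_spec()) {
  stopifnot(inherits(spec, "bdat_audio_spec"))
  item <- as.list(item)
  tp <- probe_timing(item)
  sr <- spec$sample_rate
  n <- round(tp$clip_duration * sr)
  x <- numeric(n)

  add_at <- function(x, t, burst) {
    i0 <- round(t * sr)              # 0-based onset sample
    idx <- i0 + seq_along(burst)     # 1-based indices
    keep <- idx >= 1 & idx <= length(x)
    x[idx[keep]] <- x[idx[keep]] + burst[keep]
    x
  }

  ## beat grid: all 24 beats except drop-window beats (bar 4, beats 2-4)
  beat_idx <- 0:(6 * 4 - 1)
  drop_beats <- (tp$beat_drop_bar - 1) * 4 + (tp$beat_drop_beats - 1)
  grid_beats <- setdiff(beat_idx, drop_beats)
  beat_times <- grid_beats * tp$beat_period
  beat_click <- click_burst(spec$beat_freq, spec$beat_duration,
                            spec$beat_level, sr)
  for (t in beat_times) x <- add_at(x, t, beat_click)

  ## drone spans the drop window [bar 4 beat 2, reentry)
  drone_start <- drop_beats[1] * tp$beat_period
  i0 <- round(drone_start * sr)
  i1 <- round(tp$reentry_time * sr)
  td <- (seq_len(i1 - i0) - 1) / sr
  x[(i0 + 1):i1] <- x[(i0 + 1):i1] + spec$drone_level * cos(2 * pi * spec$drone_freq * td)

  ## probe click
  if (tp$probe_onset < 0 || tp$probe_onset >= tp$clip_duration)
    stop("internal error: probe onset outside clip")
  probe_click <- click_burst(spec$probe_freq, spec$probe_duration,
                             spec$probe_level, sr)
  x <- add_at(x, tp$probe_onset, probe_click)

  peak <- max(abs(x))
  if (peak > 1) x <- x / peak        # guard; disjoint events stay below 1

  onsets <- rbind(
    data.frame(label = "beat", time = beat_times),
    data.frame(label = "drone", time = drone_start),
    data.frame(label = "probe", time = tp$probe_onset))
  onsets <- onsets[order(onsets$time), ]
  rownames(onsets) <- NULL

  structure(list(samples = matrix(rep(x, spec$channels), ncol = spec$channels),
                 sample_rate = sr, planned_onsets = onsets, timing = tp,
                 item_id = if (!is.null(item$item_id)) item$item_id else NA_character_),
            class = "bdat_stimulus")
}

#' Detect onsets in a rendered stimulus
#'
#' Simple energy-rise onset detection used as a self-check that rendering
#' matches the timing plan: a short-window RMS envelope is scanned for
#' samples whose energy exceeds an absolute floor and a multiple of the
#' energy a couple of milliseconds earlier; candidate runs closer together
#' than the refractory period collapse to their first sample.
#'
#' @param stimulus A `bdat_stimulus` from [render_stimulus()].
#' @param spec The [audio_render_spec()] used to render it.
#' @param window Short forward RMS window in seconds (default 0.0005); sets
#'   the detection time resolution.
#' @param backdrop Long backward RMS window in seconds (default 0.010). It
#'   is long relative to the drone period, so the drone's amplitude
#'   oscillation averages out instead of faking energy rises.
#' @param lookback Gap between the two windows in seconds (default 0.001).
#' @param ratio Required energy-rise factor (default 3).
#' @param floor Absolute RMS floor (default 0.02).
#' @param refractory Minimum separation between detected onsets in seconds
#'   (default 0.15; planned onsets are never closer than ~0.25 s).
#' @return A list with `detected` (numeric vector of onset times), `planned`
#'   (the stimulus' planned onsets), `max_error` (largest |detected -
#'   planned| over matched pairs, seconds) and `ok` (`TRUE` when every
#'   planned onset is recovered, there are no spurious detections, and
#'   `max_error` <= 1 ms).
#' @export
verify_onsets <- function(stimulus, spec = audio_render_spec(),
                          window = 0.0005, backdrop = 0.010,
                          lookback = 0.001, ratio = 3,
                          floor = 0.02, refractory = 0.15) {
  stopifnot(inherits(stimulus, "bdat_stimulus"))
  sr <- stimulus$sample_rate
  x <- stimulus$samples[, 1]
  w <- max(2L, round(window * sr))
  wl <- max(w, round(backdrop * sr))
  lag <- round(lookback * sr)
  ## forward-looking short RMS: env[i] summarizes samples i .. i+w-1
  cs <- cumsum(c(0, x^2))
  nenv <- length(x) - w + 1
  env <- sqrt((cs[(w + 1):(nenv + w)] - cs[1:nenv]) / w)
  ## backward long RMS over samples (i - lag - wl) .. (i - lag - 1)
  i <- seq_len(nenv)
  hi <- pmax(i - lag, 1)
  lo <- pmax(i - lag - wl, 1)
  prev <- sqrt((cs[hi] - cs[lo]) / pmax(hi - lo, 1))
  cand <- which(env > floor & env > ratio * prev + 1e-12)
  det <- numeric(0)
  if (length(cand)) {
    gap <- round(refractory * sr)
    last <- -Inf
    for (i in cand) {
      if (i - last > gap) det <- c(det, i)
      if (i - last > gap) last <- i
    }
    det <- (det - 1) / sr
  }
  planned <- stimulus$planned_onsets$time
  err <- if (length(det)) vapply(planned, function(t) min(abs(det - t)), 0) else rep(Inf, length(planned))
  spurious <- if (length(planned)) vapply(det, function(t) min(abs(planned - t)), 0) else det
  list(detected = det,
       planned = stimulus$planned_onsets,
       max_error = if (length(err)) max(err) else Inf,
       ok = length(det) == length(planned) && all(err <= 0.001) &&
         all(spurious <= 0.001))
}

#' Write / read a PCM WAV file
#'
#' Minimal RIFF/PCM writer and reader (16-bit integer samples). Channels
#' are interleaved; `read_wav` inverts `write_wav` exactly up to 16-bit
#' quantization.
#'
#' @param samples Numeric matrix (rows = frames, columns = channels) or
#'   vector, amplitudes in `[-1, 1]`, or a `bdat_stimulus`.
#' @param path File path.
#' @param sample_rate Samples per second (taken from a `bdat_stimulus`
#'   automatically).
#' @return `write_wav` returns `path` invisibly; `read_wav` returns a list
#'   with `samples` (matrix) and `sample_rate`.
#' @export
write_wav <- function(samples, path, sample_rate = 44100) {
  if (inherits(samples, "bdat_stimulus")) {
    sample_rate <- samples$sample_rate
    samples <- samples$samples
  }
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1)
  ch <- ncol(samples)
  pcm <- as.integer(pmax(pmin(round(t(samples) * 32767), 32767), -32768))
  data_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")              # PCM
  writeBin(ch, con, size = 2, endian = "little")
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * ch * 2L), con, size = 4, endian = "little")
  writeBin(as.integer(ch * 2L), con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' @rdname write_wav
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4)
  if (hdr != "RIFF") stop("not a RIFF file")
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file")
  sample_rate <- NULL; ch <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found")
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      ch <- fmt[2]
      sample_rate <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, "raw", n = sz - 8))
    } else if (id == "data") {
      pcm <- readBin(con, integer(), n = sz / 2, size = 2, endian = "little")
      break
    } else {
      invisible(readBin(con, "raw", n = sz))
    }
  }
  list(samples = t(matrix(pcm / 32767, nrow = ch)), sample_rate = sample_rate)
}
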