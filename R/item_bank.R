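## Item bank construction: displacement levels on the perceptual-accuracy
## scale, the combinatorial set of item variants, and probe timing on the
## beat grid.

#' Displacement scale settings
#'
#' Describes how off-beat probe displacements are derived. Displacements are
#' expressed as fractions of the beat period and are chosen so that
#' consecutive levels are equally spaced on the perceptual-accuracy scale
#' `cos(pi * d)^exponent`, which compresses physically equal displacement
#' steps near the beat where they are perceptually harder to tell apart.
#'
#' @param exponent Exponent of the perceptual-accuracy transform
#'   (dimensionless, default 4).
#' @param d_min,d_max Smallest and largest displacement, as fractions of the
#'   beat period. Must satisfy `0 < d_min < d_max < 0.5`; displacements at or
#'   beyond half a beat are ambiguous (a probe halfway between beats can be
#'   heard as early relative to the next beat).
#' @param n_levels Number of displacement levels (at least 2).
#' @param rounding Rounding rule applied to the inverted levels: `"percent"`
#'   rounds to the nearest whole percent of the beat period (half up),
#'   `"none"` keeps full precision.
#' @return An object of class `bdat_displacement_scale`.
#' @examples
#' displacement_levels(displacement_scale())
#' @export
displacement_scale <- function(exponent = 4, d_min = 0.15, d_max = 0.45,
                               n_levels = 7,
                               rounding = c("percent", "none")) {
  rounding <- match.arg(rounding)
  stopifnot(exponent > 0, n_levels >= 2)
  if (!(0 < d_min && d_min < d_max && d_max < 0.5))
    stop("displacement bounds must satisfy 0 < d_min < d_max < 0.5")
  structure(list(exponent = exponent, d_min = d_min, d_max = d_max,
                 n_levels = as.integer(n_levels), rounding = rounding),
            class = "bdat_displacement_scale")
}

#' Perceptual accuracy of a probe displacement
#'
#' Maps a probe displacement `d` (fraction of the beat period) to the
#' perceptual-accuracy scale `cos(pi * d)^exponent`. The transform equals 1
#' at zero displacement and 0 at half a beat, and is strictly decreasing in
#' between for a positive even exponent.
#'
#' @param d Displacement(s), fraction of the beat period, in `[0, 0.5]`.
#' @param exponent Exponent of the transform (default 4).
#' @return Perceptual accuracy value(s) in `[0, 1]`.
#' @export
perceptual_accuracy <- function(d, exponent = 4) {
  if (any(d < 0 | d > 0.5)) stop("displacement must lie in [0, 0.5]")
  cos(pi * d)^exponent
}

## Invert the perceptual-accuracy transform by bisection on [0, 0.5].
invert_perceptual_accuracy <- function(pa, exponent = 4, tol = 1e-12) {
  vapply(pa, function(target) {
    lo <- 0; hi <- 0.5
    ## PA is decreasing in d
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (perceptual_accuracy(mid, exponent) > target) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
}

round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  floor(x * s + 0.5) / s
}

#' Probe displacement levels
#'
#' Computes the displacement levels used for off-beat probes: perceptual
#' accuracy is evaluated at `d_min` and `d_max`, `n_levels` equally spaced
#' perceptual-accuracy values (inclusive of both endpoints) are taken, each
#' is inverted back to a displacement by bisection, and the rounding rule is
#' applied. With the default settings this reproduces the published level
#' set 15, 18, 20, 23, 26, 31, 45 percent of the beat period.
#'
#' @param scale A [displacement_scale()].
#' @return Increasing numeric vector of `n_levels` displacements (fractions
#'   of the beat period).
#' @export
displacement_levels <- function(scale = displacement_scale()) {
  stopifnot(inherits(scale, "bdat_displacement_scale"))
  pa_hi <- perceptual_accuracy(scale$d_min, scale$exponent)
  pa_lo <- perceptual_accuracy(scale$d_max, scale$exponent)
  targets <- seq(pa_hi, pa_lo, length.out = scale$n_levels)
  d <- invert_perceptual_accuracy(targets, scale$exponent)
  ## pin the endpoints exactly; bisection only matters in the interior
  d[1] <- scale$d_min
  d[length(d)] <- scale$d_max
  if (any(diff(d) <= 0))
    stop("perceptual-accuracy inversion produced non-increasing levels")
  if (scale$rounding == "percent") d <- round_half_up(d, 2)
  d
}

#' Tempo variants around a base tempo
#'
#' Five tempi spanning -5 percent to +5 percent of the base in even steps.
#' For the canonical 125 bpm base the published variant list
#' 119, 122, 125, 128, 132 bpm is returned verbatim; for any other base the
#' multiplicative steps are rounded half-up to integer bpm.
#'
#' @param base_bpm Base tempo in beats per minute.
#' @return Integer vector of five tempi, centred on the base.
#' @export
tempo_variants <- function(base_bpm = 125) {
  stopifnot(base_bpm > 0)
  if (isTRUE(all.equal(base_bpm, 125))) return(c(119L, 122L, 125L, 128L, 132L))
  pct <- c(-5, -2.5, 0, 2.5, 5)
  as.integer(round_half_up(base_bpm + base_bpm * pct / 100))
}

#' Default track/condition exclusions
#'
#' Tracks excluded after the calibration-study screening: one track whose
#' on-beat items showed below-chance accuracy, and three tracks whose
#' off-beat items did.
#'
#' @return Data frame with columns `track_id` and `condition`.
#' @export
default_exclusions <- function() {
  data.frame(track_id = c(3L, 12L, 27L, 30L),
             condition = c("ON", "OFF", "OFF", "OFF"),
             stringsAsFactors = FALSE)
}

#' Build the item bank
#'
#' Constructs the full combinatorial item set: for every track and tempo,
#' two on-beat items (probe on beat 3 or beat 4 of the beat-drop bar) and
#' `2 x 2 x n_levels` off-beat items (target beat 3/4, direction early/late,
#' displacement level). With 30 tracks, 7 levels and a single tempo this
#' yields 900 items; the five tempo variants yield 4,500.
#'
#' @param n_tracks Number of tracks (default 30).
#' @param scale A [displacement_scale()].
#' @param tempi Numeric vector of tempi in bpm (default 125). Duplicates are
#'   an error.
#' @param exclusions Optional data frame with columns `track_id` and
#'   `condition`; matching (track, condition) combinations are dropped.
#'   Use [default_exclusions()] for the published set.
#' @param seed Optional integer recorded in the bank metadata. Construction
#'   itself is deterministic.
#' @return A data frame of class `bdat_item_bank` with one row per item and
#'   columns `item_id`, `track_id`, `condition`, `target_beat`, `direction`,
#'   `displacement_level`, `displacement`, `tempo_bpm`. Generation
#'   parameters are stored in attributes.
#' @export
build_item_bank <- function(n_tracks = 30, scale = displacement_scale(),
                            tempi = 125, exclusions = NULL, seed = NULL) {
  stopifnot(n_tracks >= 1, length(tempi) >= 1)
  if (anyDuplicated(tempi)) stop("duplicate tempi in configuration")
  levels <- displacement_levels(scale)

  on <- expand.grid(track_id = seq_len(n_tracks), target_beat = c(3L, 4L),
                    tempo_bpm = tempi, KEEP.OUT.ATTRS = FALSE)
  on$condition <- "ON"
  on$direction <- "none"
  on$displacement_level <- 0L
  on$displacement <- 0

  off <- expand.grid(track_id = seq_len(n_tracks), target_beat = c(3L, 4L),
                     direction = c("early", "late"),
                     displacement_level = seq_along(levels),
                     tempo_bpm = tempi,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  off$condition <- "OFF"
  off$displacement <- levels[off$displacement_level]

  cols <- c("track_id", "condition", "target_beat", "direction",
            "displacement_level", "displacement", "tempo_bpm")
  bank <- rbind(on[, cols], off[, cols])
  bank <- bank[order(bank$track_id, bank$condition, bank$target_beat,
                     bank$direction, bank$displacement_level,
                     bank$tempo_bpm), ]

  if (!is.null(exclusions)) {
    stopifnot(all(c("track_id", "condition") %in% names(exclusions)))
    drop <- paste(bank$track_id, bank$condition) %in%
      paste(exclusions$track_id, exclusions$condition)
    bank <- bank[!drop, ]
  }

  bank$item_id <- sprintf("t%02d_%s_b%d_%s_l%d_%dbpm",
                          bank$track_id, tolower(bank$condition),
                          bank$target_beat,
                          substr(bank$direction, 1, 1),
                          bank$displacement_level, round(bank$tempo_bpm))
  rownames(bank) <- NULL
  bank <- bank[, c("item_id", cols)]
  structure(bank,
            scale = scale, tempi = tempi, levels = levels,
            exclusions = exclusions, seed = seed,
            class = c("bdat_item_bank", "data.frame"))
}

#' Probe timing on the beat grid
#'
#' Lays one item out in time. Clips are six bars of 4/4 starting at bar 1
#' beat 1 = 0 s; beat `k` of bar `b` (both 1-based) falls at
#' `((b - 1) * 4 + (k - 1)) * beat_period` seconds with
#' `beat_period = 60 / tempo_bpm`. The beat-drop covers beats 2-4 of bar 4;
#' the rhythm re-enters at bar 5 beat 1. The probe falls exactly on the
#' target beat for on-beat items and `displacement * beat_period` before
#' (early) or after (late) it for off-beat items.
#'
#' @param item A single item: one row of a [build_item_bank()] data frame or
#'   a list with fields `tempo_bpm`, `target_beat`, `direction`,
#'   `displacement`.
#' @return An object of class `bdat_timing_plan`: a list with `beat_period`,
#'   `bars`, `beats_per_bar`, `beat_drop_bar`, `beat_drop_beats`,
#'   `probe_onset`, `probe_duration`, `reentry_time` and `clip_duration`
#'   (all times in seconds from clip start).
#' @export
probe_timing <- function(item) {
  item <- as.list(item)
  bp <- 60 / item$tempo_bpm
  beat_time <- function(bar, beat) ((bar - 1) * 4 + (beat - 1)) * bp
  target <- beat_time(4, item$target_beat)
  shift <- switch(as.character(item$direction),
                  early = -item$displacement * bp,
                  late  =  item$displacement * bp,
                  none  = 0,
                  stop("unknown probe direction: ", item$direction))
  structure(list(beat_period = bp,
                 bars = 6L, beats_per_bar = 4L,
                 beat_drop_bar = 4L, beat_drop_beats = 2:4,
                 probe_onset = target + shift,
                 probe_duration = 0.120,
                 reentry_time = beat_time(5, 1),
                 clip_duration = 6 * 4 * bp),
            class = "bdat_timing_plan")
}

#' Write / read an item bank
#'
#' The CSV form holds one row per item with the documented columns of
#' [build_item_bank()]; the JSON form additionally carries the generation
#' metadata (scale settings, tempi, exclusions, seed).
#'
#' @param bank A `bdat_item_bank`.
#' @param path Output file; format chosen by extension (`.csv` or `.json`).
#' @return `write_item_bank` returns `path` invisibly; `read_item_bank`
#'   returns a `bdat_item_bank`.
#' @export
write_item_bank <- function(bank, path) {
  stopifnot(inherits(bank, "bdat_item_bank"))
  if (grepl("\\.json$", path)) {
    scale <- attr(bank, "scale")
    obj <- list(metadata = list(scale = unclass(scale),
                                tempi = attr(bank, "tempi"),
                                exclusions = attr(bank, "exclusions"),
                                seed = attr(bank, "seed")),
                items = as.data.frame(bank))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  } else {
    write.csv(as.data.frame(bank), path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_item_bank
#' @export
read_item_bank <- function(path) {
  if (grepl("\\.json$", path)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    bank <- obj$items
    meta <- obj$metadata
    scale <- displacement_scale(meta$scale$exponent, meta$scale$d_min,
                                meta$scale$d_max, meta$scale$n_levels,
                                meta$scale$rounding)
    structure(bank, scale = scale, tempi = meta$tempi,
              levels = displacement_levels(scale),
              exclusions = meta$exclusions, seed = meta$seed,
              class = c("bdat_item_bank", "data.frame"))
  } else {
    bank <- read.csv(path, stringsAsFactors = FALSE)
    structure(bank, class = c("bdat_item_bank", "data.frame"))
  }
}
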