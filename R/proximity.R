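# Proximity processing: sync-tone detection, RSSI-gated interval
# construction, and utterance <-> proximity matching.

#' Detect the synchronization tone in an audio signal
#'
#' Band-pass filters the signal around the configured tone frequency and
#' returns the earliest time at which the in-band frame energy exceeds an
#' adaptive threshold (`sync_tone_k` times the median frame energy) sustained
#' for at least `sync_tone_sustain` seconds. Frames are 20 ms with a 10 ms
#' hop, so onsets are resolved to about one hop.
#'
#' @param samples Numeric vector, mono audio samples.
#' @param sample_rate Sampling rate in Hz. Must exceed twice the top of the
#'   detection band.
#' @param cfg An [analysis_config()].
#' @return Onset time of the tone in seconds.
#' @examples
#' sr <- 16000
#' t <- seq(0, 3, by = 1 / sr)
#' x <- rnorm(length(t), sd = 0.01)
#' tone <- t >= 2 & t < 2.5
#' x[tone] <- x[tone] + sin(2 * pi * 1000 * t[tone])
#' detect_sync_tone(x, sr)
#' @export
detect_sync_tone <- function(samples, sample_rate, cfg = analysis_config()) {
  band <- cfg$sync_tone_freq + c(-1, 1) * cfg$sync_tone_bandwidth / 2
  if (sample_rate <= 2 * band[2]) {
    abort("sample_rate violates the Nyquist requirement for the detection band",
          class = "classtalk_config_error")
  }
  if (length(samples) < 0.5 * sample_rate) {
    abort("signal shorter than 0.5 s", class = "classtalk_config_error")
  }
  bf <- signal::butter(4, band / (sample_rate / 2), type = "pass")
  filtered <- signal::filtfilt(bf, samples)

  frame_len <- max(1L, round(0.020 * sample_rate))
  hop <- max(1L, round(0.010 * sample_rate))
  starts <- seq(1L, length(filtered) - frame_len + 1L, by = hop)
  energy <- vapply(starts, function(s) {
    mean(filtered[s:(s + frame_len - 1L)]^2)
  }, numeric(1))
  total <- vapply(starts, function(s) {
    mean(samples[s:(s + frame_len - 1L)]^2)
  }, numeric(1))

  # a tone frame must stand out against the in-band background AND carry a
  # substantial share of the frame's broadband energy, so out-of-band tones
  # and filter edge transients are not mistaken for the sync tone
  threshold <- cfg$sync_tone_k * median(energy)
  above <- energy > threshold & energy > 0 & energy > 0.25 * total
  need <- max(1L, ceiling(cfg$sync_tone_sustain * sample_rate / hop))
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  hit <- which(runs$values & runs$lengths >= need)
  if (length(hit) == 0) {
    abort("tone not found", class = "classtalk_tone_error")
  }
  first_frame <- ends[hit[1]] - runs$lengths[hit[1]] + 1L
  (starts[first_frame] - 1L) / sample_rate
}

#' Build within-threshold proximity intervals from RSSI events
#'
#' Keeps readings with `rssi >= rssi_threshold` and turns them into per-pair
#' time intervals: consecutive kept readings for a pair are merged into one
#' interval when their gap is at most `2 * ping_period` (so one missed beacon
#' ping does not fragment an interaction), and an isolated reading yields an
#' interval of one ping period centred on its timestamp. A run of kept
#' readings therefore spans `[first - ping_period/2, last + ping_period/2]`.
#'
#' @param events Proximity-event tibble (columns `timestamp`, `id_a`, `id_b`,
#'   `rssi`), sorted by timestamp with normalized pairs (see
#'   [read_proximity_log()]).
#' @param cfg An [analysis_config()]; supplies `rssi_threshold`.
#' @param ping_period Nominal beacon reporting cadence in seconds.
#' @return Tibble with columns `id_a`, `id_b`, `start`, `end`; intervals for a
#'   pair are non-overlapping and sorted.
#' @examples
#' ev <- tibble::tibble(timestamp = c(1, 2, 3), id_a = "A", id_b = "B",
#'                      rssi = -70)
#' build_proximity_intervals(ev, ping_period = 1)
#' @export
build_proximity_intervals <- function(events, cfg = analysis_config(),
                                      ping_period = 1) {
  check_positive(ping_period, "ping_period")
  empty <- tibble::tibble(id_a = character(), id_b = character(),
                          start = numeric(), end = numeric())
  if (is.null(events) || nrow(events) == 0) return(empty)
  kept <- events[events$rssi >= cfg$rssi_threshold, , drop = FALSE]
  if (nrow(kept) == 0) return(empty)

  kept |>
    dplyr::mutate(.pair = pair_key(.data$id_a, .data$id_b)) |>
    dplyr::arrange(.data$.pair, .data$timestamp) |>
    dplyr::group_by(.data$.pair, .data$id_a, .data$id_b) |>
    dplyr::group_modify(function(d, key) {
      gaps <- diff(d$timestamp)
      run <- cumsum(c(0, gaps > 2 * ping_period))
      dplyr::tibble(
        start = as.numeric(tapply(d$timestamp, run, min)) - ping_period / 2,
        end = as.numeric(tapply(d$timestamp, run, max)) + ping_period / 2
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::select("id_a", "id_b", "start", "end") |>
    dplyr::arrange(.data$id_a, .data$id_b, .data$start)
}

#' Attach proximity partners to each utterance
#'
#' Fills the `in_proximity_of` column of a transcript: for every utterance,
#' the set of partners who were within the proximity gate of the utterance's
#' speaker when it was spoken — the other member of every interval involving
#' the speaker that contains the utterance onset. These partners are the
#' candidate receivers of the utterance in [dyadic_table()]. When `focal` is
#' given, only intervals involving the focal participant are considered
#' (wearable deployments log RSSI for the focal participant's pairs), so the
#' focal child's utterances collect the partners near the child and a
#' teacher/peer utterance collects the focal child when the corresponding
#' pair is within range. Membership is decided at the utterance onset, a
#' deterministic and jitter-robust convention, and the operation is
#' idempotent, leaving ordering and all other fields unchanged.
#'
#' @param transcript A transcript tibble.
#' @param intervals Interval tibble from [build_proximity_intervals()].
#' @param focal Optional identifier of the focal participant; restricts
#'   intervals to the focal participant's pairs.
#' @return The transcript with `in_proximity_of` populated.
#' @export
attach_proximity <- function(transcript, intervals, focal = NULL) {
  iv <- intervals
  if (!is.null(focal)) {
    iv <- iv[iv$id_a == focal | iv$id_b == focal, , drop = FALSE]
  }
  transcript$in_proximity_of <- purrr::map(seq_len(nrow(transcript)), function(i) {
    sp <- transcript$speaker_id[i]
    t <- transcript$onset[i]
    hit <- (iv$id_a == sp | iv$id_b == sp) & iv$start <= t & t <= iv$end
    partner <- ifelse(iv$id_a[hit] == sp, iv$id_b[hit], iv$id_a[hit])
    sort(unique(as.character(partner)))
  })
  transcript
}

#' Write proximity intervals to CSV
#'
#' @param intervals Interval tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(intervals, path) {
  out <- tibble::tibble(
    id_a = intervals$id_a, id_b = intervals$id_b,
    start_s = sprintf("%.3f", intervals$start),
    end_s = sprintf("%.3f", intervals$end)
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
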