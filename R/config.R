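#' Analysis configuration
#'
#' Bundle of the thresholds the pipeline uses. Defaults are the operating
#' constants of the wearable classroom-sensing protocol this package
#' implements: speech is kept when the Bluetooth received signal strength is
#' at or above -74 dB (approximately 1.5 m separation), utterances are split
#' at pauses of 0.3 s or longer, teacher/peer talk counts as directed at the
#' focal child when it starts within 3 s of the child's own speech, coder
#' boundary agreement uses a 250 ms tolerance, and accuracy statistics are
#' computed over six-minute (360 s) windows.
#'
#' @param rssi_threshold RSSI gate in dB (negative); readings below it are
#'   treated as out of proximity. Default -74.
#' @param proximity_distance Nominal distance in metres corresponding to the
#'   RSSI gate. Documentation only; no dB-to-metre conversion is performed.
#' @param pause_boundary Minimum inter-word pause, in seconds, that triggers an
#'   utterance boundary when word timings are available. Default 0.3.
#' @param direct_talk_window Maximum separation in seconds between a
#'   teacher/peer utterance onset and the nearest focal-child utterance
#'   boundary for the utterance to count as direct talk. Default 3.
#' @param agreement_tolerance Boundary-agreement tolerance in seconds.
#'   Default 0.25.
#' @param eval_window Evaluation window length in seconds. Default 360.
#' @param sync_tone_freq Synchronization-tone centre frequency in Hz.
#' @param sync_tone_bandwidth Band-pass width in Hz around the tone.
#' @param sync_tone_k In-band frame energy must exceed `k` times the median
#'   frame energy to count as tone. Default 6.
#' @param sync_tone_sustain Minimum duration in seconds the tone must be
#'   sustained. Default 0.1.
#' @param punctuation_boundaries Characters treated as utterance boundaries.
#' @param turn_max_gap Maximum silence in seconds between consecutive
#'   utterances for a speaker alternation to count as a conversational turn.
#'   Default `Inf` (no cutoff).
#' @param random_seed Integer seed recorded in run manifests.
#'
#' @return A list of class `"analysis_config"`.
#' @examples
#' cfg <- analysis_config()
#' cfg$rssi_threshold
#' @export
analysis_config <- function(rssi_threshold = -74,
                            proximity_distance = 1.5,
                            pause_boundary = 0.3,
                            direct_talk_window = 3,
                            agreement_tolerance = 0.25,
                            eval_window = 360,
                            sync_tone_freq = 1000,
                            sync_tone_bandwidth = 100,
                            sync_tone_k = 6,
                            sync_tone_sustain = 0.1,
                            punctuation_boundaries = c(".", "?", "!"),
                            turn_max_gap = Inf,
                            random_seed = 1L) {
  if (!is.numeric(rssi_threshold) || rssi_threshold >= 0) {
    abort_validation("`rssi_threshold` must be negative (dB)")
  }
  for (nm in c("proximity_distance", "pause_boundary", "direct_talk_window",
               "agreement_tolerance", "eval_window", "sync_tone_freq",
               "sync_tone_bandwidth", "sync_tone_k", "sync_tone_sustain",
               "turn_max_gap")) {
    check_positive(get(nm), nm)
  }
  if (length(punctuation_boundaries) == 0) {
    abort_validation("`punctuation_boundaries` must be non-empty")
  }
  structure(
    list(
      rssi_threshold = rssi_threshold,
      proximity_distance = proximity_distance,
      pause_boundary = pause_boundary,
      direct_talk_window = direct_talk_window,
      agreement_tolerance = agreement_tolerance,
      eval_window = eval_window,
      sync_tone_freq = sync_tone_freq,
      sync_tone_bandwidth = sync_tone_bandwidth,
      sync_tone_k = sync_tone_k,
      sync_tone_sustain = sync_tone_sustain,
      punctuation_boundaries = punctuation_boundaries,
      turn_max_gap = turn_max_gap,
      random_seed = as.integer(random_seed)
    ),
    class = "analysis_config"
  )
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-22s %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  }
  invisible(x)
}
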