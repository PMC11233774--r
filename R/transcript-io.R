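# Transcript and proximity-log I/O.
#
# A transcript is an ordinary tibble with one row per utterance and columns
#   utterance_id, recording_id, speaker_id, role, onset, offset, raw_text,
#   tokens (list of character), in_proximity_of (list of character),
#   provenance ("reference" or "predicted").
# The canonical on-disk form is UTF-8 CSV with header
#   recording_id, speaker_id, role, onset_s, offset_s, text
# so ground-truth fixtures stay transparent and diff-able.

transcript_csv_columns <- c("recording_id", "speaker_id", "role",
                            "onset_s", "offset_s", "text")

#' Build a transcript tibble from utterance records
#'
#' Validates utterance records, sorts them by onset (stable ties), derives
#' tokens from the raw text, and assigns utterance identifiers. This is the
#' common constructor behind [read_transcript()] and [generate_corpus()].
#'
#' @param x A data frame with columns `recording_id`, `speaker_id`, `role`,
#'   `onset`, `offset`, `raw_text` (extra columns are preserved).
#' @param provenance `"reference"` (manually produced) or `"predicted"`
#'   (automatically produced).
#' @return A transcript tibble sorted by onset.
#' @export
as_transcript <- function(x, provenance = c("reference", "predicted")) {
  provenance <- match.arg(provenance)
  x <- tibble::as_tibble(x)
  needed <- c("recording_id", "speaker_id", "role", "onset", "offset", "raw_text")
  missing <- setdiff(needed, names(x))
  if (length(missing) > 0) {
    abort_format(sprintf("missing column(s): %s", paste(missing, collapse = ", ")))
  }
  if (nrow(x) > 0) {
    bad_role <- which(!x$role %in% roles)
    if (length(bad_role) > 0) {
      abort_validation(sprintf(
        "unknown role '%s' in row %d (expected one of %s)",
        x$role[bad_role[1]], bad_role[1], paste(roles, collapse = ", ")
      ))
    }
    bad_span <- which(x$offset < x$onset | x$onset < 0)
    if (length(bad_span) > 0) {
      abort_validation(sprintf(
        "offset < onset (or negative onset) in row %d", bad_span[1]
      ))
    }
    if (length(unique(x$recording_id)) > 1) {
      abort_validation("all utterances in a transcript must share recording_id")
    }
  }
  ord <- order(x$onset)  # order() is stable, preserving input tie order
  x <- x[ord, , drop = FALSE]
  x$onset <- round(x$onset, 3)  # 1 ms resolution
  x$offset <- round(x$offset, 3)
  x$tokens <- tokenize_text(x$raw_text)
  if (!"in_proximity_of" %in% names(x)) {
    x$in_proximity_of <- rep(list(character(0)), nrow(x))
  }
  if (!"utterance_id" %in% names(x)) {
    rec <- if (nrow(x) > 0) x$recording_id[1] else "rec"
    x$utterance_id <- sprintf("%s-u%04d", rec, seq_len(nrow(x)))
  }
  x$provenance <- provenance
  first <- c("utterance_id", "recording_id", "speaker_id", "role",
             "onset", "offset", "raw_text", "tokens", "in_proximity_of",
             "provenance")
  x[, c(first, setdiff(names(x), first)), drop = FALSE]
}

#' Read a diarized transcript
#'
#' Reads the canonical tabular transcript format (CSV with columns
#' `recording_id`, `speaker_id`, `role`, `onset_s`, `offset_s`, `text`) or an
#' ELAN `.eaf` annotation file with one tier per speaker. Utterances are
#' returned sorted by onset with tokens derived from the text.
#'
#' For the ELAN dialect each `TIER` becomes one speaker: the `TIER_ID`
#' attribute is the speaker id and the `PARTICIPANT` attribute must carry the
#' role (`teacher`, `focal_child` or `peer`); annotation values are the raw
#' text and the time slots give onset/offset in milliseconds.
#'
#' @param path Path to the file.
#' @param dialect `"tabular"` (default) or `"elan"`.
#' @param provenance Provenance tag for the transcript, `"reference"` or
#'   `"predicted"`.
#' @return A transcript tibble (see [as_transcript()]).
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c(
#'   "recording_id,speaker_id,role,onset_s,offset_s,text",
#'   "r1,T1,teacher,0.0,2.0,You are right.",
#'   "r1,C1,focal_child,2.5,3.2,okay"
#' ), f)
#' read_transcript(f)
#' @export
read_transcript <- function(path, dialect = c("tabular", "elan"),
                            provenance = c("reference", "predicted")) {
  dialect <- match.arg(dialect)
  provenance <- match.arg(provenance)
  check_file_exists(path)
  if (dialect == "elan") {
    return(read_transcript_eaf(path, provenance))
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing <- setdiff(transcript_csv_columns, names(raw))
  if (length(missing) > 0) {
    abort_format(sprintf("transcript file %s is missing column(s): %s",
                         path, paste(missing, collapse = ", ")))
  }
  onset <- suppressWarnings(as.numeric(raw$onset_s))
  offset <- suppressWarnings(as.numeric(raw$offset_s))
  bad <- which(is.na(onset) | is.na(offset))
  if (length(bad) > 0) {
    abort_validation(sprintf("non-numeric onset/offset in row %d of %s", bad[1], path))
  }
  as_transcript(
    tibble::tibble(
      recording_id = raw$recording_id,
      speaker_id = raw$speaker_id,
      role = raw$role,
      onset = onset,
      offset = offset,
      raw_text = dplyr::coalesce(raw$text, "")
    ),
    provenance = provenance
  )
}

read_transcript_eaf <- function(path, provenance = "reference") {
  doc <- xml2::read_xml(path)
  slots <- xml2::xml_find_all(doc, ".//TIME_ORDER/TIME_SLOT")
  slot_time <- stats::setNames(
    as.numeric(xml2::xml_attr(slots, "TIME_VALUE")) / 1000,
    xml2::xml_attr(slots, "TIME_SLOT_ID")
  )
  tiers <- xml2::xml_find_all(doc, ".//TIER")
  rec <- sub("\\.eaf$", "", basename(path), ignore.case = TRUE)
  rows <- purrr::map_dfr(tiers, function(tier) {
    speaker <- xml2::xml_attr(tier, "TIER_ID")
    role <- xml2::xml_attr(tier, "PARTICIPANT")
    anns <- xml2::xml_find_all(tier, ".//ALIGNABLE_ANNOTATION")
    if (length(anns) == 0) return(NULL)
    tibble::tibble(
      recording_id = rec,
      speaker_id = speaker,
      role = role,
      onset = unname(slot_time[xml2::xml_attr(anns, "TIME_SLOT_REF1")]),
      offset = unname(slot_time[xml2::xml_attr(anns, "TIME_SLOT_REF2")]),
      raw_text = xml2::xml_text(xml2::xml_find_first(anns, ".//ANNOTATION_VALUE"))
    )
  })
  if (is.null(rows) || nrow(rows) == 0) {
    rows <- tibble::tibble(recording_id = character(), speaker_id = character(),
                           role = character(), onset = numeric(),
                           offset = numeric(), raw_text = character())
  }
  as_transcript(rows, provenance = provenance)
}

#' Write a transcript to the canonical CSV format
#'
#' @param transcript A transcript tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transcript <- function(transcript, path) {
  out <- tibble::tibble(
    recording_id = transcript$recording_id,
    speaker_id = transcript$speaker_id,
    role = transcript$role,
    onset_s = sprintf("%.3f", transcript$onset),
    offset_s = sprintf("%.3f", transcript$offset),
    text = transcript$raw_text
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a proximity log
#'
#' Reads timestamped pairwise RSSI readings from a CSV with columns
#' `timestamp_s`, `id_a`, `id_b`, `rssi_db`. Events are returned sorted by
#' timestamp with the participant pair normalized to lexicographic order
#' (an exchange between A and B is the same event as one between B and A).
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `timestamp`, `id_a`, `id_b`, `rssi`.
#' @export
read_proximity_log <- function(path) {
  check_file_exists(path)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  needed <- c("timestamp_s", "id_a", "id_b", "rssi_db")
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0) {
    abort_format(sprintf("proximity log %s is missing column(s): %s",
                         path, paste(missing, collapse = ", ")))
  }
  rssi <- suppressWarnings(as.numeric(raw$rssi_db))
  bad <- which(is.na(rssi) & !is.na(raw$rssi_db))
  if (length(bad) > 0 || anyNA(raw$rssi_db)) {
    row <- if (length(bad) > 0) bad[1] else which(is.na(raw$rssi_db))[1]
    abort_validation(sprintf("non-numeric rssi in row %d of %s", row, path))
  }
  ts <- suppressWarnings(as.numeric(raw$timestamp_s))
  if (anyNA(ts)) {
    abort_validation(sprintf("non-numeric timestamp in row %d of %s",
                             which(is.na(ts))[1], path))
  }
  as_proximity_events(tibble::tibble(
    timestamp = ts, id_a = raw$id_a, id_b = raw$id_b, rssi = rssi
  ))
}

#' Validate and normalize proximity events
#'
#' @param events Data frame with columns `timestamp`, `id_a`, `id_b`, `rssi`.
#' @return Tibble sorted by timestamp with the pair in lexicographic order.
#' @export
as_proximity_events <- function(events) {
  events <- tibble::as_tibble(events)
  self_pair <- which(events$id_a == events$id_b)
  if (length(self_pair) > 0) {
    abort_validation(sprintf("id_a equals id_b in row %d", self_pair[1]))
  }
  pair <- normalize_pair(events$id_a, events$id_b)
  events$id_a <- pair$id_a
  events$id_b <- pair$id_b
  events[order(events$timestamp), , drop = FALSE]
}

#' Write a proximity log to CSV
#'
#' @param events Proximity-event tibble (see [read_proximity_log()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_proximity_log <- function(events, path) {
  out <- tibble::tibble(
    timestamp_s = sprintf("%.3f", events$timestamp),
    id_a = events$id_a,
    id_b = events$id_b,
    rssi_db = format(events$rssi, trim = TRUE)
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
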