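# The thirteen linguistic indices, computed over utterance sets and at the
# dyadic (sender -> receiver) level. Index order follows the standard table:
# UT WD AV CC SC VB AJ UW RW MLU TTR CT SD.

index_names <- c("UT", "WD", "AV", "CC", "SC", "VB", "AJ", "UW", "RW",
                 "MLU", "TTR", "CT", "SD")

#' Count conversational turns in a dyad's utterance stream
#'
#' A conversational turn is a back-and-forth alternation between the two
#' speakers: the count of adjacent utterance pairs (in time order) spoken by
#' different speakers. With `turn_max_gap` finite, an alternation only counts
#' when the silence between the previous utterance's offset and the next
#' utterance's onset is at most that many seconds; the default is no cutoff.
#'
#' @param utterances Transcript tibble containing the utterances of at most
#'   two distinct speakers, sorted by onset. Vocalization-only rows (no word
#'   tokens) are skipped.
#' @param turn_max_gap Maximum silence in seconds for an alternation to
#'   count. Default `Inf`.
#' @return Integer count of alternations.
#' @examples
#' tr <- as_transcript(tibble::tibble(
#'   recording_id = "r1", speaker_id = c("A", "B", "A"),
#'   role = c("teacher", "focal_child", "teacher"),
#'   onset = c(0, 2, 4), offset = c(1, 3, 5), raw_text = "hi there"
#' ))
#' count_turns(tr)
#' @export
count_turns <- function(utterances, turn_max_gap = Inf) {
  u <- utterances[lengths(utterances$tokens) > 0, , drop = FALSE]
  sp <- u$speaker_id
  if (length(unique(sp)) > 2) {
    abort_validation("count_turns requires at most two distinct speakers")
  }
  if (length(sp) < 2) return(0L)
  alternation <- sp[-1] != sp[-length(sp)]
  gap <- u$onset[-1] - u$offset[-length(sp)]
  sum(alternation & gap <= turn_max_gap)
}

#' Compute the thirteen linguistic indices over a set of utterances
#'
#' Returns one row with: UT (utterances), WD (words), AV (auxiliary verbs),
#' CC (coordinating conjunctions), SC (subordinating conjunctions), VB (main
#' verbs), AJ (adjectives), UW (unique words, case-folded surface forms), RW
#' (rare words, counted as distinct rare forms so RW can never exceed UW),
#' MLU (words per utterance, WD/UT), TTR (unique words over
#' words, UW/WD), CT (conversational turns, when at most two speakers are
#' present), and SD (total speech duration in seconds). Vocalization-only
#' rows (no word tokens) are skipped by every count. Undefined ratios (UT or
#' WD of zero) are reported as `NA`, never zero, so downstream accuracy
#' windows can exclude them instead of being biased toward zero.
#'
#' @param utterances Transcript tibble.
#' @param tagged Optional pre-computed tagged tokens (from
#'   [tag_transcript()], possibly ground-truth tags); when `NULL` the
#'   utterances are tagged with `tagger`.
#' @param freq Optional [frequency_list()] for rare-word classification; when
#'   `NULL`, RW is `NA`.
#' @param tagger Tagger used when `tagged` is `NULL`.
#' @param turn_max_gap Passed to [count_turns()].
#' @return One-row tibble with the thirteen index columns.
#' @examples
#' tr <- as_transcript(tibble::tibble(
#'   recording_id = "r1", speaker_id = "T1", role = "teacher",
#'   onset = c(0, 5), offset = c(4, 6),
#'   raw_text = c("I am going to read you something off of my cards",
#'                "You are right")
#' ))
#' index_vector(tr)
#' @export
index_vector <- function(utterances, tagged = NULL, freq = NULL,
                         tagger = pos_tag_rules, turn_max_gap = Inf) {
  u <- utterances[lengths(utterances$tokens) > 0, , drop = FALSE]
  if (is.null(tagged)) {
    tagged <- tag_transcript(u, tagger = tagger)
  } else {
    tagged <- tagged[tagged$utterance_id %in% u$utterance_id, , drop = FALSE]
  }
  ut <- nrow(u)
  wd <- sum(lengths(u$tokens))
  pos_count <- function(p) sum(tagged$pos == p)
  uw <- length(unique(fold_token(unlist(u$tokens))))
  # rare words are counted at the type level (distinct rare forms), so the
  # count can never exceed the unique-word count
  rw <- if (is.null(freq)) {
    NA_integer_
  } else {
    length(unique(tagged$folded[is_rare(tagged, freq)]))
  }
  ct <- if (length(unique(u$speaker_id)) <= 2) {
    count_turns(u, turn_max_gap = turn_max_gap)
  } else {
    NA_integer_
  }
  tibble::tibble(
    UT = ut,
    WD = wd,
    AV = pos_count("AUX"),
    CC = pos_count("CCONJ"),
    SC = pos_count("SCONJ"),
    VB = pos_count("VERB"),
    AJ = pos_count("ADJ"),
    UW = uw,
    RW = rw,
    MLU = if (ut > 0) wd / ut else NA_real_,
    TTR = if (wd > 0) uw / wd else NA_real_,
    CT = ct,
    SD = sum(u$offset - u$onset)
  )
}

#' Dyadic (sender -> receiver) index table
#'
#' Computes the thirteen indices for every ordered (sender, receiver) pair.
#' With proximity gating enabled (the default), a sender's utterance
#' contributes to the dyad (sender -> r) for every partner `r` in its
#' `in_proximity_of` set — an utterance heard by k partners contributes to k
#' dyads. With gating disabled, every other speaker in the transcript is
#' treated as a receiver of every utterance. CT for a dyad is computed over
#' the merged, time-ordered stream of both directions of the pair, so both
#' orientations of a dyad report the same turn count.
#'
#' @param transcript Transcript tibble; with `gate = TRUE`,
#'   [attach_proximity()] must have been applied.
#' @param freq Optional [frequency_list()] for RW.
#' @param tagged Optional pre-computed tagged tokens for the whole
#'   transcript.
#' @param tagger Tagger used when `tagged` is `NULL`.
#' @param gate Apply proximity gating (default `TRUE`).
#' @param turn_max_gap Passed to [count_turns()].
#' @return Tibble with columns `sender`, `receiver` and the thirteen indices.
#' @export
dyadic_table <- function(transcript, freq = NULL, tagged = NULL,
                         tagger = pos_tag_rules, gate = TRUE,
                         turn_max_gap = Inf) {
  empty <- tibble::as_tibble(c(
    list(sender = character(0), receiver = character(0)),
    stats::setNames(rep(list(numeric(0)), length(index_names)), index_names)
  ))
  if (nrow(transcript) == 0) return(empty)
  if (is.null(tagged)) tagged <- tag_transcript(transcript, tagger = tagger)

  speakers <- unique(transcript$speaker_id)
  receivers_of <- function(i) {
    if (gate) {
      transcript$in_proximity_of[[i]]
    } else {
      setdiff(speakers, transcript$speaker_id[i])
    }
  }
  fan <- purrr::map_dfr(seq_len(nrow(transcript)), function(i) {
    recv <- receivers_of(i)
    if (length(recv) == 0) return(NULL)
    tibble::tibble(row = i, sender = transcript$speaker_id[i], receiver = recv)
  })
  if (nrow(fan) == 0) return(empty)

  dyads <- dplyr::distinct(fan, .data$sender, .data$receiver)
  out <- purrr::map_dfr(seq_len(nrow(dyads)), function(k) {
    s <- dyads$sender[k]
    r <- dyads$receiver[k]
    sent_rows <- fan$row[fan$sender == s & fan$receiver == r]
    back_rows <- fan$row[fan$sender == r & fan$receiver == s]
    sent <- transcript[sort(sent_rows), , drop = FALSE]
    vec <- index_vector(sent, tagged = tagged, freq = freq,
                        turn_max_gap = turn_max_gap)
    stream <- transcript[sort(unique(c(sent_rows, back_rows))), , drop = FALSE]
    vec$CT <- count_turns(stream, turn_max_gap = turn_max_gap)
    dplyr::bind_cols(tibble::tibble(sender = s, receiver = r), vec)
  })
  dplyr::arrange(out, .data$sender, .data$receiver)
}

#' Write a dyadic index table to CSV
#'
#' Columns: sender, receiver, then the thirteen indices in canonical order.
#'
#' @param dyads Tibble from [dyadic_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dyadic_table <- function(dyads, path) {
  readr::write_csv(dyads[, c("sender", "receiver", index_names)], path,
                   progress = FALSE)
  invisible(path)
}

#' Speech duration by group
#'
#' Total speaking time (sum of utterance offsets minus onsets, in seconds)
#' per group of a transcript — the duration-aggregation routine behind the SD
#' index and the corpus bookkeeping totals.
#'
#' @param transcript Transcript tibble.
#' @param by Column to group by (default `"role"`).
#' @return Tibble with the grouping column and `seconds`.
#' @export
speech_duration <- function(transcript, by = "role") {
  transcript |>
    dplyr::filter(lengths(.data$tokens) > 0) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(seconds = sum(.data$offset - .data$onset), .groups = "drop")
}
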