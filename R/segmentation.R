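# Re-segmentation of running speech into C-unit approximations, and the
# temporal direct-talk selector.

#' Segmentation rule
#'
#' Controls how [resegment()] splits utterances. Sentence-final punctuation
#' (default `.`, `?`, `!`) marks a boundary; commas and ellipses are not
#' boundaries, because a C-unit (one independent clause plus its dependent
#' clauses and modifiers) routinely contains comma-joined dependent material.
#' When word timings are available and `use_word_timings` is set, an
#' inter-word pause of at least `pause_boundary` seconds also marks a
#' boundary.
#'
#' @param punctuation_boundaries Character vector of boundary characters.
#' @param pause_boundary Minimum pause in seconds that triggers a boundary.
#' @param use_word_timings Use per-word timings (columns `word_onset`,
#'   `word_offset`, lists of numeric per utterance) when present.
#' @return A list of class `"segmentation_rule"`.
#' @export
segmentation_rule <- function(punctuation_boundaries = c(".", "?", "!"),
                              pause_boundary = 0.3,
                              use_word_timings = FALSE) {
  if (length(punctuation_boundaries) == 0) {
    abort_validation("`punctuation_boundaries` must be non-empty")
  }
  check_positive(pause_boundary, "pause_boundary")
  structure(
    list(punctuation_boundaries = punctuation_boundaries,
         pause_boundary = pause_boundary,
         use_word_timings = isTRUE(use_word_timings)),
    class = "segmentation_rule"
  )
}

#' Re-segment utterances at punctuation (and pause) boundaries
#'
#' Splits each utterance into C-unit approximations at every sentence-final
#' boundary character, and — when word timings exist and the rule asks for
#' them — at inter-word pauses of at least `pause_boundary` seconds. Each
#' piece inherits speaker, role and proximity; onsets/offsets of the pieces
#' partition the parent span proportionally to token counts (or use the word
#' timings when available), so total speech duration per speaker is
#' conserved. Pieces with no word tokens are dropped. An utterance with no
#' internal boundary passes through unchanged, which makes the operation
#' idempotent.
#'
#' @param transcript A transcript tibble.
#' @param rule A [segmentation_rule()].
#' @return A transcript tibble, re-sorted by onset.
#' @examples
#' tr <- as_transcript(tibble::tibble(
#'   recording_id = "r1", speaker_id = "T1", role = "teacher",
#'   onset = 0, offset = 6,
#'   raw_text = "You are right. You can use the mirror if you need it."
#' ))
#' resegment(tr)
#' @export
resegment <- function(transcript, rule = segmentation_rule()) {
  if (nrow(transcript) == 0) return(transcript)
  boundary_re <- paste0("[", gsub("([][\\^-])", "\\\\\\1",
                                  paste(rule$punctuation_boundaries, collapse = "")),
                        "]")
  has_timings <- rule$use_word_timings &&
    all(c("word_onset", "word_offset") %in% names(transcript))

  pieces <- purrr::map(seq_len(nrow(transcript)), function(i) {
    row <- transcript[i, , drop = FALSE]
    words <- strsplit(row$raw_text, "[[:space:]]+")[[1]]
    words <- words[nzchar(words)]
    n <- length(words)
    if (n == 0 || length(row$tokens[[1]]) == 0) return(row)

    # trailing punctuation cluster of each word decides a boundary after it
    trail <- sub("^.*?([[:punct:]]*)$", "\\1", words)
    is_boundary <- grepl(boundary_re, trail)

    w_on <- NULL
    w_off <- NULL
    if (has_timings) {
      w_on <- row$word_onset[[1]]
      w_off <- row$word_offset[[1]]
      if (length(w_on) == n && length(w_off) == n && n > 1) {
        pause <- w_on[-1] - w_off[-n] >= rule$pause_boundary
        is_boundary[seq_len(n - 1)] <- is_boundary[seq_len(n - 1)] | pause
      } else {
        w_on <- NULL
        w_off <- NULL
      }
    }

    cuts <- which(is_boundary[seq_len(max(0, n - 1))])  # never cut after last word
    if (length(cuts) == 0) return(row)

    starts <- c(1L, cuts + 1L)
    ends <- c(cuts, n)
    texts <- vapply(seq_along(starts), function(k) {
      paste(words[starts[k]:ends[k]], collapse = " ")
    }, character(1))
    toks <- tokenize_text(texts)
    keep <- lengths(toks) > 0
    if (sum(keep) == 1 && identical(texts[keep], row$raw_text)) return(row)
    texts <- texts[keep]
    toks <- toks[keep]
    starts <- starts[keep]
    ends <- ends[keep]
    if (length(texts) == 0) return(row)

    if (!is.null(w_on)) {
      on_k <- w_on[starts]
      off_k <- w_off[ends]
    } else {
      counts <- lengths(toks)
      frac <- cumsum(counts) / sum(counts)
      dur <- row$offset - row$onset
      off_k <- row$onset + dur * frac
      on_k <- c(row$onset, off_k[-length(off_k)])
    }

    out <- row[rep(1L, length(texts)), , drop = FALSE]
    out$raw_text <- texts
    out$tokens <- toks
    out$onset <- round(on_k, 3)
    out$offset <- round(off_k, 3)
    if (length(texts) > 1) {
      out$utterance_id <- sprintf("%s.%d", row$utterance_id, seq_along(texts))
    }
    if (!is.null(w_on)) {
      out$word_onset <- lapply(seq_along(starts), function(k) w_on[starts[k]:ends[k]])
      out$word_offset <- lapply(seq_along(starts), function(k) w_off[starts[k]:ends[k]])
    }
    out
  })

  out <- dplyr::bind_rows(pieces)
  out[order(out$onset), , drop = FALSE]
}

#' Select talk directed at the focal child by the temporal criterion
#'
#' Keeps the focal child's own utterances plus every teacher/peer utterance
#' whose onset lies within `direct_talk_window` seconds of the nearest
#' boundary (onset or offset) of any focal-child utterance. This implements
#' the temporal criterion of direct-talk coding; proximity/orientation is
#' approximated separately by proximity gating, and topical relatedness is a
#' human judgment outside this package's scope.
#'
#' @param transcript A transcript tibble.
#' @param focal Speaker id of the focal child.
#' @param cfg An [analysis_config()]; supplies `direct_talk_window`.
#' @return The subset transcript, original order preserved.
#' @export
select_direct_talk <- function(transcript, focal, cfg = analysis_config()) {
  own <- transcript$speaker_id == focal
  if (!any(own)) {
    abort_validation(sprintf("focal id '%s' absent from transcript", focal))
  }
  f_on <- transcript$onset[own]
  f_off <- transcript$offset[own]
  near <- vapply(transcript$onset, function(t) {
    min(abs(t - f_on), abs(t - f_off))
  }, numeric(1))
  keep <- own | near <= cfg$direct_talk_window
  transcript[keep, , drop = FALSE]
}
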