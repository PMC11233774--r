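# Word error rate via minimum-edit-distance alignment.

normalize_wer_tokens <- function(tokens) {
  tokens <- fold_token(as.character(tokens))
  tokens <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", tokens)
  tokens[nzchar(tokens)]
}

#' Word error rate between a reference and a hypothesis token sequence
#'
#' Computes `(S + D + I) / N_ref * 100` where S, D and I are the
#' substitution, deletion and insertion counts of a minimum-edit-distance
#' alignment with uniform costs and `N_ref` is the reference length. Tokens
#' are case-folded and stripped of surrounding punctuation before alignment
#' (disable with `normalize = FALSE` if the caller already normalized).
#'
#' An empty reference against a non-empty hypothesis has no conventional
#' denominator; it is reported as `100 * length(hypothesis)` with a
#' `"classtalk_degenerate"` warning. Two empty sequences give 0.
#'
#' @param reference Character vector of reference tokens.
#' @param hypothesis Character vector of hypothesis tokens.
#' @param normalize Case-fold and strip punctuation first (default `TRUE`).
#' @return WER as a percentage.
#' @examples
#' word_error_rate(c("the", "cat", "sat", "on", "the", "mat"),
#'                 c("the", "cat", "sat", "the", "mat"))
#' @export
word_error_rate <- function(reference, hypothesis, normalize = TRUE) {
  if (normalize) {
    reference <- normalize_wer_tokens(reference)
    hypothesis <- normalize_wer_tokens(hypothesis)
  }
  n <- length(reference)
  if (n == 0) {
    if (length(hypothesis) == 0) return(0)
    warn("empty reference with non-empty hypothesis; WER is degenerate",
         class = "classtalk_degenerate")
    return(100 * length(hypothesis))
  }
  wer_distance_cpp(reference, hypothesis) / n * 100
}

#' Edit-operation counts of the WER alignment
#'
#' @inheritParams word_error_rate
#' @return Named integer vector with elements `S`, `D`, `I`.
#' @export
wer_counts <- function(reference, hypothesis, normalize = TRUE) {
  if (normalize) {
    reference <- normalize_wer_tokens(reference)
    hypothesis <- normalize_wer_tokens(hypothesis)
  }
  wer_counts_cpp(reference, hypothesis)
}

#' Median word error rate over segments
#'
#' @param segments A list of two-element lists (`reference`, `hypothesis`
#'   token vectors), or a data frame with list-columns `reference` and
#'   `hypothesis`, one row per segment.
#' @param normalize Passed to [word_error_rate()].
#' @return Median of the per-segment WERs (even counts: mean of the central
#'   pair).
#' @export
median_wer <- function(segments, normalize = TRUE) {
  if (is.data.frame(segments)) {
    segments <- purrr::map(seq_len(nrow(segments)), function(i) {
      list(reference = segments$reference[[i]],
           hypothesis = segments$hypothesis[[i]])
    })
  }
  if (length(segments) == 0) {
    abort_validation("median_wer requires at least one segment")
  }
  wers <- vapply(segments, function(s) {
    word_error_rate(s$reference, s$hypothesis, normalize = normalize)
  }, numeric(1))
  median(wers)
}
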