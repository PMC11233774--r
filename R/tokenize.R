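#' Tokenize raw utterance text
#'
#' Deterministic whitespace tokenization: the text is split on runs of
#' whitespace and leading/trailing punctuation is stripped from each piece, so
#' `"You are right."` yields `c("You", "are", "right")`. Internal apostrophes
#' and hyphens are preserved (`"don't"` is one token). Case is preserved;
#' consumers that need case-insensitive identity fold with [fold_token()].
#' Pieces that are pure punctuation are dropped.
#'
#' @param text Character vector of raw utterance strings.
#' @return A list of character vectors, one per input string; empty strings or
#'   punctuation-only strings give `character(0)`.
#' @examples
#' tokenize_text("You are right.")
#' tokenize_text("I don't know!")
#' @export
tokenize_text <- function(text) {
  text <- as.character(text)
  pieces <- strsplit(text, "[[:space:]]+")
  lapply(pieces, function(p) {
    p <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", p)
    p[nzchar(p)]
  })
}

#' Case-fold a token
#'
#' Single source of truth for surface-form identity: lowercasing only, no
#' stemming or lemmatization.
#'
#' @param x Character vector.
#' @return Lowercased character vector.
#' @export
fold_token <- function(x) tolower(x)
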