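# Frequency list and rare-word classification. A word is rare when its
# case-folded form is outside the inflected closure of the N most common
# words (default N = 10,000) and it is neither a proper name nor a number.

#' Generate regular inflected forms of a word
#'
#' Produces the base form plus regular affixes `-s, -es, -ed, -d, -ing, -er,
#' -est`, with consonant doubling for short consonant-vowel-consonant stems
#' ("cat" -> "catted", "catting"), e-drop before vowel-initial suffixes
#' ("bake" -> "baking") and y-to-i alternation ("carry" -> "carries",
#' "carried"). Over-generation is deliberate: the closure is only used as a
#' common-word membership set, so an implausible form can never make a word
#' count as rare.
#'
#' @param word Character vector of base forms (lower case).
#' @return Character vector of unique inflected forms including the bases.
#' @examples
#' inflect_forms("cat")
#' @export
inflect_forms <- function(word) {
  word <- fold_token(word)
  forms <- lapply(word, function(w) {
    out <- c(w, paste0(w, c("s", "es", "ed", "d", "ing", "er", "est")))
    n <- nchar(w)
    last <- substr(w, n, n)
    penult <- if (n >= 2) substr(w, n - 1, n - 1) else ""
    vowels <- c("a", "e", "i", "o", "u")
    if (last == "e" && n >= 3) {
      stem <- substr(w, 1, n - 1)
      out <- c(out, paste0(stem, c("ing", "ed", "er", "est")))
    }
    if (last == "y" && !penult %in% vowels && n >= 3) {
      stem <- paste0(substr(w, 1, n - 1), "i")
      out <- c(out, paste0(stem, c("es", "ed", "er", "est")))
    }
    if (n >= 2 && !last %in% c(vowels, "w", "x", "y") && penult %in% vowels &&
        (n < 3 || !substr(w, n - 2, n - 2) %in% vowels)) {
      dbl <- paste0(w, last)
      out <- c(out, paste0(dbl, c("ed", "ing", "er", "est")))
    }
    out
  })
  unique(unlist(forms))
}

#' Build a frequency list with its inflected closure
#'
#' @param words Character vector of word forms ordered from most to least
#'   common.
#' @param n Number of top entries to treat as the common-word list; defaults
#'   to all supplied words (the canonical setting is the 10,000 most common).
#' @return An object of class `"frequency_list"` with elements
#'   `common_words` and `closure` (a superset including inflected forms).
#' @examples
#' fl <- frequency_list(c("cat"))
#' is_rare(tibble::tibble(folded = c("cats", "dog"), pos = "OTHER"), fl)
#' @export
frequency_list <- function(words, n = length(words)) {
  words <- fold_token(as.character(words))
  common <- utils::head(words, n)
  structure(
    list(common_words = common, closure = inflect_forms(common)),
    class = "frequency_list"
  )
}

#' Read a frequency list file
#'
#' One word per line, ordered from most to least common.
#'
#' @param path Path to the file.
#' @param n Number of top entries to keep (default 10,000).
#' @return A [frequency_list()].
#' @export
read_frequency_list <- function(path, n = 10000) {
  check_file_exists(path)
  words <- readr::read_lines(path, progress = FALSE)
  words <- trimws(words)
  words <- words[nzchar(words) & !startsWith(words, "#")]
  frequency_list(words, n = min(n, length(words)))
}

#' The packaged demonstration frequency list
#'
#' A small curated list of common English words shipped with the package
#' (`inst/extdata/common_words_synthetic.txt`). It is a synthetic stand-in at
#' reduced scale for a corpus-derived 10,000-word list, suitable for examples
#' and tests; analyses of real data should supply their own list via
#' [read_frequency_list()].
#'
#' @return A [frequency_list()].
#' @export
demo_frequency_list <- function() {
  read_frequency_list(
    system.file("extdata", "common_words_synthetic.txt", package = "classtalk")
  )
}

#' Classify tokens as rare words
#'
#' A token is rare when its folded form is absent from the inflected closure
#' of the common-word list and its part of speech is neither proper noun nor
#' number.
#'
#' @param tagged Tibble of tagged tokens with columns `folded` and `pos`
#'   (see [tag_tokens()]).
#' @param freq A [frequency_list()].
#' @return Logical vector, one flag per token.
#' @export
is_rare <- function(tagged, freq) {
  if (!inherits(freq, "frequency_list")) {
    abort_validation("`freq` must be a frequency_list")
  }
  !(tagged$folded %in% freq$closure) & !(tagged$pos %in% c("PROPN", "NUM"))
}
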