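# Part-of-speech tagging behind a pluggable interface. The bundled rule-based
# tagger covers the closed classes the indices need (auxiliaries,
# coordinating/subordinating conjunctions) exactly, and approximates the open
# classes with capitalization, digit and suffix heuristics. Production use
# can supply any external statistical tagger as a function; its output is
# mapped onto the restricted Universal-POS inventory below.

pos_classes <- c("AUX", "VERB", "ADJ", "CCONJ", "SCONJ", "PROPN", "NUM", "OTHER")

aux_lexicon <- c(
  "am", "is", "are", "was", "were", "be", "been", "being",
  "do", "does", "did", "have", "has", "had",
  "will", "would", "can", "could", "shall", "should", "may", "might", "must"
)

cconj_lexicon <- c("and", "or", "but", "nor", "yet", "so")

sconj_lexicon <- c(
  "that", "if", "while", "because", "although", "though", "since", "unless",
  "until", "when", "whenever", "where", "wherever", "after", "before",
  "whereas", "once", "as"
)

verb_lexicon <- c(
  "go", "goes", "going", "went", "gone", "get", "got", "make", "made",
  "read", "look", "see", "saw", "come", "came", "put", "take", "took",
  "use", "need", "know", "want", "say", "said", "tell", "told", "play",
  "jump", "laugh", "run", "ran", "sit", "sat", "stand", "stood", "give",
  "gave", "think", "thought", "help", "find", "found", "draw", "drew",
  "cut", "color", "build", "built", "share", "clean", "wash", "eat", "ate"
)

adj_lexicon <- c(
  "good", "bad", "little", "big", "tall", "small", "happy", "sad", "nice",
  "pink", "green", "blue", "red", "yellow", "new", "old", "right", "wrong",
  "fun", "funny", "pretty", "soft", "hard", "hot", "cold", "clean", "dirty"
)

# mapping from full Universal POS tags onto the restricted inventory, for
# adapting external taggers
upos_map <- c(
  AUX = "AUX", VERB = "VERB", ADJ = "ADJ", CCONJ = "CCONJ", SCONJ = "SCONJ",
  PROPN = "PROPN", NUM = "NUM",
  NOUN = "OTHER", PRON = "OTHER", DET = "OTHER", ADP = "OTHER", ADV = "OTHER",
  PART = "OTHER", INTJ = "OTHER", SYM = "OTHER", X = "OTHER", PUNCT = "OTHER"
)

#' Rule-based part-of-speech tagger
#'
#' The default tagger behind [tag_tokens()]. Closed classes come from fixed
#' lexicons (so "am" is AUX, "and"/"or"/"but" are CCONJ, "that"/"if"/"while"
#' are SCONJ); tokens containing a digit are NUM; a capitalized token after
#' the first position is PROPN; remaining tokens are VERB or ADJ by small
#' lexicons plus suffix heuristics (-ing/-ed for verbs; -ful, -ous, -ive,
#' -able, -ible, -less, -ish for adjectives), and OTHER otherwise.
#'
#' @param tokens Character vector: the word tokens of one utterance, in order.
#' @return Character vector of tags, one per token, from
#'   `AUX, VERB, ADJ, CCONJ, SCONJ, PROPN, NUM, OTHER`.
#' @examples
#' pos_tag_rules(c("I", "am", "going", "to", "read"))
#' @export
pos_tag_rules <- function(tokens) {
  n <- length(tokens)
  if (n == 0) return(character(0))
  folded <- fold_token(tokens)
  tag <- rep("OTHER", n)
  tag[folded %in% verb_lexicon |
        (nchar(folded) > 4 & grepl("(ing|ed)$", folded))] <- "VERB"
  tag[folded %in% adj_lexicon |
        grepl("(ful|ous|ive|able|ible|less|ish)$", folded) & nchar(folded) > 4] <- "ADJ"
  tag[folded %in% aux_lexicon] <- "AUX"
  tag[folded %in% cconj_lexicon] <- "CCONJ"
  tag[folded %in% sconj_lexicon] <- "SCONJ"
  cap <- grepl("^[[:upper:]]", tokens) & seq_len(n) > 1 & tag == "OTHER"
  tag[cap] <- "PROPN"
  tag[grepl("[0-9]", tokens)] <- "NUM"
  tag
}

#' Tag the tokens of one utterance
#'
#' Applies a tagger function to an utterance's word tokens and returns one
#' tagged-token record per token, order preserved. Any tagger failure is
#' re-signalled as a tagging error carrying the utterance id.
#'
#' @param utterance One-row transcript tibble (or a list with `utterance_id`
#'   and `tokens` fields).
#' @param tagger Function from a character vector of tokens to a character
#'   vector of tags; defaults to [pos_tag_rules()]. Tags outside the
#'   restricted inventory are mapped through the Universal-POS table
#'   (unknown tags become `OTHER`).
#' @return Tibble with columns `utterance_id`, `position`, `surface`,
#'   `folded`, `pos`.
#' @export
tag_tokens <- function(utterance, tagger = pos_tag_rules) {
  toks <- if (is.list(utterance$tokens) && !is.character(utterance$tokens)) {
    utterance$tokens[[1]]
  } else {
    utterance$tokens
  }
  uid <- utterance$utterance_id[1]
  if (length(toks) == 0) {
    return(tibble::tibble(utterance_id = character(0), position = integer(0),
                          surface = character(0), folded = character(0),
                          pos = character(0)))
  }
  tags <- tryCatch(tagger(toks), error = function(e) {
    abort(sprintf("tagger failed on utterance %s: %s", uid, conditionMessage(e)),
          class = "classtalk_tagging_error")
  })
  if (length(tags) != length(toks)) {
    abort(sprintf("tagger returned %d tags for %d tokens on utterance %s",
                  length(tags), length(toks), uid),
          class = "classtalk_tagging_error")
  }
  tags <- ifelse(tags %in% pos_classes, tags,
                 dplyr::coalesce(unname(upos_map[tags]), "OTHER"))
  tibble::tibble(
    utterance_id = uid,
    position = seq_along(toks),
    surface = toks,
    folded = fold_token(toks),
    pos = tags
  )
}

#' Tag every utterance of a transcript
#'
#' @param transcript A transcript tibble.
#' @param tagger See [tag_tokens()].
#' @return Tibble with one row per word token: `utterance_id`, `position`,
#'   `surface`, `folded`, `pos`.
#' @export
tag_transcript <- function(transcript, tagger = pos_tag_rules) {
  if (nrow(transcript) == 0) {
    return(tibble::tibble(utterance_id = character(0), position = integer(0),
                          surface = character(0), folded = character(0),
                          pos = character(0)))
  }
  purrr::map_dfr(seq_len(nrow(transcript)), function(i) {
    tag_tokens(transcript[i, , drop = FALSE], tagger = tagger)
  })
}
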