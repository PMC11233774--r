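# Synthetic classroom corpus with known ground truth, plus a corruption
# model that emulates ASR/diarization error at controlled rates. Utterance
# text comes from part-of-speech templates, not a language model, so the true
# tag of every token is known by construction and index tests can bypass
# tagger error entirely; closed-class slots draw from the real function-word
# lexicons and open-class slots from a Zipfian synthetic vocabulary.

default_templates <- list(
  list(slots = c("W", "AUX", "VERB", "W", "W"), weight = 0.20),
  list(slots = c("W", "VERB", "W", "CCONJ", "W", "VERB", "W"), weight = 0.15),
  list(slots = c("W", "AUX", "ADJ", "SCONJ", "W", "VERB", "W"), weight = 0.15),
  list(slots = c("W", "VERB", "ADJ", "W"), weight = 0.20),
  list(slots = c("W", "W", "VERB", "W"), weight = 0.30)
)

#' Specification of a synthetic classroom corpus
#'
#' The defaults emulate one morning session of a preschool classroom wearing
#' proximity-aware recorders: an hour-long session with one teacher, one
#' focal child and two peers, role-specific utterance rates chosen so teacher
#' talk dominates total speaking time, child talk comes second and peer talk
#' is the smallest share (the ordering seen in naturalistic direct-talk
#' corpora), a 1,000-word Zipfian vocabulary with exponent 1, and proximity
#' pings once per second during scheduled co-location blocks.
#'
#' @param seed Integer seed; the generator is deterministic given the spec.
#' @param n_teachers,n_children Speaker counts (the first child is focal).
#' @param session_length Session length in seconds.
#' @param vocabulary_size Size of the open-class vocabulary.
#' @param zipf_exponent Zipf rank-frequency exponent.
#' @param mean_utterance_words Target mean utterance length in words;
#'   utterance length is the template length plus a Poisson-distributed
#'   number of extra open slots. One number or a vector named by role
#'   (`teacher`, `focal_child`, `peer`).
#' @param utterance_rate Utterances per minute per speaker; one number or a
#'   vector named by role. Together with `mean_utterance_words` and
#'   `word_duration`, the defaults give an hour-long session in which teacher
#'   talk is the largest share of speaking time, the focal child's own talk
#'   comes second and peer talk is the smallest — the ordering seen in
#'   naturalistic classroom direct-talk corpora.
#' @param word_duration Nominal seconds of speech per word, used to set
#'   utterance offsets.
#' @param pos_template_weights Optional numeric weights overriding the
#'   default template weights (must sum to 1).
#' @param proximity_ping_period Beacon cadence in seconds.
#' @param dyad_schedule Tibble of co-location blocks with columns `id_a`,
#'   `id_b`, `start`, `end`; `NULL` gives a default schedule in which the
#'   focal child shares blocks with the teacher and each peer.
#' @return A list of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(seed = 1L,
                           n_teachers = 1L,
                           n_children = 3L,
                           session_length = 3600,
                           vocabulary_size = 1000L,
                           zipf_exponent = 1.0,
                           mean_utterance_words = c(teacher = 8, focal_child = 5, peer = 4),
                           utterance_rate = c(teacher = 11, focal_child = 12, peer = 4),
                           word_duration = 0.4,
                           pos_template_weights = NULL,
                           proximity_ping_period = 1,
                           dyad_schedule = NULL) {
  check_positive(n_teachers, "n_teachers")
  check_positive(n_children, "n_children")
  check_positive(session_length, "session_length")
  check_positive(vocabulary_size, "vocabulary_size")
  if (!is.numeric(mean_utterance_words) || any(mean_utterance_words <= 0)) {
    abort_validation("`mean_utterance_words` must be positive")
  }
  if (!is.numeric(utterance_rate) || any(utterance_rate <= 0)) {
    abort_validation("`utterance_rate` must be positive")
  }
  check_positive(proximity_ping_period, "proximity_ping_period")
  weights <- pos_template_weights %||%
    vapply(default_templates, function(t) t$weight, numeric(1))
  if (length(weights) != length(default_templates) ||
      abs(sum(weights) - 1) > 1e-8 || any(weights < 0)) {
    abort_validation("template weights must be non-negative and sum to 1")
  }
  teachers <- sprintf("T%d", seq_len(n_teachers))
  children <- sprintf("C%d", seq_len(n_children))
  focal <- children[1]
  if (is.null(dyad_schedule)) {
    third <- session_length / 3
    blocks <- list(
      tibble::tibble(id_a = focal, id_b = teachers[1],
                     start = c(0, 1.6 * third),
                     end = c(1.4 * third, session_length))
    )
    others <- children[-1]
    for (k in seq_along(others)) {
      s <- (k - 1) * third * 1.1 + 0.2 * third
      blocks <- c(blocks, list(tibble::tibble(
        id_a = focal, id_b = others[k],
        start = s, end = min(s + third, session_length)
      )))
    }
    dyad_schedule <- dplyr::bind_rows(blocks)
  }
  dyad_schedule <- tibble::as_tibble(dyad_schedule)
  pair <- normalize_pair(dyad_schedule$id_a, dyad_schedule$id_b)
  dyad_schedule$id_a <- pair$id_a
  dyad_schedule$id_b <- pair$id_b
  # overlapping blocks for the same pair are infeasible
  by_pair <- split(dyad_schedule, pair_key(dyad_schedule$id_a, dyad_schedule$id_b))
  for (d in by_pair) {
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)])) {
      abort_validation("dyad_schedule contains overlapping blocks for one pair")
    }
  }
  structure(
    list(seed = as.integer(seed), teachers = teachers, children = children,
         focal = focal, session_length = session_length,
         vocabulary_size = as.integer(vocabulary_size),
         zipf_exponent = zipf_exponent,
         mean_utterance_words = mean_utterance_words,
         utterance_rate = utterance_rate, word_duration = word_duration,
         template_weights = weights,
         proximity_ping_period = proximity_ping_period,
         dyad_schedule = dyad_schedule),
    class = "synthetic_spec"
  )
}

#' Specification of the transcript corruption model
#'
#' Emulates recognition and diarization error with known rates: per-word
#' substitution and deletion probabilities, a per-word insertion rate,
#' zero-mean Gaussian jitter of utterance boundaries, and a per-utterance
#' probability of confusing the teacher/peer speaker label. Child speech in
#' real systems carries more error than adult speech; model that by
#' corrupting role subsets with different specs.
#'
#' @param seed Integer seed.
#' @param p_sub,p_del Per-word substitution and deletion probabilities
#'   (`p_sub + p_del <= 1`).
#' @param p_ins Insertion rate per word.
#' @param boundary_jitter_sd Standard deviation in seconds of the boundary
#'   jitter.
#' @param p_speaker_confusion Per-utterance probability of a teacher/peer
#'   role swap.
#' @return A list of class `"corruption_spec"`.
#' @export
corruption_spec <- function(seed = 1L, p_sub = 0, p_del = 0, p_ins = 0,
                            boundary_jitter_sd = 0, p_speaker_confusion = 0) {
  probs <- c(p_sub = p_sub, p_del = p_del, p_ins = p_ins,
             p_speaker_confusion = p_speaker_confusion)
  if (any(probs < 0 | probs > 1)) {
    abort_validation("corruption probabilities must lie in [0, 1]")
  }
  if (p_sub + p_del > 1) {
    abort_validation("p_sub + p_del must not exceed 1")
  }
  if (boundary_jitter_sd < 0) {
    abort_validation("boundary_jitter_sd must be non-negative")
  }
  structure(
    list(seed = as.integer(seed), p_sub = p_sub, p_del = p_del, p_ins = p_ins,
         boundary_jitter_sd = boundary_jitter_sd,
         p_speaker_confusion = p_speaker_confusion),
    class = "corruption_spec"
  )
}

# alphabetic pseudo-words: digits map to letters that cannot form English
# inflectional suffixes, so the rule tagger sees them as plain OTHER tokens
zipf_vocab <- function(spec) {
  chartr("0123456789", "abcefhikmo", sprintf("w%04d", seq_len(spec$vocabulary_size)))
}

zipf_probs <- function(spec) {
  p <- seq_len(spec$vocabulary_size)^(-spec$zipf_exponent)
  p / sum(p)
}

rate_for_role <- function(rate, role) {
  if (length(rate) == 1 && is.null(names(rate))) return(unname(rate))
  if (!role %in% names(rate)) {
    abort_validation(sprintf("utterance_rate has no entry for role '%s'", role))
  }
  unname(rate[[role]])
}

#' Generate a synthetic classroom corpus
#'
#' Draws, deterministically for a given spec, a ground-truth transcript and a
#' proximity-ping log. Utterance onsets follow a per-speaker renewal process
#' with exponential gaps at the role's utterance rate; texts are built from
#' part-of-speech templates padded with open-class slots to a
#' Poisson-distributed length, with open-class words drawn from a Zipfian
#' vocabulary; proximity pings are emitted every `proximity_ping_period`
#' seconds inside scheduled co-location blocks at an RSSI above the gate, and
#' sparse background pings below the gate outside them.
#'
#' @param spec A [synthetic_spec()].
#' @return List with elements `transcript` (reference transcript tibble),
#'   `proximity` (event tibble), `token_tags` (ground-truth tagged tokens,
#'   same layout as [tag_transcript()]), and `spec`.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, {
    vocab <- zipf_vocab(spec)
    probs <- zipf_probs(spec)
    speakers <- tibble::tibble(
      speaker_id = c(spec$teachers, spec$children),
      role = c(rep("teacher", length(spec$teachers)),
               c("focal_child", rep("peer", length(spec$children) - 1)))
    )
    slot_weights <- spec$template_weights

    rows <- list()
    tags <- list()
    for (s in seq_len(nrow(speakers))) {
      sp <- speakers$speaker_id[s]
      role <- speakers$role[s]
      rate_s <- rate_for_role(spec$utterance_rate, role) / 60
      mean_words_s <- rate_for_role(spec$mean_utterance_words, role)
      # renewal process: exponential onset-to-onset gaps
      n_max <- ceiling(rate_s * spec$session_length + 10 * sqrt(rate_s * spec$session_length) + 10)
      onsets <- cumsum(rexp(n_max, rate_s))
      onsets <- onsets[onsets <= spec$session_length]
      k <- length(onsets)
      if (k == 0) next
      gaps <- c(diff(onsets), spec$session_length - onsets[k])

      tmpl_idx <- sample(length(default_templates), k, replace = TRUE,
                         prob = slot_weights)
      slots_list <- lapply(tmpl_idx, function(i) default_templates[[i]]$slots)
      extras <- pmax(0L, rpois(k, mean_words_s) - lengths(slots_list))
      slots_list <- Map(function(sl, e) c(sl, rep("W", e)), slots_list, extras)
      utt_of <- rep(seq_len(k), lengths(slots_list))
      all_slots <- unlist(slots_list, use.names = FALSE)

      words <- character(length(all_slots))
      open <- all_slots %in% c("W", "VERB", "ADJ")
      # open-class slots draw from the Zipfian vocabulary; closed classes
      # from the real function-word lexicons
      words[open] <- sample(vocab, sum(open), replace = TRUE, prob = probs)
      lexicons <- list(AUX = aux_lexicon, CCONJ = cconj_lexicon,
                       SCONJ = sconj_lexicon)
      for (cls in names(lexicons)) {
        m <- all_slots == cls
        if (any(m)) words[m] <- sample(lexicons[[cls]], sum(m), replace = TRUE)
      }
      pos <- ifelse(all_slots %in% c("AUX", "CCONJ", "SCONJ", "VERB", "ADJ"),
                    all_slots, "OTHER")

      first_pos <- c(TRUE, utt_of[-1] != utt_of[-length(utt_of)])
      surface <- words
      substr(surface[first_pos], 1, 1) <- toupper(substr(surface[first_pos], 1, 1))
      texts <- vapply(split(surface, utt_of), paste, character(1), collapse = " ")
      terminal <- ifelse(runif(k) < 0.1, "?", ".")
      n_words <- lengths(slots_list)
      dur <- pmin(n_words * spec$word_duration, gaps * 0.9)

      rows[[length(rows) + 1]] <- tibble::tibble(
        recording_id = sprintf("sim%d", spec$seed),
        speaker_id = sp, role = role,
        onset = onsets, offset = onsets + dur,
        raw_text = paste0(texts, terminal)
      )
      tags[[length(tags) + 1]] <- tibble::tibble(
        speaker_id = sp, onset = round(rep(onsets, n_words), 3),
        position = unlist(lapply(n_words, seq_len), use.names = FALSE),
        surface = surface, folded = fold_token(surface), pos = pos
      )
    }
    transcript <- as_transcript(dplyr::bind_rows(rows), provenance = "reference")

    # attach ground-truth tags to the post-sort utterance ids
    tag_tbl <- dplyr::bind_rows(tags)
    key <- transcript[, c("utterance_id", "speaker_id", "onset")]
    tag_tbl <- dplyr::inner_join(tag_tbl, key, by = c("speaker_id", "onset"))
    tag_tbl <- tag_tbl[, c("utterance_id", "position", "surface", "folded", "pos")]
    tag_tbl <- tag_tbl[order(match(tag_tbl$utterance_id, transcript$utterance_id),
                             tag_tbl$position), , drop = FALSE]

    sched <- spec$dyad_schedule
    ping <- purrr::map_dfr(seq_len(nrow(sched)), function(b) {
      times <- seq(sched$start[b], sched$end[b], by = spec$proximity_ping_period)
      tibble::tibble(timestamp = times, id_a = sched$id_a[b],
                     id_b = sched$id_b[b],
                     rssi = pmin(-45, -60 + rnorm(length(times), sd = 3)))
    })
    pairs <- dplyr::distinct(sched, .data$id_a, .data$id_b)
    background <- purrr::map_dfr(seq_len(nrow(pairs)), function(p) {
      blocks <- sched[sched$id_a == pairs$id_a[p] & sched$id_b == pairs$id_b[p], ]
      times <- seq(0, spec$session_length, by = 5 * spec$proximity_ping_period)
      inside <- purrr::reduce(
        purrr::map(seq_len(nrow(blocks)),
                   function(b) times >= blocks$start[b] & times <= blocks$end[b]),
        `|`
      )
      times <- times[!inside]
      tibble::tibble(timestamp = times, id_a = pairs$id_a[p],
                     id_b = pairs$id_b[p],
                     rssi = -85 + rnorm(length(times), sd = 2))
    })
    proximity <- as_proximity_events(dplyr::bind_rows(ping, background))

    list(transcript = transcript, proximity = proximity,
         token_tags = tag_tbl, spec = spec)
  })
}

#' Corrupt a ground-truth transcript at known error rates
#'
#' Applies, deterministically for a given spec, per-word substitutions
#' (replacement drawn from the transcript's own vocabulary) and deletions,
#' per-word insertions, zero-mean Gaussian jitter of onsets/offsets, and
#' teacher/peer role confusion. Utterances whose words are all deleted are
#' dropped. The result carries provenance `"predicted"`.
#'
#' @param truth Reference transcript tibble.
#' @param cspec A [corruption_spec()].
#' @return A predicted transcript tibble.
#' @export
corrupt_transcript <- function(truth, cspec) {
  stopifnot(inherits(cspec, "corruption_spec"))
  withr::with_seed(cspec$seed, {
    vocab <- unique(fold_token(unlist(truth$tokens)))
    rows <- purrr::map(seq_len(nrow(truth)), function(i) {
      row <- truth[i, , drop = FALSE]
      toks <- row$tokens[[1]]
      if (length(toks) > 0) {
        u <- runif(length(toks))
        out <- character(0)
        for (k in seq_along(toks)) {
          if (u[k] < cspec$p_sub) {
            out <- c(out, sample(vocab, 1))
          } else if (u[k] < cspec$p_sub + cspec$p_del) {
            # deleted
          } else {
            out <- c(out, toks[k])
          }
          if (runif(1) < cspec$p_ins) out <- c(out, sample(vocab, 1))
        }
        if (length(out) == 0) return(NULL)
        terminal <- sub("^.*?([.?!]?)$", "\\1", row$raw_text)
        row$raw_text <- paste0(paste(out, collapse = " "), terminal)
      }
      if (cspec$boundary_jitter_sd > 0) {
        onset <- max(0, row$onset + rnorm(1, sd = cspec$boundary_jitter_sd))
        offset <- row$offset + rnorm(1, sd = cspec$boundary_jitter_sd)
        row$onset <- onset
        row$offset <- max(offset, onset + 0.05)
      }
      if (cspec$p_speaker_confusion > 0 && row$role %in% c("teacher", "peer") &&
          runif(1) < cspec$p_speaker_confusion) {
        row$role <- if (row$role == "teacher") "peer" else "teacher"
      }
      row
    })
    rows <- dplyr::bind_rows(purrr::compact(rows))
    keep <- setdiff(names(rows), c("tokens", "in_proximity_of",
                                   "utterance_id", "provenance"))
    as_transcript(rows[, keep, drop = FALSE], provenance = "predicted")
  })
}
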