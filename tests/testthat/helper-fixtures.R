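# Builders and independent oracles shared across the suite.

make_transcript <- function(speakers, onsets, offsets, texts,
                            roles = NULL, rec = "r1") {
  if (is.null(roles)) {
    roles <- ifelse(grepl("^T", speakers), "teacher",
                    ifelse(speakers == "C1", "focal_child", "peer"))
  }
  as_transcript(tibble::tibble(
    recording_id = rec, speaker_id = speakers, role = roles,
    onset = onsets, offset = offsets, raw_text = texts
  ))
}

toy_freq <- function(words = c("the", "cat", "you", "are", "right", "i",
                               "have", "a", "is")) {
  frequency_list(words)
}

# independent proximity-interval oracle: a straightforward scan that walks
# each pair's kept events and opens/extends runs by the gap rule
oracle_intervals <- function(events, threshold, ping_period) {
  kept <- events[events$rssi >= threshold, , drop = FALSE]
  if (nrow(kept) == 0) {
    return(tibble::tibble(id_a = character(), id_b = character(),
                          start = numeric(), end = numeric()))
  }
  out <- list()
  for (key in unique(paste(kept$id_a, kept$id_b))) {
    d <- kept[paste(kept$id_a, kept$id_b) == key, , drop = FALSE]
    ts <- sort(d$timestamp)
    run_start <- ts[1]
    prev <- ts[1]
    for (t in ts[-1]) {
      if (t - prev > 2 * ping_period) {
        out[[length(out) + 1]] <- tibble::tibble(
          id_a = d$id_a[1], id_b = d$id_b[1],
          start = run_start - ping_period / 2, end = prev + ping_period / 2)
        run_start <- t
      }
      prev <- t
    }
    out[[length(out) + 1]] <- tibble::tibble(
      id_a = d$id_a[1], id_b = d$id_b[1],
      start = run_start - ping_period / 2, end = prev + ping_period / 2)
  }
  d <- dplyr::bind_rows(out)
  d[order(d$id_a, d$id_b, d$start), , drop = FALSE]
}

# independent recount of the thirteen indices using plain loops over the
# token/tag records
oracle_index_recount <- function(utterances, tags, freq = NULL) {
  keep <- lengths(utterances$tokens) > 0
  u <- utterances[keep, , drop = FALSE]
  tags <- tags[tags$utterance_id %in% u$utterance_id, , drop = FALSE]
  ut <- nrow(u)
  wd <- 0
  all_folded <- character(0)
  for (i in seq_len(nrow(u))) {
    wd <- wd + length(u$tokens[[i]])
    all_folded <- c(all_folded, tolower(u$tokens[[i]]))
  }
  cnt <- function(p) {
    n <- 0
    for (i in seq_len(nrow(tags))) if (tags$pos[i] == p) n <- n + 1
    n
  }
  rw <- NA_integer_
  if (!is.null(freq)) {
    rare_forms <- character(0)
    for (i in seq_len(nrow(tags))) {
      if (!(tags$folded[i] %in% freq$closure) &&
          !(tags$pos[i] %in% c("PROPN", "NUM"))) {
        rare_forms <- c(rare_forms, tags$folded[i])
      }
    }
    rw <- length(unique(rare_forms))
  }
  ct <- NA_integer_
  if (length(unique(u$speaker_id)) <= 2) {
    ct <- 0
    if (nrow(u) > 1) {
      for (i in 2:nrow(u)) if (u$speaker_id[i] != u$speaker_id[i - 1]) ct <- ct + 1
    }
  }
  list(UT = ut, WD = wd, AV = cnt("AUX"), CC = cnt("CCONJ"), SC = cnt("SCONJ"),
       VB = cnt("VERB"), AJ = cnt("ADJ"), UW = length(unique(all_folded)),
       RW = rw, MLU = if (ut > 0) wd / ut else NA_real_,
       TTR = if (wd > 0) length(unique(all_folded)) / wd else NA_real_,
       CT = ct, SD = sum(u$offset - u$onset))
}

# random template fixture with part of speech known by construction
random_tagged_fixture <- function(n_utt = 5) {
  pool <- list(
    list(w = "am", pos = "AUX"), list(w = "can", pos = "AUX"),
    list(w = "and", pos = "CCONJ"), list(w = "but", pos = "CCONJ"),
    list(w = "if", pos = "SCONJ"), list(w = "while", pos = "SCONJ"),
    list(w = "jump", pos = "VERB"), list(w = "laugh", pos = "VERB"),
    list(w = "tall", pos = "ADJ"), list(w = "good", pos = "ADJ"),
    list(w = "Logan", pos = "PROPN"), list(w = "7", pos = "NUM"),
    list(w = "cat", pos = "OTHER"), list(w = "dog", pos = "OTHER"),
    list(w = "apple", pos = "OTHER"), list(w = "xylem", pos = "OTHER")
  )
  speakers <- sample(c("A", "B"), n_utt, replace = TRUE)
  onsets <- sort(runif(n_utt, 0, 60))
  rows <- tibble::tibble(
    recording_id = "fx", speaker_id = speakers,
    role = ifelse(speakers == "A", "teacher", "focal_child"),
    onset = onsets, offset = onsets + runif(n_utt, 0.5, 3),
    raw_text = NA_character_
  )
  words <- lapply(seq_len(n_utt), function(i) {
    k <- sample(0:6, 1)  # occasionally a vocalization-only row
    if (k == 0) return(list(w = character(0), pos = character(0)))
    picks <- pool[sample(length(pool), k, replace = TRUE)]
    list(w = vapply(picks, `[[`, character(1), "w"),
         pos = vapply(picks, `[[`, character(1), "pos"))
  })
  rows$raw_text <- vapply(words, function(x) {
    if (length(x$w) == 0) "" else paste0(paste(x$w, collapse = " "), ".")
  }, character(1))
  tr <- as_transcript(rows)
  tags <- purrr::map_dfr(seq_len(nrow(tr)), function(i) {
    x <- words[[order(rows$onset)[i]]]  # as_transcript sorted by onset
    if (length(x$w) == 0) return(NULL)
    tibble::tibble(utterance_id = tr$utterance_id[i],
                   position = seq_along(x$w), surface = x$w,
                   folded = tolower(x$w), pos = x$pos)
  })
  list(transcript = tr, tags = tags)
}
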