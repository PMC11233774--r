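test_that("generation is deterministic given the spec", {
  a <- generate_corpus(synthetic_spec(seed = 61, session_length = 400))
  b <- generate_corpus(synthetic_spec(seed = 61, session_length = 400))
  expect_identical(a$transcript, b$transcript)
  expect_identical(a$proximity, b$proximity)
  expect_identical(a$token_tags, b$token_tags)
})

test_that("generated corpora satisfy the transcript invariants", {
  co <- generate_corpus(synthetic_spec(seed = 62, session_length = 600))
  tr <- co$transcript
  expect_true(all(tr$offset >= tr$onset))
  expect_true(all(tr$onset >= 0))
  expect_true(!is.unsorted(tr$onset))
  expect_identical(tr$tokens, tokenize_text(tr$raw_text))
  expect_true(all(tr$role %in% c("teacher", "focal_child", "peer")))
  # ground-truth tags align one-to-one with tokens
  by_utt <- split(co$token_tags$surface, co$token_tags$utterance_id)
  expect_identical(unname(lengths(by_utt[tr$utterance_id])),
                   lengths(tr$tokens))
})

test_that("open-class sampling is Zipfian with the requested exponent", {
  co <- generate_corpus(synthetic_spec(seed = 63, session_length = 7200,
                                       utterance_rate = 20,
                                       mean_utterance_words = 8))
  tags <- co$token_tags
  open <- tags$folded[tags$pos %in% c("OTHER", "VERB", "ADJ")]
  expect_gt(length(open), 50000)
  cnt <- sort(as.numeric(table(open)), decreasing = TRUE)
  keep <- cnt >= 5
  slope <- unname(stats::coef(stats::lm(
    log(cnt[keep]) ~ log(seq_along(cnt)[keep])))[2])
  expect_lt(abs(slope - (-1)), 0.1)
})

test_that("utterance counts follow the renewal process", {
  co <- generate_corpus(synthetic_spec(seed = 64, session_length = 1800,
                                       utterance_rate = 10, n_children = 1))
  counts <- table(co$transcript$speaker_id)
  for (n in counts) {
    expect_lt(abs(n - 300), 3 * sqrt(300))
  }
})

test_that("identity corruption changes nothing but provenance", {
  co <- generate_corpus(synthetic_spec(seed = 65, session_length = 300))
  out <- corrupt_transcript(co$transcript, corruption_spec(seed = 66))
  expect_identical(out$raw_text, co$transcript$raw_text)
  expect_identical(out$onset, co$transcript$onset)
  expect_identical(out$offset, co$transcript$offset)
  expect_identical(out$speaker_id, co$transcript$speaker_id)
  expect_equal(unique(out$provenance), "predicted")
})

test_that("injected word-error rates are recovered by WER", {
  co <- generate_corpus(synthetic_spec(seed = 67))
  truth <- unlist(co$transcript$tokens)
  n <- length(truth)
  expect_gt(n, 5000)
  ci99 <- 2.576 * sqrt(0.2 * 0.8 / n) * 100

  del <- corrupt_transcript(co$transcript, corruption_spec(seed = 68, p_del = 0.2))
  wer_del <- word_error_rate(truth, unlist(del$tokens))
  expect_lt(abs(wer_del - 20), ci99)

  mix <- corrupt_transcript(co$transcript,
                            corruption_spec(seed = 69, p_sub = 0.1, p_del = 0.1))
  wer_mix <- word_error_rate(truth, unlist(mix$tokens))
  # substitutions and deletions both enter the numerator additively; allow
  # for the occasional substitution drawing the original word back
  expect_lt(abs(wer_mix - 20), ci99 + 0.5)
})

test_that("conversational turns survive corruption without label confusion", {
  co <- generate_corpus(synthetic_spec(seed = 70, session_length = 900))
  pred <- corrupt_transcript(co$transcript,
                             corruption_spec(seed = 71, p_sub = 0.15))
  dy_truth <- co$transcript[co$transcript$speaker_id %in% c("C1", "T1"), ]
  dy_pred <- pred[pred$speaker_id %in% c("C1", "T1"), ]
  expect_equal(count_turns(dy_pred), count_turns(dy_truth))
})

test_that("boundary jitter alone degrades agreement past the tolerance", {
  co <- generate_corpus(synthetic_spec(seed = 72, session_length = 600))
  none <- corrupt_transcript(co$transcript, corruption_spec(seed = 73))
  expect_equal(boundary_agreement(co$transcript, none)$onset_pct, 100)
  big <- corrupt_transcript(co$transcript,
                            corruption_spec(seed = 74, boundary_jitter_sd = 1.5))
  expect_lt(boundary_agreement(co$transcript, big)$onset_pct, 100)
})

test_that("overlapping co-location blocks for a pair are rejected", {
  sched <- tibble::tibble(id_a = c("C1", "C1"), id_b = c("T1", "T1"),
                          start = c(0, 50), end = c(100, 150))
  expect_error(synthetic_spec(seed = 1, dyad_schedule = sched),
               "overlap", class = "classtalk_validation_error")
})

test_that("proximity pings respect the schedule and the gate", {
  spec <- synthetic_spec(seed = 75, session_length = 600)
  co <- generate_corpus(spec)
  iv <- build_proximity_intervals(co$proximity,
                                  ping_period = spec$proximity_ping_period)
  sched <- spec$dyad_schedule
  # every scheduled block is covered by a within-gate interval
  for (b in seq_len(nrow(sched))) {
    hit <- iv$id_a == sched$id_a[b] & iv$id_b == sched$id_b[b] &
      iv$start <= sched$start[b] & iv$end >= min(sched$end[b], 600)
    expect_true(any(hit))
  }
})
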