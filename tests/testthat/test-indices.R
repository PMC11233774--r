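test_that("the rule tagger covers the closed classes", {
  u <- make_transcript("T1", 0, 3,
    "I am going to read you something off of my cards")
  tags <- tag_tokens(u[1, ])
  expect_equal(tags$pos[tags$surface == "am"], "AUX")
  expect_equal(pos_tag_rules(c("and", "or", "but")), rep("CCONJ", 3))
  expect_equal(pos_tag_rules(c("that", "if", "while")), rep("SCONJ", 3))
  expect_equal(pos_tag_rules(c("ask", "Logan")), c("OTHER", "PROPN"))
  expect_equal(pos_tag_rules(c("page", "7")), c("OTHER", "NUM"))
  expect_equal(pos_tag_rules(character(0)), character(0))
  empty <- make_transcript("T1", 0, 1, "...")
  expect_equal(nrow(tag_tokens(empty[1, ])), 0)
})

test_that("a failing tagger is reported with the utterance id", {
  u <- make_transcript("T1", 0, 1, "hello there.")
  expect_error(tag_tokens(u[1, ], tagger = function(x) stop("boom")),
               u$utterance_id[1], class = "classtalk_tagging_error")
})

test_that("rare words exclude the common-list closure, names and numbers", {
  fl <- frequency_list("cat")
  expect_true(all(c("cat", "cats", "catted", "catting") %in% fl$closure))
  tagged <- tibble::tibble(folded = c("cats", "dog", "logan", "7"),
                           pos = c("OTHER", "OTHER", "PROPN", "NUM"))
  expect_equal(is_rare(tagged, fl), c(FALSE, TRUE, FALSE, FALSE))

  demo <- demo_frequency_list()
  expect_false(is_rare(tibble::tibble(folded = "the", pos = "OTHER"), demo))
})

test_that("inflected closure applies e-drop and y-to-i rules", {
  expect_true(all(c("baking", "baked") %in% inflect_forms("bake")))
  expect_true(all(c("carries", "carried") %in% inflect_forms("carry")))
  expect_true("running" %in% inflect_forms("run"))
})

test_that("turn counting is the number of speaker alternations", {
  t1 <- make_transcript("A", c(0, 2), c(1, 3), c("a one.", "a two."),
                        roles = c("teacher", "teacher"))
  expect_equal(count_turns(t1), 0)
  t2 <- make_transcript(c("A", "B", "A"), c(0, 2, 4), c(1, 3, 5),
                        rep("hi there.", 3),
                        roles = c("teacher", "peer", "teacher"))
  expect_equal(count_turns(t2), 2)
  t3 <- make_transcript(c("A", "A", "B", "B", "A"), 0:4 * 2, 0:4 * 2 + 1,
                        rep("hi there.", 5),
                        roles = c("teacher", "teacher", "peer", "peer", "teacher"))
  expect_equal(count_turns(t3), 2)
  t4 <- make_transcript(c("A", "B", "C"), c(0, 2, 4), c(1, 3, 5),
                        rep("hi.", 3), roles = c("teacher", "peer", "peer"))
  expect_error(count_turns(t4), "two", class = "classtalk_validation_error")
  # max-gap cutoff suppresses distant alternations
  expect_equal(count_turns(t2, turn_max_gap = 0.5), 0)
})

test_that("the index vector matches a hand count on example sentences", {
  tr <- make_transcript("T1", c(0, 5), c(4, 6),
    c("I am going to read you something off of my cards", "You are right"))
  v <- index_vector(tr)
  expect_equal(v$UT, 2)
  expect_equal(v$WD, 14)
  expect_equal(v$AV, 2)       # am, are
  expect_equal(v$MLU, 7.0)
  expect_equal(v$UW, 13)      # "you" repeats
  expect_equal(v$TTR, 13 / 14)
  expect_equal(v$SD, 5)
})

test_that("degenerate index inputs give missing ratios, never zero", {
  one <- make_transcript("T1", 0, 2, "five distinct little words here.")
  v1 <- index_vector(one)
  expect_equal(v1$TTR, 1.0)
  expect_equal(v1$MLU, 5)

  none <- one[0, ]
  v0 <- index_vector(none)
  expect_equal(v0$UT, 0)
  expect_equal(v0$WD, 0)
  expect_true(is.na(v0$MLU))
  expect_true(is.na(v0$TTR))
  expect_equal(v0$SD, 0)

  # vocalization-only rows are skipped by every counting operation
  voc <- make_transcript(c("T1", "T1"), c(0, 2), c(1, 3), c("...", "two words."))
  expect_equal(index_vector(voc)$UT, 1)
})

test_that("dyads fan out to every in-proximity receiver", {
  tr <- make_transcript(c("T1", "C1"), c(0, 5), c(2, 6),
                        c("You are right.", "okay then."))
  tr$in_proximity_of <- list(c("C1", "C2"), "T1")
  dy <- dyadic_table(tr)
  expect_setequal(paste(dy$sender, dy$receiver),
                  c("T1 C1", "T1 C2", "C1 T1"))
  expect_equal(dy$WD[dy$sender == "T1" & dy$receiver == "C1"], 3)
  expect_equal(dy$WD[dy$sender == "T1" & dy$receiver == "C2"], 3)

  # nothing in proximity + gating on -> empty table
  tr$in_proximity_of <- list(character(0), character(0))
  expect_equal(nrow(dyadic_table(tr)), 0)

  # gating off reduces to plain aggregation over the sender's utterances
  dy2 <- dyadic_table(tr, gate = FALSE)
  v <- index_vector(tr[tr$speaker_id == "T1", ])
  t_row <- dy2[dy2$sender == "T1", ]
  expect_equal(t_row$WD, v$WD)
  expect_equal(t_row$UT, v$UT)
})

test_that("index computation agrees with brute-force recounts", {
  withr::local_seed(45)
  fl <- toy_freq()
  for (rep in 1:150) {
    fx <- random_tagged_fixture(n_utt = 5)
    v <- index_vector(fx$transcript, tagged = fx$tags, freq = fl)
    o <- oracle_index_recount(fx$transcript, fx$tags, freq = fl)
    for (nm in names(o)) {
      expect_equal(v[[nm]], o[[nm]], info = nm)
    }
    # invariants
    expect_lte(v$AV + v$VB + v$CC + v$SC + v$AJ, v$WD)
    expect_lte(v$UW, v$WD)
    expect_lte(v$RW, v$UW)
    if (v$UT > 0) expect_equal(v$MLU, v$WD / v$UT)
    if (v$WD > 0) expect_equal(v$TTR, v$UW / v$WD)
  }
})

test_that("indices ignore identity labels and CT is reversal-invariant", {
  withr::local_seed(46)
  fx <- random_tagged_fixture(n_utt = 8)
  tr <- fx$transcript
  v <- index_vector(tr, tagged = fx$tags, freq = toy_freq())

  relab <- tr
  new_ids <- paste0("z", rev(tr$utterance_id))
  tags2 <- fx$tags
  tags2$utterance_id <- new_ids[match(tags2$utterance_id, tr$utterance_id)]
  relab$utterance_id <- new_ids
  v2 <- index_vector(relab, tagged = tags2, freq = toy_freq())
  expect_equal(v2, v)

  rev_tr <- tr[rev(seq_len(nrow(tr))), ]
  rev_tr$onset <- max(tr$offset) - rev(tr$offset)
  rev_tr$offset <- max(tr$offset) - rev(tr$onset)
  expect_equal(count_turns(as_transcript(rev_tr[, setdiff(names(rev_tr),
    c("utterance_id", "tokens", "in_proximity_of", "provenance"))])),
    count_turns(tr))
})
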