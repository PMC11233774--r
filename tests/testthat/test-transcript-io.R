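test_that("tabular transcripts are read sorted with derived tokens", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "recording_id,speaker_id,role,onset_s,offset_s,text",
    "r1,T1,teacher,5.0,6.0,late words here",
    "r1,C1,focal_child,1.0,2.0,You are right.",
    "r1,C2,peer,2.0,3.0,mid"
  ), f)
  tr <- read_transcript(f)
  expect_equal(tr$onset, c(1, 2, 5))
  expect_equal(tr$tokens[[1]], c("You", "are", "right"))
  expect_equal(tr$raw_text[1], "You are right.")  # punctuation retained
  expect_equal(tr$provenance, rep("reference", 3))
})

test_that("an empty file with a valid header yields an empty transcript", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("recording_id,speaker_id,role,onset_s,offset_s,text", f)
  tr <- read_transcript(f)
  expect_equal(nrow(tr), 0)
})

test_that("malformed transcripts are rejected with informative errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("recording_id,speaker_id,onset_s,offset_s,text",
               "r1,T1,1,2,hi"), f)
  expect_error(read_transcript(f), "role", class = "classtalk_format_error")

  g <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("recording_id,speaker_id,role,onset_s,offset_s,text",
               "r1,T1,teacher,1.0,2.0,ok",
               "r1,T1,teacher,5.0,4.0,backwards"), g)
  expect_error(read_transcript(g), "row 2", class = "classtalk_validation_error")

  h <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("recording_id,speaker_id,role,onset_s,offset_s,text",
               "r1,T1,narrator,1.0,2.0,hi"), h)
  expect_error(read_transcript(h), "role", class = "classtalk_validation_error")
})

test_that("tokenization is deterministic and keeps internal apostrophes", {
  expect_identical(tokenize_text("I don't know!"), list(c("I", "don't", "know")))
  x <- "Well, okay... fine?!"
  expect_identical(tokenize_text(x), tokenize_text(x))
  expect_identical(tokenize_text(x)[[1]], c("Well", "okay", "fine"))
  expect_identical(tokenize_text("...")[[1]], character(0))
})

test_that("write/read round trip preserves the transcript", {
  tr <- generate_corpus(synthetic_spec(seed = 21, session_length = 300))$transcript
  f <- withr::local_tempfile(fileext = ".csv")
  write_transcript(tr, f)
  back <- read_transcript(f)
  expect_equal(nrow(back), nrow(tr))
  expect_identical(back$speaker_id, tr$speaker_id)
  expect_identical(back$raw_text, tr$raw_text)
  expect_true(all(abs(back$onset - tr$onset) <= 0.001))
  expect_true(all(abs(back$offset - tr$offset) <= 0.001))
})

test_that("proximity logs sort events and normalize pair order", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp_s,id_a,id_b,rssi_db",
               "1.0,A,B,-70",
               "0.5,B,A,-80"), f)
  ev <- read_proximity_log(f)
  expect_equal(ev$timestamp, c(0.5, 1.0))
  expect_equal(ev$id_a, c("A", "A"))
  expect_equal(ev$id_b, c("B", "B"))
  expect_equal(ev$rssi[2], -70)
})

test_that("bad proximity rows are rejected with row numbers", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp_s,id_a,id_b,rssi_db",
               "1.0,A,B,-70",
               "2.0,A,B,strong"), f)
  expect_error(read_proximity_log(f), "row 2",
               class = "classtalk_validation_error")

  g <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp_s,id_a,id_b,rssi_db", "1.0,A,A,-70"), g)
  expect_error(read_proximity_log(g), "id_a",
               class = "classtalk_validation_error")
})

test_that("ELAN files map one tier per speaker", {
  eaf <- withr::local_tempfile(fileext = ".eaf")
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<ANNOTATION_DOCUMENT>',
    '  <TIME_ORDER>',
    '    <TIME_SLOT TIME_SLOT_ID="ts1" TIME_VALUE="500"/>',
    '    <TIME_SLOT TIME_SLOT_ID="ts2" TIME_VALUE="1500"/>',
    '    <TIME_SLOT TIME_SLOT_ID="ts3" TIME_VALUE="2000"/>',
    '    <TIME_SLOT TIME_SLOT_ID="ts4" TIME_VALUE="4000"/>',
    '  </TIME_ORDER>',
    '  <TIER TIER_ID="C1" PARTICIPANT="focal_child">',
    '    <ANNOTATION><ALIGNABLE_ANNOTATION ANNOTATION_ID="a1"',
    '      TIME_SLOT_REF1="ts1" TIME_SLOT_REF2="ts2">',
    '      <ANNOTATION_VALUE>Look at this.</ANNOTATION_VALUE>',
    '    </ALIGNABLE_ANNOTATION></ANNOTATION>',
    '  </TIER>',
    '  <TIER TIER_ID="T1" PARTICIPANT="teacher">',
    '    <ANNOTATION><ALIGNABLE_ANNOTATION ANNOTATION_ID="a2"',
    '      TIME_SLOT_REF1="ts3" TIME_SLOT_REF2="ts4">',
    '      <ANNOTATION_VALUE>You are right.</ANNOTATION_VALUE>',
    '    </ALIGNABLE_ANNOTATION></ANNOTATION>',
    '  </TIER>',
    '</ANNOTATION_DOCUMENT>'
  ), eaf)
  tr <- read_transcript(eaf, dialect = "elan")
  expect_equal(nrow(tr), 2)
  expect_equal(tr$speaker_id, c("C1", "T1"))
  expect_equal(tr$role, c("focal_child", "teacher"))
  expect_equal(tr$onset, c(0.5, 2.0))
  expect_equal(tr$offset, c(1.5, 4.0))
  expect_equal(tr$tokens[[2]], c("You", "are", "right"))
})
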