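test_that("relative error follows its closed form and guards zero references", {
  expect_equal(relative_error(10, 10), 0)
  expect_equal(relative_error(8, 16), 100)
  expect_warning(out <- relative_error(0, 5),
                 class = "classtalk_zero_reference")
  expect_true(is.na(out))
})

test_that("relative error is scale-invariant and asymmetric", {
  withr::local_seed(51)
  x_r <- runif(2000, 0.1, 100)
  x_p <- runif(2000, 0, 100)
  e <- relative_error(x_r, x_p)
  expect_equal(e, abs(x_r - x_p) / x_r * 100)
  expect_true(all(e[abs(x_r - x_p) > 0] > 0))
  expect_equal(relative_error(3 * x_r, 3 * x_p), e)
  swapped <- relative_error(x_p + 0.1, x_r)
  expect_false(isTRUE(all.equal(relative_error(x_r, x_p + 0.1), swapped)))
})

test_that("windows tile the span with a flagged final partial", {
  ref <- make_transcript("T1", c(10, 400), c(20, 410),
                         c("early words.", "later words."))
  ref$offset[2] <- 720
  win <- eval_windows(ref, ref)
  expect_equal(max(win$j), 2)
  expect_false(any(win$partial))

  # a 47.42-minute span at six-minute windows: 8 windows, last one partial
  long <- make_transcript("T1", c(0, 2845.2 - 10), c(5, 2845.2),
                          c("start words.", "end words."))
  win2 <- eval_windows(long, long)
  expect_equal(max(win2$j), 8)
  expect_true(all(win2$partial[win2$j == 8]))
  expect_false(any(win2$partial[win2$j < 8]))
  expect_equal(unique(win2$end[win2$j == 8]), 2845.2)
})

test_that("an onset exactly on a boundary belongs to the later window", {
  ref <- make_transcript("T1", c(0, 360), c(5, 365),
                         c("first window.", "second window."))
  win <- eval_windows(ref, ref)
  ut <- win[win$index == "UT", ]
  expect_equal(ut$x_r, c(1, 1))
})

test_that("accuracy summaries behave on constructed window sets", {
  ref <- make_transcript("T1", c(0, 100, 400, 500, 800, 900),
                         c(10, 110, 410, 510, 810, 910),
                         c("one two three.", "four five.",
                           "six seven eight nine.", "ten eleven.",
                           "twelve thirteen three.", "fourteen fifteen sixteen four."))
  win <- eval_windows(ref, ref)
  rep1 <- summarize_accuracy(win)
  ok <- rep1[rep1$status == "ok", ]
  expect_true(nrow(ok) > 0)
  expect_true(all(ok$err_median == 0))
  expect_true(all(abs(ok$r - 1) < 1e-10))

  # doubling every prediction doubles nothing about the correlation
  win2 <- win
  win2$x_p <- 2 * win2$x_r
  rep2 <- summarize_accuracy(win2)
  ok2 <- rep2[rep2$status == "ok", ]
  expect_true(all(ok2$err_median == 100))
  expect_true(all(abs(ok2$r - 1) < 1e-10))

  # anti-correlated windows give r = -1
  win3 <- win[win$index == "WD", ]
  win3$x_p <- 10 - win3$x_r + max(win3$x_r)
  rep3 <- summarize_accuracy(win3)
  expect_equal(rep3$r[rep3$index == "WD"], -1)
})

test_that("the error median resists outliers", {
  w <- tibble::tibble(j = 1:3, start = 0, end = 1, partial = FALSE,
                      index = "WD", x_r = c(10, 10, 10),
                      x_p = c(11, 12, 110))
  rep <- summarize_accuracy(w)
  expect_equal(rep$err_median[rep$index == "WD"], 20)
})

test_that("word error rate matches hand-computed alignments", {
  expect_equal(word_error_rate(letters[1:6], letters[1:6]), 0)
  expect_equal(word_error_rate(c("the", "cat", "sat", "on", "the", "mat"),
                               c("the", "cat", "sat", "the", "mat")),
               100 / 6)
  expect_equal(word_error_rate(c("a", "b", "c", "d"), c("a", "x", "c")), 50)
  expect_equal(word_error_rate(character(0), character(0)), 0)
  expect_warning(deg <- word_error_rate(character(0), c("x", "y")),
                 class = "classtalk_degenerate")
  expect_equal(deg, 200)
  # normalization folds case and strips punctuation
  expect_equal(word_error_rate(c("The", "cat."), c("the", "cat")), 0)
})

test_that("edit counts agree with the character-level distance oracle", {
  withr::local_seed(52)
  syms <- c("a", "b", "c", "d")
  for (rep in 1:200) {
    ref <- sample(syms, sample(0:8, 1), replace = TRUE)
    hyp <- sample(syms, sample(0:8, 1), replace = TRUE)
    counts <- wer_counts(ref, hyp)
    dist <- utils::adist(paste(ref, collapse = ""), paste(hyp, collapse = ""))
    expect_equal(sum(counts), as.integer(dist))
  }
})

test_that("median WER follows the median conventions and ignores order", {
  seg <- function(r, h) list(reference = r, hypothesis = h)
  expect_equal(median_wer(list(seg(c("a", "b"), c("a", "x")))), 50)
  s3 <- list(seg(c("a"), c("a")), seg(c("a", "b"), c("a")),
             seg(c("a"), c("b")))  # WERs 0, 50, 100
  expect_equal(median_wer(s3), 50)
  s4 <- list(seg(rep("a", 10), c(rep("a", 9), "b")),          # 10
             seg(rep("a", 10), c(rep("a", 8), "b", "b")),     # 20
             seg(rep("a", 10), c(rep("a", 7), "b", "b", "b")),# 30
             seg(c("a"), rep("b", 10)))                       # 1000
  expect_equal(median_wer(s4), 25)
  expect_equal(median_wer(rev(s4)), 25)
  expect_error(median_wer(list()), class = "classtalk_validation_error")
})

test_that("boundary agreement implements the 250 ms rule", {
  ref <- make_transcript(c("T1", "T1", "C1"), c(0, 10, 20), c(2, 12, 22),
                         c("a one.", "a two.", "a three."))
  expect_equal(boundary_agreement(ref, ref),
               tibble::tibble(onset_pct = 100, offset_pct = 100))
  shift <- function(tr, by) {
    tr$onset <- tr$onset + by
    tr$offset <- tr$offset + by
    tr
  }
  expect_equal(boundary_agreement(ref, shift(ref, 0.2))$onset_pct, 100)
  expect_equal(boundary_agreement(ref, shift(ref, 0.3))$onset_pct, 0)
})

test_that("convergence curves flatten in the perfect case and need 3 windows", {
  ref <- make_transcript("T1", seq(0, 2000, by = 400),
                         seq(0, 2000, by = 400) + sample(5:10, 6, replace = TRUE),
                         sprintf("window %s words here.", letters[1:6]))
  win <- eval_windows(ref, ref)
  curve <- convergence_curve(win, "WD")
  expect_true(all(curve$err_median == 0))
  expect_equal(attr(curve, "flatness")$err_median, 0)
  expect_error(convergence_curve(win[win$j <= 2, ], "WD"),
               class = "classtalk_not_evaluable")
})

test_that("convergence variability shrinks as windows accumulate", {
  withr::local_seed(53)
  n <- 40
  finals <- replicate(30, {
    x_r <- runif(n, 20, 60)
    w <- tibble::tibble(j = 1:n, start = 0, end = 1, partial = FALSE,
                        index = "WD", x_r = x_r,
                        x_p = x_r * exp(rnorm(n, 0, 0.3)))
    c <- convergence_curve(w, "WD")
    c(head = c$err_median[1], tail = c$err_median[nrow(c)])
  })
  # the cumulative median at k = n varies less across replicates than at k = 3
  expect_lt(stats::sd(finals["tail", ]), stats::sd(finals["head", ]))
})

test_that("transcription cost scales with children, minutes and rate", {
  expect_equal(estimate_transcription_cost(18, 60, 4), 432)
  expect_equal(estimate_transcription_cost(1, 10, 4), 4)
  expect_equal(estimate_transcription_cost(6, 10, 5), 30)
  expect_error(estimate_transcription_cost(0, 10, 4),
               class = "classtalk_validation_error")
})
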