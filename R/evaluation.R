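# Accuracy protocol: six-minute windowing, absolute relative error and its
# median, Pearson correlation, median word error rate, boundary agreement,
# convergence diagnostics, and the transcription-cost estimator.

#' Absolute relative error, in percent
#'
#' `|x_r - x_p| / x_r * 100`: zero means the prediction matched the reference
#' exactly; a doubled (or zeroed) prediction gives 100. The measure is
#' scale-invariant in the pair and deliberately asymmetric in its arguments —
#' the reference is the denominator. A zero reference leaves the error
#' undefined; such values are returned as `NA` under a
#' `"classtalk_zero_reference"` warning so the caller can exclude and log the
#' affected window.
#'
#' @param x_r Reference value(s).
#' @param x_p Predicted value(s).
#' @return Numeric vector of percentages, `NA` where `x_r` is 0 or either
#'   value is missing.
#' @examples
#' relative_error(10, 10)
#' relative_error(8, 16)
#' @export
relative_error <- function(x_r, x_p) {
  out <- abs(x_r - x_p) / x_r * 100
  zero <- !is.na(x_r) & x_r == 0
  if (any(zero)) {
    warn(sprintf("undefined reference: x_r = 0 in %d case(s); returning NA",
                 sum(zero)),
         class = "classtalk_zero_reference")
    out[zero] <- NA_real_
  }
  out
}

#' Pair reference and predicted transcripts into evaluation windows
#'
#' Tiles the recording span with consecutive half-open windows
#' `[start, end)` of `eval_window` seconds (default six minutes) anchored at
#' time zero, assigns utterances to windows by onset, and computes the
#' thirteen indices for the reference and the predicted transcript in each
#' window. A final partial window is kept and flagged rather than dropped,
#' so short speaker types are not discarded.
#'
#' @param reference Reference transcript tibble.
#' @param predicted Predicted transcript tibble covering the same recording
#'   span.
#' @param cfg An [analysis_config()]; supplies `eval_window`.
#' @param freq Optional [frequency_list()] for RW.
#' @param tagger Tagger for both transcripts (or supply `tagged_ref` /
#'   `tagged_pred`).
#' @param tagged_ref,tagged_pred Optional pre-computed tagged tokens.
#' @return Long tibble with one row per (window, index): columns `j`,
#'   `start`, `end`, `partial`, `index`, `x_r`, `x_p`.
#' @export
eval_windows <- function(reference, predicted, cfg = analysis_config(),
                         freq = NULL, tagger = pos_tag_rules,
                         tagged_ref = NULL, tagged_pred = NULL) {
  span <- max(reference$offset, predicted$offset, 0)
  if (!is.finite(span) || span <= 0) {
    abort_validation("zero-length recording span")
  }
  w <- cfg$eval_window
  n <- ceiling(span / w)
  starts <- (seq_len(n) - 1) * w
  ends <- pmin(starts + w, span)

  one <- function(transcript, tagged, j) {
    inside <- transcript$onset >= starts[j] & transcript$onset < starts[j] + w
    index_vector(transcript[inside, , drop = FALSE], tagged = tagged,
                 freq = freq, tagger = tagger)
  }
  if (is.null(tagged_ref)) tagged_ref <- tag_transcript(reference, tagger)
  if (is.null(tagged_pred)) tagged_pred <- tag_transcript(predicted, tagger)

  purrr::map_dfr(seq_len(n), function(j) {
    xr <- one(reference, tagged_ref, j)
    xp <- one(predicted, tagged_pred, j)
    tibble::tibble(
      j = j, start = starts[j], end = ends[j],
      partial = ends[j] - starts[j] < w,
      index = index_names,
      x_r = as.numeric(xr[1, index_names]),
      x_p = as.numeric(xp[1, index_names])
    )
  })
}

#' Summarise accuracy over evaluation windows
#'
#' For each index: the median absolute relative error across windows
#' (windows with a zero or missing reference value are excluded per index and
#' counted in `n_excluded`), the Pearson correlation between the predicted
#' and reference window vectors with its two-sided p-value, the sums of the
#' window values for both transcripts, and a Kolmogorov-Smirnov normality
#' diagnostic of the error distribution (recorded, not acted on — the median
#' is used precisely because these error distributions are typically skewed).
#' An index needs at least three usable windows for a correlation; indices
#' with fewer are marked `"insufficient"`, indices whose window values have
#' zero variance are marked `"zero_variance"`, and indices with no usable
#' window at all are `"not_evaluable"`.
#'
#' @param windows Long window tibble from [eval_windows()].
#' @param alpha Significance level for flagging correlations (default 0.05).
#' @return A tibble of class `"accuracy_report"` with one row per index:
#'   `index`, `err_median`, `r`, `p_value`, `significant`, `sum_ref`,
#'   `sum_pred`, `n_windows`, `n_used`, `n_excluded`, `ks_stat`, `ks_p`,
#'   `normal_errors`, `status`.
#' @export
summarize_accuracy <- function(windows, alpha = 0.05) {
  out <- windows |>
    dplyr::group_by(index = factor(.data$index, levels = index_names)) |>
    dplyr::group_modify(function(d, key) {
      usable <- !is.na(d$x_r) & !is.na(d$x_p) & d$x_r != 0
      e <- suppressWarnings(relative_error(d$x_r[usable], d$x_p[usable]))
      n_used <- sum(usable)
      status <- "ok"
      r <- p <- NA_real_
      if (n_used == 0) {
        status <- "not_evaluable"
      } else if (n_used < 3) {
        status <- "insufficient"
      } else if (stats::sd(d$x_r[usable]) == 0 || stats::sd(d$x_p[usable]) == 0) {
        status <- "zero_variance"
      } else {
        ct <- stats::cor.test(d$x_p[usable], d$x_r[usable],
                              method = "pearson", alternative = "two.sided")
        r <- unname(ct$estimate)
        p <- ct$p.value
      }
      ks_stat <- ks_p <- NA_real_
      if (n_used >= 3 && stats::sd(e) > 0) {
        ks <- suppressWarnings(stats::ks.test(e, "pnorm", mean(e), stats::sd(e)))
        ks_stat <- unname(ks$statistic)
        ks_p <- ks$p.value
      }
      tibble::tibble(
        err_median = if (n_used > 0) median(e) else NA_real_,
        r = r,
        p_value = p,
        significant = !is.na(p) & p < alpha,
        sum_ref = sum(d$x_r, na.rm = TRUE),
        sum_pred = sum(d$x_p, na.rm = TRUE),
        n_windows = nrow(d),
        n_used = n_used,
        n_excluded = nrow(d) - n_used,
        ks_stat = ks_stat,
        ks_p = ks_p,
        normal_errors = !is.na(ks_p) & ks_p >= alpha,
        status = status
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(index = as.character(.data$index))
  class(out) <- c("accuracy_report", class(out))
  out
}

#' Tidy an accuracy report
#'
#' @param x An `"accuracy_report"`.
#' @param ... Unused.
#' @return The report as a plain tibble.
#' @method tidy accuracy_report
#' @export
tidy.accuracy_report <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' One-row summary of an accuracy report
#'
#' @param x An `"accuracy_report"`.
#' @param ... Unused.
#' @return One-row tibble with window and index counts and the range of the
#'   per-index statistics.
#' @method glance accuracy_report
#' @export
glance.accuracy_report <- function(x, ...) {
  evaluable <- x$status == "ok"
  tibble::tibble(
    n_windows = max(x$n_windows),
    n_indices = nrow(x),
    n_evaluable = sum(evaluable),
    median_err_median = median(x$err_median, na.rm = TRUE),
    min_r = suppressWarnings(min(x$r[evaluable])),
    max_r = suppressWarnings(max(x$r[evaluable]))
  )
}

#' Per-window word error rate for a reference/predicted transcript pair
#'
#' Concatenates the tokens of the utterances whose onsets fall in each
#' evaluation window (half-open, anchored at zero) and scores the predicted
#' against the reference token stream.
#'
#' @inheritParams eval_windows
#' @return Tibble with columns `j`, `start`, `end`, `n_ref_words`, `wer`.
#' @export
wer_windows <- function(reference, predicted, cfg = analysis_config()) {
  span <- max(reference$offset, predicted$offset, 0)
  if (!is.finite(span) || span <= 0) {
    abort_validation("zero-length recording span")
  }
  w <- cfg$eval_window
  n <- ceiling(span / w)
  purrr::map_dfr(seq_len(n), function(j) {
    lo <- (j - 1) * w
    ref_tokens <- unlist(reference$tokens[reference$onset >= lo &
                                            reference$onset < lo + w])
    hyp_tokens <- unlist(predicted$tokens[predicted$onset >= lo &
                                            predicted$onset < lo + w])
    ref_tokens <- normalize_wer_tokens(ref_tokens %||% character(0))
    hyp_tokens <- normalize_wer_tokens(hyp_tokens %||% character(0))
    wer <- if (length(ref_tokens) == 0 && length(hyp_tokens) == 0) {
      NA_real_
    } else {
      suppressWarnings(word_error_rate(ref_tokens, hyp_tokens, normalize = FALSE))
    }
    tibble::tibble(j = j, start = lo, end = min(lo + w, span),
                   n_ref_words = length(ref_tokens), wer = wer)
  })
}

#' Boundary agreement between two transcripts
#'
#' Greedy nearest-neighbour pairing of same-speaker utterances by onset
#' (candidate pairs considered in order of increasing onset difference, each
#' utterance used at most once), then the percentage of reference utterances
#' whose paired onset (resp. offset) differs by at most
#' `agreement_tolerance` seconds — the 250 ms coder-agreement rule.
#'
#' @param reference,predicted Non-empty transcript tibbles.
#' @param cfg An [analysis_config()]; supplies `agreement_tolerance`.
#' @return One-row tibble with `onset_pct` and `offset_pct`.
#' @export
boundary_agreement <- function(reference, predicted, cfg = analysis_config()) {
  if (nrow(reference) == 0 || nrow(predicted) == 0) {
    abort_validation("boundary_agreement requires non-empty transcripts")
  }
  tol <- cfg$agreement_tolerance
  n_ref <- nrow(reference)
  onset_ok <- 0L
  offset_ok <- 0L
  for (sp in unique(reference$speaker_id)) {
    r <- reference[reference$speaker_id == sp, , drop = FALSE]
    p <- predicted[predicted$speaker_id == sp, , drop = FALSE]
    if (nrow(p) == 0) next
    cand <- expand.grid(i = seq_len(nrow(r)), k = seq_len(nrow(p)))
    cand$d <- abs(r$onset[cand$i] - p$onset[cand$k])
    cand <- cand[order(cand$d), , drop = FALSE]
    used_r <- logical(nrow(r))
    used_p <- logical(nrow(p))
    for (row in seq_len(nrow(cand))) {
      i <- cand$i[row]; k <- cand$k[row]
      if (used_r[i] || used_p[k]) next
      used_r[i] <- TRUE
      used_p[k] <- TRUE
      if (abs(r$onset[i] - p$onset[k]) <= tol) onset_ok <- onset_ok + 1L
      if (abs(r$offset[i] - p$offset[k]) <= tol) offset_ok <- offset_ok + 1L
    }
  }
  tibble::tibble(onset_pct = 100 * onset_ok / n_ref,
                 offset_pct = 100 * offset_ok / n_ref)
}

#' Convergence of accuracy statistics across windows
#'
#' Cumulative median absolute relative error and Pearson correlation for one
#' index over the first k windows, k = 3..n — the diagnostic used to decide
#' whether enough data have been scored for the accuracy estimates to have
#' settled. The attached `flatness` attribute reports the maximum absolute
#' change of each curve over its last quarter; a flat tail indicates
#' convergence.
#'
#' @param windows Long window tibble from [eval_windows()].
#' @param index Index name (one of `UT, WD, ..., SD`).
#' @return Tibble with columns `k`, `err_median`, `r`, and attribute
#'   `flatness` (list with `err_median` and `r`).
#' @export
convergence_curve <- function(windows, index) {
  d <- windows[windows$index == index, , drop = FALSE]
  d <- d[order(d$j), , drop = FALSE]
  n <- nrow(d)
  if (n < 3) {
    abort("convergence_curve requires at least 3 windows",
          class = "classtalk_not_evaluable")
  }
  out <- purrr::map_dfr(3:n, function(k) {
    dd <- d[seq_len(k), , drop = FALSE]
    usable <- !is.na(dd$x_r) & !is.na(dd$x_p) & dd$x_r != 0
    e <- suppressWarnings(relative_error(dd$x_r[usable], dd$x_p[usable]))
    r <- NA_real_
    if (sum(usable) >= 3 && stats::sd(dd$x_r[usable]) > 0 &&
        stats::sd(dd$x_p[usable]) > 0) {
      r <- stats::cor(dd$x_p[usable], dd$x_r[usable])
    }
    tibble::tibble(k = k,
                   err_median = if (sum(usable) > 0) median(e) else NA_real_,
                   r = r)
  })
  tail_part <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) return(NA_real_)
    m <- max(2L, ceiling(length(x) / 4))
    x <- utils::tail(x, m)
    max(abs(diff(x)))
  }
  attr(out, "flatness") <- list(err_median = tail_part(out$err_median),
                                r = tail_part(out$r))
  out
}

#' Estimate manual transcription cost
#'
#' Hours of transcriber time needed for a classroom:
#' `n_children * (minutes_per_child / 10) * hours_per_10min`. At the
#' commonly reported rate of about 4 h of transcription per 10 min of audio,
#' 18 children recorded for an hour each cost 432 h; timestamping on top of
#' transcription brings the rate to roughly 5 h per 10 min.
#'
#' @param n_children Number of children recorded.
#' @param minutes_per_child Minutes of audio per child.
#' @param hours_per_10min Transcriber hours per 10 minutes of audio.
#' @return Total hours.
#' @examples
#' estimate_transcription_cost(18, 60, 4)
#' @export
estimate_transcription_cost <- function(n_children, minutes_per_child,
                                        hours_per_10min) {
  check_positive(n_children, "n_children")
  check_positive(minutes_per_child, "minutes_per_child")
  check_positive(hours_per_10min, "hours_per_10min")
  n_children * (minutes_per_child / 10) * hours_per_10min
}
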