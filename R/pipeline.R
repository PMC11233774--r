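# End-to-end runs: simulate, process (transcript + proximity -> dyadic index
# table), evaluate (reference vs. predicted -> accuracy report). Every run
# writes a manifest recording the configuration, input digests and output
# digests, so identical inputs + config + seed are verifiable as
# byte-identical by digest equality.

write_manifest <- function(out_dir, inputs, outputs, cfg, seed) {
  manifest <- list(
    tool = "classtalk",
    version = as.character(utils::packageVersion("classtalk")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = cfg[setdiff(names(cfg), character(0))],
    inputs = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    outputs = as.list(tools::md5sum(outputs[file.exists(outputs)]))
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Simulate a classroom session to disk
#'
#' Generates a synthetic corpus (and optionally a corrupted predicted
#' transcript) and writes the canonical CSV files plus a run manifest to a
#' directory.
#'
#' @param out_dir Output directory (created if needed).
#' @param spec A [synthetic_spec()].
#' @param corruption Optional [corruption_spec()]; when supplied,
#'   `predicted.csv` is written alongside the reference.
#' @return Named character vector of the written file paths, invisibly.
#' @export
run_simulate <- function(out_dir, spec = synthetic_spec(), corruption = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  corpus <- generate_corpus(spec)
  paths <- c(
    transcript = file.path(out_dir, "transcript.csv"),
    proximity = file.path(out_dir, "proximity.csv"),
    token_tags = file.path(out_dir, "token_tags.csv")
  )
  write_transcript(corpus$transcript, paths[["transcript"]])
  write_proximity_log(corpus$proximity, paths[["proximity"]])
  readr::write_csv(corpus$token_tags, paths[["token_tags"]], progress = FALSE)
  if (!is.null(corruption)) {
    predicted <- corrupt_transcript(corpus$transcript, corruption)
    paths <- c(paths, predicted = file.path(out_dir, "predicted.csv"))
    write_transcript(predicted, paths[["predicted"]])
  }
  write_manifest(out_dir, character(0), paths, cfg = unclass(spec)[
    setdiff(names(spec), "dyad_schedule")], seed = spec$seed)
  invisible(paths)
}

#' Process a transcript and proximity log into a dyadic index table
#'
#' The processing stages: re-segment utterances at punctuation boundaries,
#' build RSSI-gated proximity intervals, attach proximity partners to each
#' utterance, and compute the thirteen indices per (sender, receiver) dyad.
#' Writes `dyads.csv`, `intervals.csv` and a manifest to `out_dir`.
#'
#' @param transcript Transcript tibble or path to a transcript CSV.
#' @param proximity Proximity-event tibble or path to a proximity CSV;
#'   required unless `gate = FALSE`.
#' @param out_dir Output directory.
#' @param focal Focal participant id; required when `gate = TRUE`.
#' @param cfg An [analysis_config()].
#' @param freq Optional [frequency_list()] for RW.
#' @param gate Apply proximity gating (default `TRUE`).
#' @param ping_period Beacon cadence in seconds for interval construction.
#' @param tagger Tagger for the indices.
#' @return The dyadic table tibble, invisibly.
#' @export
run_process <- function(transcript, proximity = NULL, out_dir, focal = NULL,
                        cfg = analysis_config(), freq = NULL, gate = TRUE,
                        ping_period = 1, tagger = pos_tag_rules) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- character(0)
  if (is.character(transcript)) {
    inputs <- c(inputs, transcript)
    transcript <- read_transcript(transcript)
  }
  transcript <- resegment(transcript, segmentation_rule(
    punctuation_boundaries = cfg$punctuation_boundaries,
    pause_boundary = cfg$pause_boundary
  ))
  intervals <- NULL
  if (gate) {
    if (is.null(proximity)) {
      abort_validation("proximity log required when gating is enabled")
    }
    if (is.null(focal)) {
      abort_validation("`focal` participant id required when gating is enabled")
    }
    if (is.character(proximity)) {
      inputs <- c(inputs, proximity)
      proximity <- read_proximity_log(proximity)
    }
    intervals <- build_proximity_intervals(proximity, cfg, ping_period)
    transcript <- attach_proximity(transcript, intervals, focal)
  }
  dyads <- dyadic_table(transcript, freq = freq, tagger = tagger, gate = gate,
                        turn_max_gap = cfg$turn_max_gap)
  outputs <- c(dyads = file.path(out_dir, "dyads.csv"))
  write_dyadic_table(dyads, outputs[["dyads"]])
  if (!is.null(intervals)) {
    outputs <- c(outputs, intervals = file.path(out_dir, "intervals.csv"))
    write_intervals(intervals, outputs[["intervals"]])
  }
  write_manifest(out_dir, inputs, outputs, cfg = unclass(cfg),
                 seed = cfg$random_seed)
  invisible(dyads)
}

#' Evaluate a predicted transcript against a reference
#'
#' Runs the accuracy protocol per speaker role: six-minute windowing of both
#' transcripts, per-index median absolute relative error and Pearson
#' correlation, per-window word error rate with its median, boundary
#' agreement, and per-index convergence curves. Writes `accuracy_report.csv`,
#' `mwer.csv`, `boundary_agreement.csv`, `convergence.csv` and a manifest.
#'
#' @param reference Reference transcript tibble or CSV path.
#' @param predicted Predicted transcript tibble or CSV path.
#' @param out_dir Output directory.
#' @param cfg An [analysis_config()].
#' @param freq Optional [frequency_list()] for RW.
#' @param tagger Tagger for the indices.
#' @return List with elements `report`, `mwer`, `boundary`, `convergence`
#'   (tibbles), invisibly.
#' @export
run_evaluate <- function(reference, predicted, out_dir,
                         cfg = analysis_config(), freq = NULL,
                         tagger = pos_tag_rules) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- character(0)
  if (is.character(reference)) {
    inputs <- c(inputs, reference)
    reference <- read_transcript(reference, provenance = "reference")
  }
  if (is.character(predicted)) {
    inputs <- c(inputs, predicted)
    predicted <- read_transcript(predicted, provenance = "predicted")
  }
  if (nrow(reference) > 0 && nrow(predicted) > 0 &&
      !identical(reference$recording_id[1], predicted$recording_id[1])) {
    abort_validation(sprintf(
      "mismatched recording ids: reference '%s' vs predicted '%s'",
      reference$recording_id[1], predicted$recording_id[1]))
  }

  roles_present <- intersect(roles, unique(reference$role))
  report <- list()
  mwer_rows <- list()
  conv_rows <- list()
  for (rl in roles_present) {
    ref_r <- reference[reference$role == rl, , drop = FALSE]
    pred_r <- predicted[predicted$role == rl, , drop = FALSE]
    if (nrow(ref_r) == 0) next
    if (nrow(pred_r) == 0) {
      warn(sprintf("no predicted speech for role '%s'; indices not evaluable", rl))
      next
    }
    win <- eval_windows(ref_r, pred_r, cfg, freq = freq, tagger = tagger)
    rep_r <- summarize_accuracy(win)
    rep_r$role <- rl
    report[[rl]] <- rep_r

    ww <- wer_windows(ref_r, pred_r, cfg)
    mwer_rows[[rl]] <- tibble::tibble(
      role = rl,
      mwer = median(ww$wer, na.rm = TRUE),
      n_segments = sum(!is.na(ww$wer))
    )
    if (max(win$j) >= 3) {
      conv_rows[[rl]] <- purrr::map_dfr(index_names, function(ix) {
        cc <- convergence_curve(win, ix)
        cc$index <- ix
        cc$role <- rl
        cc
      })
    }
  }
  report <- dplyr::bind_rows(report)
  mwer_tbl <- dplyr::bind_rows(mwer_rows)
  conv_tbl <- dplyr::bind_rows(conv_rows)
  boundary <- boundary_agreement(reference, predicted, cfg)

  outputs <- c(
    report = file.path(out_dir, "accuracy_report.csv"),
    mwer = file.path(out_dir, "mwer.csv"),
    boundary = file.path(out_dir, "boundary_agreement.csv"),
    convergence = file.path(out_dir, "convergence.csv")
  )
  readr::write_csv(report, outputs[["report"]], progress = FALSE)
  readr::write_csv(mwer_tbl, outputs[["mwer"]], progress = FALSE)
  readr::write_csv(boundary, outputs[["boundary"]], progress = FALSE)
  readr::write_csv(conv_tbl, outputs[["convergence"]], progress = FALSE)
  write_manifest(out_dir, inputs, outputs, cfg = unclass(cfg),
                 seed = cfg$random_seed)
  invisible(list(report = report, mwer = mwer_tbl, boundary = boundary,
                 convergence = conv_tbl))
}
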