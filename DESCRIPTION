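Package: classtalk
Title: Dyadic Language-Environment Measures from Diarized Classroom Transcripts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processes diarized, timestamped classroom transcripts together with
    Bluetooth RSSI proximity logs into dyadic (sender-receiver) linguistic
    indices of a focal child's language environment: utterance, word,
    auxiliary-verb, conjunction, verb, adjective, unique-word and rare-word
    counts, mean length of utterance, type-token ratio, conversational turns
    and speech duration. Includes proximity-interval construction from RSSI
    readings, sync-tone detection, punctuation-based re-segmentation of
    utterances into C-unit approximations, a direct-talk temporal selector,
    and an accuracy-evaluation protocol comparing predicted against reference
    transcripts over six-minute windows (median absolute relative error,
    Pearson correlation, median word error rate, boundary agreement,
    convergence diagnostics). A synthetic classroom-corpus generator with a
    controlled corruption model makes every stage testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    xml2
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
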