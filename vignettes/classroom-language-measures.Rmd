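---
title: "Measuring classroom language environments from diarized transcripts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring classroom language environments from diarized transcripts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(classtalk)
```

## The measurement problem

Young children's language development tracks the talk they hear and produce,
but quantifying a preschooler's language environment has traditionally meant
hours of manual transcription per hour of audio. classtalk implements the
downstream half of a wearable-sensor measurement pipeline: given diarized,
timestamped utterances (from human coders or an ASR system) and a log of
pairwise Bluetooth RSSI readings between participants, it computes thirteen
linguistic indices of each dyadic (sender → receiver) interaction around a
focal child, and provides the accuracy protocol for validating an
automatically produced transcript against a manually produced reference.

The pipeline stages mirror the sensing workflow:

1. **Proximity gating.** Speech only counts toward a dyad while the pair is
   physically close. RSSI readings at or above −74 dB (≈ 1.5 m separation)
   are kept and merged into per-pair time intervals
   (`build_proximity_intervals()`); each utterance is then matched by onset
   to the intervals of its speaker (`attach_proximity()`). A
   synchronization-tone detector (`detect_sync_tone()`) aligns audio clocks.
2. **Re-segmentation.** Running speech is split into C-unit approximations —
   one independent clause plus its dependent material — using sentence-final
   punctuation, and inter-word pauses when word timings exist
   (`resegment()`).
3. **Direct-talk selection.** Teacher/peer talk is attributed to the focal
   child when its onset falls within 3 s of the child's own speech
   (`select_direct_talk()`).
4. **Indices.** Per dyad: utterances (UT), words (WD), auxiliary verbs (AV),
   coordinating (CC) and subordinating (SC) conjunctions, main verbs (VB),
   adjectives (AJ), unique words (UW), rare words (RW), mean length of
   utterance (MLU = WD/UT), type-token ratio (TTR = UW/WD), conversational
   turns (CT) and speech duration (SD) (`dyadic_table()`).

## The accuracy protocol

Reference and predicted transcripts are tiled into consecutive six-minute
windows anchored at time zero (`eval_windows()`). For window $j$ and index
$X$ the absolute relative error is

$$E_{X,j} = \frac{|X_{r,j} - X_{p,j}|}{X_{r,j}} \times 100,$$

and the per-index summary is the **median** of the $E_{X,j}$ — error
distributions from recognizers are heavily skewed, and a median neither lets
one catastrophic window dominate nor lets under- and over-estimates cancel.
`summarize_accuracy()` also reports the Pearson correlation between the
window vectors $X_p$ and $X_r$ with its two-sided p-value (a scale-blind
complement: a system can be biased yet track change faithfully), per-window
sums for both transcripts, and a Kolmogorov–Smirnov normality diagnostic of
the errors (recorded, not acted on). Word-level fidelity is the word error
rate $\mathrm{WER} = (S + D + I)/N_{\mathrm{ref}} \times 100$ from a
uniform-cost minimum-edit-distance alignment, summarised as the median over
windows (`wer_windows()`, `median_wer()`). Timestamp fidelity is boundary
agreement: the share of reference utterances whose greedily paired
same-speaker counterpart lies within 250 ms at onset (resp. offset)
(`boundary_agreement()`). `convergence_curve()` tracks the cumulative
statistics across windows so one can judge whether enough data have been
scored.

## Parameters that matter

| parameter | default | unit | rationale |
|---|---|---|---|
| `rssi_threshold` | −74 | dB | operating gate of the proximity hardware, ≈ 1.5 m; applied in dB exactly, no distance model |
| `pause_boundary` | 0.3 | s | minimum inter-word pause that closes an utterance |
| `direct_talk_window` | 3 | s | temporal criterion for talk directed at the focal child |
| `agreement_tolerance` | 0.25 | s | boundary-agreement tolerance between coders/systems |
| `eval_window` | 360 | s | normalises recording duration per accuracy sample; longer windows inflate apparent accuracy |
| `punctuation_boundaries` | `. ? !` | — | commas/ellipses are not boundaries: a C-unit routinely contains comma-joined dependent material |
| `turn_max_gap` | `Inf` | s | no silence cutoff on turn alternations by default; configurable |
| sync tone `k = 6`, sustain 0.1 s, 1000 ± 50 Hz | — | — | detector conventions; only the band-pass principle is fixed |

## Design choices where the design was open

* **Proximity membership is decided at the utterance onset**, not by overlap
  fraction: deterministic, cheap, and robust to boundary jitter. An
  utterance's candidate receivers are the partners of its *speaker* whose
  interval contains the onset — that is what makes a teacher utterance fan
  out to every child in range.
* **Gap bridging at 2 × ping period** tolerates one missed Bluetooth ping
  without fragmenting an interaction; an isolated ping contributes one ping
  period centred on itself.
* **Pause direction.** The segmentation literature's phrasing "a pause
  <0.3 s" is read as *a pause of at least 0.3 s opens a boundary*: splitting
  at every sub-0.3 s gap would sever nearly every word pair. The comparison
  direction is configurable through `segmentation_rule()`.
* **Proportional timestamps.** When word timings are absent, split pieces
  partition the parent span proportionally to token counts — duration is
  conserved exactly and the rule is deterministic.
* **Unique words are case-folded surface forms**, no lemmatization; MLU is
  word-based (words per utterance), not morpheme-based.
* **Rare words are counted as distinct rare forms** (type level): a form is
  rare when it is outside the inflected closure of the common-word list and
  is neither a proper name nor a number. Type-level counting keeps RW ≤ UW,
  consistent with UW's type convention. The closure over-generates
  deliberately (plain affixing plus consonant doubling, e-drop and y→i
  rules); an implausible generated form can only make a word count as
  common, never as rare. The 10,000-word list itself is a pluggable input; a
  small synthetic stand-in ships for examples.
* **Direct talk measures from the nearest focal utterance boundary** (onset
  or offset), the permissive reading of "within 3 s".
* **Windows are half-open** `[start, end)` anchored at zero; an onset
  exactly on a boundary belongs to the later window; the final partial
  window is kept and flagged rather than dropped — peer speech is scarce and
  discarding the tail would throw away a meaningful share of it.
* **Zero and missing references.** `E_{X,j}` is undefined when the reference
  is zero; such windows are excluded per index (and counted) rather than
  scored as 0 or 100, and MLU/TTR with empty denominators are missing, never
  zero — either convention would silently bias the error median toward or
  away from the system. Correlations need at least three usable windows and
  nonzero variance on both sides; indices failing that are flagged
  `insufficient`, `zero_variance` or `not_evaluable` instead of carrying a
  fabricated statistic.
* **Even-count medians** are the mean of the central pair. **WER alignment
  ties** are broken preferring substitution over insertion over deletion —
  this selects among cost-equal paths and never changes the WER value.

## The synthetic test bench

`generate_corpus()` draws a classroom session with known ground truth:
per-speaker utterance onsets from a renewal process with exponential gaps
(so counts over a duration follow the Poisson law the tests check); text
from part-of-speech templates whose closed-class slots (auxiliaries,
conjunctions) use the real function-word lexicons and whose open-class slots
draw from a Zipfian pseudo-word vocabulary (default 1,000 forms, exponent
1.0). Templates — not a language model — mean every token's part of speech
is known *by construction*, so index arithmetic is tested independently of
tagger quality; a tagger-in-the-loop mode simply omits the ground-truth
tags. Proximity pings are emitted once per second inside scheduled
co-location blocks at RSSI above the gate, with sparse below-gate background
pings elsewhere. The default spec is an hour-long session with one teacher,
a focal child and two peers, with role-specific rates chosen so teacher talk
carries the largest share of speaking time, the child's own talk the next,
and peer talk the least — the ordering of naturalistic direct-talk corpora.

`corrupt_transcript()` emulates recognition error at known rates: per-word
substitution and deletion, per-word insertion, Gaussian boundary jitter, and
teacher/peer label confusion. Because the rates are known, recovery is
checkable: at 20% deletion the measured WER must sit inside the 99% binomial
interval of 0.2 at the relevant word count, and at zero corruption the whole
evaluation must return a perfect report.

What passing these tests does **not** show: the generator has no acoustic
noise, no overlapping speech, no disfluencies, no code-switching, no real
lexicon beyond the function words — so the tests validate the *measurement
arithmetic and plumbing*, not recognition quality on real classrooms. Tagger
accuracy on real text is likewise out of scope: the bundled rule tagger is a
fallback covering closed classes exactly and open classes heuristically, and
production use should adapt a statistical tagger through the
`tag_tokens()` interface.

## Numerical conventions and problem sizes

Timestamps are seconds at 1 ms resolution (the 250 ms and 0.3 s thresholds
need sub-second precision). The edit-distance core is compiled; the
user-facing WER uses a two-row dynamic program so corpus-length token
streams do not exhaust memory. The test suite exercises: interval
construction against a brute-force scan on randomized event lists; WER
against an exhaustive character-level oracle over *all* token-sequence pairs
of length ≤ 6 on a three-symbol alphabet (1,093 sequences, ~1.2 M pairs);
index vectors against independent recounts on 1,000 randomized five-utterance
fixtures; and parameter recovery on synthetic sessions of roughly 12,000
words (hour-long default spec) with a 73,000-token session for the Zipf
rank-frequency check, where the slope is fitted on ranks with at least five
observations because the sampled tail of a finite corpus is count noise.

## Limitations

Diarization and recognition themselves sit upstream, behind the transcript
input boundary. Only the temporal criterion of direct-talk coding is
automated; proximity gating approximates the physical criterion, and
topical relatedness is a human judgment. RSSI is a coarse distance proxy and
the gate is applied in dB with no propagation model. Conversational turns
use simple adjacency in the dyad's merged stream; overlapping speech is not
resolved.
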