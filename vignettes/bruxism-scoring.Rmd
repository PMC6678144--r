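---
title: "Scoring sleep bruxism from portable EMG/ECG nights"
author: "bruxscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring sleep bruxism from portable EMG/ECG nights}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bruxscore)
```

## The scoring problem

Sleep bruxism (SB) is masticatory muscle activity during sleep, rhythmic
(phasic, the grinding-type rhythmic masticatory muscle activity, RMMA) or
non-rhythmic (tonic clenching). Portable home devices screen for it with two
surface-EMG electrodes over the masseters plus a single ECG lead, exploiting
the physiology of micro-arousals: most true SB episodes ride on a brief
autonomic activation whose cardiac signature — a transient heart-rate surge —
begins a few seconds *before* the jaw-muscle burst. Requiring that signature
separates genuine episodes from the many other overnight masseter
contractions (swallowing, position shifts, isolated clenches).

`bruxscore` implements that scoring chain end to end:

1. **Calibration.** The night opens with three maximal voluntary clenches
   (MVC) of 3 s separated by 10 s of rest. The greatest clench amplitude is
   the normalization constant: all EMG amplitudes become percent of MVC, so
   results are invariant to electrode gain.
2. **Burst detection.** A moving-RMS envelope (50 ms window) is thresholded
   at 10 %MVC with hysteresis (the burst closes at 8 %MVC); bursts shorter
   than 0.25 s are discarded.
3. **Events.** Bursts separated by less than 3 s of quiescence group into one
   masticatory event, classified *tonic* (some burst strictly longer than
   2 s), *phasic* (three or more bursts of 0.25–2 s, bounds inclusive),
   *mixed* (both), or *unclassified* (neither; excluded from counts by
   default).
4. **Cardiac coupling.** Beat-to-beat heart rate comes from R-peak detection;
   a surge is a rise of at least 20% over the trailing 10-beat baseline. An
   event becomes an SB **episode** when a surge onset precedes the event
   onset by 1–5 s (closed interval).
5. **Index and diagnosis.** The bruxism index is episodes per hour of the
   scored night (examination length minus the calibration span). A subject
   is screen-positive when the index is strictly greater than 2/h.
6. **Cohort statistics.** Screening sensitivity/specificity against a
   clinical reference, group descriptives with coefficient of variation, a
   tie-corrected Mann-Whitney z, Spearman rank correlations (with the
   t conversion `t = rho * sqrt((n-2)/(1-rho^2))`, df = n − 2) and the 2×2
   chi-square.

## The parameters that matter

All numeric rules live in one `ScoringConfig` object:

```{r}
scoringConfig()
```

| parameter | default | why |
|---|---|---|
| `burstThreshold` | 10 %MVC | the published burst criterion |
| `burstMinDur` | 0.25 s | lower bound of a phasic burst |
| `burstOffsetHysteresis` | 0.8 | stops threshold-grazing chatter from splitting one burst |
| `eventGap` | 3 s | conventional RMMA episode separation; the source protocol does not state one |
| `tonicMinDur` | 2 s (strict >) | "more than 2 s": a burst of exactly 2.000 s is phasic-eligible, not tonic |
| `phasicBurstBounds` | [0.25, 2] s inclusive | the stated phasic burst range |
| `hrRise` | 0.20 | the 20% heart-rate criterion |
| `hrBaselineBeats` | 10 | beat-domain trailing baseline; frozen while a surge is open |
| `lagWindow` | [1, 5] s closed | "immediately followed (1–5 s)", read as surge onset first |
| `diagnosticCutoff` | 2/h (strict >) | "more than 2 episodes per hour" |
| `emgPooling` | union | most sensitive defensible bilateral combination |

Design choices that were genuinely open, and how they were settled:

* **Bilateral pooling.** The device registers both masseters but no published
  rule says how sides combine. Bursts are detected per channel on that
  channel's own %MVC scale (clench asymmetry is physiological, so each side
  gets its own MVC), then pooled as a union with overlapping cross-channel
  bursts merged. `left`/`right` modes are available for sensitivity checks.
* **Direction of the 1–5 s interval.** The micro-arousal cascade puts
  cardiac activation first, so the EMG event onset must fall 1–5 s *after*
  the surge onset. The comparison is onset-to-onset.
* **Surge onset definition.** The reported onset is the start of the first
  RR interval whose rate clears the threshold — the beat at which the
  acceleration begins. Reporting the closing beat instead would bias every
  measured lag short by about one beat and silently push true lags of ~1 s
  out of the window.
* **Baseline definition.** A trailing mean of 10 beat-to-beat rates, frozen
  while a surge is open. Beat-domain baselining avoids interpolation
  artifacts; whether the original device uses beats or time windows is not
  public, so this is a documented decision, not a fact about the device.
* **Coupling cardinality.** One surge licenses at most one episode (the
  first qualifying event), and each event couples at most once. A switch
  (`oneToOneCoupling`) relaxes this.
* **Index denominator.** Episodes per hour of the *scored* night: the
  calibration clenches are deliberate maximal contractions and must not be
  scored, and true sleep length is unknowable without EEG. The examination
  length is still reported separately.
* **Unclassified activity.** One or two short bursts that are neither tonic
  nor phasic are excluded from contraction counts and episode candidacy by
  default (`countUnclassified` flips this): the tonic/phasic/mixed taxonomy
  is treated as exhaustive over countable contractions.

## What the synthetic generator emulates

There is no public reference dataset for this device class, so the package
ships a generator whose defaults are the study conditions the scoring rules
were built for: a 7 h night (25200 s), the three-clench calibration
prologue, a 59.6 bpm baseline heart rate, six coupled episodes per hour with
a tonic-heavy type mix (60/34/6), four uncoupled confounder contractions and
four surge-only micro-arousals per hour, +30% heart-rate surges, and burst
amplitudes at 40% of MVC with ±20% jitter — comfortably above the 10%
threshold, as real masseter events are.

```{r}
generatorConfig()
```

Mechanics worth knowing when reading recovery results:

* **EMG synthesis.** Band-limited (80–240 Hz) noise whose short-time RMS is
  stabilized to one, amplitude-modulated by the planted envelope (50 ms
  onset/offset ramps). Stabilization makes the planted envelope the
  *realized* envelope, so amplitude ground truth is sharp; real EMG has
  heavier amplitude fluctuation, which the 10%-vs-40% margin absorbs.
* **ECG synthesis.** A 40 ms biphasic QRS template with a dominant R lobe on
  an RR sequence with ~0.8% multiplicative jitter. Surges step to
  `(1 + surgeMagnitude) x baseline`, hold ~1 s and decay with a ~1.5 s time
  constant — back to baseline well inside the 10-beat window before the next
  structure can begin.
* **Beat-aligned surge onsets.** Autonomic input takes effect at the next
  sinus beat, so a planted surge is realized at a beat boundary and the
  truth records the realized onset and lag. Planted lags are kept strictly
  inside [1.2, 4.9] s so that beat quantization cannot push a true lag
  across the strict 1–5 s window boundary; without this, boundary losses
  would masquerade as scorer errors.
* **Separation.** Planted structures (events, confounders, surge-only
  arousals) are drawn from independent Poisson processes and thinned to
  15 s of quiescence between the end of one structure and the start of the
  next. Event spans reach ~9 s, so a raw onset-to-onset gap near 10 s would
  let two planted events close within the 3 s grouping gap and merge,
  corrupting planted counts. The 1–5 s exclusion zone around surges falls
  out of the same rule, so confounders never acquire an accidental cardiac
  signature.

What the generator does **not** emulate: sleep-stage architecture, EEG,
apnoea, body-movement artifacts, electrode detachment, heart-rate
variability beyond mild jitter, or sub-maximal calibration effort. Passing
recovery tests therefore demonstrate that the scoring rules are implemented
correctly and are mutually consistent — not that the pipeline is robust to
every failure mode of real home recordings. The calibration quality ratio
(largest/smallest clench peak) is reported per subject precisely because
careless clenching is the known weak point of unsupervised use.

## Numerical choices

* Envelope: centered moving RMS over 50 ms — long enough to suppress the
  80–240 Hz carrier, short enough to resolve 0.25 s bursts with ≤20% edge
  smearing. Edges use the available part of the window.
* R peaks: band-emphasis (5–15 Hz), differentiate, square (polarity
  invariant), 150 ms integration, adaptive signal/noise thresholds with a
  250 ms refractory period, then refinement to the sharpest band-passed
  deflection within ±100 ms.
* MVC search: threshold at five times the median envelope of the first 60 s
  (the protocol needs 29 s; the slack absorbs patient delay), candidate
  segments of 1–6 s, the three largest peaks win. Fewer than three clenches
  degrades with a warning; none is a hard error.
* Ties: midranks everywhere; the Mann-Whitney variance carries the tie
  correction (index data are rounded to 0.1 in practice). No continuity
  correction, matching the published z values. Chi-square is Pearson
  without continuity correction, df = 1.
* Degenerate inputs: identical pooled samples give z = 0, p = 1 by
  convention; |rho| = 1 reports an infinite t with p = 0; an undefined
  screening margin (no positives, or no negatives) reports NA rather than a
  number.
* α = 0.05 two-sided throughout; no multiple-testing correction is applied,
  mirroring the original analysis — a known limitation, not an endorsement.

## Problem sizes used by the shipped checks

Unit and property tests run on 10–20 min synthetic nights with elevated
event rates, which exercise every rule at a few seconds per test. The
recovery suite regresses recovered on planted index over 20 full-length
(7 h) nights spanning 0–10 episodes/h with confounders and surge-only
arousals at 4/h each, and pools episode-level precision and recall across
them; the same computation is what `scripts/acceptance.R` reports. The
Mann-Whitney enumeration oracle covers all group sizes up to 8 per side,
where full enumeration (≤ 12870 splits) is exact and fast.

## Known limitations

* EDF support is deliberately minimal: plain EDF, 16-bit, one-second
  records, no EDF+ annotations, integer sampling rates. The CSV dialect
  (single shared rate) exists for diffable fixtures, not for real nights.
* The scorer assumes the calibration prologue is present and first; there is
  no re-calibration from sleep-phase maxima.
* Sensitivity/specificity are reported without confidence intervals, and the
  >2/h cut-off is applied as published; neither is re-optimized here.
* Heart-rate processing identifies surges only; it is not an ECG diagnostic
  and handles neither arrhythmia nor ectopy.

## A worked example

```{r, eval = FALSE}
g <- generateRecording(generatorConfig(seed = 1))
s <- summarizeSubject(g$recording)
s
episodeRecovery(episodes(s), g$truth)
```
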