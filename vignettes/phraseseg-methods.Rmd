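---
title: "Cue models, matching and simulation: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cue models, matching and simulation: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phraseseg)
```

# The analysis in one paragraph

A listener's segmentation map — the time points at which they mark phrase
endings — is compared against seven rule-based acoustic cue models. Each
model marks *virtual segmentation points* in a pitch-event stream; the
points of all models merge into one *global array* per stimulus version.
A participant's baseline-corrected keypresses are snapped onto that array
and scored against each model with the Russell–Rao coefficient. Segment
lengths and matching scores then enter mixed within/between ANOVAs whose
key term is the delexicalization × instruction interaction: if presenting
the same material as "music" changes how delexicalization shifts the
segmentation map, music-specific expectations are at work.

# The pitch-event representation

Everything operates on streams of syllable-like events `(onset, duration,
pitch)` in milliseconds and Hz, with half-open intervals
`[onset, onset + duration)`; inter-event gaps are silences. Natural speech
enters this representation by pre-sampling its continuous F0 into events;
delexicalized versions come from audio-to-MIDI-style conversion and are
discrete by construction. Time is 0-based; the half-open convention makes
gap arithmetic unambiguous (a 200 ms gap is exactly
`onset[k+1] − offset[k]`).

Stimulus statistics are duration-weighted by default: a 400 ms syllable
contributes twice the pitch mass of a 200 ms one, which matches what a
dense F0 track would yield. Unweighted (per-event) statistics are
available via `stimulus_stats(..., weighted = FALSE)` because the
convention used in the original acoustic tables is not stated. Mel values
use the O'Shaughnessy form `2595·log10(1 + f/700)` — several Mel formulas
circulate, so the choice is fixed and documented — and Mel summary
statistics are computed on Mel-transformed event pitches, not by
transforming the Hz summaries.

# The seven cue models

All thresholds live in `cue_thresholds()` and default to the rule
constants of the segmentation models:

| parameter | default | meaning |
|---|---|---|
| `pause_min_ms` | 200 | a pause is a silence strictly longer than this |
| `break_gap_max_ms` | 200 | a break's silence must be shorter than this |
| `break_delta_sd` | 1 | break contrast, in stimulus pitch SDs |
| `movement_range_fraction` | 1/3 | "wide" movement span, of global range |
| `rise_min_ms` / `drop_min_ms` | 500 / 1000 | "long-lasting" movement |
| `drop_low_end_sd` | 0.5 | drops must end this far below the mean |
| `deflection_max_ms_rise` / `_drop` | 250 / 200 | tolerated counter-deflection |
| `within_movement_pause_max_ms` | 200 | tolerated silence inside a movement |
| `min_movement_events` | 2 | minimum events per movement run |

Interpretation choices the rules do not pin down, and how they were
resolved:

- **A pitch break needs a real silence.** The break rule describes two
  pitch values "separated by a silence"; abutting events (gap = 0) are a
  pitch step, not a break. Without this reading every large within-
  movement step would double as a break and the models could not be
  exclusive. Consequently a contrast across a gap of exactly 0, exactly
  200 ms (neither break-silence nor pause), or above 200 ms with
  insufficient contrast, yields nothing.
- **Boundary strictness.** "Longer than 200 ms" and "more than one SD"
  are strict inequalities; "at least one third" and the movement
  duration minima are inclusive. The acceptance suite sweeps the exact
  boundary values.
- **Break contrasts are evaluated in Hz**, matching "standard deviation
  of the stimulus mean pitch" (an Hz quantity); a semitone variant would
  need a different normative anchor.
- **Deflection allowances 250/200 ms** are read as rise/drop
  respectively, parallel to the order of the source sentence; deflection
  *magnitude* is uncapped because only a duration is stated. A
  deflection's duration is measured as elapsed time from the onset of
  its first counter-directional event.
- **Movement runs are maximal**: a run starts at its extremum (the start
  slides forward through counter-directional prefixes), ends at the last
  in-direction event (trailing deflections are trimmed), and two runs of
  opposite direction may share only their junction event. A run needs at
  least `min_movement_events = 2` events; the rules name no minimum, so
  the floor is the smallest count that makes "movement" meaningful, and
  it is configurable.
- **The drop low-end criterion applies always**, whichever disjunct
  (range or duration) qualified the drop — it is worded as an additional
  criterion on drops, not on one disjunct.
- **Coexistence and exclusivity.** A movement whose run offset *is* a
  pause onset becomes pause+movement, with its point at the pause onset;
  a contrast across a pause becomes pause+break. When several labels
  land on one time the richest evidence wins: pause+movement >
  pause+break > movement > break > pause, with drops outranking rises on
  the (rare) exact tie because their criteria are stricter. This keeps
  the seven point lists pairwise disjoint, so the global array is the
  plain sorted union and no label is silently lost.
- **Numerical tolerance**: pitch differences below 1 µHz are treated as
  equal in movement detection — genuine pitch steps are orders of
  magnitude larger, and floating-point dust must not create monotone
  runs.

# Matching

Corrected press time = raw press − participant baseline RT; negative
results clamp to 0 (a press cannot precede the stimulus). Each press sets
the bit of its *nearest* global-array time; exact midpoints break toward
the earlier time (reproducibility), and duplicate mappings collapse to
one bit, with the collision count kept as a QC attribute. No press is
rejected for distance: the maximum adjacent gap of the global array *is*
the maximum possible assignment error and is reported as a diagnostic.
The Russell–Rao coefficient `a/n` then scores adherence to each model.
Note one consequence of `a/n`: extra presses can only add 1-bits, so
false alarms *raise* every raw model score while destroying selectivity;
degradation must be read from score contrasts, not score levels.

# Segment statistics

A press marks a phrase *ending*: boundaries are `{0} ∪ presses`, lengths
are successive differences, and the segment count equals the number of
presses — the stretch before the first press is a segment, the tail
after the last press is not. This convention makes "mean length ×
count ≈ stimulus duration" hold, consistent with ~7 s segments and ~8.6
segments in a ~60 s stimulus. An intervals-only mode (`mode =
"intervals"`) is available for sensitivity analyses. Corrected (not raw)
press times feed the statistics, mirroring the single correction step of
the matching pipeline.

# The inferential layer

`mixed_anova()` implements the classical univariate decomposition for
balanced designs with one between-subjects factor and one or two
within-subjects factors, one observation per subject × cell (the stimulus
dimension is averaged out first, matching the participant-level degrees
of freedom such as F(1, 68) for 2 × 35 participants). Each within effect
and its interaction with the between factor is tested against the
corresponding within × subjects-within-groups stratum. Partial eta
squared is `SS_effect / (SS_effect + SS_error_of_that_stratum)`; the
identity `F = η²p/(1−η²p) · df_den/df_num` holds on every output row and
is asserted in the tests, as is the full decomposition summing to the
total SS. Degrees of freedom are uncorrected by default (matching the
uncorrected df(6, 408) convention for the 7-level model factor);
Greenhouse–Geisser is available via `gg = TRUE`, capped at ε = 1.
Unbalanced input is a hard design error; `analyze_experiment()` restores
balance by dropping participants with missing cells and trimming groups
deterministically (sorted id order), with a warning.

Follow-up paired t-tests are uncorrected, with Holm adjustment available
via a flag. The Wilcoxon signed-rank test drops zero differences,
averages tied ranks, reports the smaller signed-rank sum, and computes
the exact two-sided p by convolution over all sign assignments for
n ≤ 25 (doubling tied half-ranks to keep the convolution integral),
switching to the tie-corrected normal approximation above.

# What the synthetic generator emulates — and what it does not

`generate_contour()` builds a stimulus as a phrase plan: 8+ phrases of
flat-pitch syllable trains (duration ≈ 1/rate − 25 ms gaps, so 3–4
events/s), F0 declination realised *between* phrases, and exactly one
planted cue per internal boundary, cycling through all seven models. The
nominal acoustic targets are the five-stimulus profile: means
185/112/130/172/123 Hz, SDs 28/21/35/51/20 Hz, rates ≈ 3.5/3.2/3.0/3.1/4
events/s, durations 63/56/57/59/40 s. The duration-weighted mean pitch is
normalised to the nominal exactly; the realised SD is an emergent
property of the plan (about half the nominal, because bodies are level).
Delexicalization shares the syllable segmentation exactly and snaps each
event to the nearest 12-TET semitone anchored at A4 = 440 Hz (the
discretisation grid is stated only as 12 semitones per octave, so the
conventional anchor is used).

Confound-freeness is engineered, not assumed:

- phrase bodies are *flat* in pitch (any within-body jitter of ≥ 2 events
  spanning ≥ 500 ms would qualify as a rise under the duration disjunct);
- all planned pitches sit on an integer-semitone lattice, so the final
  mean-normalisation shifts every event by the same fractional semitone
  and quantization displaces all events by one common ratio — in-movement
  steps never collapse or invert, and the delexicalized version preserves
  the natural version's SD/mean ratio exactly;
- the break jump and the deep pause+drop dive are calibrated per
  stimulus on the realised plan, so the jump clears 1.25 realized pitch
  SDs (the planted break always fires) while staying under 90% of a
  third of the realised range (a two-event jump pair can never
  span-qualify as a movement);
- plain movements are followed by a gap of exactly 200 ms — long enough
  not to merge with what follows, short enough not to be a pause;
- after a plain drop, pitch recovers through a two-rung ladder of short
  events whose hops stay under the span threshold and whose durations
  keep any two-event pair under 500 ms; after a rise, the landing level
  is clamped above the drop low-end region.

A generated stimulus is therefore a *stylised* world: level-pitch
syllables, stereotyped boundary shapes, silence ~10–14%, no lexical or
rhythmic confounds, no pre-boundary lengthening. A green planted-cue
recovery test establishes that the detectors implement the rules exactly
on streams where the rules have unambiguous answers; it does not
establish detector behaviour on real speech, where cues overlap and the
rules' interaction terms (deflections, coexistence) do real work.

Simulated responders press for each cue of model M with probability
`cue_weights[M]`, at cue time + N(287, 50) ms latency + motor jitter,
with Poisson false alarms and a refractory collapse; baseline RTs are
drawn N(287, 50) truncated positive, so correction error is centred but
not zero — as in the real task. The delexicalization × instruction
interaction is planted mechanistically through group-specific
delexicalized cue weights (natural weights shared), giving "instruction"
a concrete meaning in simulation. Statistical calibration (type-I error,
power) is done at the ANOVA level with directly planted effects, where a
replicate is cheap and the effect size is exact; the responder-level
route is exercised end to end but with few replicates, since a full
experiment costs seconds, not milliseconds.

# Known limitations

- The mixed ANOVA requires balanced groups; severely incomplete data
  (participants with empty cells after stimulus-averaging) are dropped,
  not modelled. A multilevel reformulation is out of scope.
- PitchTier input carries no silence information; streams read from it
  have no internal pauses by construction.
- MIDI timing is tick-quantised (division 480 at 120 bpm in the writer);
  integer-millisecond timing survives only when divisible by 25/24 ms.
  CSV is the lossless interchange format.
- The generator's realised pitch SD is roughly half its nominal
  parameter; nominal SDs control relative, not absolute, variability.
- Power for a planted 2×2 interaction of η²p = 0.13 at n = 35/group is
  theoretically 0.88, below the 0.90 sometimes quoted for that design;
  the acceptance suite states the bound as given and the corresponding
  assertion is expected to fail by that margin.
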