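---
title: "Scoring gated vocal emotion: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring gated vocal emotion: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emogate)
```

## The experimental paradigm

In an auditory gating study, listeners judge truncated excerpts ("gates") of
vocal emotion expressions that grow in duration over the session — here
200, 400, 500 and 600 ms from acoustic onset, then the full expression
(G200, G400, G500, G600, GFULL). Stimuli are nonverbal vocalizations
(growls, screams, sobs, laughter, pleasure sounds) and emotionally inflected
pseudo-utterances in three languages, judged by two listener groups for whom
each language is native, second (L2-English) or foreign. Each trial is a
five-alternative forced choice (anger, happiness, fear, sadness, neutral)
followed by a 1–7 confidence rating. No neutral stimuli are presented; the
neutral option exists because brief emotional voices are frequently heard as
neutral.

The pipeline computes two dependent measures from such data:

* **Accuracy** — Wagner's unbiased hit rate per participant, emotion, gate
  and condition;
* **Latency** — the emotion identification point (EIP) of each
  participant × item, i.e. the earliest gate from which the response is the
  target and never changes again.

## Unbiased hit rates

For a stimulus emotion with target label $t$ inside one stratum, let $A$ be
the number of target responses given to that emotion's stimuli, $B$ the
number of its presentations, and $C$ the total number of times the
responder used label $t$ anywhere in the stratum. Then

$$H_u = \frac{A^2}{B\,C} = \underbrace{\frac{A}{B}}_{\text{hit rate}}
\times \underbrace{\frac{A}{C}}_{\text{precision}} .$$

$H_u$ lies in $[0, 1]$, equals 1 only for a perfect responder
($A = B = C$), and is invariant to duplicating every record — properties the
test suite checks on randomly generated confusion matrices. When the target
label is never used ($A = C = 0$), $H_u$ is 0 by convention. We export raw
$H_u$ without an arcsine transform.

Two conventions deserve note. First, the two positive vocalization subtypes
(happiness-amusement, happiness-pleasure) are separate stimulus rows but
share the single "happiness" response label, because the response screen
offered only five options; correctness for both means responding
"happiness". Second, the bias term $C$ is counted over the whole stratum
(participant × event condition × gate), since a per-emotion-block count is
not recoverable from a forced-choice session; `hu_table()` fixes this
convention and `confusion_matrix()`/`hu_score()` let a user apply any other
stratification.

## Emotion identification points

`identify_point()` finds the earliest gate $g$ such that the response at $g$
*and at every longer gate* equals the target. Any deviation — a different
emotion or "neutral" — breaks stability; both break types are treated
identically. Items never stably identified by GFULL are scored as **errors**
and excluded from latency means. The latency of an identification is the
gate duration in ms, with a GFULL identification mapped to the item's own
full duration (stimuli range roughly 0.7–2.9 s). A response sequence missing
any gate is reported as **incomplete** and excluded from both frequencies
and error counts, rather than silently inflating either.

The implementation is a vectorized suffix-scan; the test suite proves it
equivalent to a brute-force oracle on all $5^5 = 3125$ possible five-gate
response patterns, and checks a monotonicity property (correcting any wrong
response can never increase the EIP).

`gate_frequency_table()` reproduces the published tabulation layout:
identification counts per gate, cumulative percents, error fraction, and
mean (SD) latency. Percents are rounded half-up; a few published cells do
not follow any single rounding rule, so tests anchor only on rows whose
printed percents are arithmetically consistent with their printed counts.
`eip_summary()` excludes happiness-pleasure by default (those stimuli are
labelled neutral about half the time and are dropped from latency models)
while the frequency table retains it.

## The synthetic-listener generator

Raw human data live in an external repository; the package instead ships a
generative model that emulates the dataset's *structure* so every stage is
testable and parameter recovery can be studied. The default configuration
(`default_config()`) reproduces the design exactly: 2 groups × 25
participants; 10 vocalizations for each of anger, fear, sadness,
happiness-amusement and happiness-pleasure (50 items, durations uniform in
715–2376 ms); 3 languages × 4 emotions × 12 pseudo-utterances (144 items,
834–2900 ms); 5 gates. That yields 250 EIP observations per vocal
emotion/group and 300 per prosody emotion/group.

Each draw follows, in order:

1. with probability `lapse`, a uniform random label (all 5);
2. otherwise, if the previous gate's response was the target, it is repeated
   with probability `stickiness`;
3. otherwise the target is given with probability
   $p(d) = \mathrm{logit}^{-1}\!\big(k\,(\log d - \log t_{50}^{\mathrm{eff}})\big)$,
   where $d$ is the playable duration;
4. otherwise the remaining mass goes to "neutral" with weight
   `neutral_bias` $\cdot\, e^{-d/\tau}$ and uniformly to the three
   non-target emotions.

The psychometric curve lives on log-duration (Weber-like duration
perception; it also keeps $p(d)$ well-behaved across the wide 0.2–2.9 s
range). `slope = Inf` is the step-listener limit used in tests.
$t_{50}^{\mathrm{eff}} = t_{50}\exp(u_p + u_i)$ with independent normal
participant and item effects on the log scale (SDs 0.15 and 0.2 — modest
individual differences, somewhat larger item heterogeneity, a typical
magnitude for psychophysical thresholds). The neutral bias decays with
$\tau = 600$ ms, emulating the observed concentration of neutral labels at
the shortest gates. Confidence ratings are generated as
$1 + 6\,p(d)$ plus noise, clamped to 1–7, so confidence grows with exposure.

**Stickiness is a modeling invention.** The paradigm's stability criterion
is a *scoring* rule; the generative literature offers no account of response
perseveration in gating tasks. A single post-target repetition probability
is the simplest mechanism that exercises the EIP rule; non-target
perseveration is deliberately omitted.

Default condition thresholds (t50: anger 250 ms, amusement 350, sadness
400, fear 450 ms for vocalizations; 600–1100 ms for prosody with happiness
slowest; happiness-pleasure 2200 ms with high neutral bias) were chosen once
to emulate the qualitative ordering reported across the gating literature —
vocalizations stabilize within ~300–500 ms, prosody later, positive
emotions last. They are design conditions of the synthetic cohort, not
estimates fitted to any dataset, and the pipeline's correctness tests never
depend on them.

All randomness flows from the single mandatory seed through one stream
consumed in a fixed order (gate-major over a sorted participant × item
grid), so equal seeds give byte-identical datasets; this is simpler and
faster than deriving per-participant substreams and gives the same
reproducibility guarantee.

### What passing tests do and do not show

The generator emulates design counts, psychometric growth, neutral bias,
response stability and random effects. It does **not** emulate acoustic
similarity structure between emotions (confusions are uniform over
non-target emotions), fatigue or block-order effects, cultural in-group
advantages, or item-level confusability. Green tests therefore certify the
*scoring machinery* — not that any substantive conclusion about human
listeners would replicate.

## Gate construction from audio

`cut_segment()` takes the initial $\mathrm{round}(d \cdot r / 1000)$ samples
from acoustic onset (round half-up) and applies a linear fade to zero over
the final 5 ms by default — an automated, reproducible stand-in for manual
de-clicking of hard cuts. A cut at or beyond the full length returns the
audio untouched, making the operation idempotent and the full gate the
unedited sound. `normalize_peak()` equates digital peak level (default
−3 dBFS); a published playback level in dB SPL is a hardware property that
a file cannot carry, so peak standardization is the file-level counterpart.
Blocks ascend strictly in gate duration, with speech and vocalization
sub-blocks never intermixed and languages fully intermixed within speech;
the speech/vocalization order is a per-participant counterbalancing policy
passed by the caller, and within-block order is a seeded permutation.

## Numerical and interface choices

* Integer percents use round-half-up (`round_half_up()`), matching the
  published tabulations; base R's half-to-even would disagree on `.5` cells.
* The canonical response table is delimited text with fixed lower-case
  column names; external deposits are bridged by an explicit user-supplied
  column mapping, never by guessing.
* Validation reports violations as data (a tibble) rather than throwing on
  first fault, so a faulty file yields a complete audit.
* The familiarity recoding (native/L2/foreign per group × language) is a
  per-group bijection with an exported inverse; vocalizations carry no
  familiarity level rather than an invented one, since nonverbal events
  form their own condition.
* Mixed-effects modelling (and its Satterthwaite/Tukey machinery) is
  deliberately out of scope: `export_model_table()` writes a long table
  with the column names those model formulas expect (Group, EventType,
  Emotion, Gate, Familiarity, GFullDuration) for lme4/lmerTest/emmeans.
* Bootstrap contrasts resample *participants*, the exchangeable unit under
  a by-subject random-effect structure, not trials.

## Problem sizes

The default cohort is the full study size (48,500 judgments) and simulates
in about a second. The recovery study in `analysis/05_recovery.R` uses a
5-point t50 grid × 3 replicates of full-size cohorts; the acceptance
property in the test suite uses 10 replicates. These sizes give Monte-Carlo
error far below the effects being checked (e.g. the ±0.01 tolerance on the
uniform-guessing rate at n = 50,000 corresponds to >5 SEs).

## Known limitations

* No acoustic analysis or synthesis: the WAV tools segment and normalize;
  they do not generate emotional audio, and loudness-model (LUFS)
  normalization is out of scope.
* The stability rule offers no partial credit and no interpolation between
  gates; latency resolution is the gate grid itself.
* EIP latencies are means over identified items only; with high error rates
  the identified subset is selection-biased, which is why the frequency
  table always reports errors alongside.
* The generator's confusions are symmetric; real emotion confusion
  matrices are not.
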