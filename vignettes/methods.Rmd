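---
title: "Behavioral sleep annotation: model, rules, and simulator design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Behavioral sleep annotation: model, rules, and simulator design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsann)
```

## The scoring model

Infant sleep in the first year is organized into behavioral states that
can be read off without electrodes. `bsann` scores five states per 30-s
epoch — quiet sleep (QS), active sleep (AS), quiet awake (QA), active
awake (AA), and vocalization/crying (V) — from four observational
properties: whether the eyes are open, whether respiration is regular,
whether gross body movements occur, and whether the infant is crying.
The state table is a pure lookup on these properties; crying always wins
(V), and eyes/respiration are the discriminating pair for the remaining
four states.

Two features of real recordings make a pure lookup insufficient, and the
package mirrors the human workflow for both:

* **Unknowns.** Eyes can be invisible (covered by an arm or blanket) and
  respiration can be unreadable (too few clean breath cycles in the
  epoch). Either blocks the lookup, and movement heuristics take over:
  twitches and long quiet intervals vote for sleep, many closely spaced
  bursts or sustained (≥ 5 s) gross movement vote for wake. A tied vote
  carries the previous epoch's state forward — states are held until a
  transition is complete.
* **Non-exclusive movement.** Gross movements occur during AS and
  occasionally during QS (turning over), so movement presence cannot
  hard-exclude the sleep rows; it only splits AA from QA and flags
  ambiguous vectors for the fallback.

### The regularity criterion

Respiration separates QS from AS. Each breath cycle (one upward
zero-crossing to the next, after band-passing to the infant breathing
band, 0.2–2.0 Hz ≙ 12–120 cycles/min) is extrapolated to a per-minute
rate, `60 / duration`. Within an epoch, if the rates of the longest and
shortest cycles differ by **less than 20 cycles/min**, respiration is
regular (QS-like); otherwise irregular (AS-like). Two boundary choices
the criterion itself leaves open are fixed here:

* a range of exactly 20 cycles/min is scored irregular — AS is the more
  common infant sleep state, so ambiguity resolves toward it;
* at least 5 cycles are required for a verdict; fewer yields
  UNDETERMINED and hands the epoch to the movement fallback, the same
  escalation a human uses when the respiration trace is unclear.

Two signal-level guards matter in practice. Breath cycles overlapping a
detected movement burst are discarded before the range computation:
movement is noise in the respiration channel and would otherwise produce
artifact-driven irregular calls. The *extent* of that noise is kept as a
separate feature (fraction of the epoch covered by bursts, default
threshold 0.3), because heavy movement noise is itself evidence for the
active states. Second, a zero-crossing only starts a breath if the
excursion after it reaches 25% of the median breath amplitude
(`amp_gate_frac`); without this gate, sensor noise inside an apneic
pause fragments the pause into spurious mini-cycles, and apneas — which
should appear as one long, slow cycle tripping the rate-range criterion
— would be invisible.

An apnea alone, without a rate-range violation, does not force an
irregular verdict: the criterion is the rate range only. In practice an
apneic pause lengthens a cycle enough to trip the range, so the
distinction is mostly academic; it is noted here because the clinical
description of irregular respiration mentions apneic spells without
quantifying them.

### Movement features

A movement burst is a maximal interval where the smoothed rectified
envelope exceeds `median + 4·mad` of the whole-recording envelope, with
bursts closer than 1 s merged. Bursts are twitches when they are both
brief (≤ 0.5 s) and small (≤ 25% of the 95th-percentile gross
amplitude); everything else is gross. "Goal-directedness" and "fluency"
of movements — cues a human uses on video — are not observable in a
pressure signal and are deliberately not implemented; frequency and
duration statistics subsume them, and this is a known limitation.
Movement-cue thresholds (4 bursts/epoch at < 10 s spacing for wake,
≥ 30 s intervals or stillness for sleep, 5 s sustained duration) are
config defaults; the underlying contrasts are qualitative in the
literature, so the numbers are exposed rather than hidden. Note that the
inter-burst interval is computed within the 30-s epoch, so the "long
intervals" sleep cue effectively fires when an epoch has at most one
burst.

### Context rules

Three rules operate on the epoch sequence:

1. **Minimum duration.** Only changes lasting longer than 3 min (6
   epochs) count as a new state. Exceptions: V episodes of any length,
   and AA/QA/AS runs wholly inside the falling-asleep window (everything
   before the first sustained sleep run), where infants genuinely drift
   between states in under 3 min. The window is not capped: eye
   open/close periods of up to 10 min before sleep onset are documented.
2. **Transition completion.** During ambiguous transitions the current
   state is held; operationally, a neutral movement fallback carries the
   previous state forward, and absorption of short runs defaults
   backward in time.
3. **No wake↔QS adjacency.** QS cannot follow AA or QA and vice versa;
   AS always buffers. This is enforced as *validation* (the advised
   remedy is re-annotation); automatic repair (relabel the shorter run
   of a violating pair to AS; ties take the later run) is opt-in.

Smoothing absorbs short runs shortest-first into the preceding run's
state, falling back to AS when joining the neighbours would create a
forbidden adjacency. Two design choices were genuinely open and are
resolved as follows. A short **AS** run already buffering a forbidden
pair is absorbed backward anyway — the minimum-duration rule takes
precedence, and the resulting adjacency is left for validation to flag;
the alternative (leaving the short AS run in place) would make the
minimum-duration guarantee false. And the falling-asleep window is
recomputed as runs coalesce rather than frozen from the input, which
makes smoothing idempotent by construction: the fixed point is defined
by the same labels the stopping condition reads. Both properties
(minimum run length outside the onset window; idempotence) are asserted
over hundreds of randomized hypnograms in the test suite.

First-epoch defaults: a neutral first epoch is AS, the hub state
adjacent to every other state under the transition rules; a 50/50
eyes-open tie resolves to the previous epoch's judgment, and on the
first epoch to closed. Arbitrary but fixed and documented.

V is implemented as exclusive of the sleep states: in validation data
vocalization occurred only in awake infants, and the three-class merge
pools V into wake.

## The simulator

The simulator is the package's ground-truth source and is first-class,
tested code. It is **semi-Markov**: bout states follow the legal
transition graph (wake ↔ AS ↔ QS, V only from/to AA) and bout durations
are drawn explicitly, because the defining statistics of infant naps —
AS bouts of 20–30 min, AS+QS cycles of 50–60 min, a 3-min minimum
accepted state duration — are duration statements that a memoryless
per-epoch chain cannot produce.

Defaults (all exposed in `sim_config()`): nap length 55 min, matching a
mean observed naptime of ~54 min; truncated-normal bouts with means
AS 26, QS 28, AA 4, QA 1.5, V 2 min (relative SD 0.15, truncation at
±50% of the mean). AS 26 + QS 28 puts the mean cycle at ~54 min, inside
the 50–60 min band. The AS→QS transition weight is 0.85 (0.1 to AA, 0.05
to QA): cycles are QS-dominant enough that, even with naps truncated at
55 min cutting the trailing QS bout short, the mean QS share of sleep
epochs stays in the 30–70% band consistent with N3-heavy daytime lab
naps. Every bout is floored at 1.5 min; since any bout of ≥ 60 s fully
covers at least one 30-s epoch, majority discretization can never delete
a bout, and sampled truth sequences are free of forbidden transitions by
construction.

State-conditional channels:

* **Respiration** is built breath by breath (each cycle one full
  sinusoid, continuous at state boundaries). Regular states: base rate
  35 cycles/min with ±4 jitter (range ≤ 8, safely under the criterion).
  Irregular states: breaths alternate ±13 around the base (range ≈ 26,
  safely over) plus apneic pauses of 3–8 s at 0.1/min. These margins are
  chosen to land clearly on each side of the 20-cycles/min boundary —
  the simulator states its regularity ground truth per epoch, and the
  detector is required to recover it.
* **Movement**: per-epoch Poisson bursts at state rates (gross+twitch
  per min: QS 0.1+0.1, AS 1.0+1.5, QA 0.2, AA 4 sustained, V 3); every
  AA epoch is guaranteed one sustained (5–8 s) burst unless rates are
  zeroed. Gross bursts are also injected into the respiration channel
  (gain 1.5) so the movement-noise pathway is exercised.
* **Eyes/cry/audio**: per-second eyes-open draws (p ≈ 0.9 awake, ≤ 0.03
  asleep) with a 10% unknown mask; cry exactly covers V bouts; the audio
  envelope is elevated during V *and* during 20% of AS epochs (sleep
  sounds), which exercises the rule that V is never scored from audio
  alone.

A single root seed derives one fixed sub-stream per component, so
regenerating one channel never perturbs the others.

### What passing tests do and do not show

The simulator emulates the *structure* the scoring rules key on: state-
conditional regularity with clean margins, state-conditional movement
rates, reliable eyes/cry channels. Real recordings are harsher —
breathing rates drift with age and position, movement artifacts are
broadband and not burst-shaped, the eyes judgment comes from a human
watching video, and states blur during transitions. End-to-end recovery
on simulated naps (three-class kappa ≈ 0.99 at default noise across 20
seeded naps) therefore demonstrates internal consistency of the
pipeline — detector, classifier and rules compose correctly and the
information pathway from each channel to each state works — not expected
field performance. Published behavioral-vs-PSG agreement for the
three-class problem is around 0.74–0.85, and nothing here reproduces
those numbers: the validation recordings are not available, and the
simulator is not a model of their noise.

## Agreement statistics

Cohen's kappa is computed from the confusion matrix as
`(p_o − p_e)/(1 − p_e)`; when both raters are constant and identical
(`p_e = 1`, `p_o = 1`) kappa is 1 by convention. Per-state kappa is
one-vs-rest binarization — the standard construction when a separate
kappa per state is reported — and errors when the state is absent from
both hypnograms (agreement undefined; the same reason validation
studies exclude states with too few epochs). Per-subject kappas are
summarized as mean ± SD.

The paired test is the Wilcoxon signed-rank (comparisons are paired per
infant; the "two-sample" naming that sometimes appears alongside
signed-rank figure legends is documented as a naming conflict, not
resolved by switching tests). The null is exact — full enumeration of
the 2^n sign assignments, with average ranks under ties — for up to 12
nonzero differences, and a normal approximation with continuity and tie
correction beyond. All-zero differences give p = 1 by convention.
Bonferroni correction multiplies by the family size and caps at 1;
significance is 0.05 after correction. Note the exact test's granularity:
with n = 5 subjects the smallest achievable two-sided p is 1/16, so no
5-subject comparison can reach 0.05.

For behavioral-vs-PSG comparison, both sources are merged into a shared
three-class space (so confusion matrices are well-formed): behavioral
QA/AA/V pool into wake; PSG merges either as REM+N1+N2 vs N3
("REM+/NREM−", scheme A) or REM vs N1+N2+N3 (standard, scheme B). The
schemes differ exactly on light-NREM epochs, which in infants co-occur
with behaviorally active sleep — the acceptance suite verifies that when
AS epochs are paired with simulated REM/N1/N2 stagings, scheme A's kappa
strictly exceeds scheme B's.

## Problem sizes and numerics

The test and acceptance runs use: 1,000 random confusion matrices
(≤ 6 labels, n ≤ 200) against a brute-force kappa oracle at 1e-12;
500 random hypnograms of 20–200 epochs for the rule-engine invariants;
200 state sequences for the architecture means; 20 naps each for the
closed-loop regularity check (movement disabled, ≥ 95% epoch agreement
required) and the end-to-end kappa (≥ 0.80 required); naps are 55 min at
16 Hz. Waveform processing uses a zero-phase Butterworth band-pass
(order 2); envelope smoothing is a 0.25-s moving average; all detection
thresholds are robust (median/MAD) so regularity verdicts are invariant
under amplitude scaling, which is asserted as a property test.

## Known limitations

* Drowsy states and indeterminate sleep are not scored (by design).
* Twitch/gross thresholds and all movement-cue constants are invented
  defaults behind config; the literature defines these contrasts only
  qualitatively.
* The eyes and cry channels stand in for human video judgments; the
  package does no video or audio classification.
* The simulator does not model overnight multi-cycle sleep, feeding
  interruptions, or preterm architecture.
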