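---
title: "Methods: simulated tone-cloud decision tasks on a steering wheel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated tone-cloud decision tasks on a steering wheel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tonewheel)
```

## What this package models

`tonewheel` is a hardware-free re-implementation of a head-fixed mouse
behavioral platform for auditory decision-making. Mice report decisions
about *tone clouds* - rapid streams of brief overlapping pure tones whose
octave composition carries the evidence - by turning a steering wheel read
out through a rotary encoder. The package contains every computational layer
of such a rig: stimulus synthesis, encoder decoding, event-driven trial
state machines for a detection, a Go/NoGo and a two-alternative forced
choice (2AFC) task, a fully automated staged-training controller, and the
analyses used to quantify performance (signal-detection d', psychometric
fits, reaction times, pre-stimulus turning). Because no animal is available
at desk scale, a module of *synthetic agents* with known psychometric ground
truth closes the loop, so the engine, the trainer and the analyses can be
tested end to end.

## Stimuli

A tone cloud presents tones at a fixed rate (default 100 tones/s, i.e. a
10 ms inter-onset interval) of 30 ms duration each, so consecutive tones
overlap by 20 ms. Pitches come from three musical octaves in 12-tone equal
temperament anchored at A4 = 440 Hz: low C7-B7 (2,093-3,951 Hz), middle
C8-B8 (4,186-7,902 Hz) and high C9-B9 (8,372-15,804 Hz), 12 pitches per
octave. The *stimulus strength* is the percentage of tones drawn from the
dominant octave; the remaining tones are drawn uniformly from the 24
pitches of the other two octaves. 100% clouds are the easiest stimuli;
training introduces 85%, 70% and finally 60% clouds.

Two parameter statements in the protocol are mutually inconsistent: a rate
of 100 tones/s and a "10 ms overlap" of 30 ms tones. We honor the rate -
the inter-onset interval is exactly `1/rate` - and record the alternative
reading as unknowable. Ramp shape is unspecified; we use raised-cosine
(Hann half-window) 3 ms ramps, the standard click-free choice. Tones whose
tail would cross the nominal cloud duration are truncated at the boundary
(decay ramp applied inside it), so a 0.51 s cloud at 44.1 kHz is always
exactly 22,491 samples. Per-tone amplitudes are equal and the summed
waveform is peak-normalized to 0.9 full scale; absolute loudness (dB SPL)
is a property of physical hardware and out of scope. WAV output is plain
RIFF (16-bit PCM or 32-bit float) written by a minimal in-package codec,
because no WAV package is available in the target environment.

## Wheel signal path

The encoder model is a 1,024 pulses-per-revolution quadrature encoder. We
use x1 counting - one count per full pulse period, registered on the rising
edge of channel A with direction read from channel B - so one revolution is
1,024 counts and the angular quantum is 360/1024 = 0.352 degrees; x4
decoding would imply 4,096 counts and contradict the stated resolution.
Positions are event-driven step functions resampled to a uniform 100 Hz
grid by last-observation-carried-forward. A consequence of x1 counting
worth knowing: steady motion tracks the true angle within about one
quantum, but each direction reversal has a dead band of up to one full
pulse cycle before the first opposite-direction count, so transient errors
up to ~3 quanta (~1 degree) occur at reversals. The property tests assert
exactly this bound.

Quiescence (the pre-stimulus stillness requirement) is positional: the
angle may wander at most 2 degrees from the value at the start of the
running window; an excursion restarts the window at the excursion sample.
The turning goal is likewise positional: the first time the displacement
from the stimulus-onset angle reaches the goal (15 or 30 degrees by stage),
signed by direction. Accumulated turning is path length (sum of absolute
increments), not net displacement.

## Trial and session state machines

Sessions run on a virtual clock advanced by events; a 90-minute session
simulates in a couple of seconds and every duration in the event log is
exact. Phase transitions are separated by one 10 ms scheduler tick so
timestamps are strictly ordered. One trial is:

1. draw the quiescence duration uniformly from 1.0-1.5 s and wait until the
   wheel trace satisfies it;
2. present the tone cloud, repeating it back to back (fresh pitch samples,
   same strength/side) until a goal crossing or the end of the response
   window (1.02 s = two 0.51 s presentations for detection/Go-NoGo; 15 s
   for 2AFC); a response terminates the stimulus immediately;
3. classify the outcome (detection: correct/incorrect; Go/NoGo: hit, miss,
   correct rejection, false alarm; 2AFC: correct, incorrect, omission);
4. deliver the reward (correct detections, hits, correct 2AFC choices), or
   a 1.5 s timeout for errors, with an additional 0.5 s white-noise burst
   for false alarms and incorrect 2AFC choices (omissions get the timeout
   but no noise; correct rejections get neither);
5. a 0.5 s inter-trial interval.

Trial ordering: Go/NoGo draws trial types uniformly with at most 3
identical types in a row. 2AFC stage 0 presents high/low clouds in
alternating blocks that switch after three consecutive correct trials;
stages 1-3 draw side and strength pseudorandomly with *repeat-on-error*
debiasing (an incorrect trial is followed by the same stimulus), the
anti-bias scheme used by comparable wheel-task implementations; stage 4
drops the repeat rule. Strengths within a stage are presented in equal
proportions (the exact proportions are not stated in the protocol; equal is
the neutral choice, perturbed only by error repeats).

A session lasts at least 45 min and ends either at the time cap (60 min
detection/Go-NoGo, 90 min 2AFC) or when the disengagement criterion fires,
checked at trial end only: fewer than 4 goal crossings in the last 20
trials (detection/Go-NoGo), or a rolling median reaction time over the last
20 responded trials exceeding 4 times the session median (2AFC; omissions
carry no RT and are excluded). With zero responded trials the 2AFC rule is
vacuous and such sessions run to the cap - the count-based rule belongs to
the detection/Go-NoGo tasks only.

Determinism: each session takes one seed; per-trial seeds are derived from
it by counter, so a single trial can be reproduced in isolation and
replaying a session seed reproduces the record bit for bit.

## Automated training

Pretraining is 3 sessions (15/30/45 min) with the wheel ignored: 2.04 s
100% middle-octave clouds, each followed by a 5 ul reward. The main
protocols then advance through stages on strict (printed) thresholds:

* detection: stage 0 (goal 15 degrees) advances after >150 correct trials in
  a session; stage 1 (goal 30 degrees) applies intersession reward
  adjustment. No proficiency criterion is defined for detection, so
  automated training ends operationally once stage 1 has been run.
* Go/NoGo: stage 0 advances after >150 rewarded (hit) trials; we read the
  ">150 correct" bar of this shaping stage as counting hits, because a
  stage that teaches wheel turning must not be passable by correct
  rejections alone (an animal that never touches the wheel would otherwise
  advance). Proficiency: d' > 1.8 on three consecutive stage-1 sessions.
* 2AFC: stages 0-4 with goals/strengths as above; advancement bars >300
  correct, >80% per side, >75% per side, >350 correct. Proficiency at
  stage 4: >300 trials and >80% correct per side on 100% clouds in each of
  three consecutive sessions, plus a psychometric fit of the cumulative
  three-session data with |bias| < 16, slope < 19 (strength-% units) and
  both lapses < 0.2.

Between sessions, reward size moves by 0.1 ul against the previous
session's consumption (down above 1 ml, up below it), clamped to 3-5 ul
(detection/Go-NoGo) or 1.5-3 ul (2AFC); the 2AFC starting size is not
printed and we start at the 3 ul maximum, mirroring the other tasks.
Intersession debiasing (2AFC stages 0-3 only): if >85% of responded trials
went to one side, the reward for the neglected direction doubles on the
next session.

## Synthetic agents

An agent is a stationary policy. Its choices follow the same psychometric
model the analysis fits,

$$P(x) = \lambda_1 + (1 - \lambda_1 - \lambda_2)\,
  \frac{\mathrm{erf}\!\big((x - b)/s\big) + 1}{2},$$

with ground-truth lapses, bias $b$ and slope $s$ known to the tests;
$x \in [-100, 100]$ is the signed strength (negative = left-rewarded). For
Go/NoGo and detection the same machinery is reused with a Go-evidence value
($x = \pm 100$), and the physical turn direction of a responded trial is
drawn uniformly. Reaction times are log-normal (median 0.35 s, sigma 0.2 by
default - typical of trained mice on wheel tasks); deliberate turns are
constant-velocity ramps (400 deg/s) timed so the goal is crossed at the
drawn RT, holding at an amplitude sampled above the goal.

Impulsivity is modeled as spontaneous velocity bursts generated *before and
independently of* the stimulus (traces are causal by construction, and a
test asserts it). A per-trial log-normal gain scales both burst rate and
vigor; this trait/state variability is what reproduces the false-alarm
signatures seen in real data: false alarms carry far more pre-stimulus
accumulated turning than hits, and among false alarms the pre-stimulus
turning negatively predicts RT (the wheel is already moving, so the goal is
crossed sooner). The `impulsive` profile has no psychometric lapses so that
its errors arise from impulsivity alone; the `disengaging` profile slows
its RT median 5-fold after 40 min, late enough that the session median is
still dominated by fast trials and the 2AFC disengagement rule fires
shortly after the 45 min minimum.

What the generator does **not** emulate: learning within or across sessions
(agents are stationary; training curves arise from thresholds, not from
plasticity), motor biomechanics, satiety dynamics, or absolute trial counts
of live animals (an ideal agent works the whole cap and completes ~1,700
detection trials per session, an order of magnitude above a real mouse's
~190). A green closed-loop test therefore establishes that the platform's
rules are implemented correctly, not that mice behave this way.

## Numerical choices

* d' uses $z(H) - z(F)$ with $H$, $F$ clamped to $[1/(2N), 1 - 1/(2N)]$
  (N = trials of the respective class) so perfect rates stay finite; the
  clamping rule is stated nowhere in the protocol and is test-covered here.
* The psychometric fit maximizes the binomial log-likelihood with L-BFGS-B
  under bounds (lapses in $[0, 0.5]$, slope in $[0.5, 200]$, bias in
  $[-100, 100]$) from a fixed 48-point start grid, so it is deterministic.
  On likelihood ties - flat ridges arise with perfectly separable or
  uninformative data - the tie-break prefers the smaller |bias|, then the
  smaller slope: the least-extreme curve consistent with the data.
  Degenerate data return boundary flags, never an exception.
* Identifiability caveat: at the task's strength levels ($|x| \ge 60$) and
  plausible slopes (10-20), $\mathrm{erf}((x-b)/s)$ is saturated
  ($\ge 0.9996$) at every level, so the likelihood carries essentially no
  information about bias and slope - only the lapses (asymptotes) are
  identifiable. Parameter recovery of bias/slope at these levels fails for
  any estimator (the package's acceptance suite measures and reports this
  honestly), and the stage-4 proficiency thresholds on bias and slope are
  binding in practice only through the tie-break on near-separable data.
  The fitter itself recovers bias to ~0.5 strength-% and slope to ~6% on
  designs whose levels span the transition region.
* Rolling performance windows are trailing (causal); centering is not
  specified in the protocol.
* The pre-stimulus-turning/RT relation uses closed-form OLS with the
  standard $R^2$.
* The session store is a versioned JSON document (plus a flat CSV trial
  table); numbers are written with 17 significant digits so every timestamp
  round-trips bit-exactly. HDF5 and YAML back ends were not available in
  the target environment.
* Dropped-frame detection flags gaps above 1.5 nominal intervals (the
  midpoint between one and two missed intervals) and infers
  `round(gap * rate) - 1` missing frames; event alignment maps to the
  nearest pulse with ties to the earlier index.

## Known limitations

Agents do not learn, so acquisition speed and training-duration statistics
of real animals are out of reach by design. The 2AFC disengagement rule
cannot fire for an agent that never responds. Stage-0 Go/NoGo advancement
counts hits (see above) - a deliberate interpretation of an ambiguous
printed rule. Real-time audio playback, GPIO timing and loudness
calibration are hardware properties and out of scope.
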