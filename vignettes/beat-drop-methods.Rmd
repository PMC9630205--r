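---
title: "The Beat-Drop Alignment Test engine: models, design choices, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Beat-Drop Alignment Test engine: models, design choices, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bdat)
```

## What the test measures

The Beat-Drop Alignment Test (BDAT) probes *covert beat continuation*: the
ability to extract a pulse from music and keep it going internally when the
sensory cues disappear. Each trial is six bars of 4/4. Bars 1–3 establish
the rhythm; in bar 4 the rhythm drops out on beats 2–4 (the "beat drop"),
leaving only a non-rhythmic drone; bars 5–6 bring the rhythm back. A single
probe click falls inside the drop, either exactly on beat 3 or 4 (the ON
condition) or displaced early or late relative to one of those beats (OFF).
The listener answers "on the beat" or "off the beat" — a one-alternative
forced choice. Because there are no acoustic beat cues in the drop window,
the judgment can only be made against an internally continued pulse.

## The item bank

An item is a (track, condition, target beat, direction, displacement level,
tempo) combination. Per track and tempo there are 2 ON items (beat 3
strong, beat 4 weak) and $2 \times 2 \times 7 = 28$ OFF items, so 30 tracks
yield 900 items at one tempo and 4,500 across the five tempo variants.

**Displacement levels.** Physically equal displacement steps are not
perceptually equal: near the beat a few milliseconds matter, far from it
they do not. Displacements $d$ (fractions of the beat period) are therefore
placed on the perceptual-accuracy scale

$$\mathrm{PA}(d) = \cos(\pi d)^4,$$

which is 1 at the beat and 0 at half a beat. Seven levels between 15% and
45% of the beat period are chosen so that consecutive levels are equally
spaced in PA, then inverted numerically (bisection to $10^{-12}$; the
closed form $d = \arccos(\mathrm{PA}^{1/4})/\pi$ serves as the test oracle)
and rounded to whole percents, half up:

```{r levels}
displacement_levels(displacement_scale())
```

The scale stops below 50% because a probe exactly halfway between beats is
ambiguous — 50% late relative to beat 3 *is* 50% early relative to beat 4.
The rounding rule ("percent", half up) is a configurable default; it is the
rule that reproduces the published level set 15/18/20/23/26/31/45.

**Tempo variants.** The five tempi span ±5% around the base in even steps.
For the canonical 125 bpm base the package returns the published constant
list `119, 122, 125, 128, 132`: a plain half-up rounding of
$125 \times 1.05 = 131.25$ would give 131, not the published 132, so
fidelity to the deployed item bank takes precedence over the arithmetic
rule at this one base. Other bases use the multiplicative rule with half-up
rounding.

**Timing.** Clip start is bar 1 beat 1 at 0 s; beat $k$ of bar $b$ (both
1-based) falls at $((b-1)\,4 + (k-1)) \cdot 60/\mathrm{bpm}$ seconds. At
125 bpm the beat period is 480 ms and a clip lasts 11.52 s. The probe is
shifted by $\pm d \cdot$ beat period from its target beat; all OFF
displacements keep the probe strictly inside the drop window.

## Schematic audio

`render_stimulus()` produces a schematic realization: percussive clicks
(exponentially decaying cosine bursts — the cosine phase makes the onset
sample-sharp) on every grid beat outside the drop window, a constant-
amplitude sinusoidal drone through the drop (no amplitude periodicity at
the beat rate, hence no rhythmic cue), and the probe click — a 120 ms burst
pitched at F2 (87.31 Hz) — at `round(probe_onset * sample_rate)`. The
psychometric layer never inspects audio; items are fully described by their
spec, so schematic synthesis carries exactly the timing information the
test needs. `verify_onsets()` closes the loop: an energy-rise detector
(short forward RMS window against a long backward window that averages out
the drone's oscillation) must recover every planned onset within ±1 ms and
find nothing else.

## The response model

The probability of a correct response is a mixed-effects logistic
regression with modified asymptotes,

$$P(\text{correct}) = g + (u - g)\,
  \mathrm{logistic}(\beta^\top x + b_{\text{person}} + b_{\text{track}}),$$

with guessing floor $g$ (a 1-AFC judgment is never worse than guessing) and
inattention ceiling $u$ (nobody is perfect on every trial). ON and OFF
items get separate models. ON uses metrical strength only (strong beat 3
vs. weak beat 4); OFF adds probe direction (early is the reference
category), displacement level, and the direction × strength interaction.
This is algebraically a four-parameter logistic (4PL) IRT model in which
discrimination, guessing and inattention are constant across the bank:
taking $a = \sigma_{\text{person}}$ and $b = -\beta^\top x / a$, a
standard-normal ability $\theta$ gives
$a(\theta - b) = \beta^\top x + \theta\,\sigma_{\text{person}}$.

The shipped defaults are the calibration estimates the adaptive test
administers with (ON: intercept −0.76, strength +1.77,
$\sigma_{\text{person}} = 1.19$, $\sigma_{\text{track}} = 0.41$, $g = .4$,
$u = .98$; OFF: intercept 2.23, displacement +0.41 per level, direction
−1.91 for late, strength +0.16, interaction −1.48,
$\sigma_{\text{person}} = 1.30$, $\sigma_{\text{track}} = 0.05$, $g = .4$,
$u = .96$).

Two coding decisions deserve a note:

* **Displacement is coded as the level index 1–7**, not as raw percent.
  At +0.41 logits per level the seven levels span about 2.5 logits, which
  matches the roughly linear rise of accuracy across levels; raw-percent
  coding would imply an implausible 12-logit span for the same
  coefficient. The coding is a documented package default, serialized with
  every fit.
* **Direction's reference category is early.** The negative coefficient
  for late then encodes that listeners are more accurate when the probe
  arrives ahead of the beat — consistent with the "filled duration"
  illusion and perceptual acceleration, both of which make slightly late
  events sound on time. The shipped displacement coefficient is stored
  with the positive sign, the direction consistent with accuracy rising as
  the probe moves away from the beat.

The upper asymptote is stored directly as $u$ (the probability ceiling),
not as an inattention rate $1-u$.

At administration time the track effect is dropped: each track appears at
most once per session, so a track intercept is not identifiable from a
single session and its calibrated SD is small. It is retained in
calibration.

## Fitting the model

`fit_explanatory()` maximizes the marginal likelihood over the fixed
effects and the two random-intercept SDs (optimized on the log scale, so
they stay non-negative, with a floor of $10^{-4}$), holding the asymptotes
fixed at supplied values. The crossed random effects are integrated with a
split strategy:

* **participants by Gauss–Hermite quadrature** (20 nodes by default), and
* **tracks by a Laplace approximation** around the joint track mode
  (damped Newton with analytic gradient and Hessian, ridge-guarded
  Cholesky).

The split follows the information geometry of the design. Each participant
contributes only ~15 binary responses per condition, and the guessing
floor of .4 halves the information each response carries; the person
integrand is therefore wide and skewed, and a mode-based (Laplace)
approximation of it visibly attenuates the fixed effects — in simulation at
500 participants the attenuation exceeds two standard errors, while the
quadrature version is unbiased. Each track, in contrast, pools responses
from every participant, so its integrand is close to Gaussian and Laplace
is accurate there. The likelihood evaluator reproduces single-random-
effect adaptive quadrature (lme4, 25 nodes) to $10^{-5}$ log-units, and an
importance-sampling oracle (`marginal_log_likelihood_mc()`, multivariate-t
proposal around the joint mode) confirms the crossed evaluation to ~0.01
log-units on a 10-participant × 5-track dataset.

Standard errors come from a central-difference Hessian of the marginal
log-likelihood at the optimum (all parameters jointly, so fixed-effect SEs
account for the variance components). Convergence is reported from the
optimizer (`nlminb`, relative tolerance $10^{-8}$, 500 iteration cap).
Whether the asymptotes should themselves be estimated is left open:
they are fixed inputs here, and a user can profile them on a grid by
refitting; the default values are the shipped calibration constants.

`prediction_accuracy()` classifies each response by whether the
conditional probability — empirical-Bayes posterior-mean person effects,
modal track effects — exceeds 0.5.

**Screening.** `screen_tracks()` flags, per condition, tracks whose mean
accuracy is *strictly below* chance (0.5): systematic errors suggest a
misleading stimulus rather than a hard one; a mean exactly at chance is
not flagged. `screen_participants()` reconstructs the on/off judgment from
condition and correctness and flags participants whose dominant judgment
share reaches the threshold (default 0.9, inclusive, so `dominance = 1`
flags exactly the constant responders). Both thresholds are explicit
defaults; the qualitative rules they implement ("below chance",
"all/nearly all the same answer") do not pin down numbers.

## Adaptive administration

`run_session()` administers a fixed-length session (default 25 trials):

1. Draw the trial's condition — ON with probability 0.5, mirroring the
   calibration design. (A deterministic alternation would also be
   defensible; the probabilistic schedule was chosen because it reproduces
   the calibration item mix in expectation and keeps the schedule
   unpredictable for the listener.)
2. Among items of that condition whose track is unused this session,
   select the one with difficulty closest to the running ability estimate
   (ties broken by a seeded uniform draw). The first trial targets
   difficulty 0, the calibration-sample mean. Maximum-information and
   uniform-random selection are available as options; random selection is
   the baseline in validation. One item per track per session, the
   session-level generalization of "each track heard once".
3. Score the response and re-estimate ability.

**Ability estimation** is expected a posteriori (EAP) by default: the
posterior mean over a fixed grid $\theta \in [-4, 4]$ in steps of 0.01,
standard-normal prior, with trapezoidal end-point weights (the posterior
of an all-incorrect pattern leans on the grid boundary, where plain
rectangle sums leave an error linear in the step). EAP is defined for
every response pattern including all-correct/all-incorrect, which maximum
likelihood is not; ML is available as an option. The posterior SD is
reported as the standard error. Final abilities are also reported as
pseudo-IQ, $100 + 15\,\theta$, for participant feedback.

Note two consequences of the shipped difficulty range (−3.9 to +0.6): the
test is easy relative to a standard-normal population, so EAP estimates of
high abilities shrink noticeably toward zero (there are no items hard
enough to separate $\theta = 2$ from $\theta = 3$), and a 25-item session
reaches a posterior SE around 0.5 rather than the ~0.3 a wider bank would
give. Both are properties of the instrument, not of the estimator.

## The simulator, and what passing tests do and do not show

`simulate_study1_dataset()` reproduces the calibration design: every
respondent hears each of 30 tracks once, ON with probability 0.5, OFF
variants uniform over the 28 options, abilities standard normal, track
effects drawn once per condition with the condition's calibrated SD.
`simulated_responder()` answers items Bernoulli-correctly at a fixed
ability through the same response model (with a private RNG stream, so
oracles are reproducible independently of surrounding RNG use).
`recovery_experiment()` wires these into the two validation loops:
simulate → calibrate → compare (bias, 2-SE coverage), and simulate →
adaptive sessions → compare against random selection (RMSE, correlation).

The simulator deliberately emulates the *model*, not human behaviour: no
fatigue, learning, lapses correlated in time, tempo-specific difficulty,
or track-by-participant interaction. Passing recovery tests therefore
shows that the estimation and administration machinery is correct and
well-calibrated under the stated model — it cannot show that the model is
true of human listeners; that is what the calibration study itself is for.

## Validation scale and numerical defaults

The shipped test-suite sizes were chosen to make the checks informative
while staying desk-scale: parameter recovery uses 20 replicates of 500
simulated participants (mean absolute bias < 0.1 logits, 2-SE coverage
≥ 0.8 for every fixed effect in both models); the single-replicate
recovery check uses n = 500 with all coefficients within 2 SEs; adaptive
vs. random selection uses 500 paired respondents at 25 items. Numerical
defaults: bisection tolerance $10^{-12}$; 20 quadrature nodes; Newton
gradient tolerance $10^{-6}$ in the track mode; EAP grid step 0.01;
finite-difference step $10^{-4}$ for SE Hessians.

## Known limitations

* The fitter assumes the Study-1-like crossed design (binary responses,
  one observation per participant × track per condition); it is not a
  general GLMM engine.
* Asymptotes are fixed, not estimated; misspecifying them biases the
  other parameters.
* The schematic audio is a timing-faithful stand-in, not music; results
  about rendered stimuli speak to timing, not to timbre or musical
  salience.
* Difficulty-matched selection ignores exposure control beyond track
  uniqueness, and the information function of the 4PL is not used for
  stopping rules (sessions are fixed-length).
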