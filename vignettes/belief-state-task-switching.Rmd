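---
title: "Belief-state reinforcement learning and prediction-error neuron analysis"
author: "switchRL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Belief-state reinforcement learning and prediction-error neuron analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(switchRL)
```

## The task and its formalization

Mice can switch in a single trial between two discrimination rules: respond
to drifting gratings (visual blocks) or ignore the same gratings and respond
to odours (odour blocks). `switchRL` models this cross-modal block-switching
task as a discrete-step reinforcement-learning environment with five cues --
two gratings, two odours and an end-of-trial cue -- and two actions, lick
and no-lick. A visual-block trial has two steps (end-of-trial cue, then the
grating, which is the reward step); an odour-block trial has three steps
when an irrelevant grating precedes the odour (70% of odour trials,
i.i.d. Bernoulli) and two otherwise. A lick at any non-final step costs -1
(a needless lick); at the reward step a lick earns +1 for the rewarded cue
(VISUAL_1, ODOUR_1) and -1 for the unrewarded one, and withholding always
yields 0.

Blocks end exactly as in the animal experiment: strictly more than 80%
correct responses to the relevant stimuli over the last 30 trials and, in
odour blocks, every irrelevant grating ignored over the last 10 trials. A
transition period then constrains the stimulus sequence: after an
odour-to-visual switch only the rewarded grating is shown until the agent
licks it on three consecutive trials; after a visual-to-odour switch the
forced irrelevant grating is the unrewarded VISUAL_2 on its first
appearance (variant V1; variant V2 always forces VISUAL_1), so that the
switch is signalled by the unexpected odour rather than a reward prediction
error. A figure-legend reading of the protocol forces exactly the first
three trials instead; that variant is available via
`envConfig(forcedTrials = 3)`, but the until-three-correct rule is the
default because it is the operational rule of the training protocol.

Two details are interpretation choices. First, the "three consecutive
trials" counter for visual-to-odour transitions is counted over trials that
actually present an irrelevant grating: trials without one carry no
evidence about the animal's policy toward gratings, so they neither count
nor reset. Second, a trial is *correct* only if the final-step response is
correct **and** no needless lick occurred earlier in the trial; the
block-switch criterion, however, uses final-step (relevant-stimulus)
correctness, with irrelevant-grating discipline enforced separately by the
10-trial window. Blocks that never meet the criteria (e.g. under a random
agent) are force-ended at `maxBlockTrials` (default 500) and flagged; such
pseudo-transitions are excluded from curves and switching statistics.

## The agents

The **basic agent** is tabular SARSA: one Q-table over the four non-terminal
cues and two actions, an epsilon-greedy policy, and the update
`Q(s,a) <- Q(s,a) + alpha * (r + Q(s',a') - Q(s,a))` with
`Q(END_OF_TRIAL, .)` fixed at zero, so each trial's return terminates at
the trial boundary. The basic agent keeps learning with the same `alpha`
in the test phase.

The **belief-state agent** holds one Q-table per context plus a belief
`b = (p(v), p(o))`. Within a trial it acts epsilon-greedily on the Q-table
of the assumed block (the larger belief component; exact ties keep the
previous assumption). At every trial end the detected block `d` is read
from the cue preceding the end-of-trial cue -- a visual cue in visual
blocks, an odour in odour blocks -- and a mismatch signal `chi = d - b` is
corrupted multiplicatively, `chi' = f * chi * (1 + beta * xi)`, with a
*single* standard-normal draw `xi` per trial (the noise scales both
components together) and a silencing factor `f` (1 when intact; chosen per
trial as `silencingFactorVisual` or `silencingFactorOdour` according to the
modality of the detected block). The belief update is
`b' = b + zeta * chi'`, clipped componentwise to a floor of 1e-9 and
renormalised. The floor rather than a literal zero keeps renormalisation
well-defined; if both components are at the floor the belief resets to
(0.5, 0.5). The belief itself initialises to the uninformative (0.5, 0.5).
During training only the assumed block's Q-table is updated; after
training, Q-updates are switched off (`alpha = 0`) and only the belief
moves. A separate exploration rate `epsilonPrime` applies on steps whose
presented cue is VISUAL_2, in both block types (a config switch restricts
it to odour blocks); it captures the enhanced licking to the unrewarded
grating seen in odour blocks.

Default parameter values are the best-fit values of the primary dataset:
`zeta = 0.6858`, `beta = 1.997`, `epsilon = 0.049`,
`epsilonPrime = 0.280`, training `alpha = 0.1`; the silencing analysis
additionally uses the silenced-dataset fit
(`zeta = 0.7698, beta = 1.987, epsilon = 0.1072, epsilonPrime = 0.4516`)
with factors 0.2143 (visual) and 0.5016 (odour).

Why this produces one-shot switching: in an odour block the belief sits at
(~0, ~1). The first visual-block trial ends with a visual cue, so
`chi = (1, -1) - ish`, and the belief flips in a single update whenever
`zeta * (1 + beta * xi) > 0.5` -- at the default parameters about 55% of
transitions, matching the roughly half one-shot/half slower split of the
model. The amplitude `|chi'_1| + |chi'_2|` on that first trial is exactly
what separates one-shot from slower transitions (`peAmplitudeByOutcome()`,
which reports the noisy signal by default because that is the quantity that
drives the update; the noise-free `chi` is available via `signal = "chi"`).

The simulation loop is implemented in C++ (Rcpp) with a fast local
xoshiro256++ generator seeded from R's RNG, so `set.seed()` fully
determines a run while long fitting loops stay cheap. A pure-R step-by-step
environment (`envReset()`/`envStep()`/`checkBlockSwitch()`/
`scheduleTransitionCue()`) exposes the same semantics one step at a time;
the test suite drives it with scripted policies as a brute-force oracle for
the fast path (reward tables, minimum block lengths under a perfect
policy, forcing rules).

## Curves, fitting and model selection

`lickProbabilityCurve()` aligns every behavioural transition and records,
per cue and per trial position within `window` trials (default W = 20,
chosen to cover a typical 30-40-trial block's transition neighbourhood),
whether the agent licked to that cue; licks to a grating count whether the
grating was the reward stimulus or the irrelevant one. Cells where a cue
never occurred (e.g. VISUAL_2 during forced transition trials) are missing,
not zero, and are excluded from the RMSE. Per-transition counts are kept so
cross-validation folds can re-aggregate subsets of transitions without
re-simulation.

`fitModel()` fits by simulating each candidate parameter set (train N/2
steps with SARSA, then N/2 frozen test steps), computing the RMSE between
the candidate's curve and the data curve, and averaging across seeds, each
seed paired with a transition-period variant (default 2 x V1 + 3 x V2,
mirroring the session composition of the original protocol; when fitting
synthetic data generated under a single variant the seed table should match
that variant). A grid search over the documented ranges (`zeta` in
[0.05, 1], `beta` in [0, 4], `epsilon`, `epsilonPrime` in [0, 0.5];
`alpha` in [0.05, 1] for the basic model) is followed by Nelder-Mead
refinement from the best grid points, box-clamped to the grid ranges.
Cross-validation folds are contiguous segments of the *data's* transition
sequence; the simulation always uses its own full run, exactly as when
fitting experimental sessions. Default N = 1e5 is a desk-scale choice; the
original fits used N of 5e5 to 2e6, reachable through `nSteps`.

Two budgeting options matter for recovery studies. `screenSeedRows` +
`screenSteps` run the full grid cheaply and re-score only a shortlist with
all seeds, and `refineSteps` lengthens the *test* phase of shortlist and
local-refinement evaluations. Training always stays at `nSteps/2`: an early
version of the package let `refineSteps` extend training too, and the
resulting candidate agents -- trained several times longer than the data
agent -- produced subtly different steady-state behaviour (better-converged
off-context Q-rows), which biased recovered `zeta` and `epsilon` upward.
Matching the training protocol and extending only the frozen test phase
removed that bias; this is the main numerical trap we found in the fitting
protocol, and the reason the defaults keep candidate training identical to
the protocol being fitted.

`fitSilencingFactors()` holds all base parameters fixed, trains once per
seed without silencing, and re-uses the trained agent state across
candidate factor pairs, which only affect the frozen test phase. Because
the two factors move only a handful of curve cells near transitions, the
objective is shallow; the implementation therefore supports `refineSteps`
to lengthen the test phase of candidate evaluations, and recovery studies
should use silenced sessions with generous test-phase lengths.

Model selection replicates the held-out logic: both models are fitted to
the same curve and compared by per-fold test RMSE; the belief model should
win in at least 4 of 5 folds on belief-generated data. No information
criteria are used.

## Behavioural metrics

`behaviouralDprime()` is `qnorm(H) - qnorm(F)` with rates clipped to
`[1/(2n), 1 - 1/(2n)]`, the usual finite-sample correction for perfect
rates (the original analysis does not state its convention; this one keeps
the statistic finite and monotone). `switchingSpeed()` counts the trials
that elapse before the first run of three consecutive correct responses to
the relevant stimuli begins; 0 is a *fluke* (a correct lick to the very
first rewarded grating, before any evidence of the switch) and is excluded
from one-shot proportions and speed statistics, 1 is a one-shot
transition. `summarizeTransitions()` computes these per direction plus
stable-period d-primes, where *stable* means outside transition periods
and at least 5 trials after the transition period ended (the margin keeps
residual transition behaviour out of the steady-state rates).

## Calcium analysis

`computeDff()` computes dF/F with a baseline equal to the running minimum
(over the preceding 60 s) of the causally smoothed (0.75 s moving average)
trace; second-to-frame conversions round to the nearest frame with a
minimum of one. The statistic is invariant to positive rescaling of the
raw trace; neurons whose baseline touches zero are flagged and excluded.

`epochResponses()` extracts the three screening epochs around
odour-to-visual transitions: (1) the *odour prediction-error* epoch,
2.0 s after the offset of the first grating of the new visual block
(2.0 s being the typical grating-offset-to-odour delay), provided the
animal did not lick to that grating; (2) *odour* epochs at odour onsets at
the end of the preceding odour block, following a correctly ignored
grating; (3) *no-odour-predicted* epochs 2.0 s after unrewarded-grating
offsets later in the visual block, excluding the final 10 trials.
Conditions 2-3 average up to 7 eligible trials per transition, taking the
trials nearest the transition (a random-subset option exists); responses
are means over 1.5 s windows. `classifyNeurons()` then runs two two-sided
rank-sum tests per neuron across transitions (prediction-error vs odour,
prediction-error vs no-odour). Neurons significant in both comparisons are
prediction-error neurons, signed by whether the prediction-error mean is
the largest (positive) or smallest (negative) of the three; single-test
neurons are Type A (odour comparison) or Type B (no-odour comparison). The
significance level defaults to alpha = 0.05 two-sided without multiplicity
correction: the dual criterion itself is the specificity control (its
empirical false-positive rate on null data is well below alpha because the
two tests share the prediction-error sample), which mirrors how the
original criterion was validated empirically against a control region
rather than by a stated alpha.

`sustainedSignificance()` applies the per-frame paired t-test rule (P
below alpha for runs strictly longer than 500 ms). `decodeTimecourse()`
is a per-frame L2-regularised binary logistic regression under stratified
5-fold cross-validation with the larger class randomly subsampled to
balance; glmnet provides the classifier, with the penalty fixed at 1 by
default (the protocol specifies only that an L2 penalty is used).
`bootstrapProportionCi()` is the percentile bootstrap for a proportion
(default 10,000 resamples, 99% interval from the 0.5th/99.5th
percentiles); for binary labels the resampled count is exactly
Binomial(n, p-hat), which is how it is drawn. `fitEncodingModel()` builds
a time-lagged design (sensory regressors 0 to +2 s, motor regressors
-0.5 to +2 s, one-frame steps) and fits ridge regression per neuron with
the penalty chosen from 36 log-spaced values between 1e-2 and 1e5 under
5-fold cross-validation on contiguous frame folds, reporting held-out R^2
and its drop when the motor (running, licking) regressors are removed.

## Synthetic data: what it does and does not emulate

`generateBehaviour()` either runs the belief agent (defaults = the best-fit
parameters, so the generator's switching statistics are the study
conditions) or emits scripted i.i.d. licks from a per-cue probability
table with a deterministic rule switch a controllable number of trials
after each block boundary -- `oneShotFraction` sets the mix of one-shot
(lag 1) and slower (lag `slowSwitchLag`) transitions, and the first three
trials of each scripted visual block show the rewarded grating, matching
the transition period. `generateCalcium()` lays trials on a fixed timeline
(1.8 s stimuli, 1.8 s grating-odour gap, a post-offset window long enough
to contain the expectation epoch) and plants single-exponential transients
(tau = 0.7 s, GCaMP7f-like; default rate 4.8 Hz, a typical volumetric
two-photon rate) at class-defining moments: prediction-error-positive
neurons respond at the expected-odour omission of the first
post-transition trial only (the empirically observed restriction, relaxed
via `peFirstTrialOnly = FALSE`); prediction-error-negative neurons respond
at odour deliveries and matched no-odour moments but not at the omission;
Type A at odour deliveries only; Type B at no-odour moments only. Noise is
i.i.d. Gaussian per frame, default amplitude/noise = 3.

What passing tests show is that the pipeline recovers planted structure
under event-locked transients with independent noise. Real recordings add
correlated noise, drifting baselines, overlapping responses to licking and
running, and uncertainty in event times -- none of which the generator
emulates -- so recovery rates here are upper bounds on real-data
performance, not estimates of it.

## Problem sizes and reproducibility

All randomness flows through `set.seed()`; the C++ core draws its local
generator's seed from R's stream, so every simulation, fit and synthetic
dataset is reproducible from a single integer. The packaged analyses use
desk-scale sizes chosen to keep a full pipeline run comfortable on a
single core: 1e5-step fitting simulations (5e4 training), recovery studies
with 10 replicate fits over a 288-point grid with shortlist re-scoring,
1000-neuron recordings with about 20 usable transitions, 10,000 bootstrap
resamples, and 200-replicate coverage checks. All are plain function
arguments and scale up directly.

## Known limitations

* The belief update is the two-context multiplicative-noise filter of the
  original model -- not a Bayesian HMM -- and the environment abstracts all
  real-time structure (stimulus durations, timeouts, running initiation)
  into discrete steps; licking dynamics within a stimulus are out of scope.
* `zeta` and `beta` trade off along a flat ridge of the curve-RMSE
  objective at desk-scale data sizes; recovery of `zeta` to within 0.2
  requires the matched-training protocol described above and is still the
  least well-identified direction of the fit.
* The odour-side silencing factor is weakly identified near 1: at the
  silencing-dataset parameters the per-trial belief-flip probability at
  visual-to-odour transitions changes only from about 0.53 to 0.57 as the
  factor moves from 0.75 to 1, so null (unsilenced) fits recover it with a
  band of roughly +/-0.3, while the visual factor and strongly silenced
  odour factors are recovered much more tightly.
* The encoding model's penalty grid is shared with the pixel-level
  analysis it was specified for; per-neuron optimal penalties on cellular
  data may sit at the grid edge for very clean neurons.
* CalciumRecording serialization is plain CSV/JSON; very large recordings
  are better regenerated from seeds than shipped as text.
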