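---
title: "Models and methods: cue selection and time-locked trajectories in dyad deception games"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deceptr)
```

This vignette documents the statistical models the package implements,
the choices made where the methodology was genuinely open, and what the
synthetic-data generator does and does not emulate.

## The data model

One row per utterance: the speaker's veracity (`truth`/`lie`), the
guesser's response (`truth` = clicked the referent, the image the speaker
named), seven binary disfluency annotations, eight binary raw gesture
annotations, four binary gesture *category* flags, three continuous
speech measures, a disambiguation point (ms, possibly missing), onset
times for the focal cues, and bookkeeping flags (consistent commitment,
gesture video present). Cursor logs are long-format `(trial, t_ms, x_px,
y_px)` at a nominal 50 Hz.

Disfluencies collapse mechanically into four analysis categories —
pauses (filled or silent), repetitions, repairs (restart, substitution or
addition), prolongations — with binary utterance-level coding: one or
many occurrences count the same. Gesture categories are *not* derived
from the raw gesture flags. Whether a hand movement is an adaptor
(self-directed scratch) or an illustrator (a chopping motion
accompanying "sliced carrot") is a functional judgement about that
instance, so category membership is an annotation-level input; the
generator emits the category flags directly for the same reason.

Exclusion rules, applied per analysis and logged per rule:
inconsistent-commitment trials are dropped everywhere (the speaker's
intent is undeterminable); mouse analyses additionally drop trials with
no codable disambiguation point and trials where the focal cue (pause or
affect display) begins after disambiguation; gesture and affect analyses
drop trials without video. Marking rows against independent predicates
makes the rules order-independent by construction.

## Cue model selection

Both outcomes are modelled with binomial mixed-effects regressions with
crossed random intercepts for *dyad* and *item*, fitted by maximum
likelihood with the Laplace approximation (`lme4::glmer`, bobyqa,
deterministic given the data). Speaker and guesser are in one-to-one
correspondence within a dyad, so a single dyad factor serves both
outcomes; the item is the target image concealing the treasure. This is
configurable in principle but is the minimal faithful grouping for this
design. Logistic models carry random intercepts only; random slopes are
reserved for the trajectory models below.

The candidate set is every additive combination of the cue family —
`2^5 = 32` speech models, `2^4 = 16` gesture models, null included —
enumerated in a fixed order (by size, then lexicographically), and
compared by AICc with `K` counted as fixed effects (intercept included)
plus one per random-effect variance (the intercept-only logistic model
thus has `K = 3`). ML rather than REML likelihoods are used throughout
because REML likelihoods are not comparable across fixed-effect
structures; `n` is the number of utterances fitted. From the AICc values
we compute ΔAICc, Akaike weights, evidence ratios `exp(Δ/2)`,
per-predictor cumulative weights, and the competitive subset
(ΔAICc < 2). Ties for the minimum break by smaller `K` and then by
enumeration order — the record of a tie is visible in the table, and
the tie-break only matters for labelling, not for weights. Non-converged
fits are excluded from the set with a warning rather than aborting the
analysis. Selection tables round only on display; internal precision is
never truncated.

Binary predictors enter as 0/1 presence dummies so `exp(β)` reads as an
odds ratio. The speech-rate predictor is the first principal component
of a correlation-matrix PCA on utterance duration, silent-pause duration
and syllable rate, oriented so syllable rate loads positively (higher
score = faster speech); the orientation is a reporting convention that
flips only coefficient signs, and it is recorded in the composite
object. The component is standardized before entering models.

## Time-locked trajectory analysis

For each trial the x-displacements between consecutive cursor samples
are assigned to 20 ms bins (by the later sample's timestamp) relative to
the disambiguation point. Movement toward the referent and toward the
distractor accumulate separately; the denominator of the
proportion-of-movement measure is the total absolute x-distance
travelled since the start of the trial, regardless of direction. Only
x-axis motion enters either numerator or denominator; a switch for
including y-travel in the denominator is deliberately not provided
because the directional measure is defined along the axis separating the
objects.

The dependent variable is the empirical-logit difference
`elogit(p_ref) − elogit(p_dist)` with `elogit(p) = ln((pN + c)/((1−p)N +
c))`, `N` the cumulative distance in px and `c = 0.5` (configurable,
since the transform for continuous "counts" is a convention). Because
`p_ref + p_dist = 1` whenever any movement has occurred, the DV reduces
to `2 ln((d_ref + c)/(d_dist + c))` and is exactly antisymmetric under
swapping referent and distractor. Bins before any movement carry DV = 0
— no evidence either way — with a zero-movement flag; a drop-bin mode is
available.

The model is `DV ~ time × cue` over a 0–800 ms post-disambiguation
window, with by-dyad and by-item random intercepts and slopes for both
predictors (REML; `t` statistics reported without p-values). Time is
centred on the window midpoint and scaled to seconds; coefficient
magnitudes depend on this scaling, so it is part of the model metadata.
An `"intercepts"` random structure is provided for repeated simulation
studies where the full structure would be needlessly slow. Descriptive
mean ± SE curves of the movement proportions per condition extend to
4000 ms for plotting; trial counts per bin shrink at late times as
trials end with the guesser's click.

## The synthetic generator

`dyad_config()` defaults describe the study conditions the package is
validated under: 24 dyads × 48 trials over 96 images in fixed pairs, a
truth probability of 0.539 with a by-speaker random intercept (SD 0.35,
giving the wide per-speaker spread seen in such games), per-cue base
rates matched to observed per-utterance counts (e.g. filled pauses
288/1149, silent pauses 588/1149, eye contact 130/1101), and veracity
shifts of +0.26 (filled and silent pauses) and −0.29 (adaptors) on the
logit scale. For a single binary cue the cue-given-veracity and
veracity-given-cue log odds ratios coincide, which is what makes these
shifts recoverable by the retrospective models the analysis fits. The
guesser's click follows a logistic model on the collapsed categories
(intercept 0.36; pauses −0.39; affect displays +0.29) with random
intercepts for guesser and item (SD 0.3 each); the intercept was chosen
so the marginal perceived-truth rate sits near 55.8%. Gesture-category
base rates (adaptors .45, illustrators .35, affect displays .30) are
plausible unions of the raw gesture rates; they are not separately
observable quantities.

Continuous measures come from a trivariate latent normal with
equicorrelation magnitude 0.595 (duration–pause positive, both negative
with syllable rate), so the latent correlation matrix has first
eigenvalue `1 + 2(0.595) = 2.19`. Durations are lognormal matched to
mean 3008.92 / SD 1329.35 ms; silent-pause duration is zero without a
silent-pause flag and conditionally lognormal otherwise (marginal
moments 651.65 / 1080.5 ms); syllable rate is normal 3.82 ± 1.42 s⁻¹.
The zero mass and the lognormal transforms attenuate the *observed*
correlations, so the realized first eigenvalue of the PCA sits below
2.19 (about 1.86 at the default scale); recovery tests therefore compare
against a large-sample Monte Carlo estimate of the generator's implied
observed correlation structure rather than against the latent value.

Cursor trajectories are a constant-drift-plus-noise process: the pointer
starts at screen centre, jitters (SD 3 px/sample, 50 Hz), and after the
disambiguation point plus an onset lag drifts at 250 px/s toward the
object the guesser will click, stopping at the object (the click). The
lag is 100 ms plus an exponential decision component (mean 250 ms, so
drift typically begins inside the 0–800 ms analysis window, matching the
early-commitment behaviour the analysis is designed to detect) plus
300 ms when the utterance contains a pause and 300 ms when it lacks an
affect display. This is the simplest mechanism that produces the
qualitative target pattern — a weaker early referent bias after pauses
and in the absence of affect displays — via two routes: delayed drift
onset and the cue-dependent click direction. Disambiguation points are
uniform on 20–80% of the utterance; 18.9% of trials lose their
disambiguation point; focal-cue onsets fall post-disambiguation at the
configured rates (5.3% of pause trials, 14.3% of affect trials),
generated directly rather than through an onset-process model. Gold
versus silver treasure is counterbalanced but has no generative effect.
One dyad's gesture video is marked lost by default.

What the generator does **not** emulate: the inter-cue co-occurrence
structure of real annotations (cues are conditionally independent given
veracity), double-bluff strategy dynamics, speech audio, and any
within-trial coupling between utterance content and cursor kinematics
beyond the drift-onset lags. Passing recovery tests therefore shows that
the estimators recover the effects this mechanism encodes at these
sample sizes — not that real dyad data will show those effects.

## Numerical and validation choices

* AICc requires `n > K + 1`; smaller `n` is an error, not a warning.
* Weights are computed from ΔAICc (shift-invariant by construction);
  `ER = exp(Δ/2)` holds to 1e−10 by identity.
* Complete separation in a logistic fit (runaway |β| with huge SE) is an
  error naming the predictor.
* Zero-variance grouping structures are fitted via the `random = "none"`
  route (plain ML logistic regression); the test suite checks this route
  against a hand-rolled IRLS oracle to 1e−5 and checks lmer fits against
  OLS when the random variances vanish.
* Simulation study sizes in the test suite: type-I error at 400
  replicates of n = 1500; guesser-coefficient sign recovery at 100 seeds
  of 24 dyads; point recovery at 200 dyads (±0.1); trajectory sign
  recovery at 200 seeds of 16 dyads with the intercept-only random
  structure. These sizes are the package's chosen trade-off between
  statistical resolution and a test suite that runs in minutes.
* Determinism: one seed drives the generator; fits use fixed optimizers
  and starting values, so a pipeline rerun with the same seed reproduces
  every number.

## Limitations

The random-effects grouping ("participants") is a single dyad factor;
designs where speaker and guesser cross dyads need a different grouping.
Logistic candidate models are intercept-only in their random parts by
design; users wanting random slopes in the selection stage would need to
extend `fit_cue_glmm`. The e-logit transform treats pixels as counts,
which is a convention, not a derivation; conclusions should not hinge on
`c`. Empty time bins are possible with irregular sampling and are simply
absent rows rather than imputed bins.
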