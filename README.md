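# deceptr

Analysis of speech and gesture cues to lying in interactive two-person
deception games.

In the game this package analyses, a **Speaker** sees which of two images
conceals some treasure and describes its location — truthfully or not —
while a **Guesser** clicks the image they believe hides it. Clicking the
*referent* (the image the Speaker named) indexes a truth judgement;
clicking the other image (the *distractor*) indexes a lie judgement. Each
utterance is annotated for seven disfluency types (filled pauses, silent
pauses, repetitions, restarts, substitutions, additions, prolongations),
eight gesture types grouped into four functional categories (adaptors,
illustrators, affect displays, eye contact), three continuous speech
measures, and a *disambiguation point* — the earliest moment the utterance
identifies one image. The Guesser's mouse is sampled at 50 Hz.

The package asks two questions and provides the machinery for both:

1. **Which cues do speakers produce when lying, and which do listeners
   use?** Exhaustive AICc model selection over mixed-effects logistic
   regressions of speaker veracity and guesser response.
2. **How quickly do listeners act on those cues?** A time-locked
   empirical-logit analysis of cursor trajectories after the
   disambiguation point.

## The statistics

**Model selection.** For each outcome (veracity or response, coded
1 = truth) and cue family, every additive combination of the predictors is
fitted — 2⁵ = 32 speech models (pauses, repetitions, repairs,
prolongations, speech rate) and 2⁴ = 16 gesture models (adaptors,
illustrators, affect displays, eye contact), each a logistic mixed model
with crossed random intercepts for dyads and items, estimated by maximum
likelihood (Laplace). Models are compared by the small-sample-corrected
AIC,

    AICc = −2 log L + 2K + 2K(K+1) / (n − K − 1),

and summarised by ΔAICc, Akaike weights *wᵢ* = exp(−Δᵢ/2) / Σᵣ exp(−Δᵣ/2),
evidence ratios *ERᵢ* = exp(Δᵢ/2), per-predictor cumulative weights Σ*wᵢ*,
and the competitive subset (ΔAICc < 2). Binary cues enter as presence
dummies, so exp(β) is an odds ratio; speech rate is a standardized first
principal component of utterance duration, silent-pause duration and
syllable rate.

**Trajectories.** Cursor displacement along x is accumulated in 20 ms bins
time-locked to the disambiguation point. For each bin, the proportion of
cumulative movement toward each object is transformed to an
empirical-logit difference, elogit(p_ref) − elogit(p_dist) with
elogit(p) = ln((pN + c)/((1−p)N + c)), N the total distance travelled and
c = 0.5. The DV is regressed on centred time × cue with by-dyad and
by-item random intercepts and slopes over a 0–800 ms window.

**Synthetic games.** `simulate_dyads()` generates complete games —
trial tables and cursor logs — from known parameters (truth bias, per-cue
prevalences and veracity shifts, a guesser response model, correlated
continuous measures, and a drift-plus-noise cursor model whose drift onset
is delayed by pauses and by absent affect displays), so every stage can be
validated by parameter recovery.

## Worked example

```r
library(deceptr)

sim <- simulate_dyads(dyad_config(seed = 1))
descriptives(apply_exclusions(sim$trials, "cue_models")$included)
#> Dyad-game descriptives (1147 utterances, 24 speakers)
#>   Speaker truth rate:    54.9% (SE = 1.6, min = 41.7, max = 72.9)
#>   Perceived truth rate:  54.8% (SE = 1.7, min = 39.6, max = 72.9)
#>   Discrimination accuracy: 49.3% overall; 53.7% given truth, 43.9% given lie

sel <- cue_selection("guesser_response", "speech", sim$trials)
summary(sel)
#> Best-supported speech model for guesser_response: pauses + speech_rate
#>   Akaike weight 0.212; runner-up Delta AICc = 0.44, ER = 1.25
#>   4 model(s) within 2 Delta AICc; containment:
#>        pauses   repetitions       repairs prolongations   speech_rate
#>             4             1             1             0             3
#>
#> Best-model coefficients (odds ratio = exp(beta)):
#>         term estimate     se statistic       p odds_ratio
#>  (Intercept)   0.4908 0.1121    4.3764 1.2e-05     1.6336
#>       pauses  -0.4589 0.1294   -3.5459 3.9e-04     0.6320
#>  speech_rate  -0.0965 0.0617   -1.5636 1.2e-01     0.9080
#>
#> Cumulative Akaike weights:
#>        pauses   speech_rate       repairs   repetitions prolongations
#>        0.9934        0.5515        0.2791        0.2729        0.2670

trajectory_analysis(sim$cursor, sim$trials, "pause", random = "intercepts")
#> Trajectory analysis (pause), 921 trials, window 0-800 ms post-disambiguation
#>   time x pause interaction: beta = -0.24, SE = 0.03, t = -8.13
```

Read the output as a real analysis: the winning guesser-response model
contains pauses, whose odds ratio of 0.63 says an utterance with a pause
is 0.63 times as likely to be clicked as true — guessers treat pauses as a
lie cue (the generator injected a coefficient of −0.39). Pauses dominate
the cumulative weights (0.99), and the negative time-by-pause interaction
shows the guessers' cursor bias toward the referent building more slowly
on pause trials, already within 800 ms of disambiguation.

`run_pipeline()` chains every stage (descriptives, the four selections,
both trajectory analyses) and writes all tables plus a run manifest to a
directory. To analyse recorded rather than simulated games, export the
trial table and cursor log as delimited text with the column layout of
`simulate_dyads()` output (`?read_trials`) and pass `trials_path` /
`cursor_path` to `run_pipeline()`.

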