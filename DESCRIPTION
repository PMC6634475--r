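Package: deceptr
Title: Speech and Gesture Cues to Lying in Interactive Deception Games
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing speech and gesture cues to deception in
    two-person treasure-hunt games. Provides AICc-based exhaustive model
    selection (Akaike weights, evidence ratios, cumulative parameter weights)
    over mixed-effects logistic regressions of speaker veracity and guesser
    response with crossed random intercepts for dyads and items; a
    time-locked mouse-trajectory analysis using empirical-logit regression of
    cursor movement proportions in 20 ms bins; annotation utilities
    (disfluency and gesture category collapsing, Cohen's kappa, a principal
    component speech-rate composite); and a synthetic dyad-game generator
    with known ground truth for validation and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr
Config/testthat/edition: 3
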