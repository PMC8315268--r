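Package: lipposture
Title: Anticipatory Lip Postures in Dyadic Conversation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting anticipatory speech postures in dyadic
    conversation from time-aligned utterance annotations and facial landmark
    tracks. Classifies utterances into turn-exchange types (restart, gap,
    between-overlap, within-overlap) with floor transfer offsets, codes
    utterances as labially constrained or unconstrained from the first
    syllable of the first word via a pronunciation lexicon, computes
    pre-acoustic lip-area trajectories from OpenFace-layout landmark tracks,
    and fits time-sliced moderated linear mixed-effects models with
    Satterthwaite degrees of freedom, Johnson-Neyman regions and bootstrap
    prediction intervals. A synthetic dyad generator with known ground truth
    supports end-to-end validation without access-restricted corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
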