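---
title: "Detecting anticipatory lip postures in dyadic conversation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting anticipatory lip postures in dyadic conversation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipposture)
```

## The scientific question

When two people converse, turns are exchanged with remarkably small
downtime. One way a listener can prepare their next utterance is to
position the articulators ahead of time: if the upcoming utterance begins
with a bilabial, labiodental or rounded segment, the lips must form a
small aperture, and that configuration can in principle be assumed long
before any sound is produced. `lipposture` implements an analysis chain
that looks for exactly this signature in dyadic conversation data: lip
areas measured from facial video should diverge between *labially
constrained* and *labially unconstrained* utterances before the acoustic
onset, and the divergence should reach further back in time for shorter
utterances, which are presumably planned earlier relative to their
delivery.

The pipeline consumes three kinds of input:

* time-aligned utterance annotations (speaker, acoustic onset and offset
  in ms, transcript), in a tab-separated dialect or ELAN `.eaf` files;
* per-speaker facial landmark tracks in the OpenFace 2.0 CSV layout at
  30 fps (only lip landmarks 48–67 are used; 48/54 are the lip corners,
  51/57 the outer top/bottom centres);
* a pronunciation lexicon in the CMU dictionary dialect, used to code the
  first syllable of each utterance's first word.

## Utterance typing

For every utterance the *reference* is the most recently initiated prior
utterance, whether or not it has finished. A same-speaker reference makes
the current utterance a **restart**, as does an other-speaker reference
that was itself initiated within 500 ms of the current speaker's own
prior initiation. Restarts and the conversation-initial utterance are
expunged: the analysis concerns inter-speaker coordination. The remaining
responses carry a floor transfer offset, `FTO = onset(current) −
offset(reference)`, and are subtyped **gap** (FTO ≥ 0), **between-overlap**
(FTO < 0 but the response outlasts the reference) or **within-overlap**
(the response lies wholly inside the reference's acoustic span).

Two boundary conventions are deliberate. An FTO of exactly zero counts as
a gap: a zero-gap floor transfer is not an overlap. And because a
within-overlap's FTO is measured against the reference's *eventual*
offset, a backchannel placed early in a long turn can carry an extreme
negative FTO (minutes-long turns give values near −100 s); FTO summaries
therefore cover gaps and between-overlaps only.

## Labial coding

An utterance is **labially constrained** when its first word's first
syllable forces a small lip aperture: the syllable-initial consonant is
one of /b f m p ɹ v w/ (ARPABET `B F M P R V W`), or — checked second —
the first nuclear vowel is rounded, one of /ɔ o ʊ u/ (`AO OW UH UW`).
Diphthongs are judged on their nucleus, so `OW` and `OY` count as rounded
while `AW` does not. In an onset cluster only the first consonant is
tested (`spin` is coded from /s/, not /p/). Vowel-initial words are
judged on the vowel alone. Stress digits are stripped; lookups are
case-folded with flanking punctuation removed and internal apostrophes
kept (`that's` is one word). A small lexicon covering the bundled
vocabulary ships with the package; full CMU-style dictionaries load with
`readPronLexicon()`, and a two-column override table handles
out-of-lexicon items.

```{r}
lex <- readPronLexicon()
codeConstraint("no", lex)     # rounded nucleus
codeConstraint("which", lex)  # labial onset
codeConstraint("yeah", lex)   # neither rule fires
```

## Lip area and epochs

Lip area is computed per video frame from the outer-lip quad (landmarks
48, 51, 54, 57), walked clockwise from the left corner. Each perimeter
segment is treated as the hypotenuse of a right triangle and a residual
central rectangle is added:

$$A = \sum_{i=1}^{4}\frac{|X_i-X_{i+1}|\,|Y_i-Y_{i+1}|}{2}
      \;+\; |X_1-X_3|\,|Y_2-Y_4|, \qquad (X_5,Y_5)\equiv(X_1,Y_1).$$

This is **not** the true polygon area: for a convex quad with extremal
vertices it equals `2·boundingBox − shoelace`, a monotone inflation of
the shoelace area. It is nevertheless the package's primary metric,
because the inference rests entirely on within-speaker contrasts, which a
monotone inflation preserves; `shoelaceArea()` is exposed as an
explicitly non-default alternative, and the identity above is enforced in
the test suite. Both formulas take absolute values, so y-down pixel
coordinates need no axis flip.

For each retained utterance a 90-frame (3000 ms at 30 fps) epoch is
extracted: the anchor is the last frame strictly before the acoustic
onset (half-open window, "preceding the acoustic onset"), and epoch index
0 sits 90 frame durations before onset. Tracking dropouts
(`success = 0`) are linearly interpolated when a run is at most 3 frames
long — the filled frames stay flagged in the missing mask — and left
missing otherwise; the affected utterance simply drops out of the slices
that touch unfilled frames.

## Time-sliced inference

Models are fit at 15-frame (500 ms) intervals from −3000 ms to acoustic
onset (the onset slice uses the final pre-onset frame). At each slice:

$$\text{area} \sim \text{constraint} \times \log_{10}(\text{word count})
  + \text{random terms},$$

with the constraint dummy coded 0 = constrained, 1 = unconstrained, so a
*positive* constraint coefficient means a larger aperture for
unconstrained utterances — the posture signature. Word counts are
log10-transformed against their extreme positive skew. Clustering
factors are speaker id and the utterance's first word. The random
structure is chosen by a deterministic backward selection that starts
from a maximal structure and simplifies until a fit converges without
singularity, dropping in order (1) slope/intercept correlations, (2) the
random slope with the smallest estimated variance, (3) the random
intercept of the factor with the fewest levels; if everything fails the
model falls back to OLS with a loud warning. Fixed-effect tests use
Satterthwaite denominator degrees of freedom (REML fits via `lme4`, df
via `lmerTest`).

When a slice's interaction is reliable, the package computes a
**Johnson-Neyman region**: the moderator range over which the simple
slope of constraint, $s(w) = \beta_1 + \beta_3 w$ with variance
$V_{11} + w^2V_{33} + 2wV_{13}$, is significantly *positive*. Boundaries
solve $|s(w)| = t_{\text{crit}}(\nu(w))\,\mathrm{se}(w)$ by bisection
after a dense bracketing scan; by default the critical value uses the
per-point Satterthwaite df of the simple-slope contrast ($\nu$
recomputed at every candidate $w$; a fixed-df variant is available).
Regions are intersected with the observed moderator span and reported
both in log10 units and as word counts. An empty region is a valid
result, not an error. No multiple-testing correction is applied across
the seven slices; this mirrors the reporting convention the analysis
follows and is a known caveat.

Prediction intervals (e.g. for constrained vs unconstrained utterances of
2 and 8 words) come from a parametric bootstrap: the response is
re-simulated from the fitted model, the model refit and the
population-level prediction recomputed; intervals are percentile-based
and seed-reproducible. Maximum lip movement speed is the largest absolute
first difference of area over the final 15 steps of the epoch, scaled by
the frame rate to units²/s, and is modelled with the same fixed-effects
structure.

## The synthetic dyad generator

The source corpus for this kind of analysis is typically
access-restricted, so the package ships a generator whose ground truth is
known exactly, making the whole chain testable end to end.

```{r}
cfg <- simConfig(nDyads = 2, utterancesPerDyad = 20, seed = 1)
conv <- generateCorpus(cfg)
head(conv$truth[, c("speaker_id", "onset_ms", "offset_ms", "word",
                    "word_count", "planted_type", "constraint")])
```

Two speakers exchange utterances realising a planted multinomial over
gaps, between-overlaps and within-overlaps (the reference mix is
47/22/30, and the planted counts are preserved exactly by a constrained
arrangement of the drawn type sequence). Floor transfer offsets are drawn
from N(258, 915²) ms, truncated by type. Word counts are
shifted-lognormal with a teller/acknowledger rhythm: minimal (1–2 word)
responses follow substantive (≥ 8 word) turns and vice versa, and
within-overlaps are 1–2-word backchannels placed in the closing 400 ms of
a ≥ 10-word host turn — both a recognisable conversational regularity and
the arrangement that gives short utterances the quiet spans their long
postures need (see below). Same-speaker re-initiations are injected at
10% to exercise the restart-exclusion path.

Each speaker's lip-area signal is the idealisation the analysis assumes:
it holds at a baseline (speaker random intercept, SD 70 units²; a
by-speaker random slope on log10 word count, SD 25, modulates the level
before each utterance) plus stationary AR(1) noise (ρ = 0.9, SD 15), and
ramps linearly to a smaller constrained target before labially
constrained utterances. The ramp starts `lead(wc)` before onset with

$$\text{lead}(wc) = \max\{250, 3000\,e^{-\kappa(wc-1)}\}\ \text{ms},
  \qquad \kappa = \ln(3)/2,$$

so 1-word utterances lead by 3000 ms and 3-word utterances by about
1000 ms; the 250 ms floor reflects the minimum articulatory-to-acoustic
lead time reported in the speech-production literature. The target is
held for the final 100 ms before onset: a posture must be fully formed
slightly before the sound it enables, and without the hold the last
pre-onset frame (up to 33 ms before onset) would sit mid-ramp for
short-lead utterances, planting a spurious interaction at the onset
slice. A posture can only begin once the speaker's previous utterance has
ended, so the ramp's support is clipped 50 ms after the previous offset
while its shape is preserved (`leadPolicy = "error"` instead raises a
constraint violation listing the affected utterances). Landmarks are
synthesised as a diamond whose vertical extent is solved against the
*printed* area formula, so the pipeline's primary metric recovers the
planted area sequence exactly; a slow sinusoidal head sway checks
translation invariance in passing, and a small tracking-failure rate
(0.2%) exercises the fill policy.

`plantedEffectSurface()` gives the closed-form expected
unconstrained-minus-constrained contrast at any slice × word count,
assuming a free pre-onset interval:

```{r}
round(plantedEffectSurface(simConfig(), word_counts = c(1, 2, 3, 8)), 1)
```

### Why these defaults

The defaults were fixed once, by design analysis, and then frozen. The
posture depth (baseline 1600 → target 1000 units², a ~37% reduction of
the outer-lip quad area, consistent with strong rounding or closure) and
the noise scales were chosen so that the planted signature is detectable
in at least 90% of replicates at every slice where the ramp geometry puts
signal — the calibration the package's validation suite demands. Three
structural facts about the geometry drove the remaining choices:

* At −3000 ms, the earliest slice, the planted contrast is *identically
  zero*: the slice frame sits at most one frame duration inside the
  longest (1-word, 3000 ms) ramp, so the expected effect there is below
  1% of the posture depth. No estimator can detect it, and the validation
  suite requires detection only from −2500 ms onwards, asserting the
  boundary nullity instead.
* At −2500 ms only 1-word utterances carry signal (2-word leads are
  1732 ms), so the corpus must supply 1-word utterances with at least
  2.5 s of own-track quiet before them; the teller/acknowledger rhythm
  provides them. Without it, ramps truncate against the speaker's own
  previous utterance and detection at that slice plateaus around 75%
  regardless of posture depth.
* Requiring the onset-slice interaction to be non-significant *in every
  replicate* would cap success at ~95% by construction (it is a true
  null tested at α = 0.05); the suite therefore asserts it in aggregate
  — the rejection count over 100 replicates must stay within the
  binomial 95% bound.

The generator plants no word-level variance by default. Experiments with
a word-level random intercept (the `tauWord` parameter) showed a real
hazard worth knowing about: epochs that cross a segment boundary carry
the *previous* word's level, which attenuates apparent between-word
variance exactly where the constraint contrast — a between-word
comparison — lives, and the slice models then reject a true null
constraint effect at 2–4× the nominal rate at early slices. With
`tauWord = 0` the measured per-slice type-I error is 2–5% (mildly
conservative if anything, because the backward selection occasionally
retains a spuriously positive word-intercept variance).

### What the generator does and does not emulate

It emulates the data *shapes* (annotation tables, OpenFace-layout tracks,
the retention accounting of roughly 400 annotated → ~350 retained
utterances over 6 speakers in 8 dyads) and the hypothesised posture
process. It does not emulate: within-speech area dynamics (the signal
returns to baseline during phonation — real lips do not), head-pose
tracking error, word-specific articulatory settings (see above), lead
*variability* around the deterministic lead(wc) law, or accent
differences. Passing recovery tests therefore show that the pipeline
detects the planted process under its own assumptions — they cannot show
that real conversational postures follow an exponential-decay lead law,
which remains a modelling convenience.

## Numerical conventions

* Time base: annotations are integer ms; OpenFace timestamps (seconds)
  are converted to ms at read time.
* Slice → frame mapping: `round((offset + 3000) · fps/1000)`, with the
  onset slice clipped to the final pre-onset frame (index 89).
* Maximum speed uses 15 first differences over the final 16 frames (the
  other reading — 14 differences among 15 frames — is noted as an
  interpretation choice and not implemented).
* Convergence/singularity: lme4's convergence diagnostics plus
  `isSingular(tol = 1e-4)`; degenerate fits are reported, never silently
  accepted.
* Identical onsets across speakers raise an error unless a tie-break
  policy is set; silent choices would bias typing.
* All randomness (generator, bootstrap) flows from a single seed;
  per-conversation substreams are drawn from the corpus seed.

## Problem sizes used by the validation suite

The test suite regenerates everything it needs: 1000 random quads for the
area identity, 500 random conversations against a brute-force typing
oracle, 10 000-point grid scans against the Johnson-Neyman solver, 100
recovery corpora and 200 null corpora of ~400 utterances each for the
calibration study, and a 120-replicate coverage check of the bootstrap
intervals. These sizes were chosen to keep Monte-Carlo error comfortably
below the assertion margins.

## Known limitations

* The printed area formula inflates true polygon area; only
  within-speaker contrasts are interpretable, never absolute apertures.
* No correction across the seven slice models.
* The 500-ms restart window is measured initiation-to-initiation.
* Johnson-Neyman boundaries assume the fitted covariance is adequate at
  every moderator value; with very small cluster counts the per-point df
  can be noisy (the fixed-df option trades that noise for bias).
* The generator's lead law and the teller/acknowledger rhythm are
  conveniences; recovery results are conditional on them.
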