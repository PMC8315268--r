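# lipposture

Detects **anticipatory speech postures** in dyadic conversation: moments
when a listener, awaiting their turn, already shapes their lips for the
upcoming utterance long before any sound is produced. The package takes
time-aligned utterance annotations and facial-landmark tracks (OpenFace
2.0 CSV layout, 30 fps), and asks whether utterances whose first syllable
is *labially constrained* — initial consonant in /b f m p ɹ v w/ or a
rounded nuclear vowel in /ɔ o ʊ u/ — show smaller lip areas than
unconstrained utterances in the seconds before their acoustic onset, and
whether that contrast reaches further back in time for shorter
utterances.

The analysis chain:

1. **Utterance typing** — each utterance's reference is the most recently
   *initiated* prior utterance. Same-speaker references (or references
   initiated within 500 ms of the speaker's own prior initiation) mark
   restarts, which are expunged along with conversation-initial
   utterances. Responses get a floor transfer offset
   (FTO = onset − reference offset) and a subtype: gap, between-overlap,
   or within-overlap.
2. **Labial coding** — the first syllable of the first word is coded
   constrained/unconstrained through a CMU-dialect pronunciation lexicon
   (small lexicon bundled; overrides supported).
3. **Lip kinematics** — per-frame lip area from outer-lip landmarks
   48/51/54/57 via the four-right-triangles-plus-rectangle rule
   A = Σ|Xi−Xi+1||Yi−Yi+1|/2 + |X1−X3||Y2−Y4| (the surveyor's formula is
   available as an alternative), 90-frame pre-onset epochs, and maximum
   lip movement speed (largest |Δarea|·fps over the final 15 steps).
4. **Time-sliced inference** — at 500-ms slices from −3000 ms to onset,
   REML mixed models `area ~ constraint × log10(word count)` with
   speaker and first-word clustering, deterministic backward selection of
   the random structure, Satterthwaite degrees of freedom,
   Johnson-Neyman regions for the moderated constraint slope, and
   parametric-bootstrap prediction intervals.
5. **Synthetic dyads** — a generator with exact ground truth (planted
   turn-type mix, FTO law, posture ramps with word-count-dependent lead
   times) so the full chain is testable without access-restricted
   corpora.

## Worked example

```r
library(lipposture)

# simulate a small corpus with known ground truth, then analyze it
cfg    <- simConfig(seed = 1)            # 8 dyads, 6 speakers, ~400 utterances
corpus <- generateCorpus(cfg)
res    <- analyzeCorpus(corpus$utterances, corpus$tracks,
                        maximal = list(randomTerm("speaker_id", "log10_wc"),
                                       randomTerm("first_word")))
res
```

```
<posture_pipeline_result>
  utterances: 417 total, 18 restarts + 8 initials expunged -> 391 retained
  response mix: gap 49%, between-overlap 24%, within-overlap 27%
  floor transfer offset: mean 499.72 ms (SD 810.75, n 286)
<slice_results> 7 slices, alpha = 0.05
   -3000 ms  random: (1 + log10_wc | speaker_id) + (1 | first_word)  constraint b=   2.97 (p=0.669)     interaction b=  -7.11 (p=0.308)
   -2500 ms  random: (1 + log10_wc | speaker_id) + (1 | first_word)  constraint b=  63.80 (p=2.11e-05)  interaction b= -74.97 (p=1.97e-07)   JN wc [1.00, 3.97]
   -2000 ms  random: (none)                                          constraint b= 165.44 (p=2.05e-28)  interaction b=-170.24 (p=2.43e-22)   JN wc [1.00, 7.63]
   -1500 ms  random: (1 + log10_wc | speaker_id) + (1 | first_word)  constraint b= 238.68 (p=3.96e-11)  interaction b=-230.64 (p=6.84e-38)   JN wc [1.00, 9.45]
   -1000 ms  random: (1 + log10_wc | speaker_id) + (1 | first_word)  constraint b= 348.74 (p=8.44e-35)  interaction b=-338.68 (p=2.44e-78)   JN wc [1.00, 9.29]
    -500 ms  random: (1 | speaker_id) + (1 | first_word)             constraint b= 512.83 (p=4.97e-54)  interaction b=-470.38 (p=3.53e-124)  JN wc [1.00, 11.19]
       0 ms  random: (1 + log10_wc | speaker_id) + (1 | first_word)  constraint b= 605.31 (p=1.09e-51)  interaction b=  -3.70 (p=0.302)
  max speed ~ word count: beta 3641.27 (SE 157.24, t(268.9) = 23.16, p = 5.48e-66)
```

Reading the output: the constraint coefficient is the lip-area advantage
(units²) of unconstrained over constrained utterances for a one-word
utterance (the dummy is 0 = constrained, so positive values signal a
posture); the interaction is how that advantage changes per log10 word
count (negative: postures fade for longer utterances); the JN interval is
the word-count range over which the posture contrast is significantly
positive. Here the planted posture (depth 600 units², lead shrinking from
3000 ms at one word to ~1000 ms at three) is recovered: nothing at
−3000 ms (the planted contrast at the ramp-start boundary is zero), a
moderated contrast from −2500 ms onward over roughly 1–4 words at the
earliest informative slice, and at onset a large main effect with no
moderation. Lip movement speed rises with word count, as the shrinking
lead forces faster closing gestures.

File-based corpora work the same way through `runPipeline()` (reads
annotation TSV/EAF and OpenFace CSVs, writes result tables and a
manifest); `inst/scripts/posture-pipeline.R` wraps it as a small CLI
(`run` / `simulate` / `validate`).

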