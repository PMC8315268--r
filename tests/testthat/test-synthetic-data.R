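test_that("generation is deterministic in the seed", {
  c1 <- generateCorpus(simConfig(nDyads = 2L, utterancesPerDyad = 20L,
                                 seed = 77))
  c2 <- generateCorpus(simConfig(nDyads = 2L, utterancesPerDyad = 20L,
                                 seed = 77))
  expect_identical(c1$utterances, c2$utterances)
  expect_identical(lapply(c1$tracks, `[[`, "frames"),
                   lapply(c2$tracks, `[[`, "frames"))
  c3 <- generateCorpus(simConfig(nDyads = 2L, utterancesPerDyad = 20L,
                                 seed = 78))
  expect_false(identical(c1$utterances, c3$utterances))
})

test_that("planted types and FTOs are reproduced by the classifier", {
  corpus <- generateCorpus(simConfig(nDyads = 4L, seed = 13))
  typed <- do.call(rbind, lapply(
    split(corpus$utterances, corpus$utterances$conversation_id),
    classifyUtterances))
  expect_equal(as.character(typed$utterance_type),
               corpus$truth$planted_type)
  resp <- typed$retained
  expect_equal(typed$fto_ms[resp], round(corpus$truth$planted_fto[resp]),
               tolerance = 1.001)
  # one initial per conversation
  expect_equal(as.vector(tapply(typed$utterance_type == "initial",
                                typed$conversation_id, sum)),
               rep(1L, 4L))
})

test_that("planted response proportions are recovered", {
  cfg <- simConfig(nDyads = 1L, utterancesPerDyad = 501L, seed = 5,
                   typeProportions = c(0.5, 0.2, 0.3))
  conv <- generateConversation(cfg, seed = 5)
  typed <- classifyUtterances(conv$utterances[
    c("speaker_id", "onset_ms", "offset_ms", "transcript")])
  p <- responseTypeProportions(typed)
  # binomial 95% band around the planted multinomial probabilities
  n <- sum(typed$retained)
  for (i in 1:3) {
    expect_lt(abs(p[i] - c(0.5, 0.2, 0.3)[i]),
              2.5 * sqrt(c(0.5, 0.2, 0.3)[i] *
                           (1 - c(0.5, 0.2, 0.3)[i]) / n))
  }
})

test_that("realised FTO law matches the planted normal when feasible", {
  # gap/between split at the normal law's own positive mass, no
  # within-overlaps: the planted FTO mixture is then N(250, 900^2)
  w <- pnorm(250 / 900)
  cfg <- simConfig(nDyads = 1L, utterancesPerDyad = 320L, seed = 8,
                   ftoMeanMs = 250, ftoSdMs = 900,
                   typeProportions = c(w, 1 - w, 0))
  conv <- generateConversation(cfg, seed = 8)
  typed <- classifyUtterances(conv$utterances[
    c("speaker_id", "onset_ms", "offset_ms", "transcript")])
  s <- ftoSummary(typed)
  expect_gt(s$n, 250)
  expect_lt(abs(s$mean_ms - 250), 3 * 900 / sqrt(s$n))
})

test_that("planted effect surface follows the ramp geometry", {
  cfg <- simConfig()
  delta <- cfg$baselineArea - cfg$constrainedTarget
  s <- plantedEffectSurface(cfg, offsets_ms = c(-3000, -1500, 0),
                            word_counts = c(1, 3, 8))
  # ramp start boundary: zero effect at -Lmax for 1-word utterances
  expect_equal(s["-3000", "1"], 0)
  # ramp endpoint: full contrast at acoustic onset for every word count
  expect_equal(unname(s["0", ]), rep(delta, 3))
  # lead(3) = 1000 ms: nothing planted at -1500 for 3-word utterances
  expect_equal(s["-1500", "3"], 0)
  expect_gt(s["-1500", "1"], 0)

  # kappa -> infinity: postures distinguish the groups only at the last
  # slices (lead collapses to the articulatory floor for wc > 1)
  cfg2 <- simConfig(kappa = 50)
  s2 <- plantedEffectSurface(cfg2, offsets_ms = seq(-3000, 0, 500),
                             word_counts = 2:6)
  expect_true(all(s2[as.character(seq(-3000, -500, 500)), ] == 0))
  expect_true(all(s2["0", ] == delta))
})

test_that("noise-free epochs equal the planted ramp exactly", {
  cfg <- simConfig(nDyads = 1L, utterancesPerDyad = 30L, seed = 3,
                   noiseSd = 0, tauIntercept = 0, tauSlope = 0,
                   tauWord = 0, dropoutRate = 0)
  conv <- generateConversation(cfg, seed = 3)
  typed <- codeCorpus(classifyUtterances(conv$utterances[
    c("speaker_id", "onset_ms", "offset_ms", "transcript")]))
  typed$conversation_id <- "c1"
  eb <- buildEpochTable(typed, conv$tracks)
  ep <- eb$epochs

  tr <- conv$truth
  tr$own_prev_offset <- ave(tr$offset_ms, tr$speaker_id,
                            FUN = function(o) c(-Inf, head(o, -1)))
  delta <- cfg$baselineArea - cfg$constrainedTarget
  kept <- typed[typed$retained, ]
  kept$utterance_id <- sprintf("c1_u%04d", seq_len(nrow(kept)))
  checked <- 0L
  for (uid in unique(ep$utterance_id)) {
    e <- ep[ep$utterance_id == uid, ]
    e <- e[order(e$frame_index), ]
    row <- kept[kept$utterance_id == uid, ]
    t_row <- tr[tr$onset_ms == row$onset_ms &
                  tr$speaker_id == row$speaker_id, ]
    # only utterances with a free pre-onset interval carry the full ramp
    if (t_row$onset_ms - t_row$own_prev_offset < 3500) next
    ts <- conv$tracks[[paste0("c1/", row$speaker_id)]]$frames$timestamp_ms
    anchor <- sum(ts < t_row$onset_ms)
    frame_t <- ts[(anchor - 89):anchor]
    expected <- rep(cfg$baselineArea, 90)
    if (t_row$constraint == "constrained") {
      lead <- t_row$lead_ms
      phi <- pmin(1, pmax(0, (lead - (t_row$onset_ms - frame_t)) /
                               (lead - cfg$holdMs)))
      expected <- expected - delta * phi
    }
    expect_equal(e$area, expected, tolerance = 1e-6)
    checked <- checked + 1L
  }
  expect_gt(checked, 3L)
})

test_that("generator vocabulary labels agree with the bundled lexicon", {
  lex <- readPronLexicon()
  voc <- defaultVocabulary()
  coded <- vapply(voc$word, function(w) codeConstraint(w, lex)$value, "")
  expect_equal(unname(coded), voc$constraint)
})

test_that("strict lead policy raises the constraint-violation error", {
  cfg <- simConfig(nDyads = 1L, seed = 2, leadPolicy = "error")
  expect_error(generateConversation(cfg, seed = 2),
               "constraint violation.*lead exceeds")
})

test_that("written corpora parse back through the package readers", {
  dir <- withr::local_tempdir()
  cfg <- simConfig(nDyads = 1L, utterancesPerDyad = 16L, seed = 44)
  corpus <- generateCorpus(cfg)
  simulateCorpus(cfg, dir, corpus = corpus)

  rec <- readUtteranceTier(file.path(dir, "c01_utterances.tsv"))
  expect_equal(nrow(rec), nrow(corpus$utterances))
  expect_equal(rec$onset_ms, corpus$utterances$onset_ms)

  key <- names(corpus$tracks)[1]
  trk <- readOpenFaceCsv(file.path(dir, paste0(gsub("/", "_", key),
                                               "_openface.csv")))
  expect_equal(nrow(trk$frames), nrow(corpus$tracks[[key]]$frames))
  # written coordinates are rounded to 3 decimals; areas survive within
  # the implied tolerance
  a_mem <- lipArea(c(
    corpus$tracks[[key]]$frames$x48[1], corpus$tracks[[key]]$frames$y48[1],
    corpus$tracks[[key]]$frames$x51[1], corpus$tracks[[key]]$frames$y51[1],
    corpus$tracks[[key]]$frames$x54[1], corpus$tracks[[key]]$frames$y54[1],
    corpus$tracks[[key]]$frames$x57[1], corpus$tracks[[key]]$frames$y57[1]))
  a_disk <- lipArea(c(trk$frames$x48[1], trk$frames$y48[1],
                      trk$frames$x51[1], trk$frames$y51[1],
                      trk$frames$x54[1], trk$frames$y54[1],
                      trk$frames$x57[1], trk$frames$y57[1]))
  expect_equal(a_disk, a_mem, tolerance = 1e-3)

  truth <- jsonlite::read_json(file.path(dir, "sim_truth.json"),
                               simplifyVector = TRUE)
  expect_equal(nrow(truth), nrow(corpus$truth))
})
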