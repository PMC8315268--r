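## Synthetic dyadic conversation generator with known ground truth.
##
## Emulates the study's data shapes: two speakers exchange utterances whose
## timing realises a planted mix of gaps, between-overlaps and
## within-overlaps (backchannels inside a long host turn), with occasional
## same-speaker re-initiations (restarts); each speaker's lip-area signal
## sits at a speaker- and word-conditioned baseline with AR(1) noise, and
## ramps linearly toward a smaller constrained target before the acoustic
## onset of labially constrained utterances. The ramp starts lead(wc) ms
## before onset, where lead(wc) = max(min_lead, Lmax * exp(-kappa*(wc-1)))
## shrinks with utterance word count, and the target is held for the final
## hold_ms before onset (a posture must be in place slightly before the
## sound it enables). Landmarks 48/51/54/57 are synthesised as a diamond
## whose vertical extent is solved so that the *printed* area formula
## reproduces the planted area sequence exactly.

#' Simulation configuration
#'
#' Defaults define the package's reference study conditions: 8 dyads drawn
#' from 6 speakers, 50 utterances per dyad (roughly 350 retained responses
#' after restarts and initials are expunged), response-type mix 47/22/30,
#' floor transfer offsets from N(258, 915^2) ms truncated by type, heavily
#' right-skewed word counts, and an anticipatory posture with maximal lead
#' 3000 ms decaying so that 3-word utterances lead by about 1000 ms.
#' Area units are squared track units on a millimetre-like scale.
#'
#' @param nDyads Number of dyadic conversations.
#' @param utterancesPerDyad Planned (non-restart) utterances per dyad,
#'   including the conversation-initial one.
#' @param nSpeakers Speaker pool size; dyad pairings cycle through the pool.
#' @param fps Video frame rate.
#' @param ftoMeanMs,ftoSdMs Normal law for floor transfer offsets before
#'   type-specific truncation.
#' @param typeProportions Planted multinomial over gap, between_overlap,
#'   within_overlap (normalised internally).
#' @param wordCountMeanlog,wordCountSdlog,wcMax Shifted-lognormal word-count
#'   law: `wc = min(max(1, round(rlnorm(...))), wcMax)`.
#' @param vocabulary Data frame `word`, `constraint`, `freq`, `backchannel`;
#'   labels must agree with the bundled lexicon's coding (see
#'   [defaultVocabulary()]).
#' @param baselineArea Baseline lip area A0 (units^2).
#' @param constrainedTarget Constrained-posture target area A1 < A0; set
#'   equal to `baselineArea` for a null (no-posture) generator.
#' @param maxLeadMs Maximal posture lead Lmax (<= 3000).
#' @param kappa Lead decay rate: `lead(wc) = Lmax * exp(-kappa * (wc - 1))`.
#' @param minLeadMs Floor on the lead (articulatory-to-acoustic lead time).
#' @param holdMs Target-hold duration immediately before onset.
#' @param tauIntercept,tauSlope SDs of by-speaker random intercept and
#'   log10-word-count slope on the baseline area.
#' @param tauWord SD of by-first-word random shifts on the baseline area.
#' @param arRho,noiseSd AR(1) coefficient and *stationary* SD of the
#'   frame-level area noise.
#' @param leadPolicy What to do when a constrained utterance's nominal lead
#'   reaches back into the speaker's previous utterance: `"truncate"`
#'   (default) starts the posture only after the previous utterance ends,
#'   keeping the ramp's shape where supported; `"error"` raises a
#'   constraint-violation error listing the offending utterances.
#' @param speechAmp,speechOpen Amplitude and mean lift of an optional area
#'   modulation while a speaker is talking (default 0: the generator is the
#'   idealisation in which the signal holds at its baseline except during
#'   pre-onset ramps; see the methods vignette).
#' @param wordMs,durSdMs Utterance duration law: `wc * wordMs` plus noise.
#' @param restartRate Probability of injecting a same-speaker re-initiation
#'   after an utterance (exercises the restart-exclusion path).
#' @param dropoutRate Per-frame probability of a tracking failure
#'   (success = 0).
#' @param startMs Acoustic onset of the first utterance (track time 0 is
#'   recording start; must exceed the epoch length).
#' @param lipWidthMm Lip-corner distance used in landmark synthesis.
#' @param seed Corpus-level seed.
#' @return A `sim_config` list.
#' @export
simConfig <- function(nDyads = 8L, utterancesPerDyad = 50L, nSpeakers = 6L,
                      fps = 30,
                      ftoMeanMs = 258, ftoSdMs = 915,
                      typeProportions = c(gap = 47, between_overlap = 22,
                                          within_overlap = 30) / 99,
                      wordCountMeanlog = 0.8, wordCountSdlog = 0.9,
                      wcMax = 20L,
                      vocabulary = defaultVocabulary(),
                      baselineArea = 1600, constrainedTarget = 1000,
                      maxLeadMs = 3000, kappa = log(3) / 2,
                      minLeadMs = 250, holdMs = 100,
                      tauIntercept = 70, tauSlope = 25, tauWord = 0,
                      arRho = 0.9, noiseSd = 15,
                      leadPolicy = c("truncate", "error"),
                      speechAmp = 0, speechOpen = 0,
                      wordMs = 330, durSdMs = 60,
                      restartRate = 0.10, dropoutRate = 0.002,
                      startMs = 3600, lipWidthMm = 55,
                      seed = 1L) {
  stopifnot(constrainedTarget <= baselineArea, maxLeadMs <= 3000,
            holdMs < minLeadMs, nSpeakers >= 2L,
            all(typeProportions >= 0), sum(typeProportions) > 0)
  cfg <- as.list(environment())
  cfg$leadPolicy <- match.arg(leadPolicy)
  cfg$typeProportions <- typeProportions / sum(typeProportions)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> %d dyads x %d utterances, %d speakers; ",
                     "posture %g -> %g over lead up to %g ms\n"),
              x$nDyads, x$utterancesPerDyad, x$nSpeakers, x$baselineArea,
              x$constrainedTarget, x$maxLeadMs))
  invisible(x)
}

#' Default generator vocabulary
#'
#' First words with their labial-constraint labels (agreeing with the
#' bundled lexicon), relative frequencies loosely following the frequency
#' profile of short conversational utterances, and a backchannel flag
#' marking words eligible to open a within-overlap.
#'
#' @return Data frame `word`, `constraint`, `freq`, `backchannel`.
#' @export
defaultVocabulary <- function() {
  tab <- rbind(
    c("yeah", "unconstrained", 30, TRUE),
    c("okay", "constrained", 12, TRUE),
    c("right", "constrained", 9, TRUE),
    c("no", "constrained", 8, TRUE),
    c("mmhmm", "constrained", 6, TRUE),
    c("oh", "constrained", 5, TRUE),
    c("yes", "unconstrained", 5, TRUE),
    c("yep", "unconstrained", 4, TRUE),
    c("sure", "constrained", 3, TRUE),
    c("really", "constrained", 4, TRUE),
    c("i", "unconstrained", 16, FALSE),
    c("the", "unconstrained", 8, FALSE),
    c("so", "constrained", 9, FALSE),
    c("well", "constrained", 7, FALSE),
    c("and", "unconstrained", 8, FALSE),
    c("but", "constrained", 7, FALSE),
    c("it", "unconstrained", 7, FALSE),
    c("that's", "unconstrained", 6, FALSE),
    c("you", "constrained", 6, FALSE),
    c("we", "constrained", 5, FALSE),
    c("they", "unconstrained", 5, FALSE),
    c("this", "unconstrained", 4, FALSE),
    c("what", "constrained", 4, FALSE),
    c("there", "unconstrained", 4, FALSE),
    c("he", "unconstrained", 4, FALSE),
    c("she", "unconstrained", 3, FALSE),
    c("maybe", "constrained", 3, FALSE),
    c("how", "unconstrained", 3, FALSE),
    c("when", "constrained", 2, FALSE),
    c("actually", "unconstrained", 2, FALSE))
  data.frame(word = tab[, 1L], constraint = tab[, 2L],
             freq = as.numeric(tab[, 3L]), backchannel = as.logical(tab[, 4L]),
             stringsAsFactors = FALSE)
}

#' Posture lead time as a function of word count
#'
#' @param wc Word count(s).
#' @param config A [simConfig()].
#' @return Lead time(s) in ms.
#' @export
leadMs <- function(wc, config) {
  pmax(config$minLeadMs,
       config$maxLeadMs * exp(-config$kappa * (wc - 1)))
}

#' Planted constraint-effect surface
#'
#' Closed-form expectation of the (unconstrained - constrained) lip-area
#' difference at given offsets before acoustic onset, per word count: the
#' ramp geometry gives effect = Delta * phi(offset), where phi rises
#' linearly from 0 at `-lead(wc)` to 1 at `-holdMs` and stays 1 through
#' onset.
#'
#' @param config A [simConfig()].
#' @param offsets_ms Offsets relative to onset (<= 0).
#' @param word_counts Word counts.
#' @return Matrix `length(offsets_ms)` x `length(word_counts)` of expected
#'   effects, dimnames set accordingly.
#' @export
plantedEffectSurface <- function(config, offsets_ms = seq(-3000, 0, 500),
                                 word_counts = 1:10) {
  delta <- config$baselineArea - config$constrainedTarget
  out <- outer(offsets_ms, word_counts, function(o, wc) {
    lead <- leadMs(wc, config)
    phi <- (lead + o) / (lead - config$holdMs)
    delta * pmin(1, pmax(0, phi))
  })
  dimnames(out) <- list(offset_ms = offsets_ms, word_count = word_counts)
  out
}

## ---- timeline construction ---------------------------------------------

rtruncnorm1 <- function(mean, sd, lower = -Inf, upper = Inf) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  if (phi <= plo) stop("empty truncation interval [", lower, ", ", upper, "]")
  stats::qnorm(runif(1L, plo, phi), mean, sd)
}

## redraw until predicate holds (used for constrained word counts)
drawWc <- function(config, lo = 1L, hi = NULL) {
  if (is.null(hi)) hi <- config$wcMax
  for (k in 1:10000) {
    wc <- min(max(1L, as.integer(round(rlnorm(1L, config$wordCountMeanlog,
                                              config$wordCountSdlog)))),
              config$wcMax)
    if (wc >= lo && wc <= hi) return(wc)
  }
  stop("cannot draw word count in [", lo, ", ", hi, "]")
}

drawDuration <- function(wc, config) {
  max(round(wc * config$wordMs + rnorm(1L, 0, config$durSdMs)),
      ceiling(wc * 260), 350L)
}

drawWord <- function(config, backchannel = FALSE) {
  voc <- config$vocabulary
  if (backchannel) voc <- voc[voc$backchannel, , drop = FALSE]
  voc$word[sample.int(nrow(voc), 1L, prob = voc$freq)]
}

## Arrange planted type counts into a feasible sequence: every
## within-overlap is immediately followed by a gap (by the floor holder).
arrangeTypes <- function(n_gap, n_between, n_within) {
  if (n_gap < n_within) {
    stop("infeasible type counts: need at least as many gaps as ",
         "within-overlaps (", n_gap, " < ", n_within, ")")
  }
  blocks <- c(rep(list(c("within_overlap", "gap")), n_within),
              rep(list("gap"), n_gap - n_within),
              rep(list("between_overlap"), n_between))
  if (length(blocks) == 0L) return(character())
  unlist(blocks[sample.int(length(blocks))])
}

#' Generate one synthetic dyadic conversation
#'
#' Produces the utterance annotation table, one face track per speaker, and
#' the ground truth (planted types, realised FTOs, leads, baselines). The
#' annotation table and tracks are in exactly the dialects the package's
#' readers consume.
#'
#' @param config A [simConfig()].
#' @param seed Conversation seed (defaults to `config$seed`).
#' @param conversation_id Label for the conversation.
#' @param speakers Character vector of two speaker ids.
#' @param speaker_effects Optional list with per-speaker `intercept` and
#'   `slope` named vectors, and per-word `word` named vector (corpus-level
#'   random effects); drawn here when absent.
#' @return List with `utterances` (annotation data frame with
#'   `conversation_id`), `tracks` (named list
#'   `"<conversation_id>/<speaker>"` -> `face_track`), `truth` (data frame
#'   of planted per-utterance values) and `config`.
#' @export
generateConversation <- function(config = simConfig(), seed = config$seed,
                                 conversation_id = "c1",
                                 speakers = c("S1", "S2"),
                                 speaker_effects = NULL) {
  stopifnot(length(speakers) == 2L)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(speaker_effects)) {
    speaker_effects <- drawCorpusEffects(config, speakers)
  }
  n <- config$utterancesPerDyad
  props <- config$typeProportions
  ## planted multinomial type counts (redraw the rare infeasible case)
  for (k in 1:1000) {
    counts <- as.vector(stats::rmultinom(1L, max(n - 1L, 0L), props))
    if (counts[1L] >= counts[3L]) break
  }
  types <- c("initial", arrangeTypes(counts[1L], counts[2L], counts[3L]))

  ## word counts with feasibility constraints
  wc <- integer(n)
  for (i in seq_len(n)) {
    lo <- 1L; hi <- config$wcMax
    if (i < n && types[i + 1L] == "within_overlap") lo <- max(lo, 10L)
    if (i < n && types[i + 1L] == "between_overlap") lo <- max(lo, 3L)
    if (types[i] == "within_overlap") hi <- 2L
    if (types[i] == "between_overlap") lo <- max(lo, 3L)
    ## teller/acknowledger rhythm: minimal (1-2 word) gap responses only
    ## follow substantive turns, and substantive turns follow minimal ones
    if (types[i] == "gap" && i > 1L && wc[i - 1L] < 8L) lo <- max(lo, 3L)
    if (types[i] %in% c("gap", "between_overlap") && i > 1L &&
        wc[i - 1L] <= 2L) lo <- max(lo, 8L)
    wc[i] <- drawWc(config, lo, hi)
  }
  word <- vapply(seq_len(n), function(i) {
    drawWord(config, backchannel = types[i] == "within_overlap")
  }, "")
  dur <- vapply(seq_len(n), function(i) drawDuration(wc[i], config),
                numeric(1L))

  ## sequential timeline; `prev` is always the most recent initiation
  utt <- list()
  emit <- function(speaker, onset, offset, i_planned, planted_type,
                   planted_fto) {
    onset <- round(onset); offset <- round(offset)
    while (length(utt) &&
           onset %in% vapply(utt, function(u) u$onset, 0)) onset <- onset + 1L
    if (offset <= onset) offset <- onset + 1L
    utt[[length(utt) + 1L]] <<- list(
      speaker = speaker, onset = onset, offset = offset,
      i = i_planned, planted_type = planted_type, planted_fto = planted_fto)
    utt[[length(utt)]]
  }
  other <- function(s) setdiff(speakers, s)
  lastOffset <- setNames(c(-Inf, -Inf), speakers)
  problems <- character()

  first <- emit(speakers[1L], config$startMs, config$startMs + dur[1L], 1L,
                "initial", NA_real_)
  lastOffset[speakers[1L]] <- first$offset
  prev <- first
  n_restarts <- 0L
  for (i in seq_len(n)[-1L]) {
    t_i <- types[i]
    if (t_i == "within_overlap") {
      host <- prev
      spk <- other(host$speaker)
      d <- dur[i]
      hard_lo <- max(host$onset + 600 + d, lastOffset[spk] + 150 + d)
      hi <- host$offset - 50
      lo <- max(hard_lo, host$offset - 400)
      if (lo > hi) lo <- hard_lo
      if (lo > hi) {
        problems <- c(problems, sprintf(
          "utterance %d: within-overlap does not fit inside host (%d ms host)",
          i, host$offset - host$onset))
        next
      }
      off_w <- runif(1L, lo, hi)
      u <- emit(spk, off_w - d, off_w, i, t_i, (off_w - d) - host$offset)
      lastOffset[spk] <- u$offset
      prev <- u
      next
    }
    spk <- other(prev$speaker)
    d <- dur[i]
    hosts_within <- i < n && types[i + 1L] == "within_overlap"
    if (t_i == "gap") {
      lo <- max(1, lastOffset[spk] + 150 - prev$offset)
      fto <- rtruncnorm1(config$ftoMeanMs, config$ftoSdMs, lower = lo)
    } else {  # between_overlap
      lo <- max(-(prev$offset - prev$onset) + 600,
                -d + 700,
                lastOffset[spk] + 150 - prev$offset,
                if (hosts_within) 1050 - d else -Inf)
      if (lo > -1) {
        problems <- c(problems, sprintf(
          "utterance %d: between-overlap infeasible (lower bound %.0f ms)",
          i, lo))
        next
      }
      fto <- rtruncnorm1(config$ftoMeanMs, config$ftoSdMs, lower = lo,
                         upper = -1)
    }
    onset <- prev$offset + fto
    u <- emit(spk, onset, onset + d, i, t_i, fto)
    lastOffset[spk] <- u$offset
    prev <- u
    ## inject a same-speaker re-initiation before a following gap
    if (i < n && types[i + 1L] == "gap" && !hosts_within &&
        runif(1L) < config$restartRate / max(props[1L], 1e-9)) {
      wc_r <- drawWc(config, 3L, 6L)
      d_r <- drawDuration(wc_r, config)
      onset_r <- u$offset + runif(1L, 120, 450)
      r <- emit(u$speaker, onset_r, onset_r + d_r, NA_integer_, "restart",
                NA_real_)
      r$wc <- wc_r
      utt[[length(utt)]] <- r
      lastOffset[u$speaker] <- r$offset
      prev <- r
      n_restarts <- n_restarts + 1L
    }
  }
  if (length(problems)) {
    stop("infeasible simulation config:\n  ",
         paste(problems, collapse = "\n  "))
  }

  ## assemble tables
  planned_wc <- wc; planned_word <- word
  rows <- lapply(seq_along(utt), function(k) {
    u <- utt[[k]]
    if (!is.na(u$i)) {
      wci <- planned_wc[u$i]; wi <- planned_word[u$i]
    } else {
      wci <- if (is.null(u$wc)) 1L else u$wc
      wi <- drawWord(config)
    }
    data.frame(conversation_id = conversation_id, speaker_id = u$speaker,
               onset_ms = as.integer(u$onset), offset_ms = as.integer(u$offset),
               word = wi, word_count = wci, planted_type = u$planted_type,
               planted_fto = u$planted_fto, stringsAsFactors = FALSE)
  })
  truth <- do.call(rbind, rows)
  ord <- order(truth$onset_ms)
  truth <- truth[ord, , drop = FALSE]
  rownames(truth) <- NULL
  truth$utterance_id <- sprintf("%s_u%03d", conversation_id,
                                seq_len(nrow(truth)))
  voc <- config$vocabulary
  truth$constraint <- voc$constraint[match(truth$word, voc$word)]
  truth$lead_ms <- ifelse(truth$constraint == "constrained",
                          leadMs(truth$word_count, config), NA_real_)
  truth$transcript <- vapply(seq_len(nrow(truth)), function(k) {
    fillers <- c("the", "thing", "about", "it", "really", "is", "that",
                 "they", "said", "something", "else", "again", "then",
                 "just", "like", "a", "bit", "of", "course", "anyway")
    extra <- truth$word_count[k] - 1L
    paste(c(truth$word[k],
            if (extra > 0L) sample(fillers, extra, replace = TRUE)),
          collapse = " ")
  }, "")

  utterances <- truth[c("conversation_id", "speaker_id", "onset_ms",
                        "offset_ms", "transcript")]
  utterances$transcript <- truth$transcript

  tracks <- list()
  truncated <- character()
  for (s in speakers) {
    trk <- synthesizeTrack(truth[truth$speaker_id == s, , drop = FALSE], s,
                           config, speaker_effects)
    truncated <- c(truncated, attr(trk, "truncated_leads"))
    tracks[[paste0(conversation_id, "/", s)]] <- trk
  }
  if (config$leadPolicy == "error" && length(truncated)) {
    stop("constraint violation: posture lead exceeds the inter-utterance ",
         "time available for: ", paste(truncated, collapse = ", "))
  }
  truth$n_restarts <- n_restarts
  list(utterances = utterances, tracks = tracks, truth = truth,
       config = config)
}

drawCorpusEffects <- function(config, speakers) {
  list(intercept = setNames(rnorm(length(speakers), 0, config$tauIntercept),
                            speakers),
       slope = setNames(rnorm(length(speakers), 0, config$tauSlope),
                        speakers),
       word = setNames(rnorm(nrow(config$vocabulary), 0, config$tauWord),
                       config$vocabulary$word))
}

## Per-speaker lip-area signal and landmark synthesis.
synthesizeTrack <- function(own, speaker, config, effects) {
  fps <- config$fps
  frame_ms <- 1000 / fps
  t_end <- if (nrow(own)) max(own$offset_ms) + 1500 else
    config$startMs + 3000
  nfr <- ceiling(t_end / frame_ms) + 1L
  t <- (seq_len(nfr) - 1L) * frame_ms
  delta <- config$baselineArea - config$constrainedTarget

  own <- own[order(own$onset_ms), , drop = FALSE]
  base <- config$baselineArea + effects$intercept[[speaker]]
  word_eff <- effects$word
  area <- rep(base, nfr)
  truncated_leads <- character()

  ## baseline segments conditioned on the upcoming own utterance
  seg_start <- c(-Inf, own$offset_ms[-nrow(own)])
  for (k in seq_len(nrow(own))) {
    lvl <- base + effects$slope[[speaker]] * log10(own$word_count[k]) +
      word_eff[[own$word[k]]]
    area[t > seg_start[k] & t <= own$onset_ms[k]] <- lvl
    ## speech modulation during the utterance
    during <- t > own$onset_ms[k] & t <= own$offset_ms[k]
    area[during] <- lvl + config$speechOpen +
      config$speechAmp * sin(2 * pi * 3 * (t[during] - own$onset_ms[k]) /
                               1000)
    ## anticipatory ramp for constrained utterances; the posture can only
    ## begin once the speaker's previous utterance has ended, so the ramp's
    ## support is clipped there (its shape is unchanged where supported)
    if (own$constraint[k] == "constrained" && delta != 0) {
      lead <- own$lead_ms[k]
      ramp_from <- max(own$onset_ms[k] - lead,
                       if (is.finite(seg_start[k])) seg_start[k] + 50 else
                         -Inf)
      if (ramp_from > own$onset_ms[k] - lead) {
        truncated_leads <- c(truncated_leads, own$utterance_id[k])
      }
      ramp_idx <- which(t >= ramp_from & t < own$onset_ms[k])
      if (length(ramp_idx)) {
        phi <- pmin(1, pmax(0, (lead - (own$onset_ms[k] - t[ramp_idx])) /
                                 (lead - config$holdMs)))
        area[ramp_idx] <- lvl - delta * phi
      }
    }
  }
  if (config$noiseSd > 0) {
    sd_innov <- config$noiseSd * sqrt(1 - config$arRho^2)
    innov <- rnorm(nfr, 0, sd_innov)
    noise <- as.numeric(filter(innov, config$arRho, method = "recursive",
                               init = rnorm(1L, 0, config$noiseSd)))
    area <- area + noise
  }
  area <- pmax(area, 5)

  ## landmark synthesis: diamond solved against the printed area formula
  W <- config$lipWidthMm
  H <- area / (1.5 * W)
  cx <- 1.5 * sin(2 * pi * 0.07 * t / 1000)
  cy <- 100 + 2 * sin(2 * pi * 0.045 * t / 1000 + 1)
  success <- runif(nfr) >= config$dropoutRate
  frames <- data.frame(frame = seq_len(nfr) - 1L, timestamp_ms = t,
                       success = success,
                       x48 = cx - W / 2, y48 = cy,
                       x51 = cx, y51 = cy - 0.45 * H,
                       x54 = cx + W / 2, y54 = cy,
                       x57 = cx, y57 = cy + 0.55 * H)
  ## a few extra outer-lip points for layout realism
  frames$x49 <- cx - 0.3 * W; frames$y49 <- cy - 0.35 * H
  frames$x53 <- cx + 0.3 * W; frames$y53 <- cy - 0.35 * H
  frames$x58 <- cx; frames$y58 <- cy + 0.45 * H
  track <- faceTrack(frames, speaker_id = speaker, fps = fps)
  attr(track, "truncated_leads") <- truncated_leads
  track
}

#' Generate a multi-dyad corpus
#'
#' Draws corpus-level speaker and word random effects once, then generates
#' `nDyads` conversations over rotating speaker pairings. Deterministic for
#' a given `config$seed`.
#'
#' @param config A [simConfig()].
#' @return List with stacked `utterances`, `tracks` (all conversations),
#'   `truth`, per-speaker `effects`, and `config`.
#' @export
generateCorpus <- function(config = simConfig()) {
  set.seed(config$seed)
  speakers <- sprintf("S%d", seq_len(config$nSpeakers))
  effects <- drawCorpusEffects(config, speakers)
  pairs <- utils::combn(speakers, 2L, simplify = FALSE)
  conv_seeds <- sample.int(.Machine$integer.max - 1L, config$nDyads)
  out_utt <- list(); out_tracks <- list(); out_truth <- list()
  for (d in seq_len(config$nDyads)) {
    pair <- pairs[[(d - 1L) %% length(pairs) + 1L]]
    conv <- generateConversation(config, seed = conv_seeds[d],
                                 conversation_id = sprintf("c%02d", d),
                                 speakers = pair,
                                 speaker_effects = effects)
    out_utt[[d]] <- conv$utterances
    out_truth[[d]] <- conv$truth
    out_tracks <- c(out_tracks, conv$tracks)
  }
  list(utterances = do.call(rbind, out_utt),
       tracks = out_tracks,
       truth = do.call(rbind, out_truth),
       effects = effects, config = config)
}

#' Write a simulated corpus to disk
#'
#' Emits one annotation TSV per conversation, one OpenFace-layout CSV per
#' speaker per conversation, and a JSON ground-truth sidecar.
#'
#' @param config A [simConfig()].
#' @param out_dir Output directory (created if needed).
#' @param corpus Optional pre-generated [generateCorpus()] result.
#' @return Invisibly, a list of written paths.
#' @export
simulateCorpus <- function(config = simConfig(), out_dir, corpus = NULL) {
  if (is.null(corpus)) corpus <- generateCorpus(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(annotations = character(), tracks = character())
  for (cid in unique(corpus$utterances$conversation_id)) {
    p <- file.path(out_dir, paste0(cid, "_utterances.tsv"))
    writeUtteranceTier(
      corpus$utterances[corpus$utterances$conversation_id == cid,
                        c("speaker_id", "onset_ms", "offset_ms",
                          "transcript")], p)
    paths$annotations <- c(paths$annotations, p)
  }
  for (key in names(corpus$tracks)) {
    p <- file.path(out_dir, paste0(gsub("/", "_", key), "_openface.csv"))
    writeOpenFaceCsv(corpus$tracks[[key]], p)
    paths$tracks <- c(paths$tracks, p)
  }
  truth_path <- file.path(out_dir, "sim_truth.json")
  jsonlite::write_json(corpus$truth, truth_path, digits = NA,
                       auto_unbox = TRUE)
  paths$truth <- truth_path
  invisible(paths)
}
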