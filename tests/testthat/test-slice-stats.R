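# Direct simulation of one-slice data: y = b0 + b1*cu + b2*l + b3*cu*l
# plus optional cluster effects. Used to test the model machinery without
# the full corpus generator.
makeSliceData <- function(n = 240, beta = c(100, 10, 5, -8), sd_res = 4,
                          n_speakers = 6, tau_int = 0, tau_slope = 0,
                          n_words = 12, tau_word = 0) {
  speaker <- sample(sprintf("S%d", seq_len(n_speakers)), n, replace = TRUE)
  word <- sample(sprintf("w%02d", seq_len(n_words)), n, replace = TRUE)
  cu <- as.integer(substr(word, 2, 3) > sprintf("%02d", n_words %/% 2))
  l <- log10(sample(1:12, n, replace = TRUE))
  u0 <- rnorm(n_speakers, 0, tau_int)
  u1 <- rnorm(n_speakers, 0, tau_slope)
  uw <- rnorm(n_words, 0, tau_word)
  idx <- as.integer(factor(speaker, levels = sprintf("S%d",
                                                     seq_len(n_speakers))))
  widx <- as.integer(factor(word, levels = sprintf("w%02d",
                                                   seq_len(n_words))))
  y <- beta[1] + beta[2] * cu + beta[3] * l + beta[4] * cu * l +
    u0[idx] + u1[idx] * l + uw[widx] + rnorm(n, 0, sd_res)
  data.frame(area = y, constraint_u = cu, log10_wc = l,
             speaker_id = speaker, first_word = word,
             stringsAsFactors = FALSE)
}

test_that("with no random structure fitLmm equals closed-form OLS", {
  set.seed(20)
  d <- makeSliceData(n = 120)
  fit <- fitLmm(d, random = list())
  X <- cbind(1, d$constraint_u, d$log10_wc, d$constraint_u * d$log10_wc)
  beta_hat <- solve(crossprod(X), crossprod(X, d$area))
  expect_equal(fit$coef$beta, as.numeric(beta_hat), tolerance = 1e-10)
  expect_equal(unique(fit$coef$df), 120 - 4)
  expect_equal(fit$random_structure, "(none)")
})

# one block of rows duplicated across clusters: cluster means are exactly
# equal, so every cluster variance component is estimated at the boundary
duplicatedClusters <- function(m = 40, g = 6) {
  block <- data.frame(
    area = 100 + rnorm(m, 0, 3),
    constraint_u = rep(c(0L, 1L), m / 2),
    log10_wc = log10(sample(1:9, m, TRUE)),
    first_word = sample(c("yeah", "no", "so", "well"), m, TRUE))
  out <- do.call(rbind, replicate(g, block, simplify = FALSE))
  out$speaker_id <- rep(sprintf("S%d", seq_len(g)), each = m)
  out
}

test_that("fitLmm recovers planted fixed effects and flags degeneracies", {
  set.seed(21)
  d <- makeSliceData(n = 3000, beta = c(100, 12, 5, -9), sd_res = 3)
  fit <- suppressWarnings(
    fitLmm(d, random = list(randomTerm("speaker_id"))))
  expect_equal(fit$coef$beta, c(100, 12, 5, -9), tolerance = 0.15)
  # no cluster variance was planted: at most a whisker is estimated
  vc <- as.data.frame(lme4::VarCorr(fit$fit))
  expect_lt(vc$sdcor[vc$grp == "speaker_id"], 0.5)

  # clusters with exactly identical means -> boundary fit, singular flag
  d2 <- duplicatedClusters()
  fit2 <- suppressWarnings(
    fitLmm(d2, random = list(randomTerm("speaker_id"))))
  expect_true(fit2$singular)
  expect_error(fitLmm(d2[d2$constraint_u == 1, ], random = list()),
               "both constraint levels")
})

test_that("backward selection keeps planted slopes and drops absent terms", {
  set.seed(22)
  # strong by-speaker slopes: the full speaker term survives
  d <- makeSliceData(n = 600, n_speakers = 12, tau_int = 12, tau_slope = 10,
                     tau_word = 6, sd_res = 2)
  kept <- 0L
  for (k in 1:5) {
    d <- makeSliceData(n = 600, n_speakers = 12, tau_int = 12,
                       tau_slope = 10, tau_word = 6, sd_res = 2)
    fit <- suppressWarnings(backwardSelectRandom(d, maximal =
                                                   planted_maximal()))
    kept <- kept + grepl("log10_wc", fit$random_structure)
  }
  expect_gte(kept, 4L)

  # clusters with exactly identical means: selection descends towards OLS,
  # logging singular fits on the way
  set.seed(23)
  d0 <- duplicatedClusters(m = 50, g = 6)
  fit0 <- suppressWarnings(backwardSelectRandom(
    d0, maximal = list(randomTerm("speaker_id", "log10_wc"))))
  path <- attr(fit0, "path")
  expect_gt(length(path), 1L)
  # boundary fits surface as singular or non-convergent, never silently
  expect_true(all(grepl("singular|non-convergent", head(path, -1L))))
  expect_equal(fit0$random_structure, "(none)")

  # single-cluster factors are dropped up front
  d1 <- makeSliceData(n = 200, tau_word = 5)
  d1$speaker_id <- "S1"
  fit1 <- suppressWarnings(backwardSelectRandom(d1, maximal =
                                                  planted_maximal()))
  expect_false(grepl("speaker_id", fit1$random_structure))
})

test_that("Satterthwaite df reduces to classical forms", {
  set.seed(24)
  # OLS limit: df = n - p
  d <- makeSliceData(n = 90)
  fit <- fitLmm(d, random = list())
  expect_equal(satterthwaiteDf(fit = fit, contrast = c(0, 1, 0, 0)), 86)

  # Welch two-sample: generic moment-matcher vs textbook formula and t.test
  x <- rnorm(14, 0, 1); y <- rnorm(31, 0, 3.2)
  v <- var(x) / 14 + var(y) / 31
  varv <- 2 * (var(x) / 14)^2 / 13 + 2 * (var(y) / 31)^2 / 30
  df <- satterthwaiteDf(v, varv)
  expect_equal(df, oracleWelchDf(x, y), tolerance = 1e-12)
  expect_equal(df, unname(t.test(x, y)$parameter), tolerance = 1e-9)

  # balanced one-way random intercepts: intercept df ~ clusters - 1
  g <- 8L; m <- 10L
  d2 <- data.frame(area = rnorm(g * m, 50, 1) +
                     rep(rnorm(g, 0, 6), each = m),
                   constraint_u = rep(c(0L, 1L), g * m / 2),
                   log10_wc = 0,
                   speaker_id = rep(sprintf("S%d", 1:g), each = m),
                   first_word = "w")
  d2$log10_wc <- rep(log10(1:5), g * m / 5)
  fit2 <- suppressWarnings(fitLmm(d2, random =
                                    list(randomTerm("speaker_id"))))
  df_int <- satterthwaiteDf(fit = fit2, contrast = c(1, 0, 0, 0))
  expect_equal(df_int, g - 1, tolerance = 0.15 * (g - 1))
})

test_that("Johnson-Neyman regions behave at the analytic limits", {
  set.seed(25)
  # strong constant effect, no interaction: the region is the whole span
  d <- makeSliceData(n = 500, beta = c(100, 30, 2, 0), sd_res = 1)
  fit <- fitLmm(d, random = list())
  jn <- johnsonNeyman(fit)
  expect_equal(nrow(jn), 1L)
  expect_equal(c(jn$lo_log10, jn$hi_log10), range(d$log10_wc),
               tolerance = 1e-9)
  expect_equal(jn$lo_wc, 10^jn$lo_log10)

  # no constraint effect at all: empty region is a valid result
  d0 <- makeSliceData(n = 500, beta = c(100, 0, 2, 0), sd_res = 1)
  fit0 <- fitLmm(d0, random = list())
  jn0 <- johnsonNeyman(fit0)
  expect_equal(nrow(jn0), 0L)

  # negative-slope significance does not count as a posture region
  dneg <- makeSliceData(n = 500, beta = c(100, -30, 2, 0), sd_res = 1)
  jnneg <- johnsonNeyman(fitLmm(dneg, random = list()))
  expect_equal(nrow(jnneg), 0L)
})

test_that("Johnson-Neyman boundaries match a dense grid-scan oracle", {
  set.seed(26)
  for (k in 1:3) {
    d <- makeSliceData(n = 400, beta = c(100, 18, 3, -14), sd_res = 6,
                       tau_int = 5, tau_slope = 3, tau_word = 4)
    fit <- suppressWarnings(
      backwardSelectRandom(d, maximal = planted_maximal()))
    span <- range(d$log10_wc)
    jn <- johnsonNeyman(fit, moderator_span = span)
    bounds <- sort(setdiff(round(c(jn$lo_log10, jn$hi_log10), 10),
                           round(span, 10)))
    oracle <- oracleJnBounds(fit, span, n_grid = 2000L)
    expect_equal(length(bounds), length(oracle))
    if (length(bounds)) {
      expect_lt(max(abs(bounds - oracle)), 1e-3)
    }
  }
})

test_that("bootstrap predictions are seed-stable with shrinking intervals", {
  set.seed(27)
  d <- makeSliceData(n = 200, beta = c(100, 20, 5, -10), sd_res = 3)
  fit <- fitLmm(d, random = list())
  b1 <- bootstrapPredictions(fit, B = 25, seed = 99)
  b2 <- bootstrapPredictions(fit, B = 25, seed = 99)
  expect_equal(b1, b2)
  expect_equal(b1$word_count, c(2, 2, 8, 8))
  expect_true(all(b1$lower <= b1$predicted & b1$predicted <= b1$upper))

  # near-zero generating noise -> intervals collapse onto the prediction
  dz <- makeSliceData(n = 200, beta = c(100, 20, 5, -10), sd_res = 1e-6)
  fz <- fitLmm(dz, random = list())
  bz <- bootstrapPredictions(fz, B = 25, seed = 1)
  expect_lt(max(bz$upper - bz$lower), 1e-4)

  # the merMod path is seed-stable too
  dm <- makeSliceData(n = 200, beta = c(100, 20, 5, -10), sd_res = 3,
                      tau_int = 8)
  fm <- suppressWarnings(fitLmm(dm, random =
                                  list(randomTerm("speaker_id"))))
  m1 <- suppressWarnings(bootstrapPredictions(fm, B = 12, seed = 4))
  m2 <- suppressWarnings(bootstrapPredictions(fm, B = 12, seed = 4))
  expect_equal(m1, m2)
})

test_that("bootstrap intervals reach near-nominal coverage (OLS path)", {
  set.seed(28)
  beta <- c(100, 20, 5, -10)
  truth <- beta[1] + beta[2] + beta[3] * log10(2) + beta[4] * log10(2)
  hits <- 0L
  n_rep <- 120L
  for (k in seq_len(n_rep)) {
    d <- makeSliceData(n = 150, beta = beta, sd_res = 5)
    fit <- fitLmm(d, random = list())
    ci <- bootstrapPredictions(fit, word_counts = 2, B = 60, seed = k)
    row <- ci[ci$constraint == "unconstrained", ]
    hits <- hits + (row$lower <= truth && truth <= row$upper)
  }
  # exact binomial 95% band around 0.95 for 120 replicates
  expect_gte(hits, qbinom(0.025, n_rep, 0.95))
  expect_lte(hits, qbinom(0.975, n_rep, 0.95))
})

test_that("speed model: constant speeds give flat slopes", {
  set.seed(29)
  stab <- data.frame(max_speed = rep(30, 160) + rnorm(160, 0, 1e-3),
                     constraint_u = rep(c(0L, 1L), 80),
                     log10_wc = log10(sample(1:10, 160, TRUE)),
                     speaker_id = sample(sprintf("S%d", 1:6), 160, TRUE),
                     first_word = sample(c("yeah", "no", "so"), 160, TRUE))
  fit <- suppressWarnings(fitSpeedModel(stab, maximal = planted_maximal()))
  slopes <- fit$coef$beta[fit$coef$term != "(Intercept)"]
  expect_lt(max(abs(slopes)), 0.01)
})
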