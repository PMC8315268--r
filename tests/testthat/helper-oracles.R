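# Independent oracles and fixture builders shared across the test files.
# Everything here is deliberately written as plain brute force so it cannot
# share a code path (or a bug) with the package implementation.

# Brute-force utterance typing: for each utterance scan *all* priors for the
# latest initiation, then re-apply the three rules literally.
oracleClassify <- function(rec, window = 500) {
  rec <- rec[order(rec$onset_ms), , drop = FALSE]
  n <- nrow(rec)
  type <- character(n)
  fto <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    prior <- which(rec$onset_ms < rec$onset_ms[i])
    if (length(prior) == 0L) {
      type[i] <- "initial"
      next
    }
    ref <- prior[which.max(rec$onset_ms[prior])]
    if (rec$speaker_id[ref] == rec$speaker_id[i]) {
      type[i] <- "restart"
      next
    }
    own <- prior[rec$speaker_id[prior] == rec$speaker_id[i]]
    if (length(own)) {
      gaps <- rec$onset_ms[ref] - rec$onset_ms[own]
      if (any(gaps >= 0 & gaps <= window)) {
        type[i] <- "restart"
        next
      }
    }
    f <- rec$onset_ms[i] - rec$offset_ms[ref]
    fto[i] <- f
    type[i] <- if (rec$offset_ms[i] <= rec$offset_ms[ref]) {
      "within_overlap"
    } else if (f < 0) "between_overlap" else "gap"
  }
  list(type = type, fto = fto)
}

# Random small two-speaker conversation with overlaps, quick restarts and
# occasional very long host turns (the deep within-overlap pattern).
randomConversation <- function(n, long_turn_prob = 0.15) {
  onset <- numeric(n)
  offset <- numeric(n)
  t <- 0
  for (i in seq_len(n)) {
    step <- sample(c(sample(50:800, 1L),           # quick (restart-ish)
                     sample(-1500:2500, 1L)), 1L,  # normal / overlapping
                   prob = c(0.3, 0.7))
    t <- max(0, t + step)
    dur <- if (runif(1) < long_turn_prob) sample(20000:100000, 1L) else
      sample(200:4000, 1L)
    onset[i] <- t
    offset[i] <- t + dur
    t <- t + sample(100:3000, 1L)
  }
  onset <- round(onset)
  while (anyDuplicated(onset)) {
    onset[duplicated(onset)] <- onset[duplicated(onset)] + 1L
  }
  data.frame(speaker_id = sample(c("A", "B"), n, replace = TRUE),
             onset_ms = as.integer(onset),
             offset_ms = as.integer(pmax(round(offset), onset + 1L)),
             transcript = replicate(n, paste(
               sample(c("yeah", "okay", "so", "tell", "me", "more"),
                      sample(1:4, 1L), replace = TRUE), collapse = " ")),
             stringsAsFactors = FALSE)
}

# Convex quadrilateral with extremal vertices: p1/p3 carry the x extremes,
# p2/p4 the y extremes; rejection-sample until strictly convex.
randomExtremalQuad <- function() {
  repeat {
    W <- runif(1, 1, 60)
    H <- runif(1, 1, 60)
    q <- rbind(c(0, runif(1, 0.05, 0.95) * H),
               c(runif(1, 0.05, 0.95) * W, H),
               c(W, runif(1, 0.05, 0.95) * H),
               c(runif(1, 0.05, 0.95) * W, 0))
    q <- q + runif(2, -50, 50)[c(1, 1, 1, 1, 2, 2, 2, 2)]
    cross <- vapply(1:4, function(i) {
      a <- q[i %% 4 + 1, ] - q[i, ]
      b <- q[(i + 1) %% 4 + 1, ] - q[i %% 4 + 1, ]
      a[1] * b[2] - a[2] * b[1]
    }, 0)
    if (all(cross > 1e-9) || all(cross < -1e-9)) return(q)
  }
}

# Direct surveyor's formula, written independently of the package.
oracleShoelace <- function(q) {
  x <- q[, 1]; y <- q[, 2]
  abs(x[1] * (y[2] - y[4]) + x[2] * (y[3] - y[1]) +
        x[3] * (y[4] - y[2]) + x[4] * (y[1] - y[3])) / 2
}

# Welch-Satterthwaite two-sample df, straight from the textbook formula.
oracleWelchDf <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
}

# Grid-scan Johnson-Neyman boundaries: pointwise positive-slope t-tests on a
# dense grid, boundaries bracketed between adjacent grid points.
oracleJnBounds <- function(fit, span, alpha = 0.05, n_grid = 10000L) {
  terms <- fit$coef$term
  i1 <- match("constraint_u", terms)
  i3 <- match("constraint_u:log10_wc", terms)
  V <- as.matrix(vcov(fit$fit))
  b <- fit$coef$beta
  grid <- seq(span[1], span[2], length.out = n_grid)
  sig <- vapply(grid, function(w) {
    s <- b[i1] + b[i3] * w
    if (s <= 0) return(FALSE)
    se <- sqrt(V[i1, i1] + w^2 * V[i3, i3] + 2 * w * V[i1, i3])
    ct <- numeric(length(terms)); ct[i1] <- 1; ct[i3] <- w
    df <- satterthwaiteDf(fit = fit, contrast = ct)
    s / se > qt(1 - alpha / 2, df)
  }, logical(1L))
  flips <- which(sig[-1] != sig[-n_grid])
  (grid[flips] + grid[flips + 1]) / 2
}

# The reduced maximal random structure used by the simulation studies: the
# generating model's own structure (by-speaker intercept + word-count slope,
# by-first-word intercept).
planted_maximal <- function() {
  list(randomTerm("speaker_id", "log10_wc"), randomTerm("first_word"))
}
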