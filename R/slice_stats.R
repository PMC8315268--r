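## Time-sliced moderated mixed-effects inference.
##
## At each slice (default -3000 ... 0 ms in 500-ms / 15-frame steps) the
## model is
##
##   area ~ constraint_u * log10_wc + (random terms)
##
## with constraint_u dummy-coded 0 = constrained, 1 = unconstrained (so a
## positive constraint coefficient means larger lip area for unconstrained
## utterances, the signature of an anticipatory posture) and log10_wc the
## log10-transformed word count. Clustering factors are speaker id and the
## first word of the utterance; the random structure is chosen by a
## deterministic backward selection from a maximal structure, simplifying
## until the fit converges without singularity. Fixed-effect tests use
## Satterthwaite denominator degrees of freedom. A reliable interaction is
## followed up with a Johnson-Neyman region: the moderator range over which
## the simple slope of constraint is significantly positive.

#' Default slice specification
#'
#' Slice offsets -3000 to 0 ms in 500-ms steps (15 frames at 30 fps).
#'
#' @param offsets_ms Slice offsets relative to acoustic onset.
#' @param fps Frames per second.
#' @param stride Frame stride between slices.
#' @return List with `offsets_ms`, `fps`, `stride`.
#' @export
sliceSpec <- function(offsets_ms = seq(-3000, 0, by = 500), fps = 30,
                      stride = 15L) {
  frame_ms <- 1000 / fps
  if (any(abs(offsets_ms / (frame_ms * stride) -
                round(offsets_ms / (frame_ms * stride))) > 1e-9)) {
    stop("slice offsets must be multiples of the frame duration x stride (",
         frame_ms * stride, " ms)")
  }
  list(offsets_ms = offsets_ms, fps = fps, stride = stride)
}

## ---- random-structure descriptors -------------------------------------

#' Describe a random-effects structure
#'
#' A descriptor is a list of terms, each `list(group =, slopes =, intercept
#' =, correlated =)`. `randomTerm()` builds one term; `maximalRandom()` is
#' the package default maximal structure for the lip-area models: by-speaker
#' intercept and slopes for log10 word count and constraint, by-first-word
#' intercept and log10-word-count slope (constraint is constant within a
#' first word, so it gets no word-level slope).
#'
#' @param group Grouping factor column name.
#' @param slopes Character vector of numeric covariate columns with random
#'   slopes (may be empty).
#' @param intercept Include a random intercept (default TRUE).
#' @param correlated Estimate slope/intercept correlations (default TRUE);
#'   when FALSE the term uses lme4's `||` parameterisation.
#' @return A random-structure descriptor (list of terms).
#' @export
randomTerm <- function(group, slopes = character(), intercept = TRUE,
                       correlated = TRUE) {
  list(group = group, slopes = slopes, intercept = intercept,
       correlated = correlated)
}

#' @rdname randomTerm
#' @export
maximalRandom <- function() {
  list(randomTerm("speaker_id", c("log10_wc", "constraint_u")),
       randomTerm("first_word", "log10_wc"))
}

reTermString <- function(term) {
  parts <- c(if (term$intercept) "1" else "0", term$slopes)
  bar <- if (term$correlated || length(term$slopes) == 0L) "|" else "||"
  paste0("(", paste(parts, collapse = " + "), " ", bar, " ", term$group, ")")
}

#' @rdname randomTerm
#' @param descriptor A random-structure descriptor.
#' @export
randomStructureString <- function(descriptor) {
  if (length(descriptor) == 0L) return("(none)")
  paste(vapply(descriptor, reTermString, ""), collapse = " + ")
}

## ---- model fitting ------------------------------------------------------

#' Fit one time-slice mixed model
#'
#' REML fit of `response ~ constraint_u * log10_wc` plus the random terms in
#' `random`; falls back to ordinary least squares when `random` is empty.
#' Convergence failures and singular fits are reported in the result, never
#' silently accepted.
#'
#' @param data One-slice data frame with columns `constraint_u` (0/1 dummy),
#'   `log10_wc`, the response, and any grouping factors used by `random`.
#' @param response Response column name (e.g. `"area"` or `"max_speed"`).
#' @param random Random-structure descriptor (see [randomTerm()]); empty
#'   list for OLS.
#' @param offset_ms Slice label carried into the result.
#' @return A `slice_fit`: list with `coef` (data.frame: term, beta, se, df,
#'   t, p), `random_structure`, `converged`, `singular`, `nobs`, `offset_ms`
#'   and the underlying `fit` object.
#' @export
fitLmm <- function(data, response = "area", random = maximalRandom(),
                   offset_ms = NA_real_) {
  if (length(unique(data$constraint_u)) < 2L) {
    stop("need both constraint levels present at this slice")
  }
  rhs <- "constraint_u * log10_wc"
  for (term in random) {
    lv <- length(unique(data[[term$group]]))
    if (lv < 2L) stop("random factor '", term$group, "' has ", lv,
                      " level(s); drop it from the structure")
  }
  if (length(random) == 0L) {
    fml <- as.formula(paste(response, "~", rhs))
    fit <- lm(fml, data = data)
    X <- stats::model.matrix(fit)
    if (qr(X)$rank < ncol(X)) stop("rank-deficient fixed-effects design")
    s <- summary(fit)$coefficients
    tab <- data.frame(term = rownames(s), beta = s[, 1L], se = s[, 2L],
                      df = df.residual(fit), t = s[, 3L], p = s[, 4L],
                      row.names = NULL, stringsAsFactors = FALSE)
    return(structure(list(coef = tab, random_structure = "(none)",
                          converged = TRUE, singular = FALSE,
                          nobs = nrow(data), offset_ms = offset_ms,
                          response = response, fit = fit, data = data),
                     class = "slice_fit"))
  }
  fml <- as.formula(paste(response, "~", rhs, "+",
                          randomStructureString(random)))
  msgs <- character()
  fit <- withCallingHandlers(
    suppressMessages(lmerTest::lmer(fml, data = data, REML = TRUE)),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  converged <- isTRUE(fit@optinfo$conv$opt == 0) &&
    length(fit@optinfo$conv$lme4$messages) == 0L &&
    !any(grepl("converge", msgs, ignore.case = TRUE))
  singular <- lme4::isSingular(fit, tol = 1e-4)
  s <- suppressWarnings(summary(fit))$coefficients
  tab <- data.frame(term = rownames(s), beta = s[, "Estimate"],
                    se = s[, "Std. Error"], df = s[, "df"],
                    t = s[, "t value"], p = s[, "Pr(>|t|)"],
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(coef = tab,
                 random_structure = randomStructureString(random),
                 converged = converged, singular = singular,
                 nobs = nrow(data), offset_ms = offset_ms,
                 response = response, fit = fit, data = data),
            class = "slice_fit")
}

#' @export
print.slice_fit <- function(x, ...) {
  cat(sprintf("<slice_fit> %s at %s ms, n = %d\n  random: %s%s\n",
              x$response,
              if (is.na(x$offset_ms)) "?" else format(x$offset_ms),
              x$nobs, x$random_structure,
              paste0(if (!x$converged) " [non-convergent]" else "",
                     if (x$singular) " [singular]" else "")))
  print(format(x$coef, digits = 4L), row.names = FALSE)
  invisible(x)
}

#' Deterministic backward selection of the random structure
#'
#' Starts from the maximal structure and simplifies until a fit converges
#' without singularity, in a fixed order: (1) drop all slope/intercept
#' correlations; (2) drop the random slope with the smallest estimated
#' variance (repeatedly); (3) drop the random intercept of the factor with
#' the fewest levels (repeatedly). Grouping factors with fewer than two
#' levels are removed up front. If even the intercept-only structures fail,
#' the fall-back is the fixed-effects-only OLS fit, flagged with a warning.
#'
#' @inheritParams fitLmm
#' @param maximal Starting random-structure descriptor.
#' @return A `slice_fit` (see [fitLmm()]) with attribute `"path"`: a
#'   character vector logging each structure tried and its status.
#' @export
backwardSelectRandom <- function(data, response = "area",
                                 maximal = maximalRandom(),
                                 offset_ms = NA_real_) {
  current <- Filter(function(term) {
    length(unique(data[[term$group]])) >= 2L
  }, maximal)
  ## keep only slopes that vary within the data
  current <- lapply(current, function(term) {
    term$slopes <- term$slopes[vapply(term$slopes, function(sl) {
      var(data[[sl]]) > 0
    }, logical(1L))]
    term
  })
  path <- character()
  repeat {
    if (length(current) == 0L) {
      warning("random-effects selection exhausted every structure; ",
              "falling back to fixed-effects-only OLS")
      fit <- fitLmm(data, response = response, random = list(),
                    offset_ms = offset_ms)
      attr(fit, "path") <- c(path, "(none): OLS fall-back")
      return(fit)
    }
    fit <- tryCatch(
      fitLmm(data, response = response, random = current,
             offset_ms = offset_ms),
      error = function(e) e)
    failed <- inherits(fit, "error")
    status <- if (failed) paste0("error: ", conditionMessage(fit)) else if
    (!fit$converged) "non-convergent" else if (fit$singular) "singular" else
      "ok"
    path <- c(path, paste0(randomStructureString(current), ": ", status))
    if (!failed && fit$converged && !fit$singular) {
      attr(fit, "path") <- path
      return(fit)
    }
    current <- simplifyRandom(current, if (failed) NULL else fit)
  }
}

## One simplification step, in the documented deterministic order.
simplifyRandom <- function(descriptor, fit = NULL) {
  correlated <- vapply(descriptor, function(t) {
    t$correlated && length(t$slopes) > 0L
  }, logical(1L))
  if (any(correlated)) {
    return(lapply(descriptor, function(t) { t$correlated <- FALSE; t }))
  }
  has_slopes <- vapply(descriptor, function(t) length(t$slopes) > 0L,
                       logical(1L))
  if (any(has_slopes)) {
    drop <- smallestVarianceSlope(descriptor, fit)
    descriptor[[drop$term]]$slopes <-
      setdiff(descriptor[[drop$term]]$slopes, drop$slope)
    return(descriptor)
  }
  levels_per <- vapply(descriptor, function(t) {
    if (!is.null(fit) && !inherits(fit$fit, "lm")) {
      ngrps <- lme4::ngrps(fit$fit)
      if (t$group %in% names(ngrps)) return(as.integer(ngrps[[t$group]]))
    }
    NA_integer_
  }, integer(1L))
  ## fall back to descriptor order when level counts are unknown
  drop_idx <- if (all(is.na(levels_per))) 1L else which.min(levels_per)
  descriptor[-drop_idx]
}

## Pick the slope with the smallest estimated variance from the last fit;
## deterministic fall-back: last slope of the last term carrying slopes.
smallestVarianceSlope <- function(descriptor, fit) {
  best <- NULL
  if (!is.null(fit) && inherits(fit$fit, "merMod")) {
    vc <- lme4::VarCorr(fit$fit)
    for (i in seq_along(descriptor)) {
      term <- descriptor[[i]]
      for (sl in term$slopes) {
        v <- NA_real_
        for (g in which(names(vc) == term$group |
                          startsWith(names(vc), paste0(term$group, ".")))) {
          d <- diag(vc[[g]])
          if (sl %in% names(d)) v <- d[[sl]]
        }
        if (!is.na(v) && (is.null(best) || v < best$v)) {
          best <- list(term = i, slope = sl, v = v)
        }
      }
    }
  }
  if (is.null(best)) {
    i <- max(which(vapply(descriptor, function(t) length(t$slopes) > 0L,
                          logical(1L))))
    best <- list(term = i,
                 slope = descriptor[[i]]$slopes[length(descriptor[[i]]$slopes)],
                 v = NA_real_)
  }
  best
}

## ---- Satterthwaite degrees of freedom ----------------------------------

#' Satterthwaite degrees of freedom
#'
#' Moment-matching denominator degrees of freedom. Two call forms:
#'
#' * `satterthwaiteDf(variance, var_of_variance)`: the generic
#'   moment-matcher `df = 2 * variance^2 / var_of_variance`. With
#'   `variance = s1^2/n1 + s2^2/n2` and its sampling variance this is the
#'   Welch-Satterthwaite two-sample formula.
#' * `satterthwaiteDf(fit = <slice_fit>, contrast = c)`: the denominator df
#'   of the 1-df test of `c' beta` in a fitted slice model, computed via the
#'   fitted covariance of the variance-component estimates (delegated to
#'   lmerTest's implementation). For an OLS fall-back fit this reduces to
#'   the classical residual df `n - p`.
#'
#' @param variance Estimated variance of the contrast (first form).
#' @param var_of_variance Sampling variance of that variance estimate.
#' @param fit A `slice_fit` (second form).
#' @param contrast Numeric contrast vector over the fixed effects
#'   (length = number of coefficients).
#' @return Degrees of freedom (positive scalar).
#' @export
satterthwaiteDf <- function(variance = NULL, var_of_variance = NULL,
                            fit = NULL, contrast = NULL) {
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "slice_fit"), !is.null(contrast))
    if (inherits(fit$fit, "lm")) return(df.residual(fit$fit))
    ct <- suppressWarnings(
      lmerTest::contest1D(fit$fit, contrast, ddf = "Satterthwaite"))
    df <- ct$df
    if (!is.finite(df) || df <= 0) {
      warning("degenerate Satterthwaite variance; reporting residual df")
      df <- nrow(fit$data) - length(lme4::fixef(fit$fit))
    }
    return(df)
  }
  stopifnot(is.numeric(variance), is.numeric(var_of_variance),
            var_of_variance > 0)
  2 * variance^2 / var_of_variance
}

## ---- Johnson-Neyman -----------------------------------------------------

#' Johnson-Neyman region for the constraint simple slope
#'
#' The simple slope of the constraint dummy at moderator value `w` (log10
#' word count) is `s(w) = b_constraint + b_interaction * w` with variance
#' `V11 + w^2 V33 + 2 w V13`. The region reported is the subset of the
#' observed moderator span where `s(w)` is significantly *positive* at level
#' `alpha` (postures mean larger area for unconstrained utterances; negative
#' significant slopes are not postures). Boundaries are located by bisection
#' of the exact t-statistic crossing; by default the t critical value uses
#' the per-point Satterthwaite df of the simple-slope contrast, with
#' `df_method = "fixed"` using the interaction term's df throughout.
#'
#' @param fit A `slice_fit` from [fitLmm()] / [backwardSelectRandom()].
#' @param moderator_span Observed log10 word-count range (length-2); default
#'   the span of the fitting data.
#' @param alpha Significance level (default 0.05).
#' @param df_method `"per_point"` (default) or `"fixed"`.
#' @param scan_points Grid size for bracketing significance changes before
#'   root refinement.
#' @return A `jn_region`: data frame with one row per interval
#'   (`lo_log10`, `hi_log10`, `lo_wc`, `hi_wc`), possibly zero rows (slope
#'   never significantly positive — a valid result), with attributes `alpha`
#'   and `moderator_span`.
#' @export
johnsonNeyman <- function(fit, moderator_span = NULL, alpha = 0.05,
                          df_method = c("per_point", "fixed"),
                          scan_points = 512L) {
  df_method <- match.arg(df_method)
  stopifnot(inherits(fit, "slice_fit"))
  terms <- fit$coef$term
  i1 <- match("constraint_u", terms)
  i3 <- match("constraint_u:log10_wc", terms)
  if (is.na(i1) || is.na(i3)) {
    stop("fit lacks constraint and interaction terms")
  }
  if (is.null(moderator_span)) {
    moderator_span <- range(fit$data$log10_wc)
  }
  b <- fit$coef$beta
  V <- as.matrix(vcov(fit$fit))
  slope <- function(w) b[i1] + b[i3] * w
  se <- function(w) sqrt(V[i1, i1] + w^2 * V[i3, i3] + 2 * w * V[i1, i3])
  dfAt <- if (df_method == "fixed") {
    fixed_df <- fit$coef$df[i3]
    function(w) fixed_df
  } else {
    function(w) {
      ct <- numeric(length(terms))
      ct[i1] <- 1; ct[i3] <- w
      satterthwaiteDf(fit = fit, contrast = ct)
    }
  }
  ## positive-significance indicator margin: t(w) - t_crit(w), restricted to
  ## positive slopes
  margin <- function(w) {
    s <- slope(w)
    tcrit <- qt(1 - alpha / 2, dfAt(w))
    if (s <= 0) return(-abs(s / se(w)) - tcrit)  # never "positive sig"
    s / se(w) - tcrit
  }
  grid <- seq(moderator_span[1L], moderator_span[2L],
              length.out = scan_points)
  m <- vapply(grid, margin, 0)
  sig <- m > 0
  ## boundaries: refine every sign change by bisection
  bounds <- numeric()
  for (k in seq_len(length(grid) - 1L)) {
    if (xor(sig[k], sig[k + 1L])) {
      root <- uniroot(margin, c(grid[k], grid[k + 1L]), tol = 1e-9)$root
      bounds <- c(bounds, root)
    }
  }
  edges <- sort(unique(c(moderator_span, bounds)))
  lo <- head(edges, -1L); hi <- tail(edges, -1L)
  keep <- vapply(seq_along(lo), function(k) {
    margin((lo[k] + hi[k]) / 2) > 0
  }, logical(1L))
  region <- data.frame(lo_log10 = lo[keep], hi_log10 = hi[keep])
  region$lo_wc <- 10^region$lo_log10
  region$hi_wc <- 10^region$hi_log10
  structure(region, class = c("jn_region", "data.frame"), alpha = alpha,
            moderator_span = moderator_span)
}

#' @export
print.jn_region <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("<jn_region> empty: constraint slope never significantly positive\n")
  } else {
    cat(sprintf("<jn_region> alpha = %g\n", attr(x, "alpha")))
    for (k in seq_len(nrow(x))) {
      cat(sprintf("  log10 wc in [%.3f, %.3f]  (word count %.2f to %.2f)\n",
                  x$lo_log10[k], x$hi_log10[k], x$lo_wc[k], x$hi_wc[k]))
    }
  }
  invisible(x)
}

## ---- bootstrap predictions ----------------------------------------------

#' Bootstrapped predicted means on a word-count grid
#'
#' Population-level predictions (random effects at zero) for constrained and
#' unconstrained utterances at the given word counts, with percentile 95%
#' intervals from a parametric bootstrap: the response is re-simulated from
#' the fitted model, the model refit, and the prediction recomputed, `B`
#' times.
#'
#' @param fit A `slice_fit`.
#' @param word_counts Word counts for the prediction grid (default `c(2,
#'   8)`).
#' @param B Number of bootstrap replicates (>= 100 for real use; the
#'   examples use fewer).
#' @param seed Integer seed making the bootstrap reproducible.
#' @param level Interval level (default 0.95).
#' @param max_fail Maximum tolerated proportion of failed refits.
#' @return Data frame: `constraint`, `word_count`, `predicted`, `lower`,
#'   `upper`, `B_effective`.
#' @export
bootstrapPredictions <- function(fit, word_counts = c(2, 8), B = 1000L,
                                 seed = 1L, level = 0.95, max_fail = 0.1) {
  stopifnot(inherits(fit, "slice_fit"), B >= 2L)
  grid <- expand.grid(constraint_u = c(0L, 1L),
                      word_count = word_counts)
  grid$log10_wc <- log10(grid$word_count)
  if (inherits(fit$fit, "merMod")) {
    predfun <- function(m) predict(m, newdata = grid, re.form = NA)
    boo <- suppressWarnings(suppressMessages(
      lme4::bootMer(fit$fit, predfun, nsim = B, seed = seed,
                    type = "parametric", use.u = FALSE)))
    draws <- boo$t
    point <- predfun(fit$fit)
  } else {
    set.seed(seed)
    sims <- simulate(fit$fit, nsim = B)
    dat <- fit$data
    fml <- stats::formula(fit$fit)
    draws <- t(vapply(seq_len(B), function(b) {
      dat[[fit$response]] <- sims[[b]]
      predict(lm(fml, data = dat), newdata = grid)
    }, numeric(nrow(grid))))
    point <- predict(fit$fit, newdata = grid)
  }
  ok <- stats::complete.cases(draws)
  if (mean(!ok) > max_fail) {
    stop("bootstrap refit failure rate ", round(mean(!ok), 3),
         " exceeds ", max_fail)
  }
  qs <- apply(draws[ok, , drop = FALSE], 2L, quantile,
              probs = c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
  data.frame(constraint = ifelse(grid$constraint_u == 1L, "unconstrained",
                                 "constrained"),
             word_count = grid$word_count,
             predicted = as.numeric(point),
             lower = qs[1L, ], upper = qs[2L, ],
             B_effective = sum(ok))
}

## ---- slice loop and speed model ----------------------------------------

#' Fit the full set of time-slice models
#'
#' For each slice offset: subset the epoch table to that frame (dropping
#' missing-area rows), run backward random-structure selection from
#' `maximal`, and, when the interaction is reliable at `alpha`, compute the
#' Johnson-Neyman region.
#'
#' @param epochs Long epoch table from [buildEpochTable()] /
#'   [readEpochTable()].
#' @param slices A [sliceSpec()].
#' @param maximal Maximal random structure for the backward selection.
#' @param alpha Significance level for the interaction follow-up.
#' @param n_frames Epoch length (frames).
#' @return A `slice_results` list: `summary` (one row per slice x term),
#'   `fits` (list of `slice_fit`), `jn` (list of `jn_region` or NULL),
#'   `spec`.
#' @export
fitSliceModels <- function(epochs, slices = sliceSpec(),
                           maximal = maximalRandom(), alpha = 0.05,
                           n_frames = 90) {
  fits <- list()
  jn <- list()
  rows <- list()
  for (off in slices$offsets_ms) {
    idx <- sliceFrameIndex(off, n_frames = n_frames, fps = slices$fps)
    dat <- epochs[epochs$frame_index == idx & !is.na(epochs$area), ,
                  drop = FALSE]
    fit <- backwardSelectRandom(dat, response = "area", maximal = maximal,
                                offset_ms = off)
    key <- as.character(off)
    fits[[key]] <- fit
    inter <- fit$coef[fit$coef$term == "constraint_u:log10_wc", ]
    jn[[key]] <- if (nrow(inter) == 1L && is.finite(inter$p) &&
                       inter$p < alpha) {
      johnsonNeyman(fit, alpha = alpha)
    } else NULL
    tab <- fit$coef
    tab$offset_ms <- off
    tab$random_structure <- fit$random_structure
    tab$converged <- fit$converged
    tab$singular <- fit$singular
    tab$n <- fit$nobs
    rows[[key]] <- tab
  }
  structure(list(summary = do.call(rbind, c(rows, make.row.names = FALSE)),
                 fits = fits, jn = jn, spec = slices, alpha = alpha),
            class = "slice_results")
}

#' @export
print.slice_results <- function(x, ...) {
  cat(sprintf("<slice_results> %d slices, alpha = %g\n",
              length(x$fits), x$alpha))
  for (key in names(x$fits)) {
    f <- x$fits[[key]]
    ib <- f$coef[f$coef$term == "constraint_u:log10_wc", ]
    mb <- f$coef[f$coef$term == "constraint_u", ]
    cat(sprintf("  %6s ms  random: %-55s constraint b=%7.2f (p=%.3g)  interaction b=%7.2f (p=%.3g)%s\n",
                key, f$random_structure, mb$beta, mb$p, ib$beta, ib$p,
                if (!is.null(x$jn[[key]]) && nrow(x$jn[[key]]) > 0)
                  sprintf("  JN wc [%.2f, %.2f]", x$jn[[key]]$lo_wc[1L],
                          x$jn[[key]]$hi_wc[nrow(x$jn[[key]])]) else ""))
  }
  invisible(x)
}

#' Per-utterance maximum-speed table
#'
#' Collapses the long epoch table to one row per utterance, computing the
#' maximum lip movement speed over the final `window` steps via
#' [maxSpeed()]. Utterances with missing frames inside the window are
#' dropped (counted in the `dropped` attribute).
#'
#' @param epochs Long epoch table.
#' @param fps Frames per second.
#' @param window Final-difference window (default 15).
#' @return Data frame with one row per utterance: metadata columns plus
#'   `max_speed`.
#' @export
speedTable <- function(epochs, fps = 30, window = 15L) {
  ids <- unique(epochs$utterance_id)
  rows <- vector("list", length(ids))
  dropped <- 0L
  for (k in seq_along(ids)) {
    e <- epochs[epochs$utterance_id == ids[k], , drop = FALSE]
    e <- e[order(e$frame_index), , drop = FALSE]
    ms <- tryCatch(maxSpeed(e$area, fps = fps, window = window),
                   error = function(err) NULL)
    if (is.null(ms)) { dropped <- dropped + 1L; next }
    rows[[k]] <- data.frame(
      utterance_id = ids[k], conversation_id = e$conversation_id[1L],
      speaker_id = e$speaker_id[1L], first_word = e$first_word[1L],
      word_count = e$word_count[1L], constraint = e$constraint[1L],
      log10_wc = e$log10_wc[1L], constraint_u = e$constraint_u[1L],
      max_speed = ms$max_speed, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  attr(out, "dropped") <- dropped
  out
}

#' Fit the maximum-speed mixed model
#'
#' Same fixed-effects structure as the lip-area slice models with maximum
#' lip movement speed (units^2/s) as the response. The default maximal
#' random structure adds a by-speaker constraint slope (speakers may differ
#' in how sharply constrained utterances move).
#'
#' @param speed_tab Output of [speedTable()].
#' @param maximal Maximal random structure.
#' @return A `slice_fit` for the speed response.
#' @export
fitSpeedModel <- function(speed_tab, maximal = maximalRandom()) {
  backwardSelectRandom(speed_tab, response = "max_speed", maximal = maximal)
}
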