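## Utterance typing: restarts, response subtypes and floor transfer offsets.
##
## For each utterance the reference is the most recently *initiated* prior
## utterance, whether or not it has ended. A same-speaker reference makes the
## current utterance a restart; so does an other-speaker reference initiated
## within 500 ms of one of the current speaker's own prior initiations.
## Everything else is a response, subtyped by its floor transfer offset
## (FTO = current onset - reference offset): gap (FTO > 0), between-overlap
## (FTO <= 0 but the response outlasts the reference) or within-overlap
## (the response lies entirely inside the reference's acoustic span).

UTTERANCE_TYPES <- c("initial", "restart", "gap", "between_overlap",
                     "within_overlap")
RESPONSE_TYPES <- c("gap", "between_overlap", "within_overlap")

#' Classify utterances into turn-exchange types
#'
#' Implements the typing rules for one two-speaker conversation: the first
#' utterance is `initial`; an utterance whose reference (latest strictly
#' earlier initiation) is by the same speaker is a `restart`, as is one whose
#' other-speaker reference was itself initiated within `restart_window_ms` of
#' a prior initiation by the current speaker; remaining utterances are
#' responses subtyped `gap`, `between_overlap` or `within_overlap` with a
#' signed floor transfer offset. An FTO of exactly 0 counts as a gap
#' (non-overlapping floor transfer).
#'
#' @param records Data frame of utterance records (`speaker_id`, `onset_ms`,
#'   `offset_ms`, `transcript`), one conversation, exactly two speakers.
#' @param restart_window_ms Window for the cross-speaker restart rule
#'   (default 500).
#' @param tie_break Policy for identical onsets across speakers: `"error"`
#'   (default) or `"speaker"` (lexicographically smaller speaker id counts as
#'   initiating first).
#' @return The input plus columns `utterance_type`, `fto_ms` (NA for
#'   initial/restart), `word_count`, `first_word`, `retained` (TRUE for
#'   responses), in onset order.
#' @examples
#' rec <- data.frame(speaker_id = c("A", "B"), onset_ms = c(0L, 5200L),
#'                   offset_ms = c(5000L, 5600L),
#'                   transcript = c("so tell me more", "okay"))
#' classifyUtterances(rec)
#' @export
classifyUtterances <- function(records, restart_window_ms = 500,
                               tie_break = c("error", "speaker")) {
  tie_break <- match.arg(tie_break)
  validateUtteranceRecords(records)
  speakers <- unique(records$speaker_id)
  if (length(speakers) > 2L) {
    stop("more than two speakers in conversation: ",
         paste(speakers, collapse = ", "))
  }
  ord <- order(records$onset_ms,
               if (tie_break == "speaker") records$speaker_id else
                 seq_len(nrow(records)))
  rec <- records[ord, , drop = FALSE]
  rownames(rec) <- NULL
  n <- nrow(rec)
  if (tie_break == "error" && n > 1L && anyDuplicated(rec$onset_ms)) {
    stop("simultaneous identical onsets at ",
         rec$onset_ms[duplicated(rec$onset_ms)][1L],
         " ms; set tie_break to resolve")
  }
  type <- character(n)
  fto <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i == 1L) { type[i] <- "initial"; next }
    ref <- i - 1L
    if (rec$speaker_id[ref] == rec$speaker_id[i]) {
      type[i] <- "restart"
      next
    }
    own_prior <- which(rec$speaker_id[seq_len(ref)] == rec$speaker_id[i])
    if (length(own_prior) &&
        rec$onset_ms[ref] - max(rec$onset_ms[own_prior]) <=
          restart_window_ms) {
      type[i] <- "restart"
      next
    }
    fto[i] <- rec$onset_ms[i] - rec$offset_ms[ref]
    ## fto == 0 is a zero-gap floor transfer, not an overlap
    type[i] <- if (rec$offset_ms[i] <= rec$offset_ms[ref]) {
      "within_overlap"
    } else if (fto[i] < 0) {
      "between_overlap"
    } else {
      "gap"
    }
  }
  tokens <- strsplit(trimws(rec$transcript), "\\s+")
  rec$utterance_type <- factor(type, levels = UTTERANCE_TYPES)
  rec$fto_ms <- fto
  rec$word_count <- lengths(tokens)
  rec$first_word <- normalizeWord(vapply(tokens, `[`, "", 1L))
  rec$retained <- type %in% RESPONSE_TYPES
  rec
}

## Case-fold, normalize curly apostrophes, strip flanking punctuation
## (internal apostrophes kept: "that's" is one word).
normalizeWord <- function(w) {
  w <- tolower(w)
  w <- gsub("\u2019", "'", w)
  w <- gsub("^[^a-z0-9']+|[^a-z0-9']+$", "", w)
  w
}

#' Proportions of retained response types
#'
#' Proportions of `gap`, `between_overlap` and `within_overlap` among
#' retained utterances (restarts and the conversation-initial utterance are
#' excluded from all analyses).
#'
#' @param typed Output of [classifyUtterances()] (possibly row-bound across
#'   conversations).
#' @return Named numeric vector over the three response types, summing to 1.
#' @export
responseTypeProportions <- function(typed) {
  kept <- typed[typed$retained, , drop = FALSE]
  if (nrow(kept) == 0L) {
    stop("no retained (non-restart, non-initial) utterances")
  }
  counts <- table(factor(as.character(kept$utterance_type),
                         levels = RESPONSE_TYPES))
  setNames(as.numeric(counts) / nrow(kept), RESPONSE_TYPES)
}

#' Floor-transfer-offset summary
#'
#' Mean, sample SD (n-1 denominator) and histogram counts of floor transfer
#' offsets, restricted to gaps and between-overlaps. Within-overlaps are
#' excluded: their timing targets are mid-utterance closures, so their FTOs
#' (measured to the reference's eventual offset) can be wildly negative.
#'
#' @param typed Output of [classifyUtterances()].
#' @param breaks Passed to [graphics::hist()] binning via [base::cut()];
#'   default bin width 250 ms over the observed range.
#' @return List with `mean_ms`, `sd_ms`, `n`, and `histogram` (data.frame of
#'   bin mid-points and counts).
#' @export
ftoSummary <- function(typed, breaks = NULL) {
  fto <- typed$fto_ms[typed$utterance_type %in%
                        c("gap", "between_overlap") & !is.na(typed$fto_ms)]
  if (length(fto) < 2L) {
    stop("need at least 2 gap/between-overlap utterances, got ", length(fto))
  }
  if (is.null(breaks)) {
    lo <- floor(min(fto) / 250) * 250
    hi <- ceiling(max(fto) / 250) * 250
    if (hi == lo) hi <- lo + 250
    breaks <- seq(lo, hi, by = 250)
  }
  bins <- cut(fto, breaks = breaks, include.lowest = TRUE)
  hist <- data.frame(mid_ms = (head(breaks, -1L) + tail(breaks, -1L)) / 2,
                     count = as.integer(table(bins)))
  list(mean_ms = mean(fto), sd_ms = sd(fto), n = length(fto),
       histogram = hist)
}
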