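## Lip-area kinematics: per-frame lip area from landmarks 48/51/54/57,
## 90-frame pre-acoustic epochs aligned to annotated acoustic onsets, and the
## maximum lip movement speed over the final 15 steps of the epoch.
##
## The primary area metric walks the quad clockwise from the left lip corner
## p1=(X1,Y1) through the top-centre p2, right corner p3 and bottom-centre
## p4. Each perimeter segment is the hypotenuse of a right triangle with
## area |Xi-Xi+1|*|Yi-Yi+1|/2 (indices wrapping, X5=X1), and a residual
## central rectangle contributes |X1-X3|*|Y2-Y4|. This overestimates the true
## polygon area (for a convex quad with extremal vertices it equals
## 2*bounding_box - shoelace) but inflates monotonically, so within-speaker
## contrasts -- the only quantities the inference uses -- are unaffected.
## The surveyor's (shoelace) area is exposed as an explicitly non-default
## alternative. Both use absolute values, so pixel-style y-down orientation
## needs no axis flip.

#' Lip area by the four-triangle-plus-rectangle rule (primary metric)
#'
#' @param quad Numeric vector `c(x1, y1, x2, y2, x3, y3, x4, y4)` or a 4x2
#'   matrix, vertices ordered clockwise from the left lip corner: landmarks
#'   48 (left corner), 51 (outer top centre), 54 (right corner), 57 (outer
#'   bottom centre).
#' @return Non-negative area in squared track units.
#' @examples
#' lipArea(c(0, 0, 1, 1, 2, 0, 1, -1))  # diamond -> 6
#' @export
lipArea <- function(quad) {
  q <- asQuad(quad)
  x <- q[, 1L]; y <- q[, 2L]
  nxt <- c(2L, 3L, 4L, 1L)
  triangles <- sum(abs(x - x[nxt]) * abs(y - y[nxt])) / 2
  rectangle <- abs(x[1L] - x[3L]) * abs(y[2L] - y[4L])
  triangles + rectangle
}

#' Polygon area by the surveyor's (shoelace) formula
#'
#' Alternative metric; the true area of the quadrilateral through the same
#' four landmarks.
#'
#' @inheritParams lipArea
#' @return Non-negative area in squared track units.
#' @export
shoelaceArea <- function(quad) {
  q <- asQuad(quad)
  x <- q[, 1L]; y <- q[, 2L]
  nxt <- c(2L, 3L, 4L, 1L)
  abs(sum(x * y[nxt] - x[nxt] * y)) / 2
}

asQuad <- function(quad) {
  if (is.matrix(quad)) {
    stopifnot(identical(dim(quad), c(4L, 2L)))
    q <- quad
  } else {
    stopifnot(length(quad) == 8L)
    q <- matrix(quad, ncol = 2L, byrow = TRUE)
  }
  if (!all(is.finite(q))) stop("non-finite lip landmark coordinate")
  q
}

## Vectorized per-frame areas for a face track (used by epoch extraction).
lipAreaSeries <- function(track, metric = c("printed", "shoelace")) {
  metric <- match.arg(metric)
  fr <- track$frames
  X <- cbind(fr$x48, fr$x51, fr$x54, fr$x57)
  Y <- cbind(fr$y48, fr$y51, fr$y54, fr$y57)
  nxt <- c(2L, 3L, 4L, 1L)
  if (metric == "printed") {
    tri <- rowSums(abs(X - X[, nxt, drop = FALSE]) *
                     abs(Y - Y[, nxt, drop = FALSE])) / 2
    tri + abs(X[, 1L] - X[, 3L]) * abs(Y[, 2L] - Y[, 4L])
  } else {
    abs(rowSums(X * Y[, nxt, drop = FALSE] -
                  X[, nxt, drop = FALSE] * Y)) / 2
  }
}

#' Extract a pre-acoustic lip-area epoch
#'
#' Takes the `n_frames` frames ending at the anchor frame, where the anchor
#' is the last frame whose timestamp lies strictly before the acoustic onset
#' (half-open window `[onset - n_frames/fps, onset)`). Epoch index 0 is
#' `n_frames` frame durations before onset, index `n_frames - 1` the last
#' frame before onset. Unsuccessful frames are handled per `fill_policy`:
#' `"interpolate"` (default) linearly interpolates runs of up to
#' `max_fill_run` consecutive unsuccessful frames from their successful
#' neighbours (the filled frames keep their `TRUE` missing-mask flag so
#' provenance is preserved), leaving longer runs and unfillable edges as
#' `NA`; `"none"` leaves all unsuccessful frames `NA`. Frames before the
#' start of the track (onset within `n_frames` of the recording start) are
#' also `NA` and flagged.
#'
#' @param track A `face_track`.
#' @param onset_ms Acoustic onset (ms).
#' @param n_frames Epoch length in frames (default 90, i.e. 3000 ms at
#'   30 fps).
#' @param fill_policy `"interpolate"` or `"none"`.
#' @param max_fill_run Longest run of unsuccessful frames to interpolate.
#' @param metric Area metric, `"printed"` (default) or `"shoelace"`.
#' @param areas Optional precomputed per-frame area series for `track`
#'   (performance path for repeated extraction).
#' @return An `area_trajectory`: list with `areas` (length `n_frames`),
#'   `missing` (logical mask), `onset_ms`, `fps`, `anchor_frame`.
#' @export
extractEpoch <- function(track, onset_ms, n_frames = 90,
                         fill_policy = c("interpolate", "none"),
                         max_fill_run = 3L, metric = "printed",
                         areas = NULL) {
  fill_policy <- match.arg(fill_policy)
  fr <- track$frames
  if (nrow(fr) == 0L || fr$timestamp_ms[1L] >= onset_ms) {
    stop("epoch window entirely outside track (onset ", onset_ms, " ms)")
  }
  anchor <- sum(fr$timestamp_ms < onset_ms)  # last frame strictly before onset
  if (anchor < 1L) {
    stop("epoch window entirely outside track (onset ", onset_ms, " ms)")
  }
  if (is.null(areas)) areas <- lipAreaSeries(track, metric = metric)
  start <- anchor - n_frames + 1L
  pad <- max(0L, 1L - start)
  idx <- max(1L, start):anchor
  a <- c(rep(NA_real_, pad), areas[idx])
  ok <- c(rep(FALSE, pad), fr$success[idx])
  a[!ok] <- NA_real_
  if (fill_policy == "interpolate" && any(!ok) && sum(ok) >= 2L) {
    runs <- rle(!ok)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    fillable <- runs$values & runs$lengths <= max_fill_run &
      starts > 1L & ends < n_frames
    if (any(fillable)) {
      filled <- approx(x = which(ok), y = a[ok], xout = seq_len(n_frames),
                       method = "linear", rule = 1L)$y
      for (r in which(fillable)) {
        span <- starts[r]:ends[r]
        ## filled values flow downstream but the frames remain flagged
        a[span] <- filled[span]
      }
    }
  }
  structure(list(areas = a, missing = !ok, onset_ms = onset_ms,
                 fps = track$fps, anchor_frame = fr$frame[anchor],
                 n_frames = n_frames),
            class = "area_trajectory")
}

#' @export
print.area_trajectory <- function(x, ...) {
  cat(sprintf("<area_trajectory> %d frames before onset at %g ms (%d missing)\n",
              x$n_frames, x$onset_ms, sum(x$missing)))
  invisible(x)
}

#' Maximum lip movement speed over the final window of an epoch
#'
#' Computes the `window` first differences over the last `window + 1` frames
#' of the trajectory, scales each by `fps` to units^2 per second, and returns
#' the one with the largest absolute magnitude.
#'
#' @param traj An [extractEpoch()] trajectory, or a bare numeric vector of
#'   areas.
#' @param fps Frames per second (taken from the trajectory when available).
#' @param window Number of final first-differences (default 15).
#' @return List with `max_speed` (non-negative, units^2/s) and
#'   `argmax_frame` (1-based epoch index of the later frame of the winning
#'   difference).
#' @examples
#' maxSpeed(c(rep(10, 75), seq(10, 9, length.out = 16)), fps = 30)
#' @export
maxSpeed <- function(traj, fps = NULL, window = 15L) {
  if (inherits(traj, "area_trajectory")) {
    if (is.null(fps)) fps <- traj$fps
    areas <- traj$areas
  } else {
    if (is.null(fps)) fps <- 30
    areas <- as.numeric(traj)
  }
  n <- length(areas)
  if (n < window + 1L) {
    stop("trajectory length ", n, " < window + 1 = ", window + 1L)
  }
  tail_areas <- areas[(n - window):n]
  if (anyNA(tail_areas)) {
    stop("missing frames in the final ", window + 1L,
         " frames; apply a fill policy upstream")
  }
  speeds <- diff(tail_areas) * fps
  k <- which.max(abs(speeds))
  list(max_speed = abs(speeds[k]), argmax_frame = (n - window) + k)
}

#' Build the tidy long-format epoch table for a coded corpus
#'
#' Extracts one epoch per retained, coded utterance and stacks them in the
#' long format consumed by [fitSliceModels()] (one row per utterance x epoch
#' frame; see [writeEpochTable()] for columns).
#'
#' @param coded Output of [codeCorpus()] with a `conversation_id` column.
#' @param tracks Named list of `face_track` objects; names
#'   `"<conversation_id>/<speaker_id>"`.
#' @param n_frames,fill_policy,max_fill_run,metric Passed to
#'   [extractEpoch()].
#' @return List with `epochs` (long data frame) and `excluded` (data frame of
#'   utterance ids dropped for missing/short tracks, with reasons).
#' @export
buildEpochTable <- function(coded, tracks, n_frames = 90,
                            fill_policy = "interpolate", max_fill_run = 3L,
                            metric = "printed") {
  kept <- coded[coded$retained, , drop = FALSE]
  if (is.null(kept$conversation_id)) kept$conversation_id <- "c1"
  if (is.null(kept$utterance_id)) {
    kept$utterance_id <- sprintf("%s_u%04d", kept$conversation_id,
                                 seq_len(nrow(kept)))
  }
  area_cache <- lapply(tracks, lipAreaSeries, metric = metric)
  rows <- vector("list", nrow(kept))
  excluded <- list()
  for (i in seq_len(nrow(kept))) {
    key <- paste0(kept$conversation_id[i], "/", kept$speaker_id[i])
    track <- tracks[[key]]
    if (is.null(track)) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(utterance_id = kept$utterance_id[i],
                   reason = "missing_track")
      next
    }
    traj <- tryCatch(
      extractEpoch(track, kept$onset_ms[i], n_frames = n_frames,
                   fill_policy = fill_policy, max_fill_run = max_fill_run,
                   metric = metric, areas = area_cache[[key]]),
      error = function(e) e)
    if (inherits(traj, "error")) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(utterance_id = kept$utterance_id[i],
                   reason = "epoch_out_of_range")
      next
    }
    rows[[i]] <- data.frame(
      utterance_id = kept$utterance_id[i],
      conversation_id = kept$conversation_id[i],
      speaker_id = kept$speaker_id[i],
      first_word = kept$first_word[i],
      word_count = kept$word_count[i],
      constraint = kept$constraint[i],
      utterance_type = as.character(kept$utterance_type[i]),
      frame_index = 0:(n_frames - 1L),
      area = traj$areas,
      missing = traj$missing,
      stringsAsFactors = FALSE)
  }
  epochs <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  if (is.null(epochs)) {
    epochs <- data.frame()
  } else {
    fps <- tracks[[1L]]$fps
    epochs$offset_ms <- (epochs$frame_index - n_frames) * 1000 / fps
    epochs$log10_wc <- log10(epochs$word_count)
    epochs$constraint_u <- as.integer(epochs$constraint == "unconstrained")
  }
  list(epochs = epochs,
       excluded = if (length(excluded)) do.call(rbind, excluded) else
         data.frame(utterance_id = character(), reason = character()))
}

#' Map a slice offset to a 0-based epoch frame index
#'
#' Offset `-n_frames * 1000/fps` maps to frame 0; offset 0 (acoustic onset)
#' falls one frame past the epoch and is clipped to the final pre-onset
#' frame.
#'
#' @param offset_ms Slice offset relative to acoustic onset (<= 0).
#' @param n_frames Epoch length.
#' @param fps Frames per second.
#' @return Integer frame index in `0:(n_frames - 1)`.
#' @export
sliceFrameIndex <- function(offset_ms, n_frames = 90, fps = 30) {
  idx <- round((offset_ms + n_frames * 1000 / fps) * fps / 1000)
  as.integer(pmin(pmax(idx, 0), n_frames - 1L))
}
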