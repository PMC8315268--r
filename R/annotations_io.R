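## Readers/writers for the pipeline's external formats: utterance-tier
## annotation tables (TSV, optionally ELAN .eaf), OpenFace-layout landmark
## CSVs, and the tidy long-format epoch table consumed by the slice models.

#' Read an utterance-tier annotation table
#'
#' Reads time-aligned utterance annotations (speaker, acoustic onset/offset in
#' milliseconds, transcript). The normative interchange format is a UTF-8 TSV
#' with header `speaker_id  onset_ms  offset_ms  transcript`; a minimal ELAN
#' `.eaf` reader is provided as convenience (one alignable tier per
#' participant).
#'
#' @param path Path to the annotation file.
#' @param dialect `"tsv"` (default) or `"eaf"`.
#' @return A `data.frame` with columns `speaker_id` (character), `onset_ms`,
#'   `offset_ms` (integer milliseconds) and `transcript` (character), in file
#'   order (for `eaf`, ordered by onset).
#' @details Each row must satisfy `offset_ms > onset_ms`, non-negative onset,
#'   and a non-empty transcript; violations raise an error naming the line.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("speaker_id\tonset_ms\toffset_ms\ttranscript",
#'              "P3\t1000\t1450\tOkay"), tf)
#' readUtteranceTier(tf)
#' @export
readUtteranceTier <- function(path, dialect = c("tsv", "eaf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (dialect == "eaf") return(readEafTier(path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) == 0L) stop("empty annotation file (no header): ", path)
  hdr <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  expected <- c("speaker_id", "onset_ms", "offset_ms", "transcript")
  if (!identical(trimws(hdr), expected)) {
    stop("bad TSV header; expected '", paste(expected, collapse = "\\t"),
         "', got '", lines[[1L]], "'")
  }
  body <- lines[-1L]
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    return(data.frame(speaker_id = character(), onset_ms = integer(),
                      offset_ms = integer(), transcript = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  n_fields <- lengths(parts)
  if (any(n_fields != 4L)) {
    bad <- which(n_fields != 4L)[1L]
    stop("malformed row at line ", bad + 1L, ": expected 4 tab-separated ",
         "fields, got ", n_fields[bad])
  }
  m <- do.call(rbind, parts)
  onset <- suppressWarnings(as.integer(m[, 2L]))
  offset <- suppressWarnings(as.integer(m[, 3L]))
  if (anyNA(onset) || anyNA(offset)) {
    bad <- which(is.na(onset) | is.na(offset))[1L]
    stop("malformed row at line ", bad + 1L, ": non-integer time field")
  }
  rec <- data.frame(speaker_id = m[, 1L], onset_ms = onset,
                    offset_ms = offset, transcript = m[, 4L],
                    stringsAsFactors = FALSE)
  validateUtteranceRecords(rec, line_offset = 1L)
  rec
}

## Minimal EAF (ELAN XML) reader: alignable annotations on tiers whose
## PARTICIPANT (or TIER_ID) names the speaker.
readEafTier <- function(path) {
  if (!requireNamespace("xml2", quietly = TRUE)) {
    stop("reading .eaf files requires the 'xml2' package")
  }
  doc <- xml2::read_xml(path)
  slots <- xml2::xml_find_all(doc, ".//TIME_ORDER/TIME_SLOT")
  slot_ms <- setNames(
    as.integer(xml2::xml_attr(slots, "TIME_VALUE")),
    xml2::xml_attr(slots, "TIME_SLOT_ID"))
  tiers <- xml2::xml_find_all(doc, ".//TIER")
  out <- list()
  for (tier in tiers) {
    spk <- xml2::xml_attr(tier, "PARTICIPANT")
    if (is.na(spk) || !nzchar(spk)) spk <- xml2::xml_attr(tier, "TIER_ID")
    anns <- xml2::xml_find_all(tier, ".//ALIGNABLE_ANNOTATION")
    if (length(anns) == 0L) next
    out[[length(out) + 1L]] <- data.frame(
      speaker_id = spk,
      onset_ms = slot_ms[xml2::xml_attr(anns, "TIME_SLOT_REF1")],
      offset_ms = slot_ms[xml2::xml_attr(anns, "TIME_SLOT_REF2")],
      transcript = xml2::xml_text(
        xml2::xml_find_first(anns, ".//ANNOTATION_VALUE")),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(speaker_id = character(), onset_ms = integer(),
                      offset_ms = integer(), transcript = character(),
                      stringsAsFactors = FALSE))
  }
  rec <- do.call(rbind, out)
  rec <- rec[order(rec$onset_ms), , drop = FALSE]
  rownames(rec) <- NULL
  validateUtteranceRecords(rec)
  rec
}

validateUtteranceRecords <- function(rec, line_offset = 0L) {
  bad <- which(rec$offset_ms <= rec$onset_ms)
  if (length(bad)) {
    stop("offset_ms <= onset_ms at line ", bad[1L] + line_offset + 1L)
  }
  if (any(rec$onset_ms < 0L)) {
    stop("negative onset_ms at line ",
         which(rec$onset_ms < 0L)[1L] + line_offset + 1L)
  }
  empty <- !nzchar(trimws(rec$transcript))
  if (any(empty)) {
    stop("empty transcript at line ", which(empty)[1L] + line_offset + 1L)
  }
  invisible(rec)
}

#' Write an utterance-tier TSV
#'
#' Inverse of [readUtteranceTier()] for the TSV dialect.
#'
#' @param records Data frame with columns `speaker_id`, `onset_ms`,
#'   `offset_ms`, `transcript`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeUtteranceTier <- function(records, path) {
  validateUtteranceRecords(records)
  lines <- c("speaker_id\tonset_ms\toffset_ms\ttranscript",
             paste(records$speaker_id, records$onset_ms, records$offset_ms,
                   records$transcript, sep = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

## Lip landmarks the pipeline needs on every successful frame.
LIP_KEY_POINTS <- c(48L, 51L, 54L, 57L)

#' Read an OpenFace 2.0-layout landmark CSV into a face track
#'
#' Parses the columns `frame`, `timestamp`, `success` plus the lip-landmark
#' coordinate columns for the selected coordinate set: `X_i`/`Y_i`
#' (millimetre 3-D estimates, the default, since areas are reported in
#' squared track units on the 3-D scale) or `x_i`/`y_i` (2-D pixels).
#' OpenFace writes a space after each comma in the header; both dialects are
#' accepted. Landmarks 48, 51, 54, 57 (outer lip corners and outer top/bottom
#' centres) are required; any other of 48-67 present is retained.
#'
#' Note: the upstream tracker is described as tracking 128 facial key points,
#' but the standard 68-point landmark scheme (indices 48-67 for the lips) is
#' what its CSV layout exposes; only 48-67 matter here.
#'
#' @param path CSV path.
#' @param coordinate_set `"3d_mm"` (default) or `"2d_pixel"`.
#' @param fps Frames per second (default 30); used for validation only.
#' @param timestamp_unit `"auto"` (default), `"s"` or `"ms"`. OpenFace writes
#'   seconds; timestamps are converted to milliseconds at read time.
#' @return A `face_track` object: list with `speaker_id` (file stem), `fps`,
#'   and `frames` (data.frame with `frame`, `timestamp_ms`, `success`, and
#'   `x<i>`/`y<i>` coordinate columns).
#' @export
readOpenFaceCsv <- function(path, coordinate_set = c("3d_mm", "2d_pixel"),
                            fps = 30, timestamp_unit = c("auto", "s", "ms")) {
  coordinate_set <- match.arg(coordinate_set)
  timestamp_unit <- match.arg(timestamp_unit)
  if (!file.exists(path)) stop("OpenFace CSV not found: ", path)
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  names(raw) <- trimws(names(raw))
  prefix <- if (coordinate_set == "3d_mm") c("X_", "Y_") else c("x_", "y_")
  needed <- c("frame", "timestamp", "success",
              paste0(rep(prefix, each = length(LIP_KEY_POINTS)),
                     LIP_KEY_POINTS))
  missing <- setdiff(needed, names(raw))
  if (length(missing)) {
    stop("OpenFace CSV missing required columns: ",
         paste(missing, collapse = ", "))
  }
  frame <- as.integer(raw$frame)
  ## OpenFace numbers frames from 1; normalize to 0-based.
  if (length(frame) && frame[1L] == 1L) frame <- frame - 1L
  if (length(frame) && (frame[1L] != 0L || any(diff(frame) != 1L))) {
    stop("non-monotonic or gapped frame index in ", path)
  }
  ts <- as.numeric(raw$timestamp)
  if (timestamp_unit == "auto") {
    step <- if (length(ts) > 1L) stats::median(diff(ts)) else ts[1L]
    timestamp_unit <- if (isTRUE(step < 1)) "s" else "ms"
  }
  timestamp_ms <- if (timestamp_unit == "s") ts * 1000 else ts
  frame_ms <- 1000 / fps
  if (length(timestamp_ms) > 1L) {
    drift <- abs(timestamp_ms - frame * frame_ms)
    if (any(drift > frame_ms)) {
      stop("timestamps inconsistent with frame index at ", fps, " fps in ",
           path)
    }
  }
  present <- 48:67
  keep <- unlist(lapply(present, function(i) {
    cols <- paste0(prefix, i)
    if (all(cols %in% names(raw))) cols else character()
  }))
  frames <- data.frame(frame = frame, timestamp_ms = timestamp_ms,
                       success = as.integer(raw$success) != 0L)
  coords <- raw[keep]
  names(coords) <- tolower(sub("_", "", names(coords), fixed = TRUE))
  frames <- cbind(frames, coords)
  structure(list(speaker_id = sub("\\.[^.]*$", "", basename(path)),
                 fps = fps, coordinate_set = coordinate_set, frames = frames),
            class = "face_track")
}

#' Construct a face track from a frame table
#'
#' Low-level constructor used by the synthetic generator and tests.
#'
#' @param frames Data frame with `frame` (0-based, consecutive),
#'   `timestamp_ms`, `success` (logical) and `x<i>`/`y<i>` columns covering at
#'   least landmarks 48, 51, 54, 57.
#' @param speaker_id Speaker label.
#' @param fps Frames per second.
#' @return A `face_track` object.
#' @export
faceTrack <- function(frames, speaker_id = "S", fps = 30) {
  stopifnot(is.data.frame(frames))
  need <- c("frame", "timestamp_ms", "success",
            paste0(rep(c("x", "y"), each = 4L), LIP_KEY_POINTS))
  missing <- setdiff(need, names(frames))
  if (length(missing)) stop("face track missing columns: ",
                            paste(missing, collapse = ", "))
  if (nrow(frames) && (frames$frame[1L] != 0L ||
                       any(diff(frames$frame) != 1L))) {
    stop("frame index must be consecutive integers from 0")
  }
  structure(list(speaker_id = speaker_id, fps = fps,
                 coordinate_set = "3d_mm", frames = frames),
            class = "face_track")
}

#' @export
print.face_track <- function(x, ...) {
  cat(sprintf("<face_track> speaker %s: %d frames @ %g fps (%.1f s), %d unsuccessful\n",
              x$speaker_id, nrow(x$frames), x$fps,
              nrow(x$frames) / x$fps, sum(!x$frames$success)))
  invisible(x)
}

#' Write a face track as an OpenFace-layout CSV
#'
#' Emits `frame` (1-based as OpenFace does), `timestamp` (seconds),
#' `confidence`, `success` and `X_i`/`Y_i` columns for the landmarks present.
#'
#' @param track A `face_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeOpenFaceCsv <- function(track, path) {
  fr <- track$frames
  coord_cols <- grep("^[xy][0-9]+$", names(fr), value = TRUE)
  idx <- sort(unique(as.integer(sub("^[xy]", "", coord_cols))))
  out <- data.frame(frame = fr$frame + 1L,
                    face_id = 0L,
                    timestamp = round(fr$timestamp_ms / 1000, 3),
                    confidence = ifelse(fr$success, 0.98, 0.05),
                    success = as.integer(fr$success))
  for (i in idx) out[[paste0("X_", i)]] <- round(fr[[paste0("x", i)]], 3)
  for (i in idx) out[[paste0("Y_", i)]] <- round(fr[[paste0("y", i)]], 3)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the tidy long-format epoch table
#'
#' One row per (utterance, epoch frame). Columns: `utterance_id`,
#' `conversation_id`, `speaker_id`, `first_word`, `word_count`, `constraint`,
#' `utterance_type`, `frame_index` (0-based within the epoch; index 0 is
#' `n_frames` frame durations before acoustic onset), `area`, `missing`.
#' Frame offsets in milliseconds are recomputed from `frame_index` on read, so
#' the table round-trips losslessly.
#'
#' @param epochs Long-format epoch data frame (see [buildEpochTable()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeEpochTable <- function(epochs, path) {
  cols <- epochTableColumns()
  missing <- setdiff(cols, names(epochs))
  if (length(missing)) stop("epoch table missing columns: ",
                            paste(missing, collapse = ", "))
  counts <- table(epochs$utterance_id)
  if (length(unique(counts)) > 1L) {
    stop("ragged epochs: all utterances must have the same number of frames")
  }
  write.csv(epochs[cols], path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read the tidy epoch table written by [writeEpochTable()]
#'
#' @param path CSV path.
#' @param fps Frames per second used to recompute per-frame offsets.
#' @return Data frame in the layout of [buildEpochTable()].
#' @export
readEpochTable <- function(path, fps = 30) {
  tab <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(utterance_id = "character",
                                 conversation_id = "character",
                                 speaker_id = "character",
                                 first_word = "character",
                                 constraint = "character",
                                 utterance_type = "character"))
  tab$missing <- as.logical(tab$missing)
  n_frames <- max(tab$frame_index) + 1L
  tab$offset_ms <- (tab$frame_index - n_frames) * 1000 / fps
  tab$log10_wc <- log10(tab$word_count)
  tab$constraint_u <- as.integer(tab$constraint == "unconstrained")
  tab[c(epochTableColumns(), "offset_ms", "log10_wc", "constraint_u")]
}

epochTableColumns <- function() {
  c("utterance_id", "conversation_id", "speaker_id", "first_word",
    "word_count", "constraint", "utterance_type", "frame_index", "area",
    "missing")
}
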