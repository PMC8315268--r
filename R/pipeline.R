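## End-to-end orchestration: typing -> labial coding -> epoch extraction ->
## time-slice models (+ Johnson-Neyman) -> maximum-speed model, with
## exclusion accounting and a reproducibility manifest.

#' Analyze an in-memory corpus
#'
#' Runs the full analysis chain on already-loaded objects. This is the core
#' the file-based [runPipeline()] wraps, and the entry point simulation
#' studies use.
#'
#' @param utterances Annotation data frame (`conversation_id`, `speaker_id`,
#'   `onset_ms`, `offset_ms`, `transcript`); each conversation is typed
#'   independently.
#' @param tracks Named list `"<conversation_id>/<speaker_id>"` ->
#'   `face_track`.
#' @param lexicon A [readPronLexicon()] lexicon.
#' @param overrides Optional named override vector (see [codeCorpus()]).
#' @param slices A [sliceSpec()].
#' @param maximal Maximal random structure for backward selection.
#' @param alpha Significance level.
#' @param n_frames Epoch length in frames.
#' @param fill_policy,max_fill_run Passed to [extractEpoch()].
#' @param speed Fit the maximum-speed model (default TRUE).
#' @param bootstrap_B If > 0, bootstrap prediction intervals at word counts
#'   2 and 8 for every slice fit (expensive; default 0 = skip).
#' @param seed Seed used for the bootstrap stage.
#' @return A `posture_pipeline_result` list: `typed`, `epochs`,
#'   `slice_results`, `speed_fit`, `fto`, `proportions`, `exclusions`,
#'   `predictions` (if bootstrapped).
#' @export
analyzeCorpus <- function(utterances, tracks, lexicon = readPronLexicon(),
                          overrides = NULL, slices = sliceSpec(),
                          maximal = maximalRandom(), alpha = 0.05,
                          n_frames = 90, fill_policy = "interpolate",
                          max_fill_run = 3L, speed = TRUE,
                          bootstrap_B = 0L, seed = 1L) {
  if (is.null(utterances$conversation_id)) utterances$conversation_id <- "c1"
  typed <- do.call(rbind, lapply(split(utterances,
                                       utterances$conversation_id),
                                 classifyUtterances))
  rownames(typed) <- NULL
  typed <- codeCorpus(typed, lexicon = lexicon, overrides = overrides)
  n_total <- nrow(typed)
  n_restart <- sum(typed$utterance_type == "restart")
  n_initial <- sum(typed$utterance_type == "initial")

  eb <- buildEpochTable(typed, tracks, n_frames = n_frames,
                        fill_policy = fill_policy,
                        max_fill_run = max_fill_run)
  epochs <- eb$epochs
  slice_results <- fitSliceModels(epochs, slices = slices,
                                  maximal = maximal, alpha = alpha,
                                  n_frames = n_frames)
  speed_fit <- NULL
  stab <- NULL
  if (isTRUE(speed)) {
    stab <- speedTable(epochs, fps = slices$fps)
    ## the default maximal already carries the by-speaker constraint slope
    speed_fit <- fitSpeedModel(stab, maximal = maximal)
  }
  predictions <- NULL
  if (bootstrap_B > 0L) {
    predictions <- lapply(slice_results$fits, bootstrapPredictions,
                          B = bootstrap_B, seed = seed)
  }
  exclusions <- c(total_utterances = n_total, restarts = n_restart,
                  initials = n_initial,
                  retained = sum(typed$retained),
                  missing_track_or_range = nrow(eb$excluded),
                  speed_dropped = if (is.null(stab)) NA_integer_ else
                    attr(stab, "dropped"))
  structure(list(typed = typed, epochs = epochs,
                 slice_results = slice_results, speed_fit = speed_fit,
                 speed_table = stab,
                 fto = ftoSummary(typed),
                 proportions = responseTypeProportions(typed),
                 exclusions = exclusions, predictions = predictions,
                 alpha = alpha),
            class = "posture_pipeline_result")
}

#' @export
print.posture_pipeline_result <- function(x, ...) {
  ex <- x$exclusions
  cat("<posture_pipeline_result>\n")
  cat(sprintf("  utterances: %d total, %d restarts + %d initials expunged -> %d retained\n",
              ex[["total_utterances"]], ex[["restarts"]], ex[["initials"]],
              ex[["retained"]]))
  cat(sprintf("  response mix: gap %.0f%%, between-overlap %.0f%%, within-overlap %.0f%%\n",
              100 * x$proportions[["gap"]],
              100 * x$proportions[["between_overlap"]],
              100 * x$proportions[["within_overlap"]]))
  cat(sprintf("  floor transfer offset: mean %.2f ms (SD %.2f, n %d)\n",
              x$fto$mean_ms, x$fto$sd_ms, x$fto$n))
  print(x$slice_results)
  if (!is.null(x$speed_fit)) {
    sw <- x$speed_fit$coef[x$speed_fit$coef$term == "log10_wc", ]
    cat(sprintf("  max speed ~ word count: beta %.2f (SE %.2f, t(%.1f) = %.2f, p = %.3g)\n",
                sw$beta, sw$se, sw$df, sw$t, sw$p))
  }
  invisible(x)
}

#' Run the file-based pipeline
#'
#' Reads annotation TSVs and OpenFace-layout CSVs, executes
#' [analyzeCorpus()], and writes result tables plus a manifest to
#' `out_dir`.
#'
#' @param annotations Named character vector or list: conversation id ->
#'   annotation TSV path (names default to file stems).
#' @param track_paths Named character vector: `"<conversation>/<speaker>"`
#'   -> OpenFace CSV path. May be NULL if `track_dir` is given, in which
#'   case files named `<conversation>_<speaker>_openface.csv` are expected.
#' @param track_dir Directory to scan when `track_paths` is NULL.
#' @param out_dir Output directory (created). Written files:
#'   `typed_utterances.csv`, `epochs.csv`, `slice_models.csv`,
#'   `jn_regions.csv`, `speed_model.csv`, `run_manifest.json`.
#' @param lexicon_path Lexicon file (default: bundled lexicon).
#' @param overrides_path Optional overrides TSV.
#' @param coordinate_set Passed to [readOpenFaceCsv()].
#' @param ... Further arguments to [analyzeCorpus()].
#' @param seed Seed recorded in the manifest and used downstream.
#' @return The `posture_pipeline_result`, invisibly.
#' @export
runPipeline <- function(annotations, track_paths = NULL, track_dir = NULL,
                        out_dir, lexicon_path = NULL, overrides_path = NULL,
                        coordinate_set = "3d_mm", seed = 1L, ...) {
  if (is.null(names(annotations))) {
    names(annotations) <- sub("_utterances$", "",
                              sub("\\.[^.]*$", "", basename(annotations)))
  }
  utterances <- do.call(rbind, lapply(names(annotations), function(cid) {
    tab <- readUtteranceTier(annotations[[cid]])
    tab$conversation_id <- cid
    tab
  }))
  if (is.null(track_paths)) {
    if (is.null(track_dir)) stop("supply track_paths or track_dir")
    files <- list.files(track_dir, pattern = "_openface\\.csv$",
                        full.names = TRUE)
    keys <- sub("_openface$", "", sub("\\.[^.]*$", "", basename(files)))
    keys <- sub("_", "/", keys)  # first underscore separates conversation
    track_paths <- setNames(files, keys)
  }
  tracks <- lapply(track_paths, readOpenFaceCsv,
                   coordinate_set = coordinate_set)
  lexicon <- if (is.null(lexicon_path)) readPronLexicon() else
    readPronLexicon(lexicon_path)
  overrides <- if (is.null(overrides_path)) NULL else
    readOverrides(overrides_path)
  set.seed(seed)
  res <- analyzeCorpus(utterances, tracks, lexicon = lexicon,
                       overrides = overrides, seed = seed, ...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(res$typed, file.path(out_dir, "typed_utterances.csv"),
            row.names = FALSE)
  writeEpochTable(res$epochs, file.path(out_dir, "epochs.csv"))
  write.csv(res$slice_results$summary,
            file.path(out_dir, "slice_models.csv"), row.names = FALSE)
  jn_rows <- do.call(rbind, lapply(names(res$slice_results$jn), function(k) {
    r <- res$slice_results$jn[[k]]
    if (is.null(r) || nrow(r) == 0L) return(NULL)
    cbind(offset_ms = as.numeric(k), as.data.frame(r))
  }))
  if (is.null(jn_rows)) {
    jn_rows <- data.frame(offset_ms = numeric(), lo_log10 = numeric(),
                          hi_log10 = numeric(), lo_wc = numeric(),
                          hi_wc = numeric())
  }
  write.csv(jn_rows, file.path(out_dir, "jn_regions.csv"),
            row.names = FALSE)
  if (!is.null(res$speed_fit)) {
    write.csv(res$speed_fit$coef, file.path(out_dir, "speed_model.csv"),
              row.names = FALSE)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("lipposture")),
    seed = seed,
    annotations = unname(vapply(annotations, normalizePath, "")),
    n_tracks = length(tracks),
    exclusions = as.list(res$exclusions),
    input_md5 = vapply(unname(unlist(c(annotations, track_paths))),
                       function(p) unname(tools::md5sum(p)), ""))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

#' Validate pipeline inputs without analyzing
#'
#' Schema-checks annotation and track files, returning (not raising) the
#' problems found.
#'
#' @inheritParams runPipeline
#' @return Character vector of problems (empty when everything parses).
#' @export
validateInputs <- function(annotations, track_paths = NULL,
                           track_dir = NULL, lexicon_path = NULL) {
  problems <- character()
  for (p in unlist(annotations)) {
    err <- tryCatch({ readUtteranceTier(p); NULL },
                    error = function(e) conditionMessage(e))
    if (!is.null(err)) problems <- c(problems, paste0(p, ": ", err))
  }
  if (is.null(track_paths) && !is.null(track_dir)) {
    track_paths <- list.files(track_dir, pattern = "_openface\\.csv$",
                              full.names = TRUE)
  }
  for (p in unlist(track_paths)) {
    err <- tryCatch({ readOpenFaceCsv(p); NULL },
                    error = function(e) conditionMessage(e))
    if (!is.null(err)) problems <- c(problems, paste0(p, ": ", err))
  }
  if (!is.null(lexicon_path)) {
    err <- tryCatch({ readPronLexicon(lexicon_path); NULL },
                    error = function(e) conditionMessage(e))
    if (!is.null(err)) problems <- c(problems,
                                     paste0(lexicon_path, ": ", err))
  }
  problems
}
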