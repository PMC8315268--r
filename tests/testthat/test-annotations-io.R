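test_that("utterance TSV reader maps fields and preserves order", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("speaker_id\tonset_ms\toffset_ms\ttranscript",
               "P3\t1000\t1450\tOkay"), tf)
  rec <- readUtteranceTier(tf)
  expect_equal(rec$speaker_id, "P3")
  expect_identical(rec$onset_ms, 1000L)
  expect_identical(rec$offset_ms, 1450L)
  expect_equal(rec$transcript, "Okay")

  writeLines("speaker_id\tonset_ms\toffset_ms\ttranscript", tf)
  expect_equal(nrow(readUtteranceTier(tf)), 0L)

  writeLines(c("speaker_id\tonset_ms\toffset_ms\ttranscript",
               "A\t0\t900\tso anyway",
               "B\t700\t1400\tyeah",
               "A\t1500\t2600\tright then"), tf)
  rec <- readUtteranceTier(tf)
  expect_equal(rec$speaker_id, c("A", "B", "A"))
  expect_equal(rec$onset_ms, c(0L, 700L, 1500L))
  expect_equal(rec$transcript, c("so anyway", "yeah", "right then"))
})

test_that("utterance TSV reader rejects malformed rows with line numbers", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("speaker_id\tonset_ms\toffset_ms\ttranscript",
               "A\t0\t900\tso anyway",
               "B\t700\tnot_a_number\tyeah"), tf)
  expect_error(readUtteranceTier(tf), "line 3")
  writeLines(c("speaker_id\tonset_ms\toffset_ms\ttranscript",
               "A\t900\t900\toops"), tf)
  expect_error(readUtteranceTier(tf), "offset_ms <= onset_ms")
  writeLines(c("speaker_id\tonset_ms\toffset_ms\ttranscript",
               "A\t0\t900"), tf)
  expect_error(readUtteranceTier(tf), "4 tab-separated")
})

test_that("utterance TSV round-trips through the writer", {
  rec <- data.frame(speaker_id = c("A", "B"), onset_ms = c(0L, 1200L),
                    offset_ms = c(1000L, 2000L),
                    transcript = c("well that's fine", "mmhmm"),
                    stringsAsFactors = FALSE)
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeUtteranceTier(rec, tf)
  expect_equal(readUtteranceTier(tf), rec)
})

makeOpenFaceText <- function(spaced = FALSE) {
  hdr <- c("frame", "face_id", "timestamp", "confidence", "success",
           "X_48", "X_51", "X_54", "X_57", "Y_48", "Y_51", "Y_54", "Y_57")
  sep <- if (spaced) ", " else ","
  rows <- c(
    paste(c(1, 0, 0.000, 0.98, 1, -27.5, 0, 27.5, 0, 100, 91, 100, 111),
          collapse = ","),
    paste(c(2, 0, 0.033, 0.98, 1, -27.5, 0, 27.5, 0, 100, 90, 100, 112),
          collapse = ","))
  c(paste(hdr, collapse = sep), rows)
}

test_that("OpenFace reader handles both header dialects identically", {
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(makeOpenFaceText(spaced = FALSE), f1)
  writeLines(makeOpenFaceText(spaced = TRUE), f2)
  t1 <- readOpenFaceCsv(f1)
  t2 <- readOpenFaceCsv(f2)
  expect_equal(t1$frames, t2$frames)
  expect_equal(nrow(t1$frames), 2L)
  expect_equal(t1$frames$x48, c(-27.5, -27.5))
  expect_equal(t1$frames$y51, c(91, 90))
  # timestamps were in seconds and are converted to ms
  expect_equal(t1$frames$timestamp_ms, c(0, 33))
})

test_that("OpenFace reader flags unsuccessful frames and bad files", {
  f <- withr::local_tempfile(fileext = ".csv")
  txt <- makeOpenFaceText()
  txt[3] <- sub("0.98,1", "0.05,0", txt[3])
  writeLines(txt, f)
  trk <- readOpenFaceCsv(f)
  expect_equal(trk$frames$success, c(TRUE, FALSE))

  writeLines(gsub("X_57", "X_99", txt), f)
  expect_error(readOpenFaceCsv(f), "X_57")

  txt2 <- makeOpenFaceText()
  txt2[3] <- sub("^2,", "7,", txt2[3])
  writeLines(txt2, f)
  expect_error(readOpenFaceCsv(f), "non-monotonic|gapped")
})

test_that("EAF tier reading matches the TSV dialect", {
  eaf <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<ANNOTATION_DOCUMENT><TIME_ORDER>',
    '<TIME_SLOT TIME_SLOT_ID="ts1" TIME_VALUE="0"/>',
    '<TIME_SLOT TIME_SLOT_ID="ts2" TIME_VALUE="900"/>',
    '<TIME_SLOT TIME_SLOT_ID="ts3" TIME_VALUE="1100"/>',
    '<TIME_SLOT TIME_SLOT_ID="ts4" TIME_VALUE="1600"/>',
    '</TIME_ORDER>',
    '<TIER TIER_ID="utt@A" PARTICIPANT="A"><ANNOTATION>',
    '<ALIGNABLE_ANNOTATION ANNOTATION_ID="a1" TIME_SLOT_REF1="ts1"',
    ' TIME_SLOT_REF2="ts2"><ANNOTATION_VALUE>so anyway</ANNOTATION_VALUE>',
    '</ALIGNABLE_ANNOTATION></ANNOTATION></TIER>',
    '<TIER TIER_ID="utt@B" PARTICIPANT="B"><ANNOTATION>',
    '<ALIGNABLE_ANNOTATION ANNOTATION_ID="a2" TIME_SLOT_REF1="ts3"',
    ' TIME_SLOT_REF2="ts4"><ANNOTATION_VALUE>yeah</ANNOTATION_VALUE>',
    '</ALIGNABLE_ANNOTATION></ANNOTATION></TIER>',
    '</ANNOTATION_DOCUMENT>')
  f <- withr::local_tempfile(fileext = ".eaf")
  writeLines(eaf, f)
  rec <- readUtteranceTier(f, dialect = "eaf")
  expect_equal(rec$speaker_id, c("A", "B"))
  expect_equal(rec$onset_ms, c(0L, 1100L))
  expect_equal(rec$offset_ms, c(900L, 1600L))
  expect_equal(rec$transcript, c("so anyway", "yeah"))
})

test_that("epoch table round-trips losslessly and rejects ragged epochs", {
  set.seed(42)
  n_frames <- 12L
  mk <- function(id, constraint) {
    data.frame(utterance_id = id, conversation_id = "c1", speaker_id = "S1",
               first_word = "yeah", word_count = 2L, constraint = constraint,
               utterance_type = "gap", frame_index = 0:(n_frames - 1L),
               area = round(runif(n_frames, 900, 1700), 6),
               missing = c(TRUE, rep(FALSE, n_frames - 1L)),
               stringsAsFactors = FALSE)
  }
  epochs <- rbind(mk("u1", "constrained"), mk("u2", "unconstrained"))
  f <- withr::local_tempfile(fileext = ".csv")
  writeEpochTable(epochs, f)
  back <- readEpochTable(f)
  rownames(epochs) <- NULL
  expect_equal(back[names(epochs)], epochs)
  expect_setequal(unique(back$constraint), c("constrained", "unconstrained"))
  # one epoch of n frames -> n data rows per utterance
  expect_equal(sum(back$utterance_id == "u1"), n_frames)

  ragged <- epochs[-2L, ]
  expect_error(writeEpochTable(ragged, f), "ragged")
})
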