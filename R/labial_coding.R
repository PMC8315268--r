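## Labial-constraint coding from the first syllable of an utterance's first
## word. An utterance is labially constrained when its first syllable forces
## a small lip area: the syllable's initial consonant is bilabial,
## labiodental or rounded (IPA /b f m p r(turned) v w/, ARPABET B F M P R V
## W), or its nuclear vowel is rounded (IPA /open-o, o, horseshoe-u, u/,
## ARPABET AO OW UH UW; OY also counts, its nucleus being the rounded
## open-o). Vowel-initial words are judged on the vowel alone; in onset
## clusters only the first consonant is tested.

ARPABET_VOWELS <- c("AA", "AE", "AH", "AO", "AW", "AY", "EH", "ER", "EY",
                    "IH", "IY", "OW", "OY", "UH", "UW")
LABIAL_ONSETS <- c("B", "F", "M", "P", "R", "V", "W")
ROUNDED_NUCLEI <- c("AO", "OW", "UH", "UW", "OY")

#' Read a pronunciation lexicon (CMU dictionary dialect)
#'
#' Plain-text lines `WORD  PH1 PH2 ...` in ARPABET with optional stress
#' digits; `;;;` starts a comment. Variant entries (`WORD(2)`) after the
#' first are ignored. Words are case-folded.
#'
#' @param path Lexicon file. The package ships a small lexicon covering the
#'   bundled vocabulary at
#'   `system.file("extdata", "labial_lexicon.dict", package = "lipposture")`.
#' @return A `pron_lexicon` object (named list word -> character vector of
#'   phones, stress digits stripped).
#' @export
readPronLexicon <- function(path = defaultLexiconPath()) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub(";;;.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  entries <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\\s+")[[1L]]
    word <- tolower(sub("\\([0-9]+\\)$", "", parts[1L]))
    if (!is.null(entries[[word]])) next  # keep first variant
    phones <- toupper(gsub("[0-9]", "", parts[-1L]))
    if (length(phones) == 0L) stop("lexicon entry with no phones: ", word)
    if (!any(phones %in% ARPABET_VOWELS)) {
      stop("lexicon entry with no vowel phoneme: ", word)
    }
    entries[[word]] <- phones
  }
  structure(entries, class = "pron_lexicon")
}

defaultLexiconPath <- function() {
  system.file("extdata", "labial_lexicon.dict", package = "lipposture",
              mustWork = TRUE)
}

#' @export
print.pron_lexicon <- function(x, ...) {
  cat(sprintf("<pron_lexicon> %d entries\n", length(x)))
  invisible(x)
}

#' Code one word as labially constrained or unconstrained
#'
#' Looks the (case-folded, punctuation-stripped) word up in the lexicon and
#' applies the first-syllable rule: constrained if the syllable-initial
#' consonant is in B F M P R V W, or (checked second) if the first nuclear
#' vowel is rounded (AO OW UH UW, plus OY whose nucleus is rounded).
#'
#' @param word A single word token.
#' @param lexicon A [readPronLexicon()] object.
#' @param overrides Optional named character vector word ->
#'   `"constrained"`/`"unconstrained"`; takes precedence over the lexicon.
#' @return List with `value` (`"constrained"`/`"unconstrained"`) and `basis`
#'   (`"onset_consonant"`, `"nuclear_vowel"` or `"neither"`).
#' @examples
#' lex <- readPronLexicon()
#' codeConstraint("Yeah", lex)   # unconstrained
#' codeConstraint("No", lex)     # constrained: rounded nucleus /ow/
#' codeConstraint("Which", lex)  # constrained: onset /w/
#' @export
codeConstraint <- function(word, lexicon, overrides = NULL) {
  w <- normalizeWord(word)
  if (!is.null(overrides) && w %in% names(overrides)) {
    value <- match.arg(unname(overrides[[w]]),
                       c("constrained", "unconstrained"))
    return(list(value = value, basis = "override"))
  }
  phones <- lexicon[[w]]
  if (is.null(phones)) {
    stop("word not in lexicon: '", w,
         "' (supply an overrides table for out-of-lexicon words)")
  }
  first_vowel <- which(phones %in% ARPABET_VOWELS)[1L]
  onset <- if (first_vowel > 1L) phones[seq_len(first_vowel - 1L)] else
    character()
  if (length(onset) && onset[1L] %in% LABIAL_ONSETS) {
    return(list(value = "constrained", basis = "onset_consonant"))
  }
  if (phones[first_vowel] %in% ROUNDED_NUCLEI) {
    return(list(value = "constrained", basis = "nuclear_vowel"))
  }
  list(value = "unconstrained", basis = "neither")
}

#' Label a typed corpus with labial constraints
#'
#' Adds `constraint` and `constraint_basis` columns, coding each utterance
#' from its `first_word`. Labels depend only on the first word. Out-of-lexicon
#' words are reported in aggregate.
#'
#' @param typed Output of [classifyUtterances()].
#' @param lexicon A [readPronLexicon()] object.
#' @param overrides Optional named vector word -> label, consulted before the
#'   lexicon (see [readOverrides()] for the file format).
#' @return `typed` with `constraint` and `constraint_basis` columns.
#' @export
codeCorpus <- function(typed, lexicon = readPronLexicon(), overrides = NULL) {
  if (nrow(typed) == 0L) {
    typed$constraint <- character(0)
    typed$constraint_basis <- character(0)
    return(typed)
  }
  words <- unique(typed$first_word)
  resolvable <- vapply(words, function(w) {
    !is.null(lexicon[[w]]) ||
      (!is.null(overrides) && w %in% names(overrides))
  }, logical(1L))
  if (any(!resolvable)) {
    stop("words not in lexicon or overrides: ",
         paste(sort(words[!resolvable]), collapse = ", "))
  }
  labels <- lapply(words, codeConstraint, lexicon = lexicon,
                   overrides = overrides)
  value <- setNames(vapply(labels, `[[`, "", "value"), words)
  basis <- setNames(vapply(labels, `[[`, "", "basis"), words)
  typed$constraint <- unname(value[typed$first_word])
  typed$constraint_basis <- unname(basis[typed$first_word])
  typed
}

#' Read a constraint-override table
#'
#' Two-column TSV `word<TAB>label` with label `constrained` or
#' `unconstrained`; no header.
#'
#' @param path TSV path.
#' @return Named character vector usable as `overrides` in [codeCorpus()].
#' @export
readOverrides <- function(path) {
  tab <- read.csv(path, sep = "\t", header = FALSE,
                  col.names = c("word", "label"), stringsAsFactors = FALSE)
  bad <- !tab$label %in% c("constrained", "unconstrained")
  if (any(bad)) stop("bad override label(s): ",
                     paste(unique(tab$label[bad]), collapse = ", "))
  setNames(tab$label, normalizeWord(tab$word))
}
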