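#' Text normalization rules
#'
#' The preprocessing applied before embedding and feature extraction:
#' HTML entities are replaced by their characters, clinical abbreviations
#' are expanded on whole-token boundaries, case is folded, and an optional
#' character set is stripped. The default abbreviation lexicon is small and
#' deliberately explicit — it is data, not code, and can be extended.
#' Applying the rules twice gives the same result as applying them once.
#'
#' @param abbreviation_lexicon Named character vector mapping tokens to
#'   expansions. Keys are matched as whole tokens only (a trailing period
#'   in the key is part of the token, so `"pt."` and `"pt"` can both map).
#' @param entity_map Named character vector mapping HTML entities to
#'   characters.
#' @param lowercase Fold to lower case.
#' @param strip_characters Characters removed outright.
#' @return A list of class `normalization_rules`.
#' @export
#' @examples
#' normalize_text("Pt. denies &quot;pain&quot;", normalization_rules())
normalization_rules <- function(
    abbreviation_lexicon = default_abbreviations(),
    entity_map = default_entities(),
    lowercase = TRUE,
    strip_characters = character()) {
  structure(list(abbreviation_lexicon = abbreviation_lexicon,
                 entity_map = entity_map,
                 lowercase = lowercase,
                 strip_characters = strip_characters),
            class = "normalization_rules")
}

#' @rdname normalization_rules
#' @export
default_abbreviations <- function() {
  c("pt." = "patient", "pt" = "patient", "pts" = "patients",
    "yo" = "year old", "y.o." = "year old",
    "wks." = "weeks", "wks" = "weeks",
    "c/o" = "complains of", "sob" = "shortness of breath",
    "fob" = "father of baby", "dv" = "domestic violence",
    "sw" = "social worker")
}

#' @rdname normalization_rules
#' @export
default_entities <- function() {
  c("&quot;" = "\"", "&amp;" = "&", "&lt;" = "<", "&gt;" = ">",
    "&#39;" = "'", "&nbsp;" = " ")
}

#' Normalize a text string
#'
#' Applies [normalization_rules()]: entity replacement, case folding,
#' whole-token abbreviation expansion (longest keys first), character
#' stripping and whitespace collapsing. Idempotent.
#'
#' @param text Character vector.
#' @param rules A [normalization_rules()] object.
#' @return Character vector of normalized text.
#' @export
normalize_text <- function(text, rules = normalization_rules()) {
  stopifnot(inherits(rules, "normalization_rules"))
  out <- text
  for (ent in names(rules$entity_map)) {
    out <- gsub(ent, rules$entity_map[[ent]], out, fixed = TRUE)
  }
  if (isTRUE(rules$lowercase)) out <- tolower(out)
  lex <- rules$abbreviation_lexicon
  if (length(lex) > 0) {
    if (isTRUE(rules$lowercase)) {
      names(lex) <- tolower(names(lex))
      lex[] <- tolower(lex)
    }
    # longest keys first so "pt." wins over "pt"
    lex <- lex[order(-nchar(names(lex)))]
    for (key in names(lex)) {
      pat <- paste0("(?<![[:alnum:]])", escape_regex(key), "(?![[:alnum:].])")
      out <- gsub(pat, lex[[key]], out, perl = TRUE,
                  ignore.case = !isTRUE(rules$lowercase))
    }
  }
  if (length(rules$strip_characters) > 0) {
    cls <- paste0("[", paste0("\\", rules$strip_characters, collapse = ""), "]")
    out <- gsub(cls, "", out)
  }
  out <- gsub("[[:space:]]+", " ", out)
  trimws(out)
}

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

#' Extract free-text blocks from a clinical note
#'
#' Returns the narrative portions of a note, excluding structured-section
#' content. Structured sections are carried separately in the corpus
#' schema, so the free text is returned as blocks split on blank lines;
#' any block matching one of the structured-header patterns (a short line
#' ending in a colon, e.g. `"Vitals:"`, optionally followed by templated
#' content) is dropped.
#'
#' @param note A one-row notes tibble or a list with `free_text`.
#' @param header_patterns Regular expressions identifying structured
#'   headers embedded in free text.
#' @return Character vector of free-text blocks (possibly empty).
#' @export
extract_free_text <- function(note,
                              header_patterns = "^[A-Za-z][A-Za-z /]{0,30}:\\s*$") {
  free_text <- if (is.data.frame(note)) note$free_text[[1]] else note$free_text
  if (is.null(free_text) || !nzchar(trimws(free_text))) return(character())
  blocks <- strsplit(free_text, "\n{2,}")[[1]]
  blocks <- trimws(blocks)
  blocks <- blocks[nzchar(blocks)]
  structured <- vapply(blocks, function(b) {
    first <- strsplit(b, "\n")[[1]][1]
    any(vapply(header_patterns, function(p) grepl(p, first), logical(1)))
  }, logical(1))
  unname(blocks[!structured])
}

# Abbreviations whose trailing period never ends a sentence.
protected_abbreviations <- function() {
  c("dr.", "mr.", "mrs.", "ms.", "pt.", "wks.", "yo.", "y.o.", "vs.",
    "e.g.", "i.e.", "approx.", "hx.", "st.")
}

#' Segment text into sentences
#'
#' Deterministic rule-based splitting on `.`, `?`, `!` followed by
#' whitespace, and on newlines, with a protection list of clinical
#' abbreviations and decimal numbers whose periods never terminate a
#' sentence. Concatenating the result reproduces the input's
#' non-whitespace content.
#'
#' @param text A single string.
#' @return Character vector of sentences (empty for blank input).
#' @export
#' @examples
#' segment_sentences("Pt. stable. Fetal heart rate 140.2 bpm. Plan: monitor.")
segment_sentences <- function(text) {
  stopifnot(length(text) == 1)
  if (is.na(text) || !nzchar(trimws(text))) return(character())
  x <- text
  guard <- "\x01"
  # protect decimal numbers: 140.2 -> 140<guard>2
  x <- gsub("(?<=[0-9])\\.(?=[0-9])", guard, x, perl = TRUE)
  for (ab in protected_abbreviations()) {
    pat <- paste0("(?<![[:alnum:]])", escape_regex(ab))
    m <- gregexpr(pat, x, perl = TRUE, ignore.case = TRUE)
    regmatches(x, m) <- lapply(regmatches(x, m), function(mm) {
      gsub(".", guard, mm, fixed = TRUE)
    })
  }
  pieces <- strsplit(x, "(?<=[.?!])[[:space:]]+|\n+", perl = TRUE)[[1]]
  pieces <- gsub(guard, ".", pieces, fixed = TRUE)
  pieces <- trimws(pieces)
  pieces[nzchar(pieces)]
}

#' Build 1- to 3-sentence candidate windows
#'
#' All contiguous runs of 1 up to `max_width` sentences, the shape in
#' which both gold exemplars and retrieval candidates are represented.
#' Windows are ordered by first sentence index, then width; window text is
#' the sentences joined with single spaces.
#'
#' @param sentences Character vector of sentences (one free-text block;
#'   windows never cross block boundaries).
#' @param max_width Maximum window width (default 3).
#' @param note_id Optional note id carried into the result.
#' @param first_offset Index of the first sentence within the note (for
#'   bookkeeping when a note has several blocks).
#' @return Tibble with columns `note_id`, `first_sentence`,
#'   `last_sentence`, `width`, `text`. For `n` sentences the number of
#'   rows is `sum(n - w + 1)` over widths `w = 1..min(max_width, n)`.
#' @export
#' @examples
#' make_windows(c("A.", "B.", "C.", "D."))  # 4 + 3 + 2 = 9 windows
make_windows <- function(sentences, max_width = 3, note_id = NA_character_,
                         first_offset = 1L) {
  stopifnot(max_width >= 1)
  n <- length(sentences)
  if (n == 0) {
    return(tibble::tibble(note_id = character(), first_sentence = integer(),
                          last_sentence = integer(), width = integer(),
                          text = character()))
  }
  widths <- seq_len(min(max_width, n))
  rows <- purrr::map(widths, function(w) {
    starts <- seq_len(n - w + 1)
    tibble::tibble(
      note_id = note_id,
      first_sentence = as.integer(starts + first_offset - 1L),
      last_sentence = as.integer(starts + w - 1L + first_offset - 1L),
      width = as.integer(w),
      text = vapply(starts, function(s) {
        paste(sentences[s:(s + w - 1)], collapse = " ")
      }, character(1)))
  })
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, .data$first_sentence, .data$width)
}
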