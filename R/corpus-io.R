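#' Read a corpus of clinical notes from JSONL
#'
#' One JSON object per line with fields `note_id`, `note_type`,
#' `structured_sections` (array of `{header, text}`), `free_text` and
#' `annotated_flag`. Malformed lines and duplicate ids raise errors naming
#' the offending line.
#'
#' @param path Path to a `.jsonl` file.
#' @return A tibble of notes (see [validate_notes()] for the schema).
#' @export
#' @seealso [write_notes_jsonl()], [read_exemplars_jsonl()]
read_notes_jsonl <- function(path) {
  lines <- read_jsonl_lines(path)
  if (length(lines) == 0) return(empty_notes())
  recs <- parse_jsonl(lines, path)
  rows <- purrr::imap(recs, function(r, i) {
    need <- c("note_id", "note_type", "free_text", "annotated_flag")
    miss <- setdiff(need, names(r))
    if (length(miss) > 0) {
      stop("parse error at line ", i, " of ", path, ": missing field(s) ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    secs <- r$structured_sections
    secs <- if (is.null(secs) || length(secs) == 0) {
      tibble::tibble(header = character(), text = character())
    } else {
      tibble::tibble(
        header = purrr::map_chr(secs, "header"),
        text = purrr::map_chr(secs, "text")
      )
    }
    tibble::tibble(
      note_id = as.character(r$note_id),
      note_type = as.character(r$note_type),
      structured_sections = list(secs),
      free_text = as.character(r$free_text),
      annotated_flag = as.logical(r$annotated_flag)
    )
  })
  notes <- dplyr::bind_rows(rows)
  validate_notes(notes)
  notes
}

#' Write a corpus of clinical notes to JSONL
#'
#' @param notes A notes tibble (see [validate_notes()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_notes_jsonl <- function(notes, path) {
  validate_notes(notes)
  lines <- purrr::pmap_chr(notes, function(note_id, note_type,
                                           structured_sections, free_text,
                                           annotated_flag, ...) {
    secs <- purrr::pmap(structured_sections, function(header, text) {
      list(header = header, text = text)
    })
    jsonlite::toJSON(
      list(note_id = note_id, note_type = note_type,
           structured_sections = secs, free_text = free_text,
           annotated_flag = annotated_flag),
      auto_unbox = TRUE)
  })
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read an annotated exemplar dataset from JSONL
#'
#' One JSON object per line with fields `exemplar_id`, `note_id`, `text`,
#' `n_sentences`, `category`, `provenance` and optional `annotator_ids`.
#'
#' @param path Path to a `.jsonl` file.
#' @return A tibble of exemplars (see [validate_exemplars()]).
#' @export
read_exemplars_jsonl <- function(path) {
  lines <- read_jsonl_lines(path)
  if (length(lines) == 0) return(empty_exemplars())
  recs <- parse_jsonl(lines, path)
  rows <- purrr::imap(recs, function(r, i) {
    need <- c("exemplar_id", "note_id", "text", "n_sentences", "category",
              "provenance")
    miss <- setdiff(need, names(r))
    if (length(miss) > 0) {
      stop("parse error at line ", i, " of ", path, ": missing field(s) ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    tibble::tibble(
      exemplar_id = as.character(r$exemplar_id),
      note_id = as.character(r$note_id),
      text = as.character(r$text),
      n_sentences = as.integer(r$n_sentences),
      category = as.character(r$category),
      provenance = as.character(r$provenance),
      annotator_ids = list(as.character(unlist(r$annotator_ids)))
    )
  })
  exemplars <- dplyr::bind_rows(rows)
  validate_exemplars(exemplars)
  exemplars
}

#' Write an annotated exemplar dataset to JSONL
#'
#' @param exemplars An exemplar tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_exemplars_jsonl <- function(exemplars, path) {
  validate_exemplars(exemplars)
  if (!"annotator_ids" %in% names(exemplars)) {
    exemplars$annotator_ids <- rep(list(character()), nrow(exemplars))
  }
  lines <- purrr::pmap_chr(exemplars, function(exemplar_id, note_id, text,
                                               n_sentences, category,
                                               provenance, annotator_ids,
                                               ...) {
    jsonlite::toJSON(
      list(exemplar_id = exemplar_id, note_id = note_id, text = text,
           n_sentences = as.integer(n_sentences), category = category,
           provenance = provenance,
           annotator_ids = as.list(annotator_ids)),
      auto_unbox = TRUE)
  })
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read BRAT standoff annotations
#'
#' Reads a document/annotation pair in the BRAT standoff interchange
#' format: `<stem>.txt` holds the note free text and `<stem>.ann` holds
#' `T` lines of the form `T<k>\tCATEGORY <start> <end>\t<text>` with
#' 0-based, end-exclusive character offsets into the text file.
#'
#' @param stem Path without extension; `stem.txt` and `stem.ann` are read.
#' @param note_id Note id to attach; defaults to the file stem.
#' @return A list with `text` (string) and `spans` (tibble with columns
#'   `span_id`, `category`, `start`, `end`, `text`).
#' @export
read_brat <- function(stem, note_id = basename(stem)) {
  txt_path <- paste0(stem, ".txt")
  ann_path <- paste0(stem, ".ann")
  text <- paste(readLines(txt_path, warn = FALSE), collapse = "\n")
  ann <- readLines(ann_path, warn = FALSE)
  ann <- ann[startsWith(ann, "T")]
  if (length(ann) == 0) {
    spans <- tibble::tibble(span_id = character(), category = character(),
                            start = integer(), end = integer(),
                            text = character())
  } else {
    parts <- strsplit(ann, "\t", fixed = TRUE)
    bad <- which(lengths(parts) < 3)
    if (length(bad) > 0) {
      stop("malformed BRAT T-line ", bad[1], " in ", ann_path, call. = FALSE)
    }
    mid <- strsplit(vapply(parts, `[[`, "", 2), " ", fixed = TRUE)
    spans <- tibble::tibble(
      span_id = vapply(parts, `[[`, "", 1),
      category = vapply(mid, `[[`, "", 1),
      start = as.integer(vapply(mid, `[[`, "", 2)),
      end = as.integer(vapply(mid, `[[`, "", 3)),
      text = vapply(parts, `[[`, "", 3)
    )
    # offsets are 0-based end-exclusive; check against the text
    extracted <- substring(text, spans$start + 1L, spans$end)
    off <- which(extracted != spans$text)
    if (length(off) > 0) {
      stop("BRAT span ", spans$span_id[off[1]], " text does not match ",
           "offsets in ", ann_path, call. = FALSE)
    }
  }
  spans$note_id <- note_id
  list(text = text, spans = spans)
}

#' Write BRAT standoff annotations
#'
#' @param text Note free text.
#' @param spans Tibble with `category`, `start`, `end` (0-based,
#'   end-exclusive offsets into `text`).
#' @param stem Output path without extension.
#' @return `stem`, invisibly.
#' @export
write_brat <- function(text, spans, stem) {
  writeLines(text, paste0(stem, ".txt"), useBytes = TRUE)
  if (nrow(spans) > 0) {
    seg <- substring(text, spans$start + 1L, spans$end)
    lines <- sprintf("T%d\t%s %d %d\t%s", seq_len(nrow(spans)),
                     spans$category, spans$start, spans$end, seg)
  } else {
    lines <- character()
  }
  writeLines(lines, paste0(stem, ".ann"), useBytes = TRUE)
  invisible(stem)
}

empty_notes <- function() {
  tibble::tibble(note_id = character(), note_type = character(),
                 structured_sections = list(), free_text = character(),
                 annotated_flag = logical())
}

empty_exemplars <- function() {
  tibble::tibble(exemplar_id = character(), note_id = character(),
                 text = character(), n_sentences = integer(),
                 category = character(), provenance = character(),
                 annotator_ids = list())
}

read_jsonl_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines[nzchar(trimws(lines))]
}

parse_jsonl <- function(lines, path) {
  purrr::imap(lines, function(l, i) {
    tryCatch(
      jsonlite::fromJSON(l, simplifyVector = FALSE),
      error = function(e) {
        stop("parse error at line ", i, " of ", path, ": ",
             conditionMessage(e), call. = FALSE)
      })
  })
}
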