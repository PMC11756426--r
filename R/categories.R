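#' Language categories for clinical-note annotation
#'
#' The annotation scheme distinguishes five stigmatizing categories
#' (marginalized language/identities, difficult patient, power/privilege,
#' unilateral/authoritarian decisions, questioning patient credibility),
#' one positive/preferred category, and the negative-case label `"none"`
#' used for spans where none of the substantive categories applies.
#'
#' @param include_none Include the negative-case label `"none"`.
#' @return Character vector of category codes.
#' @export
#' @examples
#' language_categories()
#' language_categories(include_none = FALSE)
language_categories <- function(include_none = TRUE) {
  cats <- c(stigmatizing_categories(), "positive_preferred")
  if (include_none) cats <- c(cats, "none")
  cats
}

#' @rdname language_categories
#' @export
stigmatizing_categories <- function() {
  c("marginalized", "difficult_patient", "power_privilege",
    "unilateral_authoritarian", "questioning_credibility")
}

#' @rdname language_categories
#' @export
substantive_categories <- function() {
  language_categories(include_none = FALSE)
}

#' Polarity of a language category
#'
#' Maps each category code to its polarity: the five stigmatizing codes to
#' `"stigmatizing"`, `positive_preferred` to `"positive"`, and `"none"` to
#' `"negative_case"`.
#'
#' @param category Character vector of category codes.
#' @return Character vector of polarities, same length as `category`.
#' @export
#' @examples
#' category_polarity(c("marginalized", "positive_preferred", "none"))
category_polarity <- function(category) {
  check_categories(category)
  dplyr::case_when(
    category %in% stigmatizing_categories() ~ "stigmatizing",
    category == "positive_preferred" ~ "positive",
    category == "none" ~ "negative_case"
  )
}

#' Clinical note types included in the corpus
#'
#' The seven narrative note types carried through every stage of the
#' pipeline; notes of any other type are out of scope.
#'
#' @return Character vector of length 7.
#' @export
note_types <- function() {
  c("obstetric_postpartum", "obstetric_admission", "obstetric_triage",
    "anesthesia_resident", "miscellaneous_nursing",
    "social_work_initial_assessment", "initial_nutrition_assessment")
}

check_categories <- function(category, allow_none = TRUE) {
  valid <- language_categories(include_none = allow_none)
  bad <- setdiff(unique(category), valid)
  if (length(bad) > 0) {
    stop("unknown language categor", if (length(bad) > 1) "ies: " else "y: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(category)
}

check_note_types <- function(note_type) {
  bad <- setdiff(unique(note_type), note_types())
  if (length(bad) > 0) {
    stop("unknown note type(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(note_type)
}

#' Validate a notes table
#'
#' A corpus is a tibble with one row per clinical note and columns
#' `note_id` (unique), `note_type` (one of [note_types()]),
#' `structured_sections` (list column of tibbles with `header`, `text`),
#' `free_text`, and `annotated_flag`.
#'
#' @param notes A data frame of notes.
#' @return `notes`, invisibly, as a tibble; errors describe the violation.
#' @export
validate_notes <- function(notes) {
  notes <- tibble::as_tibble(notes)
  need <- c("note_id", "note_type", "structured_sections", "free_text",
            "annotated_flag")
  miss <- setdiff(need, names(notes))
  if (length(miss) > 0) {
    stop("notes table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  dup <- notes$note_id[duplicated(notes$note_id)]
  if (length(dup) > 0) {
    stop("duplicate note_id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  check_note_types(notes$note_type)
  invisible(notes)
}

#' Validate an exemplar table
#'
#' An annotated dataset is a tibble with one row per exemplar and columns
#' `exemplar_id` (unique), `note_id`, `text`, `n_sentences` (1--3),
#' `category`, `provenance` (`human_initial`, `expansion_verified`,
#' `negative_sample`) and optionally `annotator_ids` (list column).
#' Negative-case exemplars (`category == "none"`) must and may only carry
#' `provenance == "negative_sample"`.
#'
#' @param exemplars A data frame of exemplars.
#' @param corpus Optional notes table; when supplied, every `note_id` must
#'   resolve against it.
#' @return `exemplars`, invisibly, as a tibble.
#' @export
validate_exemplars <- function(exemplars, corpus = NULL) {
  exemplars <- tibble::as_tibble(exemplars)
  need <- c("exemplar_id", "note_id", "text", "n_sentences", "category",
            "provenance")
  miss <- setdiff(need, names(exemplars))
  if (length(miss) > 0) {
    stop("exemplar table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  dup <- exemplars$exemplar_id[duplicated(exemplars$exemplar_id)]
  if (length(dup) > 0) {
    stop("duplicate exemplar_id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (nrow(exemplars) > 0) {
    if (!all(exemplars$n_sentences %in% 1:3)) {
      stop("n_sentences must be 1, 2 or 3", call. = FALSE)
    }
    check_categories(exemplars$category)
    ok_prov <- c("human_initial", "expansion_verified", "negative_sample")
    bad <- setdiff(unique(exemplars$provenance), ok_prov)
    if (length(bad) > 0) {
      stop("unknown provenance: ", paste(bad, collapse = ", "), call. = FALSE)
    }
    none_mismatch <- xor(exemplars$category == "none",
                         exemplars$provenance == "negative_sample")
    if (any(none_mismatch)) {
      stop("category 'none' must pair with provenance 'negative_sample' ",
           "(and only then); offending exemplar_id(s): ",
           paste(utils::head(exemplars$exemplar_id[none_mismatch], 5),
                 collapse = ", "), call. = FALSE)
    }
  }
  if (!is.null(corpus)) {
    unresolved <- setdiff(exemplars$note_id, corpus$note_id)
    if (length(unresolved) > 0) {
      stop("exemplar note_id(s) not present in corpus: ",
           paste(utils::head(unresolved, 5), collapse = ", "), call. = FALSE)
    }
  }
  invisible(exemplars)
}

# Round half away from zero, the convention used for all displayed
# percentages (matches e.g. 397/963 -> 41.23).
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Run code with a temporary RNG state when seed is non-NULL, restoring the
# caller's state afterwards.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.null(seed) && (!is.numeric(seed) || length(seed) != 1)) {
    stop("seed must be a single number or NULL", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
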