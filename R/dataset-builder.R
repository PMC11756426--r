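#' Sample matched negative-case exemplars
#'
#' Draws windows from notes that contain no flagged content (no gold or
#' verified span) to serve as negative cases, labeled `"none"`. "Length
#' and context analogous" is operationalized as: the negatives' window
#' width histogram matches the positives' exactly (scaled by `ratio`,
#' largest-remainder rounding), and their note-type distribution matches
#' the positives' within one item per type whenever enough eligible
#' windows exist. With `ratio = 1` the resulting balanced modeling set has
#' `2 * |positives|` rows, e.g. 963 positives give a modeling set of 1926.
#'
#' @param corpus Notes tibble.
#' @param positives Exemplar tibble of substantive-category exemplars.
#' @param flagged_note_ids Notes that contain any gold or verified span;
#'   defaults to the notes referenced by `positives`.
#' @param ratio Negatives per positive (default 1, the balanced design).
#' @param seed Reproducibility seed.
#' @param rules [normalization_rules()] for pool construction.
#' @return An exemplar tibble with `category = "none"`,
#'   `provenance = "negative_sample"`.
#' @export
sample_negatives <- function(corpus, positives,
                             flagged_note_ids = unique(positives$note_id),
                             ratio = 1.0, seed = 1L,
                             rules = normalization_rules()) {
  validate_notes(corpus)
  validate_exemplars(positives)
  n_total <- as.integer(round_half_away(ratio * nrow(positives)))
  if (n_total == 0) return(empty_exemplars())

  eligible <- corpus[!(corpus$note_id %in% flagged_note_ids), , drop = FALSE]
  # negatives may come from annotated or unannotated notes as long as the
  # note carries no flagged span
  eligible$annotated_flag <- FALSE
  pool <- build_candidate_pool(eligible, gold = positives, rules = rules,
                               dedup_against_gold = TRUE)
  if (nrow(pool) == 0) {
    stop("no eligible windows for negative sampling (deficit ", n_total, ")",
         call. = FALSE)
  }

  # per-width targets: positives' width histogram, largest-remainder scaled
  w_counts <- table(factor(positives$n_sentences, levels = 1:3))
  w_target <- largest_remainder(as.numeric(w_counts) / sum(w_counts), n_total)
  names(w_target) <- names(w_counts)

  # note-type targets from the positives' note types
  pos_types <- corpus$note_type[match(positives$note_id, corpus$note_id)]
  t_counts <- table(factor(pos_types, levels = note_types()))
  t_target <- largest_remainder(as.numeric(t_counts) / sum(t_counts), n_total)
  names(t_target) <- names(t_counts)

  with_seed(seed, {
    taken <- integer(0)
    type_left <- t_target
    for (w in names(w_target)) {
      need <- w_target[[w]]
      if (need == 0) next
      avail <- setdiff(which(pool$width == as.integer(w)), taken)
      if (length(avail) < need) {
        stop("insufficient eligible windows of width ", w, ": need ", need,
             ", have ", length(avail), " (deficit ", need - length(avail),
             ")", call. = FALSE)
      }
      avail <- avail[sample.int(length(avail))]
      # prefer windows from note types still under their target
      for (i in avail) {
        if (need == 0) break
        tt <- pool$note_type[i]
        if (type_left[[tt]] > 0) {
          taken <- c(taken, i)
          type_left[[tt]] <- type_left[[tt]] - 1L
          need <- need - 1L
        }
      }
      if (need > 0) {
        # relax the type constraint for the remainder
        rest <- setdiff(avail, taken)[seq_len(need)]
        taken <- c(taken, rest)
        for (i in rest) type_left[[pool$note_type[i]]] <-
            type_left[[pool$note_type[i]]] - 1L
      }
    }
    sel <- pool[taken, , drop = FALSE]
    tibble::tibble(
      exemplar_id = sprintf("neg%06d", seq_len(nrow(sel))),
      note_id = sel$note_id,
      text = sel$text,
      n_sentences = as.integer(sel$width),
      category = "none",
      provenance = "negative_sample",
      annotator_ids = rep(list(character()), nrow(sel)))
  })
}

#' Split configuration
#'
#' @param fractions Train/validation/test fractions; default
#'   `c(0.6, 0.2, 0.2)`.
#' @param seed Reproducibility seed.
#' @return A list of class `split_config`.
#' @export
split_config <- function(fractions = c(train = 0.6, validation = 0.2,
                                       test = 0.2),
                         seed = 1L) {
  stopifnot(length(fractions) == 3, all(fractions > 0),
            isTRUE(all.equal(sum(fractions), 1)))
  if (is.null(names(fractions))) {
    names(fractions) <- c("train", "validation", "test")
  }
  structure(list(fractions = fractions, seed = seed), class = "split_config")
}

#' Stratified train/validation/test split
#'
#' Partitions an exemplar set into train (60%), validation (20%) and test
#' (20%) parts, stratified by category so each part preserves the
#' category distribution. Within each stratum the allocation uses
#' largest-remainder rounding, so per-stratum proportions deviate from
#' the fractions by less than one item. Strata smaller than 3 go entirely
#' to train with a warning.
#'
#' @param exemplars Exemplar tibble (strata are its `category` values).
#' @param config A [split_config()].
#' @return A list of class `dataset_splits` with tibbles `train`,
#'   `validation`, `test`.
#' @export
stratified_split <- function(exemplars, config = split_config()) {
  validate_exemplars(exemplars)
  fr <- config$fractions
  parts <- list(train = NULL, validation = NULL, test = NULL)
  with_seed(config$seed, {
    for (cat in unique(exemplars$category)) {
      idx <- which(exemplars$category == cat)
      n <- length(idx)
      if (n < 3) {
        warning("stratum '", cat, "' has only ", n,
                " exemplar(s); assigning all to train", call. = FALSE)
        parts$train <- c(parts$train, idx)
        next
      }
      alloc <- largest_remainder(fr, n)
      idx <- idx[sample.int(n)]
      parts$train <- c(parts$train, idx[seq_len(alloc[1])])
      parts$validation <- c(parts$validation,
                            idx[alloc[1] + seq_len(alloc[2])])
      parts$test <- c(parts$test, idx[alloc[1] + alloc[2] + seq_len(alloc[3])])
    }
  })
  out <- purrr::map(parts, function(ix) {
    exemplars[sort(ix), , drop = FALSE]
  })
  structure(out, class = "dataset_splits")
}

#' Combine initial and expanded splits into enhanced splits
#'
#' The initial and expanded modeling sets are split separately and then
#' combined part-wise, never pooled before splitting, so the enhanced
#' train/validation/test sets are the unions of the corresponding parts.
#'
#' @param initial_splits,expanded_splits [stratified_split()] results
#'   with disjoint exemplar ids.
#' @return A `dataset_splits` list.
#' @export
build_enhanced <- function(initial_splits, expanded_splits) {
  out <- purrr::map2(initial_splits[c("train", "validation", "test")],
                     expanded_splits[c("train", "validation", "test")],
                     function(a, b) {
                       if (is.null(b) || nrow(b) == 0) return(a)
                       merge_datasets(a, b)
                     })
  structure(out, class = "dataset_splits")
}

#' @export
print.dataset_splits <- function(x, ...) {
  sizes <- vapply(x, nrow, integer(1))
  cat("Dataset splits: train ", sizes[["train"]], ", validation ",
      sizes[["validation"]], ", test ", sizes[["test"]], "\n", sep = "")
  invisible(x)
}

#' Write splits to JSONL files with a manifest
#'
#' @param splits A `dataset_splits` list.
#' @param dir Output directory (created if needed).
#' @param config The [split_config()] used, recorded in the manifest.
#' @return The manifest list, invisibly.
#' @export
write_splits <- function(splits, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (part in c("train", "validation", "test")) {
    write_exemplars_jsonl(splits[[part]], file.path(dir, paste0(part, ".jsonl")))
  }
  manifest <- list(
    fractions = if (is.null(config)) NULL else as.list(config$fractions),
    seed = if (is.null(config)) NULL else config$seed,
    sizes = purrr::map(splits, nrow),
    per_stratum = purrr::map(splits, function(p) as.list(table(p$category))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
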