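#' Expansion configuration
#'
#' Settings for semantic-similarity training-set expansion: the number of
#' gold exemplars sampled as queries (study value 250), the number of
#' nearest candidates retrieved per query (study value 5), and whether
#' candidate windows whose text exactly equals a gold exemplar's text are
#' removed from the pool.
#'
#' @param n_queries Number of query exemplars sampled from the gold set.
#' @param top_k Candidates retrieved per query.
#' @param seed Seed for query sampling.
#' @param dedup_against_gold Drop pool windows textually identical to a
#'   gold exemplar.
#' @return A list of class `expansion_config`.
#' @export
expansion_config <- function(n_queries = 250L, top_k = 5L, seed = 1L,
                             dedup_against_gold = TRUE) {
  stopifnot(n_queries >= 1, top_k >= 1)
  structure(list(n_queries = as.integer(n_queries), top_k = as.integer(top_k),
                 seed = seed, dedup_against_gold = dedup_against_gold),
            class = "expansion_config")
}

#' Build the candidate pool of sentence windows
#'
#' Takes every note that was not used for human annotation
#' (`annotated_flag == FALSE`) and is of an included note type, extracts
#' its free-text blocks, normalizes them, segments sentences, and forms
#' all 1--3-sentence windows. Windows never cross block boundaries. With
#' deduplication on, windows whose normalized text equals a gold
#' exemplar's normalized text are removed.
#'
#' @param corpus A notes tibble.
#' @param gold Optional gold exemplar tibble used for deduplication.
#' @param rules [normalization_rules()] applied to blocks before
#'   segmentation.
#' @param max_width Maximum window width.
#' @param dedup_against_gold Remove exact textual duplicates of gold
#'   exemplars.
#' @return A window tibble (see [make_windows()]) with an extra
#'   `note_type` column.
#' @export
build_candidate_pool <- function(corpus, gold = NULL,
                                 rules = normalization_rules(),
                                 max_width = 3,
                                 dedup_against_gold = TRUE) {
  validate_notes(corpus)
  eligible <- corpus[!corpus$annotated_flag &
                       corpus$note_type %in% note_types(), , drop = FALSE]
  pools <- purrr::pmap(eligible, function(note_id, note_type, free_text, ...) {
    blocks <- extract_free_text(list(free_text = free_text))
    offset <- 1L
    wins <- purrr::map(blocks, function(b) {
      sents <- segment_sentences(normalize_text(b, rules))
      w <- make_windows(sents, max_width = max_width, note_id = note_id,
                        first_offset = offset)
      offset <<- offset + length(sents)
      w
    })
    out <- dplyr::bind_rows(wins)
    if (nrow(out) > 0) out$note_type <- note_type
    out
  })
  pool <- dplyr::bind_rows(pools)
  if (nrow(pool) == 0) {
    warning("candidate pool is empty", call. = FALSE)
    pool <- make_windows(character())
    pool$note_type <- character()
    return(pool)
  }
  if (dedup_against_gold && !is.null(gold) && nrow(gold) > 0) {
    gold_norm <- normalize_text(gold$text, rules)
    pool <- pool[!(pool$text %in% gold_norm), , drop = FALSE]
  }
  pool
}

#' Sample query exemplars from the gold set
#'
#' Stratified proportional-to-size sampling over the six substantive
#' categories with largest-remainder rounding of the per-category
#' allocation, so the queries represent the full range of language
#' categories in proportion to their prevalence. Negative-case exemplars
#' are never sampled. If `n_queries` meets or exceeds the number of
#' substantive exemplars, all of them are returned.
#'
#' @param gold Gold exemplar tibble.
#' @param config An [expansion_config()].
#' @return A tibble of query exemplars.
#' @export
sample_queries <- function(gold, config = expansion_config()) {
  validate_exemplars(gold)
  pos <- gold[gold$category != "none", , drop = FALSE]
  if (nrow(pos) == 0) stop("gold set has no substantive exemplars", call. = FALSE)
  if (config$n_queries >= nrow(pos)) return(pos)
  counts <- table(factor(pos$category, levels = substantive_categories()))
  counts <- counts[counts > 0]
  alloc <- largest_remainder(as.numeric(counts) / sum(counts),
                             config$n_queries)
  names(alloc) <- names(counts)
  with_seed(config$seed, {
    picked <- purrr::imap(alloc, function(k, cat) {
      idx <- which(pos$category == cat)
      idx[sample.int(length(idx), min(k, length(idx)))]
    })
    pos[sort(unlist(picked, use.names = FALSE)), , drop = FALSE]
  })
}

# Allocate `total` integer units across shares summing to 1 by the
# largest-remainder (Hamilton) method; ties go to the earlier index.
largest_remainder <- function(shares, total) {
  quota <- shares * total
  base <- floor(quota)
  rem <- total - sum(base)
  if (rem > 0) {
    ord <- order(-(quota - base), seq_along(quota))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Build a search index over candidate windows
#'
#' Embeds every pool window with the backend and stores the matrix next
#' to the window metadata. Retrieval against the index is exact: every
#' query is scored against every row by cosine similarity.
#'
#' @param pool Window tibble from [build_candidate_pool()].
#' @param backend An [embedding_backend()].
#' @return A list of class `search_index` with `vectors`
#'   (`dimension x pool_size`), `spans` (the pool tibble) and `backend`.
#' @export
build_search_index <- function(pool, backend = embedding_backend()) {
  vectors <- embed_texts(backend, pool$text)
  structure(list(vectors = vectors, spans = tibble::as_tibble(pool),
                 backend = backend),
            class = "search_index")
}

#' Exact top-k cosine retrieval
#'
#' Scores the query vector against every indexed window and returns the
#' `min(k, pool size)` most similar, sorted by similarity descending with
#' ties broken by pool insertion order.
#'
#' @param index A [build_search_index()] result.
#' @param query A query embedding vector (or a text to embed with the
#'   index's backend).
#' @param k Number of neighbours.
#' @return The matching rows of the pool tibble with a `similarity`
#'   column and a `rank` column.
#' @export
topk_search <- function(index, query, k) {
  stopifnot(inherits(index, "search_index"), k >= 1)
  n <- nrow(index$spans)
  if (n == 0) {
    out <- index$spans
    out$similarity <- numeric()
    out$rank <- integer()
    return(out)
  }
  if (is.character(query)) query <- embed_texts(index$backend, query)[, 1]
  if (length(query) != nrow(index$vectors)) {
    stop("query dimension ", length(query), " does not match index dimension ",
         nrow(index$vectors), call. = FALSE)
  }
  sims <- cosine_to_columns(index$vectors, query)
  ord <- order(-sims, seq_len(n))[seq_len(min(k, n))]
  out <- index$spans[ord, , drop = FALSE]
  out$similarity <- sims[ord]
  out$rank <- seq_along(ord)
  out
}

#' Run the expansion retrieval and build a review queue
#'
#' Embeds each query exemplar, retrieves its top-k candidates, and
#' assembles one review item per (query, candidate) hit: the candidate
#' window, the similarity, the query's category as the proposed label,
#' and a `decision` column initialized to `"pending"` for annotators to
#' fill (`accept`, `accept_with_category` plus `override_category`, or
#' `reject`). With `n` queries and a pool of at least `k` windows the
#' queue has exactly `n * k` rows.
#'
#' @param index A [build_search_index()] result.
#' @param queries Query exemplar tibble (normalized text is embedded with
#'   the index backend).
#' @param top_k Candidates per query.
#' @param rules [normalization_rules()] applied to query text.
#' @return A review-queue tibble.
#' @export
make_review_queue <- function(index, queries, top_k = 5,
                              rules = normalization_rules()) {
  qvec <- embed_texts(index$backend, normalize_text(queries$text, rules))
  rows <- purrr::map(seq_len(nrow(queries)), function(i) {
    hits <- topk_search(index, qvec[, i], top_k)
    if (nrow(hits) == 0) return(NULL)
    tibble::tibble(
      note_id = hits$note_id,
      first_sentence = hits$first_sentence,
      last_sentence = hits$last_sentence,
      width = hits$width,
      text = hits$text,
      query_exemplar_id = queries$exemplar_id[i],
      similarity = hits$similarity,
      proposed_category = queries$category[i],
      decision = "pending",
      override_category = NA_character_)
  })
  dplyr::bind_rows(rows)
}

#' Ingest review decisions into an expanded dataset
#'
#' Accepted candidates become exemplars with
#' `provenance = "expansion_verified"`; rejected candidates are dropped.
#' Candidates retrieved by several queries (same note and sentence span)
#' collapse to a single exemplar, keeping the highest-similarity item.
#' The category is the proposed one unless the decision is
#' `accept_with_category`, in which case `override_category` is used.
#'
#' @param queue A decided review-queue tibble (no `"pending"` rows).
#' @param gold Gold exemplar tibble, used to continue the exemplar id
#'   sequence and to guard against id collisions.
#' @return An exemplar tibble (the expanded dataset).
#' @export
ingest_review <- function(queue, gold = NULL) {
  ok <- c("pending", "accept", "accept_with_category", "reject")
  bad <- setdiff(unique(queue$decision), ok)
  if (length(bad) > 0) {
    stop("unknown review decision(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(queue$decision == "pending")) {
    stop(sum(queue$decision == "pending"),
         " review item(s) still pending; every item needs a decision",
         call. = FALSE)
  }
  acc <- queue[queue$decision %in% c("accept", "accept_with_category"), ,
               drop = FALSE]
  if (nrow(acc) == 0) return(empty_exemplars())
  acc$category <- ifelse(acc$decision == "accept_with_category",
                         acc$override_category, acc$proposed_category)
  if (any(is.na(acc$category))) {
    stop("accept_with_category without an override_category", call. = FALSE)
  }
  check_categories(acc$category, allow_none = FALSE)
  # collapse duplicate windows, keeping the highest similarity
  acc <- dplyr::arrange(acc, dplyr::desc(.data$similarity))
  acc <- dplyr::distinct(acc, .data$note_id, .data$first_sentence,
                         .data$last_sentence, .keep_all = TRUE)
  start <- if (is.null(gold)) 0L else nrow(gold)
  out <- tibble::tibble(
    exemplar_id = sprintf("ex%06d", start + seq_len(nrow(acc))),
    note_id = acc$note_id,
    text = acc$text,
    n_sentences = as.integer(acc$width),
    category = acc$category,
    provenance = "expansion_verified",
    annotator_ids = rep(list(character()), nrow(acc)))
  if (!is.null(gold)) {
    clash <- intersect(out$exemplar_id, gold$exemplar_id)
    if (length(clash) > 0) {
      out$exemplar_id <- paste0("exp_", out$exemplar_id)
    }
  }
  validate_exemplars(out)
  out
}

#' Write and read a review queue as CSV
#'
#' The queue round-trips through a plain CSV so annotators can fill the
#' `decision` (and optionally `override_category`) columns in any editor.
#' Similarities are written with four decimals.
#'
#' @param queue A review-queue tibble.
#' @param path CSV path.
#' @return `path` (write) or the queue tibble (read).
#' @export
write_review_queue <- function(queue, path) {
  out <- queue
  out$similarity <- sprintf("%.4f", out$similarity)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_review_queue
#' @export
read_review_queue <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$similarity <- as.numeric(df$similarity)
  df$override_category[!nzchar(trimws(ifelse(is.na(df$override_category), "",
                                             df$override_category)))] <- NA
  tibble::as_tibble(df)
}
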