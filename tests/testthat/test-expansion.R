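test_that("the candidate pool excludes annotated notes and matches the window formula", {
  notes <- make_notes(c(4, 3, 5))
  notes$annotated_flag <- c(FALSE, TRUE, FALSE)
  pool <- build_candidate_pool(notes)
  count_for <- function(n) sum(n - seq_len(min(3, n)) + 1)
  expect_equal(nrow(pool), count_for(4) + count_for(5))
  expect_false("tn002" %in% pool$note_id)

  # all notes annotated -> empty pool with a warning
  notes$annotated_flag <- TRUE
  expect_warning(pool0 <- build_candidate_pool(notes), "empty")
  expect_equal(nrow(pool0), 0)
})

test_that("deduplication removes windows textually equal to gold exemplars", {
  notes <- make_notes(c(3, 3))
  gold <- make_exemplars("marginalized")
  gold$text <- "filler sentence number 2 here."
  pool <- build_candidate_pool(notes, gold = gold)
  expect_false(any(pool$text == normalize_text(gold$text)))
  pool_nodedup <- build_candidate_pool(notes, gold = gold,
                                       dedup_against_gold = FALSE)
  expect_gt(nrow(pool_nodedup), nrow(pool))
})

test_that("query sampling is proportional with largest-remainder rounding", {
  gold <- make_exemplars(c(rep("marginalized", 60),
                           rep("positive_preferred", 40)))
  q <- sample_queries(gold, expansion_config(n_queries = 10, seed = 1))
  expect_equal(sum(q$category == "marginalized"), 6)
  expect_equal(sum(q$category == "positive_preferred"), 4)

  # saturation: everything returned, negatives never sampled
  gold2 <- make_exemplars(c("marginalized", "none", "positive_preferred"))
  q2 <- sample_queries(gold2, expansion_config(n_queries = 250))
  expect_equal(nrow(q2), 2)
  expect_false("none" %in% q2$category)

  # determinism
  qa <- sample_queries(gold, expansion_config(n_queries = 10, seed = 9))
  qb <- sample_queries(gold, expansion_config(n_queries = 10, seed = 9))
  expect_identical(qa, qb)
})

test_that("top-k retrieval matches the exhaustive cosine oracle", {
  set.seed(17)
  for (trial in 1:5) {
    n_pool <- sample(50:300, 1)
    k <- sample(1:10, 1)
    dim <- 32
    vectors <- matrix(rnorm(dim * n_pool), dim)
    pool <- tibble::tibble(note_id = sprintf("n%d", seq_len(n_pool)),
                           first_sentence = 1L, last_sentence = 1L,
                           width = 1L, text = sprintf("t%d", seq_len(n_pool)))
    index <- structure(list(vectors = vectors, spans = pool,
                            backend = embedding_backend(dimension = dim)),
                       class = "search_index")
    query <- rnorm(dim)
    got <- topk_search(index, query, k)
    expect_equal(match(got$note_id, pool$note_id),
                 brute_topk(vectors, query, k))
    expect_equal(got$similarity, sort(got$similarity, decreasing = TRUE))
  }
})

test_that("retrieval ties break by pool insertion order and k saturates", {
  dim <- 8
  v <- c(1, rep(0, dim - 1))
  vectors <- cbind(v, v, v)  # three identical pool vectors
  pool <- tibble::tibble(note_id = c("a", "b", "c"), first_sentence = 1L,
                         last_sentence = 1L, width = 1L,
                         text = c("a", "b", "c"))
  index <- structure(list(vectors = vectors, spans = pool,
                          backend = embedding_backend(dimension = dim)),
                     class = "search_index")
  got <- topk_search(index, v, 2)
  expect_equal(got$note_id, c("a", "b"))
  expect_equal(nrow(topk_search(index, v, 10)), 3)
})

test_that("n queries times top-k yields exactly n*k review items", {
  sim <- generate_corpus(generator_config(n_notes = 80, seed = 13))
  pool <- build_candidate_pool(sim$notes, gold = sim$gold)
  index <- build_search_index(pool)
  queries <- sample_queries(sim$gold, expansion_config(n_queries = 12))
  queue <- make_review_queue(index, queries, top_k = 5)
  expect_equal(nrow(queue), nrow(queries) * 5)
  expect_true(all(queue$similarity >= -1 & queue$similarity <= 1))
  expect_true(all(queue$decision == "pending"))
})

test_that("ingest honors decisions, collapses duplicates and flags pending", {
  queue <- tibble::tibble(
    note_id = c("n1", "n1", "n2"),
    first_sentence = c(1L, 1L, 2L),
    last_sentence = c(2L, 2L, 2L),
    width = c(2L, 2L, 1L),
    text = c("w one.", "w one.", "w two."),
    query_exemplar_id = c("q1", "q2", "q1"),
    similarity = c(0.8, 0.9, 0.7),
    proposed_category = c("marginalized", "marginalized", "difficult_patient"),
    decision = "pending",
    override_category = NA_character_)

  expect_error(ingest_review(queue), "pending")

  decided <- queue
  decided$decision <- c("accept", "accept", "accept_with_category")
  decided$override_category <- c(NA, NA, "positive_preferred")
  out <- ingest_review(decided)
  expect_equal(nrow(out), 2)  # duplicate window collapsed
  expect_true(all(out$provenance == "expansion_verified"))
  expect_equal(out$category[out$note_id == "n2"], "positive_preferred")

  all_rejected <- queue
  all_rejected$decision <- "reject"
  expect_equal(nrow(ingest_review(all_rejected)), 0)

  bad <- queue
  bad$decision <- c("accept", "nonsense", "reject")
  expect_error(ingest_review(bad), "unknown review decision")
})

test_that("review queues round-trip through CSV", {
  queue <- tibble::tibble(
    note_id = "n1", first_sentence = 1L, last_sentence = 1L, width = 1L,
    text = "some candidate text.", query_exemplar_id = "q1",
    similarity = 0.87654321, proposed_category = "marginalized",
    decision = "pending", override_category = NA_character_)
  path <- withr::local_tempfile(fileext = ".csv")
  write_review_queue(queue, path)
  back <- read_review_queue(path)
  expect_equal(back$similarity, 0.8765)  # written at four decimals
  expect_equal(back$text, queue$text)
  expect_true(is.na(back$override_category))
})

test_that("verified expansion only accepts windows overlapping true spans", {
  sim <- generate_corpus(generator_config(n_notes = 120, seed = 23))
  pool <- build_candidate_pool(sim$notes, gold = sim$gold)
  index <- build_search_index(pool)
  queries <- sample_queries(sim$gold, expansion_config(n_queries = 25))
  queue <- make_review_queue(index, queries, top_k = 5)
  decided <- simulate_verifier(queue, sim$truth, error_rate = 0)
  expanded <- ingest_review(decided, gold = sim$gold)
  # precision 1 by construction: every ingested exemplar overlaps a span
  for (i in seq_len(nrow(expanded))) {
    tr <- sim$truth[sim$truth$note_id == expanded$note_id[i], ]
    win <- decided[decided$note_id == expanded$note_id[i] &
                     decided$text == expanded$text[i], ][1, ]
    expect_true(any(tr$first_sentence <= win$last_sentence &
                      tr$last_sentence >= win$first_sentence))
  }
})
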