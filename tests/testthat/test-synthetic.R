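test_that("the phrase bank has ten-plus distinct templates per category", {
  bank <- phrase_bank()
  counts <- table(bank$category)
  expect_setequal(names(counts), substantive_categories())
  expect_true(all(counts >= 10))
  expect_equal(anyDuplicated(bank$template), 0)
})

test_that("zero prevalence yields an empty gold dataset", {
  cfg <- generator_config(
    n_notes = 20,
    category_prevalence = stats::setNames(rep(0, 6),
                                          substantive_categories()),
    paraphrase_rate = 0, seed = 1)
  out <- generate_corpus(cfg)
  expect_equal(nrow(out$gold), 0)
  expect_equal(nrow(out$truth), 0)
  expect_equal(nrow(out$notes), 20)
})

test_that("requested category counts are planted exactly", {
  cfg <- generator_config(
    n_notes = 100,
    category_prevalence = c(marginalized = 40, difficult_patient = 20),
    paraphrase_rate = 0, annotated_fraction = 0.5, seed = 2)
  out <- generate_corpus(cfg)
  tal <- tally_categories(out$gold)
  expect_equal(tal$n[tal$category == "marginalized"], 40L)
  expect_equal(tal$n[tal$category == "difficult_patient"], 20L)
  expect_equal(attr(tal, "total"), 60L)
})

test_that("generation is deterministic, serialized byte for byte", {
  cfg <- generator_config(n_notes = 50, seed = 33)
  a <- generate_corpus(cfg)
  b <- generate_corpus(cfg)
  pa <- withr::local_tempfile()
  pb <- withr::local_tempfile()
  write_notes_jsonl(a$notes, pa)
  write_notes_jsonl(b$notes, pb)
  expect_identical(readLines(pa), readLines(pb))
  expect_identical(a$gold, b$gold)
  expect_identical(a$truth, b$truth)
})

test_that("gold exemplars and the truth table are mutually consistent", {
  out <- generate_corpus(generator_config(n_notes = 80, seed = 44))
  gt <- out$truth[out$truth$kind == "gold", ]
  expect_setequal(gt$exemplar_id, out$gold$exemplar_id)
  m <- match(out$gold$exemplar_id, gt$exemplar_id)
  expect_equal(out$gold$category, gt$category[m])
  expect_equal(out$gold$n_sentences,
               gt$last_sentence[m] - gt$first_sentence[m] + 1L)
  # offsets cut the note text to exactly the exemplar text
  ft <- out$notes$free_text[match(gt$note_id[m], out$notes$note_id)]
  expect_equal(out$gold$text,
               substring(ft, gt$start[m] + 1L, gt$end[m]))
  # gold only in annotated notes, paraphrases only in unannotated notes
  flags <- out$notes$annotated_flag[match(out$truth$note_id,
                                          out$notes$note_id)]
  expect_true(all(flags[out$truth$kind == "gold"]))
  expect_true(all(!flags[out$truth$kind == "paraphrase"]))
})

test_that("sentence indices in the truth table survive normalization", {
  out <- generate_corpus(generator_config(n_notes = 40, seed = 19))
  for (nid in unique(out$truth$note_id)) {
    ft <- out$notes$free_text[out$notes$note_id == nid]
    raw <- segment_sentences(ft)
    norm <- segment_sentences(normalize_text(ft))
    expect_equal(length(raw), length(norm))
    spans <- out$truth[out$truth$note_id == nid, ]
    expect_true(all(spans$last_sentence <= length(raw)))
  }
})

test_that("infeasible prevalence is rejected", {
  expect_error(generate_corpus(generator_config(
    n_notes = 10, annotated_fraction = 0.1,
    category_prevalence = c(marginalized = 200), seed = 1)),
    "infeasible")
  expect_error(generate_corpus(generator_config(
    n_notes = 10, annotated_fraction = 0,
    category_prevalence = c(marginalized = 10), seed = 1)),
    "infeasible")
})

test_that("the simulated verifier is the ground-truth oracle at rate zero", {
  sim <- generate_corpus(generator_config(n_notes = 100, seed = 27))
  pool <- build_candidate_pool(sim$notes, gold = sim$gold)
  index <- build_search_index(pool)
  queries <- sample_queries(sim$gold, expansion_config(n_queries = 20))
  queue <- make_review_queue(index, queries, top_k = 5)

  decided <- simulate_verifier(queue, sim$truth, error_rate = 0)
  overlap <- vapply(seq_len(nrow(queue)), function(i) {
    tr <- sim$truth[sim$truth$note_id == queue$note_id[i], ]
    any(tr$first_sentence <= queue$last_sentence[i] &
          tr$last_sentence >= queue$first_sentence[i])
  }, logical(1))
  expect_equal(decided$decision != "reject", overlap)

  # rate one is the exact complement
  flipped <- simulate_verifier(queue, sim$truth, error_rate = 1)
  expect_equal(flipped$decision != "reject", !overlap)

  # unknown note references are rejected
  bad <- queue
  bad$note_id[1] <- "nope"
  expect_error(simulate_verifier(bad, sim$truth,
                                 known_note_ids = sim$notes$note_id),
               "unknown note")
})

test_that("verifier errors occur at the configured binomial rate", {
  sim <- generate_corpus(generator_config(n_notes = 100, seed = 27))
  pool <- build_candidate_pool(sim$notes, gold = sim$gold)
  index <- build_search_index(pool)
  queries <- sample_queries(sim$gold, expansion_config(n_queries = 25))
  queue <- make_review_queue(index, queries, top_k = 20)
  expect_gte(nrow(queue), 400)

  clean <- simulate_verifier(queue, sim$truth, error_rate = 0)
  noisy <- simulate_verifier(queue, sim$truth, error_rate = 0.1, seed = 5)
  flipped <- mean((clean$decision == "reject") != (noisy$decision == "reject"))
  n <- nrow(queue)
  half_width <- 2.58 * sqrt(0.1 * 0.9 / n)
  expect_gt(flipped, 0.1 - half_width)
  expect_lt(flipped, 0.1 + half_width)
})
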