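test_that("negative sampling matches widths exactly and types within one", {
  sim <- generate_corpus(generator_config(n_notes = 150, seed = 37))
  flagged <- unique(sim$truth$note_id)
  neg <- sample_negatives(sim$notes, sim$gold, flagged_note_ids = flagged,
                          seed = 3)
  expect_equal(nrow(neg), nrow(sim$gold))
  expect_true(all(neg$category == "none"))
  expect_true(all(neg$provenance == "negative_sample"))
  # never drawn from a note with any true span
  expect_false(any(neg$note_id %in% flagged))
  # width histogram identical to the positives'
  expect_equal(table(factor(neg$n_sentences, levels = 1:3)),
               table(factor(sim$gold$n_sentences, levels = 1:3)))
  # note-type histogram within 1 per type
  pos_types <- table(factor(
    sim$notes$note_type[match(sim$gold$note_id, sim$notes$note_id)],
    levels = note_types()))
  neg_types <- table(factor(
    sim$notes$note_type[match(neg$note_id, sim$notes$note_id)],
    levels = note_types()))
  expect_true(all(abs(as.numeric(pos_types) - as.numeric(neg_types)) <= 1))
  # reproducible under the seed
  neg2 <- sample_negatives(sim$notes, sim$gold, flagged_note_ids = flagged,
                           seed = 3)
  expect_identical(neg, neg2)
})

test_that("negative sampling handles ratios and empty positives", {
  sim <- generate_corpus(generator_config(n_notes = 120, seed = 41))
  flagged <- unique(sim$truth$note_id)
  neg_half <- sample_negatives(sim$notes, sim$gold,
                               flagged_note_ids = flagged, ratio = 0.5,
                               seed = 1)
  expect_equal(nrow(neg_half),
               as.integer(round(0.5 * nrow(sim$gold))))
  expect_equal(nrow(sample_negatives(sim$notes, make_exemplars(character()),
                                     flagged_note_ids = character(),
                                     seed = 1)), 0)
})

test_that("a balanced modeling set doubles the positive count", {
  sim <- generate_corpus(generator_config(n_notes = 150, seed = 37))
  neg <- sample_negatives(sim$notes, sim$gold,
                          flagged_note_ids = unique(sim$truth$note_id),
                          seed = 5)
  md <- merge_datasets(sim$gold, neg)
  expect_equal(nrow(md), 2 * nrow(sim$gold))
})

test_that("stratified splits partition with largest-remainder allocation", {
  # one stratum of 50 -> 30/10/10
  ex <- make_exemplars(rep("marginalized", 50))
  sp <- stratified_split(ex, split_config(seed = 1))
  expect_equal(vapply(sp, nrow, integer(1)),
               c(train = 30L, validation = 10L, test = 10L))

  # two strata (60, 40) -> 36+24 / 12+8 / 12+8
  ex2 <- make_exemplars(c(rep("marginalized", 60), rep("none", 40)))
  sp2 <- stratified_split(ex2, split_config(seed = 2))
  expect_equal(nrow(sp2$train), 60)
  expect_equal(nrow(sp2$validation), 20)
  expect_equal(nrow(sp2$test), 20)
  expect_equal(sum(sp2$train$category == "marginalized"), 36)
  expect_equal(sum(sp2$validation$category == "none"), 8)

  # partition: union equals input, parts disjoint
  ids <- c(sp2$train$exemplar_id, sp2$validation$exemplar_id,
           sp2$test$exemplar_id)
  expect_setequal(ids, ex2$exemplar_id)
  expect_equal(anyDuplicated(ids), 0)

  # per-stratum proportions deviate by less than one item
  for (cat in unique(ex2$category)) {
    n_cat <- sum(ex2$category == cat)
    for (part in c("train", "validation", "test")) {
      frac <- c(train = 0.6, validation = 0.2, test = 0.2)[[part]]
      got <- sum(sp2[[part]]$category == cat)
      expect_lt(abs(got - frac * n_cat), 1)
    }
  }
})

test_that("splits are reproducible and tiny strata fall back to train", {
  ex <- make_exemplars(c(rep("marginalized", 20), "questioning_credibility",
                         "questioning_credibility"))
  expect_warning(sp <- stratified_split(ex, split_config(seed = 4)),
                 "assigning all to train")
  expect_equal(sum(sp$train$category == "questioning_credibility"), 2)
  a <- suppressWarnings(stratified_split(ex, split_config(seed = 8)))
  b <- suppressWarnings(stratified_split(ex, split_config(seed = 8)))
  expect_identical(lapply(a, as.data.frame), lapply(b, as.data.frame))
})

test_that("enhanced splits are part-wise unions that conserve size", {
  init <- make_exemplars(rep(c("marginalized", "none"), each = 25),
                         prefix = "in")
  exp <- make_exemplars(rep(c("positive_preferred", "none"), each = 10),
                        prefix = "ex")
  sp_i <- stratified_split(init, split_config(seed = 1))
  sp_e <- stratified_split(exp, split_config(seed = 2))
  enh <- build_enhanced(sp_i, sp_e)
  expect_equal(nrow(enh$train) + nrow(enh$validation) + nrow(enh$test),
               nrow(init) + nrow(exp))
  expect_equal(nrow(enh$train), nrow(sp_i$train) + nrow(sp_e$train))

  # identity when the expanded splits are empty
  sp_empty <- stratified_split(make_exemplars(character()),
                               split_config(seed = 1))
  enh2 <- build_enhanced(sp_i, sp_empty)
  expect_equal(as.data.frame(enh2$train), as.data.frame(sp_i$train))

  # id collisions abort
  expect_error(build_enhanced(sp_i, sp_i), "collision")
})

test_that("split manifests record sizes and strata", {
  ex <- make_exemplars(rep(c("marginalized", "none"), each = 10))
  sp <- stratified_split(ex, cfg <- split_config(seed = 3))
  dir <- withr::local_tempdir()
  man <- write_splits(sp, dir, cfg)
  expect_true(file.exists(file.path(dir, "train.jsonl")))
  expect_equal(man$sizes$train, nrow(sp$train))
  back <- read_exemplars_jsonl(file.path(dir, "test.jsonl"))
  expect_equal(as.data.frame(back), as.data.frame(sp$test))
})
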