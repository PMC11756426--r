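test_that("tf-idf matches the smoothed closed form on toy corpora", {
  # single document: every idf is ln(2/2) + 1 = 1
  m1 <- tfidf_fit("a b c")
  expect_true(all(m1$idf == 1))

  # three-document corpus, hand-computed
  docs <- c("a b", "a c", "a")
  m <- tfidf_fit(docs)
  X <- as.matrix(tfidf_transform(m, docs))
  idf_a <- log(4 / 4) + 1
  idf_rare <- log(4 / 2) + 1  # b, c, and the bigrams a_b, a_c
  row1 <- c(a = idf_a, a_b = idf_rare, b = idf_rare)
  row1 <- row1 / sqrt(sum(row1^2))
  expect_equal(unname(X[1, "a"]), unname(row1["a"]), tolerance = 1e-9)
  expect_equal(unname(X[1, "b"]), unname(row1["b"]), tolerance = 1e-9)
  expect_equal(unname(X[1, "a_b"]), unname(row1["a_b"]), tolerance = 1e-9)
  expect_equal(unname(X[3, "a"]), 1)  # single-token doc, L2-normalized
  expect_equal(unname(sum(X[1, c("c", "a_c")])), 0)
  expect_equal(unname(rowSums(X^2)), c(1, 1, 1), tolerance = 1e-9)
})

test_that("tf-idf transform of empty or unseen text is a zero row", {
  m <- tfidf_fit(c("a b", "c d"))
  X <- as.matrix(tfidf_transform(m, c("", "zz qq")))
  expect_true(all(X == 0))
  expect_error(tfidf_fit("!!! ..."), "empty vocabulary")
})

test_that("chi-squared scores match the hand-computed statistic", {
  # one feature, equal class sizes, class-wise sums 8 vs 2:
  # expected (5, 5), chi2 = 9/5 + 9/5 = 3.6
  X <- matrix(c(5, 3, 1, 1), ncol = 1)
  y <- c("a", "a", "b", "b")
  sel <- chi2_select(X, y, k = 1)
  expect_equal(unname(sel$scores), 3.6)

  # class-independent feature scores zero
  X2 <- cbind(c(2, 2, 2, 2), c(5, 3, 1, 1))
  expect_equal(unname(chi2_select(X2, y, k = 2)$scores[1]), 0)

  # ranking with ties broken by lower index; saturation keeps everything
  X3 <- cbind(c(5, 3, 1, 1), c(5, 3, 1, 1), c(2, 2, 2, 2))
  sel3 <- chi2_select(X3, y, k = 10)
  expect_equal(sel3$selected, c(1L, 2L, 3L))

  expect_error(chi2_select(matrix(-1), "a", 1), "nonnegative")
})

test_that("chi-squared scores are invariant to row permutation", {
  set.seed(11)
  X <- matrix(rpois(60, 2), nrow = 12)
  y <- rep(c("a", "b", "c"), each = 4)
  perm <- sample(12)
  expect_equal(chi2_select(X, y, 5)$scores,
               chi2_select(X[perm, ], y[perm], 5)$scores)
})

test_that("classifiers fit separable data and reject bad shapes", {
  set.seed(2)
  X <- rbind(matrix(rnorm(40, 0), ncol = 2), matrix(rnorm(40, 4), ncol = 2))
  y <- rep(c("none", "marginalized"), each = 20)
  m <- train_classifier(classifier_spec("svm",
                                        hyperparameters = list(C = 100)),
                        X, y)
  expect_equal(mean(predict(m, X) == y), 1)
  expect_error(predict(m, X[, 1, drop = FALSE]), "feature count mismatch")
})

test_that("a depth-1 tree recovers a single-feature threshold rule", {
  X <- matrix(c(1, 2, 3, 10, 11, 12), ncol = 1)
  y <- c(rep("none", 3), rep("marginalized", 3))
  m <- train_classifier(
    classifier_spec("decision_tree",
                    hyperparameters = list(max_depth = 1)), X, y)
  newX <- matrix(c(0, 5, 8, 20), ncol = 1)
  expect_equal(predict(m, newX),
               c("none", "none", "marginalized", "marginalized"))
})

test_that("random forests are reproducible under their seed", {
  set.seed(3)
  X <- matrix(rnorm(200), ncol = 4)
  y <- rep(c("none", "positive_preferred"), 25)
  m1 <- train_classifier(classifier_spec("random_forest", seed = 5), X, y)
  m2 <- train_classifier(classifier_spec("random_forest", seed = 5), X, y)
  expect_identical(predict(m1, X), predict(m2, X))
})

test_that("cross-validation folds are stratified partitions", {
  set.seed(4)
  X <- matrix(rnorm(300), ncol = 2)
  y <- c(rep("marginalized", 10), rep("none", 70),
         rep("positive_preferred", 70))
  cv <- cross_validate(classifier_spec("decision_tree"), X, y, seed = 6)
  expect_equal(nrow(cv$fold_metrics), 5)
  expect_equal(sort(unique(cv$folds)), 1:5)
  # class of 10 members over 5 folds: exactly 2 per fold
  expect_true(all(table(cv$folds[y == "marginalized"]) == 2))
  # weights: inverse class frequency normalized to mean one
  w <- stigmatext:::inverse_frequency_weights(y)
  expect_equal(mean(w), 1)
  expect_gt(w[1], w[11])
  # determinism
  cv2 <- cross_validate(classifier_spec("decision_tree"), X, y, seed = 6)
  expect_identical(cv$folds, cv2$folds)
  expect_equal(cv$fold_metrics, cv2$fold_metrics)
})

test_that("model-based tuning finds a known 1-d optimum", {
  res1 <- tune_bayesian(function(p) -(p$c - 2)^2,
                        search_space(c = param_num(0, 5)),
                        budget = 1, seed = 1)
  expect_equal(nrow(res1$history), 1)
  expect_equal(res1$best_value, -(res1$best_params$c - 2)^2)

  res <- tune_bayesian(function(p) -(p$c - 2)^2,
                       search_space(c = param_num(0, 5)),
                       budget = 30, seed = 2)
  expect_lt(abs(res$best_params$c - 2), 0.25)

  # identical trajectory under the same seed
  res_b <- tune_bayesian(function(p) -(p$c - 2)^2,
                         search_space(c = param_num(0, 5)),
                         budget = 30, seed = 2)
  expect_equal(res$history$value, res_b$history$value)

  expect_error(param_num(5, 1), "invalid")
  expect_error(search_space(param_num(0, 1)), "names")
})

test_that("tuned settings do not underperform the defaults on a benchmark", {
  sim <- generate_corpus(generator_config(n_notes = 100, seed = 55))
  neg <- sample_negatives(sim$notes, sim$gold,
                          flagged_note_ids = unique(sim$truth$note_id),
                          seed = 7)
  md <- merge_datasets(sim$gold, neg)
  texts <- normalize_text(md$text)
  tf <- tfidf_fit(texts)
  X <- tfidf_transform(tf, texts)
  cv_value <- function(hp) {
    spec <- classifier_spec("decision_tree", hyperparameters = hp, seed = 1)
    suppressWarnings(
      cross_validate(spec, X, md$category, seed = 3)$mean[["macro_f1"]])
  }
  default_score <- cv_value(list())
  tuned <- tune_bayesian(function(p) cv_value(p),
                         default_search_space("decision_tree"),
                         budget = 6, seed = 4)
  expect_gte(tuned$best_value, default_score - 1e-9)
})
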