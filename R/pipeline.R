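#' Train a text classification pipeline on exemplars
#'
#' The full feature-and-model chain applied to an exemplar set: text
#' normalization, TF-IDF fitting on the training texts, chi-squared
#' feature selection (by default keeping every feature with a positive
#' score), and classifier training with inverse-class-frequency sample
#' weights. The fitted object predicts categories directly from raw
#' exemplar text.
#'
#' @param exemplars Training exemplar tibble (`text`, `category`).
#' @param spec A [classifier_spec()].
#' @param chi2_k Number of features kept; `NULL` keeps all features with
#'   a positive chi-squared score.
#' @param rules [normalization_rules()].
#' @return A list of class `text_pipeline`.
#' @export
train_text_pipeline <- function(exemplars, spec = classifier_spec("svm"),
                                chi2_k = NULL,
                                rules = normalization_rules()) {
  validate_exemplars(exemplars)
  texts <- normalize_text(exemplars$text, rules)
  tfidf <- tfidf_fit(texts)
  X <- tfidf_transform(tfidf, texts)
  sel <- chi2_select(X, exemplars$category,
                     k = if (is.null(chi2_k)) ncol(X) else chi2_k)
  keep <- if (is.null(chi2_k)) {
    sel$selected[sel$scores[sel$selected] > 0]
  } else sel$selected
  if (length(keep) == 0) keep <- sel$selected[1]
  keep <- sort(keep)
  model <- train_classifier(spec, X[, keep, drop = FALSE],
                            exemplars$category)
  structure(list(tfidf = tfidf, selected = keep, model = model,
                 rules = rules, spec = spec),
            class = "text_pipeline")
}

#' @export
print.text_pipeline <- function(x, ...) {
  cat("<text_pipeline> ", x$spec$kind, ", ",
      length(x$tfidf$vocabulary), " -> ", length(x$selected),
      " features\n", sep = "")
  invisible(x)
}

#' @rdname train_text_pipeline
#' @param object A `text_pipeline`.
#' @param newdata Exemplar tibble or character vector of texts.
#' @param ... Ignored.
#' @export
predict.text_pipeline <- function(object, newdata, ...) {
  texts <- if (is.data.frame(newdata)) newdata$text else newdata
  texts <- normalize_text(texts, object$rules)
  X <- tfidf_transform(object$tfidf, texts)
  predict(object$model, X[, object$selected, drop = FALSE])
}

#' Pipeline configuration
#'
#' One configuration object for the full study workflow; can be read
#' from a YAML file with [read_pipeline_config()].
#'
#' @param generator A [generator_config()].
#' @param expansion An [expansion_config()].
#' @param split A [split_config()].
#' @param classifier A [classifier_spec()].
#' @param backend An [embedding_backend()].
#' @param verifier_error_rate Error rate of the simulated verifier.
#' @param bootstrap_B Bootstrap replicates for evaluation.
#' @param seed Master seed; stage seeds derive from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            expansion = expansion_config(),
                            split = split_config(),
                            classifier = classifier_spec("svm"),
                            backend = embedding_backend(),
                            verifier_error_rate = 0,
                            bootstrap_B = 1000L,
                            seed = 1L) {
  seed <- as.integer(seed)
  generator$seed <- seed
  expansion$seed <- seed + 1L
  split$seed <- seed + 2L
  classifier$seed <- seed + 3L
  structure(list(generator = generator, expansion = expansion,
                 split = split, classifier = classifier, backend = backend,
                 verifier_error_rate = verifier_error_rate,
                 bootstrap_B = as.integer(bootstrap_B), seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized top-level keys: `seed`, `n_notes`, `n_queries`, `top_k`,
#' `classifier` (`kind`, `hyperparameters`), `verifier_error_rate`,
#' `bootstrap_B`, `embedding` (`backend`, `dimension`).
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  gen <- generator_config(n_notes = y$n_notes %||% 600L)
  exp <- expansion_config(n_queries = y$n_queries %||% 250L,
                          top_k = y$top_k %||% 5L)
  cls <- classifier_spec(kind = y$classifier$kind %||% "svm",
                         hyperparameters = y$classifier$hyperparameters %||%
                           list())
  be <- embedding_backend(name = y$embedding$backend %||% "hashed_ngram",
                          dimension = y$embedding$dimension %||% 512L)
  pipeline_config(generator = gen, expansion = exp, classifier = cls,
                  backend = be,
                  verifier_error_rate = y$verifier_error_rate %||% 0,
                  bootstrap_B = y$bootstrap_B %||% 1000L,
                  seed = y$seed %||% 1L)
}

#' Run the full study pipeline
#'
#' Executes the complete workflow on a synthetic corpus: generate the
#' corpus and gold annotations; build the candidate pool from
#' unannotated notes; sample query exemplars and retrieve top-k
#' candidates; pass the review queue through the simulated verifier and
#' ingest the decisions into the expanded dataset; sample matched
#' negatives for the initial and expanded sets; split each 60/20/20
#' stratified by category and combine into the enhanced splits; train
#' one classifier on the initial train+validation pool and one on the
#' enhanced train+validation pool; evaluate both on the *enhanced* test
#' set with bootstrap resampling and BCa intervals; and compare them.
#' Both models are always evaluated on the same enhanced test split,
#' never on their own test splits.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory for artifacts (JSONL datasets,
#'   reports, manifest).
#' @param progress Print stage messages.
#' @return A list of class `pipeline_result` with the corpus, datasets,
#'   splits, fitted pipelines, both [bootstrap_evaluate()] reports, the
#'   comparison, and a reproducibility manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         progress = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (progress) message(...)
  stage_times <- c()
  tic <- function() Sys.time()
  stamp <- function(name, t0) {
    stage_times[[name]] <<- as.numeric(difftime(Sys.time(), t0,
                                                units = "secs"))
  }

  t0 <- tic()
  say("simulate: generating synthetic corpus")
  sim <- generate_corpus(config$generator)
  stamp("simulate", t0)

  t0 <- tic()
  say("expand: retrieval over unannotated notes")
  pool <- build_candidate_pool(sim$notes, gold = sim$gold,
                               dedup_against_gold = config$expansion$dedup_against_gold)
  index <- build_search_index(pool, config$backend)
  queries <- sample_queries(sim$gold, config$expansion)
  queue <- make_review_queue(index, queries, top_k = config$expansion$top_k)
  decided <- simulate_verifier(queue, sim$truth,
                               error_rate = config$verifier_error_rate,
                               seed = config$seed + 11L,
                               known_note_ids = sim$notes$note_id)
  expanded <- ingest_review(decided, gold = sim$gold)
  stamp("expand", t0)

  t0 <- tic()
  say("build-datasets: negatives, splits, enhanced combination")
  flagged <- unique(sim$truth$note_id)
  neg_init <- sample_negatives(sim$notes, sim$gold,
                               flagged_note_ids = flagged,
                               seed = config$seed + 21L)
  initial_md <- merge_datasets(sim$gold, neg_init)
  splits_init <- stratified_split(initial_md, config$split)
  if (nrow(expanded) > 0) {
    neg_exp <- sample_negatives(sim$notes, expanded,
                                flagged_note_ids = c(flagged,
                                                     expanded$note_id,
                                                     neg_init$note_id),
                                seed = config$seed + 22L)
    neg_exp$exemplar_id <- paste0("x", neg_exp$exemplar_id)
    expanded_md <- merge_datasets(expanded, neg_exp)
    splits_exp <- stratified_split(expanded_md,
                                   split_config(seed = config$split$seed + 1L))
    splits_enh <- build_enhanced(splits_init, splits_exp)
  } else {
    expanded_md <- expanded
    splits_exp <- NULL
    splits_enh <- splits_init
  }
  stamp("build_datasets", t0)

  t0 <- tic()
  say("train: initial and enhanced ", config$classifier$kind)
  pool_init <- merge_datasets(splits_init$train, splits_init$validation)
  pool_enh <- merge_datasets(splits_enh$train, splits_enh$validation)
  fit_init <- train_text_pipeline(pool_init, config$classifier)
  fit_enh <- train_text_pipeline(pool_enh, config$classifier)
  stamp("train", t0)

  t0 <- tic()
  say("evaluate: both models on the enhanced test set")
  test <- splits_enh$test
  pred_init <- predict(fit_init, test)
  pred_enh <- predict(fit_enh, test)
  report_init <- bootstrap_evaluate(test$category, pred_init,
                                    B = config$bootstrap_B,
                                    seed = config$seed + 31L)
  report_enh <- bootstrap_evaluate(test$category, pred_enh,
                                   B = config$bootstrap_B,
                                   seed = config$seed + 31L)
  comparison <- compare_reports(report_init, report_enh)
  stamp("evaluate", t0)

  manifest <- list(
    seed = config$seed,
    classifier = config$classifier$kind,
    sizes = list(
      notes = nrow(sim$notes), gold = nrow(sim$gold),
      pool = nrow(pool), queries = nrow(queries),
      candidates = nrow(queue), expanded = nrow(expanded),
      initial_modeling = nrow(initial_md),
      expanded_modeling = nrow(expanded_md),
      enhanced_train = nrow(splits_enh$train),
      enhanced_validation = nrow(splits_enh$validation),
      enhanced_test = nrow(splits_enh$test)),
    digests = list(
      corpus = rlang::hash(sim$notes),
      gold = rlang::hash(sim$gold),
      expanded = rlang::hash(expanded),
      enhanced_test = rlang::hash(splits_enh$test)),
    stage_seconds = as.list(stage_times))

  result <- structure(
    list(corpus = sim$notes, gold = sim$gold, truth = sim$truth,
         expanded = expanded, splits_initial = splits_init,
         splits_enhanced = splits_enh, fit_initial = fit_init,
         fit_enhanced = fit_enh, report_initial = report_init,
         report_enhanced = report_enh, comparison = comparison,
         manifest = manifest),
    class = "pipeline_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_notes_jsonl(sim$notes, file.path(out_dir, "notes.jsonl"))
    write_exemplars_jsonl(sim$gold, file.path(out_dir, "gold.jsonl"))
    write_exemplars_jsonl(expanded, file.path(out_dir, "expanded.jsonl"))
    write_splits(splits_enh, file.path(out_dir, "splits_enhanced"),
                 config$split)
    write_report(report_init, file.path(out_dir, "report_initial.csv"))
    write_report(report_enh, file.path(out_dir, "report_enhanced.csv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$manifest$sizes
  cat("<pipeline_result>\n")
  cat("  corpus: ", s$notes, " notes, ", s$gold, " gold exemplars\n", sep = "")
  cat("  expansion: ", s$candidates, " candidates -> ", s$expanded,
      " verified exemplars\n", sep = "")
  cat("  datasets: initial ", s$initial_modeling, ", expanded ",
      s$expanded_modeling, "\n", sep = "")
  cat(sprintf("  macro F1 on enhanced test: initial %.3f, enhanced %.3f\n",
              x$report_initial$point$macro[["f1"]],
              x$report_enhanced$point$macro[["f1"]]))
  invisible(x)
}

#' @rdname run_pipeline
#' @param x A `pipeline_result`.
#' @param ... Ignored.
#' @method glance pipeline_result
#' @export
glance.pipeline_result <- function(x, ...) {
  tibble::tibble(
    n_notes = x$manifest$sizes$notes,
    n_gold = x$manifest$sizes$gold,
    n_expanded = x$manifest$sizes$expanded,
    macro_f1_initial = x$report_initial$point$macro[["f1"]],
    macro_f1_enhanced = x$report_enhanced$point$macro[["f1"]],
    macro_f1_improvement_pct = x$comparison$macro$improvement_pct[
      x$comparison$macro$metric == "f1"])
}
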