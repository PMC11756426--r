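#' Tokenize normalized text into unigrams and bigrams
#'
#' Word tokens are maximal runs of letters/digits in the lowercased text;
#' features are the unigrams plus adjacent-pair bigrams (joined with an
#' underscore), which capture short phrases such as "poor effort".
#'
#' @param texts Character vector.
#' @return List of character vectors of tokens.
#' @export
tokenize <- function(texts) {
  toks <- stringr::str_extract_all(tolower(texts), "[a-z0-9]+")
  purrr::map(toks, function(t) {
    if (length(t) >= 2) {
      c(t, paste(t[-length(t)], t[-1], sep = "_"))
    } else t
  })
}

#' Fit a TF-IDF model
#'
#' Smoothed TF-IDF: `idf(t) = ln((1 + N) / (1 + df(t))) + 1`, applied to
#' raw term frequencies (or `1 + ln(tf)` when `sublinear_tf`), with each
#' document row L2-normalized. Terms unseen at fit time are ignored at
#' transform time; an empty document transforms to a zero row.
#'
#' @param documents Character vector of training documents.
#' @param sublinear_tf Use `1 + ln(tf)` in place of raw counts.
#' @return A list of class `tfidf_model` with `vocabulary` (named index
#'   vector), `idf`, `sublinear_tf`.
#' @export
tfidf_fit <- function(documents, sublinear_tf = FALSE) {
  stopifnot(length(documents) >= 1)
  toks <- tokenize(documents)
  vocab <- sort(unique(unlist(toks)))
  if (length(vocab) == 0) {
    stop("empty vocabulary: no tokens in any document", call. = FALSE)
  }
  n <- length(documents)
  df <- integer(length(vocab))
  names(df) <- vocab
  for (t in toks) {
    u <- unique(t)
    df[u] <- df[u] + 1L
  }
  idf <- log((1 + n) / (1 + df)) + 1
  structure(list(vocabulary = stats::setNames(seq_along(vocab), vocab),
                 idf = idf, sublinear_tf = sublinear_tf,
                 n_documents = n),
            class = "tfidf_model")
}

#' @rdname tfidf_fit
#' @param model A fitted `tfidf_model`.
#' @return `tfidf_transform()`: a sparse `dgCMatrix`
#'   (documents x vocabulary) of L2-normalized TF-IDF weights.
#' @export
tfidf_transform <- function(model, documents) {
  stopifnot(inherits(model, "tfidf_model"))
  toks <- tokenize(documents)
  triplets <- purrr::imap(toks, function(t, i) {
    t <- t[t %in% names(model$vocabulary)]
    if (length(t) == 0) return(NULL)
    tab <- table(t)
    tf <- as.numeric(tab)
    if (isTRUE(model$sublinear_tf)) tf <- 1 + log(tf)
    j <- model$vocabulary[names(tab)]
    w <- tf * model$idf[j]
    nrm <- sqrt(sum(w^2))
    if (nrm > 0) w <- w / nrm
    list(i = rep(i, length(j)), j = unname(j), x = w)
  })
  triplets <- purrr::compact(triplets)
  if (length(triplets) == 0) {
    return(Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(length(documents),
                                         length(model$vocabulary)),
                                dimnames = list(NULL,
                                                names(model$vocabulary))))
  }
  Matrix::sparseMatrix(
    i = unlist(purrr::map(triplets, "i")),
    j = unlist(purrr::map(triplets, "j")),
    x = unlist(purrr::map(triplets, "x")),
    dims = c(length(documents), length(model$vocabulary)),
    dimnames = list(NULL, names(model$vocabulary)))
}

#' Chi-squared feature selection
#'
#' For each nonnegative feature, the chi-squared statistic of the
#' class-wise feature sums against their expectation under
#' class-independence: `sum((O - E)^2 / E)` where the observed values are
#' the per-class column sums and the expected values distribute the
#' feature's total mass according to the class proportions. Returns the
#' top `k` features by score, ties broken by lower column index.
#'
#' @param X Nonnegative feature matrix (dense or sparse), documents in
#'   rows.
#' @param y Class labels (one per row).
#' @param k Number of features to keep; `k >= ncol(X)` keeps all,
#'   sorted by score.
#' @return A list with `selected` (column indices, score-ordered) and
#'   `scores` (all per-feature statistics).
#' @export
chi2_select <- function(X, y, k) {
  stopifnot(k >= 1, nrow(X) == length(y))
  if (any(X < 0)) stop("chi-squared selection requires nonnegative features",
                       call. = FALSE)
  y <- factor(y)
  classes <- levels(y)
  ind <- Matrix::sparseMatrix(i = seq_along(y), j = as.integer(y), x = 1,
                              dims = c(length(y), length(classes)))
  observed <- as.matrix(Matrix::crossprod(ind, X))    # classes x features
  feat_sum <- colSums(observed)
  class_prop <- as.numeric(table(y)) / length(y)
  expected <- outer(class_prop, feat_sum)
  with_mass <- expected > 0
  contrib <- matrix(0, nrow(observed), ncol(observed))
  contrib[with_mass] <- (observed[with_mass] - expected[with_mass])^2 /
    expected[with_mass]
  scores <- colSums(contrib)
  k <- min(k, length(scores))
  selected <- order(-scores, seq_along(scores))[seq_len(k)]
  list(selected = as.integer(selected), scores = scores)
}

#' Classifier specification
#'
#' @param kind `"svm"`, `"decision_tree"` or `"random_forest"`.
#' @param hyperparameters Named list. SVM: `C`, `kernel`
#'   (`"linear"`/`"radial"`), `gamma`; tree: `max_depth`,
#'   `min_samples_leaf`; forest: `n_estimators`, `max_depth`,
#'   `max_features` (fraction of features tried per split).
#' @param class_weighting `"inverse_frequency"` (default) or `"none"`.
#' @param seed Seed for the stochastic learners.
#' @return A list of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("svm", "decision_tree", "random_forest"),
                            hyperparameters = list(),
                            class_weighting = c("inverse_frequency", "none"),
                            seed = 1L) {
  kind <- match.arg(kind)
  class_weighting <- match.arg(class_weighting)
  defaults <- switch(kind,
    svm = list(C = 1, kernel = "linear", gamma = NA),
    decision_tree = list(max_depth = 16, min_samples_leaf = 1),
    random_forest = list(n_estimators = 200, max_depth = 0,
                         max_features = NA))
  hp <- utils::modifyList(defaults, hyperparameters)
  structure(list(kind = kind, hyperparameters = hp,
                 class_weighting = class_weighting, seed = seed),
            class = "classifier_spec")
}

# Inverse-class-frequency sample weights, normalized to mean 1.
inverse_frequency_weights <- function(y) {
  y <- factor(y)
  freq <- table(y)
  w <- (1 / as.numeric(freq))[as.integer(y)]
  w / mean(w)
}

#' Train a classifier
#'
#' Fits an SVM (via \pkg{e1071}), a decision tree (via \pkg{rpart}) or a
#' random forest (via \pkg{ranger}) on a feature matrix. Sample weights
#' default to inverse class frequency normalized to mean 1; for the SVM,
#' whose backend weights classes rather than samples, the per-class mean
#' weight is passed as a class weight (identical for inverse-frequency
#' weights, which are constant within class).
#'
#' @param spec A [classifier_spec()].
#' @param X Feature matrix (documents x features).
#' @param y Labels.
#' @param sample_weights Optional per-sample weights.
#' @return A list of class `stigma_model` with a [predict][predict.stigma_model]
#'   method.
#' @export
train_classifier <- function(spec, X, y, sample_weights = NULL) {
  stopifnot(inherits(spec, "classifier_spec"), nrow(X) == length(y))
  y <- factor(y)
  if (is.null(sample_weights)) {
    sample_weights <- switch(spec$class_weighting,
                             inverse_frequency = inverse_frequency_weights(y),
                             none = rep(1, length(y)))
  }
  hp <- spec$hyperparameters
  Xd <- as.matrix(X)
  colnames(Xd) <- paste0("f", seq_len(ncol(Xd)))
  fit <- switch(spec$kind,
    svm = {
      cw <- tapply(sample_weights, y, mean)
      e1071::svm(x = Xd, y = y, kernel = hp$kernel, cost = hp$C,
                 gamma = if (is.na(hp$gamma)) 1 / ncol(Xd) else hp$gamma,
                 class.weights = cw, scale = FALSE)
    },
    decision_tree = {
      df <- data.frame(.y = y, Xd, check.names = FALSE)
      with_seed(spec$seed,
        rpart::rpart(.y ~ ., data = df, weights = sample_weights,
                     method = "class",
                     control = rpart::rpart.control(
                       maxdepth = min(30, hp$max_depth),
                       minbucket = hp$min_samples_leaf,
                       minsplit = max(2, 2 * hp$min_samples_leaf),
                       cp = 0, xval = 0)))
    },
    random_forest = {
      mtry <- if (is.na(hp$max_features)) max(1, floor(sqrt(ncol(Xd)))) else
        max(1, floor(hp$max_features * ncol(Xd)))
      ranger::ranger(x = Xd, y = y, num.trees = hp$n_estimators,
                     max.depth = hp$max_depth, mtry = mtry,
                     case.weights = sample_weights, seed = spec$seed,
                     num.threads = 1)
    })
  structure(list(spec = spec, fit = fit, levels = levels(y),
                 n_features = ncol(Xd)),
            class = "stigma_model")
}

#' Predict labels from a trained classifier
#'
#' @param object A [train_classifier()] result.
#' @param newdata Feature matrix with the training feature count.
#' @param ... Ignored.
#' @return Character vector of predicted category labels.
#' @export
predict.stigma_model <- function(object, newdata, ...) {
  Xd <- as.matrix(newdata)
  if (ncol(Xd) != object$n_features) {
    stop("feature count mismatch: model expects ", object$n_features,
         ", got ", ncol(Xd), call. = FALSE)
  }
  colnames(Xd) <- paste0("f", seq_len(ncol(Xd)))
  out <- switch(object$spec$kind,
    svm = as.character(stats::predict(object$fit, Xd)),
    decision_tree = {
      df <- data.frame(Xd, check.names = FALSE)
      as.character(stats::predict(object$fit, df, type = "class"))
    },
    random_forest = as.character(
      stats::predict(object$fit, data = Xd, num.threads = 1)$predictions))
  out
}

#' @export
print.stigma_model <- function(x, ...) {
  cat("<stigma_model> ", x$spec$kind, ", ", x$n_features, " features, ",
      length(x$levels), " classes\n", sep = "")
  invisible(x)
}

# Stratified fold assignment: within each class, shuffled round-robin, so
# per-class fold counts differ by at most 1.
stratified_folds <- function(y, n_folds, seed) {
  y <- factor(y)
  folds <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      if (length(idx) < n_folds) {
        warning("class '", cl, "' has fewer members (", length(idx),
                ") than folds (", n_folds, ")", call. = FALSE)
      }
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  folds
}

#' Stratified k-fold cross-validation
#'
#' Folds are stratified by category with per-class counts within one of
#' each other; sample weights are inverse class frequency normalized to
#' mean 1 and applied during fitting. Each fold's held-out part is scored
#' with per-category precision/recall/F1 and their macro averages over
#' the substantive categories.
#'
#' @param spec A [classifier_spec()].
#' @param X Feature matrix.
#' @param y Labels.
#' @param n_folds Number of folds (default 5).
#' @param seed Fold-assignment seed.
#' @return A list of class `cv_result` with `fold_metrics` (tibble),
#'   `mean`, `sd`, `folds` (assignment vector).
#' @export
cross_validate <- function(spec, X, y, n_folds = 5, seed = 1L) {
  y <- factor(y)
  folds <- stratified_folds(y, n_folds, seed)
  fold_metrics <- purrr::map(seq_len(n_folds), function(f) {
    tr <- folds != f
    model <- train_classifier(spec, X[tr, , drop = FALSE], y[tr],
                              inverse_frequency_weights(y[tr]))
    pred <- predict(model, X[!tr, , drop = FALSE])
    rep <- prf_report(as.character(y[!tr]), pred)
    tibble::tibble(fold = f,
                   macro_f1 = rep$macro[["f1"]],
                   macro_precision = rep$macro[["precision"]],
                   macro_recall = rep$macro[["recall"]],
                   accuracy = mean(pred == as.character(y[!tr])))
  })
  fold_metrics <- dplyr::bind_rows(fold_metrics)
  metric_cols <- setdiff(names(fold_metrics), "fold")
  structure(list(fold_metrics = fold_metrics,
                 mean = colMeans(fold_metrics[metric_cols]),
                 sd = vapply(fold_metrics[metric_cols], stats::sd, numeric(1)),
                 folds = folds, spec = spec),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> ", max(x$fold_metrics$fold), "-fold CV, mean macro F1 ",
      sprintf("%.3f", x$mean[["macro_f1"]]), "\n", sep = "")
  invisible(x)
}

#' @rdname cross_validate
#' @param x A `cv_result`.
#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) x$fold_metrics

#' @rdname cross_validate
#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(n_folds = max(x$fold_metrics$fold),
                 mean_macro_f1 = x$mean[["macro_f1"]],
                 sd_macro_f1 = x$sd[["macro_f1"]],
                 mean_accuracy = x$mean[["accuracy"]])
}

#' Describe a hyperparameter search space
#'
#' @param ... Named parameter descriptors from [param_num()],
#'   [param_int()] or [param_cat()].
#' @return A list of class `search_space`.
#' @export
search_space <- function(...) {
  sp <- list(...)
  stopifnot(length(sp) > 0, !is.null(names(sp)), all(nzchar(names(sp))))
  structure(sp, class = "search_space")
}

#' @rdname search_space
#' @param lower,upper Bounds (inclusive).
#' @param log Sample on a log10 scale.
#' @export
param_num <- function(lower, upper, log = FALSE) {
  if (!(is.finite(lower) && is.finite(upper) && lower < upper) ||
      (log && lower <= 0)) {
    stop("invalid numeric parameter bounds", call. = FALSE)
  }
  list(type = "num", lower = lower, upper = upper, log = log)
}

#' @rdname search_space
#' @export
param_int <- function(lower, upper) {
  if (!(is.finite(lower) && is.finite(upper) && lower < upper)) {
    stop("invalid integer parameter bounds", call. = FALSE)
  }
  list(type = "int", lower = as.integer(lower), upper = as.integer(upper))
}

#' @rdname search_space
#' @param values Candidate values.
#' @export
param_cat <- function(values) {
  if (length(values) < 1) stop("empty categorical parameter", call. = FALSE)
  list(type = "cat", values = values)
}

sample_space <- function(space, n) {
  purrr::map(seq_len(n), function(i) {
    purrr::map(space, function(p) {
      switch(p$type,
        num = if (p$log) 10^stats::runif(1, log10(p$lower), log10(p$upper))
              else stats::runif(1, p$lower, p$upper),
        int = sample(seq(p$lower, p$upper), 1),
        cat = p$values[[sample.int(length(p$values), 1)]])
    })
  })
}

params_to_numeric <- function(space, params) {
  unlist(purrr::imap(space, function(p, nm) {
    v <- params[[nm]]
    switch(p$type,
      num = if (p$log) log10(v) else v,
      int = as.numeric(v),
      cat = as.numeric(match(v, p$values)))
  }))
}

#' Sequential model-based (Bayesian) hyperparameter optimization
#'
#' Maximizes an objective over a [search_space()] by sequential
#' model-based search: after an initial seeded random design, a random
#' forest surrogate is fitted to the evaluated points and the next
#' candidate is chosen by expected improvement over a sampled candidate
#' set, using the spread of per-tree predictions as the uncertainty
#' estimate. Falls back to pure seeded random search (recorded in the
#' result's `method` field) when too few points are available to fit a
#' surrogate. Returns the argmax over all evaluated points.
#'
#' @param objective Function taking a named parameter list, returning a
#'   scalar to maximize (e.g. CV mean macro F1).
#' @param space A [search_space()].
#' @param budget Total number of objective evaluations.
#' @param seed Reproducibility seed.
#' @param n_init Size of the initial random design (default
#'   `max(4, budget %/% 3)`, capped at the budget).
#' @return A list of class `tune_result` with `best_params`,
#'   `best_value`, `history` (tibble of all evaluations) and `method`.
#' @export
tune_bayesian <- function(objective, space, budget, seed = 1L,
                          n_init = max(4, budget %/% 3)) {
  stopifnot(inherits(space, "search_space"), budget >= 1)
  n_init <- min(n_init, budget)
  with_seed(seed, {
    params <- sample_space(space, n_init)
    values <- vapply(params, function(p) objective(p), numeric(1))
    method <- if (budget > n_init) "smbo" else "random"
    while (length(values) < budget) {
      xmat <- do.call(rbind, purrr::map(params, params_to_numeric,
                                        space = space))
      cand <- sample_space(space, 64)
      cmat <- do.call(rbind, purrr::map(cand, params_to_numeric,
                                        space = space))
      nxt <- tryCatch({
        sur <- ranger::ranger(
          x = as.data.frame(xmat), y = values, num.trees = 100,
          seed = sample.int(.Machine$integer.max, 1), num.threads = 1)
        pr <- stats::predict(sur, data = as.data.frame(cmat),
                             predict.all = TRUE, num.threads = 1)$predictions
        mu <- rowMeans(pr)
        sdv <- apply(pr, 1, stats::sd)
        best <- max(values)
        z <- ifelse(sdv > 0, (mu - best) / sdv, 0)
        ei <- ifelse(sdv > 0,
                     (mu - best) * stats::pnorm(z) + sdv * stats::dnorm(z),
                     pmax(mu - best, 0))
        cand[[which.max(ei)]]
      }, error = function(e) {
        method <<- "random_fallback"
        cand[[1]]
      })
      params <- c(params, list(nxt))
      values <- c(values, objective(nxt))
    }
    best <- which.max(values)
    history <- tibble::tibble(
      iteration = seq_along(values),
      value = values,
      params = params)
    structure(list(best_params = params[[best]], best_value = values[best],
                   history = history, method = method),
              class = "tune_result")
  })
}

#' Default search spaces for the baseline classifiers
#'
#' SVM: `C` log-uniform on `[1e-2, 1e3]`, kernel linear or radial.
#' Decision tree: `max_depth` in `[2, 64]`. Random forest:
#' `n_estimators` in `[50, 500]`, `max_depth` in `[2, 64]`.
#'
#' @param kind Classifier kind.
#' @return A [search_space()].
#' @export
default_search_space <- function(kind = c("svm", "decision_tree",
                                          "random_forest")) {
  kind <- match.arg(kind)
  switch(kind,
    svm = search_space(C = param_num(1e-2, 1e3, log = TRUE),
                       kernel = param_cat(c("linear", "radial"))),
    decision_tree = search_space(max_depth = param_int(2, 64)),
    random_forest = search_space(n_estimators = param_int(50, 500),
                                 max_depth = param_int(2, 64)))
}

#' @export
print.tune_result <- function(x, ...) {
  cat("<tune_result> ", nrow(x$history), " evaluations (", x$method,
      "), best value ", sprintf("%.4f", x$best_value), "\n", sep = "")
  invisible(x)
}

#' @rdname tune_bayesian
#' @param x A `tune_result`.
#' @method tidy tune_result
#' @export
tidy.tune_result <- function(x, ...) {
  dplyr::bind_cols(
    x$history["iteration"],
    dplyr::bind_rows(purrr::map(x$history$params,
                                ~ tibble::as_tibble(purrr::map(.x, ~ .x)))),
    x$history["value"])
}

#' @rdname tune_bayesian
#' @param object A `tune_result`.
#' @method autoplot tune_result
#' @export
autoplot.tune_result <- function(object, ...) {
  h <- object$history
  h$best_so_far <- cummax(h$value)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$iteration)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$value), alpha = 0.6) +
    ggplot2::geom_step(ggplot2::aes(y = .data$best_so_far), colour = "red") +
    ggplot2::labs(y = "objective", x = "evaluation") +
    ggplot2::theme_minimal()
}
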