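#' Per-category and macro precision/recall/F1
#'
#' Per-class precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and F1 (their
#' harmonic mean), with `0/0` defined as 0. The macro averages are the
#' unweighted means over the six substantive language categories; the
#' negative-case label `"none"` contributes to the confusion matrix but
#' never to the macro average.
#'
#' @param y_true,y_pred Equal-length character vectors of category codes.
#' @param categories Categories over which the macro average is taken.
#' @return A list of class `metric_report` with `per_category` (tibble of
#'   `category`, `precision`, `recall`, `f1`, `support`), `macro` (named
#'   vector) and `n_test`.
#' @export
#' @examples
#' prf_report(c("none", "marginalized"), c("none", "marginalized"))
prf_report <- function(y_true, y_pred,
                       categories = substantive_categories()) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred have different lengths (", length(y_true),
         " vs ", length(y_pred), ")", call. = FALSE)
  }
  if (length(y_true) == 0) stop("empty label vectors", call. = FALSE)
  check_categories(y_true)
  check_categories(y_pred)
  lev <- language_categories()
  cm <- table(factor(y_true, levels = lev), factor(y_pred, levels = lev))
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  precision <- ifelse(tp + fp == 0, 0, tp / (tp + fp))
  recall <- ifelse(tp + fn == 0, 0, tp / (tp + fn))
  f1 <- ifelse(precision + recall == 0, 0,
               2 * precision * recall / (precision + recall))
  per_cat <- tibble::tibble(category = lev,
                            precision = unname(precision),
                            recall = unname(recall),
                            f1 = unname(f1),
                            support = unname(rowSums(cm)))
  keep <- per_cat$category %in% categories
  macro <- c(precision = mean(per_cat$precision[keep]),
             recall = mean(per_cat$recall[keep]),
             f1 = mean(per_cat$f1[keep]))
  structure(list(per_category = per_cat[keep | per_cat$support > 0 |
                                          per_cat$category %in% y_pred, ,
                                        drop = FALSE],
                 macro = macro, n_test = length(y_true),
                 macro_categories = categories),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report> n =", x$n_test, "\n")
  df <- x$per_category
  df[2:4] <- lapply(df[2:4], round_half_away, digits = 2)
  print(df, ...)
  cat(sprintf("macro (over %d categories): P %.2f  R %.2f  F1 %.2f\n",
              length(x$macro_categories), x$macro[["precision"]],
              x$macro[["recall"]], x$macro[["f1"]]))
  invisible(x)
}

#' @rdname prf_report
#' @param x A `metric_report`.
#' @param ... Ignored.
#' @method tidy metric_report
#' @export
tidy.metric_report <- function(x, ...) x$per_category

#' @rdname prf_report
#' @method glance metric_report
#' @export
glance.metric_report <- function(x, ...) {
  tibble::tibble(macro_precision = x$macro[["precision"]],
                 macro_recall = x$macro[["recall"]],
                 macro_f1 = x$macro[["f1"]],
                 n_test = x$n_test)
}

#' @rdname prf_report
#' @param object A `metric_report`.
#' @method autoplot metric_report
#' @export
autoplot.metric_report <- function(object, ...) {
  df <- tidyr::pivot_longer(object$per_category,
                            c("precision", "recall", "f1"),
                            names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

# Metric vector of one (resampled) test set: per-category F1/P/R plus
# macro values. Categories absent from the resampled truth are NA and are
# excluded from that replicate's macro average.
replicate_metrics <- function(true_int, pred_int, lev, macro_idx) {
  k <- length(lev)
  cm <- matrix(tabulate((true_int - 1L) * k + pred_int, nbins = k * k),
               nrow = k, byrow = TRUE)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  precision <- ifelse(tp + fp == 0, 0, tp / (tp + fp))
  recall <- ifelse(tp + fn == 0, 0, tp / (tp + fn))
  f1 <- ifelse(precision + recall == 0, 0,
               2 * precision * recall / (precision + recall))
  absent <- rowSums(cm) == 0
  precision[absent] <- NA_real_
  recall[absent] <- NA_real_
  f1[absent] <- NA_real_
  c(macro_f1 = mean(f1[macro_idx], na.rm = TRUE),
    macro_precision = mean(precision[macro_idx], na.rm = TRUE),
    macro_recall = mean(recall[macro_idx], na.rm = TRUE),
    stats::setNames(f1[macro_idx], paste0("f1_", lev[macro_idx])))
}

#' Bootstrap evaluation of a prediction
#'
#' Resamples the test items uniformly with replacement `B` times (default
#' 1000), recomputes per-category and macro metrics on each replicate,
#' and attaches BCa confidence intervals (bias correction from the
#' replicate distribution, acceleration from a leave-one-out jackknife
#' over test items). A category absent from a replicate's resampled truth
#' has undefined metrics there; it is recorded as missing and excluded
#' from that replicate's macro average.
#'
#' @param y_true,y_pred Test labels and predictions.
#' @param B Number of bootstrap replicates.
#' @param seed Resampling seed.
#' @param alpha Interval level is `1 - alpha`.
#' @param stratified Resample within category strata instead of uniformly
#'   (off by default).
#' @return A list of class `bootstrap_result` with `point` (the
#'   [prf_report()] on the full test set), `replicates` (B x metrics
#'   tibble) and `intervals` (tibble of `metric`, `lo`, `hi`, `method`).
#' @export
bootstrap_evaluate <- function(y_true, y_pred, B = 1000, seed = 1L,
                               alpha = 0.05, stratified = FALSE) {
  n <- length(y_true)
  if (n < 2) stop("bootstrap evaluation needs at least 2 test items",
                  call. = FALSE)
  point <- prf_report(y_true, y_pred)
  lev <- language_categories()
  macro_idx <- match(point$macro_categories, lev)
  ti <- as.integer(factor(y_true, levels = lev))
  pi <- as.integer(factor(y_pred, levels = lev))

  reps <- with_seed(seed, {
    purrr::map(seq_len(B), function(b) {
      idx <- if (stratified) {
        unlist(purrr::map(unique(ti), function(cl) {
          pool <- which(ti == cl)
          pool[sample.int(length(pool), length(pool), replace = TRUE)]
        }), use.names = FALSE)
      } else {
        sample.int(n, n, replace = TRUE)
      }
      replicate_metrics(ti[idx], pi[idx], lev, macro_idx)
    })
  })
  replicates <- tibble::as_tibble(do.call(rbind, reps))

  # leave-one-out jackknife over test items for the acceleration constant
  jack <- purrr::map(seq_len(n), function(i) {
    replicate_metrics(ti[-i], pi[-i], lev, macro_idx)
  })
  jack <- do.call(rbind, jack)

  point_values <- c(macro_f1 = point$macro[["f1"]],
                    macro_precision = point$macro[["precision"]],
                    macro_recall = point$macro[["recall"]],
                    stats::setNames(
                      point$per_category$f1[match(point$macro_categories,
                                                  point$per_category$category)],
                      paste0("f1_", point$macro_categories)))
  intervals <- purrr::map(names(point_values), function(m) {
    reps_m <- replicates[[m]]
    if (!any(is.finite(reps_m))) {
      # category absent from the test set: no replicate is defined
      return(tibble::tibble(metric = m, point = point_values[[m]],
                            lo = NA_real_, hi = NA_real_,
                            method = "undefined"))
    }
    ci <- bca_interval(reps_m, jack[, m], point_values[[m]], alpha)
    tibble::tibble(metric = m, point = point_values[[m]],
                   lo = ci[1], hi = ci[2],
                   method = attr(ci, "method") %||% "bca")
  })
  structure(list(point = point, replicates = replicates,
                 intervals = dplyr::bind_rows(intervals),
                 B = B, alpha = alpha, seed = seed),
            class = "bootstrap_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.bootstrap_result <- function(x, ...) {
  cat("<bootstrap_result> B =", x$B, ", level", 1 - x$alpha, "\n")
  df <- x$intervals
  df[c("point", "lo", "hi")] <- lapply(df[c("point", "lo", "hi")],
                                       round_half_away, digits = 2)
  print(df, ...)
  invisible(x)
}

#' @rdname bootstrap_evaluate
#' @param x A `bootstrap_result`.
#' @method tidy bootstrap_result
#' @export
tidy.bootstrap_result <- function(x, ...) x$intervals

#' @rdname bootstrap_evaluate
#' @method glance bootstrap_result
#' @export
glance.bootstrap_result <- function(x, ...) {
  mf <- x$intervals[x$intervals$metric == "macro_f1", ]
  tibble::tibble(macro_f1 = mf$point, lo = mf$lo, hi = mf$hi,
                 B = x$B, n_test = x$point$n_test)
}

#' @rdname bootstrap_evaluate
#' @param object A `bootstrap_result`.
#' @method autoplot bootstrap_result
#' @export
autoplot.bootstrap_result <- function(object, ...) {
  df <- object$intervals
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$point)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lo, ymax = .data$hi)) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Bias-corrected and accelerated (BCa) bootstrap interval
#'
#' Adjusts the percentile endpoints for both bias and skewness of the
#' bootstrap distribution: the bias correction is
#' `z0 = qnorm((#\{rep < point\} + 0.5 #\{rep == point\}) / B)` and the
#' acceleration is the jackknife skewness
#' `a = sum(d^3) / (6 (sum(d^2))^{3/2})` with `d` the deviations of the
#' leave-one-out statistics from their mean. The interval is the pair of
#' empirical replicate quantiles at the adjusted levels. Degenerate
#' replicate distributions collapse to a point interval; zero jackknife
#' variance falls back to the plain percentile interval, flagged in the
#' `"method"` attribute.
#'
#' @param replicates Bootstrap replicate values of the statistic.
#' @param jackknife Leave-one-out statistics over the original items.
#' @param point The statistic on the original sample.
#' @param alpha Interval level is `1 - alpha`.
#' @return `c(lo, hi)` with attribute `method` (`"bca"` or
#'   `"percentile"`).
#' @export
bca_interval <- function(replicates, jackknife, point, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 0.5)
  B_supplied <- length(replicates)
  replicates <- replicates[is.finite(replicates)]
  B <- length(replicates)
  if (B == 0) stop("no finite bootstrap replicates", call. = FALSE)
  if (B_supplied < 100) {
    warning("fewer than 100 bootstrap replicates; BCa interval ",
            "will be unstable", call. = FALSE)
  }
  if (diff(range(replicates)) == 0) {
    out <- c(replicates[1], replicates[1])
    attr(out, "method") <- "bca"
    return(out)
  }
  prop <- (sum(replicates < point) + 0.5 * sum(replicates == point)) / B
  prop <- min(max(prop, 1 / (2 * B)), 1 - 1 / (2 * B))
  z0 <- stats::qnorm(prop)
  jackknife <- jackknife[is.finite(jackknife)]
  d <- mean(jackknife) - jackknife
  denom <- sum(d^2)
  if (denom <= 0) {
    out <- stats::quantile(replicates, c(alpha / 2, 1 - alpha / 2),
                           names = FALSE, type = 6)
    attr(out, "method") <- "percentile"
    return(out)
  }
  a <- sum(d^3) / (6 * denom^1.5)
  zlo <- stats::qnorm(alpha / 2)
  zhi <- stats::qnorm(1 - alpha / 2)
  a1 <- stats::pnorm(z0 + (z0 + zlo) / (1 - a * (z0 + zlo)))
  a2 <- stats::pnorm(z0 + (z0 + zhi) / (1 - a * (z0 + zhi)))
  out <- stats::quantile(replicates, sort(c(a1, a2)), names = FALSE, type = 6)
  attr(out, "method") <- "bca"
  out
}

#' Wilcoxon signed-rank test for paired metrics
#'
#' Paired comparison of two metric vectors (e.g. initial vs enhanced
#' model scores). Zero differences are dropped; absolute differences are
#' ranked with midranks for ties; the statistic is
#' `W = min(W+, W-)`. The p-value is exact (full enumeration of the `2^n`
#' sign assignments) for `n <= 12` without ties in the absolute
#' differences, and otherwise uses the normal approximation with tie
#' correction and continuity correction. When every difference is zero
#' there is nothing to test and the result is flagged `no_test`.
#'
#' @param x,y Equal-length paired metric vectors.
#' @return A list with `W`, `W_plus`, `W_minus`, `p`, `n` (non-zero
#'   pairs), `method`, `no_test`.
#' @export
#' @examples
#' wilcoxon_signed_rank(c(0.73, 0.75, 0.68, 0.67, 0.56),
#'                      c(0.78, 0.77, 0.76, 0.76, 0.68))
wilcoxon_signed_rank <- function(x, y) {
  if (length(x) != length(y)) {
    stop("paired vectors have different lengths (", length(x), " vs ",
         length(y), ")", call. = FALSE)
  }
  if (length(x) == 0) stop("empty paired vectors", call. = FALSE)
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(list(W = NA_real_, W_plus = NA_real_, W_minus = NA_real_,
                p = NA_real_, n = 0L, method = "none", no_test = TRUE))
  }
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  W <- min(w_plus, w_minus)
  ties <- any(duplicated(abs(d)))
  if (n <= 12 && !ties) {
    # enumerate W+ over all 2^n sign assignments
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    dist_w <- as.vector(signs %*% r)
    p <- min(1, 2 * min(mean(dist_w <= w_plus), mean(dist_w >= w_plus)))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z_num <- w_plus - mu
    z <- (z_num - sign(z_num) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal_approx"
  }
  list(W = W, W_plus = w_plus, W_minus = w_minus, p = p, n = n,
       method = method, no_test = FALSE)
}

#' Compare an initial and an enhanced metric report
#'
#' Pairs the per-category F1 scores of two reports evaluated on the same
#' test set, computes the relative improvement of each metric and of the
#' macro averages, and runs the paired Wilcoxon signed-rank test across
#' categories.
#'
#' @param initial,enhanced [prf_report()] (or [bootstrap_evaluate()])
#'   results on the same test set.
#' @return A list with `by_category` (tibble), `macro` (tibble with
#'   improvement percentages) and `wilcoxon`.
#' @export
compare_reports <- function(initial, enhanced) {
  if (inherits(initial, "bootstrap_result")) initial <- initial$point
  if (inherits(enhanced, "bootstrap_result")) enhanced <- enhanced$point
  cats <- initial$macro_categories
  f1_i <- initial$per_category$f1[match(cats, initial$per_category$category)]
  f1_e <- enhanced$per_category$f1[match(cats, enhanced$per_category$category)]
  by_category <- tibble::tibble(
    category = cats, f1_initial = f1_i, f1_enhanced = f1_e,
    improvement_pct = ifelse(f1_i > 0, improvement_pct(pmax(f1_i, 1e-12),
                                                       f1_e), NA_integer_))
  macro <- tibble::tibble(
    metric = c("precision", "recall", "f1"),
    initial = initial$macro[c("precision", "recall", "f1")],
    enhanced = enhanced$macro[c("precision", "recall", "f1")])
  macro$improvement_pct <- ifelse(macro$initial > 0,
                                  improvement_pct(pmax(macro$initial, 1e-12),
                                                  macro$enhanced),
                                  NA_integer_)
  list(by_category = by_category, macro = macro,
       wilcoxon = wilcoxon_signed_rank(f1_i, f1_e))
}

#' Write a Table-style report CSV
#'
#' One row per substantive category plus a macro-average row; columns
#' give F1/precision/recall with the BCa interval rendered as
#' `"(lo-hi)"`. A JSON twin with full precision is written alongside.
#'
#' @param result A [bootstrap_evaluate()] result.
#' @param path CSV path (the JSON twin replaces the extension).
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path) {
  stopifnot(inherits(result, "bootstrap_result"))
  iv <- result$intervals
  fmt <- function(metric_names) {
    rows <- iv[match(metric_names, iv$metric), ]
    sprintf("%.2f (%.2f-%.2f)", rows$point, rows$lo, rows$hi)
  }
  cats <- result$point$macro_categories
  df <- data.frame(
    category = c(cats, "Macro average"),
    f1 = c(fmt(paste0("f1_", cats)),
           fmt("macro_f1")),
    stringsAsFactors = FALSE)
  macro_p <- iv[iv$metric == "macro_precision", ]
  macro_r <- iv[iv$metric == "macro_recall", ]
  df$precision <- c(sprintf("%.2f",
                            result$point$per_category$precision[
                              match(cats, result$point$per_category$category)]),
                    sprintf("%.2f (%.2f-%.2f)", macro_p$point, macro_p$lo,
                            macro_p$hi))
  df$recall <- c(sprintf("%.2f",
                         result$point$per_category$recall[
                           match(cats, result$point$per_category$category)]),
                 sprintf("%.2f (%.2f-%.2f)", macro_r$point, macro_r$lo,
                         macro_r$hi))
  utils::write.csv(df, path, row.names = FALSE)
  json_path <- sub("\\.[^.]*$", ".json", path)
  jsonlite::write_json(
    list(intervals = iv, per_category = result$point$per_category,
         macro = as.list(result$point$macro), B = result$B,
         alpha = result$alpha),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
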