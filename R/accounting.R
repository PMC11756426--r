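#' Tally exemplars by language category
#'
#' Counts exemplars per category and reports percentages of the total,
#' rounded half-away-from-zero to two decimals, together with a polarity
#' roll-up (stigmatizing vs positive). By convention the negative-case
#' label `"none"` is excluded from the tally, mirroring study tables that
#' count only the six substantive categories; set `include_none = TRUE`
#' to include it.
#'
#' @param exemplars An exemplar tibble.
#' @param include_none Count negative-case exemplars too.
#' @return An object of class `stigma_tally`: a tibble with columns
#'   `category`, `n`, `pct`, plus attributes `total` and `polarity_rollup`.
#' @export
#' @examples
#' ex <- tibble::tibble(
#'   exemplar_id = as.character(1:5), note_id = "n1", text = "t",
#'   n_sentences = 1L,
#'   category = c("marginalized", "marginalized", "difficult_patient",
#'                "positive_preferred", "none"),
#'   provenance = c(rep("human_initial", 4), "negative_sample"))
#' tally_categories(ex)
tally_categories <- function(exemplars, include_none = FALSE) {
  validate_exemplars(exemplars)
  cats <- language_categories(include_none = include_none)
  kept <- exemplars[exemplars$category %in% cats, , drop = FALSE]
  counts <- table(factor(kept$category, levels = cats))
  total <- sum(counts)
  pct <- if (total == 0) rep(0, length(cats)) else {
    round_half_away(100 * as.numeric(counts) / total, 2)
  }
  out <- tibble::tibble(category = cats, n = as.integer(counts), pct = pct)
  pol <- stats::aggregate(
    out$n, by = list(polarity = category_polarity(out$category)), FUN = sum)
  rollup <- tibble::tibble(
    polarity = pol$polarity, n = as.integer(pol$x),
    pct = if (total == 0) 0 else round_half_away(100 * pol$x / total, 2))
  structure(out, total = as.integer(total), polarity_rollup = rollup,
            class = c("stigma_tally", class(out)))
}

#' Merge two annotated datasets
#'
#' Forms the union of two exemplar sets with disjoint ids (e.g. the
#' initial human-annotated set and the verified expansion set, whose union
#' is the enhanced set). Per-category counts add.
#'
#' @param initial,expanded Exemplar tibbles with disjoint `exemplar_id`s.
#' @return The combined exemplar tibble.
#' @export
merge_datasets <- function(initial, expanded) {
  validate_exemplars(initial)
  validate_exemplars(expanded)
  clash <- intersect(initial$exemplar_id, expanded$exemplar_id)
  if (length(clash) > 0) {
    stop("exemplar_id collision(s): ",
         paste(utils::head(clash, 10), collapse = ", "), call. = FALSE)
  }
  dplyr::bind_rows(initial, expanded)
}

#' Inter-annotator agreement
#'
#' Percent agreement and unweighted Cohen's kappa for two aligned label
#' sequences over the category set. Expected agreement uses the product of
#' the raters' marginal label distributions. When expected agreement is 1
#' (both raters constant on the same single label) kappa is undefined and
#' returned as `NA` with a warning rather than silently coerced to a
#' number.
#'
#' @param labels_a,labels_b Equal-length character vectors of category
#'   codes.
#' @return A list with `percent_agreement` (0--100), `kappa`, and `n`.
#' @export
#' @examples
#' agreement(c("none", "marginalized"), c("none", "difficult_patient"))
agreement <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("label sequences have different lengths (", length(labels_a),
         " vs ", length(labels_b), ")", call. = FALSE)
  }
  n <- length(labels_a)
  if (n == 0) stop("label sequences are empty", call. = FALSE)
  check_categories(labels_a)
  check_categories(labels_b)
  lev <- language_categories()
  fa <- factor(labels_a, levels = lev)
  fb <- factor(labels_b, levels = lev)
  p_o <- mean(fa == fb)
  p_e <- sum((table(fa) / n) * (table(fb) / n))
  kappa <- if (isTRUE(all.equal(p_e, 1))) {
    warning("expected agreement is 1; kappa is undefined", call. = FALSE)
    NA_real_
  } else {
    (p_o - p_e) / (1 - p_e)
  }
  list(percent_agreement = 100 * p_o, kappa = kappa, n = n)
}

#' Relative improvement between two metric values
#'
#' `100 * (enhanced - initial) / initial`, rounded half-away-from-zero to
#' the nearest integer — the convention used when reporting F1 gains such
#' as 0.68 to 0.75 being a 10% improvement.
#'
#' @param initial,enhanced Positive baseline metric and its improved value.
#' @return Integer percent improvement (negative when performance drops).
#' @export
#' @examples
#' improvement_pct(0.56, 0.68)  # 21
improvement_pct <- function(initial, enhanced) {
  if (any(initial <= 0)) {
    stop("improvement is undefined for a non-positive baseline", call. = FALSE)
  }
  as.integer(round_half_away(100 * (enhanced - initial) / initial))
}

#' Macro average of per-category metric values
#'
#' Unweighted mean, with optional display rounding to two decimals.
#'
#' @param values Numeric vector of per-category metric values.
#' @param digits Display rounding digits (`NULL` for none).
#' @return The macro average.
#' @export
macro_average <- function(values, digits = 2) {
  m <- mean(values, na.rm = TRUE)
  if (is.null(digits)) m else round_half_away(m, digits)
}

#' @export
print.stigma_tally <- function(x, ...) {
  cat("Category tally:", attr(x, "total"), "exemplars\n")
  print(tibble::as_tibble(x), ...)
  cat("\nPolarity roll-up:\n")
  print(attr(x, "polarity_rollup"), ...)
  invisible(x)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot a category tally
#'
#' @param object A [tally_categories()] result.
#' @param ... Ignored.
#' @return A ggplot bar chart of exemplar counts per category.
#' @method autoplot stigma_tally
#' @export
autoplot.stigma_tally <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$polarity <- category_polarity(df$category)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$category, .data$n), y = .data$n,
    fill = .data$polarity)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "exemplars", fill = NULL) +
    ggplot2::theme_minimal()
}
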