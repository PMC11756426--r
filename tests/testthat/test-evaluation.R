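test_that("perfect predictions give unit metrics", {
  y <- c(substantive_categories(), "none")
  rep <- prf_report(y, y)
  expect_true(all(rep$per_category$f1[rep$per_category$category != "none"] == 1))
  expect_equal(unname(rep$macro), c(1, 1, 1))
})

test_that("a 3-class toy confusion matches hand-computed counts", {
  # truth: 4 marginalized, 3 none, 3 positive; predictions crafted so
  # marginalized has TP=2 FP=1 FN=2, positive TP=2 FP=2 FN=1
  y_true <- c(rep("marginalized", 4), rep("none", 3),
              rep("positive_preferred", 3))
  y_pred <- c("marginalized", "marginalized", "none", "positive_preferred",
              "none", "none", "positive_preferred",
              "positive_preferred", "positive_preferred", "marginalized")
  rep <- prf_report(y_true, y_pred)
  pc <- rep$per_category
  m <- pc[pc$category == "marginalized", ]
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$recall, 2 / 4)
  expect_equal(m$f1, 2 * (2 / 3) * (1 / 2) / ((2 / 3) + (1 / 2)))
  p <- pc[pc$category == "positive_preferred", ]
  expect_equal(p$precision, 2 / 4)
  expect_equal(p$recall, 2 / 3)
})

test_that("prf agrees with a brute-force oracle on random labels", {
  set.seed(606)
  cats <- language_categories()
  for (i in 1:200) {
    n <- sample(5:40, 1)
    y_true <- sample(cats, n, replace = TRUE)
    y_pred <- sample(cats, n, replace = TRUE)
    rep <- prf_report(y_true, y_pred)
    oracle <- brute_prf(y_true, y_pred, substantive_categories())
    got <- rep$per_category[match(substantive_categories(),
                                  rep$per_category$category), ]
    expect_equal(got$precision, unname(oracle[, "precision"]))
    expect_equal(got$recall, unname(oracle[, "recall"]))
    expect_equal(got$f1, unname(oracle[, "f1"]))
    expect_equal(rep$macro[["f1"]], mean(oracle[, "f1"]))
  }
})

test_that("macro differs from micro on imbalanced data and ignores order", {
  y_true <- c(rep("marginalized", 50), rep("questioning_credibility", 2))
  y_pred <- c(rep("marginalized", 50), rep("marginalized", 2))
  rep <- prf_report(y_true, y_pred)
  micro <- mean(y_true == y_pred)
  expect_false(isTRUE(all.equal(rep$macro[["f1"]], micro)))
  rep_rev <- prf_report(rev(y_true), rev(y_pred))
  expect_equal(rep$macro, rep_rev$macro)
})

test_that("prf rejects mismatched lengths", {
  expect_error(prf_report(c("none", "none"), "none"), "lengths")
})

test_that("bootstrap replicates are reproducible and centred on the point", {
  set.seed(77)
  n <- 300
  y_true <- sample(c(substantive_categories(), "none"), n, replace = TRUE)
  y_pred <- ifelse(runif(n) < 0.7, y_true,
                   sample(c(substantive_categories(), "none"), n, TRUE))
  br <- bootstrap_evaluate(y_true, y_pred, B = 1000, seed = 9)
  expect_equal(nrow(br$replicates), 1000)
  # replicate mean within 3 Monte-Carlo standard errors of the point
  reps <- br$replicates$macro_f1
  mc_se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - br$point$macro[["f1"]]), 3 * mc_se + 0.01)
  # determinism
  br2 <- bootstrap_evaluate(y_true, y_pred, B = 1000, seed = 9)
  expect_equal(br$replicates, br2$replicates)
  expect_equal(br$intervals, br2$intervals)
  # intervals are ordered
  expect_true(all(br$intervals$lo <= br$intervals$hi))
})

test_that("BCa collapses on degenerate replicates and reduces to percentile", {
  ci <- bca_interval(rep(0.8, 500), jackknife = c(0.79, 0.8, 0.81),
                     point = 0.8)
  expect_equal(unclass(ci)[1:2], c(0.8, 0.8))

  # symmetric replicates centred on the point with symmetric jackknife:
  # z0 ~ 0 and a = 0, so BCa equals the percentile interval
  set.seed(12)
  reps <- c(rnorm(2000, 0.5, 0.05), 1 - rnorm(2000, 0.5, 0.05))
  jack <- c(seq(0.45, 0.55, length.out = 21))  # symmetric: a = 0 exactly
  ci_bca <- bca_interval(reps, jack, point = stats::median(reps))
  ci_pct <- stats::quantile(reps, c(0.025, 0.975), names = FALSE, type = 6)
  expect_lt(abs(ci_bca[1] - ci_pct[1]), 0.01)
  expect_lt(abs(ci_bca[2] - ci_pct[2]), 0.01)

  # zero jackknife variance falls back to percentile, flagged
  ci_fb <- bca_interval(reps, jackknife = rep(0.5, 10), point = 0.5)
  expect_equal(attr(ci_fb, "method"), "percentile")
})

test_that("the Wilcoxon statistic matches exhaustive enumeration at n = 6", {
  x <- c(0.73, 0.75, 0.68, 0.67, 0.56, 0.63)
  y <- c(0.78, 0.77, 0.76, 0.76, 0.68, 0.60)
  res <- wilcoxon_signed_rank(x, y)
  expect_equal(res$method, "exact")
  d <- x - y
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  # independent enumeration over all 2^6 sign assignments
  signs <- expand.grid(rep(list(0:1), 6))
  dist_w <- as.matrix(signs) %*% r
  p_oracle <- min(1, 2 * min(mean(dist_w <= w_plus), mean(dist_w >= w_plus)))
  expect_equal(res$p, p_oracle)
  expect_equal(res$W, min(w_plus, sum(r) - w_plus))
  # cross-check against the reference implementation
  ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)
  expect_equal(res$p, ref$p.value)
  expect_equal(res$W_plus, unname(ref$statistic))
})

test_that("Wilcoxon handles zero differences, ties, and bad input", {
  x <- c(1, 2, 3)
  expect_true(wilcoxon_signed_rank(x, x)$no_test)
  expect_error(wilcoxon_signed_rank(1:3, 1:2), "lengths")
  # ties route through the normal approximation
  res <- wilcoxon_signed_rank(c(5, 5, 5, 5, 1, 1, 2, 8, 9, 4, 4, 6, 7),
                              c(4, 4, 4, 4, 2, 2, 1, 1, 2, 1, 1, 1, 1))
  expect_equal(res$method, "normal_approx")
  ref <- suppressWarnings(
    stats::wilcox.test(c(5, 5, 5, 5, 1, 1, 2, 8, 9, 4, 4, 6, 7),
                       c(4, 4, 4, 4, 2, 2, 1, 1, 2, 1, 1, 1, 1),
                       paired = TRUE, exact = FALSE, correct = TRUE))
  expect_equal(res$p, ref$p.value, tolerance = 1e-12)
})

test_that("report comparison computes paired improvements", {
  y_true <- rep(c(substantive_categories(), "none"), times = 12)
  set.seed(15)
  noisy <- function(rate) {
    ifelse(runif(length(y_true)) < rate, y_true,
           sample(language_categories(), length(y_true), TRUE))
  }
  rep_a <- prf_report(y_true, noisy(0.6))
  rep_b <- prf_report(y_true, noisy(0.95))
  cmp <- compare_reports(rep_a, rep_b)
  expect_equal(nrow(cmp$by_category), 6)
  f1_row <- cmp$macro[cmp$macro$metric == "f1", ]
  expect_gt(f1_row$enhanced, f1_row$initial)
  expect_true(is.numeric(cmp$wilcoxon$p) || cmp$wilcoxon$no_test)
})

test_that("report files mirror the table layout", {
  y <- rep(c(substantive_categories(), "none"), times = 10)
  set.seed(8)
  pred <- ifelse(runif(length(y)) < 0.8, y,
                 sample(language_categories(), length(y), TRUE))
  br <- bootstrap_evaluate(y, pred, B = 200, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_report(br, path)
  df <- utils::read.csv(path)
  expect_equal(nrow(df), 7)  # six categories plus the macro row
  expect_equal(df$category[7], "Macro average")
  expect_match(df$f1[7], "\\d\\.\\d+ \\(\\d\\.\\d+-\\d\\.\\d+\\)")
  expect_true(file.exists(sub("\\.csv$", ".json", path)))
})
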