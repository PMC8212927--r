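test_that("descriptives match hand-computed moment formulas", {
  d <- descriptives(c(-1, 0, 1))
  expect_equal(d$skew, 0)
  expect_equal(d$range, 2)

  x <- c(0, 0, 0, 10)
  d2 <- descriptives(x)
  o <- moments_oracle(x)
  expect_equal(d2$mean, 2.5)
  expect_equal(d2$sd, 5)
  expect_equal(d2$skew, o$skew)
  expect_equal(d2$kurtosis, o$kurt)

  expect_equal(descriptives(c(2, 5, 9))$range, 7)
  expect_error(descriptives(c(3, 3, 3)), "constant")
  expect_error(descriptives(c(1, 2)), "n >= 3")
})

test_that("scale totals validate bounds and sum rows", {
  def <- phq9_definition()
  all_max <- matrix(3L, 4, 9)
  expect_equal(scale_total(all_max, def), rep(27, 4))
  expect_equal(scale_total(matrix(0L, 2, 9), def), rep(0, 2))
  expect_equal(scale_total(matrix(1L, 1, 9), def), 9)

  bad <- matrix(0L, 3, 9); bad[2, 5] <- 4L
  expect_error(scale_total(bad, def), "row 2, item 5")

  holey <- matrix(1L, 5, 9); holey[3, 2] <- NA
  expect_error(scale_total(holey, def), "missing")
  expect_warning(tot <- scale_total(holey, def, missing = "drop"), "dropped")
  expect_length(tot, 4)
})

test_that("built-in scale definitions carry the diagnostic item mapping", {
  phq <- phq9_definition()
  expect_equal(which(phq$primary_flags), c(1L, 2L))
  expect_equal(phq$cutoff, 10L)
  gad <- gad7_definition()
  expect_equal(which(gad$primary_flags), c(2L, 3L))
  pswq <- pswq8_definition()
  expect_true(all(pswq$primary_flags))
  expect_equal(c(pswq$item_min, pswq$item_max), c(0L, 5L))
  alt <- pswq8_definition(item_min = 1L, item_max = 5L)
  expect_equal(range(scale_total(matrix(1L, 1, 8), alt)), c(8, 8))
})

test_that("the cut-off proportion is boundary-inclusive", {
  expect_equal(cutoff_proportion(c(9, 10, 11), 10), 2 / 3)
  expect_equal(cutoff_proportion(c(1, 2, 3), 10), 0)
  set.seed(71)
  totals <- rbinom(500, 27, 0.3)
  expect_equal(cutoff_proportion(totals, 10),
               sum(totals >= 10) / 500)
  expect_error(cutoff_proportion(numeric(0), 10), "empty")
})

test_that("alpha matches the parallel-items closed form", {
  set.seed(72)
  n <- 5000; k <- 9; rho <- 0.5
  f <- rnorm(n)
  items <- sqrt(rho) * f + sqrt(1 - rho) * matrix(rnorm(n * k), n)
  rel <- reliability(items)
  expect_equal(rel$alpha, k * rho / (1 + (k - 1) * rho), tolerance = 0.02)

  indep <- matrix(rnorm(2000 * 6), 2000)
  expect_lt(abs(reliability(indep)$alpha), 0.1)
})

test_that("omega recovers the analytic one-factor value", {
  set.seed(73)
  lambda <- seq(0.5, 0.9, length.out = 9)
  theta <- 1 - lambda^2
  omega_true <- sum(lambda)^2 / (sum(lambda)^2 + sum(theta))
  n <- 5000
  f <- rnorm(n)
  items <- outer(f, lambda) +
    matrix(rnorm(n * 9), n) %*% diag(sqrt(theta))
  rel <- reliability(items)
  expect_equal(rel$omega, omega_true, tolerance = 0.03)
  expect_error(reliability(items[1:10, ]), "n >= 20")
})

test_that("correlations match direct-formula and rank oracles", {
  set.seed(74)
  x <- rnorm(20)
  lin <- correlate(x, 2 * x + 1, method = "pearson")
  expect_equal(lin$estimate, 1)
  expect_equal(correlate(x, 2 * x + 1, method = "spearman")$estimate, 1)

  xs <- seq(-2, 2, length.out = 21)
  cub <- correlate(xs, xs^3, method = "pearson")
  expect_lt(cub$estimate, 1)
  expect_equal(correlate(xs, xs^3, method = "spearman")$estimate, 1)

  for (i in 1:200) {
    a <- rnorm(12); b <- rnorm(12)
    pr <- correlate(a, b, method = "pearson")
    expect_equal(pr$estimate, cosine_oracle(a - mean(a), b - mean(b)),
                 tolerance = 1e-12)
    sp <- correlate(a, b, method = "spearman")
    expect_equal(sp$estimate,
                 cosine_oracle(rank(a) - mean(rank(a)),
                               rank(b) - mean(rank(b))),
                 tolerance = 1e-12)
  }
  expect_error(correlate(rep(1, 10), rnorm(10)), "zero variance")
})

test_that("significance stars are consistent with two-tailed p thresholds", {
  set.seed(75)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    cr <- correlate(rnorm(n), rnorm(n))
    expected <- if (cr$p_value < 0.001) "***" else if (cr$p_value < 0.01)
      "**" else if (cr$p_value < 0.05) "*" else ""
    expect_identical(cr$stars, expected)
    expect_gte(cr$p_value, 0)
    expect_lte(cr$p_value, 1)
  }
})

test_that("the automatic method rule selects Spearman for skewed scales", {
  set.seed(76)
  skewed <- rexp(300)
  expect_equal(correlate(rnorm(300), skewed, method = "auto")$method,
               "spearman")
  normal <- rnorm(300)
  expect_equal(correlate(rnorm(300), normal, method = "auto")$method,
               "pearson")
})

test_that("partial correlation equals the residual-regression oracle", {
  set.seed(77)
  for (i in 1:100) {
    n <- sample(10:60, 1)
    z <- rnorm(n)
    x <- 0.5 * z + rnorm(n)
    y <- -0.3 * z + rnorm(n)
    pc <- partial_correlation(x, y, z)
    expect_equal(pc$estimate, partial_oracle(x, y, z), tolerance = 1e-10)
  }
  # an irrelevant control leaves the correlation essentially unchanged
  n <- 4000
  x <- rnorm(n); y <- 0.5 * x + rnorm(n); z <- rnorm(n)
  expect_equal(partial_correlation(x, y, z)$estimate,
               correlate(x, y, method = "pearson")$estimate,
               tolerance = 0.05)
  expect_error(partial_correlation(x, y, x), "degenerate-control")
  expect_error(partial_correlation(x, y, rep(1, n)), "degenerate-control")
})

test_that("item-total correlations favour the included item", {
  set.seed(78)
  n <- 400
  f <- rnorm(n)
  items <- outer(f, rep(0.6, 6)) + matrix(rnorm(n * 6, sd = 0.8), n)
  tot <- rowSums(items)
  for (j in 1:6) {
    with_item <- cor(items[, j], tot)
    without <- cor(items[, j], tot - items[, j])
    expect_gte(with_item, without)
  }
})

test_that("the item-level table has the right shape and degenerate checks", {
  cs <- default_cohort_scored()
  def <- cs$cohort$config$scale
  preds <- list(unipolar = cs$sss$unipolar_high,
                bipolar = cs$sss$bipolar,
                language_trained = cs$totals + rnorm(length(cs$totals)),
                valence = -cs$sss$bipolar + rnorm(length(cs$totals), sd = 0.1))
  tab <- item_level_table(cs$cohort$items, def, preds,
                          valence_scores = preds$valence)
  expect_s3_class(tab, "item_level_table")
  expect_equal(nrow(tab), def$n_items + 1L)
  expect_true(all(c("language_trained_partial", "bipolar", "item_total")
                  %in% names(tab)))
  item_means <- tab$mean[tab$item != "total"]
  expect_true(all(item_means >= def$item_min & item_means <= def$item_max))

  # a predictor equal to the total correlates perfectly in the total row
  tab2 <- item_level_table(cs$cohort$items, def,
                           list(self = as.numeric(cs$totals)),
                           method = "pearson")
  expect_equal(tab2$self[tab2$item == "total"], 1)

  expect_error(item_level_table(cs$cohort$items, def,
                                list(short = rnorm(10))),
               "join error")
})

test_that("primary-criterion items correlate more with the bipolar scale", {
  cs <- default_cohort_scored()
  def <- cs$cohort$config$scale
  tab <- item_level_table(cs$cohort$items, def,
                          list(bipolar = cs$sss$bipolar))
  item_rows <- tab[tab$item != "total", ]
  expect_gt(mean(item_rows$bipolar[item_rows$primary]),
            mean(item_rows$bipolar[!item_rows$primary]))
})

test_that("correlation strength labels follow the conventional thresholds", {
  expect_equal(correlation_label(c(0.05, -0.2, 0.35, -0.8)),
               c("negligible", "weak", "moderate", "strong"))
})
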