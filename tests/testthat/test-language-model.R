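test_that("the default penalty grid spans 1e-16 to 1e16 by powers of ten", {
  g <- penalty_grid()
  expect_length(g, 33L)
  expect_equal(min(g), 1e-16)
  expect_equal(max(g), 1e16)
  expect_equal(unique(round(diff(log10(g)), 10)), 1)
})

test_that("fixed-penalty ridge matches the closed form on preprocessed data", {
  set.seed(51)
  X <- matrix(rnorm(50 * 5), 50)
  y <- X %*% runif(5) + rnorm(50)
  for (lam in c(1e-4, 1, 1e4)) {
    fit <- ridge_fit(X, y, lambda = lam)
    expect_equal(unname(fit$coefficients),
                 unname(ridge_oracle(X, y, lam)), tolerance = 1e-8)
    # unscaled convention as well
    fit_c <- ridge_fit(X, y, lambda = lam, standardize = FALSE)
    expect_equal(unname(fit_c$coefficients),
                 unname(ridge_oracle(X, y, lam, standardize = FALSE)),
                 tolerance = 1e-8)
  }
})

test_that("an independent coordinate-descent solver agrees at a fixed penalty", {
  set.seed(52)
  n <- 200; d <- 6
  X <- matrix(rnorm(n * d), n)
  y <- as.numeric(X %*% rnorm(d) + rnorm(n))
  lam <- 2
  fit <- ridge_fit(X, y, lambda = lam, standardize = FALSE)
  # glmnet minimizes 1/(2n) RSS + lambda/2 ||b||^2 => lambda_glmnet = lam/n
  # glmnet standardizes y internally, so its penalty is in units of sd(y)
  sdn <- sqrt(mean((y - mean(y))^2))
  g <- glmnet::glmnet(X, y, alpha = 0, lambda = lam / n * sdn,
                      standardize = FALSE, intercept = TRUE,
                      thresh = 1e-16, maxit = 1e6)
  expect_equal(unname(fit$coefficients),
               unname(as.numeric(g$beta)), tolerance = 1e-3)
})

test_that("noiseless linear signal is recovered with near-perfect accuracy", {
  set.seed(53)
  X <- matrix(rnorm(200 * 5), 200)
  y <- as.numeric(X %*% c(2, -1, 0.5, 3, -2))
  m <- train_language_model(X, y, seed = 1)
  expect_gt(m$cv_accuracy, 0.99)
  expect_true(m$lambda %in% m$grid)
})

test_that("degenerate inputs raise configuration errors", {
  X <- matrix(rnorm(40), 8)
  expect_error(train_language_model(X, rep(1, 8), seed = 1), "degenerate-target")
  expect_error(train_language_model(X, rnorm(8), folds = 10, seed = 1),
               "configuration error")
  expect_error(train_language_model(X, rnorm(8), grid = numeric(0), seed = 1),
               "configuration error")
  expect_error(train_language_model(X, rnorm(8)), "seed")
})

test_that("prediction is affine, batch-consistent, and shape-checked", {
  set.seed(54)
  X <- matrix(rnorm(60 * 4), 60)
  y <- as.numeric(X %*% rnorm(4) + rnorm(60))
  m <- ridge_fit(X, y, lambda = 1)
  # a row at the training center predicts the intercept (the mean of y)
  expect_equal(predict(m, m$centers), m$intercept)
  expect_equal(m$intercept, mean(y))
  # single-row and batched predictions agree
  batch <- predict(m, X[1:5, ])
  single <- vapply(1:5, function(i) predict(m, X[i, ]), numeric(1))
  expect_equal(batch, single)
  expect_error(predict(m, matrix(0, 2, 7)), "shape error")
})

test_that("near-zero penalty reproduces least squares on training rows", {
  set.seed(55)
  X <- matrix(rnorm(30 * 3), 30)
  y <- as.numeric(X %*% c(1, 2, 3) + rnorm(30, sd = 0.1))
  m <- ridge_fit(X, y, lambda = 1e-10)
  ls_fit <- stats::lm(y ~ X)
  expect_equal(predict(m, X), unname(stats::fitted(ls_fit)), tolerance = 1e-6)
})

test_that("stronger penalties never grow the coefficient norm", {
  set.seed(56)
  X <- matrix(rnorm(80 * 6), 80)
  y <- as.numeric(X %*% rnorm(6) + rnorm(80))
  norms <- vapply(10^seq(-4, 4, by = 1), function(l) {
    sqrt(sum(ridge_fit(X, y, lambda = l)$coefficients^2))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-12))
})

test_that("cv accuracy is reproducible given the seed and explicit folds", {
  set.seed(57)
  X <- matrix(rnorm(120 * 5), 120)
  y <- as.numeric(X %*% rnorm(5) + rnorm(120))
  m1 <- train_language_model(X, y, seed = 99)
  m2 <- train_language_model(X, y, seed = 99)
  expect_identical(m1$cv_accuracy, m2$cv_accuracy)
  expect_identical(m1$cv_predictions, m2$cv_predictions)

  # row permutation with the matching explicit fold assignment; the whole
  # training fold tunes the penalty so no further randomness remains
  fold_id <- rep(1:10, length.out = 120)
  perm <- sample(120)
  ma <- train_language_model(X, y, seed = 1, fold_id = fold_id,
                             inner_prop = 1)
  mb <- train_language_model(X[perm, ], y[perm], seed = 1,
                             fold_id = fold_id[perm], inner_prop = 1)
  expect_equal(ma$cv_accuracy, mb$cv_accuracy, tolerance = 1e-10)
})

test_that("estimated weights converge to the truth as n grows", {
  w <- c(1, -2, 1.5, 0.5, -1)
  angle <- function(a, b) acos(sum(a * b) / sqrt(sum(a^2) * sum(b^2)))
  set.seed(58)
  angles <- vapply(c(100, 400, 1600), function(n) {
    X <- matrix(rnorm(n * 5), n)
    y <- as.numeric(X %*% w + rnorm(n, sd = 2))
    m <- train_language_model(X, y, seed = 3)
    angle(m$coefficients / m$scales, w)
  }, numeric(1))
  expect_true(all(diff(angles) < 0))
})

test_that("valence model training enforces lexicon preconditions", {
  space <- random_space(300, 8, seed = 61)
  tiny <- valence_lexicon(c("w0001", "w0002"), c(2, 8))
  expect_error(train_valence_model(space, tiny, seed = 1),
               "configuration error")
  flat <- valence_lexicon(space$vocabulary[1:100], rep(5, 100))
  expect_error(train_valence_model(space, flat, seed = 1),
               "degenerate-target")
})

test_that("a planted linear valence lexicon is recovered at the expected accuracy", {
  # valence linear in one embedding direction with population R^2 = 0.6
  set.seed(62)
  space <- random_space(800, 16, seed = 62)
  axis <- rnorm(16); axis <- axis / sqrt(sum(axis^2))
  signal <- as.numeric(space$vectors %*% axis)
  noise_sd <- sd(signal) * sqrt(0.4 / 0.6)
  v <- 5 + signal + rnorm(800, sd = noise_sd)
  v <- pmin(9, pmax(1, v))
  lex <- valence_lexicon(space$vocabulary, v)
  m <- train_valence_model(space, lex, seed = 8)
  expect_gt(m$cv_accuracy, 0.70)
  expect_lt(m$cv_accuracy, 0.84)
})

test_that("predicted valence is deterministic and tracks planted ratings", {
  set.seed(63)
  space <- random_space(200, 8, seed = 63)
  axis <- rnorm(8); axis <- axis / sqrt(sum(axis^2))
  v <- pmin(9, pmax(1, 5 + 1.2 * as.numeric(space$vectors %*% axis)))
  lex <- valence_lexicon(space$vocabulary, v)
  m <- train_valence_model(space, lex, seed = 8)

  extreme <- space$vocabulary[which.max(v)]
  resp <- list(word_response("a", "q", rep(extreme, 3)),
               word_response("b", "q", rep(extreme, 3)))
  out <- predicted_valence(m, space, resp)
  expect_equal(out$predicted_valence[1], out$predicted_valence[2])
  expect_lt(abs(out$predicted_valence[1] - max(v)), 0.5)
})

test_that("models survive JSON serialization with identical predictions", {
  set.seed(64)
  X <- matrix(rnorm(100 * 5), 100)
  y <- as.numeric(X %*% rnorm(5) + rnorm(100))
  m <- train_language_model(X, y, seed = 12)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  back <- read_model(path)
  expect_equal(predict(back, X[1:7, ]), predict(m, X[1:7, ]))
  expect_equal(back$lambda, m$lambda)
  expect_equal(back$cv_accuracy, m$cv_accuracy)
})

test_that("model methods print, summarise and expose coefficients", {
  set.seed(65)
  X <- matrix(rnorm(80 * 3), 80)
  y <- as.numeric(X %*% rnorm(3) + rnorm(80))
  m <- train_language_model(X, y, seed = 2)
  expect_output(print(m), "Ridge language model")
  expect_output(print(summary(m)), "selected penalties")
  cf <- coef(m)
  expect_named(cf, c("(Intercept)", "dim1", "dim2", "dim3"))
  expect_length(residuals(m), 80)
})
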