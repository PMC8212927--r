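# Independent brute-force oracles used to check the package's
# implementations, deliberately written along different code paths.

# Elementwise cosine formula.
cosine_oracle <- function(a, b) {
  num <- 0; na <- 0; nb <- 0
  for (i in seq_along(a)) {
    num <- num + a[i] * b[i]
    na <- na + a[i]^2
    nb <- nb + b[i]^2
  }
  num / (sqrt(na) * sqrt(nb))
}

# Closed-form ridge coefficients on the centered/scaled design.
ridge_oracle <- function(X, y, lambda, standardize = TRUE) {
  Xs <- scale(X, center = TRUE, scale = standardize)
  yc <- y - mean(y)
  solve(t(Xs) %*% Xs + lambda * diag(ncol(X)), t(Xs) %*% yc)[, 1]
}

# Dense co-occurrence count (triple loop) + full SVD, truncated.
cooc_svd_oracle <- function(tokens, window, d) {
  vocab <- names(sort(table(factor(tokens, levels = unique(tokens))),
                      decreasing = TRUE))
  n <- length(tokens)
  C <- matrix(0, length(vocab), length(vocab),
              dimnames = list(vocab, vocab))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && abs(i - j) <= window) {
        C[tokens[i], tokens[j]] <- C[tokens[i], tokens[j]] + 1
      }
    }
  }
  # symmetric counting as in the implementation: each unordered pair twice
  sv <- svd(C)
  V <- sv$u[, seq_len(d), drop = FALSE] %*% diag(sv$d[seq_len(d)], nrow = d)
  rownames(V) <- vocab
  V
}

# Benjamini-Hochberg step-up: sort, scale, cumulative minimum from the top.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) {
    if (m == 1) break
    q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  }
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Partial correlation as the correlation of regression residuals.
partial_oracle <- function(x, y, z) {
  rx <- stats::residuals(stats::lm(x ~ z))
  ry <- stats::residuals(stats::lm(y ~ z))
  stats::cor(rx, ry)
}

# Type-2 (small-sample adjusted) moment estimators, written from the
# formulas directly.
moments_oracle <- function(x) {
  n <- length(x)
  m <- mean(x)
  m2 <- sum((x - m)^2) / n
  m3 <- sum((x - m)^3) / n
  m4 <- sum((x - m)^4) / n
  g1 <- m3 / m2^1.5
  g2 <- m4 / m2^2 - 3
  list(skew = g1 * sqrt(n * (n - 1)) / (n - 2),
       kurt = ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3)))
}

# Tiny hand-checkable semantic space: 4 words in 4 dimensions.
toy_space_4d <- function() {
  v <- rbind(sun = c(1, 0, 0, 0),
             moon = c(0, 1, 0, 0),
             rain = c(0, 0, 1, 0),
             wind = c(0, 0, 0, 1))
  semantic_space(v, provenance = "hand-built 4d toy")
}

# A random dense space for property tests.
random_space <- function(n_words, d, seed) {
  set.seed(seed)
  v <- matrix(rnorm(n_words * d), n_words, d)
  rownames(v) <- sprintf("w%04d", seq_len(n_words))
  semantic_space(v, provenance = "random test space")
}

# Attention-control fixture: n participants, a chosen subset answering one
# control item incorrectly.
make_controls <- function(n, failing_ids = character(0)) {
  do.call(rbind, lapply(seq_len(n), function(i) {
    id <- sprintf("p%02d", i)
    ans <- c("several_days", "not_at_all")
    if (id %in% failing_ids) ans[1] <- "nearly_every_day"
    data.frame(participant_id = id, control_item = 1:2, answer = ans,
               expected = c("several_days", "not_at_all"),
               stringsAsFactors = FALSE)
  }))
}

# The default synthetic cohort (with derived scores), computed once per
# test run and shared across files.
.cohort_cache <- new.env(parent = emptyenv())
default_cohort_scored <- function(seed = 20260920) {
  key <- as.character(seed)
  if (is.null(.cohort_cache[[key]])) {
    cohort <- simulate_cohort(generator_config(seed = seed))
    sss <- semantic_scale_scores(cohort$space, cohort$responses,
                                 cohort$norms$high, cohort$norms$low)
    totals <- scale_total(cohort$items, cohort$config$scale)
    .cohort_cache[[key]] <- list(cohort = cohort, sss = sss, totals = totals)
  }
  .cohort_cache[[key]]
}
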