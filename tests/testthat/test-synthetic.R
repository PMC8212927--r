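test_that("the generator is fully deterministic under (config, seed)", {
  cfg <- generator_config(seed = 101, n_participants = 40L)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$space$vectors, b$space$vectors)
  expect_identical(a$items, b$items)
  expect_identical(lapply(a$responses, `[[`, "tokens"),
                   lapply(b$responses, `[[`, "tokens"))
  expect_identical(a$lexicon$valence_mean, b$lexicon$valence_mean)
  c2 <- simulate_cohort(generator_config(seed = 102, n_participants = 40L))
  expect_false(identical(a$items, c2$items))
})

test_that("config validation rejects impossible designs", {
  expect_error(generator_config(), "seed")
  expect_error(generator_config(seed = 1, separation = 0), "separation")
  expect_error(generator_config(seed = 1, d = 1L), "d must be")
  expect_error(generator_config(seed = 1, control_failure_rate = 2), "rate")
})

test_that("planted clusters are linearly separable at the default separation", {
  cfg <- generator_config(seed = 103, d = 16L,
                          cluster_sizes = c(high = 50L, low = 50L,
                                            neutral = 5L, filler = 5L))
  si <- make_toy_space(cfg)
  words <- split(names(si$cluster), si$cluster)
  X <- si$space$vectors[c(words$high, words$low), ]
  y <- rep(c(1, -1), c(50, 50))
  # nearest-centroid (a linear rule) classifies every word correctly
  ch <- colMeans(si$space$vectors[words$high, ])
  cl <- colMeans(si$space$vectors[words$low, ])
  pred <- ifelse(rowSums(sweep(X, 2, ch)^2) < rowSums(sweep(X, 2, cl)^2),
                 1, -1)
  expect_equal(sum(pred != y), 0)
})

test_that("high and low centroids sit at opposite ends of the severity axis", {
  cfg <- generator_config(seed = 104)
  si <- make_toy_space(cfg)
  words <- split(names(si$cluster), si$cluster)
  proj <- as.numeric(si$space$vectors %*% si$axis)
  names(proj) <- si$space$vocabulary
  expect_gt(mean(proj[words$high]), 1)
  expect_lt(mean(proj[words$low]), -1)
  expect_lt(abs(mean(proj[words$neutral])), 1)
})

test_that("item totals track latent severity within the design band", {
  cs <- default_cohort_scored()
  r <- cor(cs$cohort$truth$theta, cs$totals)
  expect_gt(r, 0.6)
  expect_lt(r, 0.9)
  # theta marginals match the standard normal model
  expect_lt(abs(mean(cs$cohort$truth$theta)), 0.15)
  expect_lt(abs(sd(cs$cohort$truth$theta) - 1), 0.15)
  # items stay within scale bounds
  def <- cs$cohort$config$scale
  expect_true(all(cs$cohort$items >= def$item_min &
                    cs$cohort$items <= def$item_max))
})

test_that("the noiseless low-temperature limit is monotone in severity", {
  cfg <- generator_config(seed = 105, n_participants = 120L,
                          item_noise_sd = 1e-9, temperature = 0.01)
  co <- simulate_cohort(cfg)
  tot <- scale_total(co$items, cfg$scale)
  expect_true(all(diff(tot[order(co$truth$theta)]) >= 0))
})

test_that("control-item failures occur at the configured binomial rate", {
  cfg <- generator_config(seed = 106, n_participants = 1000L,
                          control_failure_rate = 0.1)
  co <- simulate_cohort(cfg)
  n_fail <- sum(!co$truth$control_pass)
  band <- qbinom(c(0.005, 0.995), 1000, 0.1)
  expect_gte(n_fail, band[1])
  expect_lte(n_fail, band[2])
  # failing participants have at least one mismatching control answer
  wrong <- with(co$control_answers, tapply(answer != expected,
                                           participant_id, any))
  expect_identical(as.vector(wrong[co$truth$participant_id]),
                   !co$truth$control_pass)
})

test_that("simulated norms respect the target rule and cluster geometry", {
  cfg <- generator_config(seed = 107)
  si <- make_toy_space(cfg)
  norms <- simulate_norms(cfg, si)
  # target word tops the high norm by exactly 1
  freq <- norms$high$tokens
  target <- norms$high$target_word
  expect_identical(freq[[target]], max(freq[names(freq) != target]) + 1L)
  # token budget: participants x words per norm, plus the injected target
  organic <- sum(freq) - freq[[target]]
  expect_lte(organic, cfg$n_norm_participants * cfg$words_per_norm)

  words <- split(names(si$cluster), si$cluster)
  ch <- colMeans(si$space$vectors[words$high, ])
  cl <- colMeans(si$space$vectors[words$low, ])
  eh <- norm_embedding(si$space, norms$high)
  expect_gt(semantic_similarity(eh, ch), semantic_similarity(eh, cl))
})

test_that("the valence lexicon is planted on the severity axis", {
  cfg <- generator_config(seed = 108)
  si <- make_toy_space(cfg)
  lex <- simulate_valence_lexicon(cfg, si)
  expect_equal(lex$valence_mean[lex$word == "cat"], 4.38)
  expect_equal(lex$valence_sd[lex$word == "cat"], 2.24)
  expect_true(all(lex$valence_mean >= 1 & lex$valence_mean <= 9))

  cl <- si$cluster[lex$word]
  expect_lt(mean(lex$valence_mean[cl == "high"]),
            mean(lex$valence_mean[cl == "neutral"]))

  # zero noise: ratings perfectly anti-monotone in the axis coordinate
  cfg0 <- generator_config(seed = 108, valence_noise_sd = 0)
  lex0 <- simulate_valence_lexicon(cfg0, si)
  proj <- as.numeric(si$space$vectors[lex0$word, ] %*% si$axis)
  # clipping-free region of the 1-9 scale, minus the pinned anchor entry
  inner <- abs(proj) < 3.9 & lex0$word != "cat"
  expect_equal(cor(lex0$valence_mean[inner], proj[inner],
                   method = "spearman"), -1)
})

test_that("a lexicon of affective-norms scale is generated when configured", {
  cfg <- generator_config(seed = 109,
                          cluster_sizes = c(high = 300L, low = 300L,
                                            neutral = 250L, filler = 250L))
  si <- make_toy_space(cfg)
  lex <- simulate_valence_lexicon(cfg, si)
  expect_gte(nrow(lex), 1000L)
})

test_that("fixture files round-trip through the pipeline's readers", {
  dir <- withr::local_tempdir()
  cfg <- generator_config(seed = 110, n_participants = 15L)
  paths <- write_fixtures(dir, cfg)
  expect_true(all(file.exists(paths)))
  space <- load_space(paths[["space"]])
  expect_equal(space$d, cfg$d)
  resp <- read_responses(paths[["responses"]])
  expect_length(resp, 15L)
  expect_true(all(unlist(lapply(resp, `[[`, "tokens")) %in% space$vocabulary))
  lex <- read_lexicon(paths[["lexicon"]])
  expect_equal(nrow(lex), length(space$vocabulary))
})
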