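#' Direction embedding separating two groups of words
#'
#' The supervised dimension is the difference of the two groups' aggregated
#' (mean) embeddings, oriented so that group 2 is the positive pole. The
#' line through the origin along this vector is the projection dimension.
#'
#' @param group1_words,group2_words numeric matrices of word embeddings
#'   (one row per word token).
#' @return numeric direction vector `mean(group2) - mean(group1)`; a
#'   warning is emitted when the groups coincide and the direction is zero.
#' @export
direction_embedding <- function(group1_words, group2_words) {
  g1 <- as.matrix(group1_words); g2 <- as.matrix(group2_words)
  if (nrow(g1) == 0L || nrow(g2) == 0L) stop("input error: empty group")
  dir <- colMeans(g2) - colMeans(g1)
  if (all(dir == 0)) warning("degenerate direction: group means coincide")
  dir
}

#' Project words onto a supervised dimension
#'
#' Each word's embedding is first positioned relative to the mean embedding
#' of all words (subtracting `global_mean`) and then projected onto the
#' direction with the dot product.
#'
#' @param words character vector of words to project (must be in the space).
#' @param space a [semantic_space()].
#' @param direction direction vector from [direction_embedding()].
#' @param global_mean mean embedding of all words under study.
#' @return named numeric vector of projections.
#' @export
project_words <- function(words, space, direction, global_mean) {
  if (all(direction == 0)) stop("degenerate-dimension error: zero direction")
  missing <- setdiff(words, space$vocabulary)
  if (length(missing)) {
    stop(sprintf("word(s) not in vocabulary: %s",
                 paste(utils::head(missing, 3L), collapse = ", ")))
  }
  V <- space$vectors[words, , drop = FALSE]
  proj <- as.numeric(sweep(V, 2L, global_mean) %*% direction)
  stats::setNames(proj, words)
}

# Per-response in-vocabulary token bookkeeping shared by the observed and
# permuted projections.
response_token_sums <- function(space, responses) {
  toks <- lapply(responses, function(r) r$tokens[r$tokens %in% space$vocabulary])
  if (any(lengths(toks) == 0L)) {
    stop("unembeddable response: all tokens out of vocabulary")
  }
  sums <- t(vapply(toks, function(tk) {
    colSums(space$vectors[tk, , drop = FALSE])
  }, numeric(space$d)))
  list(tokens = toks, sums = sums, counts = lengths(toks))
}

group_direction <- function(sums, counts, labels) {
  g2 <- labels == 2L
  colSums(sums[g2, , drop = FALSE]) / sum(counts[g2]) -
    colSums(sums[!g2, , drop = FALSE]) / sum(counts[!g2])
}

#' Permutation p-values for word projections
#'
#' Builds each word's null distribution by repeatedly shuffling the group
#' labels across responses (the response, not the word token, is the
#' exchangeable unit: tokens within one response are dependent) and
#' recomputing the direction embedding and the word's projection each
#' time. By default the test statistic projects onto the *unit* direction:
#' dividing out the direction's norm makes the test ask whether the word
#' is unusually aligned with the group contrast's orientation, rather than
#' letting the single shared realization of the direction's magnitude push
#' every word's p-value up or down together — with the normalized
#' statistic the rejection rate under a true null stays at the nominal
#' level realization by realization. The flip side is conservatism when
#' the group contrast lies along the data's dominant variance direction
#' (random splits then also point that way); `statistic = "raw"` keeps
#' the direction's magnitude in the statistic for that situation, at the
#' price of a null rejection rate that fluctuates with the observed
#' direction's norm. The two-sided p-value uses add-one smoothing,
#' `(1 + #(|null| >= |observed|)) / (n_permutations + 1)`, so the smallest
#' attainable p at 999 permutations is 1/1000.
#'
#' `fixed_direction = TRUE` switches to a cheaper word-rank null that
#' never re-forms the direction: a word's p-value is the fraction of all
#' projected words whose absolute projection on the observed direction is
#' at least as large (`n_permutations` is ignored). This asks a different,
#' word-exchangeability question and is off by default.
#'
#' @param space a [semantic_space()].
#' @param responses list of [word_response()] objects.
#' @param group_labels per-response labels with exactly two levels; the
#'   second sorted level is the positive pole.
#' @param n_permutations number of label shuffles (>= 100).
#' @param seed integer seed for the shuffles.
#' @param fixed_direction use the cheaper fixed-direction word-rank null?
#' @param statistic `"normalized"` (unit-direction projection, default) or
#'   `"raw"` (plain dot product).
#' @return data.frame `word, frequency, projection, p_value` (`projection`
#'   is the raw dot product onto the unnormalized direction).
#' @export
permutation_pvalues <- function(space, responses, group_labels,
                                n_permutations = 1000L, seed,
                                fixed_direction = FALSE,
                                statistic = c("normalized", "raw")) {
  statistic <- match.arg(statistic)
  if (n_permutations < 100L) stop("n_permutations must be >= 100")
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  labels <- as.integer(factor(group_labels))
  if (length(unique(labels)) != 2L) stop("input error: need exactly two groups")
  if (length(labels) != length(responses)) {
    stop("one group label per response is required")
  }

  rt <- response_token_sums(space, responses)
  all_tokens <- unlist(rt$tokens, use.names = FALSE)
  words <- sort(unique(all_tokens))
  freq <- table(factor(all_tokens, levels = words))
  global_mean <- colSums(rt$sums) / sum(rt$counts)
  Vc <- sweep(space$vectors[words, , drop = FALSE], 2L, global_mean)

  dir_obs <- group_direction(rt$sums, rt$counts, labels)
  if (all(dir_obs == 0)) stop("degenerate-dimension error: zero direction")
  obs <- as.numeric(Vc %*% dir_obs)
  scale_obs <- if (statistic == "normalized") sqrt(sum(dir_obs^2)) else 1
  obs_stat <- abs(obs) / scale_obs

  if (fixed_direction) {
    p <- vapply(obs_stat, function(o) mean(obs_stat >= o), numeric(1))
  } else {
    rng <- local_rng(seed)
    on.exit(rng(), add = TRUE)
    exceed <- integer(length(words))
    n_eff <- 0L
    for (b in seq_len(n_permutations)) {
      perm <- sample(labels)
      dir_b <- group_direction(rt$sums, rt$counts, perm)
      nrm <- sqrt(sum(dir_b^2))
      if (nrm == 0) next
      scale_b <- if (statistic == "normalized") nrm else 1
      null_stat <- abs(as.numeric(Vc %*% dir_b)) / scale_b
      exceed <- exceed + (null_stat >= obs_stat)
      n_eff <- n_eff + 1L
    }
    p <- (1 + exceed) / (n_eff + 1)
  }
  data.frame(word = words, frequency = as.integer(freq),
             projection = obs, p_value = p, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted q-values controlling the FDR across the projected
#' words (delegates to [stats::p.adjust()] after validating the input).
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return q-values of the same length.
#' @export
fdr_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    stop("validation error: p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Supervised dimension projection of word responses
#'
#' The full word-plot computation: aggregate each group's word embeddings,
#' form the group-difference direction, center every word at the mean
#' embedding of all words and project it onto the direction (dot product),
#' attach permutation p-values, Benjamini-Hochberg q-values and per-word
#' mean external scores (e.g., the rating-scale total of the participants
#' who used the word). The result drives the word scatter: x = projection,
#' y = external score, font size grows with frequency, significant words
#' colored.
#'
#' @param space a [semantic_space()].
#' @param responses list of [word_response()] objects.
#' @param group_labels per-response two-level labels defining the dimension
#'   (e.g., depression vs. worry questions, or a low/high total split).
#' @param external_scores numeric vector aligned with `responses` (e.g.,
#'   each respondent's scale total).
#' @param n_permutations,seed,fixed_direction,statistic see
#'   [permutation_pvalues()].
#' @param alpha significance level applied to the q-values.
#' @return data.frame of class `sdp_projection` with columns
#'   `word, frequency, projection, external_y, p_value, q_value,
#'   significant`.
#' @export
sdp_projection <- function(space, responses, group_labels, external_scores,
                           n_permutations = 1000L, seed, alpha = 0.05,
                           fixed_direction = FALSE,
                           statistic = c("normalized", "raw")) {
  if (length(external_scores) != length(responses)) {
    stop("join error: one external score per response is required")
  }
  res <- permutation_pvalues(space, responses, group_labels,
                             n_permutations = n_permutations, seed = seed,
                             fixed_direction = fixed_direction,
                             statistic = statistic)
  rt <- response_token_sums(space, responses)
  res$external_y <- vapply(res$word, function(w) {
    used <- vapply(rt$tokens, function(tk) w %in% tk, logical(1))
    mean(external_scores[used])
  }, numeric(1), USE.NAMES = FALSE)
  res$q_value <- fdr_adjust(res$p_value)
  res$significant <- res$q_value < alpha
  res <- res[c("word", "frequency", "projection", "external_y",
               "p_value", "q_value", "significant")]
  attr(res, "alpha") <- alpha
  class(res) <- c("sdp_projection", "data.frame")
  res
}

#' Plot data for a supervised dimension projection
#'
#' Adds display attributes to a projection table: a font size linear in
#' `log(1 + frequency)` rescaled to `size_range`, and a color by
#' significance.
#'
#' @param projections an [sdp_projection()] result.
#' @param size_range numeric length-2: smallest and largest font size.
#' @param colors length-2 colors for non-significant and significant words.
#' @return data.frame with additional `size` and `color` columns.
#' @export
plot_data <- function(projections, size_range = c(0.6, 2),
                      colors = c("grey50", "firebrick")) {
  df <- as.data.frame(projections)
  lf <- log1p(df$frequency)
  rng <- range(lf)
  rel <- if (diff(rng) == 0) rep(0.5, length(lf)) else (lf - rng[1]) / diff(rng)
  df$size <- size_range[1] + rel * diff(size_range)
  df$color <- ifelse(df$significant, colors[2], colors[1])
  df
}

#' @export
plot.sdp_projection <- function(x, xlab = "Projection", ylab = "External score",
                                ...) {
  df <- plot_data(x)
  plot(df$projection, df$external_y, type = "n", xlab = xlab, ylab = ylab, ...)
  graphics::text(df$projection, df$external_y, labels = df$word,
                 cex = df$size, col = df$color)
  invisible(x)
}
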