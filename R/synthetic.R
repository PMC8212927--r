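#' Configuration for the synthetic cohort generator
#'
#' The generator emulates a word-response study without participant data: a
#' toy semantic space with planted vocabulary clusters, a latent severity
#' trait per participant that drives both which words they choose and how
#' they answer rating-scale items, norm participants describing the two
#' construct poles, an affect lexicon whose ratings are linear in the
#' planted severity axis, and per-participant attention-control outcomes.
#' Identical configuration and seed give bit-identical output.
#'
#' Defaults describe the study conditions the package is validated under: a
#' cohort of 400 respondents answering one construct's word-response
#' question with five words and a 9-item 0-3 scale whose first two items
#' map onto primary diagnostic criteria; 110 norm participants giving 10
#' words per pole; a 9.7% attention-check failure rate.
#'
#' @param seed integer seed (required).
#' @param n_participants cohort size.
#' @param d embedding dimension of the toy space.
#' @param cluster_sizes named integer vector: number of words in the
#'   `high` (construct), `low` (opposite pole), `neutral` and `filler`
#'   clusters.
#' @param separation distance between the high and low cluster centroids
#'   along the severity axis (embedding units; must be positive).
#' @param cluster_base magnitude of a common centroid component, orthogonal
#'   to the severity axis, shared by the high and low clusters. Real pole
#'   norms share much general mood-description vocabulary structure, so
#'   the poles are not geometric opposites; similarity to one pole norm
#'   partly reflects this shared component, which the bipolar subtraction
#'   cancels.
#' @param within_sd within-cluster coordinate standard deviation; the
#'   default (an eighth of the default centroid separation) keeps the
#'   pole clusters linearly separable by construction.
#' @param temperature softmax temperature of word choice: lower values tie
#'   word choice more tightly to severity.
#' @param words_per_response words per word-response answer.
#' @param scale a [scale_definition()] for the emitted rating scale.
#' @param discrimination_primary,discrimination_secondary latent loadings
#'   a_j of primary- and secondary-flagged items (primaries load more, so
#'   the primary-over-secondary contrast is recoverable by design).
#' @param item_noise_sd standard deviation of the item-level noise added to
#'   `a_j * theta` before discretization.
#' @param n_norm_participants,words_per_norm norm collection design.
#' @param norm_match_prob probability a norm word is drawn from the
#'   matching cluster (otherwise neutral).
#' @param valence_intercept,valence_slope,valence_noise_sd the lexicon
#'   model: rating = intercept - slope * (severity-axis coordinate) +
#'   noise, clipped to `[1, 9]`.
#' @param control_failure_rate probability a participant fails the
#'   attention-control items.
#' @param construct construct label used for question and norm ids.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(seed,
                             n_participants = 400L,
                             d = 32L,
                             cluster_sizes = c(high = 40L, low = 40L,
                                               neutral = 60L, filler = 60L),
                             separation = 4,
                             cluster_base = 2,
                             within_sd = 0.5,
                             temperature = 0.8,
                             words_per_response = 5L,
                             scale = phq9_definition(),
                             discrimination_primary = 1.4,
                             discrimination_secondary = 0.7,
                             item_noise_sd = 1.2,
                             n_norm_participants = 110L,
                             words_per_norm = 10L,
                             norm_match_prob = 0.8,
                             valence_intercept = 5,
                             valence_slope = 1,
                             valence_noise_sd = 0.5,
                             control_failure_rate = 0.097,
                             construct = "depression") {
  if (missing(seed) || is.null(seed)) stop("config error: a seed is required")
  if (separation <= 0) stop("config error: separation must be positive")
  if (any(cluster_sizes < 1L)) stop("config error: cluster sizes must be >= 1")
  if (d < 2L) stop("config error: d must be >= 2")
  if (control_failure_rate < 0 || control_failure_rate > 1) {
    stop("config error: control_failure_rate must be in [0, 1]")
  }
  stopifnot(inherits(scale, "scale_definition"))
  structure(as.list(environment()), class = "generator_config")
}

# Skewed category profile shared by all items: probabilities proportional
# to n_cat..1, giving positively skewed item distributions like those of
# community depression/anxiety screens. Thresholds on the standardized
# latent score.
default_thresholds <- function(n_cat) {
  p <- rev(seq_len(n_cat)) / sum(seq_len(n_cat))
  stats::qnorm(cumsum(p)[-n_cat])
}

cluster_words <- function(config) {
  cs <- config$cluster_sizes
  list(
    high = c(config$construct,
             sprintf("%shigh%03d", substr(config$construct, 1, 3),
                     seq_len(cs[["high"]] - 1L))),
    low = c("serene", sprintf("low%03d", seq_len(cs[["low"]] - 1L))),
    neutral = c("cat", sprintf("neut%03d", seq_len(cs[["neutral"]] - 1L))),
    filler = sprintf("fill%03d", seq_len(cs[["filler"]]))
  )
}

#' Generate a toy semantic space with planted clusters
#'
#' Draws word vectors directly around four cluster centroids: the
#' construct-high and construct-low centroids sit at opposite ends of a
#' random unit "severity axis" (`+separation/2` and `-separation/2`), and
#' the neutral and filler centroids lie along directions orthogonal to it.
#' The axis and each word's cluster membership are returned as ground
#' truth.
#'
#' @param config a [generator_config()].
#' @return list with `space` (a [semantic_space()]), `axis` (unit severity
#'   axis), `cluster` (named character vector: word -> cluster).
#' @export
make_toy_space <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  rng <- local_rng(config$seed)
  on.exit(rng(), add = TRUE)
  d <- config$d
  axis <- rnorm(d); axis <- axis / sqrt(sum(axis^2))
  ortho <- function() {
    v <- rnorm(d); v <- v - sum(v * axis) * axis
    v / sqrt(sum(v^2))
  }
  base <- config$cluster_base * ortho()
  centroids <- list(
    high = base + (config$separation / 2) * axis,
    low = base - (config$separation / 2) * axis,
    neutral = (config$separation / 2) * ortho(),
    filler = (config$separation / 2) * ortho()
  )
  words <- cluster_words(config)
  vocab <- unlist(words, use.names = FALSE)
  cluster <- rep(names(words), lengths(words))
  vectors <- t(vapply(seq_along(vocab), function(i) {
    centroids[[cluster[[i]]]] + rnorm(d, sd = config$within_sd)
  }, numeric(d)))
  rownames(vectors) <- vocab
  list(space = semantic_space(vectors, vocab,
                              provenance = sprintf(
                                "synthetic clustered space (seed %d, d %d)",
                                config$seed, d)),
       axis = axis,
       cluster = stats::setNames(cluster, vocab))
}

#' Simulate norm participants' word lists for both construct poles
#'
#' Norm participants each contribute `words_per_norm` words, drawn from the
#' matching cluster with probability `norm_match_prob` and from the neutral
#' cluster otherwise. The construct's target word is injected into the
#' high-pole norm under the most-frequent-by-1 rule.
#'
#' @param config a [generator_config()].
#' @param space_info the [make_toy_space()] result.
#' @return list with `high` and `low` [build_norm()] objects.
#' @export
simulate_norms <- function(config, space_info) {
  rng <- local_rng(config$seed + 1L)
  on.exit(rng(), add = TRUE)
  words <- cluster_words(config)
  draw_lists <- function(pool, n_people) {
    lapply(seq_len(n_people), function(i) {
      from_pool <- stats::runif(config$words_per_norm) < config$norm_match_prob
      ifelse(from_pool,
             sample(pool, config$words_per_norm, replace = TRUE),
             sample(words$neutral, config$words_per_norm, replace = TRUE))
    })
  }
  high <- build_norm(draw_lists(words$high, config$n_norm_participants),
                     target_word = config$construct,
                     construct = paste0(config$construct, "-high"))
  low <- build_norm(draw_lists(words$low, config$n_norm_participants),
                    target_word = NULL,
                    construct = paste0(config$construct, "-low"))
  list(high = high, low = low)
}

#' Simulate a valence lexicon linear in the severity axis
#'
#' Every vocabulary word receives a rating
#' `valence_intercept - valence_slope * <vector, axis> + noise`, clipped to
#' the 1-9 scale, so construct-high words are unpleasant and construct-low
#' words pleasant. A neutral anchor word ("cat") is pinned at rating 4.38
#' (SD 2.24), mirroring the canonical neutral entry of affective word
#' norms.
#'
#' @param config a [generator_config()].
#' @param space_info the [make_toy_space()] result.
#' @return a [valence_lexicon()] covering the whole vocabulary.
#' @export
simulate_valence_lexicon <- function(config, space_info) {
  rng <- local_rng(config$seed + 2L)
  on.exit(rng(), add = TRUE)
  space <- space_info$space
  proj <- as.numeric(space$vectors %*% space_info$axis)
  v <- config$valence_intercept - config$valence_slope * proj +
    rnorm(length(proj), sd = config$valence_noise_sd)
  v <- pmin(9, pmax(1, v))
  sds <- stats::runif(length(v), 1.5, 2.5)
  anchor <- match("cat", space$vocabulary)
  if (!is.na(anchor)) {
    v[anchor] <- 4.38
    sds[anchor] <- 2.24
  }
  valence_lexicon(space$vocabulary, v, sds)
}

#' Simulate a cohort of participants
#'
#' Each participant has a latent severity `theta ~ Normal(0, 1)`. Word
#' choice is a softmax over the vocabulary with weight
#' `exp(theta * loading / temperature)` where construct-high words load +1,
#' construct-low words -1 and neutral/filler words 0; `words_per_response`
#' distinct words are drawn. Item j of the rating scale discretizes the
#' standardized latent score `a_j * theta + noise` through a common set of
#' positively skewed thresholds into the scale's response categories. Each
#' participant also answers two attention-control items; a failing
#' participant (probability `control_failure_rate`) gets one of them wrong.
#'
#' @param config a [generator_config()].
#' @param space_info the [make_toy_space()] result.
#' @return list with `responses` (list of [word_response()]), `items`
#'   (n x k integer matrix), `control_answers` (long data.frame with
#'   `participant_id, control_item, answer, expected`), `truth`
#'   (data.frame `participant_id, theta, control_pass`).
#' @export
simulate_participants <- function(config, space_info) {
  rng <- local_rng(config$seed + 3L)
  on.exit(rng(), add = TRUE)
  space <- space_info$space
  n <- config$n_participants
  def <- config$scale
  loading <- c(high = 1, low = -1, neutral = 0, filler = 0)[
    space_info$cluster[space$vocabulary]]

  theta <- rnorm(n)
  ids <- sprintf("p%04d", seq_len(n))

  responses <- lapply(seq_len(n), function(i) {
    w <- exp(theta[[i]] * loading / config$temperature)
    toks <- sample(space$vocabulary, config$words_per_response, prob = w)
    word_response(ids[[i]], config$construct, toks)
  })

  a <- ifelse(def$primary_flags, config$discrimination_primary,
              config$discrimination_secondary)
  n_cat <- def$item_max - def$item_min + 1L
  thr <- default_thresholds(n_cat)
  items <- vapply(seq_len(def$n_items), function(j) {
    latent <- a[[j]] * theta + rnorm(n, sd = config$item_noise_sd)
    z <- latent / sqrt(a[[j]]^2 + config$item_noise_sd^2)
    def$item_min + findInterval(z, thr)
  }, integer(n))
  rownames(items) <- ids
  colnames(items) <- paste0("item_", seq_len(def$n_items))

  fails <- stats::runif(n) < config$control_failure_rate
  expected <- c("several_days", "not_at_all")
  alternatives <- c("not_at_all", "several_days", "more_than_half", "nearly_every_day")
  control <- do.call(rbind, lapply(seq_len(n), function(i) {
    ans <- expected
    if (fails[[i]]) {
      j <- sample(2L, 1L)
      ans[[j]] <- sample(setdiff(alternatives, expected[[j]]), 1L)
    }
    data.frame(participant_id = ids[[i]], control_item = 1:2,
               answer = ans, expected = expected, stringsAsFactors = FALSE)
  }))

  list(responses = responses, items = items, control_answers = control,
       truth = data.frame(participant_id = ids, theta = theta,
                          control_pass = !fails, stringsAsFactors = FALSE))
}

#' Generate a complete synthetic cohort
#'
#' Runs [make_toy_space()], [simulate_norms()],
#' [simulate_valence_lexicon()] and [simulate_participants()] under one
#' configuration and returns everything the analysis pipeline consumes,
#' together with the planted ground truth.
#'
#' @param config a [generator_config()].
#' @return object of class `qcla_cohort`: list with `space`, `axis`,
#'   `cluster`, `norms`, `lexicon`, `responses`, `items`,
#'   `control_answers`, `truth`, `config`.
#' @examples
#' cohort <- simulate_cohort(generator_config(seed = 7, n_participants = 50))
#' cohort$space
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  si <- make_toy_space(config)
  norms <- simulate_norms(config, si)
  lexicon <- simulate_valence_lexicon(config, si)
  pp <- simulate_participants(config, si)
  structure(
    c(list(space = si$space, axis = si$axis, cluster = si$cluster,
           norms = norms, lexicon = lexicon, config = config), pp),
    class = "qcla_cohort")
}

#' @export
print.qcla_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d participants, construct '%s', %s scale\n",
              x$config$n_participants, x$config$construct,
              x$config$scale$scale_id))
  print(x$space)
  invisible(x)
}

#' Write a miniature study to disk in the pipeline's file formats
#'
#' Emits the embedding text file, responses CSV, items CSV, norm CSVs,
#' lexicon CSV and control-answer CSV for a synthetic cohort, so the
#' file-based entry points can be exercised end to end.
#'
#' @param dir output directory (created if needed).
#' @param config a [generator_config()].
#' @return named character vector of the written paths, invisibly.
#' @export
write_fixtures <- function(dir, config) {
  cohort <- simulate_cohort(config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    space = file.path(dir, "space.txt"),
    responses = file.path(dir, "responses.csv"),
    items = file.path(dir, "items.csv"),
    norm_high = file.path(dir, "norm_high.csv"),
    norm_low = file.path(dir, "norm_low.csv"),
    lexicon = file.path(dir, "lexicon.csv"),
    controls = file.path(dir, "controls.csv"))
  write_space(cohort$space, paths[["space"]])
  write_responses(cohort$responses, paths[["responses"]],
                  n_words = config$words_per_response)
  items_df <- data.frame(participant_id = rownames(cohort$items),
                         scale_id = config$scale$scale_id,
                         cohort$items, stringsAsFactors = FALSE)
  utils::write.csv(items_df, paths[["items"]], row.names = FALSE)
  write_norm(cohort$norms$high, paths[["norm_high"]])
  write_norm(cohort$norms$low, paths[["norm_low"]])
  write_lexicon(cohort$lexicon, paths[["lexicon"]])
  utils::write.csv(cohort$control_answers, paths[["controls"]],
                   row.names = FALSE)
  invisible(paths)
}
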