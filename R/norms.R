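#' Build a word norm from per-participant word lists
#'
#' A word norm is an empirically collected bag of words describing one pole
#' of a construct (e.g., "being depressed" vs. "not at all depressed"),
#' pooled over norm participants with frequencies. When a target construct
#' word is supplied its frequency is set to one more than the highest
#' frequency among the other words, so the target is the most frequent word
#' by exactly 1 regardless of how often it occurred organically.
#'
#' @param word_lists list of character vectors, one per norm participant.
#' @param target_word optional designated construct word.
#' @param construct label for the construct pole this norm describes.
#' @return An object of class `word_norm` with elements `construct`,
#'   `tokens` (named integer frequency table) and `target_word`.
#' @export
build_norm <- function(word_lists, target_word = NULL, construct = "construct") {
  if (!is.list(word_lists)) word_lists <- list(word_lists)
  tokens <- normalize_tokens(unlist(word_lists, use.names = FALSE))
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L) stop("input error: all word lists are empty")
  freq <- table(tokens)
  freq <- stats::setNames(as.integer(freq), names(freq))
  if (!is.null(target_word)) {
    target_word <- normalize_tokens(target_word)
    others <- freq[names(freq) != target_word]
    # one more than the next-most-frequent word; a norm containing only the
    # target itself gains one on top of its organic occurrences
    if (length(others)) {
      freq[target_word] <- max(others) + 1L
    } else {
      organic <- if (target_word %in% names(freq)) freq[[target_word]] else 0L
      freq[target_word] <- organic + 1L
    }
  }
  structure(
    list(construct = construct, tokens = freq,
         target_word = if (is.null(target_word)) NA_character_ else target_word),
    class = "word_norm"
  )
}

#' @export
print.word_norm <- function(x, ...) {
  cat(sprintf("Word norm '%s': %d distinct words, %d tokens\n",
              x$construct, length(x$tokens), sum(x$tokens)))
  if (!is.na(x$target_word)) {
    cat(sprintf("Target word: '%s' (frequency %d)\n",
                x$target_word, x$tokens[[x$target_word]]))
  }
  invisible(x)
}

#' Read or write a word norm as a two-column CSV
#'
#' The on-disk form is `word,frequency`; a plain one-word-per-line file (no
#' header, no frequency column) is also accepted and read as frequency-1
#' entries pooled by repetition.
#'
#' @param path CSV path.
#' @param construct,target_word metadata not stored in the file.
#' @return [read_norm()]: a `word_norm`; [write_norm()]: `path` invisibly.
#' @export
read_norm <- function(path, construct = "construct", target_word = NA_character_) {
  first <- readLines(path, n = 1L)
  if (grepl(",", first)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    freq <- stats::setNames(as.integer(df$frequency), normalize_tokens(df$word))
  } else {
    words <- normalize_tokens(readLines(path))
    words <- words[nzchar(words)]
    tab <- table(words)
    freq <- stats::setNames(as.integer(tab), names(tab))
  }
  structure(list(construct = construct, tokens = freq,
                 target_word = target_word),
            class = "word_norm")
}

#' @rdname read_norm
#' @param norm a `word_norm`.
#' @export
write_norm <- function(norm, path) {
  utils::write.csv(
    data.frame(word = names(norm$tokens), frequency = as.integer(norm$tokens)),
    path, row.names = FALSE)
  invisible(path)
}

#' Embed a word norm
#'
#' The norm embedding is by default the frequency-weighted mean of its
#' words' vectors: each word contributes proportionally to how often norm
#' participants used it, which preserves the target word's deliberate
#' most-frequent-by-1 dominance. `weight = "unique"` averages each distinct
#' in-vocabulary word once instead. Out-of-vocabulary words are skipped; a
#' norm losing more than half its tokens to the vocabulary triggers a
#' warning, and one losing all of them is an error.
#'
#' @param space a [semantic_space()].
#' @param norm a [build_norm()] result.
#' @param weight `"frequency"` (default) or `"unique"`.
#' @return numeric embedding of length `space$d` with attributes
#'   `n_tokens_used` and `n_tokens_oov` (token counts under frequency
#'   weighting).
#' @export
norm_embedding <- function(space, norm, weight = c("frequency", "unique")) {
  weight <- match.arg(weight)
  stopifnot(inherits(space, "semantic_space"), inherits(norm, "word_norm"))
  words <- names(norm$tokens)
  hit <- words %in% space$vocabulary
  n_total <- sum(norm$tokens)
  n_oov <- sum(norm$tokens[!hit])
  if (!any(hit)) {
    stop(sprintf("unembeddable norm '%s': no words in vocabulary", norm$construct))
  }
  if (n_oov > n_total / 2) {
    warning(sprintf("norm '%s': %d of %d tokens (%.0f%%) out of vocabulary",
                    norm$construct, n_oov, n_total, 100 * n_oov / n_total))
  }
  V <- space$vectors[words[hit], , drop = FALSE]
  w <- if (weight == "frequency") as.numeric(norm$tokens[hit]) else
    rep(1, sum(hit))
  out <- as.numeric(crossprod(V, w) / sum(w))
  attr(out, "n_tokens_used") <- sum(norm$tokens[hit])
  attr(out, "n_tokens_oov") <- n_oov
  out
}

#' Unipolar and bipolar semantic similarity scales
#'
#' The unipolar semantic similarity scale for a response is the cosine
#' similarity between the response embedding (mean of its word vectors) and
#' one norm embedding. The bipolar scale subtracts the similarity to the
#' low-pole norm from the similarity to the high-pole norm: responses
#' resembling "being depressed" words score positive, responses resembling
#' "not at all depressed" words score negative. Bipolar scores have been the
#' stronger correlate of rating-scale totals, and equal
#' `unipolar_high - unipolar_low` by construction.
#'
#' @param space a [semantic_space()].
#' @param response a [word_response()] or character token vector.
#' @param norm,norm_high,norm_low [build_norm()] results.
#' @param weight norm aggregation passed to [norm_embedding()].
#' @return similarity score: unipolar in `[-1, 1]`, bipolar in `[-2, 2]`.
#' @export
unipolar_score <- function(space, response, norm, weight = "frequency") {
  semantic_similarity(embed_response(space, response),
                      norm_embedding(space, norm, weight = weight))
}

#' @rdname unipolar_score
#' @export
bipolar_score <- function(space, response, norm_high, norm_low,
                          weight = "frequency") {
  unipolar_score(space, response, norm_high, weight = weight) -
    unipolar_score(space, response, norm_low, weight = weight)
}

#' Score a set of responses on semantic similarity scales
#'
#' Vectorized convenience wrapper: computes the unipolar (high and low) and
#' bipolar scales for every response against one norm pair.
#'
#' @param space a [semantic_space()].
#' @param responses list of [word_response()] objects.
#' @param norm_high,norm_low the construct's high- and low-pole norms.
#' @param weight norm aggregation passed to [norm_embedding()].
#' @return data.frame with columns `participant_id`, `question_id`,
#'   `unipolar_high`, `unipolar_low`, `bipolar`.
#' @export
semantic_scale_scores <- function(space, responses, norm_high, norm_low,
                                  weight = "frequency") {
  eh <- norm_embedding(space, norm_high, weight = weight)
  el <- norm_embedding(space, norm_low, weight = weight)
  rows <- lapply(responses, function(r) {
    e <- embed_response(space, r)
    hi <- semantic_similarity(e, eh)
    lo <- semantic_similarity(e, el)
    data.frame(participant_id = r$participant_id, question_id = r$question_id,
               unipolar_high = hi, unipolar_low = lo, bipolar = hi - lo,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
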