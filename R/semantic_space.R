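#' Construct a semantic space
#'
#' A semantic space maps a vocabulary of lowercase words to fixed-dimension
#' embedding vectors. Spaces are usually built from a corpus with
#' [build_space()] or read from disk with [load_space()]; this constructor
#' assembles one from a ready-made matrix (used, e.g., by the synthetic
#' cohort generator, which draws vectors around planted cluster centroids).
#'
#' @param vectors numeric matrix, one row per word, `d` columns; rownames are
#'   taken as the vocabulary when `vocabulary` is missing.
#' @param vocabulary character vector of unique words, one per row.
#' @param provenance free-text label recording how the space was produced.
#' @return An object of class `semantic_space` with elements `vocabulary`,
#'   `vectors` (rownames set to the vocabulary), `d`, and `provenance`.
#' @export
semantic_space <- function(vectors, vocabulary = rownames(vectors),
                           provenance = "unspecified") {
  vectors <- as.matrix(vectors)
  if (is.null(vocabulary)) {
    stop("a vocabulary is required (vector rownames or `vocabulary`)")
  }
  vocabulary <- as.character(vocabulary)
  if (length(vocabulary) != nrow(vectors)) {
    stop("vocabulary length must equal the number of vector rows")
  }
  if (nrow(vectors) < 1L) stop("a semantic space needs at least one word")
  if (anyDuplicated(vocabulary)) {
    stop("vocabulary entries must be unique")
  }
  if (!all(is.finite(vectors))) stop("embedding vectors must be finite")
  storage.mode(vectors) <- "double"
  rownames(vectors) <- vocabulary
  structure(
    list(vocabulary = vocabulary, vectors = vectors, d = ncol(vectors),
         provenance = provenance),
    class = "semantic_space"
  )
}

#' @export
print.semantic_space <- function(x, ...) {
  cat(sprintf("Semantic space: %d words x %d dimensions\n",
              length(x$vocabulary), x$d))
  cat(sprintf("Provenance: %s\n", x$provenance))
  invisible(x)
}

#' Normalize word tokens
#'
#' Lowercases, strips leading/trailing punctuation, and applies Unicode NFC
#' normalization. Spelling correction is considered a manual preprocessing
#' step and is not attempted.
#'
#' @param tokens character vector of raw tokens.
#' @return character vector of normalized tokens; empty strings mark tokens
#'   that vanished under normalization.
#' @export
normalize_tokens <- function(tokens) {
  x <- tolower(as.character(tokens))
  x <- enc2utf8(x)
  # NFC normalization (iconv round-trip keeps pure-ASCII input untouched)
  x <- vapply(x, function(s) {
    out <- tryCatch(iconv(s, from = "UTF-8", to = "UTF-8"), error = function(e) s)
    if (is.na(out)) s else out
  }, character(1), USE.NAMES = FALSE)
  x <- gsub("^[[:punct:][:space:]]+|[[:punct:][:space:]]+$", "", x)
  x
}

#' Build a semantic space from a token sequence
#'
#' Counts symmetric word co-occurrences within a sliding window, optionally
#' applies a log(1 + count) transform, and compresses the co-occurrence
#' table by singular value decomposition. The embedding of word i is the
#' i-th row of U_k diag(s_1..s_k): the left singular vectors scaled by the
#' singular values, truncated to `d` dimensions. Each singular vector's sign
#' is fixed so that its largest-magnitude element is positive, which makes
#' the result deterministic across linear-algebra backends.
#'
#' @param corpus_tokens character vector: the corpus as a flat token
#'   sequence (already tokenized; normalized internally).
#' @param window integer co-occurrence window half-width (tokens at distance
#'   1..window on either side co-occur).
#' @param d embedding dimension to retain. The reference spaces in this
#'   literature use 512 dimensions; toy corpora use far fewer.
#' @param vocab_limit keep only this many most-frequent words (ties broken
#'   by first appearance). `Inf` keeps all.
#' @param log_weight if `TRUE`, apply `log1p` to co-occurrence counts before
#'   the SVD; recorded in the provenance string.
#' @return A [semantic_space()].
#' @export
build_space <- function(corpus_tokens, window = 5L, d = 512L,
                        vocab_limit = Inf, log_weight = FALSE) {
  tokens <- normalize_tokens(corpus_tokens)
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L) stop("empty corpus: no tokens after normalization")
  if (window < 1L) stop("window must be >= 1")
  if (d < 1L) stop("d must be >= 1")

  freq <- table(factor(tokens, levels = unique(tokens)))
  vocab <- names(sort(freq, decreasing = TRUE))
  if (is.finite(vocab_limit) && length(vocab) > vocab_limit) {
    vocab <- vocab[seq_len(vocab_limit)]
  }
  n_vocab <- length(vocab)
  if (n_vocab < d) {
    stop(sprintf(
      "dimension error: %d distinct words after truncation but d = %d",
      n_vocab, d))
  }

  idx <- match(tokens, vocab)          # NA for words outside the vocab limit
  C <- matrix(0, n_vocab, n_vocab)
  n_tok <- length(idx)
  for (off in seq_len(window)) {
    i <- idx[seq_len(n_tok - off)]
    j <- idx[seq_len(n_tok - off) + off]
    keep <- !is.na(i) & !is.na(j)
    if (!any(keep)) next
    pairs <- cbind(i[keep], j[keep])
    for (r in seq_len(nrow(pairs))) {
      C[pairs[r, 1L], pairs[r, 2L]] <- C[pairs[r, 1L], pairs[r, 2L]] + 1
      C[pairs[r, 2L], pairs[r, 1L]] <- C[pairs[r, 2L], pairs[r, 1L]] + 1
    }
  }
  if (log_weight) C <- log1p(C)

  sv <- svd(C)
  U <- sv$u[, seq_len(d), drop = FALSE]
  # deterministic sign: largest-|element| of each singular vector positive
  for (k in seq_len(d)) {
    m <- which.max(abs(U[, k]))
    if (U[m, k] < 0) U[, k] <- -U[, k]
  }
  vectors <- U %*% diag(sv$d[seq_len(d)], nrow = d)
  rownames(vectors) <- vocab
  semantic_space(
    vectors, vocab,
    provenance = sprintf(
      "co-occurrence SVD (window=%d, d=%d, weighting=%s, %d tokens)",
      window, d, if (log_weight) "log1p" else "raw", n_tok))
}

#' Read a semantic space from an embedding text file
#'
#' Supports the word2vec text dialect (first line `"n d"`, then one word and
#' d numbers per line) and the headerless GloVe dialect. Duplicate words keep
#' their first occurrence with a warning.
#'
#' @param path path to a UTF-8 embedding text file.
#' @param format `"word2vec"`, `"glove"`, or `"auto"` (detect: a first line
#'   of exactly two integers is a word2vec header).
#' @return A [semantic_space()].
#' @export
load_space <- function(path, format = c("auto", "word2vec", "glove")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("embedding file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty embedding file")

  first <- strsplit(trimws(lines[[1L]]), "[[:space:]]+")[[1L]]
  has_header <- length(first) == 2L &&
    !anyNA(suppressWarnings(as.integer(first)))
  if (format == "auto") format <- if (has_header) "word2vec" else "glove"

  if (format == "word2vec") {
    if (!has_header) stop("word2vec format requires an 'n d' header line")
    n_declared <- as.integer(first[[1L]])
    d_declared <- as.integer(first[[2L]])
    body <- lines[-1L]
    if (length(body) != n_declared) {
      warning(sprintf("header declares %d rows but file has %d",
                      n_declared, length(body)))
    }
  } else {
    body <- lines
    d_declared <- NA_integer_
  }

  parts <- strsplit(trimws(body), "[[:space:]]+")
  lens <- lengths(parts)
  d <- if (is.na(d_declared)) lens[[1L]] - 1L else d_declared
  bad <- which(lens != d + 1L)
  if (length(bad)) {
    stop(sprintf("format error: line %d has %d fields, expected %d",
                 bad[[1L]] + (format == "word2vec"), lens[[bad[[1L]]]], d + 1L))
  }
  words <- vapply(parts, `[[`, character(1), 1L)
  vals <- vapply(parts, function(p) as.numeric(p[-1L]), numeric(d))
  vectors <- if (d == 1L) matrix(vals, ncol = 1L) else t(vals)
  if (anyNA(vectors)) stop("format error: non-numeric embedding value")

  dup <- duplicated(words)
  if (any(dup)) {
    warning(sprintf("%d duplicate word(s) in embedding file; first occurrence kept",
                    sum(dup)))
    vectors <- vectors[!dup, , drop = FALSE]
    words <- words[!dup]
  }
  semantic_space(vectors, words, provenance = sprintf("%s file: %s", format, path))
}

#' Write a semantic space to an embedding text file
#'
#' @param space a [semantic_space()].
#' @param path output path.
#' @param format `"word2vec"` (with `"n d"` header) or `"glove"` (headerless).
#' @param digits significant digits for the coordinates; round-tripping with
#'   [load_space()] is exact for values representable at this precision.
#' @return `path`, invisibly.
#' @export
write_space <- function(space, path, format = c("word2vec", "glove"),
                        digits = 17L) {
  stopifnot(inherits(space, "semantic_space"))
  format <- match.arg(format)
  rows <- vapply(seq_along(space$vocabulary), function(i) {
    paste(space$vocabulary[[i]],
          paste(formatC(space$vectors[i, ], digits = digits, format = "g"),
                collapse = " "))
  }, character(1))
  if (format == "word2vec") {
    rows <- c(sprintf("%d %d", length(space$vocabulary), space$d), rows)
  }
  writeLines(rows, path, useBytes = TRUE)
  invisible(path)
}

#' One participant's word response to an open-ended question
#'
#' @param participant_id opaque participant identifier.
#' @param question_id construct label of the word-response question (e.g.,
#'   `"depression"`, `"worry"`).
#' @param tokens character vector of single-word answers (the design asks
#'   for five); normalized with [normalize_tokens()].
#' @return An object of class `word_response`.
#' @export
word_response <- function(participant_id, question_id, tokens) {
  tokens <- normalize_tokens(tokens)
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L) {
    stop(sprintf("participant %s: no tokens left after normalization",
                 participant_id))
  }
  if (any(grepl("[[:space:]]", tokens))) {
    stop("each token must be a single word (no whitespace)")
  }
  structure(
    list(participant_id = as.character(participant_id),
         question_id = as.character(question_id), tokens = tokens),
    class = "word_response"
  )
}

#' Read word responses from CSV
#'
#' Expects columns `participant_id,question_id,word1..wordK` (any K >= 1);
#' empty cells are dropped.
#'
#' @param path CSV path.
#' @return list of [word_response()] objects.
#' @export
read_responses <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  word_cols <- grep("^word", names(df), value = TRUE)
  if (!all(c("participant_id", "question_id") %in% names(df)) ||
      length(word_cols) == 0L) {
    stop("responses CSV needs participant_id, question_id, word1.. columns")
  }
  lapply(seq_len(nrow(df)), function(i) {
    toks <- unlist(df[i, word_cols], use.names = FALSE)
    toks <- toks[!is.na(toks) & nzchar(toks)]
    word_response(df$participant_id[[i]], df$question_id[[i]], toks)
  })
}

#' Write word responses to CSV
#'
#' @param responses list of [word_response()] objects.
#' @param path output CSV path.
#' @param n_words number of word columns (shorter responses padded empty).
#' @return `path`, invisibly.
#' @export
write_responses <- function(responses, path, n_words = 5L) {
  rows <- lapply(responses, function(r) {
    toks <- c(r$tokens, rep("", n_words))[seq_len(n_words)]
    c(participant_id = r$participant_id, question_id = r$question_id,
      stats::setNames(toks, paste0("word", seq_len(n_words))))
  })
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Aggregate a word response into a single embedding
#'
#' The response embedding is the arithmetic mean of the embedding vectors of
#' its in-vocabulary tokens; a token occurring twice contributes twice. The
#' counts of aggregated and skipped (out-of-vocabulary) tokens are attached
#' as attributes `n_tokens_used` and `n_tokens_oov`.
#'
#' @param space a [semantic_space()].
#' @param response a [word_response()] (or a plain character vector of
#'   tokens).
#' @param oov_policy `"skip"` drops out-of-vocabulary tokens (error only if
#'   all tokens are missing); `"error"` fails on the first missing token.
#' @return numeric vector of length `space$d` with attributes
#'   `n_tokens_used` and `n_tokens_oov`.
#' @export
embed_response <- function(space, response, oov_policy = c("skip", "error")) {
  oov_policy <- match.arg(oov_policy)
  stopifnot(inherits(space, "semantic_space"))
  if (inherits(response, "word_response")) {
    tokens <- response$tokens
    pid <- response$participant_id
  } else {
    tokens <- normalize_tokens(response)
    tokens <- tokens[nzchar(tokens)]
    pid <- "<tokens>"
  }
  hit <- tokens %in% space$vocabulary
  if (oov_policy == "error" && !all(hit)) {
    stop(sprintf("participant %s: out-of-vocabulary token '%s'",
                 pid, tokens[!hit][[1L]]))
  }
  if (!any(hit)) {
    stop(sprintf("unembeddable response for participant %s: all %d tokens out of vocabulary",
                 pid, length(tokens)))
  }
  rows <- space$vectors[tokens[hit], , drop = FALSE]
  out <- colMeans(rows)
  attr(out, "n_tokens_used") <- sum(hit)
  attr(out, "n_tokens_oov") <- sum(!hit)
  out
}

#' Cosine semantic similarity between two embeddings
#'
#' The similarity of two (sets of) words is the cosine of the angle between
#' their embeddings: `dot(a, b) / (|a| |b|)`, bounded in [-1, 1]. Unrelated
#' words in a large space tend to score near 0.
#'
#' @param a,b numeric vectors of equal length, both non-zero.
#' @return similarity score in `[-1, 1]`.
#' @export
semantic_similarity <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("embeddings differ in length")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("undefined similarity: zero embedding vector")
  s <- sum(a * b) / (na * nb)
  min(1, max(-1, s))
}
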