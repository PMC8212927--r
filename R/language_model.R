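#' Default ridge penalty search grid
#'
#' Thirty-three penalty values from 1e-16 to 1e16 in steps of powers of ten.
#'
#' @return numeric vector `10^(-16:16)`.
#' @export
penalty_grid <- function() 10^seq(-16, 16, by = 1)

# Ridge solutions for all penalties at once via one SVD of the
# (standardized) design. Returns a d x length(lambda) coefficient matrix on
# the preprocessed predictor scale plus the preprocessing constants.
ridge_path <- function(X, y, lambda, standardize = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X)
  centers <- colMeans(X)
  scales <- if (standardize) apply(X, 2L, stats::sd) else rep(1, ncol(X))
  scales[scales == 0 | !is.finite(scales)] <- 1
  Xs <- sweep(sweep(X, 2L, centers), 2L, scales, "/")
  ybar <- mean(y)
  yc <- y - ybar
  sv <- svd(Xs)
  uty <- crossprod(sv$u, yc)
  beta <- vapply(lambda, function(l) {
    shrink <- sv$d / (sv$d^2 + l)
    as.numeric(sv$v %*% (shrink * uty))
  }, numeric(ncol(X)))
  beta <- matrix(beta, nrow = ncol(X))
  list(beta = beta, centers = centers, scales = scales, intercept = ybar)
}

new_qcla_model <- function(path, lambda, extra = list()) {
  k <- 1L
  obj <- c(list(
    intercept = path$intercept,
    coefficients = path$beta[, k],
    centers = path$centers,
    scales = path$scales,
    lambda = lambda
  ), extra)
  class(obj) <- "qcla_model"
  obj
}

#' Fit a ridge regression at a fixed penalty
#'
#' Solves the penalized least-squares problem on column-centered (and, by
#' default, unit-scaled) predictors: the coefficients equal
#' `(Xs' Xs + lambda I)^-1 Xs' yc` where `Xs` is the preprocessed design and
#' `yc` the centered response, computed via the singular value
#' decomposition of `Xs`. Used both directly and as the inner solver of
#' [train_language_model()].
#'
#' @param X numeric matrix, n rows (observations) by d columns (embedding
#'   dimensions).
#' @param y numeric response of length n.
#' @param lambda non-negative ridge penalty.
#' @param standardize scale predictors to unit variance (computed on the
#'   rows of `X`)? Centering is always applied.
#' @return A `qcla_model`; `coefficients` are on the preprocessed predictor
#'   scale and [predict()] re-applies the stored preprocessing.
#' @export
ridge_fit <- function(X, y, lambda, standardize = TRUE) {
  path <- ridge_path(X, y, lambda, standardize = standardize)
  new_qcla_model(path, lambda,
                 extra = list(n_train = nrow(as.matrix(X)), cv_accuracy = NA_real_,
                              standardize = standardize, seed = NA_integer_,
                              grid = lambda))
}

#' Train a cross-validated language model from embeddings
#'
#' Fits a ridge regression mapping word-embedding dimensions to a numeric
#' score (a rating-scale item or total, or a lexicon valence rating):
#' `y = b0 + b1 x1 + ... + bd xd + e`. The penalty is tuned over a search
#' grid (default 1e-16 to 1e16 by powers of ten) with k-fold
#' cross-validation; within each outer training fold the data are further
#' split into an analysis portion (75%) used to fit every candidate penalty
#' and an assessment portion (25%) on which candidates are scored by
#' root-mean-square error (assessment-set correlation is available via
#' `metric = "correlation"`). Fold assignment is a seeded shuffle
#' stratified on the outcome: rows are grouped into consecutive blocks of
#' sorted `y` and spread across folds, the standard practice that equalizes
#' fold outcome distributions and keeps the pooled out-of-fold correlation
#' unbiased when the best model is nearly constant. Each
#' outer fold is then refit on its full training portion at the selected
#' penalty and used to predict its held-out fold. The model's accuracy
#' (`cv_accuracy`) is the Pearson correlation between the pooled
#' out-of-fold predictions and the observed scores. The returned
#' coefficients are refit on all rows at the penalty selected most often
#' across folds (ties resolved toward stronger shrinkage).
#'
#' @param X numeric matrix of embeddings, one row per observation.
#' @param y numeric scores, length `nrow(X)`, with nonzero variance.
#' @param folds number of outer cross-validation folds.
#' @param inner_prop fraction of each training fold used as the analysis
#'   set for penalty tuning (remainder is the assessment set).
#' @param grid candidate penalties; see [penalty_grid()].
#' @param seed integer seed controlling fold assignment and inner splits
#'   (required: reruns with the same data and seed are identical).
#' @param standardize center and unit-scale each embedding dimension on the
#'   training rows only (the fitting convention recorded in the model).
#' @param fold_id optional explicit fold assignment (length n, values in
#'   `1..folds`) overriding the seeded shuffle.
#' @param metric inner tuning score: `"rmse"` (default) or
#'   `"correlation"`.
#' @return A `qcla_model` with elements `intercept`, `coefficients`,
#'   `centers`, `scales`, `lambda` (selected penalty), `lambda_folds`
#'   (per-fold selections), `cv_accuracy`, `cv_predictions` (pooled
#'   out-of-fold predictions, in input row order), `grid`, `n_train`,
#'   `seed`.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(200 * 5), 200)
#' y <- X %*% rnorm(5) + rnorm(200, sd = 0.5)
#' m <- train_language_model(X, y, seed = 42)
#' m$cv_accuracy
#' @export
train_language_model <- function(X, y, folds = 10L, inner_prop = 0.75,
                                 grid = penalty_grid(), seed,
                                 standardize = TRUE, fold_id = NULL,
                                 metric = c("rmse", "correlation")) {
  metric <- match.arg(metric)
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (missing(seed) || is.null(seed)) stop("configuration error: a seed is required")
  if (length(y) != n) stop("X and y disagree in length")
  if (!all(is.finite(y))) stop("y must be finite")
  if (stats::sd(y) == 0) stop("degenerate-target error: y is constant")
  if (length(grid) == 0L) stop("configuration error: empty penalty grid")
  if (n < folds) stop(sprintf("configuration error: n = %d < folds = %d", n, folds))

  grid <- sort(as.numeric(grid))
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)

  if (is.null(fold_id)) {
    fold_id <- stratified_folds(y, folds)
  } else {
    stopifnot(length(fold_id) == n)
  }

  oof <- rep(NA_real_, n)
  lambda_folds <- numeric(folds)
  for (k in seq_len(folds)) {
    tr <- which(fold_id != k)
    te <- which(fold_id == k)
    n_an <- max(2L, floor(inner_prop * length(tr)))
    an <- sample(tr, n_an)
    as_ <- setdiff(tr, an)
    if (length(as_) == 0L) as_ <- an  # degenerate tiny folds
    path <- ridge_path(X[an, , drop = FALSE], y[an], grid,
                       standardize = standardize)
    Xas <- sweep(sweep(X[as_, , drop = FALSE], 2L, path$centers),
                 2L, path$scales, "/")
    preds <- Xas %*% path$beta + path$intercept
    score <- tuning_score(preds, y[as_], metric)
    # ties broken toward larger penalty (stronger shrinkage)
    best <- max(which(score >= max(score, na.rm = TRUE) - 1e-12))
    lambda_folds[k] <- grid[best]
    refit <- ridge_path(X[tr, , drop = FALSE], y[tr], grid[best],
                        standardize = standardize)
    Xte <- sweep(sweep(X[te, , drop = FALSE], 2L, refit$centers),
                 2L, refit$scales, "/")
    oof[te] <- as.numeric(Xte %*% refit$beta[, 1L] + refit$intercept)
  }

  cv_accuracy <- if (stats::sd(oof) == 0) {
    warning("out-of-fold predictions are constant; cv_accuracy set to 0")
    0
  } else {
    stats::cor(oof, y)
  }

  tab <- table(lambda_folds)
  winners <- as.numeric(names(tab)[tab == max(tab)])
  lambda_final <- max(winners)
  path <- ridge_path(X, y, lambda_final, standardize = standardize)
  new_qcla_model(path, lambda_final, extra = list(
    lambda_folds = lambda_folds, cv_accuracy = cv_accuracy,
    cv_predictions = oof, grid = grid, n_train = n, seed = seed,
    folds = folds, inner_prop = inner_prop, standardize = standardize,
    y = y))
}

# Outcome-stratified fold assignment: consecutive blocks of sorted y are
# each spread uniformly at random over the folds.
stratified_folds <- function(y, folds) {
  n <- length(y)
  fold_id <- integer(n)
  blocks <- split(order(y), ceiling(seq_len(n) / folds))
  for (b in blocks) {
    fold_id[b] <- sample(rep(seq_len(folds), length.out = length(b)))
  }
  fold_id
}

# Assessment-set score per penalty, larger is better. A penalty whose
# predictions are constant has no defined correlation and is never chosen
# (unless every candidate is degenerate).
tuning_score <- function(preds, y_obs, metric) {
  if (metric == "rmse") {
    return(-sqrt(colMeans((preds - y_obs)^2)))
  }
  s <- suppressWarnings(as.numeric(stats::cor(preds, y_obs)))
  if (all(is.na(s))) rep(0, length(s)) else ifelse(is.na(s), -Inf, s)
}

# Seeded RNG scope: returns a restore function.
local_rng <- function(seed) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  function() {
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}

#' @export
print.qcla_model <- function(x, ...) {
  cat(sprintf("Ridge language model: %d embedding dimensions, n = %s\n",
              length(x$coefficients),
              if (is.null(x$n_train)) "?" else x$n_train))
  cat(sprintf("Penalty lambda = %.3g", x$lambda))
  if (!is.null(x$cv_accuracy) && !is.na(x$cv_accuracy)) {
    cat(sprintf(", cross-validated accuracy r = %.3f", x$cv_accuracy))
  }
  cat("\n")
  invisible(x)
}

#' @export
summary.qcla_model <- function(object, ...) {
  structure(list(model = object), class = "summary.qcla_model")
}

#' @export
print.summary.qcla_model <- function(x, ...) {
  m <- x$model
  print(m)
  if (!is.null(m$lambda_folds)) {
    cat("Per-fold selected penalties:\n")
    print(table(m$lambda_folds))
  }
  cat(sprintf("Coefficient L2 norm: %.4f (preprocessed predictor scale)\n",
              sqrt(sum(m$coefficients^2))))
  invisible(x)
}

#' @export
coef.qcla_model <- function(object, ...) {
  b <- object$coefficients
  names(b) <- if (!is.null(names(b))) names(b) else
    paste0("dim", seq_along(b))
  c("(Intercept)" = object$intercept, b)
}

#' Predict scores from embeddings
#'
#' Applies the model's stored preprocessing (per-dimension centers and
#' scales from the training rows) and the affine map
#' `b0 + Xs %*% coefficients`. Predictions are not clipped to the training
#' response's range.
#'
#' @param object a `qcla_model`.
#' @param newdata numeric matrix (or single vector) with `d` columns.
#' @param ... unused.
#' @return numeric vector of predicted scores.
#' @export
predict.qcla_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$coefficients)) {
    stop(sprintf("shape error: model has %d dimensions, newdata has %d",
                 length(object$coefficients), ncol(newdata)))
  }
  Xs <- sweep(sweep(newdata, 2L, object$centers), 2L, object$scales, "/")
  as.numeric(Xs %*% object$coefficients + object$intercept)
}

#' @export
residuals.qcla_model <- function(object, ...) {
  if (is.null(object$y) || is.null(object$cv_predictions)) {
    stop("residuals are only available for cross-validated models")
  }
  object$y - object$cv_predictions
}

#' @export
plot.qcla_model <- function(x, ...) {
  if (is.null(x$y)) stop("plotting needs a cross-validated model")
  plot(x$cv_predictions, x$y,
       xlab = "Out-of-fold prediction", ylab = "Observed score",
       main = sprintf("Cross-validated accuracy r = %.2f", x$cv_accuracy), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' A valence lexicon
#'
#' Words with participant-rated emotional valence on a 1 (unpleasant) to 9
#' (pleasant) scale, in the style of affective word-norm lists.
#'
#' @param word character vector of unique words.
#' @param valence_mean mean valence rating per word, within `bounds`.
#' @param valence_sd non-negative rating standard deviations (optional).
#' @param bounds rating scale bounds, default `c(1, 9)`.
#' @return data.frame of class `valence_lexicon`.
#' @export
valence_lexicon <- function(word, valence_mean, valence_sd = NA_real_,
                            bounds = c(1, 9)) {
  word <- normalize_tokens(word)
  if (anyDuplicated(word)) stop("lexicon words must be unique")
  if (any(valence_mean < bounds[1] | valence_mean > bounds[2])) {
    stop(sprintf("valence ratings must lie in [%g, %g]", bounds[1], bounds[2]))
  }
  if (any(!is.na(valence_sd) & valence_sd < 0)) stop("valence SD must be >= 0")
  out <- data.frame(word = word, valence_mean = as.numeric(valence_mean),
                    valence_sd = as.numeric(valence_sd),
                    stringsAsFactors = FALSE)
  attr(out, "bounds") <- bounds
  class(out) <- c("valence_lexicon", "data.frame")
  out
}

#' @rdname valence_lexicon
#' @param path CSV path with columns `word,valence_mean,valence_sd`.
#' @export
read_lexicon <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  valence_lexicon(df$word, df$valence_mean,
                  if ("valence_sd" %in% names(df)) df$valence_sd else NA_real_)
}

#' @rdname valence_lexicon
#' @param lexicon a `valence_lexicon`.
#' @export
write_lexicon <- function(lexicon, path) {
  utils::write.csv(as.data.frame(lexicon)[c("word", "valence_mean", "valence_sd")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Train a valence model from a lexicon
#'
#' Fits the same cross-validated ridge machinery as
#' [train_language_model()] with one row per lexicon word found in the
#' semantic space: the word's embedding predicts its mean valence rating.
#' The fitted model can then score any embeddable word response via
#' [predicted_valence()], yielding a language-predicted valence scale.
#'
#' @param space a [semantic_space()].
#' @param lexicon a [valence_lexicon()].
#' @param min_words minimum number of lexicon words that must be in the
#'   vocabulary.
#' @param ... passed to [train_language_model()] (`folds`, `grid`, `seed`,
#'   ...). `folds` plays the role of k in leave-k-out-style tuning.
#' @return A `qcla_model`.
#' @export
train_valence_model <- function(space, lexicon, min_words = 50L, ...) {
  stopifnot(inherits(space, "semantic_space"))
  hit <- lexicon$word %in% space$vocabulary
  if (sum(hit) < min_words) {
    stop(sprintf("configuration error: only %d lexicon words in vocabulary (minimum %d)",
                 sum(hit), min_words))
  }
  X <- space$vectors[lexicon$word[hit], , drop = FALSE]
  train_language_model(X, lexicon$valence_mean[hit], ...)
}

#' Language-predicted valence of word responses
#'
#' Applies a lexicon-trained valence model to each response's aggregated
#' embedding. Scores are not clipped to the lexicon's rating bounds.
#'
#' @param model a `qcla_model` from [train_valence_model()].
#' @param space a [semantic_space()].
#' @param responses list of [word_response()] objects.
#' @return data.frame with `participant_id`, `question_id`,
#'   `predicted_valence`.
#' @export
predicted_valence <- function(model, space, responses) {
  rows <- lapply(responses, function(r) {
    e <- embed_response(space, r)
    data.frame(participant_id = r$participant_id, question_id = r$question_id,
               predicted_valence = predict(model, e),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Serialize a model to JSON
#'
#' Stores coefficients, penalty, preprocessing constants, grid, seed and
#' cross-validated accuracy; [read_model()] restores a functioning
#' `qcla_model` (without the training data, so residuals/plots are
#' unavailable on the restored object).
#'
#' @param model a `qcla_model`.
#' @param path JSON output path.
#' @return `path` invisibly; `read_model(path)` returns the model.
#' @export
write_model <- function(model, path) {
  keep <- c("intercept", "coefficients", "centers", "scales", "lambda",
            "lambda_folds", "cv_accuracy", "grid", "n_train", "seed",
            "folds", "inner_prop", "standardize")
  obj <- model[intersect(keep, names(model))]
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  class(obj) <- "qcla_model"
  obj
}
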