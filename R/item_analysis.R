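#' Define a rating scale
#'
#' Holds a scale's item structure, response bounds, screening cut-off, and
#' the mapping of items onto primary versus secondary diagnostic criteria.
#' Built-in definitions cover the three scales the assessment targets:
#'
#' * `phq9_definition()` — 9 depression items scored 0-3; items 1 (loss of
#'   interest) and 2 (depressed mood) map onto the primary DSM-5 criteria
#'   for major depressive disorder; screening cut-off 10.
#' * `gad7_definition()` — 7 anxiety items scored 0-3; items 2 (cannot stop
#'   worrying) and 3 (worrying about different things) map onto the primary
#'   criteria for generalized anxiety disorder; cut-off 10.
#' * `pswq8_definition()` — 8 pathological-worry items; every item contains
#'   the worry construct, so all are flagged primary. The printed anchors
#'   run 0 = "not at all typical" to 5 = "very typical", but published
#'   totals are also consistent with 1-5 scoring; both encodings are
#'   supported via `item_min`/`item_max` and neither is asserted.
#'
#' @param scale_id identifier, e.g. `"PHQ9"`.
#' @param n_items number of items.
#' @param item_min,item_max integer per-item response bounds.
#' @param primary_flags logical vector, length `n_items`: does the item map
#'   onto a primary diagnostic criterion?
#' @param item_labels optional short item descriptions.
#' @param cutoff optional integer screening cut-off on the total score.
#' @return object of class `scale_definition`.
#' @export
scale_definition <- function(scale_id, n_items, item_min, item_max,
                             primary_flags = rep(FALSE, n_items),
                             item_labels = paste0("item_", seq_len(n_items)),
                             cutoff = NA_integer_) {
  stopifnot(n_items >= 1L, item_min < item_max,
            length(primary_flags) == n_items,
            length(item_labels) == n_items)
  structure(
    list(scale_id = scale_id, n_items = as.integer(n_items),
         item_min = as.integer(item_min), item_max = as.integer(item_max),
         primary_flags = as.logical(primary_flags),
         item_labels = item_labels, cutoff = cutoff),
    class = "scale_definition"
  )
}

#' @rdname scale_definition
#' @export
phq9_definition <- function() {
  scale_definition(
    "PHQ9", 9L, 0L, 3L,
    primary_flags = c(TRUE, TRUE, rep(FALSE, 7L)),
    item_labels = c("little interest", "feeling down", "disrupted sleep",
                    "little energy", "changed food habits", "failure",
                    "no concentration", "slow or restless", "self-harm"),
    cutoff = 10L)
}

#' @rdname scale_definition
#' @export
gad7_definition <- function() {
  scale_definition(
    "GAD7", 7L, 0L, 3L,
    primary_flags = c(FALSE, TRUE, TRUE, rep(FALSE, 4L)),
    item_labels = c("nervous or anxious", "cannot stop worrying",
                    "worrying too much", "trouble relaxing",
                    "restlessness", "annoyed, irritable", "feeling afraid"),
    cutoff = 10L)
}

#' @rdname scale_definition
#' @param item_min,item_max override the 0-5 default (e.g., 1 and 5).
#' @export
pswq8_definition <- function(item_min = 0L, item_max = 5L) {
  scale_definition(
    "PSWQ8", 8L, item_min, item_max,
    primary_flags = rep(TRUE, 8L),
    item_labels = c("worries overwhelm", "situations make me worry",
                    "cannot help worrying", "worry under pressure",
                    "always worrying", "worry about tasks",
                    "lifelong worrier", "worrying about things"),
    cutoff = NA_integer_)
}

#' @export
print.scale_definition <- function(x, ...) {
  cat(sprintf("%s: %d items scored %d-%d (%d primary)%s\n",
              x$scale_id, x$n_items, x$item_min, x$item_max,
              sum(x$primary_flags),
              if (is.na(x$cutoff)) "" else sprintf(", cut-off %d", x$cutoff)))
  invisible(x)
}

#' Descriptive statistics
#'
#' Mean, sample standard deviation (n - 1 denominator), range (max - min),
#' skewness and excess kurtosis. Skewness is the adjusted Fisher-Pearson
#' estimator G1 = g1 sqrt(n(n-1))/(n-2) and kurtosis the corresponding
#' small-sample-adjusted excess estimator G2 (both `e1071` type 2).
#'
#' @param x numeric vector, n >= 3, finite.
#' @return named list with `mean`, `sd`, `range`, `skew`, `kurtosis`, `n`.
#' @export
descriptives <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 3L) stop("descriptives need n >= 3")
  if (!all(is.finite(x))) stop("non-finite values")
  if (stats::sd(x) == 0) stop("skew/kurtosis undefined for a constant vector")
  # the adjusted excess-kurtosis estimator divides by (n-2)(n-3)
  kurt <- if (length(x) >= 4L) e1071::kurtosis(x, type = 2) else NA_real_
  list(mean = mean(x), sd = stats::sd(x), range = diff(range(x)),
       skew = e1071::skewness(x, type = 2),
       kurtosis = kurt, n = length(x))
}

#' Total scores of a rating scale
#'
#' Row sums after validating that every response lies within the scale's
#' item bounds.
#'
#' @param items n x k integer matrix (participants by items).
#' @param definition a [scale_definition()].
#' @param missing `"error"` or `"drop"` (listwise deletion with a warning).
#' @return numeric totals; with `missing = "drop"`, only complete rows,
#'   named by their original row index.
#' @export
scale_total <- function(items, definition, missing = c("error", "drop")) {
  missing <- match.arg(missing)
  items <- as.matrix(items)
  if (ncol(items) != definition$n_items) {
    stop(sprintf("%s expects %d items, got %d columns",
                 definition$scale_id, definition$n_items, ncol(items)))
  }
  miss <- is.na(items)
  if (any(miss)) {
    if (missing == "error") {
      w <- which(miss, arr.ind = TRUE)[1L, ]
      stop(sprintf("missing response at row %d, item %d", w[1L], w[2L]))
    }
    keep <- rowSums(miss) == 0L
    warning(sprintf("%d incomplete row(s) dropped", sum(!keep)))
    items <- items[keep, , drop = FALSE]
    rownames(items) <- which(keep)
  }
  bad <- items < definition$item_min | items > definition$item_max
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("validation error: response %g at row %d, item %d outside [%d, %d]",
                 items[w[1L], w[2L]], w[1L], w[2L],
                 definition$item_min, definition$item_max))
  }
  rowSums(items)
}

#' Fraction of totals at or above a screening cut-off
#'
#' @param totals numeric total scores.
#' @param cutoff integer cut-off; scoring `cutoff` or higher counts
#'   (e.g., 10 or higher on the PHQ-9 screens positive for MDD).
#' @return proportion in `[0, 1]`.
#' @export
cutoff_proportion <- function(totals, cutoff) {
  if (length(totals) == 0L) stop("empty totals")
  mean(totals >= cutoff)
}

#' Internal consistency: Cronbach's alpha and McDonald's omega
#'
#' Alpha is `k/(k-1) (1 - sum(var_item)/var_total)`. Omega-total comes from
#' a one-factor maximum-likelihood factor solution on the item correlation
#' matrix: with standardized loadings l_i and uniquenesses u_i,
#' `omega = (sum l)^2 / ((sum l)^2 + sum u)`. The estimator (one-factor ML,
#' standardized metric) is recorded in the result.
#'
#' @param items n x k numeric matrix, n >= 20, k >= 2.
#' @return list with `alpha`, `omega`, `loadings`, `estimator`, `n`, `k`.
#' @export
reliability <- function(items) {
  items <- as.matrix(items)
  n <- nrow(items); k <- ncol(items)
  if (n < 20L) stop("reliability needs n >= 20")
  if (k < 2L) stop("reliability needs k >= 2 items")
  v <- apply(items, 2L, stats::var)
  if (any(v == 0)) stop("estimation error: zero-variance item")
  alpha <- k / (k - 1) * (1 - sum(v) / stats::var(rowSums(items)))
  R <- stats::cor(items)
  fa <- tryCatch(
    stats::factanal(covmat = R, factors = 1L, n.obs = n),
    error = function(e) stop("estimation error: one-factor solution failed: ",
                             conditionMessage(e)))
  l <- as.numeric(fa$loadings[, 1L])
  if (sum(l) < 0) l <- -l
  omega <- sum(l)^2 / (sum(l)^2 + sum(1 - l^2))
  list(alpha = alpha, omega = omega, loadings = l,
       estimator = "one-factor ML on correlation matrix", n = n, k = k)
}

p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Correlate two variables with a method chosen for skewed scales
#'
#' Pearson product-moment or Spearman rank correlation (Pearson on
#' average-ranked data), with a two-tailed p-value from the t approximation
#' `t = r sqrt((n-2)/(1-r^2))` on n - 2 degrees of freedom for both
#' methods. `method = "auto"` selects Spearman when `y` looks non-normal:
#' Shapiro-Wilk p < 0.05 (on at most the first 5000 values) or absolute
#' skewness above 0.2 — the rule standing in for "positively skewed,
#' deviates from normality" method choices in questionnaire work.
#'
#' @param x,y numeric vectors of equal length, n >= 4.
#' @param method `"pearson"`, `"spearman"`, or `"auto"`.
#' @return object of class `correlation_result`: list with `estimate`,
#'   `method`, `p_value`, `n`, `stars`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman", "auto")) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("correlation needs n >= 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero variance")
  }
  if (method == "auto") {
    shp <- stats::shapiro.test(y[seq_len(min(n, 5000L))])$p.value
    skw <- e1071::skewness(y, type = 2)
    method <- if (shp < 0.05 || abs(skw) > 0.2) "spearman" else "pearson"
  }
  if (method == "spearman") {
    x <- rank(x); y <- rank(y)
  }
  r <- stats::cor(x, y)
  p <- cor_p_value(r, n, df = n - 2L)
  structure(list(estimate = r, method = method, p_value = p, n = n,
                 stars = p_stars(p)),
            class = "correlation_result")
}

cor_p_value <- function(r, n, df) {
  if (abs(r) >= 1) return(0)
  t <- r * sqrt(df / (1 - r^2))
  2 * stats::pt(-abs(t), df = df)
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("%s %s = %.3f%s (p = %.3g, n = %d)\n",
              if (x$method == "pearson") "Pearson" else "Spearman",
              if (x$method == "pearson") "r" else "rho",
              x$estimate, x$stars, x$p_value, x$n))
  invisible(x)
}

#' First-order partial correlation
#'
#' Correlation between `x` and `y` after removing the linear contribution
#' of `z`: `(r_xy - r_xz r_zy) / sqrt((1 - r_xz^2)(1 - r_zy^2))`,
#' equivalently the correlation of the residuals of `x` and `y` regressed
#' on `z`. Used here to ask how much of a language-trained scale's item
#' correlation survives controlling for predicted valence. Two-tailed p
#' from the t approximation on n - 3 degrees of freedom.
#'
#' @param x,y,z numeric vectors of equal length, n >= 5.
#' @param method `"pearson"` or `"spearman"` (ranks taken first, so the
#'   partial is computed on average-ranked data).
#' @return a `correlation_result` (with `method` suffixed `"-partial"`).
#' @export
partial_correlation <- function(x, y, z, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y) & is.finite(z)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  n <- length(x)
  if (n < 5L) stop("partial correlation needs n >= 5")
  if (stats::sd(z) == 0) stop("degenerate-control error: z is constant")
  if (method == "spearman") {
    x <- rank(x); y <- rank(y); z <- rank(z)
  }
  rxy <- stats::cor(x, y); rxz <- stats::cor(x, z); rzy <- stats::cor(z, y)
  if (abs(rxz) >= 1 - 1e-12 || abs(rzy) >= 1 - 1e-12) {
    stop("degenerate-control error: control variable collinear with x or y")
  }
  r <- (rxy - rxz * rzy) / sqrt((1 - rxz^2) * (1 - rzy^2))
  p <- cor_p_value(r, n, df = n - 3L)
  structure(list(estimate = r, method = paste0(method, "-partial"),
                 p_value = p, n = n, stars = p_stars(p)),
            class = "correlation_result")
}

#' Item-level correlation table
#'
#' For each item of a rating scale and for its total: mean, SD, item-total
#' correlation, and the correlation of each predictor scale (e.g., the
#' unipolar/bipolar semantic similarity scales, the language-trained scale,
#' predicted valence) with that item — plus, when `valence_scores` are
#' supplied, a partial correlation controlling for valence for each
#' predictor named in `partial_for`.
#'
#' @param items n x k matrix of item responses, rows aligned across all
#'   vectors by participant.
#' @param definition a [scale_definition()].
#' @param predictor_scores named list of numeric vectors (length n).
#' @param valence_scores optional numeric vector (length n) used as the
#'   control variable.
#' @param partial_for names of predictors to partial; default the ones
#'   containing `"language"`.
#' @param method correlation method passed to [correlate()] (`"auto"`
#'   resolves once on the scale total and is then used for every row).
#' @return data.frame of class `item_level_table`: one row per item plus a
#'   total row, with estimate and star columns per predictor; the resolved
#'   method and definition are attached as attributes.
#' @export
item_level_table <- function(items, definition, predictor_scores,
                             valence_scores = NULL, partial_for = NULL,
                             method = "auto") {
  items <- as.matrix(items)
  n <- nrow(items)
  lens <- vapply(predictor_scores, length, integer(1))
  if (any(lens != n) || (!is.null(valence_scores) && length(valence_scores) != n)) {
    stop("join error: predictor/valence vectors must align with item rows")
  }
  totals <- scale_total(items, definition)
  if (method == "auto") {
    method <- correlate(seq_len(n), totals, method = "auto")$method
  }
  if (is.null(partial_for) && !is.null(valence_scores)) {
    partial_for <- grep("language", names(predictor_scores), value = TRUE)
  }

  make_row <- function(y, label, primary, item_total) {
    row <- data.frame(item = label, primary = primary,
                      mean = mean(y), sd = stats::sd(y),
                      item_total = item_total, stringsAsFactors = FALSE)
    for (nm in names(predictor_scores)) {
      cr <- correlate(predictor_scores[[nm]], y, method = method)
      row[[nm]] <- cr$estimate
      row[[paste0(nm, "_stars")]] <- cr$stars
      if (nm %in% partial_for) {
        pc <- partial_correlation(predictor_scores[[nm]], y, valence_scores,
                                  method = if (method == "spearman") "spearman" else "pearson")
        row[[paste0(nm, "_partial")]] <- pc$estimate
        row[[paste0(nm, "_partial_stars")]] <- pc$stars
      }
    }
    row
  }

  rows <- list(make_row(totals, "total", NA,
                        item_total = NA_real_))
  for (j in seq_len(definition$n_items)) {
    it <- correlate(items[, j], totals, method = method)
    rows[[j + 1L]] <- make_row(items[, j],
                               sprintf("item_%d (%s)", j, definition$item_labels[[j]]),
                               definition$primary_flags[[j]], it$estimate)
  }
  out <- do.call(rbind, rows)
  attr(out, "method") <- method
  attr(out, "scale_id") <- definition$scale_id
  class(out) <- c("item_level_table", "data.frame")
  out
}

#' @export
print.item_level_table <- function(x, digits = 2, ...) {
  cat(sprintf("Item-level correlations for %s (%s)\n",
              attr(x, "scale_id"), attr(x, "method")))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Verbal label for a correlation magnitude
#'
#' Conventional 0.10 / 0.30 / 0.50 thresholds for weak, moderate, and
#' strong correlations; an annotation helper only.
#'
#' @param r correlation estimate(s).
#' @return character vector of labels.
#' @export
correlation_label <- function(r) {
  a <- abs(r)
  ifelse(a >= 0.5, "strong",
         ifelse(a >= 0.3, "moderate", ifelse(a >= 0.1, "weak", "negligible")))
}
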