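#' Attention-control filter
#'
#' A participant is retained only if every attention-control answer matches
#' its required alternative; failing any control item excludes the
#' participant from all analyses.
#'
#' @param control_answers data.frame with columns `participant_id`,
#'   `control_item`, `answer` and either an `expected` column or the
#'   `expected` argument below.
#' @param expected optional named or positional character vector of
#'   required answers per control item (used when the data.frame carries no
#'   `expected` column).
#' @param n_controls number of control items every participant must have
#'   answered.
#' @return list with `retained` (character ids), `excluded` (data.frame of
#'   failing answers), `n_excluded`, `fraction_excluded`.
#' @export
attention_filter <- function(control_answers, expected = NULL,
                             n_controls = 2L) {
  df <- as.data.frame(control_answers)
  if (!all(c("participant_id", "control_item", "answer") %in% names(df))) {
    stop("control answers need participant_id, control_item, answer columns")
  }
  if (!"expected" %in% names(df)) {
    if (is.null(expected)) stop("required answers not supplied")
    df$expected <- expected[df$control_item]
  }
  counts <- table(df$participant_id)
  if (any(counts != n_controls)) {
    bad <- names(counts)[counts != n_controls][[1L]]
    stop(sprintf("validation error: participant %s has %d control records, expected %d",
                 bad, counts[[bad]], n_controls))
  }
  df$pass <- df$answer == df$expected
  failing <- unique(df$participant_id[!df$pass])
  ids <- unique(df$participant_id)
  retained <- setdiff(ids, failing)
  list(retained = retained,
       excluded = df[!df$pass, c("participant_id", "control_item",
                                 "answer", "expected")],
       n_excluded = length(failing),
       fraction_excluded = length(failing) / length(ids))
}

#' Configure an end-to-end analysis run
#'
#' Either point the paths at study files (embedding text file, responses
#' CSV, items CSV, norm CSVs, lexicon CSV, control CSV) or set
#' `synthetic = TRUE` to generate everything from `generator` (a
#' [generator_config()]).
#'
#' @param out_dir output directory for the run's artifacts.
#' @param synthetic generate inputs with the cohort simulator?
#' @param generator a [generator_config()] (synthetic mode).
#' @param paths named list of input file paths (file mode): `space`,
#'   `responses`, `items`, `norm_high`, `norm_low`, `lexicon`, `controls`
#'   (controls optional).
#' @param scale a [scale_definition()] for the items.
#' @param construct construct label for the run.
#' @param cv_folds,cv_grid,seed cross-validation settings for the
#'   language-trained and valence models.
#' @param cor_method correlation method for the item tables (`"auto"`
#'   resolves on the scale total).
#' @param sdp_permutations,sdp_alpha supervised-dimension-projection
#'   settings; the SDP contrasts the bottom vs. top half of scale totals.
#' @return object of class `run_config`.
#' @export
run_config <- function(out_dir, synthetic = TRUE, generator = NULL,
                       paths = NULL, scale = phq9_definition(),
                       construct = "depression", cv_folds = 10L,
                       cv_grid = penalty_grid(), seed = 1L,
                       cor_method = "auto", sdp_permutations = 500L,
                       sdp_alpha = 0.05) {
  if (synthetic) {
    if (is.null(generator)) generator <- generator_config(seed = seed)
    scale <- generator$scale
    construct <- generator$construct
  } else {
    need <- c("space", "responses", "items", "norm_high", "norm_low", "lexicon")
    miss <- setdiff(need, names(paths))
    if (length(miss)) {
      stop(sprintf("configuration error: missing input path(s): %s",
                   paste(miss, collapse = ", ")))
    }
    absent <- unlist(paths[need])[!file.exists(unlist(paths[need]))]
    if (length(absent)) {
      stop(sprintf("configuration error: input file(s) not found: %s",
                   paste(absent, collapse = ", ")))
    }
  }
  structure(list(out_dir = out_dir, synthetic = synthetic,
                 generator = generator, paths = paths, scale = scale,
                 construct = construct, cv_folds = cv_folds,
                 cv_grid = cv_grid, seed = as.integer(seed),
                 cor_method = cor_method,
                 sdp_permutations = as.integer(sdp_permutations),
                 sdp_alpha = sdp_alpha),
            class = "run_config")
}

load_run_inputs <- function(config) {
  if (config$synthetic) {
    cohort <- simulate_cohort(config$generator)
    list(space = cohort$space, responses = cohort$responses,
         items = cohort$items, norms = cohort$norms,
         lexicon = cohort$lexicon, control_answers = cohort$control_answers,
         truth = cohort$truth)
  } else {
    p <- config$paths
    items_df <- utils::read.csv(p$items, stringsAsFactors = FALSE)
    item_cols <- grep("^item_", names(items_df), value = TRUE)
    items <- as.matrix(items_df[item_cols])
    rownames(items) <- items_df$participant_id
    list(space = load_space(p$space),
         responses = read_responses(p$responses),
         items = items,
         norms = list(high = read_norm(p$norm_high,
                                       paste0(config$construct, "-high")),
                      low = read_norm(p$norm_low,
                                      paste0(config$construct, "-low"))),
         lexicon = read_lexicon(p$lexicon),
         control_answers = if (!is.null(p$controls))
           utils::read.csv(p$controls, stringsAsFactors = FALSE) else NULL,
         truth = NULL)
  }
}

#' Run the end-to-end analysis
#'
#' Sequences the full assessment: attention filtering, semantic-scale
#' scoring of the word responses (computed before any rating-scale-derived
#' quantity, echoing the study design in which word responses precede the
#' rating scales), valence-model training and prediction, language-model
#' training per item and for the total, descriptives, the inter-measure
#' correlation matrix, the item-level table with partial correlations
#' controlling for valence, and the supervised dimension projection of the
#' words against a bottom/top-half split of the scale totals. All tables
#' are written as CSV, models as JSON, plus a manifest with the seeds,
#' counts and an input fingerprint; a rerun under an identical
#' configuration reproduces the files byte for byte.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages?
#' @return (invisibly) list with the computed objects: `scores`
#'   (per-participant scale-score table), `descriptives`, `correlations`,
#'   `item_table`, `sdp`, `models`, `reliability`, `exclusions`,
#'   `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  inputs <- load_run_inputs(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  def <- config$scale

  # 1. attention filter
  if (!is.null(inputs$control_answers)) {
    filt <- attention_filter(inputs$control_answers)
    say("stage attention_filter: %d of %d retained",
        length(filt$retained), length(filt$retained) + filt$n_excluded)
  } else {
    filt <- list(retained = vapply(inputs$responses, `[[`, "",
                                   "participant_id"),
                 excluded = data.frame(), n_excluded = 0L,
                 fraction_excluded = 0)
  }
  keep <- vapply(inputs$responses, function(r)
    r$participant_id %in% filt$retained, logical(1))
  responses <- inputs$responses[keep]
  ids <- vapply(responses, `[[`, "", "participant_id")
  items <- inputs$items[ids, , drop = FALSE]

  # 2. semantic similarity scales (scored before any rating-scale quantity)
  say("stage semantic_scales: scoring %d responses", length(responses))
  sss <- semantic_scale_scores(inputs$space, responses,
                               inputs$norms$high, inputs$norms$low)

  # 3. valence model + predicted valence
  say("stage valence_model: training on %d lexicon words",
      nrow(inputs$lexicon))
  valence_model <- train_valence_model(inputs$space, inputs$lexicon,
                                       folds = config$cv_folds,
                                       grid = config$cv_grid,
                                       seed = config$seed)
  val <- predicted_valence(valence_model, inputs$space, responses)

  # 4. rating-scale totals and language-trained models
  totals <- scale_total(items, def)
  X <- t(vapply(responses, function(r)
    as.numeric(embed_response(inputs$space, r)), numeric(inputs$space$d)))
  say("stage language_models: total + %d items", def$n_items)
  total_model <- train_language_model(X, totals, folds = config$cv_folds,
                                      grid = config$cv_grid,
                                      seed = config$seed)
  item_models <- lapply(seq_len(def$n_items), function(j) {
    train_language_model(X, items[, j], folds = config$cv_folds,
                         grid = config$cv_grid, seed = config$seed + j)
  })

  scores <- data.frame(
    participant_id = ids,
    total = totals,
    unipolar_high = sss$unipolar_high,
    unipolar_low = sss$unipolar_low,
    bipolar = sss$bipolar,
    language_trained = total_model$cv_predictions,
    predicted_valence = val$predicted_valence,
    stringsAsFactors = FALSE, row.names = NULL)

  # 5. descriptives, reliability, correlations
  meas <- c("total", "unipolar_high", "bipolar", "language_trained",
            "predicted_valence")
  desc <- do.call(rbind, lapply(meas, function(m) {
    d <- descriptives(scores[[m]])
    data.frame(measure = m, mean = d$mean, sd = d$sd, range = d$range,
               skew = d$skew, kurtosis = d$kurtosis, stringsAsFactors = FALSE)
  }))
  rel <- reliability(items)
  method <- config$cor_method
  if (method == "auto") {
    method <- correlate(scores$bipolar, totals, method = "auto")$method
  }
  cors <- outer_correlations(scores[meas], method)

  # 6. item-level table
  preds <- list(unipolar = scores$unipolar_high, bipolar = scores$bipolar,
                language_trained = scores$language_trained,
                predicted_valence = scores$predicted_valence)
  item_tab <- item_level_table(items, def, preds,
                               valence_scores = scores$predicted_valence,
                               partial_for = "language_trained",
                               method = method)

  # 7. supervised dimension projection: bottom vs top half of totals
  say("stage sdp: %d permutations", config$sdp_permutations)
  grp <- ifelse(totals > stats::median(totals), "high", "low")
  sdp <- sdp_projection(inputs$space, responses,
                        factor(grp, levels = c("low", "high")),
                        external_scores = totals,
                        n_permutations = config$sdp_permutations,
                        seed = config$seed, alpha = config$sdp_alpha)

  # 8. write artifacts
  o <- function(f) file.path(config$out_dir, f)
  utils::write.csv(scores, o("scores.csv"), row.names = FALSE)
  utils::write.csv(desc, o("descriptives.csv"), row.names = FALSE)
  utils::write.csv(cors, o("correlations.csv"), row.names = TRUE)
  utils::write.csv(as.data.frame(item_tab), o("item_table.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(sdp), o("sdp.csv"), row.names = FALSE)
  write_model(total_model, o("model_total.json"))
  write_model(valence_model, o("model_valence.json"))

  manifest <- list(
    seed = config$seed,
    construct = config$construct,
    scale_id = def$scale_id,
    synthetic = config$synthetic,
    n_submitted = length(inputs$responses),
    n_retained = length(responses),
    n_excluded = filt$n_excluded,
    correlation_method = method,
    reliability = list(alpha = rel$alpha, omega = rel$omega),
    cutoff_proportion = if (!is.na(def$cutoff))
      cutoff_proportion(totals, def$cutoff) else NA,
    input_fingerprint = input_fingerprint(inputs),
    r_version = as.character(getRversion()))
  jsonlite::write_json(manifest, o("manifest.json"), auto_unbox = TRUE,
                       digits = NA)

  invisible(list(scores = scores, descriptives = desc, correlations = cors,
                 item_table = item_tab, sdp = sdp,
                 models = list(total = total_model, items = item_models,
                               valence = valence_model),
                 reliability = rel, exclusions = filt, manifest = manifest,
                 truth = inputs$truth))
}

outer_correlations <- function(df, method) {
  nm <- names(df)
  m <- matrix(NA_real_, length(nm), length(nm), dimnames = list(nm, nm))
  for (i in seq_along(nm)) for (j in seq_along(nm)) {
    if (i == j) m[i, j] <- 1 else
      m[i, j] <- correlate(df[[i]], df[[j]], method = method)$estimate
  }
  as.data.frame(m)
}

# Deterministic fingerprint of the run's numeric inputs (no file hashing so
# synthetic and file-based runs fingerprint identically for identical data).
input_fingerprint <- function(inputs) {
  fmt <- function(x) paste(formatC(x, digits = 10, format = "g"),
                           collapse = ",")
  parts <- c(fmt(inputs$space$vectors),
             paste(vapply(inputs$responses, function(r)
               paste(r$participant_id, paste(r$tokens, collapse = "+")),
               character(1)), collapse = ";"),
             fmt(inputs$items),
             fmt(inputs$lexicon$valence_mean))
  s <- paste(parts, collapse = "|")
  # 32-bit FNV-1a over the serialized inputs; the multiply is split into
  # 16-bit halves so every intermediate stays inside the double mantissa
  h <- 2166136261
  p <- 16777619
  for (b in utf8ToInt(s)) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    h <- ((h %% 65536) * p + ((h %/% 65536 * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
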