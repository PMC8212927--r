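---
title: "Question-based computational language assessment: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Question-based computational language assessment: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qcla)
```

## The measurement problem

Rating scales such as the PHQ-9, GAD-7 and PSWQ-8 measure depression,
generalized anxiety and pathological worry with fixed items written by
professionals. Question-based computational language assessment (QCLA)
instead asks respondents to describe their state in their own words — for
example five descriptive words about being depressed over the last two
weeks — and quantifies those words with embeddings from a semantic space.
Three families of measures are derived:

* **Semantic similarity scales.** A *word norm* is an empirically collected
  bag of words describing one pole of a construct ("being depressed",
  "not at all depressed"), with a designated target word whose frequency is
  set to one more than the next-most-frequent word. The *unipolar* scale is
  the cosine similarity between a response's mean embedding and a norm's
  frequency-weighted mean embedding; the *bipolar* scale is the similarity
  to the high pole minus the similarity to the low pole. Because the two
  pole norms share much general mood vocabulary, the subtraction cancels
  that shared component, which is why bipolar scores track severity more
  closely than unipolar scores.
* **Language-trained scales.** A cross-validated ridge regression
  `y = b0 + b1 x1 + ... + bd xd + e` maps embedding dimensions to a
  rating-scale item or total. Accuracy is the Pearson correlation between
  pooled out-of-fold predictions and observed scores.
* **Language-predicted valence.** The same ridge machinery trained on an
  affective word-norms lexicon (words rated 1 = unpleasant to 9 = pleasant)
  and applied to responses. Partial correlations controlling for predicted
  valence ask how much of a language-trained scale's item correlation is
  carried by general affective tone.

The item-level layer connects these measures to the DSM-5 criterion
structure: PHQ-9 items 1–2 (loss of interest, depressed mood) and GAD-7
items 2–3 (uncontrollable worry, worrying too much) map onto primary
criteria, the remaining items onto secondary ones; all PSWQ-8 items name
the worry construct directly. The central substantive contrast is whether
word-based measures correlate more with primary- than secondary-criterion
items.

## Semantic spaces

`build_space()` constructs an embedding space in the latent-semantic-
analysis style: a symmetric word co-occurrence table within a sliding
window, optionally `log1p`-weighted, compressed by singular value
decomposition. Word vectors are the left singular vectors scaled by the
singular values, truncated to `d` dimensions (default 512, matching
reference spaces of this kind; toy corpora use 2–16). Two conventions make
the result reproducible across linear-algebra backends: each singular
vector's sign is fixed so its largest-magnitude element is positive, and
vocabulary order is frequency with first-appearance tie-breaks. Whether
reference spaces scale by singular values or length-normalize is not
documented anywhere we know of; unnormalized `U %*% diag(s)` is the
default and the choice is recorded in the space's provenance string.

Tokens are lowercased, stripped of surrounding punctuation and
NFC-normalized; spelling correction is treated as a manual preprocessing
step outside the package. Response embeddings are plain token means:
duplicated words count once per occurrence (the mean over five answer
boxes, read literally), out-of-vocabulary tokens are skipped with counts
recorded (`oov_policy = "error"` makes them fatal), and a response whose
tokens are all out of vocabulary raises an error naming the participant.
Norm embeddings weight words by frequency so the target word's deliberate
dominance survives aggregation; `weight = "unique"` averages distinct
words instead. A norm losing more than half its tokens to the vocabulary
warns.

## The cross-validated ridge model

`train_language_model()` is the package's central fitted object. Fitting
conventions, each of which was a genuinely open choice:

* **Standardization.** Each embedding dimension is centered and unit-scaled
  using the training rows only; coefficients are stored on that scale and
  `predict()` re-applies the stored constants. At fixed penalty the
  coefficients equal the closed form `(Xs'Xs + lambda I)^-1 Xs' yc`,
  computed through the SVD of `Xs`.
* **Penalty grid.** `10^(-16:16)`, 33 values spanning effectively
  unpenalized to intercept-only fits.
* **Tuning.** Within each of 10 outer folds, a seeded 75% analysis / 25%
  assessment split; all candidate penalties are fit on the analysis
  portion and scored on the assessment portion by root-mean-square error,
  with ties resolved toward stronger shrinkage. Each outer fold refits at
  its selected penalty on the full training fold and predicts its held-out
  rows.
* **Fold assignment** is a seeded shuffle *stratified on the outcome*:
  consecutive blocks of sorted `y` are spread across folds. This standard
  practice matters more than it looks. With unstratified folds, a response
  unrelated to the embeddings drives the tuner to the intercept-only end
  of the grid, and pooled out-of-fold predictions then consist of fold
  means — which are structurally anti-correlated with their held-out
  folds, biasing the pooled accuracy to roughly `-sqrt(folds/n)` (about
  −0.12 at n = 400, k = 10) even when nothing is predictable.
  Stratification equalizes fold outcome distributions and removes the
  artifact; the package's null-calibration tests verify that accuracies
  then center on zero. (Tuning by assessment-set correlation instead was
  considered and rejected: correlation is scale-blind, so heavily shrunk
  near-constant candidates win folds on noise and degrade pooled
  predictions measurably.)
* **Accuracy** is one Pearson correlation over the pooled out-of-fold
  predictions — reading "the predicted value is correlated with the
  empirical value" as a single correlation — not a mean of per-fold
  correlations.
* **The deployed model** refits on all rows at the penalty selected most
  often across folds, ties toward stronger shrinkage; the accuracy
  definition above constrains only `cv_accuracy`, so the deployment rule
  is a package convention recorded in the model object.

`train_valence_model()` reuses this machinery with one row per lexicon
word found in the vocabulary (at least 50 required); leave-k-out style
tuning is the same k-fold procedure with configurable `folds`.
Predictions from `predicted_valence()` are deliberately not clipped to
the lexicon's 1–9 bounds.

## Item-level statistics

* `descriptives()` reports the n−1 standard deviation, max−min range, the
  adjusted Fisher–Pearson skewness G1 and adjusted excess kurtosis G2
  (`e1071` type 2); kurtosis is `NA` below n = 4 where its estimator is
  undefined.
* `correlate(method = "auto")` selects Spearman when the outcome looks
  non-normal — Shapiro–Wilk p < 0.05 (on at most 5000 values) or
  |skewness| > 0.2 — mirroring the convention of using rank correlations
  for positively skewed screening totals and Pearson otherwise. Both
  methods report the two-tailed t-approximation p-value on n−2 degrees of
  freedom (so Spearman p-values differ slightly from exact-rank methods);
  stars follow the 0.05/0.01/0.001 convention.
* `partial_correlation()` implements the first-order formula
  `(r_xy − r_xz r_zy) / sqrt((1−r_xz²)(1−r_zy²))` with p on n−3 degrees of
  freedom; it equals the correlation of residuals from regressing each
  variable on the control, which the test suite checks against `lm()`.
* `reliability()` computes Cronbach's alpha from the variance identity and
  McDonald's omega-total from a one-factor maximum-likelihood solution
  (`stats::factanal`) on the item correlation matrix:
  `(sum l)² / ((sum l)² + sum(1 − l²))`. The estimator is recorded in the
  output; a minimum-residual solution would differ negligibly for the
  well-behaved item sets considered here.
* `scale_total()` validates response bounds before summing; missing
  responses are fatal by default or dropped listwise with a logged count.
  The PSWQ-8 definition defaults to the printed 0–5 anchors but accepts
  1–5, since published totals are consistent with either encoding and the
  package asserts neither.

## Supervised dimension projection

The word plot places each word on the dimension separating two groups of
responses: the direction embedding is the difference of the groups' mean
word embeddings (second factor level positive); each word is centered at
the mean embedding of all words and projected by dot product.

The permutation test shuffles group labels across *responses* — tokens
within a response are dependent, so the response is the exchangeable
unit — and recomputes the direction and all projections each time
(`fixed_direction = TRUE` switches to a cheap word-rank null against the
observed projection distribution instead). Two-sided p-values use add-one
smoothing, so 999 permutations bound p below by 1/1000;
Benjamini–Hochberg q-values (`stats::p.adjust`) control the FDR across
words and drive the significance coloring.

One subtlety is deliberate: the test statistic projects onto the *unit*
direction. With raw dot products, every word's null comparison shares the
single observed direction's norm, so the collection of p-values rises and
falls together with that one random realization — the null rejection rate
then fluctuates far outside its nominal level from dataset to dataset.
Dividing out the norm conditions on it and keeps the test calibrated
realization by realization. The cost is conservatism when the group
contrast lies along the data's dominant variance direction, since random
splits also point that way; `statistic = "raw"` is available when the
magnitude of the separation is the question. Font sizes in `plot_data()`
grow linearly in `log(1 + frequency)` between configurable bounds.

## The synthetic cohort generator

No participant data from studies of this design are publicly deposited,
so the package ships a generator whose defaults define the conditions
under which everything is validated:

* **Space.** Four word clusters (40 construct-high, 40 construct-low, 60
  neutral, 60 filler words) in d = 32 dimensions, drawn around centroids
  with within-cluster SD 0.5. The high and low centroids sit at ±2 along
  a random unit *severity axis* (separation 4) and share a common
  component of norm 2 orthogonal to it — real pole norms share general
  mood vocabulary, so the poles must not be geometric opposites; this
  shared component is exactly what the bipolar subtraction cancels. The
  separation-to-spread ratio keeps the pole clusters linearly separable
  by construction. d = 32 (not 512) keeps the validation suite fast while
  preserving every geometric property under test.
* **Participants.** n = 400 by default. Latent severity θ ~ N(0, 1) drives
  word choice through a softmax with weight `exp(θ·loading/temperature)`
  (loadings +1/−1/0 for high/low/other words, temperature 0.8) and item
  responses through a discretized linear factor model: item j discretizes
  the standardized latent `a_j θ + ε` (noise SD 1.2) through a common set
  of positively skewed thresholds (category probabilities proportional to
  k, k−1, …, 1), giving screening-scale-like skewed items. Items flagged
  as primary criteria load a_j = 1.4 versus 0.7 for secondary items, so
  the primary-over-secondary contrast is planted and recoverable — a
  documented design feature, not an empirical claim.
* **Norms.** 110 norm participants × 10 words per pole, drawn from the
  matching cluster with probability 0.8 (else neutral), target word
  injected under the most-frequent-by-1 rule.
* **Valence lexicon.** Every vocabulary word rated
  `5 − (axis coordinate) + noise` (SD 0.5), clipped to 1–9, with the
  neutral anchor word "cat" pinned at 4.38 (SD 2.24) in the style of the
  canonical affective norms entry.
* **Attention controls.** Two control items per participant; 9.7% of
  participants fail one at random, matching the exclusion rate such
  crowdsourced studies report.

Determinism is strict: one configuration and seed give bit-identical
cohorts, and the pipeline's manifest carries a fingerprint of the numeric
inputs. What the generator does *not* emulate: real word-frequency
distributions, multi-word answers, misspellings, attrition, demographic
structure, or any nonlinear relation between embeddings and severity.
Passing tests therefore show that the estimators recover planted
structure of this simple kind — they say nothing about embedding quality
or construct validity on real language.

## Validation problem sizes

The test suite exercises the oracle equivalences (cosine, closed-form
ridge, BH step-up, partial-correlation residual identity, co-occurrence
SVD) at small dimensions; CV calibration runs 20 seeds at n = 400,
d = 20 for both a planted R² of 0.5 and a null response; permutation
calibration uses 2000 words at 499 shuffles; reliability closed forms use
n = 5000 simulees; the end-to-end recovery checks run the default n = 400
cohort. `scripts/acceptance.R` reruns the full pipeline at a
caller-chosen seed and writes the headline quantities as JSON.

## Known limitations

* The spaces built here are bag-of-context SVD embeddings; contextual
  (transformer) embeddings are out of scope.
* Spearman p-values use the t approximation rather than exact rank
  distributions; at the n of interest (hundreds) the difference is in the
  third decimal.
* Omega assumes a one-factor model; it is not reported for scales where
  the one-factor solution fails to converge.
* The SDP permutation test's default orientation statistic is
  conservative for contrasts aligned with the dominant variance axis (see
  above); interpret an absence of significant words accordingly.
* Clinical screening cut-offs are applied to rating-scale totals only;
  the package deliberately provides no cut-offs on semantic scores.
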