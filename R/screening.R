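#' Total score of one SPS response
#'
#' The Suicidal Possibility Scale (SPS) has 36 self-rating items answered on
#' a 4-point scale (1-4); the total score is the plain item sum, ranging
#' from 36 to 144.
#'
#' @param items integer vector of exactly 36 responses, each in 1..4.
#' @return Integer total.
#' @export
sps_total <- function(items) {
  if (length(items) != 36)
    stop("SPS requires exactly 36 item responses, got ", length(items))
  it <- suppressWarnings(as.integer(items))
  if (any(is.na(it)) || any(it != items) || any(it < 1 | it > 4))
    stop("SPS item responses must be integers in {1, 2, 3, 4}")
  sum(it)
}

#' Read SPS questionnaire responses from a wide CSV
#'
#' Expected header: `user_id,item_01,...,item_36`, responses 1-4.
#'
#' @param path CSV file path.
#' @return Data frame with `user_id`, the 36 item columns, and `total`.
#' @export
read_sps <- function(path) {
  if (!file.exists(path)) stop("SPS file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  item_cols <- sprintf("item_%02d", 1:36)
  missing <- setdiff(c("user_id", item_cols), names(d))
  if (length(missing) > 0)
    stop("SPS file missing column(s): ", paste(missing, collapse = ", "))
  d$total <- vapply(seq_len(nrow(d)),
                    function(i) sps_total(as.integer(d[i, item_cols])),
                    integer(1))
  d[c("user_id", item_cols, "total")]
}

#' High-risk cutoff from an SPS score distribution
#'
#' The cutoff is the sample mean plus one sample standard deviation (n - 1
#' denominator) of the observed totals; e.g. a distribution with mean 69.35
#' and SD 11.66 yields 81.01.
#'
#' @param scores numeric vector of SPS totals, length >= 2.
#' @return The cutoff (mean + SD).
#' @export
sps_threshold <- function(scores) {
  if (length(scores) < 2)
    stop("at least 2 scores are required (SD undefined otherwise)")
  mean(scores) + stats::sd(scores)
}

#' Label users as high vs non-high risk by SPS total
#'
#' A user is `high` if and only if the total is strictly greater than the
#' threshold ("scored more than" the cutoff); totals equal to the threshold
#' go to `non_high`.
#'
#' @param totals numeric vector of SPS totals.
#' @param threshold cutoff, typically from [sps_threshold()].
#' @param user_id optional ids; defaults to `names(totals)` or row index.
#' @return Data frame with `user_id`, `total`, `group` (factor with levels
#'   `high`, `non_high`) and `threshold_used`.
#' @export
label_groups <- function(totals, threshold, user_id = NULL) {
  if (is.null(user_id))
    user_id <- if (!is.null(names(totals))) names(totals)
  else as.character(seq_along(totals))
  data.frame(user_id = user_id, total = totals,
             group = factor(ifelse(totals > threshold, "high", "non_high"),
                            levels = c("high", "non_high")),
             threshold_used = threshold, stringsAsFactors = FALSE)
}

#' F-measure (harmonic mean of precision and recall)
#'
#' @param precision,recall values in \[0, 1\].
#' @return `2 * p * r / (p + r)`, or 0 when `p + r == 0`. The F-measure lies
#'   between `min(p, r)` and `max(p, r)` and is symmetric in its arguments.
#' @export
f_measure <- function(precision, recall) {
  if (any(precision < 0 | precision > 1) || any(recall < 0 | recall > 1))
    stop("precision and recall must lie in [0, 1]")
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Round half away from zero
#'
#' Conventional "round half up" at `digits` decimals (base R's `round()`
#' rounds half to even), used when reporting metrics to the 2-decimal
#' precision of published tables.
#'
#' @param x numeric vector.
#' @param digits number of decimals.
#' @return Rounded values.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Precision, recall and F-measure of predicted risk groups
#'
#' Precision is the fraction of predicted-positive users that are truly
#' positive; recall is the fraction of truly positive users that were
#' retrieved. Zero-denominator cases return 0 and are flagged.
#'
#' @param predicted,actual factors or character vectors of equal length with
#'   values in `{high, non_high}`.
#' @param positive_class the positive label (default `"high"`).
#' @return List of class `evaluation_report`: `precision`, `recall`,
#'   `f_measure`, `n`, `tp`, `fp`, `fn`, and `degenerate` (TRUE when a
#'   zero-denominator convention was applied).
#' @export
evaluate_classification <- function(predicted, actual,
                                    positive_class = "high") {
  if (length(predicted) != length(actual))
    stop("predicted and actual must have equal length")
  if (length(actual) < 1) stop("need at least one observation")
  pred_pos <- as.character(predicted) == positive_class
  act_pos <- as.character(actual) == positive_class
  tp <- sum(pred_pos & act_pos)
  fp <- sum(pred_pos & !act_pos)
  fn <- sum(!pred_pos & act_pos)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  structure(list(precision = precision, recall = recall,
                 f_measure = f_measure(precision, recall),
                 n = length(actual), tp = tp, fp = fp, fn = fn,
                 degenerate = (tp + fp == 0) || (tp + fn == 0)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("precision %.2f  recall %.2f  F %.2f  (n = %d)\n",
              round_half_up(x$precision), round_half_up(x$recall),
              round_half_up(x$f_measure), x$n))
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' Thin validated wrapper around [stats::cor()]: requires equal lengths
#' (n >= 3) and nonzero variance in both vectors, the conditions under
#' which the convergent-validity correlation is defined.
#'
#' @param x,y numeric vectors.
#' @return Sample correlation in \[-1, 1\].
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance")
  stats::cor(x, y)
}

feature_matrix <- function(features) {
  if (is.data.frame(features)) {
    cols <- intersect(lexicon_categories(), names(features))
    if (length(cols) == 0)
      stop("no category-ratio columns found in features")
    m <- as.matrix(features[cols])
    rownames(m) <- features$user_id
    m
  } else as.matrix(features)
}

#' Train a margin classifier on category-ratio features
#'
#' Fits a support vector machine (linear kernel, unit cost by default,
#' features standardised on the training data) mapping per-user
#' category-ratio vectors to the high / non-high risk groups. The fit is
#' deterministic given the data and settings.
#'
#' @param features feature data frame from [extract_features()] (category
#'   columns are used) or a numeric matrix.
#' @param labels factor/character vector of group labels aligned with the
#'   feature rows; both classes must be present.
#' @param cost SVM regularisation cost (default 1).
#' @param kernel kernel name passed to [e1071::svm()] (default "linear").
#' @param scale standardise features on the training data (default TRUE).
#' @param class_weights `NULL` (default, unweighted), `"balanced"` (inverse
#'   training-class prevalence; useful when the high-risk group is a small
#'   tail of the sample) or a named numeric vector of per-class weights.
#' @return Object of class `risk_classifier` wrapping the fitted SVM.
#' @export
train_classifier <- function(features, labels, cost = 1, kernel = "linear",
                             scale = TRUE, class_weights = NULL) {
  x <- feature_matrix(features)
  y <- factor(as.character(labels), levels = c("high", "non_high"))
  if (nrow(x) != length(y)) stop("features and labels must align")
  if (nlevels(droplevels(y)) < 2)
    stop("training set contains a single class; both groups are required")
  if (identical(class_weights, "balanced"))
    class_weights <- 1 / prop.table(table(y))
  # constant columns cannot be standardised; exclude them from scaling
  scale_cols <- if (isTRUE(scale)) apply(x, 2, stats::sd) > 0 else FALSE
  fit <- if (is.null(class_weights))
    e1071::svm(x, y, kernel = kernel, cost = cost, scale = scale_cols,
               type = "C-classification")
  else
    e1071::svm(x, y, kernel = kernel, cost = cost, scale = scale_cols,
               type = "C-classification", class.weights = class_weights)
  structure(list(fit = fit, settings = list(kernel = kernel, cost = cost,
                                            scale = scale,
                                            class_weights = class_weights)),
            class = "risk_classifier")
}

#' @export
predict.risk_classifier <- function(object, newdata, ...) {
  x <- feature_matrix(newdata)
  factor(as.character(predict(object$fit, x)), levels = c("high", "non_high"))
}

#' @export
print.risk_classifier <- function(x, ...) {
  cat("<risk_classifier>", x$settings$kernel, "SVM, cost",
      x$settings$cost, "-", x$fit$tot.nSV, "support vectors\n")
  invisible(x)
}

stratified_folds <- function(y, folds, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  fold
}

#' Stratified cross-validated evaluation of the risk classifier
#'
#' Splits users into `folds` stratified folds, trains on each training
#' partition and predicts the held-out fold; reports per-fold precision,
#' recall and F plus their means and the metrics of the pooled out-of-fold
#' predictions.
#'
#' @param features,labels as in [train_classifier()].
#' @param folds number of folds (default 5).
#' @param seed integer seed controlling the fold assignment.
#' @param ... passed to [train_classifier()].
#' @return List of class `cv_report`: `per_fold` (data frame), `mean`
#'   (averaged fold metrics), `pooled` (an [evaluate_classification()]
#'   report over all out-of-fold predictions), `folds`, `seed`, `settings`.
#' @export
cross_validate <- function(features, labels, folds = 5, seed = 1, ...) {
  x <- feature_matrix(features)
  y <- factor(as.character(labels), levels = c("high", "non_high"))
  if (min(table(y)) < folds)
    stop("each class needs at least `folds` members for stratified CV")
  fold <- stratified_folds(y, folds, seed)
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  per_fold <- data.frame(fold = seq_len(folds), precision = NA_real_,
                         recall = NA_real_, f_measure = NA_real_)
  for (f in seq_len(folds)) {
    tr <- fold != f
    model <- train_classifier(x[tr, , drop = FALSE], y[tr], ...)
    pf <- predict(model, x[!tr, , drop = FALSE])
    pred[!tr] <- pf
    ev <- evaluate_classification(pf, y[!tr])
    per_fold[f, 2:4] <- c(ev$precision, ev$recall, ev$f_measure)
  }
  structure(list(
    per_fold = per_fold,
    mean = colMeans(per_fold[2:4]),
    pooled = evaluate_classification(pred, y),
    folds = folds, seed = seed, settings = list(...)
  ), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold CV (seed %d): mean precision %.2f, recall %.2f, F %.2f\n",
              x$folds, x$seed, round_half_up(x$mean["precision"]),
              round_half_up(x$mean["recall"]),
              round_half_up(x$mean["f_measure"])))
  invisible(x)
}

#' Permutation-null F-measure for the risk classifier
#'
#' Repeats the cross-validated evaluation with labels randomly permuted
#' (seeded), giving the F-measure expected under no association between
#' features and groups — the chance baseline against which the real
#' cross-validated F is compared.
#'
#' @param features,labels,folds as in [cross_validate()].
#' @param n_perm number of label permutations (default 20).
#' @param seed integer seed (drives both permutations and fold splits).
#' @param ... passed to [train_classifier()].
#' @return List with `f_null` (mean pooled F over permutations), `f_perm`
#'   (per-permutation values) and `n_perm`.
#' @export
permutation_null <- function(features, labels, folds = 5, n_perm = 20,
                             seed = 1, ...) {
  y <- factor(as.character(labels), levels = c("high", "non_high"))
  set.seed(seed)
  perm_seeds <- sample.int(1e6, n_perm)
  f_perm <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    set.seed(perm_seeds[p])
    yp <- sample(y)
    cv <- cross_validate(features, yp, folds = folds, seed = perm_seeds[p],
                         ...)
    f_perm[p] <- cv$pooled$f_measure
  }
  list(f_null = mean(f_perm), f_perm = f_perm, n_perm = n_perm)
}
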