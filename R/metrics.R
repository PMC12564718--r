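# Metrics, stratified k-fold cross-validation and rank-based model
# comparison.

#' Confusion counts and threshold metrics
#'
#' Positive class is 1. Ratios with a zero denominator are reported as 0 and
#' flagged (`undefined` lists which metrics were degenerate).
#'
#' @param labels Binary vector of reference labels.
#' @param predictions Binary vector of hard predictions.
#' @return A list with `tp`, `fp`, `tn`, `fn`, `precision`, `recall`, `f1`,
#'   `specificity` and `undefined` (character vector of flagged metrics).
#' @export
confusion_and_rates <- function(labels, predictions) {
  if (length(labels) != length(predictions)) {
    stop_validation("labels and predictions must have equal length")
  }
  if (length(labels) < 1L) stop_validation("need at least one sample")
  labels <- as.integer(labels)
  predictions <- as.integer(predictions)
  tp <- sum(labels == 1L & predictions == 1L)
  fp <- sum(labels == 0L & predictions == 1L)
  tn <- sum(labels == 0L & predictions == 0L)
  fn <- sum(labels == 1L & predictions == 0L)
  undefined <- character(0)
  safe <- function(num, den, name) {
    if (den == 0L) {
      undefined <<- c(undefined, name)
      0
    } else {
      num / den
    }
  }
  precision <- safe(tp, tp + fp, "precision")
  recall <- safe(tp, tp + fn, "recall")
  specificity <- safe(tn, tn + fp, "specificity")
  f1 <- if (precision + recall == 0) {
    undefined <- c(undefined, "f1")
    0
  } else {
    2 * precision * recall / (precision + recall)
  }
  if (length(undefined)) {
    warning("degenerate denominator for: ", paste(undefined, collapse = ", "),
            "; reported as 0", call. = FALSE)
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn, precision = precision,
       recall = recall, f1 = f1, specificity = specificity,
       undefined = undefined)
}

#' Area under the ROC curve
#'
#' Rank-based with midranks for ties; identical to the Mann-Whitney U
#' statistic of positive-class scores divided by `n_pos * n_neg`.
#'
#' @param scores Numeric scores (larger means more positive).
#' @param labels Binary labels.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop_validation("AUROC needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average precision: the sum over positives, in score-descending
#' order, of precision at each positive's rank times the recall increment.
#' No linear interpolation in PR space.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (at least one positive).
#' @return AUPRC in `(0, 1]`.
#' @export
auprc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  if (n1 == 0L) stop_validation("AUPRC needs at least one positive")
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  tp_cum <- cumsum(y)
  prec <- tp_cum / seq_along(y)
  sum(prec[y == 1L]) / n1
}

#' Full per-fold metric report from scores
#'
#' @param labels Binary labels.
#' @param scores Numeric scores in `[0, 1]`.
#' @param threshold Classification threshold; predictions are
#'   `scores >= threshold` (default 0.5).
#' @return A one-row data.frame with precision, recall, f1, specificity,
#'   auprc, auroc and the confusion counts.
#' @export
fold_report <- function(labels, scores, threshold = 0.5) {
  cm <- suppressWarnings(confusion_and_rates(labels, as.integer(scores >= threshold)))
  data.frame(precision = cm$precision, recall = cm$recall, f1 = cm$f1,
             specificity = cm$specificity,
             auprc = auprc(scores, labels), auroc = auroc(scores, labels),
             tp = cm$tp, fp = cm$fp, tn = cm$tn, fn = cm$fn)
}

# Stratified fold assignment: shuffle within class, deal round-robin.
stratified_folds <- function(labels, k, seed) {
  labels <- as.integer(labels)
  if (any(table(labels) < k)) {
    stop_validation("every class needs at least k samples for stratified folds")
  }
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Stratified k-fold cross-validation
#'
#' Partitions the dataset into k stratified folds; for each fold the trainer
#' fits on the remainder (handling its own internal validation and model
#' selection) and is scored on the held-out fold. Fold metrics are averaged
#' with the arithmetic mean and reported with two-sided t-intervals on
#' `k - 1` degrees of freedom.
#'
#' @param dataset A data.frame with a `label` column, or a list of records
#'   each carrying `$label`.
#' @param trainer Function `(train, test, fold_seed) -> numeric scores` for
#'   the test subset, scores in `[0, 1]`.
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the fold assignment and fold seeds.
#' @param threshold Classification threshold for threshold metrics.
#' @param alpha Significance level for the confidence intervals (default
#'   0.05, i.e. 95% intervals).
#' @return An object of class `rac_cv_report`: `k`, `per_fold` (data.frame),
#'   `mean`, `ci` (lower/upper per metric), `alpha`, and the pooled
#'   out-of-fold `scores`/`labels`.
#' @export
kfold_cv <- function(dataset, trainer, k = 5L, seed = 1L, threshold = 0.5,
                     alpha = 0.05) {
  k <- check_count(k, "k")
  labels <- ds_labels(dataset)
  n <- length(labels)
  if (n < k) stop_validation("dataset smaller than k")
  fold <- stratified_folds(labels, k, seed)
  metrics <- c("precision", "recall", "f1", "specificity", "auprc", "auroc")
  per_fold <- vector("list", k)
  oof_scores <- numeric(n)
  for (i in seq_len(k)) {
    test_idx <- which(fold == i)
    train_idx <- which(fold != i)
    scores <- trainer(ds_subset(dataset, train_idx), ds_subset(dataset, test_idx),
                      child_seed(seed, paste0("fold", i)))
    oof_scores[test_idx] <- scores
    rep_i <- fold_report(labels[test_idx], scores, threshold)
    per_fold[[i]] <- cbind(fold_index = i, rep_i)
  }
  per_fold <- do.call(rbind, per_fold)
  means <- vapply(metrics, function(m) mean(per_fold[[m]]), numeric(1))
  ci <- lapply(metrics, function(m) {
    x <- per_fold[[m]]
    se <- stats::sd(x) / sqrt(k)
    half <- if (se == 0) 0 else stats::qt(1 - alpha / 2, df = k - 1) * se
    c(lower = mean(x) - half, upper = mean(x) + half)
  })
  names(ci) <- metrics
  structure(list(k = k, per_fold = per_fold, mean = as.list(means), ci = ci,
                 alpha = alpha, scores = oof_scores, labels = labels),
            class = "rac_cv_report")
}

#' @export
print.rac_cv_report <- function(x, ...) {
  cat("<rac_cv_report>", x$k, "folds\n")
  for (m in names(x$mean)) {
    cat(sprintf("  %-12s %.3f  [%.3f, %.3f]\n", m, x$mean[[m]],
                x$ci[[m]]["lower"], x$ci[[m]]["upper"]))
  }
  invisible(x)
}

ds_labels <- function(dataset) {
  if (is.data.frame(dataset)) {
    as.integer(dataset$label)
  } else {
    vapply(dataset, function(r) as.integer(r$label), integer(1))
  }
}

ds_subset <- function(dataset, idx) {
  if (is.data.frame(dataset)) dataset[idx, , drop = FALSE] else dataset[idx]
}

#' Mann-Whitney U comparison of two metric samples
#'
#' Two-sided test on the fold-level metric values of two models. Uses the
#' exact permutation null (with midranks, so ties are handled exactly) when
#' both samples have at most 8 values, and the tie-corrected normal
#' approximation otherwise. Significance is declared iff `p < alpha`
#' (strictly).
#'
#' @param metric_a,metric_b Numeric vectors (at least 3 values each).
#' @param alpha Significance level (default 0.05).
#' @return A list with `U` (the smaller of the two U statistics), `p_value`,
#'   `significant`, and `method`.
#' @export
compare_models <- function(metric_a, metric_b, alpha = 0.05) {
  n1 <- length(metric_a)
  n2 <- length(metric_b)
  if (n1 < 3L || n2 < 3L) stop_validation("need at least 3 values per sample")
  r <- rank(c(metric_a, metric_b), ties.method = "average")
  U1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  U2 <- n1 * n2 - U1
  mu <- n1 * n2 / 2
  obs_dev <- abs(U1 - mu)
  if (n1 <= 8L && n2 <= 8L) {
    combos <- utils::combn(n1 + n2, n1)
    devs <- abs(colSums(matrix(r[combos], nrow = n1)) -
                  n1 * (n1 + 1) / 2 - mu)
    p <- mean(devs >= obs_dev - 1e-12)
    method <- "exact permutation (midranks)"
  } else {
    n <- n1 + n2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma <- sqrt(n1 * n2 / 12 * (n + 1 - tie_term))
    p <- if (sigma == 0) 1 else min(1, 2 * stats::pnorm(-obs_dev / sigma))
    method <- "normal approximation with tie correction"
  }
  list(U = min(U1, U2), p_value = p, significant = p < alpha, method = method)
}

#' Serialise a CV report to the metrics JSON schema
#'
#' @param report An `rac_cv_report`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_cv_report <- function(report, path) {
  stopifnot(inherits(report, "rac_cv_report"))
  out <- list(k = report$k,
              per_fold = report$per_fold,
              mean = report$mean,
              ci95 = lapply(report$ci, as.list),
              alpha = report$alpha)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
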