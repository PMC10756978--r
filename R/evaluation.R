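#' One-vs-rest confusion counts and the K x K confusion matrix
#'
#' For each class `k`, TP counts samples of class `k` predicted `k`, FP
#' counts other-class samples predicted `k`, FN counts class-`k` samples
#' predicted otherwise, and TN the rest; `TP + FP + TN + FN` equals the
#' total sample count for every class.
#'
#' @param y_true,y_pred Equal-length integer class-index vectors (0-based).
#' @param n_classes Number of classes K (default: inferred).
#' @return A `confusion_counts`: list with `matrix` (K x K, rows = true
#'   class) and `per_class` tibble (`class`, `tp`, `fp`, `tn`, `fn`).
#' @export
confusion_counts <- function(y_true, y_pred, n_classes = NULL) {
  if (length(y_true) != length(y_pred)) {
    abort_validation("`y_true` and `y_pred` have different lengths.")
  }
  K <- n_classes %||% (max(y_true, y_pred) + 1L)
  if (any(c(y_true, y_pred) < 0L | c(y_true, y_pred) >= K)) {
    abort_validation("class index out of range.")
  }
  cm <- table(factor(y_true, levels = 0:(K - 1L)),
              factor(y_pred, levels = 0:(K - 1L)))
  cm <- matrix(as.integer(cm), K, K,
               dimnames = list(true = 0:(K - 1L), pred = 0:(K - 1L)))
  n <- length(y_true)
  per <- tibble::tibble(
    class = 0:(K - 1L),
    tp = as.integer(diag(cm)),
    fp = as.integer(colSums(cm) - diag(cm)),
    fn = as.integer(rowSums(cm) - diag(cm))
  )
  per$tn <- as.integer(n - per$tp - per$fp - per$fn)
  structure(list(matrix = cm, per_class = per, n = n),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> %d samples, %d classes\n", x$n, nrow(x$per_class)))
  print(x$matrix)
  invisible(x)
}

safe_div <- function(num, den, what) {
  out <- ifelse(den > 0, num / den, 0)
  if (any(den == 0)) {
    rlang::warn(sprintf("%s had a 0/0 division; reporting 0 by convention.", what))
  }
  out
}

#' Accuracy, precision, recall and F1 from confusion counts
#'
#' Applies the standard formulas `recall = TP/(TP+FN)`, `precision =
#' TP/(TP+FP)`, `accuracy = (TP+TN)/(TP+TN+FP+FN)` and `F1 = 2 pr /
#' (p + r)`. Micro averaging pools the one-vs-rest counts across classes
#' before applying the formulas; macro averages the per-class metrics.
#' 0/0 divisions are reported as 0 with a warning.
#'
#' @param counts A [confusion_counts()] result.
#' @param averaging `"micro"` (default) or `"macro"`.
#' @return An `evaluation_report`: list with `accuracy`, `precision`,
#'   `recall`, `f1`, `averaging`, `per_class` (tibble of per-class metrics)
#'   and the confusion `counts`. `auc` is `NA` until [compute_auc()] fills
#'   it.
#' @export
compute_metrics <- function(counts, averaging = c("micro", "macro")) {
  averaging <- match.arg(averaging)
  per <- counts$per_class
  per$precision <- safe_div(per$tp, per$tp + per$fp, "per-class precision")
  per$recall <- safe_div(per$tp, per$tp + per$fn, "per-class recall")
  per$f1 <- safe_div(2 * per$precision * per$recall,
                     per$precision + per$recall, "per-class F1")
  overall_accuracy <- sum(diag(counts$matrix)) / counts$n
  if (averaging == "micro") {
    tp <- sum(per$tp); fp <- sum(per$fp); tn <- sum(per$tn); fn <- sum(per$fn)
    precision <- safe_div(tp, tp + fp, "micro precision")
    recall <- safe_div(tp, tp + fn, "micro recall")
    accuracy <- (tp + tn) / (tp + tn + fp + fn)
    f1 <- safe_div(2 * precision * recall, precision + recall, "micro F1")
  } else {
    precision <- mean(per$precision)
    recall <- mean(per$recall)
    f1 <- mean(per$f1)
    accuracy <- overall_accuracy
  }
  structure(list(accuracy = accuracy, precision = precision, recall = recall,
                 f1 = f1, auc = NA_real_, averaging = averaging,
                 overall_accuracy = overall_accuracy,
                 per_class = per, counts = counts),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "<evaluation_report> (%s) accuracy %.4f | precision %.4f | recall %.4f | F1 %.4f | AUC %s\n",
    x$averaging, x$accuracy, x$precision, x$recall, x$f1,
    ifelse(is.na(x$auc), "-", sprintf("%.4f", x$auc))))
  invisible(x)
}

#' Macro one-vs-rest ROC AUC via the rank statistic
#'
#' For each class, the one-vs-rest AUC is the normalized Mann-Whitney U of
#' that class's probability column: tied scores receive half credit (average
#' ranks). Classes absent from `y_true` are skipped with a warning; the
#' result is the unweighted mean over the remaining classes.
#'
#' @param y_true Integer class indices (0-based).
#' @param probability_rows `N x K` matrix of class probabilities (rows sum
#'   to 1).
#' @param averaging Only `"macro_ovr"` is implemented.
#' @return Macro-averaged AUC in \[0, 1\].
#' @export
compute_auc <- function(y_true, probability_rows, averaging = "macro_ovr") {
  averaging <- match.arg(averaging, "macro_ovr")
  probability_rows <- as.matrix(probability_rows)
  if (nrow(probability_rows) != length(y_true)) {
    abort_validation("`probability_rows` must have one row per sample.")
  }
  K <- ncol(probability_rows)
  aucs <- rep(NA_real_, K)
  for (k in seq_len(K)) {
    pos <- y_true == (k - 1L)
    n_pos <- sum(pos); n_neg <- sum(!pos)
    if (n_pos == 0L) {
      rlang::warn(sprintf("class %d absent from y_true; skipped in AUC.", k - 1L))
      next
    }
    if (n_neg == 0L) {
      rlang::warn(sprintf("class %d is the only class present; skipped in AUC.", k - 1L))
      next
    }
    r <- rank(probability_rows[, k])      # average ranks: ties get half credit
    aucs[k] <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  }
  mean(aucs, na.rm = TRUE)
}

#' Evaluate predictions end to end
#'
#' Convenience wrapper: confusion counts, micro and macro metrics, and the
#' macro one-vs-rest AUC in one report.
#'
#' @param y_true Integer class indices (0-based).
#' @param probability_rows `N x K` class-probability matrix.
#' @param averaging Averaging mode for the headline metrics.
#' @return An `evaluation_report` with `auc` filled in and a `macro` /
#'   `micro` companion report attached as attribute `other_averaging`.
#' @export
evaluate_predictions <- function(y_true, probability_rows,
                                 averaging = c("micro", "macro")) {
  averaging <- match.arg(averaging)
  y_pred <- max.col(as.matrix(probability_rows), ties.method = "first") - 1L
  counts <- confusion_counts(y_true, y_pred, ncol(probability_rows))
  report <- compute_metrics(counts, averaging)
  other <- compute_metrics(counts, setdiff(c("micro", "macro"), averaging))
  report$auc <- compute_auc(y_true, probability_rows)
  other$auc <- report$auc
  attr(report, "other_averaging") <- other
  report
}

#' Per-class metrics of an evaluation report as a tibble
#'
#' @param x An `evaluation_report`.
#' @param ... Unused.
#' @return Tibble of per-class TP/FP/TN/FN, precision, recall and F1.
#' @export
tidy.evaluation_report <- function(x, ...) {
  x$per_class
}

#' One-row summary of an evaluation report
#'
#' @param x An `evaluation_report`.
#' @param ... Unused.
#' @return One-row tibble: accuracy, precision, recall, f1, auc, averaging.
#' @export
glance.evaluation_report <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, precision = x$precision,
                 recall = x$recall, f1 = x$f1, auc = x$auc,
                 averaging = x$averaging)
}

#' Write an evaluation report as JSON (+ per-class CSV)
#'
#' @param report An `evaluation_report`.
#' @param path Output JSON path; the per-class table is written next to it
#'   as `<path-sans-ext>_per_class.csv`.
#' @return `path`, invisibly.
#' @export
write_evaluation <- function(report, path) {
  other <- attr(report, "other_averaging")
  jsonlite::write_json(list(
    averaging = report$averaging,
    accuracy = report$accuracy, precision = report$precision,
    recall = report$recall, f1 = report$f1, auc = report$auc,
    other_averaging = if (!is.null(other)) list(
      averaging = other$averaging, accuracy = other$accuracy,
      precision = other$precision, recall = other$recall, f1 = other$f1),
    confusion_matrix = unname(apply(report$counts$matrix, 1L, as.list))
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  csv <- sub("\\.json$", "_per_class.csv", path)
  readr::write_csv(tidy(report), csv, progress = FALSE)
  invisible(path)
}
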