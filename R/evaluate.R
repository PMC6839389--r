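# Classifier evaluation: confusion matrix, per-class rates, ROC and AUC.

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over every distinct score and returns the
#' operating points; the AUC is the trapezoidal-rule area under the resulting
#' curve, which equals the normalized Mann-Whitney U statistic.
#'
#' @param scores Numeric vector of classifier scores (higher = more positive).
#' @param positive Logical vector, `TRUE` for positive-class samples.
#' @return List with `fpr`, `tpr` (points from (0,0) to (1,1) as the
#'   threshold decreases), `thresholds`, and `auc`.
#' @export
roc_curve <- function(scores, positive) {
  positive <- as.logical(positive)
  if (length(scores) != length(positive)) {
    sono_stop("sonodct_dimension_error", "scores and labels differ in length")
  }
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  if (n_pos == 0L || n_neg == 0L) {
    sono_stop("sonodct_input_error", "AUC undefined: data contain a single class")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- positive[ord]
  # accumulate at each distinct score value (ties collapse to one point)
  keep <- c(diff(s) != 0, TRUE)
  tp <- cumsum(y)[keep]
  fp <- cumsum(!y)[keep]
  fpr <- c(0, fp / n_neg)
  tpr <- c(0, tp / n_pos)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(fpr = fpr, tpr = tpr, thresholds = c(Inf, s[keep]), auc = auc)
}

#' Evaluate a trained model on a labeled dataset
#'
#' @param model A trained `sono_net`.
#' @param data A [labeled_dataset()]; use a held-out subset for honest
#'   estimates.
#' @return A `sono_metrics` list:
#' \describe{
#'   \item{confusion}{k x k count matrix, rows = true class, columns =
#'     predicted class.}
#'   \item{class_rates}{per-class TP/FP/TN/FN counts and percentages of the
#'     full sample (one-vs-rest).}
#'   \item{accuracy}{overall fraction correct.}
#'   \item{roc}{per-class one-vs-rest [roc_curve()] results.}
#'   \item{auc}{AUC of the last class for binary problems (the conventional
#'     "positive" class), otherwise the macro average over classes.}
#' }
#' @export
evaluate <- function(model, data) {
  stopifnot(inherits(model, "sono_net"), inherits(data, "labeled_dataset"))
  P <- predict(model, data$features)
  k <- ncol(P)
  pred <- max.col(P, ties.method = "first")
  truth <- data$labels
  n <- length(truth)
  confusion <- matrix(0L, k, k,
                      dimnames = list(true = data$class_names,
                                      predicted = data$class_names))
  for (i in seq_len(n)) {
    confusion[truth[i], pred[i]] <- confusion[truth[i], pred[i]] + 1L
  }
  class_rates <- lapply(seq_len(k), function(ci) {
    tp <- sum(truth == ci & pred == ci)
    fn <- sum(truth == ci & pred != ci)
    fp <- sum(truth != ci & pred == ci)
    tn <- n - tp - fn - fp
    list(class = data$class_names[ci],
         tp = tp, fp = fp, tn = tn, fn = fn,
         tp_pct = 100 * tp / n, fp_pct = 100 * fp / n,
         tn_pct = 100 * tn / n, fn_pct = 100 * fn / n)
  })
  names(class_rates) <- data$class_names
  roc <- lapply(seq_len(k), function(ci) roc_curve(P[, ci], truth == ci))
  names(roc) <- data$class_names
  auc <- if (k == 2L) roc[[2L]]$auc else mean(vapply(roc, `[[`, numeric(1), "auc"))
  structure(list(confusion = confusion, class_rates = class_rates,
                 accuracy = sum(pred == truth) / n, roc = roc, auc = auc,
                 n = n),
            class = "sono_metrics")
}

#' @export
print.sono_metrics <- function(x, ...) {
  cat(sprintf("<sono_metrics> n = %d, accuracy = %.3f, AUC = %.3f\n",
              x$n, x$accuracy, x$auc))
  cat("confusion (rows = true, cols = predicted):\n")
  print(x$confusion)
  invisible(x)
}

#' Write an evaluation report as structured JSON
#'
#' The per-class table mirrors the clinical reporting convention: percentage
#' of false negatives, false positives, true positives, and true negatives
#' per class, plus the confusion matrix and per-class AUCs.
#'
#' @param metrics A `sono_metrics` object from [evaluate()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(metrics, path) {
  stopifnot(inherits(metrics, "sono_metrics"))
  obj <- list(
    n = metrics$n,
    accuracy = metrics$accuracy,
    auc = metrics$auc,
    confusion = unclass(metrics$confusion),
    class_rates = lapply(metrics$class_rates, function(r) {
      r[c("class", "fn_pct", "fp_pct", "tp_pct", "tn_pct", "tp", "fp", "tn", "fn")]
    }),
    auc_per_class = lapply(metrics$roc, `[[`, "auc")
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
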