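#' Classification metrics for one fold
#'
#' Builds the confusion matrix (rows = truth, columns = prediction) and
#' per-class precision, recall and F1, with the convention that a class
#' whose precision and recall are both undefined or zero scores F1 = 0.
#' Macro F1 is the unweighted mean of per-class F1 over all classes
#' present in either the truth or the predictions; a class absent from
#' both is excluded from the macro average (it is neither rewarded nor
#' penalized) and reported in the `excluded` field.
#'
#' @param truth,pred Integer label vectors of equal length, values in
#'   `1..C`.
#' @param C Number of classes.
#' @param fold Optional fold identifier carried through to reports.
#' @return An object of class `metrics_report`: list with `confusion`,
#'   `per_class` (data.frame `precision`, `recall`, `f1`, `support`),
#'   `macro_f1`, `excluded`, `fold`.
#' @export
compute_metrics <- function(truth, pred, C, fold = NA_integer_) {
  if (length(truth) != length(pred)) {
    stop("truth and prediction vectors differ in length")
  }
  if (length(truth) &&
      (min(c(truth, pred)) < 1 || max(c(truth, pred)) > C)) {
    stop("labels must lie in 1..C")
  }
  lev <- seq_len(C)
  confusion <- table(factor(truth, levels = lev), factor(pred, levels = lev))
  confusion <- matrix(as.integer(confusion), C, C,
                      dimnames = list(truth = lev, pred = lev))
  tp <- diag(confusion)
  pred_tot <- colSums(confusion)
  truth_tot <- rowSums(confusion)
  precision <- ifelse(pred_tot > 0, tp / pred_tot, 0)
  recall <- ifelse(truth_tot > 0, tp / truth_tot, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  present <- truth_tot > 0 | pred_tot > 0
  macro_f1 <- if (any(present)) mean(f1[present]) else NA_real_
  structure(list(
    confusion = confusion,
    per_class = data.frame(precision = precision, recall = recall, f1 = f1,
                           support = truth_tot),
    macro_f1 = macro_f1,
    excluded = unname(which(!present)),
    fold = fold), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics_report%s: macro F1 = %.4f\n",
              if (is.na(x$fold)) "" else paste0(" (fold ", x$fold, ")"),
              x$macro_f1))
  print(round(x$per_class, 4))
  if (length(x$excluded)) {
    cat("classes excluded from the macro average (absent from truth and",
        "predictions):", paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Aggregate per-fold metrics reports
#'
#' Fold-then-average pooling: per-class metrics and macro F1 are computed
#' per fold and then averaged across folds.
#'
#' @param reports List of `metrics_report` objects.
#' @return data.frame with one row per fold plus attributes
#'   `mean_macro_f1` and `sd_macro_f1`.
#' @export
summarize_metrics <- function(reports) {
  stopifnot(length(reports) > 0)
  C <- nrow(reports[[1]]$per_class)
  rows <- lapply(reports, function(r) {
    row <- data.frame(fold = r$fold, macro_f1 = r$macro_f1)
    for (c in seq_len(C)) row[[paste0("f1_class", c)]] <- r$per_class$f1[c]
    row
  })
  out <- do.call(rbind, rows)
  attr(out, "mean_macro_f1") <- mean(out$macro_f1, na.rm = TRUE)
  attr(out, "sd_macro_f1") <- stats::sd(out$macro_f1)
  out
}
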