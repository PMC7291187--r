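#' Confusion-matrix metrics for imputed categorical values
#'
#' For a binary comparison, metrics come from the 2x2 table with `positive`
#' as the positive class. For more than two classes, precision, sensitivity,
#' specificity and F-measure are macro-averaged one-vs-rest, while accuracy
#' stays the overall fraction correct. A ratio with a zero denominator is
#' reported as 0 (with a note), so degenerate predictors still score.
#'
#' @param actual Vector of true labels (the held-out values).
#' @param predicted Vector of imputed labels, same length.
#' @param positive Positive-class label for the binary case; defaults to the
#'   first label encountered. Ignored (beyond validation) for multi-class.
#' @return An object of class `sice_confusion`: list with `accuracy`,
#'   `balanced_accuracy`, `sensitivity`, `precision`, `specificity`,
#'   `f_measure`, plus `n` and `labels`.
#' @examples
#' confusion_metrics(c("M","M","F","F"), c("M","F","M","F"), positive = "M")
#' @export
confusion_metrics <- function(actual, predicted, positive = NULL) {
  actual <- as.character(actual); predicted <- as.character(predicted)
  if (length(actual) != length(predicted) || length(actual) < 1L) {
    stop("'actual' and 'predicted' must have equal length >= 1", call. = FALSE)
  }
  labels <- unique(c(actual, predicted))
  if (!is.null(positive)) {
    if (!positive %in% labels) {
      stop("positive label '", positive, "' not among the observed labels",
           call. = FALSE)
    }
    labels <- c(positive, setdiff(labels, positive))
  }
  accuracy <- mean(actual == predicted)
  if (length(labels) <= 2L) {
    per <- one_vs_rest(actual, predicted, labels[1L])
    out <- per
  } else {
    per <- lapply(labels, function(lb) one_vs_rest(actual, predicted, lb))
    out <- lapply(stats::setNames(nm = names(per[[1L]])), function(f) {
      mean(vapply(per, `[[`, numeric(1), f))
    })
  }
  structure(list(accuracy = accuracy,
                 balanced_accuracy = (out$sensitivity + out$specificity) / 2,
                 sensitivity = out$sensitivity,
                 precision = out$precision,
                 specificity = out$specificity,
                 f_measure = out$f_measure,
                 n = length(actual), labels = labels),
            class = "sice_confusion")
}

one_vs_rest <- function(actual, predicted, lb) {
  tp <- sum(actual == lb & predicted == lb)
  fp <- sum(actual != lb & predicted == lb)
  fn <- sum(actual == lb & predicted != lb)
  tn <- sum(actual != lb & predicted != lb)
  sens <- safe_ratio(tp, tp + fn)
  prec <- safe_ratio(tp, tp + fp)
  list(sensitivity = sens,
       precision = prec,
       specificity = safe_ratio(tn, tn + fp),
       f_measure = if (prec + sens > 0) 2 * prec * sens / (prec + sens) else {
         note_zero("F-measure")
         0
       })
}

safe_ratio <- function(num, den) {
  if (den == 0) {
    note_zero("metric")
    return(0)
  }
  num / den
}

note_zero <- function(what) {
  message("note: ", what, " has a zero denominator; reported as 0")
}

#' @export
print.sice_confusion <- function(x, digits = 4L, ...) {
  cat("<sice_confusion> n = ", x$n, "\n", sep = "")
  for (f in c("accuracy", "balanced_accuracy", "sensitivity", "precision",
              "specificity", "f_measure")) {
    cat(sprintf("  %-18s %.*f\n", f, digits, x[[f]]))
  }
  invisible(x)
}

#' Root mean squared error of imputed numeric values
#'
#' `sqrt(mean((actual - predicted)^2))`, in the target's units: 0 exactly
#' when every pair agrees, and equal to `|delta|` under a constant shift.
#'
#' @param actual Numeric vector of held-out true values.
#' @param predicted Numeric vector of imputed values, same length.
#' @return An object of class `sice_rmse`: list with `value` and `n`.
#' @examples
#' rmse(c(1, 2, 3), c(1, 2, 5))$value  # sqrt(4/3)
#' @export
rmse <- function(actual, predicted) {
  actual <- as.numeric(actual); predicted <- as.numeric(predicted)
  if (length(actual) != length(predicted) || length(actual) < 1L) {
    stop("'actual' and 'predicted' must have equal length >= 1", call. = FALSE)
  }
  if (!all(is.finite(actual)) || !all(is.finite(predicted))) {
    stop("rmse requires finite inputs", call. = FALSE)
  }
  structure(list(value = sqrt(mean((actual - predicted)^2)),
                 n = length(actual)),
            class = "sice_rmse")
}

#' @export
print.sice_rmse <- function(x, ...) {
  cat("<sice_rmse> ", format(x$value), " over ", x$n, " cells\n", sep = "")
  invisible(x)
}

#' Score a completed table against amputation ground truth
#'
#' Convenience wrapper: extracts the imputed values at the masked cells and
#' dispatches to [rmse()] (numeric target) or [confusion_metrics()]
#' (categorical target). Only artificially masked cells are scored.
#'
#' @param completed A completed `sice_table`.
#' @param amputed The `sice_amputed` that produced the missing cells.
#' @param positive Passed to [confusion_metrics()] for binary targets;
#'   defaults to the first schema level.
#' @return A `sice_rmse` or `sice_confusion`.
#' @export
score_imputation <- function(completed, amputed, positive = NULL) {
  target <- amputed$target
  spec <- table_schema(completed)[[target]]
  rows <- amputed$truth$row
  imputed <- completed[[target]][rows]
  if (anyNA(imputed)) stop("completed table has missing cells at the mask",
                           call. = FALSE)
  truth <- truth_values(amputed)
  if (spec$vartype == "numeric") {
    rmse(truth, as.numeric(imputed))
  } else {
    if (is.null(positive) && spec$vartype == "binary") positive <- spec$levels[1L]
    confusion_metrics(truth, as.character(imputed), positive = positive)
  }
}
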