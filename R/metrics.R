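# Confusion matrix and one-vs-rest evaluation metrics. A K-class confusion
# matrix (rows = true class, columns = predicted class) is marginalized
# one-vs-rest into TP (D), TN (E), FP (F), FN (G) counts per class, from
# which accuracy, precision, recall, F1 and the Matthews correlation
# coefficient derive.

#' Build a confusion matrix from label vectors
#'
#' @param true,pred factors/characters of true and predicted labels.
#' @param classes class-name ordering; defaults to the union of levels.
#' @return An object of class `ddrnet_confusion`: integer count matrix with
#'   rows = true class, columns = predicted class.
#' @export
confusion_matrix <- function(true, pred,
                             classes = union(levels(factor(true)),
                                             levels(factor(pred)))) {
  t <- factor(as.character(true), levels = classes)
  p <- factor(as.character(pred), levels = classes)
  counts <- unclass(table(true = t, predicted = p))
  structure(list(counts = counts, class_names = classes),
            class = "ddrnet_confusion")
}

#' @export
print.ddrnet_confusion <- function(x, ...) {
  cat("Confusion matrix (rows = true, cols = predicted):\n")
  print(x$counts)
  invisible(x)
}

# one-vs-rest marginal counts for class k: D = TP, E = TN, F = FP, G = FN
ovr_counts <- function(cm, class_k) {
  k <- if (is.character(class_k)) match(class_k, cm$class_names) else class_k
  if (is.na(k) || k < 1L || k > nrow(cm$counts))
    stop("unknown class: ", class_k)
  m <- cm$counts
  D <- m[k, k]
  F_ <- sum(m[, k]) - D
  G <- sum(m[k, ]) - D
  E <- sum(m) - D - F_ - G
  c(D = D, E = E, F = F_, G = G)
}

safe_div <- function(num, den) if (den == 0) 0 else num / den

#' One-vs-rest classification metrics for one class
#'
#' Standard one-vs-rest definitions with TP = D, TN = E, FP = F, FN = G:
#' accuracy (D+E)/(D+E+F+G), precision D/(D+F), recall D/(D+G), and
#' F1 = 2 * precision * recall / (precision + recall). A zero denominator
#' yields 0 with the corresponding flag set in `degenerate`.
#'
#' @param cm a [confusion_matrix()].
#' @param class_k class name or index.
#' @return List with `accuracy`, `precision`, `recall`, `f1` and a
#'   character vector `degenerate` naming any zero-denominator metric.
#' @export
classification_metrics <- function(cm, class_k) {
  n <- ovr_counts(cm, class_k)
  degenerate <- character()
  if (n["D"] + n["F"] == 0) degenerate <- c(degenerate, "precision")
  if (n["D"] + n["G"] == 0) degenerate <- c(degenerate, "recall")
  precision <- safe_div(n[["D"]], n[["D"]] + n[["F"]])
  recall <- safe_div(n[["D"]], n[["D"]] + n[["G"]])
  if (precision + recall == 0) degenerate <- c(degenerate, "f1")
  list(accuracy = safe_div(n[["D"]] + n[["E"]], sum(n)),
       precision = precision,
       recall = recall,
       f1 = safe_div(2 * precision * recall, precision + recall),
       degenerate = degenerate)
}

#' Matthews correlation coefficient (one-vs-rest)
#'
#' `MCC = (D*E - F*G) / sqrt((D+F)(D+G)(E+F)(E+G))`; returns 0 (flagged via
#' attribute `"degenerate"`) when any factor under the root is 0.
#'
#' @inheritParams classification_metrics
#' @return Numeric in \[-1, 1\].
#' @export
matthews_cc <- function(cm, class_k) {
  n <- ovr_counts(cm, class_k)
  den2 <- (n[["D"]] + n[["F"]]) * (n[["D"]] + n[["G"]]) *
    (n[["E"]] + n[["F"]]) * (n[["E"]] + n[["G"]])
  if (den2 == 0) return(structure(0, degenerate = TRUE))
  (n[["D"]] * n[["E"]] - n[["F"]] * n[["G"]]) / sqrt(den2)
}

#' Full metrics report
#'
#' Per-class one-vs-rest precision, recall, F1 and MCC plus overall accuracy
#' and unweighted macro averages.
#'
#' @param cm a [confusion_matrix()].
#' @return An object of class `ddrnet_metrics`: list with `per_class` (data
#'   frame), `overall_accuracy` and `macro` averages.
#' @export
metrics_report <- function(cm) {
  per <- lapply(cm$class_names, function(cl) {
    m <- classification_metrics(cm, cl)
    data.frame(class = cl, precision = m$precision, recall = m$recall,
               f1 = m$f1, mcc = as.numeric(matthews_cc(cm, cl)),
               accuracy = m$accuracy)
  })
  per <- do.call(rbind, per)
  structure(list(
    per_class = per,
    overall_accuracy = sum(diag(cm$counts)) / max(1, sum(cm$counts)),
    macro = list(precision = mean(per$precision), recall = mean(per$recall),
                 f1 = mean(per$f1), mcc = mean(per$mcc))),
    class = "ddrnet_metrics")
}

#' @export
print.ddrnet_metrics <- function(x, ...) {
  cat(sprintf("Overall accuracy: %.4f\n", x$overall_accuracy))
  print(x$per_class, row.names = FALSE, digits = 4)
  cat(sprintf("Macro: precision %.4f | recall %.4f | F1 %.4f | MCC %.4f\n",
              x$macro$precision, x$macro$recall, x$macro$f1, x$macro$mcc))
  invisible(x)
}

metrics_to_list <- function(rep) {
  list(overall_accuracy = rep$overall_accuracy,
       macro = rep$macro,
       per_class = rep$per_class)
}
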