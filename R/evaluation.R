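# Evaluation against reference labels: overall accuracy plus one-vs-rest
# precision/recall/F1 per reference label, summarised by the median F1.
# Unknown/unclassified are ordinary labels here, matching the practice of
# merging rare populations into an unknown bucket before scoring.

#' Overall annotation accuracy
#'
#' Percentage of cells whose predicted label equals the reference label.
#'
#' @param predicted,reference label vectors of equal length.
#' @return accuracy in percent (0-100).
#' @export
overall_accuracy <- function(predicted, reference) {
  predicted <- as.character(predicted)
  reference <- as.character(reference)
  if (length(predicted) != length(reference)) {
    stop("'predicted' and 'reference' must have the same length",
         call. = FALSE)
  }
  100 * mean(predicted == reference)
}

#' Per-label precision, recall and F1
#'
#' One-vs-rest confusion counts for every label of the reference set:
#' precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, `F1 = 2PR/(P+R)`. Fractions
#' with a zero denominator are 0 by convention (a label never predicted
#' scores zero precision and F1 rather than dropping out).
#'
#' @inheritParams overall_accuracy
#' @return data frame with columns `label`, `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f1`, one row per reference label (C-locale sorted).
#' @export
per_label_prf <- function(predicted, reference) {
  predicted <- as.character(predicted)
  reference <- as.character(reference)
  if (length(predicted) != length(reference)) {
    stop("'predicted' and 'reference' must have the same length",
         call. = FALSE)
  }
  labels <- sort(unique(reference), method = "radix")
  rows <- lapply(labels, function(L) {
    tp <- sum(predicted == L & reference == L)
    fp <- sum(predicted == L & reference != L)
    fn <- sum(predicted != L & reference == L)
    p <- if (tp + fp == 0L) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0L) 0 else tp / (tp + fn)
    f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    data.frame(label = L, tp = tp, fp = fp, fn = fn,
               precision = p, recall = r, f1 = f1,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Median F1 across labels
#'
#' @param f1 numeric vector of per-label F1 scores, or the data frame
#'   returned by [per_label_prf()].
#' @return the median (mean of the central pair for an even label count).
#' @export
median_f1 <- function(f1) {
  if (is.data.frame(f1)) f1 <- f1$f1
  f1 <- as.numeric(f1)
  if (!length(f1)) stop("at least one label is required", call. = FALSE)
  stats::median(f1)
}

#' Full evaluation summary
#'
#' Convenience wrapper returning the overall accuracy, the per-label table
#' and the median F1 both over all reference labels and with the
#' unknown-type labels excluded.
#'
#' @inheritParams overall_accuracy
#' @param unknown_labels labels treated as the unknown class for the
#'   `median_f1_known` variant.
#' @return list with `accuracy`, `per_label`, `median_f1`,
#'   `median_f1_known`.
#' @export
evaluate_annotation <- function(predicted, reference,
                                unknown_labels = c("unknown",
                                                   "unclassified")) {
  prf <- per_label_prf(predicted, reference)
  known <- prf[!prf$label %in% unknown_labels, , drop = FALSE]
  list(accuracy = overall_accuracy(predicted, reference),
       per_label = prf,
       median_f1 = median_f1(prf),
       median_f1_known = if (nrow(known)) median_f1(known) else NA_real_)
}
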