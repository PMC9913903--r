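#' Deterministic k-nearest-neighbour classification
#'
#' Euclidean-distance majority vote with fully deterministic
#' tie-breaking: equal distances are resolved by training-set order, and
#' a tied vote is resolved in favour of the class of the nearest
#' neighbour among the tied classes.
#'
#' @param reference n_train x t matrix of reference points.
#' @param reference_labels factor of n_train labels.
#' @param queries m x t matrix of points to classify.
#' @param k neighbourhood size, `k <= n_train`. Odd k avoids most vote
#'   ties in 2-class problems; even k is allowed but flagged unless
#'   `allow_even = TRUE`.
#' @param allow_even suppress the warning for even k.
#' @return Factor of m predicted labels (levels of `reference_labels`).
#' @export
knn_predict <- function(reference, reference_labels, queries, k = 1L,
                        allow_even = FALSE) {
  reference <- as.matrix(reference)
  queries <- as.matrix(queries)
  reference_labels <- factor(reference_labels)
  n <- nrow(reference)
  if (length(reference_labels) != n) stop("one label per reference row required")
  if (ncol(queries) != ncol(reference))
    stop("queries have ", ncol(queries), " columns; references have ",
         ncol(reference))
  k <- as.integer(k)
  if (k < 1L || k > n) stop("k must be in 1..n_train (", n, ")")
  if (k %% 2L == 0L && !allow_even)
    warning("even k can produce vote ties; tie-break is deterministic ",
            "(nearest neighbour among tied classes)")
  d2 <- .sqdist(queries, reference)             # m x n
  lab_int <- as.integer(reference_labels)
  out <- integer(nrow(queries))
  for (q in seq_len(nrow(queries))) {
    ord <- order(d2[q, ], seq_len(n))           # distance, then train index
    nb <- lab_int[ord[seq_len(k)]]
    votes <- tabulate(nb, nbins = nlevels(reference_labels))
    top <- which(votes == max(votes))
    out[q] <- if (length(top) == 1L) top else nb[match(TRUE, nb %in% top)]
  }
  factor(levels(reference_labels)[out], levels = levels(reference_labels))
}

#' Tabulate classification results
#'
#' @param predictions factor/vector of predicted labels.
#' @param truth factor/vector of true labels, same length.
#' @return A list of class `classification_report`: `accuracy` (exact
#'   fraction in `[0, 1]`), `correct_count`, `total`, `confusion`
#'   (c x c table, rows = truth), and `accuracy_pct` (the display value,
#'   percent rounded to 2 decimals, e.g. 106/108 -> 98.15).
#' @examples
#' r <- evaluate_classification(c("a", "a", "b"), c("a", "b", "b"))
#' r$accuracy_pct
#' @export
evaluate_classification <- function(predictions, truth) {
  if (length(predictions) != length(truth))
    stop("predictions and truth must have equal length")
  lev <- union(levels(factor(truth)), levels(factor(predictions)))
  truth <- factor(truth, levels = lev)
  predictions <- factor(predictions, levels = lev)
  confusion <- table(truth = truth, predicted = predictions)
  correct <- sum(diag(confusion))
  total <- length(truth)
  structure(list(accuracy = correct / total,
                 correct_count = as.integer(correct),
                 total = as.integer(total),
                 confusion = confusion,
                 accuracy_pct = round(100 * correct / total, 2)),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("Accuracy: ", format(x$accuracy_pct, nsmall = 0), "% (",
      x$correct_count, "/", x$total, " correct)\n", sep = "")
  cat("Confusion matrix (rows = truth):\n")
  print(x$confusion)
  invisible(x)
}
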