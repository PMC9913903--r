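#' @export
print.fmlda <- function(x, ...) {
  cat("Discriminant fit (", toupper(x$method), "): ",
      length(x$lev), " classes, ", nrow(x$scaling), " channels -> ",
      x$ncomp, " components\n", sep = "")
  cat("Class counts:\n")
  print(x$counts)
  cat("Component eigenvalues",
      if (x$method == "dlda") " (within-class spread, ascending)" else
        " (separation criterion, descending)", ":\n", sep = "")
  print(signif(x$eigvals, 5))
  if (!is.null(x$fcm))
    cat("FCM: m = ", x$fcm$control$fuzzifier, ", ", x$fcm$iterations,
        " iteration(s)", if (x$fcm$converged) ", converged" else "",
        "\n", sep = "")
  invisible(x)
}

#' @export
summary.fmlda <- function(object, ...) {
  sep <- .projected_separation(object)
  out <- list(method = object$method, ncomp = object$ncomp,
              d = nrow(object$scaling), n = sum(object$counts),
              counts = object$counts, eigvals = object$eigvals,
              separation = sep, fcm = object$fcm)
  class(out) <- "summary.fmlda"
  out
}

#' @export
print.summary.fmlda <- function(x, ...) {
  cat("Discriminant fit summary\n")
  cat("  method:     ", toupper(x$method), "\n", sep = "")
  cat("  data:       ", x$n, " samples x ", x$d, " channels, ",
      length(x$counts), " classes\n", sep = "")
  cat("  components: ", x$ncomp, "\n", sep = "")
  cat("  projected between/within trace ratio: ",
      format(x$separation, digits = 5), "\n", sep = "")
  if (!is.null(x$fcm))
    cat("  fcm:        m = ", x$fcm$control$fuzzifier, ", ",
        x$fcm$iterations, " iteration(s)\n", sep = "")
  invisible(x)
}

# trace(W'SbW) / trace(W'SwW) on the training data: a scalar measure of
# class separation in the extracted subspace.
.projected_separation <- function(object) {
  sc <- object$scores
  st <- class_statistics(sc, object$labels)
  pair <- scatter_matrices(sc, object$labels)
  tw <- sum(diag(as.matrix(pair$within)))
  tb <- sum(diag(as.matrix(pair$between)))
  if (tw <= 0) Inf else tb / tw
}

#' @export
coef.fmlda <- function(object, ...) object$scaling

#' Project spectra, or classify them by KNN in the discriminant space
#'
#' `type = "scores"` returns the n x t score matrix X W (the subspace
#' coordinates). `type = "class"` additionally runs a k-nearest-neighbour
#' vote against the projected training samples stored in the fit.
#'
#' @param object an [fmlda()] fit.
#' @param newdata numeric matrix with d columns, or a [spectra_set()].
#'   Defaults to the training data.
#' @param type `"scores"` (default) or `"class"`.
#' @param k neighbourhood size for `type = "class"` (default 1).
#' @param ... ignored.
#' @return A score matrix, or a factor of predicted labels.
#' @export
predict.fmlda <- function(object, newdata = NULL, type = c("scores", "class"),
                          k = 1L, ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    sc <- object$scores
  } else {
    X <- if (inherits(newdata, "spectra_set")) newdata$absorbance else as.matrix(newdata)
    if (ncol(X) != nrow(object$scaling))
      stop("newdata has ", ncol(X), " channels; model expects ",
           nrow(object$scaling))
    sc <- X %*% object$scaling
  }
  if (type == "scores") return(sc)
  knn_predict(object$scores, object$labels, sc, k = k)
}

#' Plot discriminant scores
#'
#' Scatter plot of two discriminant components of the training scores,
#' coloured by class.
#'
#' @param x an [fmlda()] fit.
#' @param comps length-2 integer vector of components to plot.
#' @param ... passed to [graphics::plot()].
#' @export
plot.fmlda <- function(x, comps = c(1L, 2L), ...) {
  if (x$ncomp < 2L) stop("need at least 2 components to plot")
  sc <- x$scores[, comps, drop = FALSE]
  cls <- as.integer(x$labels)
  graphics::plot(sc[, 1], sc[, 2], col = cls, pch = cls,
                 xlab = paste0("Component ", comps[1]),
                 ylab = paste0("Component ", comps[2]), ...)
  graphics::legend("topright", legend = x$lev, col = seq_along(x$lev),
                   pch = seq_along(x$lev), cex = 0.8)
  invisible(x)
}
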