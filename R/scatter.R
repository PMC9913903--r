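#' Per-class and global mean statistics
#'
#' @param X n x d data matrix.
#' @param labels factor of n class labels.
#' @return A list of class `class_statistics` with `global_mean`
#'   (d-vector), `class_means` (c x d, rows named by level), and
#'   `class_counts` (named integer c-vector). The count-weighted average
#'   of the class means equals the global mean.
#' @export
class_statistics <- function(X, labels) {
  X <- as.matrix(X)
  labels <- factor(labels)
  if (length(labels) != nrow(X)) stop("one label per row required")
  if (any(table(labels) < 1L)) stop("empty class level: ",
    paste(levels(labels)[table(labels) < 1L], collapse = ", "))
  cm <- rowsum(X, labels) / as.vector(table(labels))
  structure(list(global_mean = colMeans(X),
                 class_means = cm,
                 class_counts = c(table(labels))),
            class = "class_statistics")
}

#' Within- and between-class scatter matrices
#'
#' Crisp scatter: \eqn{S_w = \sum_i \sum_{x_k \in c_i}
#' (x_k - \bar{x}_i)(x_k - \bar{x}_i)^T} and
#' \eqn{S_b = \sum_i n_i (\bar{x}_i - \bar{x})(\bar{x}_i - \bar{x})^T}.
#' Both are symmetric PSD; \eqn{rank(S_b) \le c - 1}.
#'
#' @param X n x d data matrix.
#' @param labels factor of n class labels (c >= 2 levels; with a single
#'   class, `between` is the zero matrix and a warning is issued).
#' @return A list of class `scatter_pair` with d x d matrices `within`
#'   and `between`, and `flavor = "crisp"`.
#' @export
scatter_matrices <- function(X, labels) {
  X <- as.matrix(X)
  st <- class_statistics(X, labels)
  labels <- factor(labels)
  if (nlevels(labels) < 2L)
    warning("single class: between-class scatter is the zero matrix")
  cx <- X - st$class_means[as.integer(labels), , drop = FALSE]
  within <- crossprod(cx)
  dm <- sweep(st$class_means, 2L, st$global_mean)
  between <- crossprod(dm * sqrt(st$class_counts))
  structure(list(within = within, between = between, flavor = "crisp"),
            class = "scatter_pair")
}

#' Fuzzy within- and between-class scatter matrices
#'
#' Scatter built around supplied cluster centers rather than the class
#' means: \eqn{S_{fw} = \sum_i \sum_{x_k \in c_i} (x_k - v_i)(x_k - v_i)^T}
#' (crisp class membership of the samples, fuzzy centers) and
#' \eqn{S_{fb} = \sum_i n_i (v_i - \bar{x})(v_i - \bar{x})^T}, where
#' \eqn{\bar{x}} is the global data mean. Row i of `centers` must
#' correspond to class level i (the class-mean initialisation of
#' [fcm_fit()] guarantees this). With centers equal to the class means
#' this reduces exactly to [scatter_matrices()].
#'
#' @param X n x d data matrix.
#' @param labels factor of n class labels.
#' @param centers c x d matrix of centers, one row per class level.
#' @return A `scatter_pair` with `flavor = "fuzzy"`.
#' @export
fuzzy_scatter_matrices <- function(X, labels, centers) {
  X <- as.matrix(X); centers <- as.matrix(centers)
  labels <- factor(labels)
  st <- class_statistics(X, labels)
  if (nrow(centers) != nlevels(labels))
    stop("centers must have one row per class (", nlevels(labels),
         "), got ", nrow(centers))
  if (ncol(centers) != ncol(X)) stop("centers and X must share dimensions")
  cx <- X - centers[as.integer(labels), , drop = FALSE]
  within <- crossprod(cx)
  dm <- sweep(centers, 2L, st$global_mean)
  between <- crossprod(dm * sqrt(st$class_counts))
  structure(list(within = within, between = between, flavor = "fuzzy"),
            class = "scatter_pair")
}

#' Maximum-uncertainty eigenvalue shrinkage of the within-class scatter
#'
#' Stabilizes a (possibly singular) within-class scatter matrix: the
#' pooled matrix \eqn{S_p = S_w / (n - c)} is eigendecomposed, every
#' eigenvalue below the average eigenvalue \eqn{\bar\lambda} (zeros from
#' the null space included in the average) is raised to
#' \eqn{\bar\lambda}, and the matrix is rebuilt as
#' \eqn{S_w^* = \phi \Lambda^* \phi^T (n - c)}. The result is symmetric
#' positive definite, so classical discriminant directions
#' \eqn{S_w^{*-1} S_b} exist even when d > n.
#'
#' @param within d x d symmetric PSD within-class scatter.
#' @param n total sample count.
#' @param c number of classes; requires n > c.
#' @return A list of class `shrunken_scatter` with `eigvecs` (d x d
#'   orthonormal), `eigvals` (pooled eigenvalues, descending),
#'   `mean_eigval`, `adjusted_eigvals` (`pmax(eigvals, mean_eigval)`),
#'   `reconstructed` (the d x d \eqn{S_w^*}), `n`, and `c`.
#' @examples
#' S <- diag(c(4, 2, 0))
#' sh <- shrink_within_scatter(S * 10, n = 13, c = 3)
#' sh$adjusted_eigvals  # 4 2 2
#' @export
shrink_within_scatter <- function(within, n, c) {
  within <- as.matrix(within)
  if (nrow(within) != ncol(within)) stop("within must be square")
  if (n <= c) stop("need n > c for the pooled scatter S_w/(n - c)")
  pooled <- within / (n - c)
  eg <- eigen((pooled + t(pooled)) / 2, symmetric = TRUE)
  lambda <- pmax(eg$values, 0)          # clip tiny negative round-off
  lbar <- mean(lambda)
  adj <- pmax(lambda, lbar)
  recon <- eg$vectors %*% (adj * t(eg$vectors)) * (n - c)
  recon <- (recon + t(recon)) / 2
  structure(list(eigvecs = eg$vectors, eigvals = lambda, mean_eigval = lbar,
                 adjusted_eigvals = adj, reconstructed = recon,
                 n = n, c = c),
            class = "shrunken_scatter")
}
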