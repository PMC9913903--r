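#' Fuzzy c-means control parameters
#'
#' @param fuzzifier exponent m > 1 controlling membership softness.
#'   m near 1 approaches crisp assignment; large m approaches uniform
#'   membership 1/c.
#' @param epsilon convergence threshold on the maximum per-center
#'   Euclidean displacement between successive iterations (default 1e-5).
#' @param max_iter maximum number of update iterations (default 100).
#'   `max_iter = 0` is allowed and means: evaluate memberships at the
#'   initial centers without updating them (used to pin centers, e.g. to
#'   the class means).
#' @return A list of class `fcm_control`.
#' @export
fcm_control <- function(fuzzifier = 2, epsilon = 1e-5, max_iter = 100L) {
  if (!is.numeric(fuzzifier) || fuzzifier <= 1)
    stop("fuzzifier m must be > 1")
  if (!is.numeric(epsilon) || epsilon <= 0) stop("epsilon must be > 0")
  if (max_iter < 0) stop("max_iter must be >= 0")
  structure(list(fuzzifier = fuzzifier, epsilon = epsilon,
                 max_iter = as.integer(max_iter)),
            class = "fcm_control")
}

# squared Euclidean distances, centers (c x d) vs points (n x d) -> c x n
.sqdist <- function(centers, X) {
  d2 <- outer(rowSums(centers^2), rep(1, nrow(X))) +
    outer(rep(1, nrow(centers)), rowSums(X^2)) -
    2 * tcrossprod(centers, X)
  d2[d2 < 0] <- 0
  d2
}

#' Fuzzy membership degrees for fixed cluster centers
#'
#' Computes the c x n column-stochastic membership matrix
#' \deqn{u_{ij} = 1 / \sum_k (\|x_j - v_i\| / \|x_j - v_k\|)^{2/(m-1)}.}
#' If a point coincides with one or more centers, membership 1/#coinciding
#' is assigned to those centers and 0 elsewhere (the standard resolution
#' of the singularity, keeping columns normalized).
#'
#' @param X n x d data matrix (rows are samples).
#' @param centers c x d matrix of cluster centers.
#' @param fuzzifier m > 1.
#' @return c x n matrix with entries in `[0, 1]`, columns summing to 1.
#' @export
fcm_memberships <- function(X, centers, fuzzifier = 2) {
  X <- as.matrix(X); centers <- as.matrix(centers)
  if (ncol(X) != ncol(centers)) stop("X and centers must share dimensions")
  if (fuzzifier <= 1) stop("fuzzifier m must be > 1")
  d2 <- .sqdist(centers, X)                     # c x n
  pw <- d2^(-1 / (fuzzifier - 1))               # d^(-2/(m-1)); Inf at d = 0
  u <- sweep(pw, 2L, colSums(pw), "/")
  sing <- which(apply(d2, 2L, min) == 0)
  for (j in sing) {
    hit <- d2[, j] == 0
    u[, j] <- ifelse(hit, 1 / sum(hit), 0)
  }
  u
}

#' Fuzzy cluster centers for fixed memberships
#'
#' \deqn{v_i = \sum_j u_{ij}^m x_j / \sum_j u_{ij}^m.}
#'
#' @param X n x d data matrix.
#' @param memberships c x n membership matrix (columns sum to 1).
#' @param fuzzifier m > 1.
#' @return c x d matrix of centers.
#' @export
fcm_centers <- function(X, memberships, fuzzifier = 2) {
  X <- as.matrix(X); u <- as.matrix(memberships)
  if (ncol(u) != nrow(X)) stop("memberships must be c x n for n = nrow(X)")
  um <- u^fuzzifier
  w <- rowSums(um)
  if (any(w == 0))
    stop("cluster(s) with all-zero raised memberships: ",
         paste(which(w == 0), collapse = ", "))
  (um %*% X) / w
}

#' Fit fuzzy c-means
#'
#' Alternates the membership and center updates from initial centers
#' until the maximum per-center Euclidean displacement falls below
#' `control$epsilon` or `control$max_iter` iterations complete. When used
#' ahead of the fuzzy discriminant fit, the initial centers are the
#' labelled class means, so cluster index i keeps corresponding to class i.
#'
#' @param X n x d data matrix.
#' @param centers initial c x d centers (c distinct rows), or a single
#'   integer c in which case initial centers are drawn as c distinct
#'   random rows of X (requires a prior `set.seed()` for reproducibility).
#' @param control an [fcm_control()] list.
#' @return A list of class `fcm_fit` with `centers` (c x d),
#'   `memberships` (c x n), `iterations`, `converged`, `objective`
#'   (the value of \eqn{\sum_{ij} u_{ij}^m \|x_j - v_i\|^2} per
#'   iteration), and `control`.
#' @export
fcm_fit <- function(X, centers, control = fcm_control()) {
  X <- as.matrix(X)
  if (!inherits(control, "fcm_control")) control <- do.call(fcm_control, control)
  if (is.numeric(centers) && length(centers) == 1L) {
    c_n <- as.integer(centers)
    if (c_n > nrow(X)) stop("more clusters than samples")
    centers <- X[sample(nrow(X), c_n), , drop = FALSE]
  }
  centers <- as.matrix(centers)
  if (nrow(centers) > nrow(X)) stop("more clusters than samples")
  m <- control$fuzzifier
  obj <- numeric(0)
  u <- fcm_memberships(X, centers, m)
  converged <- FALSE
  iter <- 0L
  while (iter < control$max_iter) {
    iter <- iter + 1L
    new_centers <- fcm_centers(X, u, m)
    delta <- sqrt(max(rowSums((new_centers - centers)^2)))
    centers <- new_centers
    u <- fcm_memberships(X, centers, m)
    obj <- c(obj, sum(u^m * .sqdist(centers, X)))
    if (delta < control$epsilon) { converged <- TRUE; break }
  }
  if (!converged && control$max_iter > 0L)
    message("fcm_fit: not converged after ", iter, " iterations")
  structure(list(centers = centers, memberships = u, iterations = iter,
                 converged = converged, objective = obj, control = control),
            class = "fcm_fit")
}

#' @export
print.fcm_fit <- function(x, ...) {
  cat("Fuzzy c-means fit: ", nrow(x$centers), " clusters, ",
      ncol(x$memberships), " samples, m = ", x$control$fuzzifier, "\n",
      "  iterations: ", x$iterations,
      if (x$converged) " (converged)" else " (max_iter reached)", "\n", sep = "")
  invisible(x)
}
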