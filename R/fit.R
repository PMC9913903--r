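# Column sign convention: the entry of largest absolute value in each
# column is made positive, so fits are reproducible across eigensolvers
# and sample orderings.
.fix_signs <- function(W) {
  for (j in seq_len(ncol(W))) {
    i <- which.max(abs(W[, j]))
    if (W[i, j] < 0) W[, j] <- -W[, j]
  }
  W
}

# Operator y -> Sw*^(-1/2) y for the maximum-uncertainty shrunken within
# scatter, built from the matrix A (n x d) of center-deviation rows so
# that Sw = A'A. Dense route eigendecomposes the d x d scatter; the Gram
# route works from the n x n matrix AA' and handles the (d - r)-dim null
# space implicitly (its eigenvalues, all 0, shrink to the mean lambda).
.shrink_inv_half <- function(A, n, n_classes, route = c("auto", "dense", "gram")) {
  route <- match.arg(route)
  d <- ncol(A)
  if (route == "auto") route <- if (d > nrow(A)) "gram" else "dense"
  if (route == "dense") {
    sh <- shrink_within_scatter(crossprod(A), n, n_classes)
    scl <- 1 / sqrt(sh$adjusted_eigvals * (n - n_classes))
    Phi <- sh$eigvecs
    function(Y) Phi %*% (scl * crossprod(Phi, Y))
  } else {
    G <- tcrossprod(A)                          # n x n
    eg <- eigen((G + t(G)) / 2, symmetric = TRUE)
    s <- pmax(eg$values, 0)
    keep <- s > max(s, 0) * 1e-10 & s > 0
    r <- sum(keep)
    if (r == 0L) stop("within-class scatter is identically zero")
    Phi <- sweep(crossprod(A, eg$vectors[, keep, drop = FALSE]),
                 2L, sqrt(s[keep]), "/")        # d x r, orthonormal
    lam <- s[keep] / (n - n_classes)
    lbar <- sum(s) / (d * (n - n_classes))
    adj <- pmax(lam, lbar)
    scl_r <- 1 / sqrt(adj * (n - n_classes))
    scl_null <- 1 / sqrt(lbar * (n - n_classes))
    function(Y) {
      proj <- crossprod(Phi, Y)                 # r x k
      Phi %*% (scl_r * proj) + scl_null * (Y - Phi %*% proj)
    }
  }
}

# Shared MLDA/FMLDA eigen-extraction: whiten the between scatter with
# Sw*^(-1/2), solve the small symmetric problem in the span of the c
# center deviations, map back. Mathematically the top eigenpairs of
# Sw*^(-1) Sb.
.mu_directions <- function(A, Hb, n, n_classes, ncomp, route) {
  inv_half <- .shrink_inv_half(A, n, n_classes, route)
  B <- inv_half(t(Hb))                          # d x c
  small <- crossprod(B)                         # c x c, = B'B
  eg <- eigen((small + t(small)) / 2, symmetric = TRUE)
  avail <- sum(eg$values > max(eg$values, 0) * 1e-10 & eg$values > 0)
  if (avail == 0L) stop("between-class scatter has rank 0")
  t_use <- min(ncomp, avail)
  mu <- eg$values[seq_len(t_use)]
  wt <- sweep(B %*% eg$vectors[, seq_len(t_use), drop = FALSE],
              2L, sqrt(mu), "/")                # whitened eigvecs, unit norm
  W <- inv_half(wt)
  W <- sweep(W, 2L, sqrt(colSums(W^2)), "/")    # unit-norm columns
  list(W = .fix_signs(W), eigvals = mu, available = avail,
       factorization = NULL)
}

.dlda_directions <- function(A, Hb, ncomp) {
  cb <- tcrossprod(Hb)                          # c x c, = Sb in center span
  eg <- eigen((cb + t(cb)) / 2, symmetric = TRUE)
  keep <- eg$values > max(eg$values, 0) * 1e-10 & eg$values > 0
  rb <- sum(keep)
  if (rb == 0L) stop("between-class scatter has rank 0")
  db <- eg$values[keep]                         # descending
  Y <- sweep(crossprod(Hb, eg$vectors[, keep, drop = FALSE]),
             2L, sqrt(db), "/")                 # d x rb, orthonormal
  Z <- sweep(Y, 2L, sqrt(db), "/")              # whitens Sb: Z'SbZ = I
  AZ <- A %*% Z                                 # n x rb
  M <- crossprod(AZ)                            # Z'SwZ
  egw <- eigen((M + t(M)) / 2, symmetric = TRUE)
  ord <- order(egw$values)                      # smallest within-scatter first
  t_use <- min(ncomp, rb)
  sel <- ord[seq_len(t_use)]
  dw <- pmax(egw$values[sel], 1e-12)
  U <- egw$vectors[, sel, drop = FALSE]
  W <- sweep(Z %*% U, 2L, sqrt(dw), "/")        # = (Dw^-1/2 U'Z')'
  list(W = .fix_signs(W), eigvals = dw, available = rb,
       factorization = list(Y = Y, Db = db, Z = Z,
                            Dw = egw$values, U = egw$vectors))
}

#' Fit a discriminant subspace for high-dimensional spectra
#'
#' Learns a d x t projection matrix W separating c classes, by one of
#' three methods that remain well-defined when the channel count d
#' exceeds the sample count n:
#'
#' \describe{
#'   \item{`"mlda"`}{maximum-uncertainty LDA. The pooled within-class
#'     scatter \eqn{S_p = S_w/(n-c)} is eigendecomposed and every
#'     eigenvalue below the average eigenvalue is raised to that average
#'     (see [shrink_within_scatter()]); W holds the top eigenvectors of
#'     \eqn{S_w^{*-1} S_b}.}
#'   \item{`"fmlda"`}{fuzzy MLDA. Fuzzy c-means ([fcm_fit()]),
#'     initialised at the class means so cluster i stays matched to
#'     class i, supplies centers \eqn{v_i}; the scatter pair is built
#'     around those centers ([fuzzy_scatter_matrices()]) and then
#'     treated exactly as in MLDA.}
#'   \item{`"dlda"`}{direct LDA. Finds Y with \eqn{Y^T S_b Y = D_b}
#'     (descending), sets \eqn{Z = Y D_b^{-1/2}}, eigendecomposes
#'     \eqn{Z^T S_w Z = U D_w U^T}, and returns
#'     \eqn{W = (D_w^{-1/2} U^T Z^T)^T}, which diagonalizes both scatter
#'     matrices simultaneously. When fewer components are requested than
#'     \eqn{rank(S_b)}, those with smallest within-class spread are kept.}
#' }
#'
#' The MLDA/FMLDA eigenproblem is solved by symmetric whitening
#' (factorize \eqn{S_w^*}, whiten \eqn{S_b}, symmetric eigensolve, map
#' back), never by forming the non-symmetric product; for d > n the
#' within-scatter eigenbasis comes from the n x n Gram matrix so the
#' d x d scatter is never formed. Columns of W are unit-normalized
#' (MLDA/FMLDA) with the largest-magnitude entry made positive.
#'
#' @param x an n x d numeric matrix (samples in rows), a
#'   [spectra_set()], or a formula `grouping ~ .`.
#' @param grouping factor of class labels (matrix interface).
#' @param method `"fmlda"` (default), `"mlda"`, or `"dlda"`.
#' @param ncomp number of discriminant vectors t; default and maximum
#'   c - 1 for mlda/fmlda (requesting more is an error), and
#'   \eqn{rank(S_b)} for dlda.
#' @param fuzzifier fuzzy coefficient m > 1 (fmlda only; default 2).
#' @param fcm an [fcm_control()] list for the fuzzy c-means run
#'   (fmlda only). Its `fuzzifier` is overridden by the `fuzzifier`
#'   argument. `max_iter = 0` pins the centers at `centers`.
#' @param centers optional initial c x d FCM centers (fmlda only); rows
#'   must follow the order of the factor levels. Default: class means.
#' @param ... passed between methods.
#' @return An object of class `"fmlda"`: a list with `scaling` (the
#'   d x t projection W), `eigvals` (component eigenvalues, per the
#'   method's criterion), `method`, `ncomp`, `lev`, `counts`, `means`
#'   (class means), `global_mean`, `scores` (training scores, n x t),
#'   `labels` (training labels), `centers` and `fcm` (fmlda),
#'   `factorization` (dlda), and `call`.
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 2), 20))
#' g <- rep(c("a", "b"), each = 20)
#' fit <- fmlda(x, g, method = "mlda")
#' head(predict(fit, x))
#' @export
fmlda <- function(x, ...) UseMethod("fmlda")

#' @rdname fmlda
#' @export
fmlda.default <- function(x, grouping, method = c("fmlda", "mlda", "dlda"),
                          ncomp = NULL, fuzzifier = 2,
                          fcm = fcm_control(fuzzifier), centers = NULL, ...) {
  method <- match.arg(method)
  X <- as.matrix(x)
  storage.mode(X) <- "double"
  labels <- factor(grouping)
  if (length(labels) != nrow(X)) stop("one label per row required")
  st <- class_statistics(X, labels)
  n <- nrow(X); d <- ncol(X); c_n <- nlevels(labels)
  if (c_n < 2L) stop("need at least 2 classes")
  if (is.null(ncomp)) ncomp <- c_n - 1L
  if (ncomp < 1L) stop("ncomp must be >= 1")
  if (method %in% c("mlda", "fmlda")) {
    if (ncomp > c_n - 1L)
      stop("ncomp must be <= c - 1 = ", c_n - 1L,
           " (rank bound of the between-class scatter)")
    if (n <= c_n) stop("need n > c samples for the pooled within scatter")
  }

  fcm_res <- NULL
  ctr <- st$class_means
  if (method == "fmlda") {
    if (!inherits(fcm, "fcm_control")) fcm <- do.call(fcm_control, fcm)
    if (!missing(fuzzifier)) fcm$fuzzifier <- fuzzifier
    if (fcm$fuzzifier <= 1) stop("fuzzifier m must be > 1")
    init <- if (is.null(centers)) st$class_means else as.matrix(centers)
    if (nrow(init) != c_n || ncol(init) != d)
      stop("centers must be a ", c_n, " x ", d, " matrix")
    fcm_res <- fcm_fit(X, init, fcm)
    ctr <- fcm_res$centers
  }

  # rows of A are deviations from the (class-mean or fuzzy) centers;
  # rows of Hb are sqrt(n_i)-weighted center deviations from the global
  # mean, so Sw = A'A and Sb = Hb'Hb without forming d x d matrices.
  A <- X - ctr[as.integer(labels), , drop = FALSE]
  Hb <- sweep(ctr, 2L, st$global_mean) * sqrt(st$class_counts)

  if (method == "dlda") {
    res <- .dlda_directions(A, Hb, ncomp)
    if (ncomp > res$available)
      stop("ncomp must be <= rank of the between-class scatter (",
           res$available, ")")
  } else {
    res <- .mu_directions(A, Hb, n, c_n, ncomp, route = "auto")
  }

  W <- res$W
  obj <- structure(list(scaling = W, eigvals = res$eigvals, method = method,
                        ncomp = ncol(W), lev = levels(labels),
                        counts = st$class_counts, means = st$class_means,
                        global_mean = st$global_mean,
                        scores = X %*% W, labels = labels,
                        centers = if (method == "fmlda") ctr else NULL,
                        fcm = fcm_res,
                        factorization = res$factorization,
                        call = match.call()),
                   class = "fmlda")
  obj
}

#' @rdname fmlda
#' @export
fmlda.spectra_set <- function(x, ...) {
  fit <- fmlda.default(x$absorbance, x$labels, ...)
  fit$wavenumbers <- x$wavenumbers
  fit$call <- match.call()
  fit
}

#' @rdname fmlda
#' @param formula a formula of the form `grouping ~ .` (or naming
#'   predictor columns), with `data` a data frame.
#' @param data data frame holding the variables of `formula`.
#' @export
fmlda.formula <- function(x, data, ...) {
  formula <- x
  mf <- stats::model.frame(formula, data)
  grouping <- stats::model.response(mf)
  X <- stats::model.matrix(stats::terms(formula, data = data), mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  fit <- fmlda.default(X, grouping, ...)
  fit$call <- match.call()
  fit
}
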