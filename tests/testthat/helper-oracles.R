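# Independent oracles and small fixtures shared across tests.

# Brute-force scatter matrices: literal double loops over samples and
# classes, no matrix algebra shortcuts.
brute_scatter <- function(X, labels, centers = NULL) {
  labels <- factor(labels)
  lev <- levels(labels)
  d <- ncol(X)
  gm <- colMeans(X)
  Sw <- matrix(0, d, d); Sb <- matrix(0, d, d)
  for (i in seq_along(lev)) {
    idx <- which(labels == lev[i])
    ci <- if (is.null(centers)) colMeans(X[idx, , drop = FALSE]) else centers[i, ]
    for (k in idx) {
      dk <- X[k, ] - ci
      Sw <- Sw + outer(dk, dk)
    }
    db <- ci - gm
    Sb <- Sb + length(idx) * outer(db, db)
  }
  list(within = Sw, between = Sb)
}

# Exhaustive-search KNN: per query, sort all distances and majority-vote,
# written independently of the package's vectorized implementation.
brute_knn <- function(ref, ref_labels, queries, k) {
  ref_labels <- factor(ref_labels)
  out <- character(nrow(queries))
  for (q in seq_len(nrow(queries))) {
    d <- sqrt(rowSums((ref - matrix(queries[q, ], nrow(ref), ncol(ref),
                                    byrow = TRUE))^2))
    ord <- order(d, seq_along(d))
    nb <- ref_labels[ord[seq_len(k)]]
    tab <- table(nb)
    top <- names(tab)[tab == max(tab)]
    out[q] <- if (length(top) == 1L) top else
      as.character(nb[match(TRUE, as.character(nb) %in% top)])
  }
  factor(out, levels = levels(ref_labels))
}

# Gaussian class blobs: c classes of n_per samples in d dimensions with
# unit-variance noise around separated means.
gaussian_classes <- function(n_per = 10, d = 5, c = 3, sep = 3, seed = 1) {
  set.seed(seed)
  mu <- matrix(rnorm(c * d), c, d) * sep
  X <- do.call(rbind, lapply(seq_len(c), function(i)
    matrix(rnorm(n_per * d), n_per, d) + matrix(mu[i, ], n_per, d, byrow = TRUE)))
  list(X = X, labels = factor(rep(seq_len(c), each = n_per)), means = mu)
}

# Straightforward FCM reimplementation for cross-checking fcm_fit.
simple_fcm <- function(X, centers, m, eps, max_iter) {
  upd_u <- function(v) {
    u <- matrix(0, nrow(v), nrow(X))
    for (j in seq_len(nrow(X))) {
      dd <- sqrt(rowSums((v - matrix(X[j, ], nrow(v), ncol(v), byrow = TRUE))^2))
      if (any(dd == 0)) {
        u[, j] <- ifelse(dd == 0, 1 / sum(dd == 0), 0)
      } else {
        for (i in seq_len(nrow(v)))
          u[i, j] <- 1 / sum((dd[i] / dd)^(2 / (m - 1)))
      }
    }
    u
  }
  v <- centers
  for (it in seq_len(max_iter)) {
    u <- upd_u(v)
    vn <- (u^m %*% X) / rowSums(u^m)
    delta <- sqrt(max(rowSums((vn - v)^2)))
    v <- vn
    if (delta < eps) return(list(centers = v, memberships = upd_u(v), iterations = it))
  }
  list(centers = v, memberships = upd_u(v), iterations = max_iter)
}

# The frozen end-to-end fixture: the default generator recipe at 200
# channels with its default seed.
fixture_config <- function() synthetic_config(channels = 200)
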