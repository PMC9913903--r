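test_that("class statistics are exact and internally consistent", {
  X <- matrix(c(0, 2, 4, 6))
  g <- factor(c("a", "a", "b", "b"))
  st <- class_statistics(X, g)
  expect_equal(as.vector(st$class_means), c(1, 5))
  expect_equal(as.vector(st$global_mean), 3)
  expect_equal(as.vector(st$class_counts), c(2L, 2L))
  # weighted class-mean average equals the global mean
  set.seed(2)
  X2 <- matrix(rnorm(60), 20, 3)
  g2 <- factor(sample(3, 20, replace = TRUE))
  st2 <- class_statistics(X2, g2)
  expect_lt(max(abs(colSums(st2$class_means * st2$class_counts) /
                      sum(st2$class_counts) - st2$global_mean)), 1e-12)
  # single sample per class: means equal the samples
  st3 <- class_statistics(X2[1:3, ], factor(1:3))
  expect_equal(unname(st3$class_means), unname(X2[1:3, ]))
})

test_that("crisp scatter matches hand values and the brute-force oracle", {
  X <- matrix(c(0, 2, 4, 6))
  g <- factor(c("a", "a", "b", "b"))
  sp <- scatter_matrices(X, g)
  expect_equal(as.vector(sp$within), 4)
  expect_equal(as.vector(sp$between), 16)
  set.seed(31)
  for (rep in 1:8) {
    n <- sample(6:50, 1); d <- sample(2:10, 1); c_n <- sample(2:4, 1)
    Xr <- matrix(rnorm(n * d), n, d)
    gr <- factor(sample(c_n, n, replace = TRUE))
    while (nlevels(droplevels(gr)) < c_n) gr <- factor(sample(c_n, n, replace = TRUE))
    got <- scatter_matrices(Xr, gr)
    want <- brute_scatter(Xr, gr)
    expect_lt(max(abs(got$within - want$within)), 1e-10)
    expect_lt(max(abs(got$between - want$between)), 1e-10)
    # symmetry and PSD
    expect_lt(max(abs(got$within - t(got$within))), 1e-10)
    ev <- eigen(got$between, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8 * max(ev))
    expect_lte(sum(ev > 1e-8 * max(ev)), c_n - 1)
  }
  # degenerate inputs
  expect_equal(max(abs(scatter_matrices(X, factor(1:4))$within)), 0)
  expect_warning(scatter_matrices(X, factor(rep(1, 4))), "single class")
})

test_that("fuzzy scatter follows the printed center-based sums", {
  X <- matrix(c(0, 2, 4, 6))
  g <- factor(c("a", "a", "b", "b"))
  # centers pinned at the class means: exact reduction to the crisp pair
  st <- class_statistics(X, g)
  crisp <- scatter_matrices(X, g)
  fz <- fuzzy_scatter_matrices(X, g, st$class_means)
  expect_equal(fz$within, crisp$within)
  expect_equal(fz$between, crisp$between)
  # hand/brute-force values with centers (0, 6), global mean 3:
  # Sfw = 0 + 4 + 4 + 0 = 8, Sfb = 2*9 + 2*9 = 36
  ctr <- matrix(c(0, 6))
  fz2 <- fuzzy_scatter_matrices(X, g, ctr)
  want <- brute_scatter(X, g, centers = ctr)
  expect_equal(as.vector(fz2$within), 8)
  expect_equal(as.vector(fz2$between), 36)
  expect_equal(fz2$within, want$within)
  expect_equal(fz2$between, want$between)
  # translation invariance of the within part
  fz3 <- fuzzy_scatter_matrices(X + 5, g, ctr + 5)
  expect_equal(fz3$within, fz2$within, tolerance = 1e-12)
  expect_error(fuzzy_scatter_matrices(X, g, matrix(c(0, 3, 6))), "one row per class")
})

test_that("fuzzy scatter matches brute force on random instances", {
  set.seed(17)
  for (rep in 1:8) {
    n <- sample(6:50, 1); d <- sample(2:10, 1); c_n <- sample(2:4, 1)
    Xr <- matrix(rnorm(n * d), n, d)
    gr <- factor(rep(seq_len(c_n), length.out = n))
    ctr <- matrix(rnorm(c_n * d), c_n, d)
    got <- fuzzy_scatter_matrices(Xr, gr, ctr)
    want <- brute_scatter(Xr, gr, centers = ctr)
    expect_lt(max(abs(got$within - want$within)), 1e-10)
    expect_lt(max(abs(got$between - want$between)), 1e-10)
  }
})

test_that("eigenvalue shrinkage applies the max(lambda, mean) rule", {
  # pooled eigenvalues (4, 2, 0): mean 2, adjusted (4, 2, 2)
  S <- diag(c(4, 2, 0)) * 10      # n - c = 10
  sh <- shrink_within_scatter(S, n = 13, c = 3)
  expect_equal(sh$eigvals, c(4, 2, 0))
  expect_equal(sh$mean_eigval, 2)
  expect_equal(sh$adjusted_eigvals, c(4, 2, 2))
  expect_equal(eigen(sh$reconstructed, symmetric = TRUE)$values,
               c(40, 20, 20), tolerance = 1e-10)
  # isotropic within is unchanged
  iso <- diag(3, 4)
  sh2 <- shrink_within_scatter(iso, n = 10, c = 2)
  expect_equal(sh2$reconstructed, iso, tolerance = 1e-10)
  expect_error(shrink_within_scatter(iso, n = 2, c = 2), "n > c")
})

test_that("shrinkage matches an independent dense eigensolver on rank-deficient input", {
  set.seed(41)
  for (rep in 1:5) {
    d <- 20; r <- 8; n <- 30; c_n <- 3
    H <- matrix(rnorm(d * r), d, r)
    S <- H %*% t(H)               # PSD, rank 8
    sh <- shrink_within_scatter(S, n, c_n)
    lam <- eigen(S / (n - c_n), symmetric = TRUE, only.values = TRUE)$values
    lam <- pmax(lam, 0)
    lbar <- mean(lam)
    want <- sort(pmax(lam, lbar) * (n - c_n), decreasing = TRUE)
    got <- eigen(sh$reconstructed, symmetric = TRUE, only.values = TRUE)$values
    expect_lt(max(abs(got - want)), 1e-8)
    # monotonicity: no eigenvalue shrinks, floor at lbar*(n-c)
    expect_gte(min(got), lbar * (n - c_n) * (1 - 1e-8))
    expect_true(all(got >= sort(lam * (n - c_n), decreasing = TRUE) - 1e-8))
  }
})
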