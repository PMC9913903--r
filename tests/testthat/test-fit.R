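test_that("mlda matches a naive direct solve on a small dense instance", {
  gc <- gaussian_classes(n_per = 10, d = 5, c = 3, seed = 4)
  fit <- fmlda(gc$X, gc$labels, method = "mlda", ncomp = 2)
  sp <- scatter_matrices(gc$X, gc$labels)
  sh <- shrink_within_scatter(sp$within, nrow(gc$X), 3)
  eg <- eigen(solve(sh$reconstructed) %*% sp$between)
  expect_equal(fit$eigvals, Re(eg$values[1:2]), tolerance = 1e-8)
  for (j in 1:2) {
    v <- Re(eg$vectors[, j]); v <- v / sqrt(sum(v^2))
    expect_gte(abs(sum(v * fit$scaling[, j])), 1 - 1e-8)
  }
})

test_that("mlda/fmlda enforce the c-1 component bound; dlda the Sb rank bound", {
  gc <- gaussian_classes(n_per = 8, d = 6, c = 3, seed = 5)
  expect_error(fmlda(gc$X, gc$labels, method = "mlda", ncomp = 3), "c - 1")
  expect_error(fmlda(gc$X, gc$labels, method = "fmlda", ncomp = 5), "c - 1")
  expect_error(fmlda(gc$X, gc$labels, method = "dlda", ncomp = 3), "rank")
  # 6-class input at the default gives 5 components for every method
  gc6 <- gaussian_classes(n_per = 8, d = 12, c = 6, seed = 6)
  for (meth in c("mlda", "fmlda", "dlda")) {
    f <- suppressMessages(fmlda(gc6$X, gc6$labels, method = meth))
    expect_equal(f$ncomp, 5L)
    expect_equal(dim(coef(f)), c(12L, 5L))
  }
  # 2-class data: rank(Sb) = 1, exactly one dlda component
  gc2 <- gaussian_classes(n_per = 10, d = 4, c = 2, seed = 7)
  expect_equal(fmlda(gc2$X, gc2$labels, method = "dlda")$ncomp, 1L)
})

test_that("a single mlda component aligns with the mean-difference direction", {
  set.seed(9)
  d <- 6
  mu <- rnorm(d)
  X <- rbind(matrix(rnorm(30 * d), 30, d),
             matrix(rnorm(30 * d), 30, d) + matrix(8 * mu, 30, d, byrow = TRUE))
  g <- factor(rep(1:2, each = 30))
  fit <- fmlda(X, g, method = "mlda", ncomp = 1)
  dmu <- colMeans(X[31:60, ]) - colMeans(X[1:30, ])
  cosang <- abs(sum(fit$scaling[, 1] * dmu)) / sqrt(sum(dmu^2))
  expect_gte(cosang, 0.99)
})

test_that("gram and dense within-shrinkage routes agree when d > n", {
  gc <- gaussian_classes(n_per = 8, d = 80, c = 3, seed = 10)
  st <- class_statistics(gc$X, gc$labels)
  A <- gc$X - st$class_means[as.integer(gc$labels), ]
  fg <- fmlda:::.shrink_inv_half(A, nrow(gc$X), 3, "gram")
  fd <- fmlda:::.shrink_inv_half(A, nrow(gc$X), 3, "dense")
  Y <- matrix(rnorm(80 * 3), 80, 3)
  expect_lt(max(abs(fg(Y) - fd(Y))), 1e-10)
  # whole-fit agreement through both routes
  Hb <- sweep(st$class_means, 2, st$global_mean) * sqrt(st$class_counts)
  rg <- fmlda:::.mu_directions(A, Hb, nrow(gc$X), 3, 2, "gram")
  rd <- fmlda:::.mu_directions(A, Hb, nrow(gc$X), 3, 2, "dense")
  expect_equal(rg$eigvals, rd$eigvals, tolerance = 1e-8)
  expect_lt(max(abs(rg$W - rd$W)), 1e-8)
})

test_that("fmlda with centers pinned to the class means reproduces mlda", {
  gc <- gaussian_classes(n_per = 10, d = 30, c = 4, seed = 12)
  st <- class_statistics(gc$X, gc$labels)
  f_m <- fmlda(gc$X, gc$labels, method = "mlda", ncomp = 3)
  f_f <- fmlda(gc$X, gc$labels, method = "fmlda", ncomp = 3,
               centers = st$class_means, fcm = fcm_control(max_iter = 0))
  # up-to-sign agreement of projections (sign already fixed by convention)
  expect_lt(max(abs(abs(f_f$scaling) - abs(f_m$scaling))), 1e-8)
  expect_lt(max(abs(abs(f_f$scores) - abs(f_m$scores))), 1e-6)
})

test_that("fmlda with a free fcm run yields a valid separated model", {
  cfg <- synthetic_config(classes = 6, samples_per_class = 12, channels = 120)
  ds <- synthetic_spectra(cfg, seed = 3)
  X <- snv(ds$absorbance)
  fit <- suppressMessages(fmlda(X, ds$labels, method = "fmlda",
                                fuzzifier = 2.7, ncomp = 5))
  expect_equal(fit$ncomp, 5L)
  expect_true(all(is.finite(fit$scaling)))
  expect_equal(dim(fit$centers), c(6L, 120L))
  # projected class separation beats the first-5-PC projection
  sep_fit <- {
    pr <- scatter_matrices(fit$scores, ds$labels)
    sum(diag(pr$between)) / sum(diag(pr$within))
  }
  pc <- prcomp(X, center = TRUE)$rotation[, 1:5]
  sc_pc <- X %*% pc
  sep_pc <- {
    pr <- scatter_matrices(sc_pc, ds$labels)
    sum(diag(pr$between)) / sum(diag(pr$within))
  }
  expect_gte(sep_fit, sep_pc)
})

test_that("dlda factorization satisfies its stated identities", {
  gc <- gaussian_classes(n_per = 20, d = 8, c = 4, seed = 14)
  fit <- fmlda(gc$X, gc$labels, method = "dlda")
  fac <- fit$factorization
  sp <- scatter_matrices(gc$X, gc$labels)
  expect_lt(max(abs(crossprod(fac$Y) - diag(ncol(fac$Y)))), 1e-8)
  expect_lt(max(abs(t(fac$Y) %*% sp$between %*% fac$Y - diag(fac$Db))), 1e-6)
  expect_lt(max(abs(crossprod(fac$Z, sp$between %*% fac$Z) - diag(ncol(fac$Z)))),
            1e-6)
  # W diagonalizes both scatters simultaneously
  W <- fit$scaling
  for (S in list(sp$between, sp$within)) {
    M <- t(W) %*% S %*% W
    off <- sum(abs(M - diag(diag(M)))) / sum(abs(diag(M)))
    expect_lt(off, 1e-6)
  }
})

test_that("fits are invariant to sample ordering up to the sign convention", {
  gc <- gaussian_classes(n_per = 9, d = 7, c = 3, seed = 15)
  perm <- sample(length(gc$labels))
  for (meth in c("mlda", "fmlda", "dlda")) {
    f1 <- suppressMessages(fmlda(gc$X, gc$labels, method = meth, ncomp = 2))
    f2 <- suppressMessages(fmlda(gc$X[perm, ], gc$labels[perm],
                                 method = meth, ncomp = 2))
    expect_lt(max(abs(f1$scaling - f2$scaling)), 1e-6)
  }
})

test_that("predict projects to scores of the right shape, deterministically", {
  gc <- gaussian_classes(n_per = 10, d = 20, c = 3, seed = 16)
  fit <- fmlda(gc$X, gc$labels, method = "mlda", ncomp = 2)
  Q <- matrix(rnorm(5 * 20), 5, 20)
  sc <- predict(fit, Q)
  expect_equal(dim(sc), c(5L, 2L))
  expect_equal(sc, Q %*% coef(fit))
  expect_identical(predict(fit, Q[1, , drop = FALSE]),
                   predict(fit, Q[1, , drop = FALSE]))
  expect_equal(predict(fit, matrix(0, 2, 20)), matrix(0, 2, 2))
  expect_error(predict(fit, matrix(0, 2, 19)), "channels")
  # class prediction returns labels
  cls <- predict(fit, gc$X, type = "class", k = 1)
  expect_s3_class(cls, "factor")
  expect_equal(as.character(cls), as.character(gc$labels))
})

test_that("formula and spectra_set interfaces agree with the matrix interface", {
  gc <- gaussian_classes(n_per = 8, d = 4, c = 2, seed = 18)
  df <- data.frame(gc$X, grade = gc$labels)
  f1 <- fmlda(gc$X, gc$labels, method = "mlda", ncomp = 1)
  f2 <- fmlda(grade ~ ., data = df, method = "mlda", ncomp = 1)
  expect_equal(unname(f2$scaling), unname(f1$scaling), tolerance = 1e-10)
  ds <- spectra_set(gc$X, seq(9000, 6000, length.out = 4), gc$labels)
  f3 <- fmlda(ds, method = "mlda", ncomp = 1)
  expect_equal(f3$scaling, f1$scaling)
  expect_output(print(f3), "MLDA")
  expect_output(print(summary(f3)), "trace ratio")
})
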