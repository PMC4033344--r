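test_that("degenerate training sets give zero scatter", {
  g <- matrix(runif(12), 3, 4)
  b <- fit_basis(list(g, g), d = 2)
  expect_equal(b$cov, matrix(0, 4, 4))
  expect_equal(b$eigenvalues, rep(0, 4))
  expect_error(fit_basis(list(g), d = 1), "at least 2")
  expect_error(fit_basis(list(g, g), d = 5), "between 1")
})

test_that("a diagonal image covariance yields the standard basis", {
  a <- sqrt(1.5); b <- sqrt(0.5)
  tmpls <- list(matrix(c(a, 0), 1), matrix(c(-a, 0), 1),
                matrix(c(0, b), 1), matrix(c(0, -b), 1))
  fit <- fit_basis(tmpls, d = 2)
  expect_equal(fit$cov, diag(c(3, 1)))
  expect_equal(fit$eigenvalues, c(3, 1))
  expect_equal(abs(fit$W), diag(2))
})

test_that("2DPCA matches an independent SVD oracle on random templates", {
  set.seed(101)
  for (rep in 1:5) {
    mats <- random_templates(10, 8, 6)
    d <- sample(2:6, 1)
    fit <- fit_basis(mats, d = d)
    orc <- oracle_2dpca(mats, d)
    expect_equal(fit$mean, orc$mean, tolerance = 1e-10)
    expect_equal(fit$cov, orc$cov, tolerance = 1e-10)
    expect_equal(fit$eigenvalues, orc$eigenvalues, tolerance = 1e-8)
    expect_equal(abs(fit$W), abs(orc$W), tolerance = 1e-8)
    # orthonormality
    expect_equal(crossprod(fit$W), diag(d), tolerance = 1e-9)
  }
})

test_that("scatter trace is the quadratic form, maximized by the top axis", {
  set.seed(102)
  mats <- random_templates(8, 6, 5)
  fit <- fit_basis(mats, d = 5)
  expect_equal(scatter_trace(fit, fit$W[, 1]), fit$eigenvalues[1],
               tolerance = 1e-8)
  for (i in 1:10) {
    w <- rnorm(5); w <- w / sqrt(sum(w^2))
    v <- scatter_trace(fit, w)
    expect_equal(v, drop(t(w) %*% fit$cov %*% w), tolerance = 1e-10)
    expect_lte(v, fit$eigenvalues[1] + 1e-9)
  }
  g <- matrix(runif(30), 6, 5)
  zero <- fit_basis(list(g, g), d = 5)
  expect_equal(scatter_trace(zero, c(1, 0, 0, 0, 0)), 0)
  expect_error(scatter_trace(fit, rep(1, 5)), "unit")
})

test_that("projection assembles columns G W_k in eigenvalue order", {
  set.seed(103)
  G <- matrix(runif(30), 6, 5)
  mats <- random_templates(6, 6, 5)
  fit <- fit_basis(mats, d = 3)
  # selector projection
  fit_sel <- fit
  fit_sel$W <- diag(5)[, 1:3]
  expect_equal(unclass(project_template(G, fit_sel)), G[, 1:3],
               ignore_attr = TRUE)
  # matrix-product oracle
  Y <- unclass(project_template(G, fit))
  for (k in 1:3) expect_equal(Y[, k], drop(G %*% fit$W[, k]))
  # full orthonormal basis preserves the Frobenius norm
  fit_full <- fit_basis(mats, d = 5)
  Yf <- unclass(project_template(G, fit_full))
  expect_equal(norm(Yf, "F"), norm(G, "F"), tolerance = 1e-10)
})

test_that("projection is linear in the input grid", {
  set.seed(104)
  mats <- random_templates(6, 5, 4)
  fit <- fit_basis(mats, d = 3)
  A <- matrix(rnorm(20), 5, 4); B <- matrix(rnorm(20), 5, 4)
  lhs <- unclass(project_template(2.5 * A - 1.2 * B, fit))
  rhs <- 2.5 * unclass(project_template(A, fit)) -
    1.2 * unclass(project_template(B, fit))
  expect_equal(lhs, rhs, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("feature distance is a sum of column norms", {
  A <- matrix(0, 2, 1); B <- matrix(c(3, 4), 2, 1)
  expect_equal(feature_distance(A, A), 0)
  expect_equal(feature_distance(A, B), 5)
  set.seed(105)
  for (i in 1:10) {
    X <- matrix(rnorm(12), 4, 3); Y <- matrix(rnorm(12), 4, 3)
    Z <- matrix(rnorm(12), 4, 3)
    expect_equal(feature_distance(X, Y), oracle_distance(X, Y))
    expect_equal(feature_distance(X, Y), feature_distance(Y, X))
    expect_lte(feature_distance(X, Z),
               feature_distance(X, Y) + feature_distance(Y, Z) + 1e-12)
  }
  expect_error(feature_distance(A, matrix(0, 3, 1)), "mismatch")
})

test_that("reconstruction converges to the original as d grows", {
  set.seed(106)
  mats <- random_templates(8, 7, 6)
  G <- mats[[1]]
  fit <- fit_basis(mats, d = 6)
  Y <- project_template(G, fit)
  expect_lte(norm(reconstruct_template(Y, fit) - G, "F"), 1e-8)
  expect_equal(reconstruct_template(Y, fit, components = integer(0)),
               matrix(0, 7, 6))
  errs <- vapply(1:6, function(d) {
    norm(reconstruct_template(Y, fit, components = seq_len(d)) - G, "F")
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-10))
  # truncated-expansion oracle
  for (d in 1:6) {
    manual <- matrix(0, 7, 6)
    for (k in seq_len(d))
      manual <- manual + unclass(Y)[, k] %*% t(fit$W[, k])
    expect_equal(reconstruct_template(Y, fit, components = seq_len(d)),
                 manual, tolerance = 1e-10)
  }
})

test_that("image covariance is PSD and trace-conserving; eigen tail decays", {
  set.seed(107)
  pop <- fixture_population(5, 2, 24, flip_prob = 0)
  tmpls <- lapply(pop, build_agdi)
  fit <- fit_basis(tmpls, d = 20)
  expect_true(all(fit$eigenvalues >= -1e-9 * fit$eigenvalues[1]))
  expect_equal(sum(diag(fit$cov)), sum(fit$eigenvalues), tolerance = 1e-8)
  # correlated templates concentrate scatter in the leading axes
  tail_frac <- sum(fit$eigenvalues[-(1:20)]) / sum(fit$eigenvalues)
  expect_lt(tail_frac, 0.05)
})

test_that("PCA baseline matches a flatten-then-eigendecompose oracle", {
  set.seed(108)
  mats <- random_templates(6, 5, 4)
  fit <- fit_pca_baseline(mats, d = 4)
  X <- vapply(mats, as.numeric, numeric(20))
  Xc <- X - rowMeans(X)
  e <- eigen(tcrossprod(Xc), symmetric = TRUE)
  expect_equal(fit$eigenvalues, e$values, tolerance = 1e-8)
  expect_equal(abs(fit$W), abs(e$vectors[, 1:4]), tolerance = 1e-8)
  # projection distances match the oracle
  y1 <- crossprod(e$vectors[, 1:4], Xc[, 1])
  y2 <- crossprod(e$vectors[, 1:4], Xc[, 2])
  p1 <- project_pca(mats[[1]], fit); p2 <- project_pca(mats[[2]], fit)
  expect_equal(feature_distance(p1, p2), sqrt(sum((y1 - y2)^2)),
               tolerance = 1e-8)
})

test_that("PCA rank is bounded by M - 1 and full-rank reconstruction is exact", {
  g1 <- matrix(runif(12), 3, 4); g2 <- matrix(runif(12), 3, 4)
  fit2 <- fit_pca_baseline(list(g1, g2), d = 1)
  expect_equal(sum(fit2$eigenvalues > fit2$eigenvalues[1] * 1e-9), 1)
  expect_error(fit_pca_baseline(list(g1, g2), d = 2), "rank")

  set.seed(109)
  mats <- random_templates(8, 4, 3)            # mn = 12 > M, rank = 7
  fit <- fit_pca_baseline(mats, d = 7)
  G <- mats[[3]]
  expect_lte(norm(reconstruct_pca(project_pca(G, fit), fit) - G, "F"), 1e-8)
})

test_that("basis serialization round-trips bit-exactly", {
  set.seed(110)
  mats <- random_templates(7, 6, 5)
  fit <- fit_basis(mats, d = 3)
  f <- tempfile(fileext = ".bin")
  write_basis(fit, f)
  back <- read_basis(f)
  expect_identical(back$mean, fit$mean)
  expect_identical(back$cov, fit$cov)
  expect_identical(back$eigenvalues, fit$eigenvalues)
  expect_identical(back$W, fit$W)

  pca <- fit_pca_baseline(mats, d = 4)
  f2 <- tempfile(fileext = ".bin")
  write_basis(pca, f2)
  back2 <- read_basis(f2)
  expect_identical(back2$mean, pca$mean)
  expect_identical(back2$W, pca$W)
  expect_identical(back2$dims, pca$dims)
})
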