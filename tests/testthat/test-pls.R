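test_that("one exact latent factor is recovered perfectly", {
  x <- matrix(1:4, ncol = 1)
  y <- 2 * x
  fit <- fit_stpls(x, y, n_components = 1)
  expect_equal(unname(predict(fit, x)), unname(y), tolerance = 1e-12)
  expect_equal(unname(fit$B[1, 1]), 2, tolerance = 1e-12)
})

test_that("kernel-algorithm fit matches the NIPALS reference up to column sign", {
  set.seed(42)
  for (nT in c(1, 2)) {
    x <- matrix(rnorm(20 * 10), 20, 10)
    y <- x[, 1:nT] %*% diag(nT) * 2 + matrix(rnorm(20 * nT), 20, nT)
    fit <- fit_mtpls(x, y, n_components = 3)
    ref <- nipals_reference(x, y, a = 3)
    expect_lt(max_reldiff_signfree(fit$W, ref$W), 1e-8)
    expect_lt(max_reldiff_signfree(fit$P, ref$P), 1e-8)
    expect_lt(max_reldiff_signfree(fit$Q, ref$Q), 1e-8)
    expect_lt(max(abs(fit$B - ref$B)) / max(abs(ref$B)), 1e-8)
  }
})

test_that("single-trait PLS is the one-column special case and starts from x'y", {
  set.seed(5)
  x <- matrix(rnorm(15 * 6), 15, 6)
  y <- rnorm(15)
  st <- fit_stpls(x, y, n_components = 2)
  mt <- fit_mtpls(x, matrix(y, ncol = 1), n_components = 2)
  expect_identical(st$B, mt$B)
  # first weight vector proportional to x'y on the centered data
  xc <- scale(x, scale = FALSE); yc <- y - mean(y)
  w1 <- crossprod(xc, yc)
  expect_lt(max_reldiff_signfree(st$W[, 1, drop = FALSE],
                                 w1 / sqrt(sum(w1^2))), 1e-10)
})

test_that("with a full component budget predictions equal least squares", {
  set.seed(10)
  x <- matrix(rnorm(30 * 5), 30, 5)
  y <- rnorm(30)
  fit <- fit_stpls(x, y, n_components = 5)
  ols <- lm(y ~ x)
  expect_equal(unname(predict(fit, x)[, 1]), unname(fitted(ols)),
               tolerance = 1e-6)
})

test_that("score geometry: unit-norm orthogonal scores, R and B identities", {
  set.seed(77)
  x <- matrix(rnorm(25 * 12), 25, 12)
  y <- matrix(rnorm(25 * 3), 25, 3)
  fit <- fit_mtpls(x, y, n_components = 4)
  TT <- crossprod(fit$T)
  expect_lt(max(abs(TT - diag(4))), 1e-8)
  expect_lt(max(abs(fit$R - fit$W %*% solve(crossprod(fit$P, fit$W)))), 1e-10)
  expect_lt(max(abs(fit$B - fit$R %*% fit$b)), 1e-10)
})

test_that("training residual sum of squares is non-increasing in the component count", {
  set.seed(13)
  x <- matrix(rnorm(40 * 8), 40, 8)
  y <- matrix(rnorm(40 * 2), 40, 2)
  fit <- fit_mtpls(x, y, n_components = 6)
  rss <- vapply(1:6, function(a) {
    sum((y - predict(fit, x, n_components = a))^2)
  }, numeric(1))
  expect_true(all(diff(rss) <= 1e-10))
})

test_that("truncated prediction equals an exact refit at the smaller component count", {
  set.seed(99)
  x <- matrix(rnorm(30 * 10), 30, 10)
  y <- matrix(rnorm(30 * 2), 30, 2)
  xh <- matrix(rnorm(7 * 10), 7, 10)
  full <- fit_mtpls(x, y, n_components = 6)
  for (a in c(1, 3, 5)) {
    refit <- fit_mtpls(x, y, n_components = a)
    expect_equal(predict(full, xh, n_components = a), predict(refit, xh),
                 tolerance = 1e-9)
  }
})

test_that("both prediction routes agree and behave at the training means", {
  set.seed(21)
  x <- matrix(rnorm(20 * 7), 20, 7)
  y <- matrix(rnorm(20 * 2), 20, 2)
  fit <- fit_mtpls(x, y, n_components = 3)
  xh <- matrix(rnorm(5 * 7), 5, 7)
  expect_equal(predict(fit, xh, method = "coefficients"),
               predict(fit, xh, method = "scores"), tolerance = 1e-10)
  # prediction at the training column means is the response mean
  expect_equal(unname(predict(fit, matrix(colMeans(x), 1))[1, ]),
               unname(colMeans(y)), tolerance = 1e-10)
  # explicit-loop oracle for held-out rows
  xc <- sweep(xh, 2, fit$x_means)
  manual <- matrix(0, 5, 2)
  for (i in 1:5) for (t in 1:2) {
    manual[i, t] <- sum(xc[i, ] * (fit$R %*% fit$b)[, t]) + fit$y_means[t]
  }
  expect_equal(unname(predict(fit, xh)), manual, tolerance = 1e-10)
})

test_that("permuting predictor columns permutes B rows and leaves predictions invariant", {
  set.seed(33)
  x <- matrix(rnorm(20 * 6), 20, 6)
  y <- rnorm(20)
  xh <- matrix(rnorm(4 * 6), 4, 6)
  perm <- sample(6)
  f1 <- fit_stpls(x, y, n_components = 3)
  f2 <- fit_stpls(x[, perm], y, n_components = 3)
  expect_equal(unname(f2$B), unname(f1$B[perm, , drop = FALSE]), tolerance = 1e-9)
  expect_equal(predict(f2, xh[, perm]), predict(f1, xh), tolerance = 1e-9)
})

test_that("scaling flag standardizes, errors on constant y, tolerates constant x", {
  set.seed(50)
  x <- cbind(matrix(rnorm(20 * 4), 20, 4), 1)   # constant predictor column
  y <- rnorm(20)
  fit <- fit_mtpls(x, matrix(y), n_components = 2, scale = TRUE)
  xh <- cbind(matrix(rnorm(3 * 4), 3, 4), 1)
  expect_true(all(is.finite(predict(fit, xh))))
  expect_error(fit_mtpls(x, matrix(1, 20, 1), n_components = 2, scale = TRUE),
               "zero-variance")
})

test_that("component budget violations and degenerate inputs are rejected", {
  x <- matrix(rnorm(10 * 3), 10, 3)
  y <- rnorm(10)
  expect_error(fit_stpls(x, y, n_components = 4), "n_components")
  expect_error(fit_stpls(x, y, n_components = 0), "n_components")
  # orthogonal y (x'y = 0) leaves nothing to extract
  expect_error(fit_stpls(matrix(c(1, -1, 1, -1)), c(1, 1, -1, -1), 1), "zero")
})

test_that("early stop on a rank-deficient predictor block records the achieved count", {
  set.seed(61)
  base <- matrix(rnorm(12 * 2), 12, 2)
  x <- cbind(base, base %*% matrix(rnorm(4), 2, 2))  # rank 2
  y <- rnorm(12)
  fit <- fit_stpls(x, y, n_components = 4)
  expect_lte(fit$n_components, 2L)
  expect_identical(ncol(fit$W), fit$n_components)
})

test_that("a saved model round-trips with bit-identical predictions", {
  set.seed(71)
  x <- matrix(rnorm(15 * 5), 15, 5)
  y <- matrix(rnorm(15 * 2), 15, 2)
  fit <- fit_mtpls(x, y, n_components = 3)
  path <- withr::local_tempfile(fileext = ".rds")
  write_pls_model(fit, path)
  fit2 <- read_pls_model(path)
  xh <- matrix(rnorm(6 * 5), 6, 5)
  expect_identical(predict(fit2, xh), predict(fit, xh))
})
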