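test_that("the RBF kernel is a unit-peak positive semi-definite similarity", {
  expect_equal(rbf_kernel(c(1, 2), c(1, 2), 0.7), 1)
  expect_equal(rbf_kernel(0, 1, 1), exp(-1))
  expect_equal(rbf_kernel(c(1, 0), c(0, 1), 2), rbf_kernel(c(0, 1), c(1, 0), 2))
  expect_error(rbf_kernel(1:2, 1:3, 1), "equal length")
  set.seed(2)
  P <- matrix(rnorm(15), 5, 3)
  K <- outer(1:5, 1:5, Vectorize(function(i, j)
    rbf_kernel(P[i, ], P[j, ], 0.5)))
  expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
             -1e-10)
})

test_that("a constant response yields a flat fitted function", {
  set.seed(3)
  X <- matrix(rnorm(20), 10, 2)
  fit <- fit_svr(X, rep(1.7, 10), svr_config())
  expect_true(all(abs(predict(fit, X) - 1.7) <= 0.01 + 1e-8))
})

test_that("the fit agrees with an independent QP solution of the dual", {
  skip_if_not_installed("kernlab")
  set.seed(3)
  for (n in c(4, 7, 10)) {
    X <- matrix(rnorm(n), ncol = 1)
    y <- sin(2 * X[, 1]) + 0.1 * rnorm(n)
    fit <- fit_svr(X, y, svr_config(C = 100, epsilon = 0.01, gamma = 0.5,
                                    standardize = FALSE))
    oracle <- svr_qp_oracle(X, y, C = 100, eps = 0.01, gamma = 0.5)
    Xq <- matrix(seq(min(X), max(X), length.out = 9), ncol = 1)
    expect_lt(max(abs(predict(fit, Xq) - oracle(Xq))), 1e-3)
  }
  # 1-D interpolation toy: near-zero training error is attainable
  X <- matrix(0:3, ncol = 1)
  fit <- fit_svr(X, as.numeric(0:3),
                 svr_config(C = 100, epsilon = 0.01, gamma = 0.5,
                            standardize = FALSE))
  expect_lt(rmse(0:3, predict(fit, X)), 0.05)
})

test_that("duplicated training rows with equal response leave the fit unchanged", {
  set.seed(5)
  X <- matrix(rnorm(16), 8, 2)
  y <- sin(X[, 1]) + 0.2 * X[, 2]
  cfg <- svr_config(C = 100, epsilon = 0.05, gamma = 0.7,
                    standardize = FALSE)
  f1 <- fit_svr(X, y, cfg)
  f2 <- fit_svr(rbind(X, X[3, , drop = FALSE]), c(y, y[3]), cfg)
  Xq <- matrix(rnorm(10), 5, 2)
  expect_equal(predict(f1, Xq), predict(f2, Xq), tolerance = 1e-6)
})

test_that("predictions are invariant to training-row order and standardization route", {
  set.seed(7)
  X <- matrix(rnorm(30), 15, 2)
  y <- X[, 1]^2 + 0.1 * rnorm(15)
  Xq <- matrix(rnorm(8), 4, 2)
  fit <- fit_svr(X, y, svr_config())
  perm <- sample(15)
  fit_p <- fit_svr(X[perm, ], y[perm], svr_config())
  # agreement limited only by the dual solver's stopping tolerance
  expect_equal(predict(fit, Xq), predict(fit_p, Xq), tolerance = 1e-5)

  ctr <- colMeans(X); scl <- apply(X, 2, sd)
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  Xqs <- sweep(sweep(Xq, 2, ctr), 2, scl, "/")
  fit_m <- fit_svr(Xs, y, svr_config(standardize = FALSE))
  expect_equal(predict(fit, Xq), predict(fit_m, Xqs), tolerance = 1e-8)

  expect_error(predict(fit, Xq[, 1, drop = FALSE]), "columns")
})

test_that("dual feasibility holds on small instances", {
  set.seed(11)
  X <- matrix(rnorm(24), 12, 2)
  y <- rnorm(12)
  for (C in c(0.5, 1, 10)) {
    fit <- fit_svr(X, y, svr_config(C = C))
    expect_true(all(abs(fit$coefficients) <= C + 1e-8))
    expect_lt(abs(sum(fit$coefficients)), 1e-8)
  }
})

test_that("support-vector count is non-increasing in epsilon", {
  set.seed(9)
  X <- matrix(rnorm(60), 30, 2)
  y <- X[, 1]^2 + 0.1 * rnorm(30)
  nsv <- vapply(c(0.01, 0.05, 0.1, 0.2, 0.4), function(e)
    length(fit_svr(X, y, svr_config(epsilon = e))$coefficients), numeric(1))
  expect_true(all(diff(nsv) <= 0))
})

test_that("the linear-kernel, small-epsilon, large-C limit matches OLS", {
  set.seed(13)
  X <- matrix(rnorm(40), 20, 2)
  y <- 2 + X %*% c(1.5, -0.5)
  fit <- fit_svr(X, drop(y), svr_config(C = 1e4, epsilon = 1e-6,
                                        kernel = "linear"))
  Xq <- matrix(rnorm(10), 5, 2)
  ols <- lm(drop(y) ~ X)
  expect_equal(predict(fit, Xq),
               drop(cbind(1, Xq) %*% coef(ols)), tolerance = 1e-3)
})

test_that("zero-variance columns pass through without error", {
  set.seed(15)
  X <- cbind(rnorm(10), rep(3, 10))
  y <- X[, 1] + 1
  fit <- fit_svr(X, y, svr_config())
  expect_equal(fit$unscaled_columns, 2L)
  expect_true(all(is.finite(predict(fit, X))))
})

test_that("JSON serialization round-trips a model exactly", {
  set.seed(17)
  X <- matrix(rnorm(24), 12, 2, dimnames = list(NULL, c("u", "v")))
  y <- X[, 1] - X[, 2]^2
  fit <- fit_svr(X, y, svr_config())
  path <- withr::local_tempfile(fileext = ".json")
  write_svr_json(fit, path)
  back <- read_svr_json(path)
  Xq <- matrix(rnorm(10), 5, 2)
  expect_equal(predict(back, Xq), predict(fit, Xq), tolerance = 1e-12)
  expect_equal(back$descriptor_names, c("u", "v"))
})
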