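test_that("descriptor generation is deterministic and respects blocks", {
  spec <- synthetic_spec(n = 30, p = 5, informative_idx = 1:2, seed = 7)
  X1 <- generate_descriptors(spec)
  X2 <- generate_descriptors(spec)
  expect_identical(X1, X2)
  # independent columns: no spuriously extreme sample correlation
  expect_true(max(abs(cor(X1)[upper.tri(diag(5))])) < 0.8)

  # one equicorrelated block at rho = 0.9: Monte-Carlo check
  spec9 <- synthetic_spec(n = 500, p = 4, informative_idx = 1,
                          block_correlation = 0.9, seed = 11)
  C <- cor(generate_descriptors(spec9))
  expect_equal(mean(C[upper.tri(C)]), 0.9, tolerance = 0.05)
})

test_that("responses follow the configured link with exact noiseless limits", {
  spec <- synthetic_spec(n = 20, p = 4, informative_idx = 1,
                         link = "linear", beta = 1, noise_sd = 0, seed = 5)
  X <- generate_descriptors(spec)
  resp <- generate_response(X, spec)
  expect_equal(resp$y, X[, 1])
  expect_equal(resp$y, resp$y_noiseless)

  # rbf link, one center: the center row attains exactly its weight
  spec_r <- synthetic_spec(n = 15, p = 3, informative_idx = 1:2,
                           link = "rbf_mixture", n_centers = 1,
                           noise_sd = 0, seed = 9)
  Xr <- generate_descriptors(spec_r)
  rr <- generate_response(Xr, spec_r)
  w <- rr$ground_truth$weights
  expect_equal(max(rr$y_noiseless), w, tolerance = 1e-12)
  peak <- which.max(rr$y_noiseless)
  expect_equal(unname(Xr[peak, 1:2]), unname(drop(rr$ground_truth$centers)))
})

test_that("OLS on the true columns recovers the planted linear coefficients", {
  spec <- synthetic_spec(n = 200, p = 6, informative_idx = c(2, 5),
                         link = "linear", beta = c(1.5, -2), noise_sd = 0.1,
                         seed = 21)
  X <- generate_descriptors(spec)
  resp <- generate_response(X, spec)
  fit <- summary(lm(resp$y ~ X[, 2] + X[, 5]))
  est <- coef(fit)[2:3, "Estimate"]
  se <- coef(fit)[2:3, "Std. Error"]
  expect_true(all(abs(est - c(1.5, -2)) < 3 * se))
})

test_that("noiseless linear data admits an exact linear fit", {
  spec <- synthetic_spec(n = 30, p = 5, informative_idx = 1:2,
                         link = "linear", beta = c(2, -1), noise_sd = 0,
                         seed = 13)
  ds <- synthesize_dataset(spec, test_fraction = 0.2)
  fit <- lm(ds$y ~ ds$X[, 1] + ds$X[, 2])
  expect_lt(max(abs(residuals(fit))), 1e-10)
})

test_that("the noiseless response is independent of non-informative columns", {
  # permutation test per nuisance column at alpha = 0.01; across seeds the
  # rejection count stays near the nominal false-positive rate
  perm_p <- function(y, x, B = 400, seed = 1) {
    obs <- abs(cor(y, x))
    set.seed(seed)
    null <- replicate(B, abs(cor(y, sample(x))))
    (1 + sum(null >= obs)) / (B + 1)
  }
  rejections <- 0L
  total <- 0L
  for (s in 1:5) {
    spec <- synthetic_spec(n = 40, p = 10, informative_idx = 1:2,
                           link = "rbf_mixture", noise_sd = 0, seed = 700 + s)
    X <- generate_descriptors(spec)
    resp <- generate_response(X, spec)
    for (j in 3:10) {
      total <- total + 1L
      if (perm_p(resp$y_noiseless, X[, j], seed = s * 100 + j) < 0.01)
        rejections <- rejections + 1L
    }
  }
  expect_lte(rejections, ceiling(0.01 * total) + 2L)
})

test_that("paper-scale instances have the study dimensions and splits", {
  q <- make_paper_like_instance("quinolone", seed = 1)
  expect_equal(dim(q), c(21L, 313L))
  expect_equal(sum(q$split == "train"), 16L)
  expect_equal(sum(q$split == "test"), 5L)
  expect_true(all(q$y >= 0))

  s <- make_paper_like_instance("sulfonamide", seed = 1)
  expect_equal(dim(s), c(39L, 113L))
  expect_equal(colnames(s$X)[113], "mobile_phase")
  expect_equal(sum(s$split == "train"), 30L)
  expect_equal(sum(s$split == "test"), 9L)

  s2 <- make_paper_like_instance("sulfonamide", seed = 2)
  expect_equal(dim(s2), dim(s))
  expect_false(identical(s2$y, s$y))
})

test_that("stratified splits preserve the response distribution", {
  spec <- synthetic_spec(n = 80, p = 4, informative_idx = 1,
                         link = "linear", noise_sd = 0.2, seed = 31)
  ds <- synthesize_dataset(spec, test_fraction = 0.25)
  ytr <- ds$y[ds$split == "train"]
  yte <- ds$y[ds$split == "test"]
  expect_equal(length(yte), 20L)
  # both sets span the response range rather than clustering at one end
  expect_lt(abs(median(ytr) - median(yte)), sd(ds$y))
  expect_gt(ks.test(ytr, yte)$p.value, 0.01)
})
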