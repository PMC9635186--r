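test_that("retention factor follows the dead-time normalization", {
  expect_equal(compute_retention_factor(2.9, 2.9), 0)
  expect_equal(compute_retention_factor(7.482, 2.9), 1.580, tolerance = 1e-3)
  expect_equal(compute_retention_factor(6.0, 2.0), 2.0)
  expect_equal(compute_retention_factor(c(2.9, 5.8), 2.9), c(0, 1))
  expect_error(compute_retention_factor(2.5, 2.9), "dead time")
  expect_error(compute_retention_factor(3, 0), "positive")
})

test_that("datasets load from CSV with strict numeric validation", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,d1,d2,k", "a,1,2,0.5", "b,3,4,0.7", "c,5,6,0.9"), path)
  ds <- suppressMessages(load_dataset(path, "k", "id"))
  expect_s3_class(ds, "qsrr_dataset")
  expect_equal(dim(ds), c(3L, 2L))
  expect_equal(ds$descriptor_names, c("d1", "d2"))
  expect_equal(ds$y, c(0.5, 0.7, 0.9))

  writeLines(c("id,d1,k", "a,1,0.5", "b,,0.7"), path)
  expect_error(suppressMessages(load_dataset(path, "k", "id")),
               "column 'd1', row 2")
  writeLines(c("id,d1,k", "a,1,0.5", "a,2,0.7"), path)
  expect_error(suppressMessages(load_dataset(path, "k", "id")), "duplicate")
  writeLines(c("id,d1,k", "a,x,0.5"), path)
  expect_error(suppressMessages(load_dataset(path, "k", "id")),
               "non-numeric")
  writeLines(c("id,d1,k", "a,1,-0.5"), path)
  expect_error(suppressMessages(load_dataset(path, "k", "id")), ">= 0")
})

test_that("write_dataset / load_dataset round-trips X, y and ids", {
  set.seed(42)
  X <- matrix(round(rnorm(24), 6), 8, 3,
              dimnames = list(NULL, c("alpha", "beta", "gamma")))
  ds <- qsrr_dataset(X, abs(round(rnorm(8), 6)), sprintf("cmp%02d", 1:8),
                     split = "train")
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(ds, path)
  back <- suppressMessages(load_dataset(path, "k", "id",
                                        split_column = "split"))
  expect_equal(unname(back$X), unname(ds$X))
  expect_equal(back$y, ds$y)
  expect_equal(back$ids, ds$ids)
  expect_equal(back$split, ds$split)
})

test_that("variance filtering drops constant and zero columns, idempotently", {
  X <- cbind(a = c(1, 2, 3, 4), b = rep(2.5, 4), c = c(0, 0, 0, 0))
  ds <- qsrr_dataset(X, c(1, 2, 3, 4), letters[1:4])
  f <- filter_descriptors(ds)
  log <- attr(f, "removal_log")
  expect_equal(f$descriptor_names, "a")
  expect_equal(sort(log$descriptor), c("b", "c"))
  expect_equal(log$reason[log$descriptor == "c"], "all_zero")
  expect_equal(log$reason[log$descriptor == "b"], "constant")
  expect_equal(length(f$y), 4L)

  # identity on clean data, with an empty log
  ds2 <- qsrr_dataset(matrix(rnorm(20), 5, 4), rnorm(5), letters[1:5])
  f2 <- filter_descriptors(ds2)
  expect_equal(f2$X, ds2$X)
  expect_equal(nrow(attr(f2, "removal_log")), 0L)

  # idempotence
  ff <- filter_descriptors(f)
  expect_equal(ff$X, f$X)
  expect_equal(nrow(attr(ff, "removal_log")), 0L)

  expect_error(filter_descriptors(
    qsrr_dataset(matrix(1, 4, 2), 1:4, letters[1:4])), "no modeling")
})

test_that("a 313-descriptor fund with 20 degenerate columns filters to 293", {
  ds <- make_paper_like_instance("quinolone", seed = 3)
  expect_equal(dim(ds), c(21L, 313L))
  f <- filter_descriptors(ds)
  expect_equal(length(f$descriptor_names), 293L)
  expect_equal(nrow(attr(f, "removal_log")), 20L)
})

test_that("split assignment validates ids and reproduces fixture membership", {
  ds <- qsrr_dataset(matrix(rnorm(12), 6, 2), rnorm(6), letters[1:6])
  ds <- assign_split(ds, c("b", "e"))
  expect_equal(sum(ds$split == "test"), 2L)
  expect_error(assign_split(ds, "zz"), "unknown")
  all_train <- assign_split(ds, character(0))
  expect_true(all(all_train$split == "train"))

  q <- qsrr_fixture("quinolones", "retention")
  expect_equal(c(sum(q$split == "train"), sum(q$split == "test")), c(16L, 5L))
  s <- qsrr_fixture("sulfonamides", "retention")
  expect_equal(c(sum(s$split == "train"), sum(s$split == "test")), c(30L, 9L))
})

test_that("packaged tables are internally consistent", {
  # retention-table k values agree with the prediction-table experimental k
  for (which in c("quinolones", "sulfonamides")) {
    ret <- qsrr_fixture(which, "retention")
    pred <- qsrr_fixture(which, "predictions")
    expect_setequal(ret$ids, pred$id)
    expect_equal(ret$y[match(pred$id, ret$ids)], pred$observed)
    # split membership matches between the two files
    expect_equal(ret$split[match(pred$id, ret$ids)], pred$set)
    # printed residuals follow predicted - experimental to printed rounding
    printed <- attr(pred, "printed_residual")
    expect_true(all(abs(pred$residual - printed) <= 0.0015))
    cvp <- attr(pred, "printed_cv_residual")
    keep <- !is.na(cvp)
    expect_true(all(abs(pred$cv_residual[keep] - cvp[keep]) <= 0.0015))
  }
})

test_that("prediction tables enforce the residual sign convention", {
  pt <- prediction_table(c("a", "b"), c("train", "test"),
                         observed = c(0.92, 1.1), predicted = c(1.175, 1.0),
                         cv_predicted = c(1.0, NA))
  expect_equal(pt$residual, c(0.255, -0.1))
  expect_error(prediction_table("a", "test", 1, 1, cv_predicted = 1),
               "test rows")
})
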