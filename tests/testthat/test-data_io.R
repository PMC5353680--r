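test_that("load_table parses features, flags missing cells, rejects degenerate labels", {
  path <- write_fixture_csv(c("f1,f2,class",
                              "1.5,2,a", "2.5,3,b", "3.5,4,a", "4.5,5,b"))
  ds <- load_table(path, "class")
  expect_s3_class(ds, "kiedra_dataset")
  expect_equal(dim(ds), c(4L, 2L))
  expect_equal(ds$feature_names, c("f1", "f2"))
  expect_equal(ds$features[, "f1"], c(1.5, 2.5, 3.5, 4.5))

  # empty cell and UCI '?' marker both flagged missing; load still succeeds
  path2 <- write_fixture_csv(c("f1,f2,class",
                               ",2,a", "2.5,?,b", "3.5,4,a", "4.5,5,b"))
  ds2 <- load_table(path2, "class")
  expect_true(is.na(ds2$features[1, 1]))
  expect_true(is.na(ds2$features[2, 2]))

  path3 <- write_fixture_csv(c("f1,class", "1,a", "2,a", "3,a", "4,a"))
  expect_error(load_table(path3, "class"), "degenerate labels")
  expect_error(load_table(path, "nope"), "class column not found")
  expect_error(load_table(tempfile(), "class"), "file not found")
})

test_that("writer mirrors reader (round-trip)", {
  path <- write_fixture_csv(c("f1,f2,class",
                              "0.1,2,a", "0.2,3,b", "0.3,4,a", "0.4,5,b"))
  ds <- load_table(path, "class")
  out <- tempfile(fileext = ".csv")
  write_table(ds, out)
  ds2 <- load_table(out, "class")
  expect_equal(ds2$features, ds$features)
  expect_equal(as.character(ds2$labels), as.character(ds$labels))
})

test_that("impute_missing: identity, mode fill, and NB hits the co-observed bin", {
  # no missing entries: identical dataset
  ds <- kiedra_dataset(cbind(f1 = 1:4, f2 = c(2, 2, 3, 3)), c("a", "b", "a", "b"))
  expect_identical(impute_missing(ds)$features, ds$features)

  # mode fill for a near-constant categorical-looking column
  X <- cbind(f1 = c(0.4, 0.4, NA, 0.4, NA, 0.4), f2 = 1:6)
  ds2 <- kiedra_dataset(X, rep(c("a", "b"), 3))
  got <- impute_missing(ds2, "mode_mean")
  expect_equal(got$features[c(3, 5), 1], c(0.4, 0.4))
  expect_false(anyNA(got$features))

  # deterministic-rule oracle: f2 duplicates f1; NB must put holes in the bin
  # dictated by f1 (>= 9/10)
  set.seed(42)
  f1 <- runif(100, 0, 10)
  f2 <- f1
  holes <- sample(100, 10)
  f2[holes] <- NA
  ds3 <- kiedra_dataset(cbind(f1 = f1, f2 = f2), rep(c("a", "b"), 50))
  got3 <- impute_missing(ds3, "naive_bayes", bins = 5L)
  obs <- f1[-holes]
  cuts <- seq(min(obs), max(obs), length.out = 6L)
  mids <- (cuts[-1] + cuts[-6]) / 2
  want_bin <- findInterval(f1[holes], cuts, rightmost.closed = TRUE, all.inside = TRUE)
  got_bin <- findInterval(got3$features[holes, 2], cuts,
                          rightmost.closed = TRUE, all.inside = TRUE)
  expect_gte(sum(got_bin == want_bin), 9)
  expect_false(anyNA(got3$features))

  # a feature missing everywhere is an error
  ds4 <- kiedra_dataset(cbind(f1 = c(NA, NA, NA, NA), f2 = 1:4),
                        c("a", "b", "a", "b"))
  expect_error(impute_missing(ds4), "missing in every row")
})

test_that("normalize_minmax maps to [0,1], constants to 0, and is idempotent", {
  ds <- kiedra_dataset(cbind(a = c(2, 4, 6), b = c(5, 5, 5), c = c(0, 1, 0.5)),
                       c("x", "y", "x"))
  nm <- normalize_minmax(ds)
  expect_equal(nm$features[, "a"], c(0, 0.5, 1))
  expect_equal(nm$features[, "b"], c(0, 0, 0))
  expect_equal(nm$features[, "c"], c(0, 1, 0.5))
  expect_equal(normalize_minmax(nm)$features, nm$features)

  ds_na <- kiedra_dataset(cbind(a = c(1, NA, 3)), c("x", "y", "x"))
  expect_error(normalize_minmax(ds_na), "impute_missing")
})

test_that("split_train_test honors fractions, partitions rows, stratifies, repeats", {
  ds <- make_toy_classification("linear", m = 100, seed = 3)
  p25 <- split_train_test(ds, 0.25, seed = 9)
  expect_equal(nrow(p25$train$features), 25L)
  expect_equal(nrow(p25$test$features), 75L)
  p50 <- split_train_test(ds, 0.5, seed = 9)
  expect_equal(nrow(p50$train$features), 50L)

  # partition law: union = original multiset of rows, intersection empty
  key <- function(d) apply(cbind(d$features, as.character(d$labels)), 1, paste,
                           collapse = "|")
  expect_setequal(c(key(p25$train), key(p25$test)), key(ds))
  expect_length(intersect(key(p25$train), key(p25$test)), 0)

  # per-class counts within 1 of exact proportionality
  for (cl in ds$class_values) {
    exact <- 0.25 * sum(ds$labels == cl)
    expect_lte(abs(sum(p25$train$labels == cl) - exact), 1)
  }

  # same seed -> bit-identical; different seed -> different
  again <- split_train_test(ds, 0.25, seed = 9)
  expect_identical(again$train$features, p25$train$features)
  other <- split_train_test(ds, 0.25, seed = 10)
  expect_false(identical(other$train$features, p25$train$features))

  expect_error(split_train_test(ds, 1.2), "strictly between")
  ds_small <- kiedra_dataset(cbind(f = 1:5), c("a", "a", "a", "a", "b"))
  expect_error(split_train_test(ds_small, 0.5, stratified = TRUE),
               "at least 2 instances per class")
})
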