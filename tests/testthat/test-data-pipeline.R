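test_that("the stratified 80/20 split reproduces the floor-rule sizes", {
  y <- rep(c(0, 1), c(1998, 1278))            # 3276 samples
  sp <- stratified_split(y, 0.8, seed = 1)
  expect_equal(length(sp$train), 2621)
  expect_equal(length(sp$test), 655)
  expect_equal(sort(c(sp$train, sp$test)), 1:3276)
  # class proportions preserved within one sample per class
  expect_lte(abs(sum(y[sp$test] == 1) - 655 * 1278 / 3276), 1)
  sp2 <- stratified_split(y, 0.8, seed = 1)
  expect_identical(sp, sp2)
})

test_that("small balanced splits give each class its exact quota", {
  y <- rep(c("a", "b"), each = 5)
  sp <- stratified_split(y, 0.8, seed = 2)
  expect_equal(sum(y[sp$test] == "a"), 1)
  expect_equal(sum(y[sp$test] == "b"), 1)
  expect_error(stratified_split(c("a", "b", "b"), 0.8), "at least 2")
})

test_that("stratified folds partition the data evenly by class", {
  y <- rep(c(0, 1), each = 50)
  folds <- kfold_stratified(y, k = 5, seed = 3)
  expect_equal(sort(unlist(folds)), 1:100)
  expect_true(all(lengths(folds) == 20))
  for (f in folds)
    expect_lte(abs(sum(y[f] == 1) - 10), 1)
  expect_error(kfold_stratified(rep(c(0, 1), c(3, 50)), k = 5), "at least k")
})

test_that("imputation picks mean or median by skewness", {
  # symmetric column -> mean
  out <- impute(data.frame(sym = c(1, 2, 3, NA)))
  expect_equal(out$sym[4], 2)
  expect_equal(attr(out, "impute_stats")$statistic, "mean")
  # heavy right skew -> median
  out <- impute(data.frame(skw = c(1, 1, 1, 100, NA)))
  expect_equal(out$skw[5], 1)
  expect_equal(attr(out, "impute_stats")$statistic, "median")
  # complete table unchanged
  z <- data.frame(a = c(1, 2, 3))
  expect_equal(impute(z)$a, z$a)
  expect_error(impute(data.frame(bad = c(NA_real_, NA_real_))), "bad")
})

test_that("preprocessing statistics transfer without leakage", {
  train <- data.frame(v = c(1, 2, 3, NA))
  test <- data.frame(v = c(NA, 10))
  tr <- impute(train)
  te <- impute(test, stats = attr(tr, "impute_stats"))
  expect_equal(te$v[1], 2)               # train mean, not test mean
  # recomputing on the shifted test data gives a different transform
  te_leaky <- impute(test)
  expect_false(te_leaky$v[1] == te$v[1])

  ntr <- minmax_normalize(data.frame(v = c(0, 5, 10)))
  nte <- minmax_normalize(data.frame(v = c(20)), ranges = attr(ntr, "ranges"))
  expect_equal(ntr$v, c(0, 0.5, 1))
  expect_equal(nte$v, 2)                 # outside [0,1], not clipped
  expect_warning(minmax_normalize(data.frame(c0 = c(2, 2))), "constant")
})

test_that("the generator meets its contracts", {
  tab <- generate_synthetic_table(n_samples = 1200, missing_rate = 0,
                                  seed = 11)
  expect_equal(nrow(tab$x), 1200)
  expect_equal(ncol(tab$x), 8)
  expect_false(anyNA(tab$x))
  expect_lte(abs(mean(tab$y) - 0.4), 0.02)
  tab2 <- generate_synthetic_table(n_samples = 1200, missing_rate = 0,
                                   seed = 11)
  expect_identical(tab$x, tab2$x)
  expect_identical(tab$y, tab2$y)
  # labels depend only on the informative block: adding noise features
  # leaves them untouched
  tab3 <- generate_synthetic_table(n_samples = 1200, missing_rate = 0,
                                   n_noise = 5, seed = 11)
  expect_identical(tab$y, tab3$y)
  # missingness rate is honored
  tabm <- generate_synthetic_table(n_samples = 2000, missing_rate = 0.1,
                                   seed = 12)
  expect_lt(abs(mean(is.na(as.matrix(tabm$x))) - 0.1), 0.01)
})

test_that("the radial label rule is nonlinear in any single feature", {
  tab <- generate_synthetic_table(n_samples = 400, missing_rate = 0,
                                  label_rule = "radial", seed = 13)
  x <- as.matrix(tab$x)
  # best single-feature threshold accuracy stays modest...
  best_single <- 0
  for (j in seq_len(ncol(x))) {
    for (thr in unique(x[, j])) {
      acc <- max(mean((x[, j] <= thr) == (tab$y == 1)),
                 mean((x[, j] > thr) == (tab$y == 1)))
      best_single <- max(best_single, acc)
    }
  }
  expect_lte(best_single, 0.8)
  # ...while a nearest-neighbour rule on the informative block succeeds
  xi <- scale(x[, tab$informative])
  fit <- nn1_fit(xi, tab$y)
  expect_gte(mean(predict(fit, xi) == tab$y), 0.95)
})

test_that("delimited tables round-trip and reject malformed input", {
  tab <- data.frame(a = c(1.123456789012, NA, 3), b = c(4, 5, 6.5))
  path <- tempfile(fileext = ".csv")
  write_table_checked(tab, path)
  back <- read_table_checked(path)
  expect_equal(back$a, tab$a, tolerance = 1e-12)
  expect_true(is.na(back$a[2]))

  # nine-column layout (8 features + binary label)
  wq <- as.data.frame(matrix(runif(45), ncol = 9))
  names(wq) <- c(paste0("f", 1:8), "label")
  write_table_checked(wq, path)
  expect_equal(dim(read_table_checked(path)), c(5L, 9L))

  ragged <- tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2", "3,4,5"), ragged)
  expect_error(read_table_checked(ragged), "ragged row 3")

  alpha <- tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,x", "3,4"), alpha)
  expect_error(read_table_checked(alpha), "row 1, column 'b'")
})
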