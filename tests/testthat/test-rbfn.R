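test_that("design_matrix is a Gaussian kernel with unit self-similarity", {
  X <- matrix(c(0.2, 0.4, 0.8, 0.1), ncol = 2, byrow = TRUE)
  Phi <- design_matrix(X, X, gamma = 1)
  expect_equal(diag(Phi), c(1, 1))
  expect_equal(Phi, t(Phi))
  expect_true(all(Phi > 0 & Phi <= 1))
  # gamma = 1 and squared distance log(2) gives exactly 0.5
  C <- matrix(c(0, 0), ncol = 2)
  x <- matrix(c(sqrt(log(2)), 0), ncol = 2)
  expect_equal(design_matrix(x, C, 1)[1, 1], 0.5, tolerance = 1e-12)
  # large gamma kills off-center activations
  expect_lt(design_matrix(x, C, 100)[1, 1], 1e-10)
})

test_that("fit_output_weights solves the ridge problem in closed form", {
  I5 <- diag(5)
  y <- c(1, 0, 1, 1, 0)
  expect_equal(fit_output_weights(I5, y, lambda = 0), y)
  expect_equal(fit_output_weights(I5, y, lambda = 1), y / 2)
  set.seed(3)
  Phi <- matrix(runif(40), nrow = 8)
  yy <- runif(8)
  w0 <- fit_output_weights(Phi, yy, 0)
  for (lam in c(0.01, 0.1, 1))
    expect_lte(sqrt(sum(fit_output_weights(Phi, yy, lam)^2)),
               sqrt(sum(w0^2)) + 1e-12)
  # rank-deficient unpenalized system falls back to minimum norm
  Phi_sing <- cbind(Phi, Phi[, 1])
  expect_warning(fit_output_weights(Phi_sing, yy, 0), "rank-deficient")
})

test_that("select_centers honors each method's contract", {
  set.seed(4)
  X <- matrix(runif(20), ncol = 2)
  C <- select_centers(X, 10, "random_subset", seed = 1)
  expect_equal(dim(C), dim(X))
  expect_equal(C[order(C[, 1]), ], X[order(X[, 1]), ])  # a permutation
  expect_error(select_centers(X, 11, "random_subset"), "M <=")
  expect_error(select_centers(X[0, , drop = FALSE], 2, "kmeans"), "empty")
  expect_identical(select_centers(X, 4, "kmeans", seed = 2),
                   select_centers(X, 4, "kmeans", seed = 2))
  G <- select_centers(X, 9, "grid")
  expect_equal(nrow(G), 9)
  expect_true(all(G[, 1] >= min(X[, 1]) & G[, 1] <= max(X[, 1])))
})

test_that("k-means centers match the exhaustive 2-means optimum on blobs", {
  set.seed(8)
  blob1 <- matrix(rnorm(16, mean = 0, sd = 0.05), ncol = 2)
  blob2 <- matrix(rnorm(16, mean = 3, sd = 0.05), ncol = 2)
  X <- rbind(blob1, blob2)
  C <- select_centers(X, 2, "kmeans", seed = 1)
  # exhaustive oracle: best 2-partition by within-group sum of squares
  n <- nrow(X)
  best <- list(ss = Inf)
  for (code in 1:(2^(n - 1) - 1)) {
    grp <- bitwAnd(code, 2^(0:(n - 1))) > 0
    if (!any(grp) || all(grp)) next
    m1 <- colMeans(X[grp, , drop = FALSE])
    m2 <- colMeans(X[!grp, , drop = FALSE])
    ss <- sum(sweep(X[grp, , drop = FALSE], 2, m1)^2) +
      sum(sweep(X[!grp, , drop = FALSE], 2, m2)^2)
    if (ss < best$ss) best <- list(ss = ss, m = rbind(m1, m2))
  }
  C <- C[order(C[, 1]), ]
  M <- best$m[order(best$m[, 1]), ]
  expect_equal(unname(C), unname(M), tolerance = 1e-6)
})

test_that("the interpolation limit reproduces training labels exactly", {
  set.seed(5)
  X <- matrix(runif(24), ncol = 2)
  y <- rep(c(0L, 1L), 6)
  fit <- rbfn(X, y, centers = 12, gamma = 2, lambda = 0,
              center_method = "random_subset", seed = 1)
  expect_equal(predict(fit, X), y)
  expect_equal(fit$train_accuracy, 1)
})

test_that("hyperparameter encoding maps the unit cube log-uniformly", {
  lo <- encode_hyperparams(c(0, 0, 0))
  expect_equal(lo$centers, 10L)
  expect_equal(lo$gamma, 0.01)
  expect_equal(lo$lambda, 1e-4)
  hi <- encode_hyperparams(c(1, 1, 1))
  expect_equal(hi$centers, 500L)
  expect_equal(hi$gamma, 10)
  expect_equal(hi$lambda, 1)
  mid <- encode_hyperparams(c(0.5, 0.5, 0.5))
  expect_equal(mid$centers, 71L)
  expect_equal(mid$gamma, sqrt(0.1), tolerance = 1e-10)
  expect_equal(mid$lambda, 0.01, tolerance = 1e-10)
  # decode is the inverse up to center rounding
  expect_equal(decode_hyperparams(hi), c(1, 1, 1))
  expect_equal(decode_hyperparams(list(centers = 10, gamma = 0.01,
                                       lambda = 1e-4)), c(0, 0, 0))
  # out-of-cube inputs are clipped first
  expect_equal(encode_hyperparams(c(2, -1, 0.5))$centers, 500L)
})

test_that("defaults separate a radially structured problem", {
  dat <- two_ring_data(n = 120, seed = 21)
  fit <- rbfn(dat$x, dat$y, seed = 2)   # M capped at n
  expect_gte(fit$train_accuracy, 0.95)
})

test_that("the formula interface and factor labels round-trip", {
  dat <- two_ring_data(n = 80, seed = 31)
  df <- data.frame(dat$x, quality = factor(ifelse(dat$y == 1, "good", "bad"),
                                           levels = c("bad", "good")))
  fit <- rbfn(quality ~ ., data = df, centers = 30, seed = 3)
  pred <- predict(fit, df)
  expect_s3_class(pred, "factor")
  expect_equal(levels(pred), c("bad", "good"))
  expect_gte(mean(pred == df$quality), 0.9)
  expect_equal(length(coef(fit)), nrow(fit$centers))
})

test_that("a saved model predicts identically after reload", {
  dat <- two_ring_data(n = 50, seed = 41)
  fit <- rbfn(dat$x, dat$y, centers = 20, seed = 4)
  path <- tempfile(fileext = ".json")
  write_rbfn(fit, path)
  back <- read_rbfn(path)
  expect_equal(predict(back, dat$x, type = "score"),
               predict(fit, dat$x, type = "score"), tolerance = 1e-12)
  expect_equal(predict(back, dat$x), predict(fit, dat$x))
})
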