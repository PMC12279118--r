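# Shared fixtures and tiny independent oracles, all built in code.

# Deterministic 1-nearest-neighbour classifier used as an external learner
# in wrapper-objective oracle tests (ties -> lowest index).
nn1_fit <- function(x, y) {
  structure(list(x = as.matrix(x), y = as.integer(y)), class = "nn1")
}
predict.nn1 <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  vapply(seq_len(nrow(X)), function(i) {
    d2 <- rowSums(sweep(object$x, 2, X[i, ])^2)
    object$y[which.min(d2)]
  }, integer(1))
}

# Stub learner that always predicts class 0 regardless of input; lets tests
# pin the CV error exactly from the fold label composition.
zero_fit <- function(x, y) structure(list(), class = "zero_clf")
predict.zero_clf <- function(object, newdata, ...) {
  rep(0L, nrow(as.matrix(newdata)))
}

# S3 dispatch needs these visible from the global environment.
assign("predict.nn1", predict.nn1, envir = globalenv())
assign("predict.zero_clf", predict.zero_clf, envir = globalenv())

# Construct k groups of m values with exactly prescribed between- and
# within-group sums of squares (used to exercise the ANOVA layout on the
# published SS/DF combinations).
make_anova_groups <- function(SS_between, SS_within, k, m, grand_mean = 0.5) {
  offs <- numeric(k)
  e <- sqrt(SS_between / (2 * m))
  offs[1] <- e
  offs[2] <- -e
  s <- sqrt(SS_within / (k * m))
  resid <- s * rep(c(1, -1), length.out = m)
  lapply(seq_len(k), function(j) grand_mean + offs[j] + resid)
}

# Brute-force exact two-tailed signed-rank p-value by explicit iteration
# over all 2^n sign assignments (n small); independent of the package's
# convolution-based computation.
brute_wilcoxon_p <- function(values, mu = 0) {
  d <- values - mu
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  t_obs <- sum(r[d > 0])
  sums <- vapply(0:(2^n - 1), function(code) {
    signs <- bitwAnd(code, 2^(0:(n - 1))) > 0
    sum(r[signs])
  }, numeric(1))
  p_ge <- mean(sums >= t_obs - 1e-9)
  p_le <- mean(sums <= t_obs + 1e-9)
  min(1, 2 * min(p_ge, p_le))
}

# A small radially separable binary problem in [0, 1]^2.
two_ring_data <- function(n = 60, seed = 42) {
  set.seed(seed)
  x <- matrix(runif(2 * n), ncol = 2)
  y <- as.integer(rowSums((x - 0.5)^2) < 0.08)
  list(x = x, y = y)
}
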