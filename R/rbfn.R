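#' Radial basis function network classifier
#'
#' A three-layer network for binary classification: hidden units are
#' Gaussian kernels `phi_i(x) = exp(-gamma ||x - c_i||^2)` around centers
#' `c_i`, the output is the linear combination `f(x) = sum_i w_i phi_i(x)`,
#' thresholded to a class label. Centers come from unsupervised selection
#' (k-means by default), output weights from closed-form ridge regression on
#' the 0/1 targets. With the `sigma` width parameterization
#' `sigma^2 = 1 / (2 gamma)`, so `gamma = 1` corresponds to
#' `sigma = 1/sqrt(2)`.
#'
#' @param x A numeric matrix or data frame of features (default method), or
#'   a formula.
#' @param ... Passed to methods.
#' @return An object of class `"rbfn"` with elements `centers`, `gamma`,
#'   `weights`, `lambda`, `threshold`, `levels` (original class labels) and
#'   `train_accuracy`.
#' @examples
#' set.seed(1)
#' x <- matrix(runif(60), ncol = 2)
#' y <- as.integer(rowSums((x - 0.5)^2) < 0.08)
#' fit <- rbfn(x, y, centers = 10, seed = 1)
#' mean(predict(fit, x) == y)
#' @export
rbfn <- function(x, ...) UseMethod("rbfn")

#' @rdname rbfn
#' @param formula Model formula; the response must be binary (0/1, logical
#'   or a two-level factor).
#' @param data Data frame holding the variables of `formula`.
#' @export
rbfn.formula <- function(formula, data, ...) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  tm <- attr(mf, "terms")
  x <- stats::model.matrix(tm, mf)
  x <- x[, colnames(x) != "(Intercept)", drop = FALSE]
  fit <- rbfn.default(x, y, ...)
  fit$terms <- tm
  fit$call <- match.call()
  fit
}

#' @rdname rbfn
#' @param y Binary response: 0/1 numeric, logical, or a two-level factor
#'   (second level is treated as the positive class).
#' @param centers Number of hidden units `M` (default 100, capped at the
#'   number of training samples and, for k-means, at the number of distinct
#'   rows).
#' @param gamma Gaussian kernel coefficient (> 0, default 1).
#' @param lambda Ridge penalty on the output weights (>= 0, default 0.001).
#' @param center_method One of `"kmeans"`, `"random_subset"`, `"grid"`.
#' @param threshold Decision threshold on the network output (default 0.5).
#' @param seed Optional seed for the center selection.
#' @export
rbfn.default <- function(x, y, centers = 100, gamma = 1, lambda = 0.001,
                         center_method = c("kmeans", "random_subset", "grid"),
                         threshold = 0.5, seed = NULL, ...) {
  center_method <- match.arg(center_method)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("rbfn does not accept missing feature values; impute first")
  lv <- NULL
  if (is.factor(y)) {
    if (nlevels(y) != 2) stop("response must be binary")
    lv <- levels(y)
    y <- as.integer(y == lv[2])
  } else if (is.logical(y)) {
    y <- as.integer(y)
  }
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("response must be coded 0/1")
  stopifnot(gamma > 0, lambda >= 0, centers >= 1)
  M <- min(as.integer(centers), nrow(x))
  C <- select_centers(x, M, center_method, seed = seed)
  Phi <- design_matrix(x, C, gamma)
  w <- fit_output_weights(Phi, y, lambda)
  scores <- drop(Phi %*% w)
  fit <- structure(list(centers = C, gamma = gamma, weights = w,
                        lambda = lambda, threshold = threshold,
                        center_method = center_method, levels = lv,
                        train_accuracy = mean(as.integer(scores >= threshold) == y),
                        n_train = nrow(x), call = match.call()),
                   class = "rbfn")
  fit
}

#' Select RBF centers
#'
#' `"kmeans"` uses seeded [stats::kmeans()] centroids, `"random_subset"`
#' draws `M` distinct training rows, `"grid"` lays `M` points on a uniform
#' lattice spanning the observed per-dimension ranges.
#'
#' @param X Sample matrix (rows = samples).
#' @param M Number of centers.
#' @param method Center selection method.
#' @param seed Optional seed.
#' @return An `M x d` matrix of centers.
#' @export
select_centers <- function(X, M, method = c("kmeans", "random_subset", "grid"),
                           seed = NULL) {
  method <- match.arg(method)
  X <- as.matrix(X)
  if (nrow(X) == 0) stop("cannot select centers from an empty sample matrix")
  M <- as.integer(M)
  with_seed(seed, {
    switch(method,
      kmeans = {
        Mx <- min(M, nrow(unique(X)))
        if (Mx == nrow(unique(X))) unique(X)
        else stats::kmeans(X, centers = Mx, nstart = 3, iter.max = 50)$centers
      },
      random_subset = {
        if (M > nrow(X))
          stop("random_subset requires M <= number of samples")
        X[sample.int(nrow(X), M), , drop = FALSE]
      },
      grid = {
        d <- ncol(X)
        lo <- apply(X, 2, min)
        hi <- apply(X, 2, max)
        m <- ceiling(M^(1 / d))
        axes <- lapply(seq_len(d), function(j) {
          if (m == 1) (lo[j] + hi[j]) / 2 else seq(lo[j], hi[j], length.out = m)
        })
        G <- as.matrix(expand.grid(axes))
        colnames(G) <- colnames(X)
        G[seq_len(min(M, nrow(G))), , drop = FALSE]
      })
  })
}

#' Gaussian design matrix
#'
#' Entry `(i, j)` is `exp(-gamma ||x_i - c_j||^2)`, in `(0, 1]`, equal to 1
#' iff the sample coincides with the center.
#'
#' @param X `N x d` sample matrix.
#' @param centers `M x d` center matrix.
#' @param gamma Kernel coefficient (> 0).
#' @return An `N x M` matrix.
#' @export
design_matrix <- function(X, centers, gamma) {
  stopifnot(gamma > 0)
  X <- as.matrix(X)
  centers <- as.matrix(centers)
  # squared distances via the expansion ||x||^2 + ||c||^2 - 2 x.c
  d2 <- outer(rowSums(X^2), rowSums(centers^2), `+`) - 2 * X %*% t(centers)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

#' Closed-form ridge fit of the output weights
#'
#' Minimizes `||Phi w - y||^2 + lambda ||w||^2`. With `lambda = 0` the
#' minimum-norm least-squares solution is returned (a warning is issued if
#' the system is rank deficient).
#'
#' @param Phi Design matrix.
#' @param y 0/1 targets.
#' @param lambda Ridge penalty (>= 0).
#' @return Weight vector of length `ncol(Phi)`.
#' @export
fit_output_weights <- function(Phi, y, lambda = 0.001) {
  stopifnot(lambda >= 0, nrow(Phi) == length(y))
  if (lambda > 0) {
    M <- ncol(Phi)
    drop(solve(crossprod(Phi) + diag(lambda, M), crossprod(Phi, y)))
  } else {
    sv <- svd(Phi)
    tol <- max(dim(Phi)) * .Machine$double.eps * sv$d[1]
    r <- sum(sv$d > tol)
    if (r < ncol(Phi))
      warning("rank-deficient design with lambda = 0; ",
              "returning the minimum-norm solution")
    idx <- seq_len(r)
    drop(sv$v[, idx, drop = FALSE] %*%
           ((crossprod(sv$u[, idx, drop = FALSE], y)) / sv$d[idx]))
  }
}

#' @rdname rbfn
#' @param object A fitted `rbfn`.
#' @param newdata Matrix or data frame of features (for formula fits, a data
#'   frame with the original variables).
#' @param type `"class"` (default) for thresholded labels, `"score"` for the
#'   raw network output `f(x)`.
#' @export
predict.rbfn <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  if (!is.null(object$terms) && is.data.frame(newdata)) {
    tm <- stats::delete.response(object$terms)
    mm <- stats::model.matrix(tm, stats::model.frame(tm, newdata))
    newdata <- mm[, colnames(mm) != "(Intercept)", drop = FALSE]
  }
  X <- as.matrix(newdata)
  scores <- drop(design_matrix(X, object$centers, object$gamma) %*%
                   object$weights)
  if (type == "score") return(scores)
  cls <- as.integer(scores >= object$threshold)
  if (!is.null(object$levels))
    cls <- factor(object$levels[cls + 1L], levels = object$levels)
  cls
}

#' @export
print.rbfn <- function(x, ...) {
  cat("Radial basis function network classifier\n")
  cat(sprintf("  %d centers (%s), gamma = %.4g, lambda = %.4g, threshold = %.3g\n",
              nrow(x$centers), x$center_method, x$gamma, x$lambda,
              x$threshold))
  cat(sprintf("  trained on %d samples; training accuracy %.4f\n",
              x$n_train, x$train_accuracy))
  invisible(x)
}

#' @export
summary.rbfn <- function(object, ...) {
  print(object)
  cat("  output weights: min", signif(min(object$weights), 4),
      "median", signif(stats::median(object$weights), 4),
      "max", signif(max(object$weights), 4), "\n")
  invisible(object)
}

#' @export
coef.rbfn <- function(object, ...) object$weights

#' Map a unit-cube position to RBFN hyperparameters (and back)
#'
#' Log-uniform interpolation of the tuning ranges: centers in `[10, 500]`
#' (rounded), `gamma` in `[0.01, 10]`, `lambda` in `[1e-4, 1]`. Used to let
#' any continuous optimizer tune the network. `decode_hyperparams` is the
#' inverse (exact up to the rounding of `centers`).
#'
#' @param position Numeric vector of length 3 in `[0, 1]^3` (clipped first).
#' @return `encode_hyperparams`: a list with `centers`, `gamma`, `lambda`.
#' @export
encode_hyperparams <- function(position) {
  p <- pmin(1, pmax(0, as.numeric(position)))
  if (length(p) != 3) stop("position must have length 3")
  logi <- function(u, lo, hi) exp(log(lo) + u * (log(hi) - log(lo)))
  list(centers = as.integer(round(logi(p[1], 10, 500))),
       gamma = logi(p[2], 0.01, 10),
       lambda = logi(p[3], 1e-4, 1))
}

#' @rdname encode_hyperparams
#' @param config A list with `centers`, `gamma`, `lambda`.
#' @export
decode_hyperparams <- function(config) {
  inv <- function(v, lo, hi) (log(v) - log(lo)) / (log(hi) - log(lo))
  c(inv(config$centers, 10, 500), inv(config$gamma, 0.01, 10),
    inv(config$lambda, 1e-4, 1))
}

#' Save / load a fitted RBFN as a structured text file
#'
#' The model (centers, gamma, weights, threshold, labels) is stored as JSON
#' at full double precision, so a round trip reproduces predictions exactly.
#'
#' @param model A fitted `rbfn`.
#' @param path File path.
#' @export
write_rbfn <- function(model, path) {
  obj <- list(centers = unclass(as.data.frame(model$centers)),
              gamma = model$gamma, weights = as.numeric(model$weights),
              lambda = model$lambda, threshold = model$threshold,
              center_method = model$center_method,
              levels = model$levels, n_train = model$n_train,
              train_accuracy = model$train_accuracy)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_rbfn
#' @return `read_rbfn` returns the restored `rbfn` object.
#' @export
read_rbfn <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(centers = as.matrix(as.data.frame(obj$centers)),
                 gamma = obj$gamma,
                 weights = as.numeric(obj$weights),
                 lambda = obj$lambda, threshold = obj$threshold,
                 center_method = obj$center_method,
                 levels = obj$levels,
                 train_accuracy = obj$train_accuracy,
                 n_train = obj$n_train,
                 call = quote(read_rbfn(path))),
            class = "rbfn")
}
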