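#' Generate a synthetic water-quality style table
#'
#' Emulates a physicochemical water-monitoring table: continuous features
#' with heterogeneous scales and right skew (log-normal / gamma draws),
#' a binary suitability label driven *nonlinearly* by a planted subset of
#' informative features, decoy (pure-noise) features, redundant features
#' (noisy linear mixtures of the informative ones), and
#' completely-at-random missingness.
#'
#' Label rules: `"radial"` marks a sample positive when the standardized
#' informative features fall inside a centered ball (classes are not
#' linearly separable in any single feature); `"logistic"` thresholds a
#' quadratic form of the standardized informative features. Both rules set
#' the threshold at the `class_balance` quantile of the score, so the label
#' frequency matches `class_balance` up to label noise.
#'
#' @param n_samples Number of rows (default 3276, matching a typical
#'   potability-style monitoring table).
#' @param n_informative Number of planted informative features (default 3).
#' @param n_noise Number of pure-noise features (default 3).
#' @param n_redundant Number of redundant features, each a noisy mixture of
#'   two informative ones (default 2).
#' @param missing_rate Fraction of feature cells set to `NA` completely at
#'   random (default 0.1).
#' @param label_rule `"radial"` or `"logistic"`.
#' @param class_balance Target positive-class frequency (default 0.4).
#' @param label_noise Fraction of labels flipped at random (default 0).
#' @param seed Integer seed.
#' @return A list of class `"synth_table"`: `x` (data frame of features),
#'   `y` (integer 0/1 labels), index vectors `informative`, `redundant`,
#'   `noise`, and the generating `config`.
#' @examples
#' tab <- generate_synthetic_table(n_samples = 200, missing_rate = 0, seed = 1)
#' table(tab$y)
#' @export
generate_synthetic_table <- function(n_samples = 3276, n_informative = 3,
                                     n_noise = 3, n_redundant = 2,
                                     missing_rate = 0.1,
                                     label_rule = c("radial", "logistic"),
                                     class_balance = 0.4, label_noise = 0,
                                     seed = NULL) {
  label_rule <- match.arg(label_rule)
  stopifnot(n_informative >= 1, n_noise >= 0, n_redundant >= 0,
            missing_rate >= 0, missing_rate < 1,
            class_balance > 0, class_balance < 1,
            label_noise >= 0, label_noise < 0.5)
  with_seed(seed, {
    n <- as.integer(n_samples)
    # informative features: skewed, heterogeneous scales
    scales <- 10^seq(0, n_informative - 1)
    info <- sapply(seq_len(n_informative), function(j) {
      if (j %% 2 == 1) stats::rlnorm(n, meanlog = log(scales[j]), sdlog = 0.6)
      else stats::rgamma(n, shape = 2, scale = scales[j] / 2)
    })
    info <- matrix(info, nrow = n)
    z <- scale(info)
    score <- switch(label_rule,
      radial = sqrt(rowSums(z^2)),
      logistic = drop(z %*% seq_len(n_informative)) + rowSums(z^2))
    y <- as.integer(score <= stats::quantile(score, class_balance))
    if (label_noise > 0) {
      flip <- stats::runif(n) < label_noise
      y[flip] <- 1L - y[flip]
    }
    red <- NULL
    if (n_redundant > 0) {
      red <- sapply(seq_len(n_redundant), function(j) {
        j1 <- ((j - 1) %% n_informative) + 1
        j2 <- (j %% n_informative) + 1
        mix <- 0.6 * z[, j1] + 0.4 * z[, j2]
        mix + stats::rnorm(n, sd = 0.1)
      })
      red <- matrix(red, nrow = n)
    }
    noise <- NULL
    if (n_noise > 0) {
      noise <- sapply(seq_len(n_noise), function(j) {
        if (j %% 2 == 1) stats::rlnorm(n, meanlog = log(5 * j), sdlog = 0.8)
        else stats::rnorm(n, mean = 50 * j, sd = 10 * j)
      })
      noise <- matrix(noise, nrow = n)
    }
    x <- cbind(info, red, noise)
    colnames(x) <- c(sprintf("inf_%d", seq_len(n_informative)),
                     if (n_redundant > 0) sprintf("red_%d", seq_len(n_redundant)),
                     if (n_noise > 0) sprintf("noise_%d", seq_len(n_noise)))
    if (missing_rate > 0) {
      holes <- matrix(stats::runif(length(x)) < missing_rate, nrow = n)
      x[holes] <- NA
    }
    structure(list(x = as.data.frame(x), y = y,
                   informative = seq_len(n_informative),
                   redundant = if (n_redundant > 0)
                     n_informative + seq_len(n_redundant) else integer(0),
                   noise = if (n_noise > 0)
                     n_informative + n_redundant + seq_len(n_noise)
                     else integer(0),
                   config = list(n_samples = n, n_informative = n_informative,
                                 n_noise = n_noise, n_redundant = n_redundant,
                                 missing_rate = missing_rate,
                                 label_rule = label_rule,
                                 class_balance = class_balance,
                                 label_noise = label_noise, seed = seed)),
              class = "synth_table")
  })
}

#' @export
print.synth_table <- function(x, ...) {
  cat(sprintf("<synth_table> %d samples x %d features (%d informative, %d redundant, %d noise)\n",
              nrow(x$x), ncol(x$x), length(x$informative),
              length(x$redundant), length(x$noise)))
  cat(sprintf("  label rule: %s; positives: %.3f; missing cells: %.3f\n",
              x$config$label_rule, mean(x$y), mean(is.na(as.matrix(x$x)))))
  invisible(x)
}

#' Skew-guided imputation
#'
#' Per column, the sample skewness of the observed values decides the
#' statistic: `|skew| > 1` imputes the median (robust for skewed
#' measurements), otherwise the mean. To keep preprocessing leakage-free,
#' call once on the training table and pass the returned `stats` when
#' transforming a test table.
#'
#' @param table Data frame or matrix of numeric features.
#' @param stats Optional data frame from a previous call (training
#'   statistics); when supplied, its values are reused instead of being
#'   recomputed.
#' @return The imputed table, with the per-column statistics attached as
#'   attribute `"impute_stats"` (columns `column`, `skewness`, `statistic`,
#'   `value`).
#' @export
impute <- function(table, stats = NULL) {
  x <- as.data.frame(table)
  if (is.null(stats)) {
    stats <- do.call(rbind, lapply(names(x), function(nm) {
      v <- x[[nm]]
      obs <- v[!is.na(v)]
      if (length(obs) == 0)
        stop("column '", nm, "' is fully missing; cannot impute")
      # classic moment-ratio skewness (type 1): m3 / m2^(3/2)
      sk <- if (length(obs) >= 3) e1071::skewness(obs, type = 1) else 0
      if (!is.finite(sk)) sk <- 0
      use_median <- abs(sk) > 1
      data.frame(column = nm, skewness = sk,
                 statistic = if (use_median) "median" else "mean",
                 value = if (use_median) stats::median(obs) else mean(obs))
    }))
  }
  for (i in seq_len(nrow(stats))) {
    nm <- stats$column[i]
    if (!nm %in% names(x)) stop("no column named '", nm, "' in table")
    v <- x[[nm]]
    v[is.na(v)] <- stats$value[i]
    x[[nm]] <- v
  }
  attr(x, "impute_stats") <- stats
  x
}

#' Min-max normalization to the unit interval
#'
#' `(x - min) / (max - min)` per column. When `ranges` from a training fit
#' is supplied, those extremes are reused, so test values may legitimately
#' fall outside `[0, 1]` and are not clipped. A constant column is mapped
#' to 0 with a warning.
#'
#' @param table Numeric data frame or matrix (no missing values).
#' @param ranges Optional data frame (`column`, `min`, `max`) from a
#'   previous call.
#' @return Normalized table with attribute `"ranges"`.
#' @export
minmax_normalize <- function(table, ranges = NULL) {
  x <- as.data.frame(table)
  if (is.null(ranges)) {
    ranges <- do.call(rbind, lapply(names(x), function(nm) {
      data.frame(column = nm, min = min(x[[nm]]), max = max(x[[nm]]))
    }))
  }
  for (i in seq_len(nrow(ranges))) {
    nm <- ranges$column[i]
    lo <- ranges$min[i]; hi <- ranges$max[i]
    if (hi <= lo) {
      warning("column '", nm, "' is constant; mapped to 0")
      x[[nm]] <- 0
    } else {
      x[[nm]] <- (x[[nm]] - lo) / (hi - lo)
    }
  }
  attr(x, "ranges") <- ranges
  x
}

#' Stratified train/test split
#'
#' The test set holds `floor((1 - train_fraction) * n)` samples (so 3276
#' samples at 80/20 give 2621 train / 655 test); each class contributes by
#' largest-remainder rounding of its proportional quota, preserving the
#' label distribution.
#'
#' @param y Class labels (any atomic type; each class needs >= 2 members).
#' @param train_fraction Fraction of samples for training (default 0.8).
#' @param seed Optional seed making the within-class sampling reproducible.
#' @return A list with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(y, train_fraction = 0.8, seed = NULL) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  n <- length(y)
  tab <- table(y)
  if (any(tab < 2)) stop("every class needs at least 2 members")
  # epsilon guard: (1 - 0.8) * n can sit a hair below the integer it
  # represents in binary floating point, which would corrupt the floor rule
  n_test <- floor((1 - train_fraction) * n + 1e-9)
  quota <- n_test * as.numeric(tab) / n
  base <- floor(quota)
  rem <- n_test - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  with_seed(seed, {
    test_idx <- integer(0)
    classes <- names(tab)
    for (ci in seq_along(classes)) {
      members <- which(as.character(y) == classes[ci])
      take <- base[ci]
      if (take > 0)
        test_idx <- c(test_idx, sample(members, take))
    }
    test_idx <- sort(test_idx)
    list(train = setdiff(seq_len(n), test_idx), test = test_idx)
  })
}

#' Stratified k-fold partition
#'
#' Folds partition the index set; per-fold class proportions stay within
#' one sample of the global proportions (round-robin dealing of a shuffled
#' order within each class).
#'
#' @param y Class labels; every class needs at least `k` members.
#' @param k Number of folds (default 5).
#' @param seed Optional seed.
#' @return A list of `k` disjoint integer index vectors.
#' @export
kfold_stratified <- function(y, k = 5, seed = NULL) {
  stopifnot(k >= 2)
  tab <- table(y)
  if (any(tab < k)) stop("every class needs at least k members")
  with_seed(seed, {
    folds <- vector("list", k)
    for (cl in names(tab)) {
      members <- sample(which(as.character(y) == cl))
      assign_to <- rep(seq_len(k), length.out = length(members))
      for (f in seq_len(k))
        folds[[f]] <- c(folds[[f]], members[assign_to == f])
    }
    lapply(folds, sort)
  })
}

#' Read / write a delimited feature table
#'
#' Comma-separated text with a header row; missing cells are empty fields.
#' `read_table_checked` validates shape (ragged rows are an error citing
#' the row) and numeric content (a non-numeric cell is an error citing row
#' and column).
#'
#' @param path File path.
#' @return `read_table_checked`: a data frame of numeric columns.
#' @export
read_table_checked <- function(path) {
  nf <- utils::count.fields(path, sep = ",", quote = "\"")
  if (length(unique(nf)) > 1) {
    bad <- which(nf != nf[1])[1]
    stop("ragged row ", bad, " in '", path, "': ", nf[bad],
         " fields where ", nf[1], " expected")
  }
  x <- utils::read.csv(path, na.strings = c("", "NA"))
  for (j in seq_along(x)) {
    if (!is.numeric(x[[j]])) {
      v <- suppressWarnings(as.numeric(x[[j]]))
      bad <- which(is.na(v) & !is.na(x[[j]]))
      if (length(bad) > 0)
        stop("non-numeric cell at row ", bad[1], ", column '", names(x)[j],
             "'")
      x[[j]] <- v
    }
  }
  x
}

#' @rdname read_table_checked
#' @param table Data frame to write.
#' @export
write_table_checked <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}
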