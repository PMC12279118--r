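#' Sigmoid transfer function for binary encodings
#'
#' The steep logistic `S(x) = 1 / (1 + exp(-10 (x - 0.5)))` centered at
#' 0.5, mapping a continuous optimizer coordinate to an inclusion
#' probability. Strictly increasing, `S(0.5) = 0.5`, and symmetric:
#' `S(x) + S(1 - x) = 1`.
#'
#' @param x Numeric vector.
#' @return Values in `(0, 1)`.
#' @export
transfer_sigmoid <- function(x) 1 / (1 + exp(-10 * (x - 0.5)))

#' Threshold a continuous position into a feature mask
#'
#' Bit `j` is 1 iff `S(position_j) >= 0.5`, equivalently
#' `position_j >= 0.5` (a tie at exactly 0.5 selects the feature; a fixed
#' tie rule keeps runs deterministic).
#'
#' @param position Numeric vector.
#' @return Integer 0/1 vector of the same length.
#' @export
binarize <- function(position) {
  as.integer(transfer_sigmoid(position) >= 0.5)
}

#' Repair an empty feature mask
#'
#' No empty subset may reach the learner: if all bits are 0, the bit at the
#' largest position value is set (ties go to the lowest index); otherwise
#' the mask is returned unchanged.
#'
#' @param mask Integer 0/1 vector.
#' @param position The continuous position the mask was decoded from.
#' @return A mask with at least one set bit.
#' @export
repair_empty <- function(mask, position) {
  if (sum(mask) >= 1) return(mask)
  mask[which.max(position)] <- 1L
  mask
}

#' Wrapper feature-selection objective
#'
#' Builds the fitness function optimized by the binary ("b"-prefixed)
#' variants: a continuous position is binarized (sigmoid + threshold,
#' repaired if empty), the learner is cross-validated on the selected
#' columns, and the fitness is
#' `alpha * cv_error + (1 - alpha) * |mask| / d`.
#' Lower is better; at equal error a smaller subset wins.
#'
#' Cross-validation folds are frozen at construction (stratified, seeded),
#' so the objective is deterministic per mask; results are cached by mask,
#' which leaves every value unchanged but avoids refitting when the
#' optimizer revisits a subset. A single-class training fold is skipped
#' with a warning; if every fold degenerates the error is 1.
#'
#' @param x Feature table (complete, numeric).
#' @param y Binary 0/1 labels.
#' @param alpha Weight on the classification error (default 0.99, keeping
#'   error primary and the subset-size penalty a tie-breaker).
#' @param folds Number of stratified CV folds (default 5).
#' @param learner Function `(x_train, y_train) -> model` whose model is
#'   used with [predict()]; default is a fast RBFN configuration (k-means
#'   with `min(30, n)` centers, `gamma = 5`, `lambda = 0.001`). The
#'   narrower-than-default kernel suits min-max normalized features, whose
#'   local class structure a `sigma` around 0.3 resolves better than the
#'   full-model default width.
#' @param seed Seed fixing the CV folds (and the learner's internal
#'   randomness per fold).
#' @return A function `position -> fitness` with attributes `"d"` (number
#'   of features) and helper closure `"mask_error"` (mask -> CV error).
#' @export
fs_objective <- function(x, y, alpha = 0.99, folds = 5, learner = NULL,
                         seed = 1) {
  stopifnot(alpha > 0, alpha < 1)
  x <- as.matrix(x)
  y <- as.integer(y)
  d <- ncol(x)
  fold_idx <- kfold_stratified(y, k = folds, seed = seed)
  if (is.null(learner)) {
    learner <- function(xtr, ytr)
      rbfn(xtr, ytr, centers = min(30, nrow(xtr)),
           center_method = "kmeans", gamma = 5, lambda = 0.001,
           seed = seed)
  }
  cache <- new.env(parent = emptyenv())
  mask_error <- function(mask) {
    key <- paste(mask, collapse = "")
    if (!is.null(cache[[key]])) return(cache[[key]])
    cols <- which(mask == 1L)
    errs <- c()
    for (f in seq_along(fold_idx)) {
      te <- fold_idx[[f]]
      tr <- setdiff(seq_len(nrow(x)), te)
      if (length(unique(y[tr])) < 2) {
        warning("skipping single-class CV fold")
        next
      }
      fit <- learner(x[tr, cols, drop = FALSE], y[tr])
      pred <- predict(fit, x[te, cols, drop = FALSE])
      errs <- c(errs, mean(as.integer(as.character(pred)) != y[te]))
    }
    err <- if (length(errs) == 0) 1 else mean(errs)
    cache[[key]] <- err
    err
  }
  obj <- function(position) {
    mask <- repair_empty(binarize(position), position)
    alpha * mask_error(mask) + (1 - alpha) * sum(mask) / d
  }
  attr(obj, "d") <- d
  attr(obj, "mask_error") <- mask_error
  obj
}

#' Summarize repeated feature-selection runs
#'
#' Implements the standard multi-run report: mean classification error,
#' mean selected fraction, mean / best (min) / worst (max) fitness, and the
#' sample standard deviation (`M - 1` denominator) of fitness over the `M`
#' runs. With a single run the standard deviation is `NA`.
#'
#' @param runs A data frame (or list of per-run lists) with columns/fields
#'   `error`, `selected_fraction`, `fitness`.
#' @return A one-row data frame with `avg_error`, `avg_select_size`,
#'   `avg_fitness`, `best_fitness`, `worst_fitness`, `sd_fitness`, `runs`.
#' @export
summarize_fs_runs <- function(runs) {
  if (!is.data.frame(runs)) runs <- do.call(rbind.data.frame, runs)
  stopifnot(nrow(runs) >= 1,
            all(c("error", "selected_fraction", "fitness") %in% names(runs)))
  M <- nrow(runs)
  data.frame(avg_error = mean(runs$error),
             avg_select_size = mean(runs$selected_fraction),
             avg_fitness = mean(runs$fitness),
             best_fitness = min(runs$fitness),
             worst_fitness = max(runs$fitness),
             sd_fitness = if (M >= 2) stats::sd(runs$fitness) else NA_real_,
             runs = M)
}

#' Run a binary (wrapper feature-selection) optimizer
#'
#' Composes any registered continuous optimizer with the sigmoid-transfer
#' feature-selection objective: the optimizer searches `[0, 1]^d`, the
#' objective binarizes. Tags mirror the binary naming convention
#' (`"bdtoprs"`, `"bdto"`, `"bgwo"`, `"bpso"`, `"bba"`, `"bwoa"`,
#' `"bsbo"`, `"bfa"`).
#'
#' @param algorithm Optimizer tag (with or without the `b` prefix).
#' @param x,y Feature table and binary labels.
#' @param n,iters Population size and iterations.
#' @param alpha,folds,learner Passed to [fs_objective()].
#' @param seed Seed for both the CV folds and the optimizer.
#' @return A list with the decoded `mask`, `selected` column indices,
#'   `error` (CV error of the selected mask), `selected_fraction`,
#'   `fitness`, and the full `result` (`opt_result`).
#' @export
run_binary_fs <- function(algorithm, x, y, n = 30, iters = 100,
                          alpha = 0.99, folds = 5, learner = NULL,
                          seed = 1) {
  obj <- fs_objective(x, y, alpha = alpha, folds = folds, learner = learner,
                      seed = derive_seed(seed, "folds"))
  d <- attr(obj, "d")
  optimizer <- optimizer_registry(algorithm)
  res <- optimizer(obj, search_space(d), n = n, iters = iters, seed = seed)
  mask <- repair_empty(binarize(res$best_position), res$best_position)
  list(algorithm = algorithm, mask = mask, selected = which(mask == 1L),
       error = attr(obj, "mask_error")(mask),
       selected_fraction = sum(mask) / d,
       fitness = res$best_fitness, result = res)
}
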