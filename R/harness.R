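#' Cross-validated error of an RBFN configuration
#'
#' Mean misclassification rate over stratified folds for a given
#' hyperparameter configuration. Used as the tuning objective.
#'
#' @param x,y Training features (complete, numeric) and 0/1 labels.
#' @param config List with `centers`, `gamma`, `lambda` (see
#'   [encode_hyperparams()]).
#' @param folds Number of stratified folds or a precomputed fold list from
#'   [kfold_stratified()].
#' @param center_method Center selection method for each fold fit.
#' @param seed Seed for folds (when `folds` is a count) and fold fits.
#' @return Mean CV misclassification rate.
#' @export
rbfn_cv_error <- function(x, y, config = list(centers = 100, gamma = 1,
                                              lambda = 0.001),
                          folds = 5, center_method = "kmeans", seed = 1) {
  x <- as.matrix(x)
  y <- as.integer(y)
  fold_idx <- if (is.list(folds)) folds
              else kfold_stratified(y, k = folds, seed = seed)
  errs <- vapply(seq_along(fold_idx), function(f) {
    te <- fold_idx[[f]]
    tr <- setdiff(seq_len(nrow(x)), te)
    fit <- rbfn(x[tr, , drop = FALSE], y[tr], centers = config$centers,
                gamma = config$gamma, lambda = config$lambda,
                center_method = center_method,
                seed = derive_seed(seed, "fold", f))
    mean(predict(fit, x[te, , drop = FALSE]) != y[te])
  }, numeric(1))
  mean(errs)
}

#' Tune RBFN hyperparameters with a metaheuristic
#'
#' Minimizes the stratified CV misclassification rate over the unit cube
#' of encoded hyperparameters (centers, gamma, ridge penalty; see
#' [encode_hyperparams()]). The optimizer population is warm-started with
#' the default configuration's encoding, so the tuner never does worse than
#' the default under the same CV folds.
#'
#' @param x,y Training features and 0/1 labels.
#' @param optimizer Optimizer tag (default `"dtoprs"`).
#' @param n,iters Population size and iterations for the tuner.
#' @param folds CV folds (count or fold list).
#' @param center_method Center selection method.
#' @param seed Seed for folds, fold fits and the optimizer.
#' @param default_config Warm-start configuration (default: 100 centers,
#'   `gamma = 1`, `lambda = 0.001`).
#' @return List with `config` (best hyperparameters), `cv_error`, and the
#'   optimizer `result`.
#' @export
tune_rbfn <- function(x, y, optimizer = "dtoprs", n = 10, iters = 15,
                      folds = 5, center_method = "kmeans", seed = 1,
                      default_config = list(centers = 100, gamma = 1,
                                            lambda = 0.001)) {
  y <- as.integer(y)
  fold_idx <- if (is.list(folds)) folds
              else kfold_stratified(y, k = folds, seed = derive_seed(seed, "folds"))
  objective <- function(position) {
    cfg <- encode_hyperparams(position)
    rbfn_cv_error(x, y, cfg, folds = fold_idx,
                  center_method = center_method,
                  seed = derive_seed(seed, "cv"))
  }
  opt_fn <- optimizer_registry(optimizer)
  res <- opt_fn(objective, search_space(3), n = n, iters = iters,
                seed = seed, init = rbind(decode_hyperparams(default_config)))
  list(config = encode_hyperparams(res$best_position),
       cv_error = res$best_fitness, result = res)
}

#' Run a multi-optimizer feature-selection experiment
#'
#' For each binary optimizer tag, performs `runs` seeded wrapper
#' feature-selection executions and aggregates the per-run error, selected
#' fraction and fitness into the standard multi-run report (one column per
#' optimizer; rows: average error, average select size, average / best /
#' worst fitness, fitness standard deviation, mean wall time).
#'
#' @param x,y Feature table (complete, numeric) and binary 0/1 labels.
#' @param algorithms Character vector of optimizer tags (default the full
#'   binary family).
#' @param runs Independent runs per algorithm (default 10).
#' @param n,iters Population size and iterations per run.
#' @param alpha,folds,learner Passed to [fs_objective()].
#' @param seed Base seed; run `i` of algorithm `o` uses a seed derived from
#'   `(seed, o, i)`.
#' @return An object of class `"fs_experiment"`: list with `per_run` (data
#'   frame), `summary` (metrics x algorithms data frame), `masks` (final
#'   masks per algorithm and run) and `selection_frequency` (per-feature
#'   selection rate per algorithm).
#' @export
run_feature_selection_experiment <- function(x, y,
                                             algorithms = c("bdtoprs", "bdto",
                                                            "bgwo", "bpso",
                                                            "bba", "bwoa",
                                                            "bsbo", "bfa"),
                                             runs = 10, n = 30, iters = 100,
                                             alpha = 0.99, folds = 5,
                                             learner = NULL, seed = 1) {
  per_run <- list()
  masks <- list()
  for (algo in algorithms) {
    for (i in seq_len(runs)) {
      run_seed <- derive_seed(seed, algo, i)
      t0 <- proc.time()[["elapsed"]]
      fs <- run_binary_fs(algo, x, y, n = n, iters = iters, alpha = alpha,
                          folds = folds, learner = learner, seed = run_seed)
      per_run[[length(per_run) + 1L]] <-
        data.frame(algorithm = algo, run = i, error = fs$error,
                   selected_fraction = fs$selected_fraction,
                   fitness = fs$fitness,
                   time = proc.time()[["elapsed"]] - t0)
      masks[[algo]] <- rbind(masks[[algo]], fs$mask)
    }
  }
  per_run <- do.call(rbind, per_run)
  summaries <- lapply(algorithms, function(a) {
    s <- summarize_fs_runs(per_run[per_run$algorithm == a, ])
    c(avg_error = s$avg_error, avg_select_size = s$avg_select_size,
      avg_fitness = s$avg_fitness, best_fitness = s$best_fitness,
      worst_fitness = s$worst_fitness, sd_fitness = s$sd_fitness,
      time = mean(per_run$time[per_run$algorithm == a]))
  })
  summary <- as.data.frame(summaries, col.names = algorithms)
  sel_freq <- lapply(masks, colMeans)
  structure(list(per_run = per_run, summary = summary, masks = masks,
                 selection_frequency = sel_freq,
                 config = list(runs = runs, n = n, iters = iters,
                               alpha = alpha, folds = folds, seed = seed)),
            class = "fs_experiment")
}

#' @export
print.fs_experiment <- function(x, digits = 4, ...) {
  cat(sprintf("Feature-selection experiment: %d runs x %d algorithms\n",
              x$config$runs, ncol(x$summary)))
  print(round(x$summary, digits))
  invisible(x)
}

#' Run a model-tuning experiment
#'
#' For each optimizer tag and each run: stratified 80/20 split, leakage-free
#' preprocessing (skew-guided imputation and min-max normalization fitted on
#' the training split only), optional feature mask, metaheuristic RBFN
#' hyperparameter tuning on the training split, final fit, and held-out
#' evaluation with the six confusion-matrix metrics. A `"default"` tag may
#' be included to evaluate the untuned default configuration.
#'
#' @param x,y Full feature table (may contain `NA`) and binary 0/1 labels.
#' @param optimizers Tags to compare (default `c("dtoprs", "dto")`).
#' @param runs Independent runs (default 10).
#' @param n,iters Tuner population and iterations.
#' @param train_fraction,folds Split and CV configuration.
#' @param mask Optional 0/1 feature mask applied before tuning.
#' @param seed Base seed.
#' @return An object of class `"tuning_experiment"`: `per_run` data frame of
#'   metrics, `summary` (mean/sd accuracy per model via
#'   [summarize_models()]), and `accuracy` (runs x models data frame).
#' @export
run_optimization_experiment <- function(x, y, optimizers = c("dtoprs", "dto"),
                                        runs = 10, n = 10, iters = 15,
                                        train_fraction = 0.8, folds = 5,
                                        mask = NULL, seed = 1) {
  x <- as.data.frame(x)
  y <- as.integer(y)
  if (!is.null(mask)) x <- x[, which(mask == 1L), drop = FALSE]
  per_run <- list()
  for (tag in optimizers) {
    for (i in seq_len(runs)) {
      run_seed <- derive_seed(seed, tag, i)
      sp <- stratified_split(y, train_fraction, seed = run_seed)
      xtr <- impute(x[sp$train, , drop = FALSE])
      xte <- impute(x[sp$test, , drop = FALSE],
                    stats = attr(xtr, "impute_stats"))
      xtr <- minmax_normalize(xtr)
      xte <- minmax_normalize(xte, ranges = attr(xtr, "ranges"))
      ytr <- y[sp$train]; yte <- y[sp$test]
      if (tag == "default") {
        cfg <- list(centers = 100, gamma = 1, lambda = 0.001)
      } else {
        tuned <- tune_rbfn(as.matrix(xtr), ytr, optimizer = tag, n = n,
                           iters = iters, folds = folds, seed = run_seed)
        cfg <- tuned$config
      }
      fit <- rbfn(as.matrix(xtr), ytr, centers = cfg$centers,
                  gamma = cfg$gamma, lambda = cfg$lambda,
                  seed = derive_seed(run_seed, "final"))
      pred <- predict(fit, as.matrix(xte))
      m <- classification_metrics(confusion_counts(yte, pred))
      per_run[[length(per_run) + 1L]] <-
        data.frame(model = tag, run = i, t(m),
                   centers = cfg$centers, gamma = cfg$gamma,
                   lambda = cfg$lambda)
    }
  }
  per_run <- do.call(rbind, per_run)
  acc <- as.data.frame(split(per_run$accuracy, per_run$model)[optimizers])
  structure(list(per_run = per_run, summary = summarize_models(acc),
                 accuracy = acc,
                 config = list(runs = runs, n = n, iters = iters,
                               train_fraction = train_fraction,
                               folds = folds, seed = seed)),
            class = "tuning_experiment")
}

#' @export
print.tuning_experiment <- function(x, digits = 4, ...) {
  cat(sprintf("RBFN tuning experiment: %d runs\n", x$config$runs))
  print(x$summary, digits = digits)
  invisible(x)
}

#' ANOVA + Wilcoxon statistics report over per-run results
#'
#' One-way ANOVA across the model/optimizer columns plus a per-column
#' exact Wilcoxon signed-rank test against a theoretical median of 0,
#' rendered in the conventional report layout.
#'
#' @param runs_by_model Data frame or matrix; columns = models/optimizers,
#'   rows = runs (>= 2 of each).
#' @return An object of class `"stats_report"`: list with `anova`
#'   (`anova_oneway`) and `wilcoxon` (named list of `wilcoxon_exact`).
#' @export
run_stats_report <- function(runs_by_model) {
  df <- as.data.frame(runs_by_model)
  stopifnot(ncol(df) >= 2, nrow(df) >= 2)
  structure(list(anova = anova_oneway(df),
                 wilcoxon = lapply(df, wilcoxon_exact)),
            class = "stats_report")
}

#' @export
print.stats_report <- function(x, ...) {
  print(x$anova)
  cat("\nPer-column Wilcoxon signed-rank (theoretical median 0):\n")
  hdr <- names(x$wilcoxon)
  W <- vapply(x$wilcoxon, function(w) w$W_signed, numeric(1))
  p <- vapply(x$wilcoxon, function(w) w$p_two_tailed, numeric(1))
  med <- vapply(x$wilcoxon, function(w) w$actual_median, numeric(1))
  out <- rbind(`Actual median` = med, `Sum of signed ranks (W)` = W,
               `P value (two tailed)` = round(p, 3))
  colnames(out) <- hdr
  print(out)
  invisible(x)
}
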