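#' Confusion counts from labels
#'
#' @param truth,pred Binary 0/1 vectors (positives = 1).
#' @return A list with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(truth, pred) {
  truth <- as.integer(truth)
  pred <- as.integer(pred)
  stopifnot(length(truth) == length(pred),
            all(truth %in% 0:1), all(pred %in% 0:1))
  list(TP = sum(truth == 1 & pred == 1), TN = sum(truth == 0 & pred == 0),
       FP = sum(truth == 0 & pred == 1), FN = sum(truth == 1 & pred == 0))
}

#' Confusion-matrix classification metrics
#'
#' The six standard binary metrics: accuracy `(TP+TN)/total`, sensitivity
#' (TPR) `TP/(TP+FN)`, specificity (TNR) `TN/(TN+FP)`, positive predictive
#' value `TP/(TP+FP)`, negative predictive value `TN/(TN+FN)`, and the
#' F-score `2 TP / (2 TP + FP + FN)`. A metric whose denominator is zero is
#' undefined and reported as `NA` (never silently 0).
#'
#' @param counts A list with `TP`, `TN`, `FP`, `FN` (see
#'   [confusion_counts()]), or the `TP` count when the four counts are given
#'   positionally.
#' @param TN,FP,FN Individual counts when not passing a list.
#' @return Named numeric vector with `accuracy`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `f_score`.
#' @examples
#' classification_metrics(list(TP = 50, TN = 40, FP = 5, FN = 5))
#' @export
classification_metrics <- function(counts, TN = NULL, FP = NULL, FN = NULL) {
  if (!is.list(counts))
    counts <- list(TP = counts, TN = TN, FP = FP, FN = FN)
  with(counts, {
    stopifnot(TP >= 0, TN >= 0, FP >= 0, FN >= 0)
    safe <- function(num, den) if (den == 0) NA_real_ else num / den
    c(accuracy = safe(TP + TN, TP + TN + FP + FN),
      sensitivity = safe(TP, TP + FN),
      specificity = safe(TN, TN + FP),
      ppv = safe(TP, TP + FP),
      npv = safe(TN, TN + FN),
      f_score = safe(2 * TP, 2 * TP + FP + FN))
  })
}

#' One-way ANOVA decomposition
#'
#' Standard between/within sum-of-squares decomposition across groups with
#' the F ratio and its upper-tail p-value, computed through the base linear
#' model machinery and returned in the explicit table layout
#' (SS / DF / MS / F / p). If the within-group variance is zero the F
#' statistic is undefined and reported as `NA`.
#'
#' @param groups A list of numeric vectors (>= 2 groups, each >= 2 values),
#'   or a matrix/data frame whose columns are the groups.
#' @return An object of class `"anova_oneway"`: a list with `SS_between`,
#'   `SS_within`, `SS_total`, `DF_between`, `DF_within`, `DF_total`,
#'   `MS_between`, `MS_within`, `F`, `p`.
#' @export
anova_oneway <- function(groups) {
  if (is.matrix(groups) || is.data.frame(groups))
    groups <- lapply(as.data.frame(groups), as.numeric)
  stopifnot(length(groups) >= 2, all(vapply(groups, length, 1L) >= 2))
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  tab <- stats::anova(stats::lm(values ~ g))
  SSb <- tab$`Sum Sq`[1]
  SSw <- tab$`Sum Sq`[2]
  DFb <- tab$Df[1]
  DFw <- tab$Df[2]
  # zero within-group variance (up to numerical fuzz) leaves F undefined
  degenerate <- SSw <= 1e-14 * max(1, SSb)
  Fv <- if (degenerate) NA_real_ else tab$`F value`[1]
  p <- if (degenerate) NA_real_ else tab$`Pr(>F)`[1]
  structure(list(SS_between = SSb, SS_within = SSw, SS_total = SSb + SSw,
                 DF_between = DFb, DF_within = DFw, DF_total = DFb + DFw,
                 MS_between = SSb / DFb, MS_within = SSw / DFw,
                 F = Fv, p = p),
            class = "anova_oneway")
}

#' @export
print.anova_oneway <- function(x, ...) {
  cat("One-way ANOVA\n")
  cat(sprintf("  %-28s %-12s %-4s %-12s %s\n", "", "SS", "DF", "MS",
              "F (DFn, DFd) / P"))
  cat(sprintf("  %-28s %-12.4g %-4d %-12.4g F(%d, %d) = %.4g, %s\n",
              "Treatment (between columns)", x$SS_between, x$DF_between,
              x$MS_between, x$DF_between, x$DF_within, x$F,
              format_pvalue(x$p)))
  cat(sprintf("  %-28s %-12.4g %-4d %-12.4g\n",
              "Residual (within columns)", x$SS_within, x$DF_within,
              x$MS_within))
  cat(sprintf("  %-28s %-12.4g %-4d\n", "Total", x$SS_total, x$DF_total))
  invisible(x)
}

# report-style p rounding: 3 decimals with a "<0.0001" floor
format_pvalue <- function(p) {
  if (is.na(p)) return("P undefined")
  if (p < 1e-4) "P<0.0001" else sprintf("P=%.3f", p)
}

#' Exact Wilcoxon signed-rank test against a theoretical median
#'
#' Differences from `mu` are computed, zeros dropped, absolute differences
#' ranked with midranks for ties, and the two-tailed p-value is obtained
#' from the exact null distribution of the positive-rank sum over all
#' `2^n` equiprobable sign assignments of the realized rank vector
#' (computed by exact convolution on a half-integer grid, equivalent to
#' full enumeration) for `n <= 25`; beyond that a normal approximation
#' with tie correction is used.
#'
#' @param values Numeric vector.
#' @param mu Theoretical median (default 0).
#' @return An object of class `"wilcoxon_exact"`: a list with `W_signed`
#'   (`sum_positive - sum_negative`), `sum_positive`, `sum_negative`,
#'   `n_used` (after zero removal), `p_two_tailed`, `exact` (logical), and
#'   `actual_median`.
#' @examples
#' wilcoxon_exact(c(0.9, 0.95, 0.91, 0.92, 0.93, 0.94, 0.96, 0.97, 0.9, 0.98))
#' @export
wilcoxon_exact <- function(values, mu = 0) {
  d <- as.numeric(values) - mu
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all differences are zero; the test is undefined")
  r <- rank(abs(d))
  sum_pos <- sum(r[d > 0])
  sum_neg <- sum(r[d < 0])
  Ttot <- n * (n + 1) / 2
  exact <- n <= 25
  if (exact) {
    # exact null distribution of the positive-rank sum: convolution over
    # the doubled ranks (integers even under midranks), equivalent to
    # enumerating all 2^n sign assignments
    r2 <- as.integer(round(2 * r))
    maxs <- sum(r2)
    dist <- numeric(maxs + 1)
    dist[1] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), dist[seq_len(maxs + 1 - ri)])
      dist <- dist + shifted
    }
    dist <- dist / 2^n
    t2 <- as.integer(round(2 * sum_pos))
    p_ge <- sum(dist[(t2 + 1):(maxs + 1)])
    p_le <- sum(dist[1:(t2 + 1)])
    p <- min(1, 2 * min(p_ge, p_le))
  } else {
    tie_tab <- table(r)
    mu_T <- Ttot / 2
    var_T <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (sum_pos - mu_T) / sqrt(var_T)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  structure(list(W_signed = sum_pos - sum_neg, sum_positive = sum_pos,
                 sum_negative = sum_neg, n_used = n, p_two_tailed = p,
                 exact = exact, theoretical_median = mu,
                 actual_median = stats::median(as.numeric(values))),
            class = "wilcoxon_exact")
}

#' @export
print.wilcoxon_exact <- function(x, ...) {
  cat("Wilcoxon signed-rank test\n")
  cat(sprintf("  Theoretical median       %g\n", x$theoretical_median))
  cat(sprintf("  Actual median            %g\n", x$actual_median))
  cat(sprintf("  Number of values         %d\n", x$n_used))
  cat(sprintf("  Sum of signed ranks (W)  %g\n", x$W_signed))
  cat(sprintf("  Sum of positive ranks    %g\n", x$sum_positive))
  cat(sprintf("  Sum of negative ranks    %g\n", x$sum_negative))
  cat(sprintf("  P value (two tailed)     %.3f\n", x$p_two_tailed))
  cat(sprintf("  Exact or estimate?       %s\n",
              if (x$exact) "Exact" else "Estimate"))
  invisible(x)
}

#' Mean/sd summary of repeated model runs
#'
#' @param runs A named list of numeric vectors (per-model accuracy runs) or
#'   a data frame whose columns are models.
#' @return A data frame with one row per model: `model`, `mean`, `sd`
#'   (sample standard deviation, `M - 1` denominator), `runs`.
#' @export
summarize_models <- function(runs) {
  if (is.data.frame(runs) || is.matrix(runs))
    runs <- lapply(as.data.frame(runs), as.numeric)
  out <- do.call(rbind, lapply(names(runs), function(nm) {
    v <- runs[[nm]]
    data.frame(model = nm, mean = mean(v),
               sd = if (length(v) >= 2) stats::sd(v) else NA_real_,
               runs = length(v))
  }))
  rownames(out) <- NULL
  out
}
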