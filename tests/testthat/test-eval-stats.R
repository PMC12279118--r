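test_that("classification metrics follow the confusion-matrix formulas", {
  m <- classification_metrics(list(TP = 50, TN = 40, FP = 5, FN = 5))
  expect_equal(unname(m["accuracy"]), 0.9)
  expect_equal(unname(m["sensitivity"]), 50 / 55, tolerance = 1e-10)
  expect_equal(unname(m["f_score"]), 100 / 110, tolerance = 1e-10)
  perfect <- classification_metrics(list(TP = 10, TN = 10, FP = 0, FN = 0))
  expect_true(all(perfect == 1))
  undef <- classification_metrics(list(TP = 0, TN = 5, FP = 3, FN = 0))
  expect_true(is.na(undef["sensitivity"]))
  expect_false(is.na(undef["specificity"]))
})

test_that("the F-score equals the harmonic mean of PPV and TPR", {
  set.seed(6)
  for (i in 1:200) {
    cts <- as.list(stats::rpois(4, 20) + 1)
    names(cts) <- c("TP", "TN", "FP", "FN")
    m <- classification_metrics(cts)
    hm <- 2 / (1 / m["ppv"] + 1 / m["sensitivity"])
    expect_equal(unname(m["f_score"]), unname(hm), tolerance = 1e-12)
  }
})

test_that("confusion_counts tallies and validates", {
  cc <- confusion_counts(c(1, 1, 0, 0, 1), c(1, 0, 0, 1, 1))
  expect_equal(cc, list(TP = 2L, TN = 1L, FP = 1L, FN = 1L))
  expect_error(confusion_counts(c(1, 2), c(0, 1)))
})

test_that("the ANOVA decomposition identity holds across random layouts", {
  set.seed(9)
  for (i in 1:60) {
    k <- sample(2:6, 1)
    groups <- lapply(seq_len(k), function(j)
      rnorm(sample(3:12, 1), mean = runif(1, -2, 2), sd = runif(1, 0.2, 2)))
    a <- anova_oneway(groups)
    expect_equal(a$SS_total, a$SS_between + a$SS_within,
                 tolerance = 1e-9)
    expect_equal(a$MS_between, a$SS_between / a$DF_between)
    expect_equal(a$F, a$MS_between / a$MS_within, tolerance = 1e-9)
    shifted <- lapply(groups, function(g) g + 3.7)
    b <- anova_oneway(shifted)
    expect_equal(b$F, a$F, tolerance = 1e-9)
    expect_equal(b$SS_between, a$SS_between, tolerance = 1e-9)
  }
})

test_that("identical groups give zero between-group variation", {
  g <- c(0.1, 0.5, 0.9, 0.2)
  a <- anova_oneway(list(g, g))
  expect_equal(a$SS_between, 0, tolerance = 1e-12)
  expect_equal(a$F, 0, tolerance = 1e-12)
  # fully constant data leaves F undefined (lm warns about the perfect fit)
  const <- suppressWarnings(anova_oneway(list(rep(1, 4), rep(1, 4))))
  expect_true(is.na(const$F))
})

test_that("groups built with prescribed sums of squares reproduce them", {
  groups <- make_anova_groups(0.08163, 0.007528, k = 8, m = 10)
  a <- anova_oneway(groups)
  expect_equal(a$SS_between, 0.08163, tolerance = 1e-9)
  expect_equal(a$SS_within, 0.007528, tolerance = 1e-9)
  expect_equal(a$DF_between, 7)
  expect_equal(a$DF_within, 72)
})

test_that("exact signed-rank enumeration matches the closed cases", {
  w <- wilcoxon_exact(c(0.65, 0.68, 0.74, 0.73, 0.75, 0.74, 0.74, 0.73,
                        0.66, 0.70))
  expect_equal(w$W_signed, 55)
  expect_equal(w$sum_positive, 55)
  expect_equal(w$sum_negative, 0)
  expect_equal(w$n_used, 10)
  expect_true(w$exact)
  expect_equal(w$p_two_tailed, 2 / 1024, tolerance = 1e-12)
  expect_equal(round(w$p_two_tailed, 3), 0.002)

  sym <- wilcoxon_exact(c(-1, 1))
  expect_equal(sym$W_signed, 0)
  expect_equal(sym$p_two_tailed, 1)

  expect_error(wilcoxon_exact(c(0, 0, 0)), "undefined")
})

test_that("sum identities hold after zero removal", {
  v <- c(2, -1, 0, 3, -2, 0, 5)
  w <- wilcoxon_exact(v)
  expect_equal(w$n_used, 5)
  expect_equal(w$sum_positive + w$sum_negative, 5 * 6 / 2)
  expect_equal(w$W_signed, w$sum_positive - w$sum_negative)
})

test_that("enumeration agrees with independent oracles on random data", {
  set.seed(13)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    v <- round(rnorm(n, 0.2, 1), 3)
    v <- v[v != 0]
    if (length(v) < 2) next
    w <- wilcoxon_exact(v)
    # brute-force enumeration over all sign assignments (helper oracle)
    expect_equal(w$p_two_tailed, brute_wilcoxon_p(v), tolerance = 1e-9)
    # tie-free cases also match the base exact test
    if (!any(duplicated(abs(v)))) {
      ref <- suppressWarnings(stats::wilcox.test(v, mu = 0, exact = TRUE))
      expect_equal(w$sum_positive, unname(ref$statistic))
      expect_equal(w$p_two_tailed, ref$p.value, tolerance = 1e-9)
    }
  }
})

test_that("large samples switch to the normal approximation", {
  set.seed(14)
  v <- rnorm(40, 0.3)
  w <- wilcoxon_exact(v)
  expect_false(w$exact)
  ref <- suppressWarnings(stats::wilcox.test(v, mu = 0, exact = FALSE,
                                             correct = FALSE))
  expect_equal(w$p_two_tailed, ref$p.value, tolerance = 1e-6)
})

test_that("summarize_models reports sample mean and sd per model", {
  s <- summarize_models(list(a = c(0.9, 1.0), b = c(0.99, 0.99)))
  expect_equal(s$mean, c(0.95, 0.99))
  expect_equal(s$sd[1], sd(c(0.9, 1.0)), tolerance = 1e-12)
  expect_equal(s$sd[2], 0)
  # stochastic dominance preserves mean ordering
  expect_true(s$mean[2] > s$mean[1])
})
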