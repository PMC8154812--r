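test_that("t-test ranking orders by p-value with catalogue-order ties", {
  tab <- simulate_feature_table(120, 0.3, effect_multiplier = 0, seed = 8)
  df <- as.data.frame(tab)
  # one feature perfectly separated (10 pooled SDs), one identical across classes
  df$amp_h1 <- ifelse(df$ar_label == 1, 10, 0) + rnorm(120, sd = 1)
  df$resp_rate <- 20
  tab <- feature_table(df)
  rk <- rank_by_ttest(tab)
  expect_equal(rk$feature[1], "amp_h1")
  expect_equal(rk$feature[19], "resp_rate")  # constant: p = 1, ranked last

  # closed-form two-sample pooled-t oracle for one feature
  x0 <- df$rpm_ils[df$ar_label == 0]; x1 <- df$rpm_ils[df$ar_label == 1]
  sp <- sqrt(((length(x0) - 1) * var(x0) + (length(x1) - 1) * var(x1)) /
               (length(x0) + length(x1) - 2))
  tstat <- (mean(x0) - mean(x1)) / (sp * sqrt(1 / length(x0) + 1 / length(x1)))
  p_oracle <- 2 * pt(-abs(tstat), length(x0) + length(x1) - 2)
  expect_equal(rk$p_value[rk$feature == "rpm_ils"], p_oracle, tolerance = 1e-12)

  expect_error(rank_by_ttest(feature_table(
    within(as.data.frame(tab), ar_label <- 0 * ar_label))), "single-class")
})

test_that("Gini ranking finds separating features and is seed-deterministic", {
  tab <- simulate_feature_table(150, 0.3, effect_multiplier = 0, seed = 9)
  df <- as.data.frame(tab)
  df$amp_h1 <- ifelse(df$ar_label == 1, 10, 0)
  tab <- feature_table(df)
  rk <- rank_by_gini(tab, seed = 3)
  expect_equal(rk$feature[1], "amp_h1")
  expect_identical(rank_by_gini(tab, seed = 3), rk)

  # permuting a feature's values destroys its importance
  df2 <- df
  set.seed(1); df2$amp_h1 <- sample(df2$amp_h1)
  rk2 <- rank_by_gini(feature_table(df2), seed = 3)
  expect_gt(which(rk2$feature == "amp_h1"), 9)
})

test_that("internal LOOCV discriminant error matches a brute-force MASS oracle", {
  set.seed(5)
  n <- 60
  y <- rep(c(0, 1), each = n / 2)
  X <- cbind(rnorm(n, y * 1.5), rnorm(n, -y), rnorm(n))
  mine <- lvadsound:::.lda_loo_error(X, y)
  wrong <- 0
  for (i in seq_len(n)) {
    fit <- MASS::lda(X[-i, ], grouping = factor(y[-i], levels = c(0, 1)))
    wrong <- wrong + (as.integer(as.character(predict(fit, X[i, , drop = FALSE])$class)) != y[i])
  }
  expect_equal(mine, wrong / n)
})

test_that("filter selection returns the minimum-error prefix", {
  tab <- simulate_feature_table(100, 0.4, effect_multiplier = 0, seed = 12)
  df <- as.data.frame(tab)
  df$amp_h1 <- ifelse(df$ar_label == 1, 100, 0)  # perfect separator
  tab <- feature_table(df)
  out <- filter_select(tab, rank_by_ttest(tab))
  expect_equal(out$subset, "amp_h1")
  expect_equal(out$trace$loo_error[1], 0)
  expect_equal(nrow(out$trace), 19)

  # all-noise tables keep the subset small under the earliest-prefix tie rule
  sizes <- vapply(1:10, function(s) {
    t0 <- simulate_feature_table(80, 0.4, effect_multiplier = 0, seed = 100 + s)
    length(filter_select(t0, rank_by_ttest(t0))$subset)
  }, numeric(1))
  expect_lt(median(sizes), 6)
})

test_that("selection recovers planted informative features in most replicates", {
  hits <- 0L
  for (s in 1:50) {
    tab <- simulate_feature_table(160, 0.3, class_stats = informative_stats(),
                                  seed = 1000 + s)
    filt <- filter_select(tab, rank_by_ttest(tab))
    if (all(c("amp_h1", "rpm_ils", "ils_ampvar_h1") %in% filt$subset))
      hits <- hits + 1L
  }
  expect_gte(hits / 50, 0.8)
})

test_that("wrapper selection is greedy, non-worsening and duplicate-proof", {
  tab <- simulate_feature_table(120, 0.3, class_stats = informative_stats(),
                                seed = 21)
  expect_equal(wrapper_select(tab, "amp_h1")$subset, "amp_h1")

  # an exact duplicate of a selected feature is never also selected
  df <- as.data.frame(tab)
  df$freq_h1 <- df$amp_h1  # catalogue-earlier exact copy
  dup_tab <- feature_table(df)
  w <- wrapper_select(dup_tab, c("freq_h1", "amp_h1", "rpm_ils", "ils_ampvar_h1"))
  expect_false(all(c("freq_h1", "amp_h1") %in% w$subset))

  filt <- filter_select(tab, rank_by_ttest(tab))
  w2 <- wrapper_select(tab, filt$subset)
  expect_lte(min(w2$trace$loo_error),
             min(filt$trace$loo_error[length(filt$subset)]))
  expect_true(all(w2$subset %in% filt$subset))
})

test_that("NCA weighting identifies separating features deterministically", {
  tab <- simulate_feature_table(100, 0.4, effect_multiplier = 0, seed = 31)
  df <- as.data.frame(tab)
  df$ils_ampvar_h1 <- ifelse(df$ar_label == 1, 8, 0) + rnorm(100, sd = 0.5)
  tab <- feature_table(df)
  rk <- rank_by_nca(tab, seed = 1)
  expect_equal(rk$feature[1], "ils_ampvar_h1")
  expect_identical(rank_by_nca(tab, seed = 1), rk)

  # pure noise: no single weight dominates the weight mass
  noise <- simulate_feature_table(80, 0.4, effect_multiplier = 0, seed = 32)
  w <- rank_by_nca(noise)$weight
  expect_lt(max(w^2) / sum(w^2), 0.5)
})

test_that("metrics follow their definitions", {
  expect_equal(evaluate_metrics(c(1, 0, 1, 0), c(0.9, 0.1, 0.8, 0.2),
                                c(1, 0, 1, 0)),
               c(accuracy = 1, auc = 1, tpr = 1, tnr = 1))
  # identical scores for every sample: AUC 0.5 by the midrank convention
  m <- evaluate_metrics(rep(0, 6), rep(0.3, 6), c(1, 1, 0, 0, 0, 0))
  expect_equal(m[["auc"]], 0.5)
  # all-negative predictions on a 26/219 table
  labels <- c(rep(1, 26), rep(0, 219))
  m2 <- evaluate_metrics(rep(0, 245), rep(0.1, 245), labels)
  expect_equal(m2[["accuracy"]], 219 / 245)
  expect_equal(round(m2[["accuracy"]], 2), 0.89)
  expect_equal(m2[["tpr"]], 0)
  expect_equal(m2[["tnr"]], 1)
})

test_that("AUC is invariant to monotone score transforms and matches pROC", {
  set.seed(77)
  labels <- rbinom(80, 1, 0.3)
  scores <- rnorm(80) + labels
  m <- evaluate_metrics(as.integer(scores > 0.5), scores, labels)
  m_exp <- evaluate_metrics(as.integer(scores > 0.5), exp(scores), labels)
  expect_equal(m[["auc"]], m_exp[["auc"]])
  skip_if_not_installed("pROC")
  auc_ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                            direction = "<")))
  expect_equal(m[["auc"]], auc_ref, tolerance = 1e-12)
})

test_that("a linearly separable cohort is classified perfectly by every algorithm", {
  tab <- simulate_feature_table(80, 0.4, effect_multiplier = 0, seed = 41)
  df <- as.data.frame(tab)
  df$amp_h1 <- ifelse(df$ar_label == 1, 30, 70)
  df$rpm_ils <- ifelse(df$ar_label == 1, 6500, 8000)
  tab <- feature_table(df)
  rep <- benchmark_classifiers(tab, c("amp_h1", "rpm_ils"), split_seed = 2,
                               tune = FALSE)
  expect_equal(nrow(rep), 9)
  expect_setequal(rep$classifier, classifier_names())
  expect_true(all(rep$accuracy == 1))
  expect_true(all(rep$auc == 1))
})

test_that("permuted labels drive every classifier to chance AUC", {
  aucs <- matrix(NA_real_, 20, 9)
  for (s in 1:20) {
    tab <- simulate_feature_table(100, 0.3, seed = 500 + s)
    df <- as.data.frame(tab)
    df$ar_label <- withr::with_seed(600 + s, sample(df$ar_label))
    tab <- feature_table(df)
    rep <- benchmark_classifiers(tab, c("amp_h1", "rpm_ils", "ils_ampvar_h1"),
                                 split_seed = s, tune = FALSE)
    aucs[s, ] <- rep$auc
  }
  med <- apply(aucs, 2, median)
  expect_true(all(med > 0.35 & med < 0.65))
  expect_lt(abs(median(aucs) - 0.5), 0.1)
})

test_that("benchmark is deterministic given a seed and refuses empty subsets", {
  tab <- simulate_feature_table(90, 0.3, seed = 51)
  r1 <- benchmark_classifiers(tab, c("amp_h1", "rpm_ils"), split_seed = 7,
                              tune = FALSE)
  r2 <- benchmark_classifiers(tab, c("amp_h1", "rpm_ils"), split_seed = 7,
                              tune = FALSE)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_error(benchmark_classifiers(tab, character(0)), "non-empty")
})

test_that("training-side pipeline is blind to test-row leakage (canary)", {
  # canary feature: equals the label (scaled) on the test rows, constant on
  # the training rows. A pipeline that lets test rows into ranking would put
  # the canary first; one fitted on training rows only must rank it last.
  tab <- simulate_feature_table(160, 0.3, class_stats = informative_stats(),
                                seed = 61)
  y <- tab$ar_label
  split <- stratified_split(y, 0.75, seed = 61)
  test_rows <- setdiff(seq_along(y), split)
  df <- as.data.frame(tab)
  df$freq_h1 <- 163                       # constant (uninformative) on train
  df$freq_h1[test_rows] <- 163 + y[test_rows] * 50  # leaked into test rows

  leaky_rank <- rank_by_ttest(feature_table(df))
  expect_lte(which(leaky_rank$feature == "freq_h1"), 6)  # the trap works

  train_tab <- feature_table(df[split, , drop = FALSE])
  rk <- rank_by_ttest(train_tab)
  expect_equal(which(rk$feature == "freq_h1"), 19)  # blind pipeline: last
  filt <- filter_select(train_tab, rk)
  expect_false("freq_h1" %in% wrapper_select(train_tab, filt$subset)$subset)
})
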