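test_that("MCC reproduces the published univariate contingencies", {
  expect_equal(round(mcc(contingency(TP = 122, TN = 43, FP = 11, FN = 41)), 3), 0.484)
  expect_equal(round(mcc(contingency(TP = 90, TN = 34, FP = 20, FN = 22)), 3), 0.429)
  expect_equal(mcc(contingency(TP = 50, TN = 30, FP = 0, FN = 0)), 1)
  expect_error(contingency(TP = -1, TN = 0, FP = 0, FN = 0), "non-negative")
})

test_that("MCC symmetry and zero-denominator convention", {
  set.seed(41)
  for (i in 1:25) {
    ct <- as.list(sample(0:40, 4)); names(ct) <- c("TP", "TN", "FP", "FN")
    a <- mcc(do.call(contingency, ct))
    # symmetric under swapping the roles of the two classes
    b <- mcc(contingency(TP = ct$TN, TN = ct$TP, FP = ct$FN, FN = ct$FP))
    expect_equal(a, b, tolerance = 1e-12)
    # negated when predictions are inverted
    d <- mcc(contingency(TP = ct$FN, TN = ct$FP, FP = ct$TN, FN = ct$TP))
    expect_equal(a, -d, tolerance = 1e-12)
  }
  expect_equal(mcc(contingency(TP = 0, TN = 10, FP = 0, FN = 0)), 0)
})

test_that("cross-validation is deterministic and partitions the samples", {
  set.seed(42)
  n <- 40
  x <- cbind(a = c(rnorm(20, 0), rnorm(20, 3)), b = rnorm(n))
  y <- factor(rep(c("Control", "Case"), each = 20), levels = c("Control", "Case"))
  r1 <- crossvalidate(x, y, folds = 5, seed = 9)
  r2 <- crossvalidate(x, y, folds = 5, seed = 9)
  expect_identical(r1$per_classifier, r2$per_classifier)
  # every sample lands in exactly one test fold: counts add to n
  expect_true(all(r1$per_classifier$TP + r1$per_classifier$TN +
                    r1$per_classifier$FP + r1$per_classifier$FN == n))
  # averaged MCC is the mean of the per-classifier MCCs
  expect_equal(r1$mcc, mean(r1$per_classifier$mcc), tolerance = 1e-12)
})

test_that("well-separated classes are classified nearly perfectly", {
  set.seed(43)
  n <- 60
  x <- cbind(f1 = c(rnorm(30, 0, 1), rnorm(30, 5, 1)),
             f2 = c(rnorm(30, 0, 1), rnorm(30, -5, 1)))
  y <- factor(rep(c("Control", "Case"), each = 30), levels = c("Control", "Case"))
  rep_ <- crossvalidate(x, y, seed = 3)
  expect_gte(rep_$sensitivity, 95)
  expect_gte(rep_$specificity, 95)
})

test_that("permuted labels give near-zero average MCC", {
  set.seed(44)
  n <- 60
  x <- cbind(f1 = c(rnorm(30, 0), rnorm(30, 2)), f2 = rnorm(n))
  mccs <- vapply(1:10, function(s) {
    set.seed(700 + s)
    y <- factor(sample(rep(c("Control", "Case"), each = 30)),
                levels = c("Control", "Case"))
    crossvalidate(x, y, seed = s)$mcc
  }, numeric(1))
  expect_lt(abs(mean(mccs)), 0.15)
})

test_that("matched train/test split halves each class and balances age", {
  sim <- generate_panel(synth_config(
    n_per_group = c(Control = 54, MCI_Progressor = 54), n_analytes = 5,
    n_informative = 0, seed = 15))
  # rare genotype strata of size 1 are assigned randomly, each with a warning
  w <- capture_warnings(sp <- split_train_test_matched(sim$panel, seed = 2))
  expect_true(length(w) >= 1 && all(grepl("stratum of size 1", w)))
  cls <- panel_classes(sim$panel)
  expect_equal(sum(cls[sp$train] == "Control"), 27)
  expect_equal(sum(cls[sp$train] == "MCI_Progressor"), 27)
  expect_equal(sort(c(sp$train, sp$test)), sort(names(cls)))
  # age matching beats unmatched random halves on average
  age <- with(sim$panel$sample_meta, stats::setNames(age, sample_id))
  diff_matched <- vapply(1:40, function(s) {
    sp <- suppressWarnings(split_train_test_matched(sim$panel, seed = s))
    abs(mean(age[sp$train]) - mean(age[sp$test]))
  }, numeric(1))
  diff_random <- vapply(1:40, function(s) {
    set.seed(10000 + s)
    tr <- sample(names(age), length(age) / 2)
    abs(mean(age[tr]) - mean(age[setdiff(names(age), tr)]))
  }, numeric(1))
  expect_lte(mean(diff_matched), mean(diff_random))
})

test_that("size matching returns balanced groups with matched gender ratio", {
  sim <- generate_panel(synth_config(
    n_per_group = c(Control = 54, MCI_Progressor = 163), n_analytes = 5,
    n_informative = 0, seed = 16))
  ids <- size_match(sim$panel, seed = 4)
  cls <- panel_classes(sim$panel)[ids]
  expect_equal(as.integer(table(cls)), c(54L, 54L))
  sm <- sim$panel$sample_meta
  g_min <- table(sm$gender[sm$class == "Control"])
  g_maj <- table(sm$gender[sm$sample_id %in% ids & sm$class == "MCI_Progressor"])
  expect_equal(as.vector(g_maj), as.vector(g_min))
  # equal classes are returned unchanged
  sim2 <- generate_panel(synth_config(
    n_per_group = c(Control = 10, AD = 10), n_analytes = 3, seed = 17))
  expect_setequal(size_match(sim2$panel, seed = 1),
                  sim2$panel$sample_meta$sample_id)
})

test_that("Welch table matches a hand-computed t-test and orders by p", {
  a <- c(1.1, 2.0, 2.9, 4.2); b <- c(5.5, 6.1, 7.0, 8.4)
  v <- rbind(cbind(a, rnorm(4, 0, 1)), cbind(b, rnorm(4, 0, 1)))
  colnames(v) <- c("strong", "noise")
  p <- toy_panel(10^v, classes = rep(c("A", "B"), each = 4))
  lp <- log_transform(apply_ldd_floor(p))
  tab <- welch_ttest_table(lp)
  # textbook Welch statistic for the first analyte
  se <- sqrt(var(a) / 4 + var(b) / 4)
  t_manual <- (mean(a) - mean(b)) / se
  df <- se^4 / ((var(a) / 4)^2 / 3 + (var(b) / 4)^2 / 3)
  p_manual <- 2 * pt(-abs(t_manual), df)
  row <- tab[tab$analyte == "strong", ]
  expect_equal(row$t, t_manual, tolerance = 1e-10)
  expect_equal(row$p, p_manual, tolerance = 1e-10)
  expect_equal(tab$analyte[1], "strong")          # sorted by p ascending
  # identical distributions give t = 0, p = 1
  v2 <- matrix(rep(c(1, 2, 3, 4), 2), ncol = 1)
  p2 <- toy_panel(v2, classes = rep(c("A", "B"), each = 4))
  tab2 <- welch_ttest_table(p2)
  expect_equal(tab2$t, 0); expect_equal(tab2$p, 1)
})

test_that("planted large effects reach extreme significance at study sizes", {
  hits <- 0; total <- 20
  for (s in 1:total) {
    sim <- generate_panel(synth_config(
      n_per_group = c(Control = 54, MCI_Progressor = 163), n_analytes = 6,
      n_informative = 1, effect_size = 3, seed = 3000 + s))
    lp <- log_transform(apply_ldd_floor(sim$panel))
    tab <- welch_ttest_table(lp)
    planted <- sim$truth$informative_analytes$analyte
    if (tab$p[tab$analyte == planted] < 1e-6) hits <- hits + 1
  }
  expect_gte(hits / total, 0.95)
})
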