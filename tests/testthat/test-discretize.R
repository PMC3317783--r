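test_that("best_cut finds the forced midpoint on separable data", {
  v <- c(1, 2, 3, 10, 11, 12)
  y <- rep(c("A", "B"), each = 3)
  bc <- best_cut(v, y)
  expect_equal(bc$cut, 6.5)
  expect_equal(bc$entropy, 0)
  # order invariance
  perm <- c(4, 1, 6, 3, 2, 5)
  bc2 <- best_cut(v[perm], y[perm])
  expect_equal(bc2$cut, bc$cut)
  expect_equal(bc2$entropy, bc$entropy)
})

test_that("best_cut agrees with the exhaustive midpoint scan", {
  # the frozen 4-point case: alternating labels, scanned by hand
  oracle <- brute_best_cut(c(1, 2, 3, 4), c("A", "B", "A", "B"))
  bc <- best_cut(c(1, 2, 3, 4), c("A", "B", "A", "B"))
  expect_equal(bc$cut, oracle$cut)
  expect_equal(bc$entropy, oracle$entropy, tolerance = 1e-12)
  # random vectors, including ties in values
  set.seed(17)
  for (i in 1:50) {
    n <- sample(6:40, 1)
    v <- round(rnorm(n), sample(0:2, 1))
    y <- sample(c("A", "B"), n, replace = TRUE)
    if (length(unique(v)) < 2 || length(unique(y)) < 2) next
    bc <- best_cut(v, y)
    oracle <- brute_best_cut(v, y)
    expect_equal(bc$entropy, oracle$entropy, tolerance = 1e-12)
    expect_equal(bc$cut, oracle$cut)
  }
})

test_that("best_cut rejects degenerate input", {
  expect_error(best_cut(c(1, 1, 1), c("A", "B", "A")), "identical")
  expect_error(best_cut(c(1, 2, 3), c("A", "A", "A")), "class")
})

test_that("MDL criterion matches the worked separable case and rejects noise", {
  v <- c(1, 2, 3, 10, 11, 12)
  y <- rep(c("A", "B"), each = 3)
  md <- mdl_accepts(v, y, 6.5)
  expect_equal(md$info_gain, 1)                            # H(S) = 1, E = 0
  expect_equal(md$mdl_criterion, (log2(5) + log2(7) - 2) / 6, tolerance = 1e-12)
  expect_equal(md$mdl_criterion, 0.5215, tolerance = 5e-4)
  expect_true(md$accepted)
  # labels carrying no information about the values are rejected
  v2 <- c(1, 2, 3, 4); y2 <- c("A", "B", "A", "B")
  bc <- best_cut(v2, y2)
  md2 <- mdl_accepts(v2, y2, bc$cut)
  expect_false(md2$accepted)
  # pure side: entropy 0, criterion finite
  md3 <- mdl_accepts(c(1, 2, 3, 4), c("A", "A", "A", "B"), 3.5)
  expect_true(is.finite(md3$mdl_criterion))
})

test_that("entropy filter keeps exactly the separating analyte", {
  set.seed(1)
  n <- 40
  y <- rep(c("Control", "MCI_Progressor"), each = n / 2)
  good <- c(rnorm(n / 2, 0, 0.2), rnorm(n / 2, 5, 0.2))
  noise1 <- rnorm(n); noise2 <- rnorm(n)
  m <- cbind(good = good, n1 = noise1, n2 = noise2)
  rownames(m) <- sprintf("S%02d", 1:n)
  disc <- entropy_filter(m, y)
  expect_equal(colnames(disc$binary), "good")
  expect_false(disc$empty)
  # acceptance decisions are invariant to sample reordering
  perm <- sample(n)
  disc2 <- entropy_filter(m[perm, ], y[perm])
  expect_equal(disc2$cuts$accepted, disc$cuts$accepted)
  expect_equal(disc2$cuts$cut, disc$cuts$cut)
})

test_that("empty filter result is flagged with a warning, not an error", {
  set.seed(2)
  m <- matrix(rnorm(40), 20, 2, dimnames = list(sprintf("S%02d", 1:20), c("a", "b")))
  y <- rep(c("A", "B"), 10)
  expect_warning(disc <- entropy_filter(m, y), "no feature")
  expect_true(disc$empty)
  expect_equal(ncol(disc$binary), 0L)
})

test_that("cuts transform covariantly under log10 so binaries are unchanged", {
  set.seed(3)
  n <- 60
  y <- rep(c("A", "B"), each = 30)
  m <- cbind(x1 = 10^(c(rnorm(30, 1), rnorm(30, 2)) * 0.3),
             x2 = 10^rnorm(n, 1, 0.4))
  rownames(m) <- sprintf("S%02d", 1:n)
  d_raw <- suppressWarnings(entropy_filter(m, y))
  d_log <- suppressWarnings(entropy_filter(log10(m), y))
  expect_equal(d_raw$cuts$accepted, d_log$cuts$accepted)
  expect_identical(d_raw$binary, d_log$binary)
  # the cut separates the same order statistics on both scales
  for (j in which(!is.na(d_raw$cuts$cut))) {
    expect_equal(sum(m[, j] > d_raw$cuts$cut[j]),
                 sum(log10(m[, j]) > d_log$cuts$cut[j]))
  }
})

test_that("univariate ranking reproduces published contingency MCCs", {
  # 43/54 controls and 122/163 progressors correct -> MCC 0.484
  b1 <- c(rep(0, 43), rep(1, 11), rep(1, 122), rep(0, 41))
  # 54/54 controls and 32/163 progressors correct -> MCC 0.239
  b2 <- c(rep(0, 54), rep(1, 32), rep(0, 131))
  y <- rep(c("Control", "MCI_Progressor"), c(54, 163))
  disc <- toy_disc(cbind(apoe_like = b1, cd5_like = b2), y)
  rk <- rank_univariate(disc)
  expect_equal(rk$feature, c("apoe_like", "cd5_like"))  # sorted by MCC desc
  r1 <- rk[rk$feature == "apoe_like", ]
  expect_equal(round(r1$mcc, 3), 0.484)
  expect_equal(r1$neg_correct, 43); expect_equal(r1$neg_percent, 79.6)
  expect_equal(r1$pos_correct, 122); expect_equal(r1$pos_percent, 74.8)
  r2 <- rk[rk$feature == "cd5_like", ]
  expect_equal(round(r2$mcc, 3), 0.239)
  expect_equal(r2$neg_percent, 100.0); expect_equal(r2$pos_percent, 19.6)
})

test_that("ranking MCC always recomputes from its reported contingency", {
  set.seed(4)
  y <- sample(c("A", "B"), 50, replace = TRUE, prob = c(0.3, 0.7))
  B <- matrix(sample(0:1, 50 * 6, replace = TRUE), 50, 6)
  disc <- toy_disc(B, y)
  rk <- rank_univariate(disc)
  nA <- sum(y == "A"); nB <- sum(y == "B")
  for (i in seq_len(nrow(rk))) {
    ct <- contingency(TP = rk$pos_correct[i], TN = rk$neg_correct[i],
                      FP = nA - rk$neg_correct[i], FN = nB - rk$pos_correct[i])
    expect_equal(rk$mcc[i], mcc(ct), tolerance = 1e-12)
    expect_equal(rk$pos_percent[i], round(100 * rk$pos_correct[i] / nB, 1))
  }
  # perfect separation scores 100/100 and MCC 1
  disc2 <- toy_disc(cbind(f = rep(0:1, c(20, 30))), rep(c("A", "B"), c(20, 30)))
  rk2 <- rank_univariate(disc2)
  expect_equal(rk2$mcc, 1)
  expect_equal(rk2$neg_percent, 100); expect_equal(rk2$pos_percent, 100)
})
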