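test_that("instance enumerates all pairs with the cover relation", {
  B <- cbind(f1 = c(0, 0, 1, 1), f2 = c(0, 1, 0, 1))
  inst <- build_instance(toy_disc(B, c("A", "A", "B", "B")))
  expect_equal(sum(inst$between), 4L)       # 2x2 between-pairs
  expect_equal(sum(!inst$between), 2L)      # C(2,2)+C(2,2) within-pairs
  # f1 separates the classes perfectly: covers all 4 between and both within
  expect_true(all(inst$covers[, "f1"]))
  # independent double-loop recomputation on random instances
  set.seed(5)
  for (r in 1:10) {
    labels <- c(rep("A", 4), rep("B", 4))
    B <- matrix(sample(0:1, 8 * 5, replace = TRUE), 8, 5,
                dimnames = list(sprintf("S%d", 1:8), sprintf("f%d", 1:5)))
    inst <- build_instance(toy_disc(B, labels))
    for (p in seq_along(inst$pair_i)) {
      bi <- B[inst$pair_i[p], ]; bj <- B[inst$pair_j[p], ]
      expected <- if (inst$between[p]) bi != bj else bi == bj
      expect_equal(unname(inst$covers[p, ]), unname(expected))
    }
  }
})

test_that("duplicate-pattern pruning removes only cross-class identical rows", {
  # identical rows within a class are harmless
  B <- rbind(S1 = c(0, 1), S2 = c(0, 1), S3 = c(1, 0), S4 = c(1, 1))
  colnames(B) <- c("f1", "f2")
  pr <- prune_duplicate_patterns(toy_disc(B, c("A", "A", "B", "B")))
  expect_length(pr$pruned, 0)
  # one A-row equal to one B-row: exactly one sample pruned
  B2 <- rbind(S1 = c(0, 1), S2 = c(0, 0), S3 = c(0, 1), S4 = c(1, 1))
  colnames(B2) <- c("f1", "f2")
  pr2 <- prune_duplicate_patterns(toy_disc(B2, c("A", "A", "B", "B")))
  expect_length(pr2$pruned, 1)
  expect_true(pr2$pruned %in% c("S1", "S3"))
  # after pruning the solver never reports infeasibility from identical rows
  set.seed(6)
  for (r in 1:20) {
    B3 <- matrix(sample(0:1, 10 * 4, replace = TRUE), 10, 4,
                 dimnames = list(sprintf("S%02d", 1:10), sprintf("f%d", 1:4)))
    lab <- rep(c("A", "B"), each = 5)
    dup <- sample(1:5, 1)                    # inject a cross-class duplicate
    B3[5 + sample(1:5, 1), ] <- B3[dup, ]
    pr3 <- prune_duplicate_patterns(toy_disc(B3, lab))
    sig <- solve_min_k(pr3$instance)
    if (sig$status == "infeasible") {
      # any remaining infeasibility must come from an uncoverable within-pair,
      # not from identical cross-class rows
      expect_true(all(!sig$uncoverable_pairs$between))
    }
  }
})

test_that("single perfect feature solves at k = 1", {
  B <- cbind(f1 = c(0, 0, 1, 1), f2 = c(0, 1, 0, 1))
  inst <- build_instance(toy_disc(B, c("A", "A", "B", "B")))
  sig <- solve_min_k(inst)
  expect_equal(sig$k, 1L)
  expect_equal(sig$features, "f1")
  expect_equal(sig$status, "exact")
  expect_gte(sig$achieved_alpha, 1)
  expect_gte(sig$achieved_beta, 1)
})

test_that("uncoverable between-pair returns Infeasible with the pair reported", {
  B <- cbind(f1 = c(0, 0, 0, 1))        # S2 (A) and S3 (B) identical on f1
  inst <- build_instance(toy_disc(B, c("A", "A", "B", "B")))
  sig <- solve_min_k(inst)
  expect_equal(sig$status, "infeasible")
  expect_true(nrow(sig$uncoverable_pairs) >= 1)
})

test_that("solver matches the exhaustive oracle on random instances", {
  for (s in 1:60) {
    inst <- random_instance(n_features = sample(3:8, 1),
                            n_samples = sample(6:10, 1), seed = 4000 + s)
    o <- exhaustive_oracle(inst)
    sig <- solve_min_k(inst)
    expect_equal(sig$status == "infeasible", o$status == "infeasible")
    if (o$status != "infeasible") {
      expect_equal(sig$k, o$k)
      expect_equal(sig$coverage, o$coverage)   # coverage tie-break agrees
      expect_gte(sig$achieved_alpha, 1)
      expect_gte(sig$achieved_beta, 1)
      # post-hoc verification independent of solver internals
      S <- match(sig$features, inst$features)
      cnt <- rowSums(inst$covers[, S, drop = FALSE])
      expect_true(all(cnt >= 1))
    }
  }
})

test_that("adding a feature never increases the optimal k", {
  for (s in 1:15) {
    inst_big <- random_instance(6, 8, seed = 7000 + s)
    disc_small <- toy_disc(inst_big$binary[, 1:5, drop = FALSE],
                           unname(inst_big$labels))
    inst_small <- build_instance(disc_small)
    o_small <- exhaustive_oracle(inst_small)
    o_big <- exhaustive_oracle(inst_big)
    if (o_small$status != "infeasible") {
      expect_false(o_big$status == "infeasible")
      expect_lte(o_big$k, o_small$k)
    }
  }
})

test_that("fixed-k selection is lexicographically optimal", {
  # k = 1: best single feature by (alpha, beta, coverage), checked exhaustively
  for (s in 1:20) {
    inst <- random_instance(6, 8, seed = 9000 + s)
    sig <- solve_fixed_k(inst, k = 1)
    stats_all <- sapply(seq_along(inst$features), function(j) {
      cnt <- inst$covers[, j]
      c(min(cnt[inst$between]), min(cnt[!inst$between]),
        inst$between_weight[j])
    })
    best <- order(-stats_all[1, ], -stats_all[2, ], -stats_all[3, ])[1]
    got <- match(sig$features, inst$features)
    expect_equal(stats_all[, got], stats_all[, best])
  }
  # k = full set returns everything
  inst <- random_instance(5, 8, seed = 1234)
  sig_full <- solve_fixed_k(inst, k = 5)
  expect_setequal(sig_full$features, inst$features)
  expect_error(solve_fixed_k(inst, k = 6), "between 1 and")
})

test_that("fixed-k at k = 3 matches brute force over all triples", {
  for (s in 1:10) {
    inst <- random_instance(7, 8, seed = 11000 + s)
    sig <- solve_fixed_k(inst, k = 3)
    combos <- combn(7, 3)
    best <- c(-Inf, -Inf, -Inf)
    for (c_ in seq_len(ncol(combos))) {
      cnt <- rowSums(inst$covers[, combos[, c_], drop = FALSE])
      st <- c(min(cnt[inst$between]), min(cnt[!inst$between]),
              sum(inst$between_weight[combos[, c_]]))
      if (st[1] > best[1] || (st[1] == best[1] && st[2] > best[2]) ||
          (st[1] == best[1] && st[2] == best[2] && st[3] > best[3])) best <- st
    }
    S <- match(sig$features, inst$features)
    cnt <- rowSums(inst$covers[, S, drop = FALSE])
    expect_equal(c(min(cnt[inst$between]), min(cnt[!inst$between]),
                   sum(inst$between_weight[S])), best)
  }
})

test_that("solver output is deterministic", {
  inst <- random_instance(8, 10, seed = 555)
  a <- solve_min_k(inst); b <- solve_min_k(inst)
  expect_identical(a$features, b$features)
  expect_identical(a$coverage, b$coverage)
})
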