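test_that("generated panel has the configured shape and positive values", {
  sim <- generate_panel(synth_config(
    n_per_group = c(Control = 10, MCI_Progressor = 10), n_analytes = 5,
    n_informative = 2, seed = 42))
  expect_equal(dim(sim$panel), c(20L, 5L))
  expect_true(all(sim$panel$values > 0))
  expect_equal(as.integer(table(sim$panel$sample_meta$class)), c(10L, 10L))
  expect_true(all(sim$panel$analyte_meta$ldd > 0))
  expect_equal(nrow(sim$truth$informative_analytes), 2)
})

test_that("identical configs give bit-identical panels", {
  cfg <- synth_config(n_per_group = c(Control = 8, AD = 12), n_analytes = 6,
                      seed = 11)
  a <- generate_panel(cfg)
  b <- generate_panel(cfg)
  expect_identical(a$panel$values, b$panel$values)
  expect_identical(a$truth, b$truth)
  # and a different seed changes the draw
  c_ <- generate_panel(synth_config(n_per_group = c(Control = 8, AD = 12),
                                    n_analytes = 6, seed = 12))
  expect_false(identical(a$panel$values, c_$panel$values))
})

test_that("invalid configurations are rejected naming the field", {
  expect_error(synth_config(ldd_quantile = 0.6), "ldd_quantile")
  expect_error(synth_config(n_informative = 300, n_analytes = 10), "n_informative")
  expect_error(synth_config(block_rho = 1), "block_rho")
  expect_error(synth_config(n_per_group = c(Control = 0, AD = 5)), "n_per_group")
})

test_that("control-class censoring matches the configured LDD quantile", {
  q <- 0.2
  sim <- generate_panel(synth_config(
    n_per_group = c(Control = 80, MCI_Progressor = 20), n_analytes = 50,
    n_informative = 0, ldd_quantile = q, block_rho = 0, seed = 21))
  ctrl <- sim$panel$sample_meta$sample_id[sim$panel$sample_meta$class == "Control"]
  counts <- colSums(sweep(sim$panel$values[ctrl, ], 2,
                          sim$panel$analyte_meta$ldd, `<`))
  # per-analyte binomial 99% bounds; the genotype-graded analyte is skewed by
  # design so it is not held to the control-only quantile
  keep <- setdiff(colnames(sim$panel$values), sim$truth$apoe_like_analyte)
  lo <- qbinom(0.005, length(ctrl), q); hi <- qbinom(0.995, length(ctrl), q)
  inside <- counts[keep] >= lo & counts[keep] <= hi
  expect_gte(mean(inside), 0.95)
})

test_that("APOE-like analyte decreases monotonically in e4 allele count", {
  sim <- generate_panel(synth_config(
    n_per_group = c(Control = 100, MCI_Progressor = 200, AD = 150),
    n_analytes = 10, n_informative = 0, genotype_effect = -0.8, seed = 8))
  lv <- log10(sim$panel$values[, sim$truth$apoe_like_analyte])
  n4 <- sim$truth$n_e4[names(lv)]
  means <- tapply(lv, n4, mean)
  expect_true(all(diff(means) < 0))
})

test_that("zero-drift zero-noise follow-up is identical to baseline", {
  cfg <- synth_config(n_per_group = c(Control = 6, MCI_Progressor = 6),
                      n_analytes = 4, n_informative = 1, noise_sd = 0,
                      followup_drift = 0, seed = 2)
  sim <- generate_panel(cfg)
  fu <- generate_followup(sim$panel, sim$truth, cfg)
  expect_equal(fu$values, sim$panel$values, tolerance = 1e-12)
  expect_true(all(fu$sample_meta$timepoint == "m12"))
})

test_that("follow-up drift has the configured mean log10 change in progressors", {
  # pooled direction-adjusted changes across seeds: mean within 3 SE of drift
  drift <- 2.0
  changes <- numeric(0)
  for (s in 1:30) {
    cfg <- synth_config(n_per_group = c(Control = 10, MCI_Progressor = 10),
                        n_analytes = 6, n_informative = 2, noise_sd = 0.3,
                        followup_drift = drift, seed = 100 + s)
    sim <- generate_panel(cfg)
    fu <- generate_followup(sim$panel, sim$truth, cfg)
    ch <- compute_change(log_transform(sim$panel), log_transform(fu), "log10")
    prog <- names(ch$classes)[ch$classes == "MCI_Progressor"]
    for (i in seq_len(nrow(sim$truth$informative_analytes))) {
      a <- sim$truth$informative_analytes$analyte[i]
      d <- sim$truth$informative_analytes$direction[i]
      changes <- c(changes, d * ch$values[prog, a])
    }
  }
  se <- sd(changes) / sqrt(length(changes))
  expect_lt(abs(mean(changes) - drift), 3 * se)
})

test_that("follow-up subsetting keeps requested samples and rejects strangers", {
  cfg <- synth_config(n_per_group = c(Control = 60, MCI_Progressor = 100),
                      n_analytes = 5, seed = 4)
  sim <- generate_panel(cfg)
  ctrl <- sim$panel$sample_meta$sample_id[sim$panel$sample_meta$class == "Control"][1:50]
  prog <- sim$panel$sample_meta$sample_id[sim$panel$sample_meta$class == "MCI_Progressor"][1:92]
  fu <- generate_followup(sim$panel, sim$truth, cfg, sample_ids = c(ctrl, prog))
  expect_equal(nrow(fu$values), 142L)
  expect_true(all(rownames(fu$values) %in% rownames(sim$panel$values)))
  expect_error(generate_followup(sim$panel, sim$truth, cfg,
                                 sample_ids = c(ctrl, "NOT_A_SAMPLE")),
               "absent")
})
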