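#!/usr/bin/env Rscript
# Classification accuracy of the selected signatures (original, non-discrete
# values), averaged over the default set of 10 classifiers: 10-fold
# cross-validation and a covariate-matched train/test split, on the full
# comparison groups and on size-matched groups. Size matching removes the
# sensitivity/specificity imbalance that unequal class sizes induce.

suppressPackageStartupMessages(library(absig))
dir.create("results/evaluation", recursive = TRUE, showWarnings = FALSE)

lp <- read_panel("results/processed/baseline")
cls <- panel_classes(lp)
two <- subset_panel(lp, samples = names(cls)[cls %in% c("Control", "MCI_Progressor")])

sigs <- list(
  with_apoe = "results/signatures/single_with_apoe.json",
  without_apoe = "results/signatures/single_without_apoe.json",
  metafeature_diff = "results/metafeatures/signature_difference.json")

rows <- list()
for (nm in names(sigs)) {
  if (!file.exists(sigs[[nm]])) next
  sig <- jsonlite::read_json(sigs[[nm]], simplifyVector = TRUE)
  if (grepl("metafeature", nm)) {
    z <- zscore(two)
    mf <- make_metafeatures(z, "difference")
    x_all <- mf$values[, sig$features, drop = FALSE]
  } else {
    x_all <- two$values[, sig$features, drop = FALSE]
  }
  for (scope in c("full", "size_matched")) {
    ids <- if (scope == "full") rownames(x_all) else size_match(two, seed = 101)
    x <- x_all[ids, , drop = FALSE]
    y <- factor(panel_classes(two)[ids], levels = c("Control", "MCI_Progressor"))
    cv <- crossvalidate(x, y, seed = 101)
    sp <- suppressWarnings(split_train_test_matched(
      subset_panel(two, samples = ids), seed = 101))
    tt <- evaluate_train_test(x[sp$train, , drop = FALSE],
                              y[match(sp$train, ids)],
                              x[sp$test, , drop = FALSE],
                              y[match(sp$test, ids)], seed = 101)
    cat(sprintf("%-18s %-12s cv: sens %.1f spec %.1f mcc %.2f | test: sens %.1f spec %.1f mcc %.2f\n",
                nm, scope, cv$sensitivity, cv$specificity, cv$mcc,
                tt$sensitivity, tt$specificity, tt$mcc))
    rows[[length(rows) + 1]] <- data.frame(
      signature = nm, scope = scope, k = sig$k,
      cv_sens = cv$sensitivity, cv_spec = cv$specificity, cv_mcc = cv$mcc,
      test_sens = tt$sensitivity, test_spec = tt$specificity, test_mcc = tt$mcc)
  }
}
tab <- do.call(rbind, rows)
write.table(tab, "results/evaluation/accuracy.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote results/evaluation/accuracy.tsv\n")
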