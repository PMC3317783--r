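#!/usr/bin/env Rscript
# Heat-map presentation of the single-analyte signature: Z-scores of the
# selected analytes over the comparison population, with samples and analytes
# ordered by the memetic seriation (minimizing summed correlation distance
# between adjacent rows and between adjacent columns).

suppressPackageStartupMessages(library(absig))
dir.create("results/heatmap", recursive = TRUE, showWarnings = FALSE)

lp <- read_panel("results/processed/baseline")
cls <- panel_classes(lp)
two <- subset_panel(lp, samples = names(cls)[cls %in% c("Control", "MCI_Progressor")])
sig <- jsonlite::read_json("results/signatures/single_with_apoe.json",
                           simplifyVector = TRUE)
z <- zscore(two)
m <- z$zvalues[, sig$features, drop = FALSE]

res <- seriate_memetic(m, pop_size = 30, generations = 100, seed = 17)
cat(sprintf("identity objective %.2f -> seriated objective %.2f\n",
            objective_value(m), res$objective))

perm <- list(row_order = rownames(m)[res$row_perm],
             col_order = colnames(m)[res$col_perm],
             objective = res$objective,
             identity_objective = objective_value(m))
jsonlite::write_json(perm, "results/heatmap/ordering.json",
                     auto_unbox = TRUE, digits = NA)

if (requireNamespace("pheatmap", quietly = TRUE)) {
  plot_seriated_heatmap(m, res, filename = "results/heatmap/signature_heatmap.png")
  cat("wrote results/heatmap/signature_heatmap.png\n")
}
cat("wrote results/heatmap/ordering.json\n")
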