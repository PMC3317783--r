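#!/usr/bin/env Rscript
# Preprocess the simulated panels the way the assay data would be handled:
# floor readings below half the least detectable dose, drop analytes
# undetectable in more than 10% of baseline samples, and move to the log10
# scale. The detectability decision is made once, on the baseline cohort, and
# applied to both timepoints so the longitudinal analysis sees one analyte set.

suppressPackageStartupMessages(library(absig))
dir.create("results/processed", recursive = TRUE, showWarnings = FALSE)

base <- apply_ldd_floor(read_panel("results/data/baseline"))
cat("baseline: floored", sum(attr(base, "floored")), "readings across",
    sum(attr(base, "floored") > 0), "analytes\n")
fd <- filter_detectability(base)
cat("baseline: removed", length(fd$removed), "analytes >10% below LDD\n")
if (length(fd$removed)) cat("  ", paste(fd$removed, collapse = ", "), "\n")
write_panel(log_transform(fd$panel), "results/processed/baseline")

fu <- apply_ldd_floor(read_panel("results/data/followup"))
fu <- subset_panel(fu, analytes = colnames(fd$panel$values))
write_panel(log_transform(fu), "results/processed/followup")

cat("wrote results/processed/{baseline,followup} with",
    ncol(fd$panel$values), "analytes\n")
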