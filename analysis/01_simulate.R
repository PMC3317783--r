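#!/usr/bin/env Rscript
# Simulate the study panels: a baseline cohort of 54 controls, 233 stable MCI,
# 163 MCI progressors and 112 AD patients over 190 plasma analytes, plus a
# 12-month follow-up for the 50 controls and 92 progressors retained at that
# visit. Planted ground truth (which analytes carry disease signal, and which
# one is genotype-graded) is written alongside so later steps can audit
# recovery.

suppressPackageStartupMessages(library(absig))
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

cfg <- synth_config(effect_size = 2.5, n_informative = 5,
                    followup_drift = 2 * 0.3, seed = 20260919L)
sim <- generate_panel(cfg)
cat("baseline panel:\n"); print(sim$panel)

# follow-up subset mirrors the cohort retained at the 12-month visit
sm <- sim$panel$sample_meta
keep <- c(sm$sample_id[sm$class == "Control"][1:50],
          sm$sample_id[sm$class == "MCI_Progressor"][1:92])
fu <- generate_followup(sim$panel, sim$truth, cfg, sample_ids = keep)
cat("follow-up panel:\n"); print(fu)

write_panel(sim$panel, "results/data/baseline")
write_panel(fu, "results/data/followup")
write_truth(sim$truth, "results/data/truth.json")
cat("wrote results/data/{baseline,followup,truth.json}\n")
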