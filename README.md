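# absig — plasma analyte biomarker signatures by combinatorial feature selection

`absig` discovers small multivariate **signatures** of plasma analytes that
separate two diagnostic groups in multiplex immunoassay panel data — the
setting of blood-biomarker studies of pre-clinical Alzheimer's disease, where
a panel of ~190 analytes is measured in controls, MCI patients who later
progress to AD, stable MCI patients, and AD patients. It is aimed at
bioinformaticians analysing such panels who want per-individual,
combinatorial feature selection rather than rankings of group-mean
differences.

## The method

1. **Preprocessing.** Readings below half an analyte's least detectable dose
   (LDD) are floored to LDD/2; analytes undetectable (< LDD) in more than 10%
   of samples are removed; analysis proceeds on log10 concentrations.
2. **Entropy filter.** Per analyte, the threshold `T` minimizing the weighted
   class-information entropy `E(T;S) = |S₁|/|S|·H(S₁) + |S₂|/|S|·H(S₂)` is
   found, and the analyte is kept only when its information gain exceeds the
   minimum-description-length criterion `(log₂(N−1) + Δ)/N`,
   `Δ = log₂(3ᶜ−2) − (c·H(S) − c₁H(S₁) − c₂H(S₂))`. Survivors become binary
   features (above/below threshold).
3. **(α,β)-k feature set selection.** A feature *covers* a between-class
   sample pair when its binary values differ, and a within-class pair when
   they agree. The signature is the minimum-cardinality feature set covering
   every between-pair ≥ α times and every within-pair ≥ β times (α = β = 1),
   with ties broken by maximal *coverage* (total feature/between-pair
   covering incidences). Solved exactly by branch and bound, with a labelled
   greedy fallback beyond the node budget, and a fixed-k lexicographic
   variant for infeasible instances.
4. **Meta-features.** Differences and sums of per-analyte Z-scores
   (`zᵢ − zⱼ`, `zᵢ + zⱼ`) for all analyte pairs — log-scale ratios and
   products of relative abundance — ranked univariately by MCC, top 100 fed
   to the same selector.
5. **Evaluation.** Signatures are scored on original values by 10 classifiers
   (Bayes, logistic/linear, margin, instance, tree, ensemble, rules
   families), averaged: sensitivity, specificity and the Matthews correlation
   coefficient `MCC = (TP·TN − FP·FN)/√((TP+FP)(TP+FN)(TN+FP)(TN+FN))`,
   under 10-fold cross-validation or covariate-matched train/test splits,
   optionally on size-matched groups.
6. **Longitudinal change.** 12-month minus baseline log10 changes,
   stability-filtered (analytes changing > 20% on average in controls are
   dropped), then the same selection pipeline.
7. **Seriation.** Heat-map row/column orders minimizing adjacent correlation
   distance (1 − r), found by an elitist memetic algorithm.

A synthetic ADNI-like panel generator (`generate_panel()`) with planted
discriminative analytes, detection-limit censoring, a genotype-graded
APOE-like analyte and follow-up drift provides ground truth for every stage.

## Worked example

```r
library(absig)

cfg <- synth_config(n_per_group = c(Control = 54, MCI_Progressor = 163),
                    n_informative = 5, effect_size = 2.5, seed = 42)
sim <- generate_panel(cfg)
panel <- log_transform(filter_detectability(apply_ldd_floor(sim$panel))$panel)

disc <- entropy_filter(panel)
disc
#> discretized_panel: 6 of 190 features accepted; 217 samples

head(rank_univariate(disc), 3)
#>       feature      cut neg_correct neg_percent pos_correct pos_percent    mcc
#> 1 analyte_005 2.195974          52        96.3         151        92.6 0.843
#> 2 analyte_003 2.074134          48        88.9         155        95.1 0.830
#> 3 analyte_001 2.886934          48        88.9         153        93.9 0.808

sig <- solve_min_k(prune_duplicate_patterns(disc)$instance)
sig
#> signature: k = 6  alpha = 1  beta = 1  coverage = 38989  [ exact ]
#>  features: analyte_001, ..., analyte_006

sum(sig$features %in% sim$truth$informative_analytes$analyte)
#> [1] 5    # all five planted analytes recovered

ids <- size_match(panel, seed = 1)   # 54 controls + 54 age/gender-matched progressors
crossvalidate(panel$values[ids, sig$features],
              factor(panel_classes(panel)[ids],
                     levels = c("Control", "MCI_Progressor")), seed = 1)
#> classification_report ( cv-10fold ), averaged over 10 classifiers:
#>   sensitivity 98.1%  specificity 98.1%  MCC 0.963
```

The ranking table mirrors the univariate view (per-class percent correct at
each analyte's entropy threshold, ordered by MCC); the signature is the
smallest analyte set in which every pair of samples from different groups is
distinguished by at least one analyte; the report averages ten classifiers on
the original concentrations of the selected analytes.

## The analysis workflow

`analysis/` contains numbered drivers that run the full study on a simulated
cohort and write tables under `results/`:

    01_simulate.R      cohort + 12-month follow-up with planted truth
    02_preprocess.R    LDD floor, detectability filter, log10
    03_univariate.R    Welch t-tests, entropy filter, MCC ranking
    04_signatures.R    min-k signatures with/without the APOE-like analyte
    05_metafeatures.R  pairwise difference/sum meta-feature signatures
    06_evaluate.R      cross-validation and matched train/test accuracy
    07_longitudinal.R  change signatures with control-stability filter
    08_heatmap.R       memetic seriation and heat map

Run them in order from the repository root: `Rscript analysis/01_simulate.R`
and so on.

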