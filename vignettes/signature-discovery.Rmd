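---
title: "Combinatorial discovery of plasma biomarker signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combinatorial discovery of plasma biomarker signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(absig)
```

## The problem

Multiplex immunoassay panels measure a hundred or more plasma analytes per
sample. Given such a panel over two diagnostic groups — say cognitively
normal controls versus individuals with mild cognitive impairment who later
progress to Alzheimer's disease — the task is to find a small set of analytes
(a *signature*) whose joint pattern separates the groups, in a way that keeps
per-individual information rather than collapsing each analyte to group means.

`absig` implements that workflow as composable stages: detection-limit
handling, supervised single-cut discretization with a minimum description
length (MDL) acceptance rule, exact combinatorial signature selection, pair
meta-features, a multi-classifier evaluation harness, longitudinal change
signatures, and memetic seriation for heat-map presentation. A synthetic
panel generator with planted ground truth makes every stage testable without
access-controlled clinical data.

## Preprocessing model

Concentrations are positive reals in analyte-specific units. Each analyte
carries a *least detectable dose* (LDD): the concentration producing signal
reliably above background. Three rules are applied, in order:

1. **Flooring.** Readings below LDD/2 are replaced by LDD/2. Readings at or
   above the boundary are untouched; the per-analyte floored count is kept.
2. **Detectability.** An analyte with strictly more than 10% of readings
   strictly below its LDD is removed. "Below detection" is read as strictly
   below the LDD — the boundary reading counts as detected. The comparison
   operator is a design choice; the underlying convention (is a reading equal
   to the LDD detected?) is rarely stated by assay providers, and the strict
   reading is the one under which the flooring rule and the filter compose
   without contradiction.
3. **Log transform.** Plasma concentrations are approximately log-normal, so
   analysis proceeds on log10 values. A `raw` analysis scale is also
   supported end to end: the discretizer depends only on value order, so
   signatures are identical on either scale, and only classifier inputs and
   change definitions differ.

Z-scores, used for meta-features and heat maps, are computed per analyte with
the sample (n−1) standard deviation over a stated reference population —
by default the pooled two-class comparison population, recorded in the
result's provenance. Constant analytes abort with an error naming the
analyte: silently emitting zeros would corrupt every meta-feature built on
them.

## Discretization and the entropy filter

For one analyte with values $x_1,\dots,x_n$ and two-class labels, every
midpoint between consecutive distinct sorted values is a candidate threshold
$T$. The threshold minimizing the weighted class-information entropy

$$E(T;S) = \frac{|S_1|}{|S|}H(S_1) + \frac{|S_2|}{|S|}H(S_2)$$

is selected ($S_1, S_2$ are the samples below/above $T$; $H$ is Shannon
entropy in bits; ties go to the smallest midpoint, making the cut
deterministic and order-invariant). The analyte is *accepted* only when its
information gain $H(S) - E(T;S)$ exceeds the MDL criterion

$$\frac{\log_2(N-1) + \Delta}{N}, \qquad
\Delta = \log_2(3^c - 2) - \left(c\,H(S) - c_1 H(S_1) - c_2 H(S_2)\right),$$

with $c, c_1, c_2$ the number of classes present in $S, S_1, S_2$. Scanning
all midpoints (not only class-boundary points) costs nothing at these sizes
and makes the exhaustive test oracle trivial to state. Only the single binary
cut is implemented — the recursive multi-interval extension of this family of
algorithms is not needed for two-class signature work, where one threshold
per analyte is the model.

Accepted analytes are ranked by their univariate accuracy: the binary
orientation (which side predicts disease) is chosen per analyte to maximize
the Matthews correlation coefficient (MCC), and the table reports per-class
correct counts, percents, and MCC, sorted by MCC. The orientation rule is a
design choice; maximizing MCC is the one consistent with ranking by MCC.

## The (α,β)-k feature set problem

The binary matrix of accepted features defines a covering problem over sample
pairs. A feature *covers* a between-class pair when its binary values differ
across the pair, and covers a within-class pair when they agree. A signature
must cover every between-class pair at least α times and every within-class
pair at least β times; the optimum is the minimum size $k^*$ at α = β = 1,
and among size-$k^*$ solutions the one maximizing *coverage* — the total
number of (selected feature, between-class pair) covering incidences. Within
pair incidences are excluded from the tie-break, following the emphasis on
covering pairs from different classes; whether the historical tie-break also
counted within pairs is not recoverable, and the choice is recorded in the
solver output.

Because coverage is additive over selected features, the tie-break is a
weighted completion problem. The solver runs two exact branch-and-bound
stages: minimize $k$ (branching on the uncovered pair with fewest available
covering features, with a greedy upper bound and a deficiency lower bound),
then maximize coverage at $k = k^*$ (enumerating minimal covers with an
optimistic top-weight bound and topping up to $k^*$ with the heaviest unused
features). Both stages carry a node budget (default $2\times10^5$ nodes);
when the proof does not close within budget, the greedy + local-search
solution is returned and the result is labelled `"heuristic"` instead of
`"exact"`. Solver correctness is certified against exhaustive subset
enumeration on hundreds of random instances in the test suite. An ILP
formulation would be the other natural route; the dedicated branch and bound
keeps the package dependency-free and is exact at the scales produced by the
entropy filter (typically 5–25 features).

Two practical complications are handled explicitly:

- **Unsolvable patterns.** A control and a disease sample with identical
  binary rows make a between-pair no feature covers; a same-class pair
  differing on *every* feature does the same on the within side. Samples
  involved in such zero-cover pairs are pruned greedily (most conflicts
  first), reported, and reinstated for classification. With many features the
  complementary-row case is vanishingly rare, but with few accepted features
  it occurs regularly and would otherwise produce spurious infeasibility.
- **Genuine infeasibility.** When pruning is not requested and some pair is
  uncoverable, the solver returns an `Infeasible` result (not an error) with
  the offending pairs — the analysis-level response is to constrain the
  signature size instead (`solve_fixed_k`), which maximizes
  (α, β, coverage) lexicographically at a fixed k, by exhaustive enumeration
  when $\binom{n}{k}$ is tractable and labelled hill-climbing otherwise.

## Meta-features

For analytes $i < j$ (panel order), difference meta-features $z_i - z_j$ and
sum meta-features $z_i + z_j$ are formed from Z-scores — on log10 data these
correspond to ratios and products of relative abundance. All $\binom{n}{2}$
pairs are generated, entropy filtered, ranked univariately by MCC, and the
top 100 (configurable) feed the feature-set solver; selecting from the full
accepted set is not computationally feasible, and the ranking metric for the
top-m cut (MCC rather than raw percent correct) is recorded in the output.
Exclusion lists (e.g. removing an APOE analyte) are applied before pairing,
so every pair containing an excluded analyte disappears.

## Classification evaluation

Signatures are evaluated on the *original* (non-discretized) values. Ten
classifiers spanning the families commonly screened for panel data — naive
Bayes, logistic regression, LDA, nearest centroid, linear and radial SVM,
5-NN, a classification tree, a random forest, and a single-feature threshold
rule — are each trained and scored, and the report averages their
sensitivities, specificities and MCCs (score-then-average; how a
multi-classifier average should pool folds is a genuine choice, and the
per-classifier contingencies are retained so the alternative can be
recomputed). 10-fold cross-validation uses plain random folds; out-of-fold
predictions are pooled into one contingency per classifier. A classifier
failing on any fold is dropped with a warning rather than poisoning the
average. MCC returns 0 whenever a denominator factor is zero — the
uninformative-classifier convention.

Because unequal group sizes bias most training objectives toward the larger
class, the harness provides *size matching* (all minority samples plus an
equal number of majority samples, gender-stratified greedy nearest-age
matching) and *matched train/test splits* (50/50 within gender × genotype
strata, age-paired, leftovers balanced). Stratified analyses — single-gender,
age-median, single-genotype subsets — are expressed as metadata filters via
`subset_panel()` before evaluation rather than as bespoke operations.

The univariate statistical companion is a per-analyte Welch two-tailed
t-test. Welch's correction is applied always (not "where appropriate"): the
conservative choice avoids a variance pre-test. No multiple-testing
correction enters the ranking; a Bonferroni column is emitted for
information.

## Longitudinal change

With a baseline and a 12-month panel, the change score is `12m − baseline`
on the log10 scale (equivalently `12m / baseline` on the raw scale; the two
are related by exact exponentiation and tested as such). Analytes that drift
in healthy controls carry non-disease variation, so any analyte whose
average control fold change deviates from 1 by more than 20% is excluded.
"Average change more than 20%" admits several readings (arithmetic mean of
ratios, geometric mean, mean absolute change); the geometric mean ratio with
a symmetric |fold − 1| rule is implemented because it is the one that is
exactly scale-consistent between the raw and log10 pipelines, and the
per-analyte statistic is exported so alternative rules can be audited. The
retained change matrix then flows through the same entropy filter → feature
set pipeline, in single-analyte or pair-difference mode.

## Seriation for heat maps

Heat maps order samples and analytes so that similar profiles are adjacent.
The objective is the summed correlation distance (1 − Pearson r) between
adjacent rows plus adjacent columns. Pearson correlation between two rows is
invariant to column order, so the row and column problems decouple into two
independent path-seriation problems over precomputed distance matrices. Each
is solved by a memetic algorithm: permutation encoding, order crossover,
pairwise-swap and segment-reversal local search on each new candidate,
elitist replacement (population 30, 200 generations by default — all
configurable). The adjacency (path) objective is the minimal reading of
"minimize correlation distance between different analytes and between
different samples"; an all-pairs weighted formulation would be a different
model. Quality is certified only by the exhaustive oracle property in the
test suite: on small matrices the memetic optimum matches full enumeration
in ≥95% of seeded runs. Elitism guarantees the best objective never worsens
and never exceeds the identity ordering's objective.

## The synthetic panel generator

`generate_panel()` emulates the structure of a four-group plasma proteomics
study: group sizes 54/233/163/112, 190 analytes, log10-normal concentrations
with analyte-specific baselines, exchangeable within-block correlation
(blocks of 10, ρ = 0.2), detection-limit censoring at a configured control
quantile, a planted set of class-discriminative analytes (shift in
within-group SD units on the log10 scale), a genotype-graded APOE-like
analyte, and a 12-month follow-up with disease-linked drift in progressors.

Defaults were fixed once, as the package's study conditions:

- `noise_sd = 0.3` log10 units: a typical within-group spread for plasma
  immunoassay analytes spanning a few-fold concentration range.
- `effect_size = 1.5` SD by default; parameter-recovery studies in the test
  suite use 2.5 SD with 5 planted analytes.
- `informative_directions = "up"`: planted effects raise the affected
  classes. Down-shifted effects interact with censoring — a −2.5 SD shift
  pushes roughly half the affected class below the LDD and the detectability
  filter then removes the analyte before selection ever sees it, which is
  precisely how heavily censored analytes are excluded from real panels a
  priori. The `"down"` and `"mixed"` options keep that interplay available.
- `ldd_quantile = 0.001`: detectable analytes sit well above their LDD.
  Larger values emulate poorly detectable analytes and are used in the
  censoring tests.
- `genotype_effect = −1` SD per ε4 allele (ε2 counteracting), with ε4 allele
  frequencies 9/43/67/68% per group: under these settings the APOE-like
  analyte is retained by the detectability filter, passes the entropy filter,
  and ranks with a univariate MCC around 0.3–0.5 across seeds — the
  behaviour a genotype-driven confound should show. The gradient direction
  (ε2 > ε3 > ε4 in plasma level) is monotone by construction.
- Inter-analyte correlation in real panels is not characterized here;
  `block_rho` is a free knob, not an estimate.
- Age and gender are generated group-balanced so matching operations have
  work to do but no confound unless configured.

What the generator does *not* emulate: real analyte names and units, heavy
tails and assay saturation, batch effects, missingness, or any QC structure.
Passing tests therefore demonstrate correctness of the pipeline's logic and
its statistical behaviour under a log-normal world — not performance on real
assay data.

## Numerical and degenerate-input conventions

- Entropies in bits throughout; cut ties break to the smallest midpoint.
- Constant features are recorded as rejected (no cut exists); constant
  reference analytes abort Z-scoring with the analyte named.
- An empty entropy-filter result is a warning plus an empty, flagged
  object — downstream stages return "no signature" reports rather than
  erroring, mirroring comparisons where no analyte discriminates.
- MCC's zero-denominator convention is 0.
- All stochastic steps (generator, folds, matching, seriation) take explicit
  seeds and restore the caller's RNG state; identical configuration is
  bit-reproducible.

## Problem sizes used in the checks

The test suite certifies the solvers against exhaustive oracles on instances
of up to 10 features and 12 samples (200 random instances), the discretizer
on 1000 random vectors, parameter recovery on 20 simulated cohorts of
54 + 163 samples × 190 analytes with 5 planted analytes at 2.5 SD,
longitudinal recovery on 50 cohorts of 50 + 92 samples with 2 SD drift, and
seriation on 100 random matrices of up to 6 rows against full enumeration.
These sizes exercise every code path at the study's own scale while keeping
the whole suite inside a few minutes.

## Known limitations

- At α = β = 1 the covering problem is plain set cover; the general
  multicover path (α, β > 1) is exact but exercised mainly through
  `solve_fixed_k`'s lexicographic search.
- The exact solver's node budget makes optimality proofs on 100-feature
  meta-feature pools intermittent; results are then labelled heuristic, and
  the analysis scripts surface that label rather than hiding it.
- Only two timepoints are modelled; the change score is a difference, not a
  trajectory.
- The classifier set deliberately avoids hyperparameter tuning; it
  characterizes signatures, it does not chase the best achievable accuracy.
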