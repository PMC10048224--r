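---
title: "Methods: co-expression modules, triangle motifs, and prognostic/diagnostic models for EMT-subtype tumors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-expression modules, triangle motifs, and prognostic/diagnostic models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical machinery of `emtmotif`: the models
each stage fits, the assumptions they rest on, the tunable parameters and
their defaults, what the synthetic-data generator does and does not
emulate, and the numerical and design choices made where the methodology
was genuinely open.

## The scientific setting

Gastric adenocarcinomas are classified by the ACRG scheme into four
molecular subtypes; the mesenchymal (MSS/EMT) subtype has the worst
prognosis and the most distinct transcriptional profile. The pipeline's
goal is to extract small, robust RNA marker panels for this subtype:
triangles of interacting genes inside its dominant co-expression module,
and pairs of regulatory miRNAs targeting those genes. All stages operate
on genes-by-samples expression matrices from two (or more) cohorts that may
live on different measurement platforms — RNA-seq counts and microarray
log-intensities.

## Normalization

Count cohorts are transformed with `vst_transform()`: median-of-ratios
size factors (the per-sample median of the gene-wise ratio to the per-gene
geometric mean, ignoring genes with any zero) followed by
`log2(count / sf + 1)`. This is deliberately a transparent
variance-stabilizing-style transform rather than a fitted mean–dispersion
VST: downstream stages need log-scale, depth-corrected, roughly
homoskedastic values, not any particular parametric curve, and a transform
with a two-line definition is testable against hand arithmetic. A caveat
inherited from all ratio-based normalizations: when a large, one-sided
fraction of the genome is differentially expressed, size factors absorb
part of the signal (composition bias); the package's tests measure
generator calibration on equal-depth data for exactly this reason.

Cross-platform diagnostic modelling uses `pool_and_normalize()`: the two
cohorts are restricted to shared features, brought to log2 scale, pooled,
quantile normalized together, and re-separated — after which any per-column
quantile is identical across cohorts, making frozen logistic coefficients
portable. An independent test cohort is quantile normalized alone, which
probes robustness of the models to the normalization reference. Tied
values receive the mean of the reference values at their tied ranks; note
that under ties this rule intentionally takes precedence over exact
marginal equality (averaging tied reference values perturbs the column's
multiset at the tied ranks). Outlier screening (`detect_outliers()`) flags
samples more than `k_sd = 4` robust standard deviations (MAD) from the
median on either of the first two principal components; the threshold is a
package choice — the source methodology names PCA flagging without a rule —
and is exposed as an argument.

## Differential expression

`nb_wald_test()` fits, per gene, a negative-binomial GLM with log link,
design intercept + class, and log size-factor offsets. The gene-wise
dispersion is a pooled method-of-moments estimate
(`Var = μ + φ μ²`, floored at 1e−8); the Wald statistic is the class
coefficient over its standard error, with two-sided normal p-values and
Benjamini–Hochberg adjustment. This is intentionally simpler than
empirical-Bayes dispersion shrinkage: the pipeline consumes only
`−log10(padj)`, the log2 fold change, and per-gene AUC, and a moment
estimator keeps the implementation auditably close to the likelihood it
maximizes. The fit runs as a single vectorized IRLS across all genes
(the design has two columns), so genome-scale matrices take seconds.
Intensity cohorts use a per-gene Welch t-test behind the same result
contract. Per-gene separability is the tie-corrected Mann–Whitney AUC;
for motif scoring it is used direction-free (`max(AUC, 1 − AUC)`), since
the score treats separability as a magnitude alongside `|LFC|`.

## Module discovery

`find_modules()` implements the signed weighted co-expression workflow:
Pearson correlation across samples, signed adjacency
`((1 + r)/2)^β`, topological overlap
`ω_ij = (Σ_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 − a_ij)`, and
average-linkage hierarchical clustering of `1 − ω`. Defaults follow the
source methodology: soft threshold β = 20 (forceable; `pick_soft_threshold()`
scans 1–20 and reports scale-free fit R² and mean connectivity), minimum
module size 20, eigengene merge height 0.25. Module discovery is meant to
run on the EMT-subtype samples only — `run_all()` enforces this — while
module significance (mean member `−log10(padj)`) is computed from the
full-cohort EMT-vs-rest contrast.

The tree cut is a simplified static-hybrid rule: cut the dendrogram at
99% of the tallest merge height, demote clusters below the minimum size to
unassigned ("grey"), then let grey genes be adopted by the module whose
eigengene they correlate with at `|kME| ≥ 0.5`. The adoption threshold
deserves a note: the null kME of an unrelated gene is approximately
`Normal(0, 1/√n)` across `n` samples, so with the ~45 EMT samples of a
default synthetic cohort a 0.3 threshold sits at ~2σ and adopts roughly 5%
of all background genes into each module, visibly polluting the partition;
0.5 sits at ~3.4σ and keeps adoption to genuinely correlated genes. The
parameter is exposed for larger cohorts where 0.3 is defensible.
Eigengenes are unit-norm first principal components of the
row-standardized module submatrix, sign-oriented to correlate positively
with the module's mean standardized profile, so module–trait correlations
have a reproducible sign.

## Motif scoring

Triangles are enumerated on the module-induced PPI subnetwork and scored
with

S_ij = (W1j/2)·ND_i/max(ND) + (W1j/2)·BC_i/max(BC) + W2j·DP_i/max(DP) +
W3j·AUC_i/max(AUC) + W4j·|LFC|_i/max(|LFC|)

with every maximum taken over the enumerated motif list, and a component
whose maximum is zero contributing zero (this makes the pathway term
well-defined when no motif touches the pathway set). Two interpretation
choices were open and are settled as follows. First, the topology weight
W1 is split evenly between node degree and betweenness — the score lists
two W1/2 terms — and the split is exposed in the scenario table. Second,
degree and betweenness are computed on the module-induced network in which
the motifs live, not the global interactome: the score compares motifs
within the module, and module-internal topology is the comparable
quantity. The 13 default weighting scenarios (`default_scenarios()`) span
the four single-criterion emphases, all pairwise mixes, the uniform
scenario, and two tilted mixes; they are a documented default, not a
reproduction of any external scenario table, and any data frame with
columns `id, w1..w4` can replace them. Motif selection takes the top 10
per scenario (ties: higher mean degree, then lexicographic triple), unions
across scenarios, and removes redundancy by *node set* only — motifs
sharing two of three genes stay distinct, which matches how overlapping
triangles are reported in this literature.

## Survival analysis

Per-gene groups are the top and bottom `⌊0.4 n⌋` samples by expression;
per-motif groups are the intersections of the member-wise sets, so only
samples with concordant expression of all three members are analyzed.
Groups need ≥ 30 samples each and ≥ 100 combined (interpreted as the sum
of the two analyzed groups) to enter the Cox model. The Cox fit uses the
Breslow tie approximation — the simplest consistent choice — with age
z-scored and sex coded 0/1; standardizing age stabilizes the Newton steps
without changing the group hazard ratio. Cross-cohort consistency is the
intersection of the two cohorts' top-5 motifs by hazard ratio, with ties
broken by smaller Wald p; significance is deliberately not a ranking
criterion, only a tie-break, because the source rule ranks by HR alone.

At the default synthetic scale (150 samples per cohort) the intersection
groups of a correlated triple hold ~45 + 45 samples, below the 100-sample
filter — the filter is doing its job; the consistency screen is exercised
and tested at 300-sample cohorts, the scale of the cohorts the filter was
designed for.

## Diagnostics

Motif logistic models are fitted by IRLS (`glm`), with complete separation
detected by divergence or non-convergence and resolved by refitting with a
negligible L2 ridge (λ = 1e−6) so coefficients stay finite and the model
usable; the flag is carried on the result. Validation always applies
frozen coefficients. The miRNA combination search is exhaustive over
combinations of size ≤ 2 (configurable) of the candidate miRNAs —
differentially expressed (BH-adjusted p ≤ 0.05, configurable) with a
validated target among the selected motif genes — ranked by LDA
leave-one-out cross-validated AUC on the 80% stratified training split,
with the winner refit on the full training split and scored on the
held-out 20%. LDA is two-class Fisher with pooled covariance, priors from
training frequencies, and a 1e−6 ridge when the pooled covariance is
near-singular; it emits a plain linear index
`Σ coef_k · miRNA_k + intercept`, the form in which such two-marker
discriminants are usually published. Exact AUC ties in the search resolve
to the smaller combination (parsimony); with ≤ 3 features the search is
exhaustive by construction, which the tests assert directly.

## The miRNA–mRNA network

`build_mixed_network()` joins PPI edges among the selected motif genes
with validated miRNA→gene edges; centralities treat the graph as
undirected, matching how mixed regulatory/interaction networks are
visualized and profiled. The default registry computes 12 measures
(degree, betweenness, classic and Latora/harmonic closeness, eigenvector,
PageRank, Katz, subgraph centrality, local clustering, k-core, inverse
eccentricity, leverage); the registry is keyed by name and extensible, the
point being the PCA selection method rather than any fixed catalog:
measures are z-scored, PCA is run on the node × measure matrix, and the
measure with the largest squared PC1 loading is chosen (constant columns
dropped with a warning; float-level ties resolve by name order). Latora
closeness — `Σ_u 1/d(v,u)` with `1/∞ = 0` — is the measure of choice for
disconnected mixed networks because it is finite everywhere.

## The synthetic-data generator

`generate_study()` emulates, with known truth: block co-expression from
per-module latent factors (default five modules of 100/80/60/50/40 genes,
loadings ~ Normal(0.6, 0.1), giving within-block correlations around 0.7
once platform noise is added); a +2 log2 shift on the first module in EMT
samples (30% of each cohort); negative-binomial counts (dispersion 0.05,
log-normal(0, 0.2) library factors, so normalization is non-trivial) or
Gaussian log-intensities (sd 0.3); a Bernoulli(0.02) background PPI with
two planted triangles inside the EMT module; exponential survival with
rate `0.01 · exp(Σ β_g z_g + 0.3 z_age + 0.3 male)` (default β = 0.5 on
the first planted triple) under independent exponential censoring; and a
miRNA layer in which each miRNA is `−0.3 ·` the mean standardized
expression of its targets plus Gaussian noise (sd 0.7), with a planted
pair shifted ±1.5 between classes. Age is Normal(62, 11) truncated to
[30, 90] and sex Bernoulli(0.6), matching the clinical ranges typical of
gastric-cancer cohorts, and both enter the hazard so covariate adjustment
is testable.

Two defaults are worth their arithmetic. The miRNA noise sd of 0.7 puts a
single planted miRNA at d′ ≈ 2.1 (AUC ≈ 0.93) and the pair at Mahalanobis
≈ 3 (AUC ≈ 0.98): the regime where a two-marker panel genuinely beats its
members, which is the behavior the combination search exists to detect.
And because the discriminative pair must target EMT-module genes to pass
the candidate filter, its repression term is itself class-correlated and
partially opposes the +1.5 shift; the default repression strength of 0.3
keeps the planted shifts dominant.

What the generator does *not* emulate: read-level sequencing artifacts,
batch effects beyond the count/intensity platform split, copy-number or
mutation structure, realistic PPI degree distributions, or miRNA
multi-targeting regulation beyond linear repression. Passing recovery
tests therefore demonstrates that the pipeline's logic is correct and
well-calibrated under its own model assumptions — not that it would rank
the same motifs on any real cohort.

## Numerical choices and degenerate inputs

- NB IRLS: 25 iterations, tolerance 1e−8, coefficients clamped to ±30,
  means floored at 1e−10; all-zero genes report lfc 0, p 1.
- Zero-variance genes get correlation 0 in the adjacency; adjusted
  p-values are floored at 1e−300 before `−log10`.
- `split_by_expression()` fills both groups from opposite ends of a
  stable ranking, so fully tied values still produce disjoint groups (and
  a `degenerate` flag).
- Cox fits flag monotone likelihood (|β| > 15 or exploding SE); the
  log-rank test returns p = 1 when there are no events.
- All generator and pipeline randomness flows from one root seed with
  fixed per-stage offsets, so every reported number is reproducible from
  the seed alone.

## Problem sizes used in the test suite

Unit tests run on matrices of tens to hundreds of genes. The end-to-end
recovery properties are asserted at the generator's default scale —
2,000 genes, 150 miRNAs, two cohorts of 150 samples, 20 seeds — which the
package treats as its reference desk-scale experiment; survival
consistency is asserted at 300-sample cohorts as discussed above.

## Known limitations

- The static-hybrid tree cut is simpler than full dynamic branch cutting;
  very unequal module densities may require adjusting the cut fraction.
- Moment dispersion estimates are noisier than shrunken ones at very small
  n; the Wald test's type-I error is verified at ~5–6% but p-values for
  individual low-count genes are approximate.
- The VST stand-in does not flatten the mean–variance trend as completely
  as a fitted transform at very low counts.
- The 13 scenario weights and the centrality registry are documented
  defaults, chosen to span the score's behavior, not canonical constants.
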