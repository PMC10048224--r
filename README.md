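# emtmotif

Network-based biomarker discovery for the mesenchymal (EMT) subtype of
gastric cancer, packaged as a reusable, fully tested R pipeline.

Gastric tumors of the EMT molecular subtype (one of the four ACRG classes:
MSS/EMT, MSI, MSS/TP53+, MSS/TP53−) carry the worst prognosis and the least
understood biology. `emtmotif` implements an end-to-end workflow that
extracts candidate diagnostic and prognostic markers for this subtype from
multi-cohort expression data:

1. **Co-expression module discovery** — a signed weighted gene
   co-expression network (adjacency `a_ij = ((1 + cor_ij)/2)^β`, topological
   overlap, average-linkage clustering with minimum module size 20 and
   eigengene merging at cut height 0.25) is built on the EMT-subtype samples
   only; the module with the highest mean `−log10(adjusted p)` of EMT-vs-rest
   differential expression is designated the EMT module.
2. **Triangle motif ranking** — all 3-node/3-edge cliques of the EMT
   module's protein–protein interaction subnetwork are enumerated and scored
   with a multi-objective function over weighting scenarios *j*:

   ```
   S_ij = (W1j/2)·ND_i/max(ND) + (W1j/2)·BC_i/max(BC) + W2j·DP_i/max(DP)
          + W3j·AUC_i/max(AUC) + W4j·|LFC|_i/max(|LFC|)
   ```

   where ND is the mean member node degree, BC the mean betweenness
   centrality, DP the number of members in the cancer KEGG pathway set,
   AUC the mean per-gene ROC AUC (EMT vs rest), and |LFC| the mean absolute
   log2 fold change. The top 10 motifs of each scenario are pooled and
   deduplicated by node set.
3. **Prognostic evaluation** — per motif, the high/low-expression groups are
   the intersections of the per-member top/bottom 40% samples; groups with
   ≥ 30 samples each and ≥ 100 in total enter an age/sex-adjusted Cox model
   (Breslow ties), and motifs in the top five by hazard ratio in *both*
   cohorts are reported as consistent.
4. **Diagnostic evaluation** — motif members predict subtype in a logistic
   model fitted on the training cohort after pooled quantile normalization
   with the validation cohort; frozen coefficients are evaluated on every
   cohort (ROC/AUC). Candidate miRNAs (differentially expressed, with a
   validated target among the top-motif genes) feed an exhaustive LDA
   combination search ranked by leave-one-out cross-validated AUC on an
   80/20 stratified split.
5. **Network centrality** — the mixed miRNA–mRNA network (PPI edges among
   motif genes, validated miRNA→gene edges) is profiled with a registry of
   centrality measures; PCA on the standardized node × measure matrix picks
   the most representative measure, and the top central RNAs are reported.

Because the original cohorts are external, the package ships a first-class
**synthetic-data generator** (`synthetic_config()`, `generate_study()`) that
emulates the study's statistical structure with known ground truth: latent
factor co-expression blocks, a planted EMT module with a configurable log2
effect, negative-binomial counts vs Gaussian log-intensity platforms,
planted PPI triangles, proportional-hazards survival tied to expression
with age/sex covariates, and a miRNA layer with target repression and a
planted discriminative pair. Every stage of the pipeline is tested against
this ground truth and against independent oracles.

## Worked example

A complete synthetic run at the default desk scale (2,000 genes, 150
miRNAs, two cohorts of 150 samples — counts and intensity platforms):

```r
library(emtmotif)
report <- run_all(pipeline_config(seed = 1, verbose = FALSE))
print(report)
#> EMT-subtype motif analysis report
#>   seed: 1
#>   modules: 5 (top module M1, 103 genes, significance 46.26)
#>   triangles in module subnetwork: 3; selected motifs: 3
#>   cross-cohort consistent top motifs: (none)
#>   best diagnostic motif: g0004|g0005|g0006 (validation AUC 0.991)
#>   miRNA combination: mir001 + mir002 (LOOCV 0.989, held-out 0.984)
#>   centrality measure: subgraph; top nodes: g0005, mir002, g0002, g0003, g0006
```

The report says: the five planted co-expression modules were recovered, and
the planted EMT module (100 genes plus 3 adopted neighbors) had by far the
most significant differential expression (mean −log10 adjusted p = 46.3).
Its PPI subnetwork contained 3 triangles, including both planted motifs.
The planted motif `g0004|g0005|g0006` discriminates EMT from non-EMT
samples in the held-out cohort with AUC 0.991, and the planted miRNA pair
was found by the LDA search:

```r
print(report$mirna$search)
#> mirna_search: best combination mir001 + mir002
#>   training LOOCV AUC = 0.9894, held-out AUC = 0.9841
#> lda_model index: (1.714728 x mir001) + (-4.351842 x mir002) + -5.37708
```

The linear index has a positive coefficient for the miRNA up-regulated in
EMT samples and a negative one for the down-regulated miRNA, mirroring how
such two-marker discriminant indices are reported in practice. At this
cohort size (150 per cohort) the motif survival groups hold fewer than 100
samples, so the cross-cohort consistency list is empty by the sample-size
filter; at 300-sample cohorts the planted high-hazard motif passes and is
recovered (see `scripts/acceptance.R`).

Individual stages are exported and usable on real data read from TSV files
(`read_expression()`, `read_annotations()`, `read_network()`, `read_gmt()`):
`vst_transform()`, `quantile_normalize()`, `pool_and_normalize()`,
`nb_wald_test()`, `find_modules()`, `enumerate_triangles()`,
`score_motifs()`, `motif_survival()`, `motif_diagnostics()`,
`search_mirna_combinations()`, `compute_centralities()`.

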