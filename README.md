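# clonescape

Clonal evolution analysis from multi-region tumor sequencing, built around
the progression of intraductal papillary mucinous neoplasms (IPMN) — cystic
precursor lesions of the pancreas — to invasive pancreatic ductal
adenocarcinoma (PDAC). Multi-region whole-genome sequencing of such lesions
asks: do the sampled regions descend from one ancestral clone or from
several independently initiated ones, does the tumor grow linearly or by
branching, which mutational processes act on which branch, and how does
the transcriptome (squamous vs. classical character, stromal and immune
content) track progression? clonescape implements that analysis as a
tested, reusable R package, together with a synthetic cohort generator
with known ground truth so every stage is verifiable by parameter
recovery.

## What it computes

**Cancer cell fractions.** For a mutation at multiplicity *m* in a sample
of purity ρ with tumor copy number *n<sub>t</sub>* at the locus, the
expected variant allele fraction is

&nbsp;&nbsp;&nbsp;&nbsp;*f* = CCF · ρ · *m* / (ρ *n<sub>t</sub>* + (1 − ρ) · 2)

`expected_vaf()` / `compute_ccf()` invert each other exactly;
`estimate_multiplicity_joint()` fixes *m* from the data before
clustering.

**Subclonal deconvolution.** `dp_cluster()` fits a truncated
stick-breaking Dirichlet-process binomial mixture to alt/depth counts
across regions by Gibbs sampling (compiled kernel), with a deterministic
consensus: co-clustering cut, soft-EM polish on the CCF grid, and a
split/merge hill-climb on a penalized likelihood. It returns a classed
fit with `print`, `summary`, `coef`, `logLik` and `plot` methods.

**Clone trees.** `build_forest()` places clusters with the
nesting/pigeonhole rule, the sum rule (children's CCFs cannot exceed the
parent's, per region) and the crossing rule (clusters whose CCF ordering
flips between regions cannot share a lineage). `classify_trajectory()`
calls single vs. multiple MRCA and linear vs. branching growth;
`subclone_fractions()` gives per-region exclusive fractions; trees
serialize to Newick (branch lengths = SNV+indel counts) and annotated
JSON.

**Signatures and timing.** SBS96/ID83/CN48 channel encoders, NNLS
exposure refitting with pruning, per-mutation signature probabilities,
per-branch profiles, a minimal KL-NNMF extractor, and
clonal-early/late/subclonal timing from multiplicity at gained loci.

**Transcriptome.** Squamous–classical gradient score (squamous set score
minus classical set score), rank-based stromal/immune/ESTIMATE-like
scores, constrained-least-squares cell-fraction deconvolution with an
explicit uncharacterized remainder, and PCA + k-means sample clustering.

**Statistics.** Fisher–Pitman permutation test (exact enumeration or
Monte Carlo), Mann–Whitney, Fisher exact 2×2, Pearson/Spearman
correlation — all verified against brute-force enumeration oracles.

## Worked example

```r
library(clonescape)

out <- file.path(tempdir(), "demo")
coh <- simulate_cohort(out, n_patients = 3, seed = 42)   # writes VCF/BEDPE/segments/purity/expression + manifest
res <- run_cohort_analysis(coh$manifest, file.path(out, "report"), seed = 1)

res$trajectories
#>   patient_id mrca_pattern growth_pattern n_clusters n_roots
#> 1     case01  single_mrca      branching          3       1
#> 2     case02  single_mrca      branching          5       1
#> 3     case03  single_mrca      branching          3       1

res$cases[[2]]$fit
#> Dirichlet-process CCF clustering
#>   1734 mutations, 5 regions, 5 retained clusters
#>      n   R1   R2   R3   R4   R5
#> C1 466 1.00 1.00 0.99 1.01 0.99
#> C2 539 0.55 0.46 0.69 0.06 0.30
#> C3 257 0.32 0.37 0.02 0.36 0.55
#> C4 244 0.04 0.22 0.67 0.04 0.00
#> C5 228 0.00 0.03 0.62 0.00 0.00

res$cases[[2]]$tree
#> Clone tree: 5 clusters, 1 root(s); single_mrca / branching
#> - C1 (n=466; CCF 1.00/1.00/0.99/1.01/0.99)
#>   - C2 (n=539; CCF 0.55/0.46/0.69/0.06/0.30)
#>     - C4 (n=244; CCF 0.04/0.22/0.67/0.04/0.00)
#>       - C5 (n=228; CCF 0.00/0.03/0.62/0.00/0.00)
#>   - C3 (n=257; CCF 0.32/0.37/0.02/0.36/0.55)
```

Reading: case02's five regions share one truncal cluster at CCF ≈ 1
(single MRCA), which split into two coexisting lineages (branching
growth); the C2→C4→C5 lineage swept region R3 while C3 dominates R5. The
report directory holds per-case Newick/JSON trees, the cohort trajectory
table, per-region subclone (oval-plot) fractions, branch signature
profiles, and — when expression is present — gradient, stromal/immune
and cell-fraction tables per sample. On a full 12-patient cohort the
report also compares per-region structural-variant counts between
branching and linear cases with a two-sided Fisher–Pitman permutation
test.

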