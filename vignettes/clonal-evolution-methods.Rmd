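---
title: "Methods: multi-region clonal evolution analysis with clonescape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-region clonal evolution analysis with clonescape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonescape)
```

# Scope

clonescape reconstructs the subclonal architecture of tumors sampled in
several spatially distinct regions, in the setting where cystic pancreatic
precursor lesions (IPMN, graded LGD/HGD) progress to invasive pancreatic
ductal adenocarcinoma (PDAC). The pipeline takes per-region somatic calls
with read counts, allele-specific copy-number segments with purity (as
produced by Battenberg-style callers), structural-variant breakpoints and,
optionally, bulk expression, and produces: mutation clusters with cancer
cell fractions (CCF), clone trees with trajectory calls (single versus
multiple ancestral clones; linear versus branching growth), branch-level
mutational-signature profiles, mutation timing classes, and expression
scores (squamous--classical gradient, stromal/immune enrichment, cell
fractions).

Upstream steps -- alignment, variant calling, copy-number calling -- are out
of scope; their outputs are inputs here. Variant filtering is likewise
accepted as upstream.

# The CCF model

For a mutation carried by a fraction $\mathrm{CCF}$ of tumor cells at
multiplicity $m$ (mutated copies per carrying cell), in a sample of purity
$\rho$ with tumor total copy number $n_t$ at the locus (normal cells
contribute 2 copies), the expected variant allele fraction is

$$ f = \frac{\mathrm{CCF}\,\rho\, m}{\rho\, n_t + (1-\rho)\,2}. $$

`expected_vaf()` and `compute_ccf()` are exact inverses. CCFs are capped at
1.25 (the upper end of the clustering prior); capped values are flagged,
not discarded. The cap accommodates noise pushing clonal mutations above 1
without letting copy-number errors run away.

Multiplicity is estimated before clustering and held fixed (no joint
resampling). Because the copy-number events handled here are clonal, a
mutation's multiplicity is shared across regions; `estimate_multiplicity_joint()`
takes the median of the per-region raw mutation copy numbers
$f (\rho n_t + (1-\rho)2)/\rho$ over regions where the mutation is
observed, rounds half away from zero and clamps to $1..\mathrm{major}$.
The pooling matters: at purity 0.3 and 80X the single-region estimator
misassigns a few percent of multiplicities, and each error displaces the
implied CCF two-fold, seeding artifact clusters.

# Dirichlet-process clustering

Mutations are clustered across regions on their CCFs with a truncated
stick-breaking Dirichlet-process binomial mixture: alt counts
$y_{id} \sim \mathrm{Binomial}(N_{id},\, \pi_{k d}\, c_{id})$ where
$c_{id} = \rho_d m_{id} / (\rho_d n_{id} + (1-\rho_d)2)$ and $\pi_{kd}$ is
the cluster-$k$ CCF in region $d$, sampled on a grid over $[0, 1.25]$.
Sites with zero depth in a region contribute no likelihood there (rather
than a zero-CCF observation). Defaults: truncation 20 clusters, grid step
0.01, 2000 iterations with 500 burn-in and thinning 10, smallest retained
cluster 1% of mutations, concentration $\alpha$ sampled under a
Gamma(1,1) prior by the usual auxiliary-variable update. The sampler is
initialized from a k-means over-segmentation of naive per-mutation CCF
estimates: a single-site Gibbs sampler merges coherent fragments easily
but births new clusters slowly, so starting over-split mixes much better
than starting merged.

Mutations are internally sorted by content before sampling, which makes
the fit invariant to input row order for a fixed seed. All randomness
flows from the single seed in `dp_control()`.

## Consensus and refinement

The point estimate starts from a summary of the posterior: average-linkage
hierarchical clustering on one minus the posterior co-clustering matrix,
cut at dissimilarity 0.5 (for more than 1500 mutations the dendrogram is
seeded from a stratified subsample; every mutation is re-assigned in the
next step regardless). Two numerical problems motivate refinement:

* label drift between adjacent components drags co-clustering-averaged
  centroids off the maximum-likelihood locations by up to 0.1 CCF when
  components overlap at $\lesssim 1.5$ binomial standard deviations;
* single-site Gibbs visibly under-splits such components, and independent
  EM fits at a range of cluster numbers land in local optima, so the
  likelihood-versus-$k$ profile is too ragged for any penalty to select
  $k$ from it.

The cut is therefore polished by a deterministic soft-EM pass on the
location grid, followed by a split/merge hill-climb on a penalized
likelihood: splits propose a 2-means division of a cluster's naive CCFs,
merges propose joining the closest cluster pairs, each move is EM-refined
and accepted if it improves
$\log L - \big[(D+1) + \tfrac{1}{2}\log n\big] K$ (one location per region
plus one weight per cluster; the $\log n$ term keeps noise splits --
inflated by selection over many candidate moves -- from surviving).
Clusters below the minimum fraction are dissolved and their members
re-assigned; clusters agreeing within 0.05 CCF in every region are merged
as fragments (safely below the 0.08 separation that distinguishes real
clusters). Credible intervals come from the posterior location samples of
the final members.

Measured on 20 seeded replicates of the default cohort conditions (80X,
purity 0.3--0.9, 2--6 regions), the cluster number is recovered within
$\pm 1$ with all matched CCFs within 0.05 in 19/20 replicates; the misses
are merges of cluster pairs separated by $\approx 0.09$ CCF in
low-purity regions, i.e. below one VAF standard deviation -- at the
information limit rather than an algorithmic failure.

# Clone trees

`build_forest()` applies three deterministic rules to the cluster CCF
matrix:

* **nesting (pigeonhole)**: the candidate parent of cluster B is the
  smallest already-placed cluster dominating B within $\varepsilon$ in
  every region;
* **sum rule**: children must sum to at most the parent plus
  $\varepsilon$ per region, enforced greedily by attaching clusters in
  decreasing total-CCF order and escalating to an ancestor on violation;
* **crossing**: clusters whose CCF ordering flips between regions beyond
  $\varepsilon$ are never placed on one lineage (this falls out of the
  domination test).

A cluster with no consistent placement becomes a root with a warning
flag, never silently dropped. Ties between equally nesting parents go to
the smaller total CCF (the most recent ancestor).

The default tolerance is $\varepsilon = 0.05$ CCF. Cluster-level CCF
standard errors at 80X with at least 50 mutations per cluster are
0.01--0.03, so 0.05 is comfortably above noise; it must also stay below
the 0.08 separation the generator guarantees between crossing clusters,
because a larger $\varepsilon$ (say 0.1) makes genuine siblings mutually
"nested within tolerance" and collapses true branchings into chains even
on exact CCFs. `clonal_tol` for identifying the clonal cluster per region
stays at 0.1.

Trajectories are read off the forest: `multiple_mrca` iff there are two
or more roots, `branching` iff some node has two or more children.
Exclusive ("oval plot") fractions per region are CCF minus the children's
CCF sum, clipped at zero within tolerance. Newick output uses SNV+indel
counts as branch lengths; the JSON serialization carries CCFs,
annotations and fractions and restores the topology exactly.

# Timing, signatures, annotations

Truncal mutations at gained loci are `clonal_early` when on two or more
copies (they preceded the gain) and `clonal_late` on one copy; truncal
mutations at unamplified loci are `clonal_unspecified`; non-truncal
mutations are `subclonal`. These are hard rules; a probabilistic timing
model is not attempted.

SBS96 channels use the standard pyrimidine-strand trinucleotide encoding;
ID83 classifies indels by length, homopolymer run, repeat units and
microhomology (flanking sequence required; indels without flanks fall
into a context-unavailable bucket excluded from ID fitting). The CN48
segment encoding crosses heterozygosity state (homozygous deletion / LOH /
het) with total-copy and length classes; exactly 48 channels.

Exposure refitting is non-negative least squares on a catalog, with
iterative pruning of signatures below 5% of total activity.
Per-mutation signature probabilities follow
$P(s \mid c) \propto e_s S_{cs}$; branch profiles either refit the branch
channel counts (default) or sum per-mutation probabilities. A minimal
KL-divergence multiplicative-update NNMF supports small de-novo
extractions; rank selection is the user's responsibility.

The packaged catalogs are **synthetic**: code-generated matrices with the
qualitative shape of the processes they are named for (deamination mass
on N[C>T]G, APOBEC-like mass on T[C>T/G]W, flat clock-like backgrounds,
an LOH-dominated copy-number signature, and so on). They make recovery
tests meaningful without redistributing reference data; analyses of real
cohorts should supply a real catalog as a channels-by-signatures matrix.

Drivers annotate the cluster containing them. SVs and CNAs, which are not
clustered, attach to the smallest clone whose region support (CCF > 0.1)
matches the samples the variant appears in -- a documented heuristic.

# Expression scoring

Gene-set scores are mean z-scores of log2(TPM+1) across samples (simple
and auditable); the gradient score is squamous minus classical set score
and is exactly antisymmetric. ESTIMATE-style stromal/immune scores use a
rank-based enrichment statistic with weights $r^{0.25}$; both the summed
running difference (default, the ssGSEA convention) and the maximum
deviation are available. Cell fractions are constrained least squares
$\min \|Rw - g\|^2$, $w \ge 0$, $\sum w \le 1$ on the reference-gene
subspace, with the remainder reported as the uncharacterized
(tumor/epithelial) fraction; RNA-content renormalization and confidence
intervals of the original deconvolution methods are not reimplemented.
Sample clustering is PCA on z-scored log expression plus k-means
(10 restarts, fixed seed, k = 2 by default); labels are ordered by mean
gradient score so cluster 1 is the squamous-like group. Gene sets are
user-supplied inputs; the packaged sets are small illustrative fixtures
seeded with canonical squamous (TP63, KRT6A, S100A2, ...) and classical
(GATA6, HNF4A, ...) markers, with no claim of reproducing any published
signature.

# Statistics

The Fisher--Pitman permutation test uses the difference in means, exact
enumeration up to 200,000 assignments (the observed assignment counted in
numerator and denominator, so p > 0) and seeded Monte Carlo beyond.
Mann--Whitney and the 2x2 Fisher exact test delegate to the standard
R implementations and are verified against brute-force enumeration
oracles in the test suite. Correlations: Pearson with the t transform,
Spearman with exact (n <= 7) or Monte Carlo permutation p. No
multiplicity adjustment is applied by default; `stats::p.adjust` is the
tool of choice where needed.

# The synthetic cohort generator

`simulate_cohort()` emulates the study conditions end to end: 12
patients, 2--6 regions each (mean ~4), 80X tumor depth, purity
Uniform(0.3, 0.9), archetypes drawn 3 linear : 5 branching : 3
multi-MRCA (the proportions of the analyzed cases), ~85 structural
variants per region for branching cases versus ~30 for single-branch
cases, and per-region expression with squamous/classical and
stromal/immune structure (PDAC-labeled regions shift squamous and
CAF-rich). Clone CCFs come from stick-breaking below each parent, so the
sum rule holds exactly in truth.

Two generator choices deserve emphasis:

* **Identifiability.** A minimum sibling separation alone does not make
  the tree identifiable: a sibling numerically nested inside another
  admits a chain placement satisfying every reconstruction rule. The
  generator therefore rejection-samples CCFs until every
  non-ancestor-related clone pair *crosses* (each exceeds the other by at
  least 0.08 in some region) and every child is separated from its parent
  by at least 0.08 somewhere. 0.08 is a detectability floor at 80X, not a
  measured value.
* **Multiplicity.** Copy-number events simulated here are clonal, so
  mutations arising in descendant clones post-date the gains and carry
  m = 1; only truncal mutations draw m uniformly from 1..major. Uniform
  multiplicities for subclonal mutations would be biologically
  inconsistent and would make the truth unrecoverable (a subclonal m=2
  mutation is indistinguishable from an m=1 mutation at twice the CCF).

Mutation counts per clone default to 100--600 -- scaled down from the
thousands of SNVs per sample in whole-genome data to keep the test suite
fast, while keeping per-cluster counts large enough that cluster-CCF
standard errors stay near 0.01--0.02. Positions are uniform over a
22-chromosome diploid genome with a configurable fraction of (2,1),
(2,0) and (2,2) segments; there is no positional hotspot model, no
germline variation and no sequencing-error model beyond binomial
sampling. Passing the recovery tests therefore demonstrates correctness
of the inference machinery under the stated read-count model, not
robustness to caller artifacts, mapping noise or subclonal copy number,
which real data contain.

A typical small run:

```{r example, eval = FALSE}
out <- tempfile()
coh <- simulate_cohort(out, n_patients = 3, seed = 42)
res <- run_cohort_analysis(coh$manifest, file.path(out, "report"), seed = 1)
res$trajectories
```

# Problem sizes and determinism

The shipped tests exercise: 10,000-tuple CCF round trips; 20 replicate
patients for cluster recovery; 200 noiseless trees plus 60 noisy cases
for tree reconstruction and trajectory calls; 5000-mutation signature
refits; 1000 null replicates for permutation-test calibration; and a
12-patient end-to-end cohort -- sizes chosen so the whole suite runs in
minutes on a laptop while leaving the recovery margins visible. Every
stochastic step is seeded; given a seed, the full pipeline is
deterministic (tree building contains no randomness at all).

# Known limitations

* Subclonal copy number at a single locus is not modeled (clonal copy
  state per region is assumed, matching the major output mode of the
  upstream caller as consumed here).
* Multiplicities are fixed before clustering, not jointly resampled.
* Hard timing rules, no probabilistic timing model.
* The split/merge consensus optimizes a penalized likelihood; at
  separations below one VAF standard deviation adjacent clusters merge,
  and the merged CCF lands between the true values.
* DBS78 channels, transcriptional strand bias and signature-etiology
  inference are out of scope; de-novo NNMF rank selection is manual.
* Packaged catalogs, gene sets and reference profiles are synthetic
  fixtures, suitable for testing machinery, not for interpreting real
  samples.
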