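---
title: "Immune gene signatures and dual-centroid subtyping: models and methods"
author: "immunosig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Immune gene signatures and dual-centroid subtyping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunosig)
```

# Scope and data model

`immunosig` analyses bulk RNA-seq expression of tumour cohorts that are
partitioned into four molecular clusters (I–IV) and asks which immune
genes distinguish the clusters, how a signature built from those genes
transfers to new cohorts, and which annotation categories the signature
over-represents. The central container is `ImmuneCohort`, a
`SummarizedExperiment` subclass with a tracked expression scale
(`raw`, `log2`, `zscore`), optional per-sample cluster labels and
optional per-gene truth flags. The input convention is RSEM-style
upper-quartile-normalized expression; the package performs no
library-size normalization of its own and works on
`log2(x + pseudocount)` values throughout (pseudocount 1 by default,
the standard choice for matrices containing exact zeros).

# Gene panels

The registry combines four panels: the packaged 722-gene pan-cancer
immune profiling panel (shipped verbatim as a plain-text fixture) and
three panels of the interferon-α (97 genes), interferon-γ (200 genes)
and T-cell cytotoxicity (115 genes) pathways. The three pathway panels
shipped with the package are *synthetic stand-ins* of the stated sizes
(their filenames carry a `_synthetic` tag): the true pathway lists live
in an external database, and their exact overlap with the 722-gene
panel is not published. The stand-ins mix real symbols drawn from the
722-gene panel (including the key IFN-γ response genes CXCL9, CXCL10,
CXCL11 and their receptor CXCR3) with clearly marked `SYN*`
placeholders, with overlaps arranged so that the combined unique set
has exactly 924 genes — one consistent realisation of the published
panel arithmetic (722 + 97 + 200 + 115 = 1134 entries, 210 overlap
occurrences). Users with the real lists substitute them via
`loadPanel()` + `panelRegistry()`.

Symbols are compared case-insensitively after trimming and stored
upper-case; duplicates are collapsed and counted, and no alias
resolution is attempted — unmatched symbols are reported, never
silently mapped.

# One-vs-rest ranking ensemble

For each panel and each cluster, genes are ranked on their ability to
discriminate the cluster's samples from all remaining samples. The
ensemble combines five discriminators chosen to span parametric,
rank-based and information-theoretic families:

1. absolute Welch two-sample *t* statistic,
2. the rank-sum statistic expressed as $|\mathrm{AUC} - 0.5|$,
3. the signal-to-noise ratio $|\mu_1 - \mu_0| / (\sigma_1 + \sigma_0)$,
4. the absolute difference of group means (log2 fold change of means),
5. the mutual information between the one-vs-rest label and expression
   binarized at the pooled median.

Each ranker orders the genes (midranks for ties); the aggregate rank is
the mean of the five per-ranker ranks, with residual ties broken
lexicographically by symbol, so aggregate ranks are always 1..m with no
gaps and the whole procedure is deterministic — no seed enters the
ranking stage. All five scores are shift-tolerant, so adding a constant
to a gene across all samples changes nothing, and scores are computed
on the log2 scale, never on z-scored values. A gene that is constant
across all samples scores worst in every ranker; a gene with zero
within-group variance but distinct means is a perfect separator.

Signatures take the top $\lceil q \cdot m \rceil$ genes of each table
and merge them by set union: $q = 0.20$ within each panel and
$q = 0.05$ over the combined panel. The ceiling is inclusive by design;
published signature sizes cannot disambiguate the rounding convention,
and the monotonicity property ($q_1 \le q_2$ implies nested signatures)
holds either way.

# Dual-centroid classification

Training computes, per cluster, the arithmetic mean expression vector
of the cluster's samples (*main* centroid) and of all samples outside
the cluster (*alternative* centroid), restricted to the signature genes
— eight vectors in total. A sample $s$ is assigned to
$c^* = \arg\min_c d(s, \mathrm{main}_c)$ (Euclidean) **only if**
$d(s, \mathrm{main}_{c^*}) < d(s, \mathrm{alt}_{c^*})$ strictly;
otherwise it is `UNCLASSIFIED`. The alternative centroid acts as a
one-class gate: a sample that is no closer to its best cluster than to
"everything else" carries no usable subtype signal. Consequently the
assigned-label set is always a subset of a plain nearest-centroid
assignment — each sample either agrees or abstains.

Numerical choices: a tie among main-centroid minima yields
`UNCLASSIFIED` with a warning (measure-zero for continuous data);
distances are computed on unstandardized log2 values, matching
centroids defined as mean expression, with an optional per-gene
z-scoring flag whose training statistics are frozen into the model
(off by default); signature genes missing from a prediction cohort are
dropped from the model symmetrically for that cohort, with a stronger
warning above 10% missing.

# Hierarchical clustering

Unsupervised validation clusters samples with Euclidean distance on
row-z-scored log2 signature expression under average linkage — the most
common heatmap convention; no metric or linkage is canonical for this
analysis, so both are recorded in the result object and overridable.
Row z-scoring uses the sample (n − 1) standard deviation; the choice
affects display and distances by a constant factor only. Merge ties
follow `hclust`'s deterministic lowest-index convention, so trees
depend only on the input order, and cutting to k groups never changes
partition content under sample reordering (leaf order may differ).
Agreement with known labels is scored by the adjusted Rand index.

# Binomial over/under-representation

For an analysed list of $n$ genes scored against a catalog whose
categories contain $K$ of $N$ reference genes, the expected count is
$E = nK/N$ (kept unrounded internally), the fold enrichment $k/E$, and
the direction "+" iff $k \ge E$ (the $k = E$ boundary is reported "+"
with FE 1.0). The p-value is the one-sided binomial tail
$P(X \ge k)$ for over- and $P(X \le k)$ for under-representation with
$X \sim \mathrm{Binomial}(n, K/N)$, evaluated via `pbinom` (log-space
internally, so tails near $10^{-40}$ are exact), then multiplied by the
Bonferroni count $B$ and capped at 1. $B$ defaults to the number of
categories tested and is overridable, because published runs use the
database's tested-category count (158) rather than the list size.
Annotation databases may map one symbol to several reference entries,
so $n$ is accepted directly as an input (e.g. 377 unique symbols
mapping to 385 entries); when the catalog carries an explicit reference
universe, $n$ is computed as the mapped-gene count and unmapped genes
are reported. Reports print $E$ and FE to 2 decimals and p to 3
significant figures in scientific notation; machine output keeps full
precision. A hypergeometric tail agrees with the binomial within an
order of magnitude on typical instances — a sanity check, not an
equality, since sampling without replacement is a different model.

# Synthetic cohorts

`generateCohort()` emulates the structure the analysis assumes: four
clusters whose "responsive" genes carry a monotone mean gradient from
cluster I to cluster IV on the log2 scale, on a background of
uninformative genes. Defaults mirror the discovery-cohort scale:
cluster sizes (30, 30, 31, 31) (n = 122), the 924-gene combined panel
plus 2000 background genes, gradient (0, 1, 2, 3) log2 units, noise sd
0.5, half the panel responsive, baselines N(6, 2²) on the log2 scale.
The gradient step and noise sd are package choices — no effect-size
estimates are published for the real cohorts — picked as a clearly
separable but noisy regime (adjacent clusters differ by 2 noise sds per
responsive gene).

Three structural decisions matter for how the generator is used:

* **Noise model.** Additive Gaussian on the log2 scale (equivalently
  log-normal on the raw scale), because every downstream statistic
  operates on log2 values. Count-level (negative binomial) noise, tumour
  purity and batch effects are deliberately out of scope. The final
  matrix is floored at 0 so the raw-scale export $2^x - 1$ is a valid
  non-negative expression matrix that round-trips exactly through
  $\log_2(x + 1)$.
* **What is gene-determined vs seed-determined.** The responsive subset
  (first `responsiveFraction` of the sorted panel) and the per-gene
  baseline levels (a dedicated fixed RNG stream) are deterministic
  functions of the gene list. Cohorts generated with different seeds
  therefore represent *new samples of the same genes* — the covariance
  structure a discovery/validation pair requires. During development,
  versions of the generator that redrew either quantity per seed broke
  cross-cohort classification in exactly the way real cross-platform
  transfer fails, which is not the regime this generator emulates.
* **Permutation invariance.** Cluster blocks are generated in a
  canonical order (sorted by gradient, then size), so jointly permuting
  `(clusterSizes, gradient)` yields the same cohort up to relabeling.
  For this reason a non-monotone gradient is accepted with a warning
  rather than rejected.

`generateMarkerCohort()` is a companion generator for per-cluster
marker structure (each cluster's markers elevated in that cluster
only), under which one-vs-rest ranking has an exact per-cluster truth —
the construction used to measure signature recovery.
`generateAnnotation()` builds catalogs with one category planted to
overlap a gene list exactly `overlapSize` times (its filler avoids the
list, so the observed count is exact) and all others at chance.

Passing tests on these cohorts demonstrate correctness of the
*procedure* under its stated assumptions — they do not certify
performance on real tumours, where cluster separations are weaker,
noise is heteroskedastic and gene-gene correlation is substantial.

# Validation experiments and problem sizes

The test suite runs three replicated experiments at the study scale,
averaged over 20 replicate cohorts each: (1) signature + centroids
trained on a (30, 30, 31, 31) discovery cohort assign an independent
225-sample validation cohort with mean accuracy ≥ 0.90 and
unclassified rate ≤ 0.10; (2) with 40 planted per-cluster markers and
q chosen to take 10 genes per table, the merged signature recovers
≥ 90% of markers; (3) cutting the sample dendrogram at k = 4 attains
mean adjusted Rand index ≥ 0.9 against truth. Exact oracles back the
numerics: binomial tails equal exhaustive pmf summation for all
n ≤ 12, and the assignment rule matches a brute-force enumeration of
all eight distances on random instances. The published pathway table is
reproduced cell by cell from its printed per-category inputs.
`scripts/acceptance.R` re-runs all of this against the installed
package and writes the resulting numbers as JSON.

# Pipeline orchestration

`runPipeline()` chains the stages file-to-file from a single validated
configuration (`pipelineConfig()`): preprocess → ranking grid (16 + 4
tables) → two signatures (per-panel q = 0.20, combined q = 0.05) →
centroid fit on cohort 1 → assignment of cohort 2 → hierarchical
clustering of both cohorts → over-representation of both signatures.
Each stage is wrapped so failures name the stage; the manifest records
package version, parameters, input and output MD5 checksums, and the
seed, making reruns verifiable byte for byte. Each stage is equally
usable as a plain function call on in-memory objects, which is the
intended interactive interface.

# Known limitations

* The five-ranker ensemble is this package's own documented
  construction; the original feature-selection ensemble behind the
  published gene lists is unpublished, so exact published signature
  gene lists (377/44/91/62 and 157) are out of reach by design — the
  package reproduces the *procedure* and its printed downstream
  statistics, not those lists.
* The packaged IFN/cytotoxic panels are synthetic stand-ins (above).
* Whether genes should be standardized before centroid distances is
  unstated in the source analysis; the default here is unstandardized,
  with z-scoring as a frozen-statistics option.
* The enrichment module implements the binomial test with Bonferroni
  correction only — no GO-graph propagation, no FDR alternatives — and
  treats the annotation catalog as given.
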