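---
title: "Methods: key gene-module discovery for phenotype gene sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: key gene-module discovery for phenotype gene sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis

`abkey` implements an integrative case-control transcriptomics analysis that
narrows a broad phenotype gene set — prototypically the mouse "abnormal
behavior" (AB) set used as a candidate pool for schizophrenia risk genes —
to *key* gene modules, separately per brain region and per type of genetic
evidence. The chain is:

1. **Expression filter.** Keep genes whose mean normalized expression
   (RPKM-like scale) is strictly greater than 0.1; these are the
   "brain-expressed" genes and the universe for every downstream test.
2. **Differential expression.** A negative-binomial Wald test between cases
   and controls on counts; DEGs are genes with BH-adjusted p < 0.05 and fold
   change > 1.2 in either direction.
3. **Overlap tests.** Upper-tail hypergeometric tests of the AB set against
   the DEG, CNV and DNM sets, Bonferroni-adjusted.
4. **Co-expression network.** A WGCNA-style unsigned weighted network on the
   AB-restricted expression matrix: soft-thresholded adjacency
   $a_{ij} = |\mathrm{cor}(x_i, x_j)|^\beta$, topological overlap
   $\mathrm{TOM}_{ij} = (\ell_{ij} + a_{ij}) / (\min(k_i,k_j) + 1 - a_{ij})$
   with $\ell_{ij} = \sum_u a_{iu} a_{uj}$, average-linkage clustering of
   $1 - \mathrm{TOM}$, a static cut, and merging of modules whose eigengenes
   correlate above 0.75.
5. **Key-module selection.** For each target set (DEG∩AB and MUT∩AB, where
   MUT = CNV ∪ DNM), a per-module 2×2 odds ratio over the network gene
   universe with a 1-df chi-square test; the enriched module (OR > 1) with
   the highest OR among those with p < 0.01 is the key module, and *all* its
   genes form the key set (kDEG or kMUT per region).
6. **Characterization.** Over-representation of each key set in a user
   supplied gene-set collection (hypergeometric + BH, p ≤ 0.01 and q ≤
   0.05); expression-weighted specificity bootstrap across cell types or
   developmental periods; and a degree bootstrap against the brain-expressed
   PPI background.

# Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `rpkm_threshold` | 0.1 | strict mean-expression filter (RPKM-like units) |
| `p_adj_threshold`, `fc_threshold` | 0.05, 1.2 | DEG calling (BH-adjusted p; linear fold change) |
| `target_r2` | 0.9 | scale-free fit needed when choosing the soft power |
| `min_module_size` | 30 genes | smallest retained module |
| `cut_height` | 0.99 | static dendrogram cut on the TOM-dissimilarity scale |
| `merge_height` | 0.25 | eigengene dissimilarity below which modules merge |
| `module_p` | 0.01 | chi-square threshold for key-module selection |
| `n_boot` | 10,000 | resamples for both bootstrap tests |

The fold-change threshold is interpreted on the *linear* scale (1.2 means
$|\log_2 \mathrm{FC}| > \log_2 1.2 \approx 0.263$); `fc_scale = "log2"` gives the
alternative reading, and `direction` restricts calling to one direction.

# Differential expression model

Counts are modelled as negative binomial with variance
$\mu + \alpha \mu^2$. Size factors are median-of-ratios (per sample, the
median over all-nonzero genes of the count over the gene's geometric mean),
rescaled to geometric mean 1. Dispersion is method-of-moments from the
pooled within-group variance of normalized counts, floored at $10^{-8}$,
with no shrinkage: the package's acceptance surface is calibration and
recovery on synthetic data, not concordance with any particular published
implementation. The Wald statistic compares log fitted group means with the
delta-method standard error; a 0.5 pseudocount on raw group sums enters only
when a fitted group mean is zero. Covariate adjustment (age, batch, RIN) is
out of scope; the only metadata use is the age > 18 sample filter.

# Numerical and design choices

**Static cut height, not a height quantile.** Modules are cut from the
average-linkage dendrogram at the absolute dissimilarity 0.99 (the classic
static tree cut). A quantile-of-merge-heights rule was evaluated and
rejected: the top percentiles of merge heights are background
consolidation, whose heights interleave with the module-background joins,
so any high quantile absorbs true modules into the background. The full
dynamic hybrid tree cut is deliberately not reimplemented; the static cut
is deterministic and sufficient for planted-block recovery.

**Soft-power selection with a connectivity floor.** The smallest power
with scale-free $R^2 \ge 0.9$ and negative slope is chosen, but powers
whose mean connectivity falls below 1 are ineligible: past that point the
network is effectively edgeless and the scale-free statistic rewards
degeneracy rather than topology (the standard guidance to keep mean
connectivity reasonably high). If no eligible power reaches the target, the
best-fitting eligible power is used with a warning. Connectivities are
binned into 10 equal-width bins and $\log_{10}$ frequency is regressed on
$\log_{10}$ mean bin connectivity; empty bins are dropped.

**Unsigned network, Pearson correlation.** The unsigned transform
$|r|^\beta$ is the cited methodology's default; biweight midcorrelation and
signed networks are not implemented. Everything runs single-block — the
AB-restricted matrices (hundreds to a few thousand genes) fit comfortably
in memory.

**Key-module selection.** The 2×2 table is formed over all network genes
(assigned plus unassigned), since the network itself is already restricted
to expressed AB genes. The odds ratio uses a Haldane–Anscombe 0.5 on every
cell only when some cell is zero (and the output records when it did); the
chi-square is computed on the uncorrected table without continuity
correction (`yates = TRUE` is available). Selection considers only enriched
modules (OR > 1): the chi-square is two-sided, and a strongly *depleted*
module would otherwise qualify. Ties go to the smaller p, then label order.

**Two p-value conventions, on purpose.** The specificity bootstrap uses the
permutation-test pseudocount $(\#\{ \bar s^{(b)} \ge \bar s \} + 1)/(B+1)$,
which never returns 0. The PPI degree bootstrap instead uses the raw
fraction $\#\{ \bar d^{(b)} \ge \bar d \}/B$ with ties counted toward
"larger", because that is the convention under which 38 exceedances in
10,000 resamples print exactly p = 0.0038; its two-tailed p is
$2\min(p_\text{larger}, p_\text{smaller})$ capped at 1. Each result carries
its convention in an attribute. Both tests sample gene sets of matched size
without replacement, sort genes internally (input order cannot change
results), and are exactly reproducible from their seed.

**MUT definition.** CNV and DNM sets are tested separately against AB, but
key-module selection uses the single target MUT = (CNV ∪ DNM) ∩ AB — the
only reading that yields one mutation target per region.

**Seeds.** `run_pipeline()` derives stage seeds from the config seed with
fixed offsets (specificity tests: seed + 101 + stage index; degree tests:
seed + 201 + stage index), so each stochastic stage is independently
reproducible and deterministic stages are seed-free.

# What the synthetic data emulates

The generator produces every input the pipeline consumes, with planted
ground truth:

* **Counts**: negative binomial (shared dispersion α = 0.05, variance
  $\mu + \alpha\mu^2$) with log-means
  $b_g + \lambda f_{m(g)}(s) + \pm\log(\mathrm{FC}) \cdot \text{case}(s)$. One
  standard-normal latent factor per module per sample with shared loading
  λ = 1 gives within-module correlations around 0.9 on log counts. Baselines
  are log-uniform on $[1.5, 5.5]$ (natural log), i.e. means of roughly 4 to
  250 counts. Defaults: 1000 genes, 5 modules of 30, 60 cases / 60 controls.
* **Planted DE** is bidirectional: each DE gene (background rate 0.1) is up-
  or down-regulated in cases with equal probability at fold change 4. A
  one-directional burden of strong DE would bias the median-of-ratios
  reference itself (about −0.13 log2 on every null gene at these defaults),
  which is a property of unbalanced data, not of the test. DE genes planted
  inside the designated disease module (via `de_enrichment`) share one
  direction, since a co-regulated module responds coherently; the default
  `de_enrichment = 1` spreads DE uniformly.
* **Annotation sets**: AB membership is Bernoulli with odds multiplied by 8
  inside planted modules (base rate 0.3, echoing a broad phenotype set
  covering a third of the genome at this scale); CNV/DNM are weighted
  samples of 150 genes each favouring the designated mutation module and AB
  members.
* **PPI**: Barabási–Albert preferential attachment with 2 edges per node;
  the 20 earliest-attached nodes are the planted hub set.
* **Profiles**: near-uniform group means with ±15% noise; planted specific
  genes carry 85% of their row mass in one group.

The `n_boot` default of 10,000 matches the degree test's published usage;
the uniform-profile noise level was set so that a non-specific gene's
maximum row specificity stays below 0.25 at 10 groups.

What it does **not** emulate: library-preparation artifacts (GC content,
batch, 3' bias), realistic gene-length distributions (the RPKM-like scale
uses a fixed 1 kb pseudo-length — the filter only needs a scale), eQTL
structure, ortholog mapping, cell-type taxonomies, or overlapping/nested
modules. Passing tests therefore demonstrate recoverability and calibration
under a clean generative model, not performance on real tissue data.

# Verification strategy and problem sizes

The test suite checks each stage against an independent oracle: exhaustive
enumeration for the hypergeometric test (every universe up to N = 12),
closed-form hand calculations for TOM, odds ratios and BH, the reference
chi-square implementation, planted truth for recovery (adjusted Rand index
≥ 0.8 over 5 seeds at the default 1000-gene study; DEG recall ≥ 90% with
realized FDP ≤ 0.10), and uniformity of null bootstrap p-values
(Kolmogorov–Smirnov at α = 0.01 over 200 null targets at 1000 resamples).
Type-I calibration of the DE test is measured on independent null genes
(no planted modules): correlated blocks share latent-factor imbalances, so
block-correlated p-values inflate the *variance* of the realized rejection
fraction without biasing its mean — a data property, not miscalibration.

The end-to-end demonstration study uses two regions with 5 modules of 60
genes and a coherently diagnosis-responsive disease module
(`de_enrichment = 50`): networks there are built on AB genes only, so a
module survives the restriction with ≥ 30 members only when most of its
genes carry the annotation, and a half-responsive module would split into
sub-threshold fragments.

# Known limitations

* The static cut cannot separate nested or partially overlapping modules;
  the dynamic hybrid algorithm would.
* Method-of-moments dispersion without shrinkage loses power at very small
  sample sizes (the intended scale is dozens of samples per group).
* BH-adjusted p stands in for the q-value in the over-representation
  cutoffs; π₀ estimation is out of scope.
* The degree bootstrap's raw-fraction p can be exactly 0; the specificity
  test's pseudocount p cannot — comparisons across the two tests should use
  ranks, not raw values.
* Gene identity is exact string match; any ortholog or identifier mapping
  must happen upstream.
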