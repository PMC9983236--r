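---
title: "Methods: co-occurrence networks, ligand-receptor permutation tests, and planted-truth validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-occurrence networks, ligand-receptor permutation tests, and planted-truth validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models behind TMEcrosstalk, the
parameters that matter, the design choices made where the procedure was
genuinely open, and what the synthetic-data validation does and does not
demonstrate about real data.

# The co-occurrence model

The central object is a network over annotated cell types whose edges mean
"these two types tend to infiltrate the same bulk tumors". The inference runs
in five steps for each focal type $i$:

1. **Abundance.** With signature set $S_i$ (markers with expressing fraction
   strictly above 25% and log2 fold change strictly above 0.5 in the
   single-cell data), the abundance of type $i$ in bulk sample $s$ is
   $a_{is} = \mathrm{mean}_{g \in S_i} \log_2(x_{gs}+1)$, on
   median-of-ratios-normalized values. This is a relative score, not a
   deconvolved proportion: it is only used through its correlation across
   samples, so the baseline offset contributed by signature gene abundance
   cancels.
2. **Correlation.** Every gene is Pearson-correlated with $a_{i\cdot}$ over
   samples (both on the $\log_2(x+1)$ scale). At least 3 samples are
   required; zero-variance genes are recorded as undefined and excluded.
3. **Self-exclusion.** Genes the focal type expresses itself — mean
   log-normalized expression $> 1$ *and* expressing fraction $> 0.2$ in its
   own cells — are removed, since they trivially track the type's own
   abundance. Both inequalities are strict, so a mean of exactly 1 does not
   exclude.
4. **Candidate program and enrichment.** The top $k = 20$ remaining genes by
   *signed* correlation form the candidate program. Its per-type mean
   log-normalized expression $e_t$ is z-scored across types using the sample
   standard deviation ($T-1$ denominator). With $T \approx 6\text{–}10$
   types the choice of denominator is material; the sample-sd convention
   makes the 1.28 cutoff correspond to the usual one-sided 90% normal point.
5. **Edges.** A directed hit $i \to j$ ($j \ne i$) requires
   $z_{ij} > 1.28$, strictly. Mutual hits merge into one undirected edge
   weighted by $\max(z_{ij}, z_{ji})$; a one-directional hit still creates
   an edge with its single passing score (`mutualOnly = TRUE` gives the
   stricter reading). Hub types are ranked by degree, then weighted degree,
   then id.

Open choices, and how they were resolved:

* **Signed vs absolute correlation** for the top-$k$ ranking: signed.
  "Highly correlated" is read as positive co-occurrence; negative
  correlations encode exclusion, a different biological statement. The
  `absCorr` flag provides the alternative.
* **Scale of the "average expression > 1" self filter**: the log-normalized
  single-cell scale, the scale on which single-cell means are conventionally
  reported; exposed as `exprMin`.
* **Bulk scale**: all bulk-side computation uses $\log_2(x+1)$ of normalized
  values, the standard choice for correlation work on expression data.
* **One-directional edges**: kept by default. The focal type's own z-row
  includes itself; a genuinely co-occurring partner can absorb enough z-mass
  in one direction only, and the null calibration (below) shows the
  permissive rule does not inflate false edges.

A useful property of the z-transformation emerged in null calibration: when
the candidate program of type $i$ is driven by chance correlations, those
chance-selected genes are precisely the genes whose empirical means are
elevated in type $i$ itself, so the largest z lands on the (excluded)
diagonal and partner types rarely cross 1.28. This is why the identity-mixing
null yields essentially zero false edges despite the z-scores being
scale-free.

# The ligand-receptor permutation test

For an ordered cluster pair (donor $A$, acceptor $B$) and pair (ligand $L$,
receptor $R$), the observed statistic is
$(\bar{L}_A + \bar{R}_B)/2$ on cluster-mean log-normalized expression — the
mean-of-means statistic standard in cluster-level interaction screens. Genes
expressed in fewer than `minExprFrac = 0.10` of a cluster's cells are masked
there, and masked combinations are *skipped*, never scored as zero. The null
permutes cell labels (preserving cluster sizes) and recomputes; the p-value
is the plain proportion of null statistics $\ge$ observed.

* **p-value convention**: $\#\{null \ge obs\}/n_{perm}$ without the +1
  correction, so that exhaustive enumeration reproduces the exact
  permutation p-value bit for bit (`plusOne = TRUE` gives the conservative
  variant). Comparisons use a $10^{-12}$ relative tolerance so the observed
  labelling and exact ties count as $\ge$ despite summation-order rounding.
* **Exhaustive mode**: all distinct assignments of the label multiset are
  enumerated when feasible (capped at $10^5$); the suite verifies equality
  with an independent brute-force enumeration on instances of up to 10
  cells.
* **Display statistic** $\sqrt{\mathrm{mean}(L \times R + 1)}$: reported per
  row for plotting, computed over a resampled cell pairing (each cluster
  resampled with replacement to the larger cluster size, deterministic under
  the run seed) since the full cross product is quadratic in cells. Whether
  such a statistic is evaluated over cells or over cluster means is an
  interpretation choice; the per-cell-pairing default is documented here
  rather than asserted as canonical.
* **Filtering**: significance requires $p < 0.05$ (strict) *and* a secreted
  pair; both rules are exposed. The interaction-strength matrix counts
  significant pairs per ordered cluster pair; its symmetrized sum locates
  the dominant crosstalk axis.
* Multi-subunit receptor complexes are not modeled; the database schema is
  simple pairs.

# Marker detection and signatures

One-vs-rest Wilcoxon rank-sum per cluster (normal approximation with tie
correction, no continuity correction — verified against
`stats::wilcox.test(exact = FALSE, correct = FALSE)`), after pre-filtering by
expressing fraction ($\ge$ 10%) and log2 fold change ($\ge$ 0.5). The fold
change convention is
$\log_2\!\big(\frac{\mathrm{mean}(\mathrm{expm1}(ln_{in}))+1}{\mathrm{mean}(\mathrm{expm1}(ln_{out}))+1}\big)$,
with "expressing" meaning log-normalized value $> 0$. Benjamini–Hochberg
adjustment is applied within each cluster's tested set, matching the
one-vs-rest framing (a global adjustment would couple unrelated contrasts).
Signature admission (25%/0.5) is strictly greater-than on both thresholds.
Clusters with fewer than 3 cells are skipped with a warning.

# QC and normalization

Cells are filtered first (detected genes $< 200$, or mitochondrial count
fraction strictly $> 10\%$, where the mito flag comes from `rowData$mito` or
the `MT-` prefix), then genes detected in fewer than 10 remaining cells are
dropped; the order follows the listing order of the thresholds and the
filter is idempotent. Log-normalization is
$\ln(1 + 10^4 \, c_{gc} / \sum_g c_{gc})$, exactly invariant to per-cell
count rescaling. (Variance-stabilizing regression is deliberately
approximated by log-normalization; which transform feeds downstream scoring
is ambiguous in common toolchains, and log-normalization is used throughout
and stated as such.)

Bulk normalization is self-implemented median-of-ratios: the reference is
the per-gene geometric mean over samples (genes with any zero excluded), and
each sample's factor is the median ratio to the reference — verified in the
suite against DESeq2's implementation to $10^{-10}$.

# Gene-set scoring

* **Module score** (binned-control, after Tirosh et al. 2016): genes are
  binned into `nBins = 24` equal-frequency bins of average expression;
  `nCtrl = 100` controls per set gene are drawn with replacement from the
  matching bin; the score is set mean minus control mean per cell. Additive
  shifts of the matrix cancel exactly; the null is centered at 0.
* **ssGSEA**: genes ranked descending (ties broken by gene id for
  determinism), in-set weights $(N-j+1)^{\alpha}$ with $\alpha = 0.25$,
  score = sum of (weighted in-set ECDF − out-set ECDF) divided by $N$ to
  bound the scale. One property deserves emphasis: the rank weighting gives
  the *null* a deterministic positive offset
  $\tfrac12 - \tfrac1{2+\alpha} \approx 0.056$, independent of $N$ (the
  closed-form integral of the cumulative-weight excess). The score is
  therefore used comparatively — across cells, groups, or after
  `zscoreAcrossGroups()` — never against an absolute zero. At $\alpha = 0$
  the statistic is exactly centered.

ssGSEA can be run per cell or on per-cluster pseudobulk profiles
(`groupBy = "label"`); both are supported since either granularity is
defensible and they answer slightly different questions.

# Survival

Kaplan–Meier estimation and the log-rank test delegate to the survival
package (`survfit`/`survdiff`) behind the package's interface; the test
suite validates the product-limit values against an independent direct
implementation of $\prod (1 - d_i/n_i)$ on 100 random small tables.
Median-split assigns High strictly above the median (ties Low), so "High"
always means strictly elevated. For a ligand-receptor pair the default
stratification score is the mean of the two genes' z-scored
$\log_2(x+1)$ expression ("mean-z"); the wording of such analyses is
ambiguous between a combined score and a joint high/high rule, so
`rule = "both-high"` implements the alternative reading.

# The synthetic-data generator

The generator emulates the structure the pipeline consumes, with planted
truth for every stage:

* **Single cell**: negative-binomial counts, mean profiles per type,
  baseline means lognormal ($\mu = e^{\mathcal{N}(\log 0.5,\, 1)}$),
  dispersion $\phi = 0.4$ shared across genes (variance $\mu + \phi\mu^2$;
  per-gene dispersion fitting adds nothing for method validation). Each
  type's markers have mean multiplied by `markerFold` in that type only;
  `markerFold = 1` is an exact null. The first 5% of genes carry the `MT-`
  prefix so QC is exercised. Markers are drawn from non-mitochondrial genes
  so QC cannot silently remove planted structure.
* **Bulk**: a logistic-normal mixture. A latent Gaussian with the target
  correlation matrix (nearest-PSD repaired by clipping eigenvalues below
  $10^{-8}$; matrices whose smallest eigenvalue is below $-0.1$ are rejected
  as beyond repair) and logit-scale sd 0.7 passes through a softmax; bulk
  expression is the proportion-weighted sum of the *empirical* per-type mean
  profiles times lognormal noise with CV 0.2. Realized simplex correlations
  are attenuated relative to the latent matrix: compositional closure drags
  off-diagonal correlations toward $-1/(T-1)$, and a single planted 0.8
  among six types realizes around 0.55–0.67. This attenuation is intrinsic
  to proportions living on a simplex, not a defect.
* **Ligand-receptor database**: planted pairs take ligand/receptor from the
  marker genes of their donor/acceptor clusters (genuinely up-regulated
  there); decoys use uniformly expressed non-marker genes; exactly
  `round(secretedFrac × lrPairs)` pairs are secreted, planted first.
* **Survival**: exponential event times with log hazard
  $\beta \times$ (standardized mean $\log_2$ expression of the effect
  genes), baseline rate $\log 2 / 20$ (median ~20 time units at score 0),
  independent uniform censoring on $[0, 60]$ (roughly one third censored).

Default problem sizes — 1000 genes, 6 types × 100 cells, 25 markers per type
at fold 4, 200 bulk samples for network work — are desk-scale choices that
keep the full calibration loop (20-seed network recovery and null, 10-seed
permutation testing at 1000 permutations, 200-replicate survival
calibration) comfortable on a laptop while leaving all recovery rates
clearly away from boundary effects.

What the simulations do **not** show: robustness to doublets, ambient RNA,
batch effects, per-gene dispersion structure, annotation errors, or bulk
cohorts whose composition drifts with clinical covariates. Passing the
planted-truth suite demonstrates the statistics are implemented correctly
and calibrated under their own assumptions, not that those assumptions hold
in any particular real dataset.

# Numerical and degenerate-input conventions

* Determinism everywhere: each generator stage derives its stream from the
  config seed (offsets +1, +2, +3), permutation and control-gene sampling
  take explicit seeds, and the RNG state of the caller is always restored.
  Re-running any stage with the same seed reproduces byte-identical files.
* Degenerate enrichment profiles (all types equal) yield all-zero z-scores
  with a flag rather than NaN; constant genes get correlation 0 flagged
  undefined and can never enter a candidate list; all-identical values
  refuse a median split with an informative error.
* QC failure (nothing survives) raises an error carrying the per-rule
  report.
* Ties in ssGSEA ranking are broken by gene id; ties at the median go Low;
  ties between null and observed permutation statistics count as $\ge$.
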