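---
title: "Methods: spatial niche enrichment for rare marker-positive cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial niche enrichment for rare marker-positive cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rareniche)
```

## The problem

Spatial transcriptomics slides often contain a handful of cells positive for
a transcript of interest — here on the order of 13 positives among ~50,000
cells — and the scientific question is whether those rare cells occupy a
distinctive tissue niche: are their neighbourhoods enriched for a particular
cell type relative to what any random set of cells of the same size would
see? With so few positives, parametric assumptions are fragile; `rareniche`
implements a permutation approach whose null distribution is built from the
slide itself, together with the companion analyses such a study typically
pairs with it (marker-restricted co-expression, peak-to-gene logFC
concordance, DEG filtering and overlap significance, and qPCR/3C
quantification utilities).

## The permutation enrichment test

For each marker-positive cell, its $k = 20$ nearest neighbours (exact 2D
Euclidean kNN, self excluded) are found and their cell-type identities
recorded as a composition vector on the probability simplex. The observed
statistic is the mean composition over the $m$ positive cells. The null is
built by drawing $m$ distinct cells uniformly from the *full* slide —
positives included, since the null hypothesis is exactly that the positives
are exchangeable with any subset of the same size — $B = 1000$ times
(configurable), and recording each draw's mean composition. The empirical
p-value per type $t$ is

$$ p_t = \frac{\#\{b : \bar{C}^{\mathrm{null}}_{b,t} \ge \bar{C}^{\mathrm{obs}}_t\}}{B}, $$

with ties counting as extreme; types with $p_t < 0.05$ (strict) are called
enriched. This is one-sided by construction: depletion is visible in the
composition table but is not what the call reports.

Numerical and procedural choices worth knowing:

* **Tie-breaking in kNN.** Equidistant neighbours are ordered by ascending
  cell index. This never matters on continuous coordinates but makes
  results bit-identical across platforms. The exhaustive compiled search
  returns the same index sets as any exact nearest-neighbour structure
  (e.g. a k-d tree) on tie-free input.
* **Self-exclusion.** A cell is not its own neighbour; including it would
  dilute every positive cell's composition by its own type. Positive cells
  *may* appear in other positives' neighbourhoods — excluding them would
  distort the comparison with null draws, which face no such exclusion.
* **Without-replacement resampling.** Each null draw consists of distinct
  cells; a cell appearing twice in one draw has no biological reading. A
  `replace = TRUE` option exists for sensitivity checks.
* **The p = 0 question.** The plain counting estimator can return 0 when
  the observed mean exceeds every null mean. The positively biased
  estimator $(count+1)/(B+1)$ is available via `add_one = TRUE`; it is off
  by default so that the reported p is exactly the counting proportion. The
  suite verifies empirically that the add-one p is stochastically no
  smaller than uniform under the null (valid, slightly conservative).
* **No multiple-testing correction by default.** The enrichment call uses
  the raw per-type p at `alpha`; a Benjamini–Hochberg-adjusted column is
  reported when `adjust = "BH"` but never drives the call.
* **t-test variant.** `enrichment_t_test()` provides a clearly labelled
  alternative: a two-sided one-sample t of the positives' per-cell focal
  fractions against the null grand mean. It uses the closed form so the
  degenerate constant sample is defined ($t = 0$ when centred). With ~13
  bounded fractions the permutation test remains the primary inference; the
  two are reported side by side, and a radius-based neighbourhood
  (`radius_query()`) is likewise provided as an explicitly labelled
  alternative definition of the niche.

## The synthetic slide generator

No public accession is needed to test any stage: `generate_null_slide()`
and `generate_enriched_slide()` emulate the statistical structure the test
assumes, with the study-scale defaults (50,000 cells, six types dominated
by cancer epithelium, 13 positives, $k = 20$) baked into `slide_config()`.
Under the null, coordinates are i.i.d. uniform on a square field, labels
i.i.d. from the type proportions, and positives a uniform random subset.
Under the alternative, focal-type cells form a mixture of `n_clusters`
isotropic Gaussian clusters (centres uniform, `cluster_sd = 30` length
units on a 1,000-unit field — clusters an order of magnitude smaller than
the field, the regime where a niche is local rather than a gradient),
truncated to the field by rejection sampling so edge density stays finite.
Positives are then drawn without replacement with weight
$w_i = 1 + \rho f_i$, where $f_i$ is the focal fraction among cell $i$'s
`k_local` neighbours.

Injecting enrichment through *selection weights on existing cells* — rather
than relocating cells — keeps the marginal spatial and type distributions
identical between null and alternative, so power comparisons isolate the
neighbourhood effect. The realised weights are returned as ground truth.
Two consequences are worth stating. First, $\rho = 0$ reduces exactly to
uniform selection. Second, as $\rho \to \infty$ the constant term vanishes
and selection tends to *f-proportional* sampling: cells with $f_i = 0$ are
never chosen and the positives' expected focal fraction rises to
$E[f^2]/E[f]$, well above the slide mean — but the limit is not argmax
selection, and the property tests assert the former, correct statement.

The generator does not attempt platform artifacts (bead sharing,
segmentation error), label-transfer noise, or realistic transcriptome-wide
expression; a real slide's spatial point process is also unknown, so the
Gaussian-cluster alternative is a stand-in for "the focal type is spatially
organised", not a claim about tissue. Passing tests therefore demonstrate
calibration and power of the *statistic* under a controlled alternative,
not performance on any particular tissue section.

The co-expression generator draws latent bivariate normal pairs with
correlation `r_true`, exponentiates (`scale * exp(z)`), and applies
independent dropout. Observed values are thus on the natural scale; the
correlation analyses expect log-normalized input (as an upstream
single-cell pipeline would supply), and on the log scale the Pearson
estimate equals the latent correlation exactly when dropout is absent —
on the natural scale it would be attenuated by the lognormal's
$(e^r - 1)/(e - 1)$ bias, which is the reason the package leaves the
transform to the caller rather than silently correlating raw values.

## Co-expression, concordance, overlap

`correlate()` restricts to cells with marker expression strictly greater
than zero ("detectable"), optionally also dropping zero-target cells as a
secondary analysis, then reports Pearson and/or Spearman $r$ with the
two-sided p from $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ df (Spearman on
average ranks, same approximation). Published conventions differ on which
coefficient is headline, so `method = "both"` reports the two side by side
rather than guessing. At least 3 cells must survive the restriction.

`assign_nearest_peak()` assigns each gene the nearest peak whose edge
distance from the TSS is at most 5,000 bp, *inclusive* ("within 5 kb");
distance is 0 inside the 0-based half-open interval, else bases to the
nearer edge (midpoint distance is a labelled option). Equidistant flanking
peaks go to the smaller start — the convention is arbitrary but
deterministic. The minus-strand TSS of a BED6 interval is `end - 1`, the
genome-browser convention. `concordance()` then correlates peak and gene
logFC over assigned pairs.

`filter_degs()` applies strict double thresholds (`|logFC| >` cut *and*
stat `<` cut), so a gene sitting exactly on a boundary is excluded.
`overlap_test()` is the hypergeometric upper tail
$P(X \ge k)$ — the one-sided Fisher exact equivalent — evaluated in log
space so tails far beyond double precision of individual terms remain
accurate. The universe size is a *required* argument: overlap significance
is undefined without it, and no default is silently assumed.

## qPCR and 3C utilities

`delta_cq()` is $2^{-(Cq_\mathrm{target} - Cq_\mathrm{ref})}$ with
amplification efficiency fixed at 2 (the delta-Cq convention;
efficiency-corrected variants are out of scope). `normalize_3c()` composes
the BAC-library PCR-efficiency ratio with the between-sample
reference-locus ratio; both steps are pure ratios, so their order is
irrelevant and the function documents a single composition.

## Problem sizes used by the test suite

The statistical property checks run at: 300 null slides of 5,000 cells /
5 types / 13 positives / $k=20$ / $B=500$ for calibration (per-type
rejection in $[0.02, 0.08]$, a ~2.4-sigma binomial band around the
effective level $25/501$); 100 slides per $\rho \in \{0, 2, 5, 20\}$ for
power and monotonicity; 50 slides of 1,000 cells against the full-sort kNN
oracle; 200 replicates of $n = 2000$ cells for correlation recovery; and
exhaustive enumeration for every overlap configuration with universe
$\le 12$. Slides of 5,000 cells preserve the rare-positive regime
($m/n \approx$ the study's $13/50{,}000$ in spirit while keeping 13
positives exactly) at a size where hundreds of replicates are routine on a
laptop.

## Known limitations

* The niche statistic conditions on the slide's cell-type map; label
  transfer or segmentation errors upstream propagate directly.
* The test is one-sided (enrichment); depletion calls would need the
  mirrored tail.
* Empirical p-values are granular at $1/B$; with $B = 1000$ the smallest
  reportable nonzero p is 0.001.
* The 2D Euclidean metric assumes planar sections; no 3D or graph-based
  distances.
* Reported headline correlations of the motivating study (e.g. marker–ISG
  Spearman r of ~0.65) depend on deposited tumour data and are outside
  what synthetic fixtures can or should reproduce.
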