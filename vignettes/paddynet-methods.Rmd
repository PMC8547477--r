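---
title: "Models and methods behind paddynet"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Models and methods behind paddynet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

paddynet implements a complete analysis pipeline for continental-scale
paddy-soil microbiome surveys: from an OTU count table, sample metadata and
a phylogeny to diversity profiles, compositional co-occurrence networks,
edge-specificity tests, keystone statistics, null-model quantification of
community assembly, and the comparison of biotic versus environmental
predictability of taxon abundances. This vignette explains the models the
package implements, the tunable parameters that matter, the numerical
choices made where the design was genuinely open, and what the synthetic
data generator does and does not emulate.

## The data model

The canonical community object is an integer matrix of read counts with
samples as rows and OTUs as columns (`otu_table()`), the community-matrix
convention of **vegan**. Relative abundances p_ia = x_ia / sum_a x_ia are
derived on demand; nothing downstream ever sees negative or fractional
counts. Sample metadata carries two design factors — soil type
(paddy/nonpaddy) and region — plus numeric environmental variables, each
assigned to exactly one of three groups (edaphic, geographic, climatic)
through an explicit map, because the variation-partitioning step needs
that grouping to be exhaustive and unambiguous. Trees are **ape** `phylo`
objects, rooted, with branch lengths in substitutions per site.

Every stochastic stage takes an explicit integer seed. A pipeline-level
seed is stretched into per-stage seeds by hashing the stage name
(`derive_seed()`), so inserting or reordering stages never silently shifts
another stage's random stream, and all results are bit-reproducible.

## SparCC: correlations from compositions

Counts from amplicon sequencing are compositional: only relative
information survives library-size normalization, and naive correlations of
relative abundances are distorted by the closure. SparCC inverts log-ratio
variances instead. Writing t_ab = var(log(f_a/f_b)) for fractions f, the
model t_ab = w2_a + w2_b - 2 rho_ab w_a w_b plus the sparsity assumption
(most pairs uncorrelated) gives a linear system for the basis variances
w2; correlations follow as

    rho_ab = (w2_a + w2_b - t_ab) / (2 w_a w_b),

clipped to [-1, 1]. The strongest-correlated pairs violate the sparsity
assumption most, so up to `n_excl_iter` pairs with |rho| above
`excl_threshold` (default 0.1) are excluded from the system and the basis
variances re-solved. The outer loop repeats the whole estimate over
`n_iter` Dirichlet resamplings of the fractions and reports the
elementwise median.

Two parameters govern how counts become fractions, and they are
deliberately separate:

* `dirichlet_prior` (default 1) is the per-cell prior mass of the
  Dirichlet resampling draw. It cannot meaningfully be made tiny: a zero
  count under a prior `a` has log-fraction variance trigamma(`a`), which
  is about 10^12 at `a` = 1e-6 — the correlations of every OTU with any
  zeros would be erased by that variance. Prior 1 is the resampling
  default of the original algorithm.
* `pseudocount` (default 1e-6) is the mass added when fractions are
  computed deterministically as (x + pseudocount)/sum, the form used with
  `resample = FALSE`. This deterministic form is also the one under which
  the estimator's compositional scale invariance is exact: multiplying one
  sample's counts by any constant (with its pseudocount co-scaled) leaves
  every rho unchanged to machine precision, which the test suite asserts
  at 1e-6.

Bootstrap p-values shuffle each OTU's counts independently across samples
— preserving every marginal abundance distribution while destroying
co-variation — and recompute SparCC per shuffle; two-sided p-values use
the add-one permutation convention, so the smallest attainable p is
1/(n_boot + 1). This floor matters: an adjusted-p cutoff of 0.001 is only
reachable when the bootstrap is large enough to resolve p-values well
below it, which is why the desk-scale analysis drivers pair a 199-draw
bootstrap with a proportionally looser cutoff while the function defaults
keep the survey-scale values (999 draws, cutoff 0.001).

Multiplicity is controlled by the two-stage Benjamini–Hochberg procedure:
stage one counts BH rejections at level alpha/(1+alpha) to estimate the
number of true nulls m0, stage two rescales BH-adjusted p-values by m0/m.
The test suite pins this against an independent step-by-step
implementation on random p-vectors.

## The random-matrix-theory threshold

The correlation cutoff for network edges is selected from the eigenvalue
spectrum of the thresholded correlation matrix. Dense correlated noise
produces level repulsion — nearest-neighbour spacings follow the
Wigner–Dyson (GOE) surmise (pi s/2) exp(-pi s^2/4) — while modular signal
isolated by thresholding produces independent spectra whose superposition
follows the Poisson law exp(-s). For each candidate threshold the spectrum
is unfolded through a monotone (Hyman-filtered) cubic spline fit to the
empirical spectral CDF at 10 quantile knots, isolated nodes are dropped,
and the spacing histogram (20 bins over s in [0, 3]) is compared to the
two laws by chi-square distance; the selected threshold is the smallest
candidate whose spacings sit closer to Poisson. Candidates whose
thresholded matrix retains fewer off-diagonal entries than `min_edges`
(default: the matrix dimension) are ruled invalid — a near-empty matrix
has a trivially degenerate spectrum — and a grid with no valid
Poisson-closer candidate is an error, which is the expected outcome on
pure noise.

A caveat worth stating plainly: on block-plus-noise fixtures the
GOE-to-Poisson transition tracks the density of retained *noise* edges,
which for noise of standard deviation sigma dies out near 2.5 sigma. The
transition therefore sits just above the noise scale, not midway between
the noise scale and the block correlation. The unfolding itself is
validated in the suite against pure-GOE, independent-eigenvalue and
superposed spectra.

## Network construction and topology

Network assembly follows a two-scale filter: a fixed-size random subsample
per region (13 by convention) determines which OTUs pass the occupancy
filter (present in at least 9 of the subsampled set), relative abundances
are recomputed on the filtered OTU set, but correlations are computed on
all samples of the soil type. Edges keep pairs with |rho| at or above the
RMT cutoff and TSBH-adjusted p below the cutoff; the node abundance is the
mean over regions of the region-mean relative abundance.

Module detection is Louvain-style greedy optimization of
resolution-scaled modularity Q(gamma) = sum_c [e_c/m - gamma (d_c/2m)^2]
on |rho| edge weights (signs are censused, not partitioned on), best of
`n_restarts`. The conventional resolution 8 is honoured as the default, with a
warning in spirit: module counts are strongly resolution-sensitive, and on
networks far smaller than a full survey's, resolution 8 over-fragments — the
analysis drivers fall back to resolution 1 for module-level summaries when
the top two modules fail to dominate. PageRank uses damping 0.85 (the
canonical value of the underlying web-search algorithm) on the undirected
|rho|-weighted graph; the suite checks it against a dense linear solve.
Keystones are the top-PageRank nodes per module (default 5).

The abiotic–biotic interplay statistics slide a stride-1 window (default
100 nodes) along the abundance- or PageRank-ranked node list and report
the Pearson correlation between PageRank and environmental Pseudo-R²
within each window, plus linear fits for fixed windows with and without
"peripheral" nodes. Peripherality has no canonical definition;
the operational default is the lowest PageRank decile within the window,
exposed as a parameter and flagged in the output.

## Omission scores and edge specificity

The specificity of an edge to a sample group (a soil type or a region) is
quantified by the omission score: the SparCC correlation recomputed with
that group's samples removed. Attenuation relative to the original score
(signed ratio OS/|rho| below 1) indicates the group carried the
co-variation. Significance comes from `n_random` (500) same-size random
omission sets; the p-value is the add-one-smoothed fraction of random
sets at least as attenuating — on the signed scale sign(rho)·OS, so that
"more attenuated" has one meaning for positive and negative edges; an
absolute-value variant is available because the verbal rule is ambiguous
for negative edges. P-values are TSBH-adjusted per group across the edge
family, and an edge is labelled specific when the ratio is below 1 and
the adjusted p below 0.05.

Because SparCC is a whole-matrix estimator, each random omission set is
evaluated once and shared across all edges — 500 sets cost 500
recomputations rather than 500 per edge — drawn deterministically from a
seed-derived stream so results are independent of evaluation order. The
omission recomputations default to 5 outer iterations rather than 20; on
fixtures the mean |delta rho| against the full setting stays below 0.02.

## Assembly processes

Pairwise phylogenetic turnover is the abundance-weighted beta mean
nearest-taxon distance; betaNTI is its z-score against `n_null`
taxa-shuffle permutations of the tip labels (equivalently joint
row/column permutations of the cophenetic matrix), making it invariant to
tree rescaling. RC.bray compares observed Bray–Curtis with null
communities assembled by drawing each sample's observed richness with
selection probability proportional to occurrence frequency and filling to
the observed total proportionally to mean relative abundance, with the
half-tie convention, rescaled to [-1, 1]. The five-process classification
applies the conventional thresholds: betaNTI below -2 homogeneous
selection, above +2 variable selection, otherwise RC.bray above +0.95
dispersal limitation, below -0.95 homogenizing dispersal, else drift.

The normalized stochasticity ratio compares observed pairwise similarity
C (one minus Bray–Curtis or Jaccard) with the null expectation E under
the same assembly null ("pf", fixed richness; a richness-free "pp"
variant exists). The pairwise ratio is E/C when C exceeds E and C/E
otherwise, so 1 means indistinguishable from the null and 0 fully
deterministic; the group value is the mean over within-group pairs with a
bootstrap standard error. Two design points matter. First, the species
pool for the null is the regional pool over all samples, not the group's
own samples — a group of near-identical communities would otherwise
regenerate itself as its own null and read as stochastic. Second, the
index is relative to a null with no overdispersion: data whose latent
abundances fluctuate log-normally (as real communities and the default
generator both do) sit below the null expectation even without any
selection. The directional experiment in the acceptance suite — NST
falling monotonically as planted environmental filtering rises —
therefore runs the generator with reduced idiosyncratic noise
(`latent_sd = 0.5`) so the filter is the leading source of variation;
with the default noise level the baseline starts well below 1 and the
trend is masked rather than reversed.

## Interaction-adjusted beta diversity (TINA)

The TINA family scores community similarity through an inter-taxon
association matrix s_ab rather than shared taxa alone. The default
association is the cosine similarity between rows of the inter-OTU
Spearman correlation matrix of relative abundances; SparCC correlations
are available as an alternative. Weighted TINA similarity between samples
j and k is the s-weighted bilinear form of their abundance profiles
normalized by the geometric mean of the self-association energies, and
the distance is one minus the similarity; unweighted TINA substitutes
normalized presence/absence profiles. With the identity association the
weighted index reduces exactly to cosine similarity, which the suite
asserts at 1e-10; self-similarity is exactly 1. Because associations can
be negative the index is not bounded by 1 and is reported as-is.

## Per-OTU predictability: M_OTU versus M_ENV

For every OTU with occupancy at least 10, two cross-validated ensemble
regressions of its relative abundance are fitted: on all other OTUs'
profiles, and on the environmental variables. Predictor screening inside
each training fold discretizes each predictor by the Fayyad–Irani MDLP
criterion against the quantile-binned (4-class) response and selects at
most 20 predictors by greedy mRMR (mutual information in bits, relevance
minus mean redundancy, index-order tie-breaks); the ensemble — 500 bagged
regression trees via **ranger** — is then fitted on the continuous values
of the selected predictors only. Pseudo-R² is one minus the
cross-validated mean squared error over the response variance. All
selection happens inside folds; the no-leakage property is tested by
checking that pure-noise targets score at or below 0.1. Specifying
leave-one-out as a 99-fold scheme is internally inconsistent for 178
samples, so the default here is plain 5-fold with a leave-one-out option.
The paired Wilcoxon signed-rank test compares the two Pseudo-R² columns
across OTUs, BH-adjusted when occupancy strata are tested separately.

## The synthetic generator and what passing tests mean

`generate_community()` emulates the survey design: 99 paddy and 79
nonpaddy samples split across four rice-growing regions, depths uniform
in [40000, 100000], two mutually antagonistic planted modules (within-
module correlation 0.7, between-module -0.4 by default) on log-normal
latent abundances, region-separated environmental gradients (region means
2 within-region standard deviations apart, so regional signal is
detectable at desk scale), Gaussian taxon response curves to one driver
variable each, a paddy habitat-preference term (moisture is also shifted
up in paddy samples, standing in for flooding), and optional Brownian
evolution of optima and habitat preference along a simulated pure-birth
tree normalized to unit height. Counts are multinomial given the softmax
of the latent log-abundances — exactly the compositional observation
model SparCC inverts. The full ground truth (post-repair planted
correlation matrix, module labels, per-OTU environmental effects, latent
log-abundances) is returned for recovery tests. Correlation targets that
are not positive semidefinite are repaired by eigenvalue clipping and the
*repaired* matrix is recorded as truth.

What the generator does not emulate: read-level error, chimeras, taxonomy
mis-assignment, overdispersion beyond the log-normal latent layer,
group-specific co-occurrence (the planted correlation structure is shared
by both soil types — so the edge-specificity stage correctly finds
nothing specific on default synthetic data and its power is tested on
purpose-built fixtures), spatial autocorrelation within regions, and
rare-taxon dynamics at realistic richness (default 150 OTUs versus tens
of thousands in a real survey). Recovery results on synthetic data
therefore validate the estimators' correctness and calibration, not their
field performance at survey richness.

## Problem sizes and numerical choices

The test and acceptance computations run at desk scale chosen to keep the
whole suite in minutes while leaving each statistical check well-powered:
SparCC recovery at 200 samples x 60 OTUs and depth 40000; bootstrap and
omission nulls at 199–500 draws; betaNTI/RC nulls at 199 permutations;
calibration loops at 1000 replicates; the model comparison at 100 target
OTUs. Degenerate inputs are handled explicitly rather than silently:
constant OTUs are dropped from association matrices with a warning,
negative solved basis variances are clipped with a counter, zero null
standard deviations yield missing betaNTI values with a reason, Pielou
evenness is undefined for single-OTU samples, and zero denominators in
enrichment and module ratios receive a 1e-6 pseudo-fraction and a flag.
Shannon entropy is reported in nats; Chao1 uses the bias-corrected form;
ACE uses the Chao–Lee form with rare cutoff 10; the Chao–Jaccard
estimator omits the unseen-species correction by default (toggleable)
since the naming convention does not pin the variant.

## Known limitations

Louvain partitions are seed-dependent on degenerate landscapes even with
restarts; only the best-Q partition is reported. The RMT threshold's
selection rule is honest about sparse spectra but, as noted above, lands
near the noise scale on block fixtures rather than midway to the signal
scale. The NST implementation follows the pairwise-ratio contract stated
here rather than any one published variant's exact normalization. GraphML
round-trips preserve node and edge attributes but not the provenance
list, which is written separately as JSON by the analysis drivers.
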