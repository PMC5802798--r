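---
title: "Models and methods behind mtstruct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mtstruct}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtstruct)
```

`mtstruct` analyzes the maternal population structure of (ancient) human
groups from mitochondrial DNA: within-population diversity, AMOVA-based
differentiation, haplogroup-frequency multivariate structure, haplotype
networks, and lineage tracing across epochs. This vignette documents the
statistical models, the parameters that matter, the numerical conventions,
and what the synthetic validation does and does not establish.

## Coordinates, haplotypes, and missing data

All positions are 1-based inclusive rCRS nucleotide coordinates (the
16,569-nt revised Cambridge Reference Sequence). A *region* is one or more
non-overlapping intervals; multi-interval regions behave as the
concatenation of their intervals in ascending coordinate order, which is
how joint HVS-II + HVS-I haplotypes are built. Treating the two
hypervariable segments as one concatenated locus (rather than two loci) is
a deliberate choice: haplotype identity is then a single exact string
comparison, which matches how shared-haplotype analyses are done in
practice; the regions are explicit arguments, so a two-locus analysis can
be run as two calls.

Sequences are uppercase strings over `A,C,G,T,N,-`. `N` (uncalled) and `-`
(alignment gap) are both "non-called": any comparison — distances, π,
network weights — excludes, for each pair, the sites not called in both
members (*pairwise deletion*). Pairwise deletion is the robust default for
ancient-DNA data with ragged coverage; complete deletion is available via
`complete_deletion = TRUE` where it matters. For haplotype *identity*
(HD, shared-haplotype analyses) `N` is **not** a wildcard: strings must be
exactly equal, because wildcard matching would silently merge distinct
haplotypes and inflate diversity and sharing estimates. In the lineage
analyses, target haplotypes containing any non-called position are
excluded and reported rather than matched.

## Diversity estimators

Haplotype diversity uses the small-sample-corrected estimator
$\widehat{HD} = \frac{n}{n-1}\bigl(1 - \sum_i p_i^2\bigr)$ over haplotype
class frequencies, with Nei's (1987) sampling variance
$V = \frac{2}{n(n-1)}\Bigl[2(n-2)\bigl(\sum p^3 - (\sum p^2)^2\bigr) +
\sum p^2 - (\sum p^2)^2\Bigr]$; the reported spread is $\sqrt{V}$.

Nucleotide diversity is the mean per-pair per-site difference proportion
$\hat\pi = \binom{n}{2}^{-1} \sum_{i<j} d_{ij}/L_{ij}$, where $L_{ij}$
counts the jointly called sites of the pair. Its uncertainty is Tajima's
(1983) *total* variance (sampling plus evolutionary stochasticity)
$V = \frac{n+1}{3(n-1)}\frac{\hat\pi}{\bar L} +
\frac{2(n^2+n+3)}{9n(n-1)}\hat\pi^2$. These are the estimators the field's
standard tools report, which keeps results comparable across studies.
Whether a study computes HD before or after removing identical
(potentially maternally related) sequences is analysis-dependent, so
deduplication is an explicit, separate step (`deduplicate()`), and the
pipeline exposes both modes.

## Distances and AMOVA

Sequence distances (`seq_distance`, `dist_matrix`) are computed on jointly
called sites in four models: difference counts, p-distance, and
Tamura–Nei (TN93) with optional gamma rate heterogeneity. Substitution-model
*selection* is out of scope: the gamma shape is a user input, and the
default model for haplotypic AMOVA is the plain difference count — the
convention of the standard AMOVA implementations, in which the "squared
Euclidean-like" distance entering the sums of squares *is* the difference
count. For other models the distance is squared.

The AMOVA follows Excoffier–Smouse–Quattro: sums of squares at three
levels (among groups, among populations within groups, within
populations), method-of-moments variance components with the standard
unequal-size coefficients, and
$\Phi_{CT} = \sigma_a^2/\sigma_T^2$,
$\Phi_{SC} = \sigma_b^2/(\sigma_b^2+\sigma_c^2)$,
$\Phi_{ST} = (\sigma_a^2+\sigma_b^2)/\sigma_T^2$ with
$\sigma_T^2 = \sigma_a^2+\sigma_b^2+\sigma_c^2$. A one-group grouping
yields the two-level decomposition (σ²ₐ undefined, Φ_ST only), and the
pairwise population Φ_ST matrix is exactly this two-level model applied
per pair — one shared code path, verified in the tests against an
independent double-loop implementation to 10⁻¹⁰. Negative variance
components are reported as computed (they are the method-of-moments
signature of no differentiation, and published tables print negative Fst);
`truncate_negative = TRUE` clamps them. The additivity that holds by
definition is that of the sums of squares
(SSD_total = SSD_AG + SSD_AP/WG + SSD_WP), which the tests assert; the
component sum σ²_T is the Φ denominator, not SSD_total/(N−1).

### Permutation inference

All permutation p-values use $p = (1 + \#\{\text{perm} \ge
\text{obs}\})/(n_\text{perm}+1)$, so the minimum attainable value is
$1/(n_\text{perm}+1)$ and a p-value is never 0 — where a published table
prints "0.00000", this package prints the attainable floor instead.
Φ_ST permutes individuals among populations, Φ_SC permutes individuals
among populations within their group, and Φ_CT permutes whole populations
among groups — the standard scheme; permuting individuals for Φ_CT is not
offered because it tests a different null. Permutations are sampled with
replacement; when fewer distinct population-level permutations exist than
requested, a warning says so. Benjamini–Hochberg correction is applied
across the strict lower triangle of the pairwise p-value matrix (each
unordered pair once).

### Grouping search

The hierarchical-structure question — *which partition of populations into
groups best explains the variance?* — is answered by evaluating every
candidate grouping and selecting the one that maximizes Φ_CT, breaking
ties (within 10⁻⁹) by minimal Φ_SC. The criterion is resolved
lexicographically (Φ_CT first) because a single optimum must be reported;
the full ranked table and Pareto flags are always returned so users can
re-rank when the two criteria disagree. Candidate lists are the primary
interface (published analyses enumerate hand-chosen combinations);
`enumerate_groupings()` generates all set partitions of the non-fixed
populations around a fixed block as a helper.

## Haplogroup-frequency analyses

Phylotree-style labels are binned by longest-matching prefix with
scheme-defined specificity (`H5a1 → H5`, not `H`; `HV0a → HV0/V` before
`HV`), macro-bins (Asian `A,C,D,F,G,Z`; African `L`) match on the first
letter, and anything unmatched falls to `others`. Three schemes are
shipped: `CEPT23` (Central European transect), `EPT25` (ancient
pan-European; the published bin list names one haplogroup twice, so 24
distinct bins are defined), and `WORLD23` (worldwide, with both
macro-bins). The `others` bin participates in clustering and PCA like any
other bin.

Clustering is Ward's method on Euclidean distances between frequency rows
using the squared-distance (`ward.D2`) update — the published analyses do
not name the Ward variant, and `ward.D2` is the variant for which the
Lance–Williams update is exact on Euclidean distances. Ties merge the
lowest-index pair first (the `hclust` convention), so trees are
deterministic. Bootstrap clade support resamples the *bin columns* of the
count matrix with replacement (the convention of cluster-support tools),
renormalizes, rebuilds the tree, and reports the plain bootstrap
proportion — the percentage of replicates reproducing each observed leaf
set — not the approximately-unbiased variant. Resampling populations
instead is available behind a flag. Replicates that zero out a
population's row (possible with sparse counts) are redrawn.

PCA is the eigen-decomposition of the *covariance* of frequency rows
(column-centered, unscaled): bins share a scale by construction, so
correlation scaling would up-weight rare bins. Explained-variance
fractions sum to 1 and loadings are returned per bin.

Fisher's test on an R×C haplogroup count table uses the exact two-sided
hypergeometric rule for 2×2 tables and a fixed-margins Monte-Carlo
estimate otherwise (`r2dtable` null, $p = (1+\#\{P \le
P_\text{obs}\})/(n_\text{sim}+1)$), with $n_\text{sim} = 10^5$ by default
— the exact network algorithm is deliberately not reimplemented.

## Minimum spanning networks

Identical sequences collapse into haplotype nodes (node label =
lexicographically first member id). The ε = 0 network is the union of all
minimum spanning trees, built by Kruskal's algorithm in equal-weight
batches: within a batch, every edge joining two components of the
pre-batch partition is kept. ε > 0 additionally admits edges within ε of
the weight at which their endpoints' components merged. The default is
ε = 0. Deduplication removes, from each connected component of the
identical-sequence graph, every member but the lexicographically first —
a component rule, so a triple of identical sequences loses two members;
which member a published analysis kept is typically unstated, and the
lexicographic rule is deterministic.

## Lineage tracing

The classical shared-haplotype fraction is the percentage of a target
population's haplotypes found identically in at least one reference
population. Ancestral assignment gives each target haplotype the
*earliest* epoch (ordering `HG < EN < MN < LN/EBA < IA < present`) whose
references contain it, or `novel`. Because published denominators are
ambiguous between distinct haplotypes and individual carriers, both
weightings are computed (`weight = "haplotypes"` is the default;
`"individuals"` weights by carrier counts).

## Sex stratification

Consensus sex gives the genetic assignment precedence over the
anthropological one (disagreements are flagged, genetic wins); individuals
of unknown sex belong to neither subgroup but remain in pooled analyses.
Subgroups are re-run through the diversity, frequency, and distance stages
as pseudo-populations, and the female-vs-male bin-count table (zero-total
bins dropped) is tested with the Monte-Carlo Fisher rule. For the shipped
Kowalewko table this uses consensus sex over the 40 analyzable
individuals (21 F / 15 M); the published subgroup sizes (17/14) refer to
the full-genome subset, whose membership is not derivable from the
assignment table alone, so exact reproduction of the published p-value is
not claimed — only that the sex contrast is significant under the
documented choices.

## The synthetic generator

`simulate_divergence_populations()` is a founder-divergence model, not a
coalescent: the analyses under test need controllable within- and
between-population variance, not genealogical realism. Each truth *group*
founder receives Poisson(d/2) private substitutions from a common root at
positions disjoint across groups, so founders of different groups differ
at Poisson(d) sites in expectation; populations in the same group share a
founder. Within a population, each individual descends from the founder
*or a uniformly chosen earlier member* and adds Poisson(θ_w) private
mutations. The copying chain matters: a pure star (everyone = founder +
private mutations) makes pairwise distances additive (d_ij ≈ k_i + k_j),
which collapses the permutation distribution of Φ_ST to a handful of tied
values; shared within-population polymorphisms restore the statistical
structure the permutation tests assume. Haplogroup labels are drawn from
per-population profiles, sex is Bernoulli, and identical / one-difference
pairs can be planted for duplicate-detection tests. Everything is
deterministic given the seed, and the caller's RNG stream is never
consumed.

Default conditions (3 populations × 20 individuals, 400 nt, d = 8,
θ_w = 1) are the regime of the validation experiments: the 400-nt region
matches the scale of an HVS-I fragment, d = 8 with θ_w = 1 gives clear
but not trivial structure, and n = 20 is a realistic ancient-population
sample size.

What the generator does **not** emulate: transition/transversion bias and
rate heterogeneity (distances are exercised by the TN93±Γ models, but the
generator mutates uniformly), damage-driven miscalls, heteroplasmy,
time-stratified sampling within a population, and realistic haplogroup–
sequence linkage (labels are drawn independently of the sequences).
Passing tests therefore validate the *estimators and algorithms*, not any
claim about real aDNA error processes.

## Validation problem sizes

The test suite validates AMOVA against a definitional double-loop oracle
on 50 random unbalanced datasets (tolerance 10⁻¹⁰); permutation-test
calibration on 200 replicates of exchangeable data (KS uniformity at
α = 0.01, 199 permutations each — the Fst case uses a random label split
of one panmictic sample, the Φ_CT case eight exchangeable populations
under an arbitrary 4+4 grouping); the MSN against exhaustive enumeration
of all minimum spanning trees for graphs of up to 6 nodes;
Benjamini–Hochberg against the step-up oracle on all 720 orderings of six
p-values; and the grouping search by recovery of a generating 3-group
partition over 6 populations in ≥95 of 100 seeded simulations at d = 8,
θ_w = 1, n = 20. These sizes keep the full suite within a few minutes on
one CPU while leaving each check statistically meaningful.

## Known limitations

* No locus-by-locus AMOVA and at most three hierarchy levels.
* No median-joining networks (no inferred median vectors), no
  isolation-by-distance tests, no migration-rate estimation.
* Haplogroup *calling* from sequence is out of scope: the package bins
  given labels.
* The Monte-Carlo Fisher p is an estimate; at the default 10⁵ draws its
  binomial standard error near p = 0.01 is ≈ 3×10⁻⁴.
* TN93 distances error out on saturated pairs (logarithm domain) rather
  than truncating; such pairs are named in the error.
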