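---
title: "Diagnosing hybrid swarms from morphology, markers and geography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing hybrid swarms from morphology, markers and geography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridscan)
```

# The problem

A population of columbines with intermediate floral phenotypes is found
where only one of the candidate parental species occurs. Is it a hybrid
swarm? If so, which species was the maternal parent, and is there evidence
that gene flow between the parents is a general, range-wide phenomenon
rather than a local accident? `hybridscan` treats this as four linked
inference problems — phenotype, nuclear genotype, plastid haplotype and
geography — and ships a simulator whose ground truth exercises every one of
them.

Throughout, the two parental species are just two labels (defaults
`"formosa"` and `"flavescens"`); all methods treat them symmetrically.
Individuals labelled `UNKNOWN` are the queries.

# Morphometric discrimination

`fit_lda()` fits the two-group Fisher discriminant on seven floral traits
(cm). Writing \(S\) for the pooled within-group covariance and
\(\mu_1, \mu_2\) for the group mean vectors, the loadings are

\[ w \propto S^{-1}(\mu_1 - \mu_2), \qquad \lVert w \rVert = 1 , \]

with the sign fixed so the first group's centroid projects above the
second's. Posteriors come from the two Gaussian class densities with shared
covariance \(S\) and, by default, equal priors — appropriate when a query
population's membership should not be prejudged by reference sample sizes.
Rows with a missing trait are excluded from fitting (complete-case) and
skipped, with a warning, in prediction; we deliberately do not impute, as
imputation from group means would leak label information into the
cross-validation below.

`repeated_kfold_cv()` estimates the misclassification rate: each repetition
partitions the labelled specimens into \(k = 5\) random folds, fits on four
and scores the fifth, averaging the per-fold error rates; the reported
error is the mean over repetitions (default 1000). Folds are stratified by
group. Plain random folds at realistic sample sizes (a few dozen specimens
per species) occasionally produce a single-class training fold, where the
discriminant is undefined; stratification removes that failure mode without
materially changing the estimate.

The binary cleft-laminae trait is excluded from the feature set by default
and available via `include_cleft = TRUE` as a 0/1 feature. A point
indicator violates the Gaussian model, but its discriminating value is
real; both behaviours are supported because neither is canonical.

Descriptive statistics follow the conventions of printed floral trait
tables: `trait_summary()` uses \( \bar x \pm 1.96\,\mathrm{SE} \) with
\(z = 1.96\) exactly (not a \(t\) quantile — this is what reproduces
published 2-decimal CI bounds from published means and SEs), and
`proportion_ci()` uses the Wilson score interval, which unlike the Wald
interval behaves correctly near 0 and 1 (a species in which no flower has
cleft laminae gets a CI with a zero lower bound, not a degenerate one).

# Sepal colour

`log_rg()` maps calibrated mean channel values to \(\log(R/G)\). In
additive RGB, yellow is red + green, so the red:green ratio tracks the
yellow-to-red axis a field botanist scores by eye; the log centres the
ratio at zero and makes the two directions symmetric. The logarithm base
(default natural) only rescales the score — orderings, correlations and
group comparisons are base-invariant — so it is an option, not a decision.
`score_correlation()` validates the metric against integer visual scores.

# Microsatellite analyses

Per-locus and per-population summaries use standard estimators: expected
heterozygosity \(H_e = 1 - \sum_k \hat p_k^2\) pooled over all individuals;
within populations, Shannon entropy \(-\sum p \ln p\), observed
heterozygosity, Nei's unbiased gene diversity
\(H_s = \frac{n}{n-1}\bigl(1 - \sum \hat p^2 - H_o/2n\bigr)\), averaged
over loci, and \(F_{IS} = 1 - H_o/H_s\). Whether a pooled or
population-averaged \(H_e\) is wanted at a locus is context-dependent; the
locus table pools, the population table does not, and both are plain data
frames.

`bruvo_distance()` implements the geometric-mutation-model distance for
microsatellites: allele distance \(1 - 2^{-|a-b|/m}\) with \(m\) the motif
length, per-locus genotype distance the minimum over the two one-to-one
allele pairings of the mean allele distance, individual distance the mean
over loci complete in both individuals (pairwise deletion). Fractional
repeat differences are used as-is — observed ladders are not always perfect
multiples of the motif, and rounding would silently discard signal. All
data here are diploid; the genome-addition machinery needed for mixed
ploidy is out of scope.

`pcoa_ordination()` double-centres \(-\tfrac12 d^2\) and eigendecomposes.
Bruvo distances are typically non-Euclidean, so negative eigenvalues are
expected; when any falls below \(-10^{-8}\) the Cailliez additive constant
is applied (Lingoes available). `build_tree()` provides neighbour joining
and UPGMA; NJ's occasional small negative branch lengths can be clamped to
zero (deficit moved to the adjacent edge) behind a flag, off by default so
that additive matrices are reproduced exactly.

`dapc_fit()` performs DAPC for two groups: allele dosages (counts/2 per
locus-allele column), centred, unit-scaled, mean-imputed where missing,
projected onto principal components, and a linear discriminant fitted on
the leading PCs. Retaining too many PCs overfits (reassignment looks
perfect even for random labels), so the retained count maximises the
a-score — observed reassignment proportion minus its mean under random
label permutations (default 100 permutations; the original a-score
literature leaves the count open, and 100 keeps the Monte Carlo error below
the differences that matter). A tiny ridge (\(10^{-6}\) of the mean
diagonal) stabilises the within-group covariance on PCs with zero
within-group variance, which arise under perfect separation.

# Supervised admixture

`fit_supervised()` is a Gibbs sampler for the two-population admixture
model in which allele frequencies are learned **only** from flagged
reference individuals (the POPFLAG convention of supervised STRUCTURE
analyses). Each sweep:

1. draws each species' per-locus frequencies from
   \(\mathrm{Dirichlet}(\lambda + \text{reference allele counts})\);
2. draws an origin indicator for every query allele copy with probability
   \(\propto q_k\, p_k(\text{allele})\);
3. draws each query's \(q\) from
   \(\mathrm{Beta}(\alpha + n_A,\ \alpha + n_B)\).

Because the reference counts never change, the frequency conditionals do
not depend on the query assignments: cluster 1 *is* species A in every
sweep, label switching is impossible, and independent runs can be averaged
directly (`average_runs()`), with the across-run SD reported as a
consistency diagnostic. This replaces the external label-alignment step
(CLUMPP) that unsupervised analyses require.

Choices: the frequency prior is an independent Dirichlet with
\(\lambda = 1\) per allele, which also guarantees nonzero likelihood for
query alleles absent from both reference samples; the correlated-frequency
model used by some STRUCTURE configurations is second-order when
frequencies are reference-only and is left as an extension point.
\(\alpha = 1\) is fixed rather than sampled — with supervision and
\(K = 2\), \(\alpha\) is weakly identified at tens of individuals. Defaults
are desk-scale: burn-in 10 000, 10 000 retained sweeps, 20 runs; at the
simulated scale the estimates are insensitive to an order of magnitude more
of either (across-run SD below 0.01). The prior shrinks each query's
posterior mean toward ½ by roughly \(1/(n_{\text{copies}}+2)\), visible as
a ~0.02–0.05 bias for backcrosses at 11 loci — worth remembering when
reading Q values near the extremes.

`assignment_posteriors()` scores each reference individual leave-one-out
against point-estimate frequencies with equal priors, the quantity usually
displayed for reference bars in ancestry plots.

# Plastid haplotypes

`simple_indel_coding()` turns every maximal gap run with a distinct
(start, end) into one binary character; a sequence whose own gap strictly
contains a character's span is *inapplicable* for it (its state is simply
unobservable), all others score present/absent. `collapse_haplotypes()`
builds signatures from the variable alignment columns that are gap- and
ambiguity-free in every sequence (columns containing N anywhere are
excluded — conservative, since an ambiguity could hide a real difference)
plus the indel characters, and merges identical signatures.

`build_network()` connects haplotypes by mutational steps (each
substitution or indel = 1) and keeps every edge occurring in *some*
minimum spanning tree, so tied alternatives are shown rather than broken
arbitrarily. At the scale where plastid networks are used for maternal-
origin arguments — a handful of haplotypes a few steps apart — this
minimum-spanning construction coincides with a statistical parsimony (TCS)
network; the TCS 95 % connection-probability limit is not computed, but a
hard step limit is available via `connection_limit`. `maternal_origin()`
then classifies each query haplotype by exact signature identity with the
reference species' haplotypes.

# Geographic clines

`range_centroid()` computes the spherical mean: coordinates to radians,
\((\phi, \theta)\) to unit vectors
\((\cos\theta\cos\phi,\ \cos\phi\sin\theta,\ \sin\phi)\), arithmetic mean,
back-projection by \(\mathrm{lat} = \arcsin(z/\lVert v\rVert)\) and
\(\mathrm{lon} = \operatorname{atan2}(y, x)\). The two-argument
arctangent is essential: a plain \(\arctan(y/x)\) is ambiguous for
\(x \le 0\), which includes the whole western hemisphere beyond 90°W.
Antipodally balanced inputs (\(\lVert v\rVert \approx 0\)) have no
meaningful centroid and raise an error. `haversine_km()` uses the haversine
great-circle formula on a 6371-km sphere (the conventional mean radius;
configurable) — consistent with the spherical assumption of the centroid.

`cline_records()` joins discriminant scores to coordinates, computes each
species' centroid from its own specimens, and stores
\(\log(d_{\mathrm{con}}/d_{\mathrm{het}})\) per specimen: positive means
closer to the *other* species' range centre. The stored score is recentred
at the midpoint of the two species' mean scores, because \(|w^\top x|\) is
only a measure of extremity if zero sits on the between-species boundary —
a raw projection carries an arbitrary offset. `clinal_association()`
reports the Pearson correlation (Spearman optional) of \(|\text{score}|\)
with the log ratio, per species and pooled, with the least-squares slope; a
negative value reproduces the clinal-introgression signature. No claim is
made that any particular published analysis used this exact test — the
association has usually been presented graphically — so both statistics are
reported and neither is privileged.

# The simulator

`simulate_dataset()` generates all five input tables plus ground truth
(`true_q`, pedigree class, maternal species). The generative model is
deliberately the same one the estimators assume, making parameter recovery
a clean test:

* **Allele frequencies**: per locus, ancestral frequencies from a flat
  Dirichlet over an allele ladder (base + k·motif), then each species from
  \(\mathrm{Dirichlet}(p_{\mathrm{anc}}(1-F)/F)\) — the Balding–Nichols
  model, the minimal standard way to dial divergence with one knob
  (\(F\), default 0.5; the expected squared frequency difference between
  species is \(2Fp(1-p)\)).
* **Genotypes**: references draw both copies from their own species; an F1
  draws exactly one copy per locus from each species; F2, backcrosses and
  fixed-\(q\) classes draw each copy independently from species A with
  probability \(q\) — exactly the admixture model's assumption.
* **Traits**: multivariate normal with mean
  \(q\mu_A + (1-q)\mu_B\) — additive inheritance — and common covariance.
  Default means are typical *A. formosa* / *A. flavescens* herbarium-scale
  values (e.g. lamina length 0.31 vs 0.58 cm). The default covariance is
  diagonal with per-trait SD set to **half** the range-wide
  herbarium-implied SD (\(\mathrm{SE}\sqrt n\)): single allopatric
  populations are phenotypically much tighter than a species' whole range,
  which mixes geographic clines and introgressed zones. With that choice
  the simulated parental Mahalanobis separation is ≈ 7, i.e. a
  cross-validated error of order \(10^{-4}\), the regime reported for
  field-collected allopatric populations; using the full range-wide SD
  instead reproduces the noisier herbarium regime (error of order
  \(10^{-1.1}\)). The cleft-laminae flag is Bernoulli with defaults 0.37
  (species A) and 0 (species B), mixed by \(q\) in hybrids.
* **Colour**: normal on the log R/G scale (defaults ±0.5, SD 0.1 — parental
  distributions ≈ 5 SD apart, hence non-overlapping, as observed for field
  populations), back-transformed at fixed G = 80; hybrids also receive an
  integer visual score equal to their empirical log R/G quintile, which is
  how the colour-metric validation was designed.
* **Plastid**: one haplotype per species differing by
  `n_substitution_diffs` (default 3) substitutions plus a species-
  diagnostic 5-bp indel (species A gapped); hybrids inherit their maternal
  haplotype (default: all maternally species A, the orphan-swarm scenario).
* **Coordinates**: isotropic Gaussian (SD 0.8°) around separated species
  centres, hybrids around a third site inside species A's range.

Default sizes mirror the motivating study — 12 + 12 reference individuals,
29 hybrids, 11 loci with motifs 2–5 bp — so the whole pipeline runs in
seconds. `simulate_cline()` adds the range-wide scenario: specimens placed
along the axis between the two range centres whose ancestry decays linearly
from pure (\(q = 1\)) at their own centre to half-admixed (\(q = 0.5\)) at
the far end, or a null variant with geography independent of phenotype.

What the simulator does **not** emulate: linkage and mutation within
pedigrees, selection, spatially explicit dispersal, genotyping artefacts
(stutter, allele dropout produce half-calls, which the readers reject
rather than model), colour-calibration error, and geolocation error in
herbarium records. Tests passing on these simulations therefore validate
the estimators under their own assumptions; they do not certify robustness
to those real-data complications.

# Numerical conventions and degenerate inputs

* Missing genotype calls are wholly missing or an error (half-calls are
  rejected by the readers, never imputed) — silent imputation would bias
  heterozygosity.
* Bruvo distances use pairwise deletion; a pair of individuals sharing no
  complete locus is an error, not an NA.
* PCoA applies the eigenvalue correction only when an eigenvalue falls
  below \(-10^{-8}\); an all-zero distance matrix short-circuits to a zero
  embedding.
* UPGMA output is ultrametric to \(10^{-9}\); NJ reproduces additive
  matrices to machine precision.
* Tied minimum-spanning edges are all retained; the network never depends
  on input order.
* West longitude is negative decimal degrees everywhere; alignment columns
  are 1-based inclusive.
* Every stochastic routine takes a seed and is bit-reproducible given it;
  `run_pipeline()` derives per-stage seeds from its single seed.

# Problem sizes used in the shipped checks

The package's own test suite and `scripts/acceptance.R` run the estimators
at the study's natural scale: 11 loci and 24 reference + 29 query
individuals for the default swarm; 90 queries (30 per pedigree class,
F1/BC\(_A\)/BC\(_B\)) with 10 000 + 10 000 MCMC sweeps and 2 averaged runs
for ancestry recovery (recovered within ±0.07); 170 parental specimens and
1000 CV repetitions for the morphometric error (< 0.01, against ≈ 0.5
under permuted labels); 160 specimens for the clinal statistic (negative
under introgression; |r| < 0.3 in ≥ 95 % of null replicates). These sizes
were chosen to match the scale of the data the methods are meant for while
keeping a full run in the tens of seconds.

# Known limitations

Two-group methods throughout (no multi-parent swarms, no unsupervised K
selection); diploid microsatellites only; no Hardy–Weinberg or F-statistics
testing; plastid networks assume pre-aligned input and exact-match
haplotype classification; spherical rather than ellipsoidal geometry; and
the admixture sampler's credible intervals inherit the usual caveat that
they are conditional on the model — with few loci, an F2 and an F1 are
genotypically indistinguishable in expectation, and only \(q\), not the
pedigree class, is estimated.
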