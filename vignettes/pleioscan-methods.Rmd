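---
title: "Methods: bivariate QTL co-localization and class-contrast differentiation"
author: "pleioscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bivariate QTL co-localization and class-contrast differentiation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

pleioscan re-implements, over fully synthetic data with recorded ground
truth, the computational chain used to show that a single flowering-time
locus (*FRIGIDA*-like, "the focal locus" below) pleiotropically controls
water-use efficiency (WUE, measured as carbon-isotope composition),
growth rate and flowering time (FT), and that functional variation at
that locus structures natural populations. This vignette documents the
models, the parameter choices and the numerical decisions. No empirical
claim is made here beyond what the package's tests and
`scripts/acceptance.R` compute.

## The RIL simulator

Recombinant inbred lines (RILs) from a biparental cross are effectively
homozygous mosaics of the two parental genomes. We simulate genotypes
directly at the RIL (F-infinity) scale as a two-state Markov chain along
each chromosome: for an interval of d cM (meiotic scale), the per-meiosis
recombination fraction is the inverse Haldane value
r = (1 − e^(−2d/100))/2 (no crossover interference), and the probability
that a line carries different parental alleles at the interval's ends is
the map-expanded R = 2r/(1 + 2r). Simulating at the RIL scale rather than
through eight explicit selfing generations gives the same marginal
genotype process for mapping purposes and admits closed-form oracles
(the map-expansion law is verified on 10 000 simulated lines at
d = 5, 10, 20 cM in the test suite). Residual F9 heterozygosity
(~0.4% in a real F9 population) is ignored by default; the
`residual_het` switch simulates it and records such calls as missing,
which is how inbred-line pipelines treat them. One caveat of the Markov
construction: the chain composes per-interval transition probabilities,
while true RIL-scale recombination fractions are not exactly closed under
Markov composition, so inserting a locus inside an interval perturbs the
end-to-end recombination fraction by a quantity that is second-order in r
(well under sampling error at every design size used here).

Phenotypes are built on a standardized (z) scale as the sum of QTL
effects (each QTL's effect is the difference between the two homozygote
classes, in phenotype-SD units), a polygenic term (independent
N(0, σ²_poly/(0.25·M)) effects on all M markers, giving expected
polygenic variance σ²_poly despite marker linkage), and Gaussian
residual noise; each trait is then placed on its natural scale by an
affine map (WUE around −33.5 per mil, FT around 55 days). Leaf areas at
days 14 and 21 are derived from a growth-rate trait so the
`growth_rate()` formula applies downstream.

The default design is the study's: 343 lines, 166 markers on 5
chromosomes of 85 cM (the sources do not state the map's chromosome
lengths; 5 × ~85 cM is a realistic *Arabidopsis* linkage map and is our
fixed choice), a shared pleiotropic QTL at 4 cM on chromosome 4
explaining 25% of WUE and 15% of FT variance (and 9% of growth rate,
with opposite sign), plus one 8% trait-specific QTL per mapped trait.
The WUE and FT residuals are correlated at 0.26, chosen once so that the
line-mean WUE–FT correlation is r ≈ 0.37 (r² ≈ 0.14), the RIL-scale
value the design targets; the `genetic_correlation()` recovery test runs
at exactly this design.

## Genome scans

Scanning follows the Haley–Knott regression form: at every grid position
x the phenotype is regressed on the expected parent-A dosage
E[g | flanking markers], and

LOD(x) = (n/2) · log10(RSS0 / RSS1(x)).

The pseudo-marker grid subdivides every inter-marker gap into
ceiling(gap/step) equal pieces (step 2 cM by default), so no two grid
points are more than the step apart and every true marker is retained.
Genotype probabilities condition on the nearest informative flanking
markers of each line under the two-state chain — not an EM over all
markers — which is standard, exactly testable against brute-force
enumeration of the hidden state, and reduces to 0/1 at observed markers
and to 0.5 for a line with no information on a chromosome (logged).
The original analysis used multiple imputation (256 draws) to the same
grid; we default to the exact conditional-expectation regression because
it is deterministic and has an algebraic oracle. LODs differ slightly
between the two engines at unobserved positions; all oracle equivalences
are asserted at fully observed markers, where the engines coincide.

A subtlety the API makes explicit: a cM distance can live on the meiotic
scale or on the already-expanded RIL scale (maps estimated from RIL data
are on the latter). `genetic_map` objects carry a `map_scale` flag; the
simulator marks its maps `meiotic` (its configured distances are
per-meiosis) and `ril_transition()` converts accordingly, while maps of
unknown provenance default to `ril`, matching what mapping software
estimates from RIL data.

Numerical choices: RSS1 is floored at 1e-12·RSS0, capping the LOD on
degenerate perfect fits; argmax ties resolve to the lowest (chromosome,
position); missing phenotypes are dropped pairwise. The permutation
threshold is the k-th largest genome-wide maximum over phenotype
permutations with k = floor(alpha·(n_perm + 1)) — the order statistic
whose null exceedance probability is alpha, so the threshold's type-I
error calibrates without interpolation artifacts (verified at 200 null
replicates × 500 permutations; the original analysis used 10 000
permutations, a size difference that only narrows the threshold's Monte
Carlo error).

Model selection is forward inclusion while the penalized LOD
(model LOD − penalty × model size) increases, followed by backward
pruning, with the permutation threshold as the per-QTL penalty. Only
additive terms are scanned: the pleiotropic QTL of interest is additive,
and epistatic penalty machinery is out of scope. Position refinement
re-scans one QTL at a time holding the others fixed and accepts only
LOD-improving moves, so the model LOD is non-decreasing and terminates
at a fixed point. Effects, drop-one LODs and drop-one percent variance
explained come from the joint linear fit; collinear dosage columns get a
drop-one LOD of 0 with a warning rather than an error, since stepwise
search can transiently propose them.

## The bivariate co-localization statistic

Each trait's profile is standardized by its genome-wide maximum
(stand.LOD, maximum exactly 1) and the two standardized profiles are
summed: S(x) ∈ [0, 2], approaching 2 only where both traits peak
together. The joint peak is the argmax of S.

The interval rule needed a design decision. Read literally, the source
formulation — the interval ends where the summed score falls to "the
average single phenotype odds ratio at a given map position" — sets the
threshold at S(x)/2, which S(x) exceeds everywhere, so the interval
would always span the chromosome. We therefore default to a
`peak_fraction` rule: the interval extends from the peak until S first
drops below α·S(peak), with α = 0.5 (widening as α decreases, shrinking
to the peak grid point as α → 1, and always containing the peak). The
literal reading is preserved as a documented alternative
(`rule = "literal"`, with the positionwise average of the two raw
profiles rescaled to the summed profile's maximum as the crossing
threshold). Interval coverage of the true shared QTL is checked by
simulation at the default design (≥ 90% over 100 replicates).

Only two traits are supported, matching the use case; the container
generalizes.

## Class-contrast FST and resampling nulls

Accessions are inbred, so genotypes are haploid-coded 0/1 allele calls;
heterozygous VCF calls are set missing with a warning. Two per-SNP
estimators are provided:

* `nei`: FST = (Ht − Hs)/Ht with Ht = 2p̄(1 − p̄) at the pooled
  complete-case frequency and Hs the *unweighted* mean of the two
  within-class expected heterozygosities (the source took "the mean of
  those" without sample-size weighting; the choice is recorded in the
  result metadata). The closed form is pinned to 1e-12 over the full
  two-class frequency grid in the tests.
* `wc`: the Weir–Cockerham variance-components estimator for haploid
  samples, aggregated as ratio-of-sums by default (the dialect of the
  original plink-based analysis), mean-of-ratios optionally. Note the
  two estimators target different parameters: for two fixed classes at
  frequencies p ± δ, the Nei ratio is δ²/(p(1−p)) while the
  variance-components estimand treats classes as random draws and
  converges near 2δ²/(2δ² + Hs/2); they agree in sign and rank datasets
  the same way but are not numerically equal, so cross-checks assert
  sign agreement and stability, not equality.

SNPs monomorphic in the pooled sample, with fewer than two observed
accessions in a class, or with more than 20% missing calls are skipped
and counted. The genome-wide statistic is the unweighted mean of per-SNP
values (Nei) or the ratio-of-sums (WC).

Two nulls are implemented. The *permutation null* redraws the class
partition uniformly at random preserving exact class counts (5000
divisions in the original; K is a parameter and the empirical p-value
uses the (1 + b)/(1 + K) convention, so p is never 0 and is
seed-reproducible). The *frequency-matched bootstrap* instead divides
the panel by the alleles of randomly drawn SNPs whose minor-allele
frequency lies within ±0.02 (configurable; the source gives no
tolerance) of the focal class frequency — a null that holds the division
frequency at the focal locus's. Each drawn SNP defines one division and
is excluded from its own recomputed statistic: its FST is 1 by
construction, and because the focal-locus division has no counterpart
SNP inside the genome scan, keeping it would bias every resample upward
by ~1/m and make the test conservative (we measured exactly this before
adopting the exclusion). With the exclusion the empirical p-value is
uniform on null panels (rejection rate at the 5% level inside the
binomial CI over 200 replicate panels at K = 199).

Regional FST controls for geographic structure: within each cluster,
SNPs are thinned greedily to ≥ 50 kb spacing (first SNP kept, duplicated
positions keep the first), Ht is the mean pooled heterozygosity over
thinned SNPs, Hs the unweighted two-class mean of within-class
heterozygosities averaged over SNPs, and FST = (Ht − Hs)/Ht. Clusters
lacking two accessions of either class are skipped and flagged.

## Functionality imputation

Features are the 0/1 alleles of every SNP within ±100 kb (closed
interval) of the focal locus; missing entries take the SNP's major
allele (the source is silent on missing handling; major-allele fill is
the simplest choice that keeps the feature matrix binary). The
classifier is a support vector machine with a radial-basis kernel
(libsvm via e1071). Hyperparameters come from a grid search —
width γ ∈ {2^−6 … 2^2}, cost C ∈ {2^−2 … 2^6}, log-spaced — scored by
stratified inner cross-validation; ties resolve to the smallest cost,
then the smallest width (preferring the least flexible model). The
search runs inside each training split of every protocol, so no
information leaks from held-out data into model selection; the
label-permutation control (CV accuracy within a binomial CI of the
majority baseline) tests precisely this. When a training split is too
small to stratify the inner CV (subset leave-one-out at n = 10 can
leave one class with a single member), the mid-grid parameter pair is
used without search rather than leaking.

Two CV protocols mirror the original study: stratified fourfold CV on
all labeled accessions, and the sample-size sensitivity protocol —
draw n accessions at random (re-drawing up to 100 times if a draw lands
single-class), run leave-one-out CV within the subset, repeat. Decisions
are taken at margin 0 with no probability calibration: binary binning is
all the pipeline needs downstream. Imputed accessions keep their
observed label when one exists; accessions missing every window SNP are
labeled unknown and excluded downstream.

## Downstream statistics

Relative growth rate is GR_la = (ln LA_t2 − ln LA_t1)/(t2 − t1).
Genotype effects are one-way ANOVAs with PVE = SSB/SST × 100 (the
identity SST = SSB + SSW is asserted to 1e-10, and the two-group F
equals the pooled-variance t²). The WUE–FT genetic correlation is a
Pearson r on pairwise-complete line means with the t-transform p-value.
Climate variables are compared between classes by Welch t-tests (the
variant is unstated in the source; unequal variances are the safe
default) with Bonferroni correction over the 19-variable family, and
summarized non-parametrically as each class's mean rank normalized by
(N + 1) — 0.5 for identical distributions, approaching 0.25/0.75 under
complete separation with equal class sizes, invariant to monotone
transformation.

## What the accession-panel generator does and does not emulate

The generator draws a functional/non-functional label at a configurable
frequency (default 0.35 functional, 317 labeled of 1188 accessions, the
study's panel sizes), window SNPs whose agreement with the label is
calibrated to a target r² (default 0.9) by solving the flip probability
of a noisy copy, genome-wide SNPs with class frequencies p ± δ where
δ = sqrt(FST · p(1 − p)) hits a target per-SNP Nei FST exactly at equal
class weights (base frequencies U(0.2, 0.8) keep δ feasible up to
FST ≈ 0.25; infeasible SNPs are truncated to the boundary and flagged),
11 geographic clusters of which one carries no differentiation
(genotypes in it ignore the label, mirroring the one-of-eleven
non-elevated region), and 19 climate variables that are independent
Gaussians given class, the first five shifted by 1 SD — the simplest
structure satisfying the t-test stage's assumptions.

It deliberately does **not** emulate coalescent haplotype structure,
linkage disequilibrium decay between genome SNPs, isolation by distance,
or ascertainment of real SNP panels. Consequently, passing tests show
that the estimators and protocols are correct and calibrated under
their stated assumptions — they do not show robustness to background LD
(which inflates frequency-matched nulls built from linked SNPs) or to
spatially confounded climate gradients. With no LD, imputation from a
tagged window is easier than on real data: the default-window CV
accuracies here saturate near 1.0, above the 95% reported on the real
panel, and only the perfect-tag limit and the qualitative accuracy rise
with n are asserted.

## Problem sizes

The test suite and acceptance script run at the design sizes: 343
lines × 166 markers for every mapping check, 10 000 lines for the
map-expansion law, 100 replicates for QTL localization and coverage,
200 replicates × 500 permutations for threshold calibration, 50 000
SNPs for FST parameter recovery, 200 null panels at K = 199 for
bootstrap calibration, and 20 repeats per subset size for the
leave-one-out accuracy curve. The permutation engine is vectorized (one
matrix product per batch of permutations), which is what makes those
replicate counts cheap.

## Known limitations

* The Markov RIL chain is exact pairwise but only approximately
  consistent across nested intervals (no interference, no exact
  F-infinity composition).
* Haley–Knott regression slightly mis-states LODs at positions with
  high genotype uncertainty relative to full-likelihood or
  multiple-imputation engines.
* The `literal` interval rule is retained for reference but is
  near-degenerate by construction.
* The WC estimator's estimand differs from the Nei ratio on fixed
  two-class designs (see above); report which estimator you used.
* Climate tests assume independent accessions; no spatial or kinship
  correction is applied.
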