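---
title: "Methods: spatial structure, clade tests and ancestry outliers in driftscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial structure, clade tests and ancestry outliers in driftscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

driftscape studies how much individual movement is compatible with stable
spatial population structure in historical-period west Eurasia, using
(pseudohaploid) ancient-DNA genotype data and forward simulations.  This
vignette documents the models, the tunable parameters, the synthetic worlds
the tests run in, and the numerical and design choices a maintainer should
know about.  It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Data model

Genotypes live in a `geno_matrix`: sites x samples dosages in {0, 1, 2} with
`NA` as the missing sentinel throughout (EIGENSTRAT digit 9 on disk).
Pseudohaploid samples — one randomly drawn allele represented as a
homozygous call, the standard representation for low-coverage ancient
genomes — carry per-sample ploidy `"pseudohaploid"` and contribute exactly
one allele per non-missing call to every frequency computation; diploid
samples contribute two.  This weighting is what makes the n−1 sample-size
corrections in the FST estimator well defined at the individual level.

Only the plain-text EIGENSTRAT dialect is supported (not
PACKEDANCESTRYMAP): synthetic pipelines do not need the packed format and
plain text keeps fixtures diffable in tests.  CpG-transition exclusion is
taken as a precomputed site list (plus a blunt `drop_transitions` flag)
because identifying CpG context requires flanking sequence the genotype
files do not carry.  Site filtering (dataset-wide MAF, default 0.01) is
idempotent and errors rather than returning an empty matrix.

Seven period bins cover Mesolithic & Neolithic through Present-day.  The
outlier workflow clusters individuals from the Copper Age up to (and
excluding) Present-day, and counts regional denominators from the Bronze
Age onward — both windows are configurable in `workflow_config()`.

## f4-statistics and the one-component (clade) test

For groups A, B and rights (base, r_2..r_k), the statistic
`f4(A, B; base, r_j)` is the per-site average of
`(pA − pB)(p_base − p_rj)`.  It is zero in expectation exactly when (A, B)
form a clade relative to the rights.  The test of the joint null collects
`v_j = f4(a, b; base, r_j)` over the k−1 non-base rights on the common set
of usable sites and forms `T = v' Σ⁻¹ v`, with Σ a weighted block-jackknife
covariance (5-Mb physical blocks by default; block site counts as weights;
the Busing-style weighted combination).  T is compared to a chi-square with
k−1 degrees of freedom (the effective rank if Σ is degenerate — Σ is
inverted by SVD pseudoinverse at relative tolerance 1e−8).  The
dissimilarity is `d = −log10(max(p, 1e−320))`; the floor keeps d finite for
clustering.  T is invariant under a change of base reference because v and
Σ transform by the same full-rank linear map.

Choices worth knowing:

* Groups of size 1 are allowed (individual-level tests); a site is usable
  only if every involved group has at least one called allele, so
  individual pairs use the intersection of their coverage.
* Usable-site guardrails: warn below 5000 sites, error below 500 (both
  configurable).  Unstable covariances, not precision, are the concern.
* The chi-square form is a Hotelling-style approximation of the rank test
  run by admixtools-type software; exact numerical agreement with that
  software is not claimed and block size there is not published.  With
  several hundred blocks the approximation is well calibrated — the
  acceptance suite measures the type-I error of `d > 1.3` under a
  panmictic null at 1000 replicates and requires 5% ± 1.5%.
* The two-component admixture fit is generalized least squares on the same
  f4 machinery: `y_j = f4(t, s2; base, r_j)`, `X_j = f4(s1, s2; base,
  r_j)`, `α̂ = (X'Σ⁻¹y)/(X'Σ⁻¹X)` with Σ the jackknife covariance of y,
  residual chi-square on k−2 degrees of freedom, and
  `se(α̂) = (X'Σ⁻¹X)^{−1/2}`.  Sources that are clades of each other make X
  ≈ 0 and are rejected as indistinguishable.

## The ancestry-outlier workflow

The pipeline mirrors a qpWave/qpAdm-style workflow: (1) one-component
tests between all pairs of individuals within a region (Copper Age up to
Present-day, exclusive); (2) UPGMA (average-linkage) clustering of the d
matrix, cut at d = 1.3 (nominal p = 0.05); (3) clusters with fewer than 5%
of the regional total (strict) OR at most two individuals become outlier
candidates — the two rules are alternatives, either suffices; (4) clusters
are split into region-period clusters; (5) candidates connected to a
same-region majority by a valid one-component model (p > 0.01) are
absorbed; (6) surviving candidates are tested against majority clusters of
all other regions — valid models are candidate sources; (7) model
competition: each source x is re-tested with every rival y added to the
rights, and x is dropped if any rival rejects it (this eliminates
sub-optimal sources; it does not crown a best one); (8) same-period sources
are preferred, else the nearest earlier period, remaining ties all kept;
(9) the network summary reports per-region outlier proportions, directed
source-to-outlier edges, and a chi-square test (df = 2) of sex against
{non-outlier, outlier with source, outlier without source}.

Cluster-level tests pool member allele counts into one pseudo-population,
which gives grouped tests more power than individual ones.  Pairs that fail
the usable-site minimum get `d = NA`, are imputed as max(d) + 1 for
clustering (so chronically low-coverage individuals form their own
clusters rather than being silently attached), and are flagged.  UPGMA
ties are resolved by `stats::hclust`'s deterministic ordering rather than
an explicit lowest-index rule; with continuous d values exact ties do not
occur in practice.  The cross-region validity threshold reuses the 0.01
absorption threshold (configurable — the choice between 0.01 and 0.05 for
that step is not determinable from the method description).  Denominators
for the 5% rule count the region's clustered individuals inside the time
window; how individuals spanning period boundaries should enter that
denominator is under-determined, and this definition keeps totals conserved
at every stage.

## Synthetic data: what it emulates and what it does not

The generator produces aDNA-like fixtures with known ground truth: allele
frequencies drift along a population tree under the Balding–Nichols model
(child ~ Beta given parent, `E = p`, `Var = F·p(1−p)`, closed-form moments
that double as oracles), individuals are binomial draws, study samples are
pseudohaploidized with per-individual missingness spanning 0.15–0.85
(emulating the order-of-magnitude spread in covered sites per ancient
sample), and migrants are planted by drawing genotypes from one regional
leaf while placing the individual's metadata in another region.

One structural decision matters most.  A tree in which all regional leaves
hang off one clade and all rights off another makes
`E[f4(a, b; base, r)] = 0` for *every* pair of regional leaves (the a–b
path shares no branch with any base–r path), so the clade test has no
power and no outlier is detectable, however strong the per-leaf drift.
What powers the real workflow is that the references are *differentially*
related to the focal groups.  The standard fixture therefore builds the
regional leaves as two-way admixtures along a cline: two deep ancestry
components (F = 0.25 each — on the order of the differentiation between
major prehistoric west-Eurasian ancestries), mixing proportions alpha from
0 to 1 across the six regions, light leaf-specific drift (F in
[0.01, 0.05]) on top, and eight rights of which two descend from each
component and four from the root (F in [0.1, 0.3]; the most drifted root
branch is the outgroup-like base).  Migrants are then first-generation,
cross-cline individuals — the analogue of the cross-Mediterranean outliers
the real analysis flags.

Synthetic sites are independent (no linkage), laid out evenly over 22
autosome-scale chromosomes so that 5-Mb blocking yields several hundred
jackknife blocks.  A green test therefore establishes calibration and
power under independence and known ancestry structure; it does not
establish robustness to LD, reference misspecification, or contamination.

## Spatial FST and the isolation-by-distance curve

Hudson's estimator with unequal sample-size correction is computed per
site as `N = (p1−p2)² − p1(1−p1)/(n1−1) − p2(1−p2)/(n2−1)`,
`D = p1(1−p2) + p2(1−p1)`, combined across sites as the ratio of sums
(never a mean of per-site ratios); sites need at least two called alleles
on both sides; multi-site estimates may be negative and are reported
as-is.  The sliding grid uses 10°x10° cells anchored at (−180°, −90°) —
the anchor is a convention the method description leaves open — slid 1°
north and east ten times; cells need `min_cell_n = 2` samples (the n−1
correction needs two alleles; the original threshold, if any, is not
stated).  Distances are haversine kilometres (Earth radius 6371.0088 km)
between all cross-cell individual pairs, averaged; simulated habitats use
euclidean distance.  Samples within one cell width of the antimeridian are
rejected rather than wrapped.

The FST-distance relationship is smoothed by lowess (span 0.67, 3
robustifying iterations — unstated upstream, so standard values) evaluated
on 100 equally spaced distances.  Confidence bands come from a spatial
bootstrap that respects the sliding grid's double counting: populated
cells are grouped into connected components of the overlap graph (two
cells overlap iff both coordinate intervals intersect with positive
length), components are resampled with replacement, and a point enters a
replicate once per joint inclusion of its two components (t_A·t_B times
for distinct components, t times within one).  With densely sampled maps
the overlap graph can collapse into a single component; the bootstrap is
then degenerate and says so in a warning — the upstream description does
not resolve this case, so the bands are still computed.

## The continuous-space simulator

A constant-size, non-overlapping-generations Wright–Fisher population
lives on the unit square.  Three Gaussian kernels govern demography, with
the upstream parameter values as defaults: mate choice (maxDistance 0.1,
maxStrength 1.0, sigma 0.02 — the strength scale cancels in sampling but
is kept for fidelity), competition (0.3, 3.0, 0.1) entering fitness as
`1.1 − competition/N` floored at zero with self excluded, and maternal
dispersal with standard deviation `sigma_disp`.  Mothers are drawn by
fitness, fathers by kernel weight within range (a mateless mother is
redrawn, capped at 1000 attempts); offspring genomes recombine with
Poisson crossovers (`r_per_bp x genome_length` expected, uniform
positions) and mutate by per-site flips; positions reflect at the habitat
boundary (conserving N; wrapping or absorbing would change the geometry).
Long-range dispersal replaces the dispersal kernel for a fraction `p_lr`
of offspring with a wider Gaussian (`sigma_lr = 0.20`), rejection-sampled
until the displacement exceeds the base kernel's radial 99% quantile
`r99 = sigma_disp·sqrt(2 ln 100)` — so the long-range fraction genuinely
means "dispersed beyond the 99th percentile of base dispersal".  The two
upstream spellings of the long-range parameter are treated as one
parameter.

Initialization replaces coalescent completion of deep history: per-site
ancestral frequencies are drawn from the neutral 1/x site-frequency
spectrum on [1/(2N), 1−1/(2N)], alleles assigned independently per
haplotype (no spatial structure at generation 0), and burn-in establishes
isolation by distance.  This preserves the quantity under study —
spatial differentiation of standing variation — without tree-sequence
machinery; it is an approximation of deep history, not a reproduction of
it.

**Desk scale.**  The reference analysis runs N = 50,000 with
sigma_disp = 0.02 for 2000 + 120 generations on a 10⁸-bp genome.  Spatial
FST depends on Wright's neighborhood size `Nb = 4π·sigma²·N/area`, so the
desk-scale operating point is re-calibrated directly against the same
target (maximum-distance FST ≈ 0.03) rather than assuming transfer across
N.  At that target Nb ≈ 110, which on the unit square forces
`sigma ≈ 0.105/sqrt(N/1000)`: the calibration grid is therefore N in
{2000, 4000} x sigma_disp in {0.03, 0.05, 0.08} (screened at 2000 sites,
500 burn-in generations — several times the habitat-crossing time at the
operating point — with FST averaged over three post-burn-in records).
Small-N/large-sigma solutions (e.g. N = 1000, sigma = 0.12) also reach
FST 0.03 but erase the contrast between sigma_disp and sigma_lr = 0.20
that the long-range scenarios measure — the measured dose-response
vanishes there — so the grid favors the largest desk-scale N.  The
maximum-distance FST summary is the mean over cell pairs whose mean
inter-individual distance is at least 0.8 of the largest observed pair
distance.  Mutation and recombination rates are 2.5e−7 (the reference
1e−8 scaled x25 on a 2e7-bp genome), which preserves the expected ~5
crossovers per meiosis; new mutations are negligible over the simulated
span, and differentiation dynamics ride on standing variation.

The long-range scenarios share one burned-in state per seed across
`p_lr` in {0, 0.04, 0.08} (matched starts), track the trajectory every 10
generations over the 120-generation historical window, and report the
relative change in maximum-distance FST plus a Mann–Kendall trend test
per run.  Flatness of the p_lr = 0 control is a genuine equilibrium
check: it fails if burn-in is too short.

## Principal components

The reference-space PCA centres each site by the reference mean dosage μ
and scales by `sqrt((μ/2)(1−μ/2))` (the standard unit-variance scaling for
allele dosages); monomorphic sites are dropped and missing reference
entries mean-imputed (references are assumed high-quality).  Outlier
removal runs up to 5 iterations, removing any reference beyond 6 standard
deviations (per-PC SD over currently retained references — the plainest
reading of the upstream setting) on any of the first 10 PCs, refitting
each round.  Loadings are column-orthonormal with the largest-magnitude
entry of each component forced positive, so orientations are deterministic
for tests.  Projection of a (possibly very sparse) sample solves the
normal equations restricted to its observed sites; with no missingness
this is exactly the direct score projection.  Samples below 1000 shared
sites are refused by name.  Simulated cohorts use the same machinery as a
plain PCA after a MAF ≥ 0.01 filter.

## Known limitations

* No LD in synthetic data; block jackknife is exercised structurally, not
  against real linkage.
* The clade test's chi-square calibration degrades below a few dozen
  blocks; the guardrails warn rather than forbid.
* The spatial bootstrap is honest but under-determined upstream; with one
  overlap component its bands are not confidence bands.
* Desk-scale simulation reproduces the calibration target and the
  direction and ordering of the long-range dispersal effect, not the
  reference run's absolute variant counts or timescales.
* VCF import, packed EIGENSTRAT, rotating-outgroup strategies and models
  with three or more sources are out of scope.
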