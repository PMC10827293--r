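# driftscape

Population-genetic tooling for a question about the historical period
(roughly the last 3000 years) in western Eurasia: people demonstrably moved
a lot — ancient genomes keep turning up far from ancestrally similar
populations — yet spatial population structure (the isolation-by-distance
relationship between genetic differentiation and geography) stayed
remarkably stable. driftscape packages the computational machinery needed
to quantify both sides of that tension from pseudohaploid ancient-DNA
genotypes and from forward simulations:

* **Ancestry outliers** (`run_outlier_workflow()`): qpWave-style
  one-component models — the joint test that an f4-statistic vector
  `f4(a, b; base, r_j)` is zero, i.e. that `a` and `b` form a clade
  relative to a panel of distal reference populations — turned into a full
  workflow: pairwise tests within regions, UPGMA clustering of the
  dissimilarity `d = -log10(p)` at cutoff 1.3, size-based outlier
  candidacy (< 5% of the region or ≤ 2 individuals), absorption against
  same-region majorities (p > 0.01), cross-region source attribution,
  model competition (rotating rival sources into the right set), period
  prioritization, and a migration network with per-region outlier
  proportions and a sex-bias chi-square.
* **Spatial FST** (`grid_fst_distance_table()`, `spatial_bootstrap_ci()`):
  Hudson's estimator with unequal-sample-size correction,
  `sum(N)/sum(D)` across sites, on a 10°x10° grid slid 1° ten times;
  lowess FST-distance curves with an overlap-aware spatial bootstrap (200
  replicates) that resamples connected components of overlapping cells so
  no individual is double-counted.
* **PCA projection** (`fit_reference_pca()`, `lsq_project()`):
  reference-space PCA with Patterson normalization, 5 rounds of 6-SD
  outlier removal over 10 PCs, and least-squares projection of
  low-coverage genomes restricted to their observed sites.
* **Continuous-space simulation** (`run_simulation()`,
  `calibrate_dispersal()`, `run_lrd_scenarios()`): a Wright-Fisher
  population on the unit square with Gaussian mate-choice
  (maxDistance 0.1, sigma 0.02) and competition (0.3, sigma 0.1) kernels,
  fitness `1.1 - competition/N`, maternal dispersal SD `sigma_disp`, and a
  long-range fraction `p_lr` dispersing beyond the base kernel's 99%
  radius with `sigma_lr = 0.20`. Dispersal is calibrated by grid search so
  maximum-distance FST ≈ 0.03, then 120 generations (~3000 years at 25
  years/generation) are run at `p_lr` in {0, 0.04, 0.08} to measure how
  long-range dispersal erodes spatial structure.
* **Synthetic data** (`build_fixture()`): Balding-Nichols drift with an
  admixture cline, pseudohaploid calls with 15-90% missingness, deep
  reference panels and planted cross-region migrants — ground-truthed
  fixtures for every stage, no downloads.

EIGENSTRAT (.geno/.snp/.ind) I/O, site filters (MAF, exclusion lists,
transitions) and per-group allele counting are shared plumbing
(`read_eigenstrat()`, `apply_site_filters()`, `group_allele_counts()`).

## Worked example

Build a ground-truthed fixture (six regions on an ancestry cline, eight
reference populations, 3% planted migrants) and run the outlier workflow:

```r
library(driftscape)
set.seed(3)
fx <- build_fixture(standard_fixture_spec(n_sites = 20000,
                                          n_per_region = 15))
res <- run_outlier_workflow(fx$geno, fx$meta, fx$rights)
res$network
#> migration network: 6 regions, 6 edges
#>   region n_total n_outlier n_outlier_with_source prop_outlier ...
#>  Region1      17         2                     2    0.1176471
#>  Region2      16         1                     1    0.0625000
#>  Region3      16         1                     1    0.0625000
#>  Region4      16         1                     1    0.0625000
#>  Region5      16         1                     1    0.0625000
#>  Region6      16         1                     1    0.0625000
```

All seven planted migrants are flagged as `outlier_with_source` and every
directed edge points back to the migrant's true source region (e.g. the
two migrants planted into Region1 from the Region2 ancestry produce the
edge Region2 → Region1); no resident is misclassified. `res$clusters`
holds the per-individual region-period cluster table, `res$outliers` the
per-outlier source attributions, and `res$test_log` every clade test run
(pair, p, d, SNPs used).

The dissimilarity scale is the clade-test p-value: `dissimilarity(0.05)`
= 1.30, the clustering cutoff, so clusters split where pairs stop looking
like clades at the nominal 5% level.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch against the installed package, the empirical
type-I error of the one-component clade test at the d > 1.3 cutoff: 1000
replicate pairs of pseudohaploid individuals are drawn from one panmictic
synthetic population (20k sites, the standard drift-derived reference
panel), each pair is tested, and the fraction with d > 1.3 is written as a
JSON proportion (`t4`). A well-calibrated test sits near 0.05.
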