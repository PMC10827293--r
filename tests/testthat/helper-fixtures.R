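# Shared in-code fixtures.  Everything is generated at test time under fixed
# seeds; heavier objects are memoized so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# a tiny hand-checkable genotype matrix
tiny_geno <- function() {
  calls <- matrix(c(0L, 2L, NA, 1L, NA, 0L), nrow = 2, byrow = TRUE)
  variants <- data.frame(id = c("s1", "s2"), chrom = "1",
                         genpos = c(0, 0.05), physpos = c(100L, 5000100L),
                         ref = c("A", "C"), alt = c("C", "T"),
                         stringsAsFactors = FALSE)
  geno_matrix(calls, variants, c("i1", "i2", "i3"), "diploid")
}

# counts object straight from frequency columns (complete data), plus blocks
counts_from_freqs <- function(freq_mat, n_sites = nrow(freq_mat)) {
  list(freq = freq_mat)
}

synthetic_blocks <- function(n_sites) {
  make_blocks(driftscape:::synthetic_variants(n_sites))
}

# small admixture-cline fixture shared across outlier/pca tests
small_fixture <- function() {
  memo("small_fixture", {
    set.seed(202)
    spec <- standard_fixture_spec(n_sites = 12000, n_per_region = 12)
    build_fixture(spec)
  })
}

# a pair of strongly differentiated leaves with rights that are
# differentially related to them (power fixtures for the clade test)
power_freqs <- function(n_sites = 20000, seed = 99) {
  set.seed(seed)
  standard_ancestry_freqs(n_sites, alphas = c(0, 1),
                          f_leaves = c(0.05, 0.05))
}

right_labels <- paste0("Right", 1:8)
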