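# Synthetic aDNA-like fixtures with known ground truth.  Allele frequencies
# drift along a population tree under the Balding-Nichols model (closed-form
# moments make analytic oracles possible); individuals are drawn binomially,
# study samples are pseudohaploidized with per-individual missingness, and
# migrants are planted by drawing genotypes from one regional leaf while
# placing the individual (metadata) in another region.

#' Sample ancestral allele frequencies
#'
#' Uniform on [0.05, 0.95] so that sites stay informative after drift.
#'
#' @param n_sites number of sites.
#' @return numeric vector of frequencies.
#' @export
sample_ancestral_freqs <- function(n_sites) {
  stopifnot(n_sites >= 1)
  runif(n_sites, 0.05, 0.95)
}

#' Construct a drift tree
#'
#' A rooted tree given as a branch table: each row is a branch from `parent`
#' to `child` with Balding-Nichols drift parameter `F` in (0, 0.5].  The root
#' node is named `"ROOT"`.  Leaves (nodes that are never parents) are the
#' populations genotypes can be drawn for.
#'
#' @param parent,child character vectors defining branches.
#' @param F per-branch drift parameters.
#' @return data.frame of class `drift_tree`.
#' @export
drift_tree <- function(parent, child, F) {
  if (any(F <= 0 | F > 0.5)) stop("branch F must be in (0, 0.5]")
  if (any(duplicated(child))) stop("a node may have only one parent")
  tr <- data.frame(parent = parent, child = child, F = F,
                   stringsAsFactors = FALSE)
  roots <- setdiff(tr$parent, tr$child)
  if (!identical(sort(unique(roots)), "ROOT"))
    stop("tree must be rooted at a single node named 'ROOT'")
  class(tr) <- c("drift_tree", "data.frame")
  tr
}

#' Leaves of a drift tree
#' @param tree a [drift_tree()].
#' @return character vector of leaf names.
#' @export
tree_leaves <- function(tree) setdiff(tree$child, tree$parent)

#' The standard validation tree
#'
#' Six shallow regional leaves (branch F drawn in [0.01, 0.05]) hanging off a
#' common regional clade, plus `n_rights` deep, mutually independent
#' reference leaves (F in [0.1, 0.3]) attached directly to the root —
#' mirroring the requirement that right populations be distally but
#' differentially related to the focal samples.
#'
#' @param n_regional,n_rights leaf counts (defaults 6 and 8).
#' @return a [drift_tree()]; regional leaves are named `Leaf1..`, rights
#'   `Right1..`.
#' @export
standard_tree <- function(n_regional = 6, n_rights = 8) {
  reg <- paste0("Leaf", seq_len(n_regional))
  rts <- paste0("Right", seq_len(n_rights))
  f_reg <- seq(0.01, 0.05, length.out = n_regional)
  f_rts <- seq(0.10, 0.30, length.out = n_rights)
  drift_tree(parent = c("ROOT", rep("RC", n_regional), rep("ROOT", n_rights)),
             child = c("RC", reg, rts),
             F = c(0.02, f_reg, f_rts))
}

#' Drift allele frequencies along a tree
#'
#' Along each branch with parameter `F`, the child frequency is drawn from
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` given the parent frequency `p`
#' (Balding-Nichols), so `E[child] = p` and `Var[child] = F p (1-p)`.
#' Frequencies that have hit 0 or 1 stay fixed/lost on all descendants.
#'
#' @param tree a [drift_tree()].
#' @param ancestral numeric vector of root frequencies.
#' @return matrix of frequencies, sites x nodes (all nodes incl. internal).
#' @export
drift_along_tree <- function(tree, ancestral) {
  nodes <- c("ROOT", tree$child)
  freqs <- matrix(NA_real_, length(ancestral), length(nodes),
                  dimnames = list(NULL, nodes))
  freqs[, "ROOT"] <- ancestral
  todo <- tree
  while (nrow(todo) > 0) {
    ready <- !is.na(freqs[1, todo$parent])
    if (!any(ready)) stop("tree is not connected to ROOT")
    for (i in which(ready)) {
      p <- freqs[, todo$parent[i]]
      F <- todo$F[i]
      seg <- p > 0 & p < 1
      child <- p
      a <- p[seg] * (1 - F) / F
      b <- (1 - p[seg]) * (1 - F) / F
      child[seg] <- rbeta(sum(seg), a, b)
      freqs[, todo$child[i]] <- child
    }
    todo <- todo[!ready, , drop = FALSE]
  }
  freqs
}

#' Draw diploid genotypes from leaf frequencies
#'
#' Genotypes are Binomial(2, p) independently per site and individual
#' (Hardy-Weinberg within the leaf).
#'
#' @param freqs per-site derived-allele frequencies.
#' @param n number of individuals.
#' @return integer matrix, sites x n, values 0/1/2.
#' @export
genotypes_from_freqs <- function(freqs, n) {
  S <- length(freqs)
  matrix(rbinom(S * n, 2L, rep(freqs, n)), nrow = S, ncol = n)
}

#' Pseudohaploidize a diploid genotype matrix
#'
#' Per call, one allele is drawn at random and represented as a homozygous
#' call (heterozygotes become 0 or 2 with probability 1/2 each); then each
#' individual's sites are masked missing at its missingness rate.
#'
#' @param calls integer matrix sites x individuals (0/1/2, NA allowed).
#' @param missingness per-individual missing fraction (recycled).
#' @return integer matrix with values in \{0, 2, NA\}.
#' @export
pseudohaploidize <- function(calls, missingness = 0) {
  S <- nrow(calls); n <- ncol(calls)
  missingness <- rep_len(missingness, n)
  out <- calls
  het <- which(!is.na(out) & out == 1L)
  out[het] <- 2L * rbinom(length(het), 1L, 0.5)
  for (j in seq_len(n)) {
    if (missingness[j] > 0) {
      drop <- runif(S) < missingness[j]
      out[drop, j] <- NA_integer_
    }
  }
  out
}

#' Standard ancestry model: an admixture cline over two deep components
#'
#' A pure drift tree in which the focal leaves hang off one clade and all
#' rights off another has, by f4 path-counting, `E[f4(a, b; base, r)] = 0`
#' for every pair of focal leaves — the clade test then has no power and no
#' outlier is detectable.  What gives the paper's workflow its power is that
#' the reference populations are *differentially* related to the focal
#' groups.  This model emulates that: two deeply drifted ancestry components
#' (think hunter-gatherer vs early-farmer west-Eurasian ancestries,
#' `F = 0.25` each) mix into the regional leaves along a cline of admixture
#' proportions `alphas`, with light leaf-specific drift (`F` in
#' [0.01, 0.05]) on top; four of the eight reference leaves descend from the
#' components (two each, branch `F` in [0.12, 0.2]) and four from the root
#' (`F` in [0.1, 0.3], the most drifted serving as the Mbuti-like base).
#'
#' @param n_sites number of sites.
#' @param alphas admixture proportion of component 1 per regional leaf.
#' @param f_components drift of each ancestry component from the root.
#' @param f_leaves leaf-specific drift (recycled over leaves).
#' @return list with `freqs` (sites x leaves matrix, columns Leaf1..k then
#'   Right1..8, Right1 the base), `alphas`, and the component frequencies.
#' @export
standard_ancestry_freqs <- function(n_sites,
                                    alphas = seq(0, 1, length.out = 6),
                                    f_components = 0.25,
                                    f_leaves = seq(0.01, 0.05,
                                                   length.out =
                                                     length(alphas))) {
  bn <- function(p, F) {
    seg <- p > 0 & p < 1
    out <- p
    out[seg] <- rbeta(sum(seg), p[seg] * (1 - F) / F,
                      (1 - p[seg]) * (1 - F) / F)
    out
  }
  anc <- sample_ancestral_freqs(n_sites)
  C1 <- bn(anc, f_components)
  C2 <- bn(anc, f_components)
  f_leaves <- rep_len(f_leaves, length(alphas))
  leaves <- vapply(seq_along(alphas), function(i)
    bn(alphas[i] * C1 + (1 - alphas[i]) * C2, f_leaves[i]),
    numeric(n_sites))
  colnames(leaves) <- paste0("Leaf", seq_along(alphas))
  rights <- cbind(Right1 = bn(anc, 0.30),    # deep outgroup-like base
                  Right2 = bn(anc, 0.15),
                  Right3 = bn(C1, 0.12), Right4 = bn(C1, 0.20),
                  Right5 = bn(C2, 0.12), Right6 = bn(C2, 0.20),
                  Right7 = bn(anc, 0.10), Right8 = bn(anc, 0.22))
  list(freqs = cbind(leaves, rights), alphas = alphas, C1 = C1, C2 = C2,
       ancestral = anc)
}

# Evenly spaced synthetic site annotations laid out over 22 autosome-scale
# chromosomes so that 5-Mb jackknife blocks are plentiful (several hundred),
# which the chi-square calibration of the clade test relies on.
synthetic_variants <- function(n_sites, n_chrom = 22, chrom_len_bp = 120e6) {
  per <- ceiling(n_sites / n_chrom)
  chrom <- rep(seq_len(n_chrom), each = per)[seq_len(n_sites)]
  within <- sequence(tabulate(chrom, n_chrom))
  spacing <- floor(chrom_len_bp / (per + 1))
  pos <- within * spacing
  data.frame(id = paste0("snp", seq_len(n_sites)),
             chrom = as.character(chrom),
             genpos = pos * 1e-8,    # ~1 cM/Mb in Morgans
             physpos = as.integer(pos),
             ref = "A", alt = "C", stringsAsFactors = FALSE)
}

#' Fixture specification
#'
#' @param n_sites number of sites.
#' @param n_per_region study individuals per regional leaf.
#' @param n_per_right diploid reference individuals per right leaf.
#' @param regions data.frame region, leaf, lat, lon (one regional leaf per
#'   region); default: six regions on a Mediterranean-like arc.
#' @param jitter_deg uniform jitter applied to individual coordinates.
#' @param missingness_range per-individual missingness for study samples is
#'   drawn uniformly from this range (aDNA-like coverage spread).
#' @param right_missingness missingness for reference individuals.
#' @param migrant_plan data.frame with columns `source_leaf`, `sink_region`,
#'   `count`, `period`: individuals whose genotypes come from `source_leaf`
#'   but who are placed (coordinates, region, period) in `sink_region`.
#' @param periods periods assigned (uniformly) to study individuals.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_sites = 50000, n_per_region = 40,
                         n_per_right = 6,
                         regions = NULL, jitter_deg = 2,
                         missingness_range = c(0.15, 0.85),
                         right_missingness = 0.02,
                         migrant_plan = NULL,
                         periods = c("Bronze Age", "Iron Age",
                                     "Imperial Rome & Late Antiquity",
                                     "Medieval Ages & Early Modern")) {
  if (is.null(regions))
    regions <- data.frame(
      region = paste0("Region", 1:6),
      leaf = paste0("Leaf", 1:6),
      lat = c(41, 38, 45, 36, 48, 40),
      lon = c(12, 23, 5, -5, 16, 44),
      stringsAsFactors = FALSE)
  if (!is.null(migrant_plan)) {
    src_reg <- regions$region[match(migrant_plan$source_leaf, regions$leaf)]
    if (any(!is.na(src_reg) & src_reg == migrant_plan$sink_region))
      stop("migrant sink region equals source region")
  }
  structure(list(n_sites = n_sites, n_per_region = n_per_region,
                 n_per_right = n_per_right, regions = regions,
                 jitter_deg = jitter_deg,
                 missingness_range = missingness_range,
                 right_missingness = right_missingness,
                 migrant_plan = migrant_plan, periods = periods),
            class = "fixture_spec")
}

#' The standard end-to-end fixture specification
#'
#' Six regional leaves x 40 study individuals, eight deep rights x 6
#' reference individuals, 50k sites, and 3% planted migrants (7 individuals
#' routed between regions), matching the scale used by the recovery
#' acceptance checks.
#'
#' @param n_sites number of sites (default 50000).
#' @param n_per_region study individuals per region (default 40).
#' @return a [fixture_spec()].
#' @export
standard_fixture_spec <- function(n_sites = 50000, n_per_region = 40) {
  # ~3% of 240 study individuals = 7 migrants, spread over distinct routes
  plan <- data.frame(
    source_leaf = c("Leaf2", "Leaf2", "Leaf3", "Leaf4", "Leaf5", "Leaf6",
                    "Leaf1"),
    sink_region = c("Region1", "Region1", "Region5", "Region2", "Region3",
                    "Region4", "Region6"),
    count = 1L,
    period = c("Imperial Rome & Late Antiquity",
               "Imperial Rome & Late Antiquity", "Iron Age",
               "Imperial Rome & Late Antiquity", "Iron Age",
               "Medieval Ages & Early Modern", "Iron Age"),
    stringsAsFactors = FALSE)
  fixture_spec(n_sites = n_sites, n_per_region = n_per_region,
               migrant_plan = plan)
}

#' Build a synthetic fixture
#'
#' Generates per-leaf allele frequencies (by default from
#' [standard_ancestry_freqs()]), draws diploid reference panels for the
#' right leaves and pseudohaploid study individuals for the regional leaves,
#' plants migrants per the migrant plan, and returns the genotypes, metadata
#' and ground truth in memory.  Use [write_fixture()] to materialize
#' EIGENSTRAT + TSV + JSON files.
#'
#' @param spec a [fixture_spec()].
#' @param freqs optional sites x leaves frequency matrix (columns must cover
#'   the spec's regional leaves plus `Right1..`); e.g. leaf columns of
#'   [drift_along_tree()] output for a pure-tree world.
#' @return list with `geno` ([geno_matrix]), `meta` (metadata data.frame
#'   incl. rights), `rights` (named vector id -> right label), `truth`
#'   (data.frame id, true_leaf, migrant, source_region).
#' @export
build_fixture <- function(spec, freqs = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (is.null(freqs))
    freqs <- standard_ancestry_freqs(
      spec$n_sites, alphas = seq(0, 1,
                                 length.out = nrow(spec$regions)))$freqs
  leaves <- colnames(freqs)
  rights <- grep("^Right", leaves, value = TRUE)
  if (!all(spec$regions$leaf %in% leaves))
    stop("region leaf not among frequency columns: ",
         paste(setdiff(spec$regions$leaf, leaves), collapse = ", "))

  calls <- list(); meta <- list(); truth <- list(); ploidy <- c()
  # reference (right) panels: diploid, low missingness
  for (r in rights) {
    g <- genotypes_from_freqs(freqs[, r], spec$n_per_right)
    if (spec$right_missingness > 0) {
      drop <- matrix(runif(length(g)) < spec$right_missingness, nrow(g))
      g[drop] <- NA_integer_
    }
    ids <- paste0(r, "_", seq_len(spec$n_per_right))
    colnames(g) <- ids
    calls[[r]] <- g
    ploidy <- c(ploidy, rep("diploid", length(ids)))
    meta[[r]] <- data.frame(id = ids, sex = "U", lat = 0, lon = -170 +
                              5 * match(r, rights), region = r,
                            period = "Present-day", role = "reference",
                            group = r, ploidy = "diploid",
                            stringsAsFactors = FALSE)
    truth[[r]] <- data.frame(id = ids, true_leaf = r, migrant = FALSE,
                             source_region = NA_character_,
                             stringsAsFactors = FALSE)
  }
  # study individuals per region (pseudohaploid, variable missingness)
  sexes <- c("M", "F")
  for (i in seq_len(nrow(spec$regions))) {
    rg <- spec$regions[i, ]
    n <- spec$n_per_region
    dip <- genotypes_from_freqs(freqs[, rg$leaf], n)
    miss <- runif(n, spec$missingness_range[1], spec$missingness_range[2])
    ph <- pseudohaploidize(dip, miss)
    ids <- paste0(rg$region, "_", seq_len(n))
    colnames(ph) <- ids
    calls[[rg$region]] <- ph
    ploidy <- c(ploidy, rep("pseudohaploid", n))
    meta[[rg$region]] <- data.frame(
      id = ids, sex = sample(sexes, n, replace = TRUE),
      lat = rg$lat + runif(n, -spec$jitter_deg, spec$jitter_deg),
      lon = rg$lon + runif(n, -spec$jitter_deg, spec$jitter_deg),
      region = rg$region,
      period = sample(spec$periods, n, replace = TRUE),
      role = "study", group = rg$region, ploidy = "pseudohaploid",
      stringsAsFactors = FALSE)
    truth[[rg$region]] <- data.frame(id = ids, true_leaf = rg$leaf,
                                     migrant = FALSE,
                                     source_region = NA_character_,
                                     stringsAsFactors = FALSE)
  }
  # planted migrants: genotypes from source leaf, metadata in sink region
  if (!is.null(spec$migrant_plan)) {
    mp <- spec$migrant_plan
    for (i in seq_len(nrow(mp))) {
      n <- mp$count[i]
      sink <- spec$regions[spec$regions$region == mp$sink_region[i], ]
      if (nrow(sink) != 1) stop("unknown sink region: ", mp$sink_region[i])
      src_region <- spec$regions$region[spec$regions$leaf ==
                                          mp$source_leaf[i]]
      if (!mp$source_leaf[i] %in% colnames(freqs))
        stop("unknown source leaf: ", mp$source_leaf[i])
      dip <- genotypes_from_freqs(freqs[, mp$source_leaf[i]], n)
      miss <- runif(n, spec$missingness_range[1], spec$missingness_range[2])
      ph <- pseudohaploidize(dip, miss)
      ids <- paste0("Mig", i, "_", mp$source_leaf[i], "_",
                    mp$sink_region[i], "_", seq_len(n))
      colnames(ph) <- ids
      key <- paste0("mig", i)
      calls[[key]] <- ph
      ploidy <- c(ploidy, rep("pseudohaploid", n))
      meta[[key]] <- data.frame(
        id = ids, sex = sample(sexes, n, replace = TRUE),
        lat = sink$lat + runif(n, -spec$jitter_deg, spec$jitter_deg),
        lon = sink$lon + runif(n, -spec$jitter_deg, spec$jitter_deg),
        region = sink$region, period = mp$period[i],
        role = "study", group = sink$region, ploidy = "pseudohaploid",
        stringsAsFactors = FALSE)
      truth[[key]] <- data.frame(
        id = ids, true_leaf = mp$source_leaf[i], migrant = TRUE,
        source_region = if (length(src_region)) src_region else
          NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  allcalls <- do.call(cbind, calls)
  meta <- do.call(rbind, meta); rownames(meta) <- NULL
  truth <- do.call(rbind, truth); rownames(truth) <- NULL
  gm <- geno_matrix(allcalls, synthetic_variants(spec$n_sites),
                    colnames(allcalls), ploidy)
  rights_map <- setNames(meta$region[meta$role == "reference"],
                         meta$id[meta$role == "reference"])
  list(geno = gm, meta = meta, rights = rights_map, truth = truth,
       leaf_freqs = freqs[, leaves, drop = FALSE])
}

#' Write a fixture to disk
#'
#' Emits `<prefix>.geno/.snp/.ind`, `<prefix>_meta.tsv` and
#' `<prefix>_truth.json`.
#'
#' @param fx output of [build_fixture()].
#' @param prefix output path prefix.
#' @return invisibly, the paths written.
#' @export
write_fixture <- function(fx, prefix) {
  ind <- data.frame(id = fx$meta$id, sex = fx$meta$sex,
                    group = fx$meta$group)
  paths <- write_eigenstrat(fx$geno, prefix, ind)
  meta_path <- paste0(prefix, "_meta.tsv")
  write.table(fx$meta, meta_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth_path <- paste0(prefix, "_truth.json")
  jsonlite::write_json(fx$truth, truth_path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(c(paths, meta = meta_path, truth = truth_path))
}

#' Null calibration of the one-component clade test
#'
#' Draws replicate pairs of pseudohaploid individuals from a single
#' panmictic population (one regional leaf of the [standard_tree()]) and
#' runs the clade test of each pair against the standard right panel.  Under
#' this null the pair always forms a clade, so p should be uniform and the
#' fraction of replicates with dissimilarity d above 1.3 estimates the
#' type-I error at the nominal 5% cutoff.
#'
#' @param n_reps number of replicate pairs.
#' @param n_sites sites per replicate (default 20000).
#' @param missingness per-individual missingness of the pseudohaploid pair.
#' @param n_per_right diploid individuals per right panel.
#' @return data.frame with one row per replicate: `T`, `df`, `p`, `d`,
#'   `n_snps`.
#' @export
simulate_clade_null <- function(n_reps = 1000, n_sites = 20000,
                                missingness = 0.3, n_per_right = 6) {
  tree <- standard_tree()
  freqs <- drift_along_tree(tree, sample_ancestral_freqs(n_sites))
  rights <- grep("^Right", tree_leaves(tree), value = TRUE)
  variants <- synthetic_variants(n_sites)
  blocks <- make_blocks(variants)
  # estimated right-panel frequencies from finite diploid samples
  rfreq <- vapply(rights, function(r)
    rowMeans(genotypes_from_freqs(freqs[, r], n_per_right)) / 2,
    numeric(n_sites))
  p_pop <- freqs[, "Leaf1"]
  out <- vector("list", n_reps)
  for (rep in seq_len(n_reps)) {
    pair <- pseudohaploidize(genotypes_from_freqs(p_pop, 2), missingness)
    counts <- list(freq = cbind(a = pair[, 1] / 2, b = pair[, 2] / 2,
                                rfreq))
    ct <- one_component_test("a", "b", rights, counts, blocks,
                             min_sites_warn = 0)
    out[[rep]] <- data.frame(T = ct$T, df = ct$df, p = ct$p, d = ct$d,
                             n_snps = ct$n_snps_used)
  }
  do.call(rbind, out)
}
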