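test_that("UPGMA flat clusters match the hand-computed dendrogram", {
  d <- matrix(c(0, 0.5, 3.0,
                0.5, 0, 3.5,
                3.0, 3.5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  cl <- upgma_flat_clusters(d, cutoff = 1.3)
  expect_equal(cl[["a"]], cl[["b"]])     # merged at 0.5
  expect_false(cl[["a"]] == cl[["c"]])   # {a,b} joins c at (3.0+3.5)/2

  dz <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_equal(length(unique(upgma_flat_clusters(dz, 1.3))), 1L)

  d10 <- matrix(10, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(d10) <- 0
  expect_equal(length(unique(upgma_flat_clusters(d10, 1.3))), 3L)

  dna <- d; dna["a", "c"] <- dna["c", "a"] <- NA
  expect_warning(upgma_flat_clusters(dna, 1.3), "imputed")
})

test_that("outlier candidacy applies the strict-5% OR at-most-2 rule", {
  cfg <- workflow_config()
  expect_equal(unname(classify_clusters(c(x = 2), 20, cfg)),
               "outlier_candidate")            # 10% but <= 2 individuals
  expect_equal(unname(classify_clusters(c(x = 4), 100, cfg)),
               "outlier_candidate")            # 4% < 5%
  expect_equal(unname(classify_clusters(c(x = 3), 60, cfg)),
               "majority")                     # exactly 5%, > 2: strict <
})

test_that("period machinery: split conserves members, prioritization walks
           backwards in time", {
  m <- data.frame(id = paste0("i", 1:5), region = "R",
                  period = c("Iron Age", "Iron Age",
                             "Imperial Rome & Late Antiquity",
                             "Iron Age", "Imperial Rome & Late Antiquity"),
                  cluster = c("c1", "c1", "c1", "c2", "c2"),
                  classification = "majority")
  sp <- split_by_period(m)
  expect_equal(length(unique(sp$rp_cluster)), 4)
  expect_equal(nrow(sp), 5)                      # members conserved
  expect_error(split_by_period(transform(m, period = "Atomic Age")),
               "unknown period")

  src <- data.frame(rp_cluster = c("s_iron", "s_imperial"),
                    period = c("Iron Age", "Imperial Rome & Late Antiquity"))
  expect_equal(prioritize_sources_by_period(
    src, "Imperial Rome & Late Antiquity"), "s_imperial")
  src2 <- data.frame(rp_cluster = c("s_bronze", "s_copper"),
                     period = c("Bronze Age", "Copper Age"))
  expect_equal(prioritize_sources_by_period(
    src2, "Imperial Rome & Late Antiquity"), "s_bronze")
  src3 <- data.frame(rp_cluster = c("s1", "s2"),
                     period = c("Iron Age", "Iron Age"))
  expect_setequal(prioritize_sources_by_period(src3, "Iron Age"),
                  c("s1", "s2"))
  expect_equal(prioritize_sources_by_period(src3[0, ], "Iron Age"),
               character())
})

test_that("network summary counts proportions and the sex chi-square
           matches the textbook formula", {
  assign <- data.frame(
    id = paste0("i", 1:50),
    region = rep(c("A", "B"), c(40, 10)),
    period = "Iron Age",
    sex = c(rep(c("M", "F"), 20), rep("M", 5), rep("F", 5)),
    cluster = "c",
    classification = c(rep("majority", 37),
                       rep("outlier_with_source", 3),
                       rep("majority", 10)),
    rp_cluster = "rp")
  net <- summarize_network(assign, NULL, workflow_config())
  pa <- net$proportions[net$proportions$region == "A", ]
  expect_equal(pa$prop_outlier, 3 / 40)          # 3 planted among 40
  expect_equal(pa$n_outlier_with_source, 3)
  expect_null(net$edges)

  # chi-square of a 3 x 2 status-by-sex table against the direct formula
  tab <- as.table(rbind(c(20, 20), c(3, 2), c(2, 3)))
  exp_tab <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat_hand <- sum((tab - exp_tab)^2 / exp_tab)
  cs <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  expect_equal(unname(cs$statistic), stat_hand, tolerance = 1e-12)
  expect_equal(unname(cs$parameter), 2)
})

test_that("pairwise dissimilarity is symmetric with a zero diagonal and
           separates leaves but not clade-mates", {
  fx <- small_fixture()
  counts <- group_allele_counts(
    fx$geno, c(setNames(fx$meta$id, fx$meta$id)[fx$meta$role == "study"],
               fx$rights))
  blocks <- make_blocks(fx$geno$variants)
  cfg <- workflow_config(min_sites_warn = 0, min_sites_error = 300)
  reg1 <- fx$meta$id[fx$meta$region == "Region1" & fx$meta$role == "study"]
  ids <- c(reg1[1:4], fx$meta$id[fx$meta$region == "Region6" &
                                   fx$meta$role == "study"][1:2])
  d <- pairwise_dissimilarity(ids, right_labels, counts, blocks, cfg)
  expect_true(all(diag(d) == 0))
  expect_equal(d, t(d))
  same <- d[1:4, 1:4][upper.tri(diag(4))]
  cross <- d[1:4, 5:6]
  expect_lt(median(same), 1.3)      # same-leaf pairs look like clades
  expect_gt(min(cross), 1.3)        # opposite cline ends do not
  lg <- attr(d, "log")
  expect_equal(nrow(lg), choose(6, 2))
})

test_that("the full workflow absorbs same-ancestry candidates, finds the
           true cross-region source and names migrants", {
  fx <- small_fixture()
  res <- run_outlier_workflow(fx$geno, fx$meta, fx$rights,
                              workflow_config(min_sites_warn = 0,
                                              min_sites_error = 300))
  cl <- res$clusters
  truth <- fx$truth[match(cl$id, fx$truth$id), ]
  detected <- cl$classification %in% c("outlier_with_source",
                                       "outlier_without_source")
  expect_gte(mean(detected[truth$migrant]), 0.8)
  expect_lte(mean(detected[!truth$migrant]), 0.05)
  # detected migrants point at their true source region
  det <- res$outliers[res$outliers$has_source, ]
  hits <- vapply(seq_len(nrow(det)), function(i) {
    members <- cl$id[cl$rp_cluster == det$rp_cluster[i]]
    true_src <- unique(truth$source_region[truth$id %in% members &
                                             truth$migrant])
    length(true_src) == 1 &&
      true_src %in% strsplit(det$source_regions[i], ";")[[1]]
  }, logical(1))
  expect_gte(mean(hits), 0.8)
  # every clustered individual sits in exactly one region_period cluster
  expect_false(any(duplicated(cl$id)))
  expect_true(all(table(cl$id) == 1))
  # totals conserved across the split
  expect_equal(nrow(cl),
               sum(fx$meta$role == "study" &
                     fx$meta$period %in%
                       workflow_config()$cluster_periods))
})

test_that("model competition keeps clade-equivalent sources and prunes a
           distant false source", {
  set.seed(60)
  S <- 15000
  am <- standard_ancestry_freqs(S, alphas = c(0, 0, 0.45, 1),
                                f_leaves = c(0.01, 0.01, 0.02, 0.02))
  fr <- am$freqs
  bl <- synthetic_blocks(S)
  # candidate drawn from Leaf1's twin ancestry (Leaf2), with Leaf3 a
  # related-but-worse source and Leaf4 unrelated
  cand <- rowMeans(genotypes_from_freqs(fr[, "Leaf2"], 3)) / 2
  mk_pool <- function(leaf, n = 8)
    rowMeans(genotypes_from_freqs(fr[, leaf], n)) / 2
  cnt <- list(freq = cbind(cand = cand, srcA = mk_pool("Leaf1"),
                           srcB = mk_pool("Leaf3"),
                           fr[, right_labels]))
  cfg <- workflow_config(min_sites_warn = 0, min_sites_error = 300)
  kept <- compete_sources("cand", c("srcA", "srcB"), right_labels, cnt, bl,
                          cfg)
  expect_true("srcA" %in% kept)
  expect_false("srcB" %in% kept)
  # single source: returned unchanged
  expect_equal(compete_sources("cand", "srcA", right_labels, cnt, bl, cfg),
               "srcA")
  # two identical-ancestry sources (pools of the same leaf): both retained
  cand1 <- rowMeans(genotypes_from_freqs(fr[, "Leaf1"], 3)) / 2
  cnt2 <- list(freq = cbind(cand = cand1, s1 = mk_pool("Leaf1"),
                            s2 = mk_pool("Leaf1"), fr[, right_labels]))
  expect_setequal(compete_sources("cand", c("s1", "s2"), right_labels,
                                  cnt2, bl, cfg), c("s1", "s2"))
})
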