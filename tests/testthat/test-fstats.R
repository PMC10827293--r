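test_that("block assignment is deterministic and chromosome-aware", {
  v <- data.frame(chrom = "1", physpos = c(1, 4999999, 5000001))
  b <- make_blocks(v, 5e6)
  expect_equal(as.integer(b), c(1L, 1L, 2L))

  v2 <- data.frame(chrom = c("1", "1", "2", "2"),
                   physpos = c(1, 2, 1, 2))
  b2 <- make_blocks(v2, 5e6)
  expect_false(any(b2[1:2] %in% b2[3:4]))   # ids never shared across chroms

  v3 <- data.frame(chrom = "1", physpos = seq(1, 2e7, length.out = 50))
  expect_equal(attr(make_blocks(v3, 5e6), "n_blocks"), 4L)

  expect_error(make_blocks(data.frame(chrom = "1", physpos = 1:10), 5e6),
               "smaller block_size_bp")
})

test_that("f4 matches hand evaluation, antisymmetry and the A=B null", {
  freq <- cbind(A = c(1, 0), B = c(0, 0), C = c(1, 1), D = c(0, 1))
  v <- data.frame(chrom = "1", physpos = c(1, 6000001))
  blocks <- make_blocks(v, 5e6)
  counts <- list(freq = freq)
  expect_equal(f4("A", "B", "C", "D", counts, blocks)$est, 0.5)
  expect_equal(f4("B", "A", "C", "D", counts, blocks)$est, -0.5)
  # A = B (identical frequencies) -> exactly zero
  freq2 <- cbind(A = c(0.3, 0.7), B = c(0.3, 0.7), C = c(1, 1),
                 D = c(0, 1))
  expect_equal(f4("A", "B", "C", "D", list(freq = freq2), blocks)$est, 0)
  # antisymmetry on a random fixture
  set.seed(5)
  fr <- matrix(runif(400), 100, 4, dimnames = list(NULL, LETTERS[1:4]))
  bl <- synthetic_blocks(100)
  expect_equal(f4("A", "B", "C", "D", list(freq = fr), bl)$est,
               -f4("B", "A", "C", "D", list(freq = fr), bl)$est)
})

test_that("f4 vector: a = b gives zeros; k = 2 reduces to a single f4;
           permuting non-base rights permutes values", {
  set.seed(6)
  fr <- matrix(runif(500 * 6), 500, 6,
               dimnames = list(NULL, c("a", "b", "R1", "R2", "R3", "R4")))
  fr[, "b"] <- fr[, "a"]
  bl <- synthetic_blocks(500)
  fv0 <- f4_vector("a", "b", c("R1", "R2", "R3"), list(freq = fr), bl,
                   min_sites_warn = 0, min_sites_error = 1)
  expect_equal(unname(fv0$values), c(0, 0))

  fr[, "b"] <- runif(500)
  cnt <- list(freq = fr)
  fv1 <- f4_vector("a", "b", c("R1", "R2"), cnt, bl,
                   min_sites_warn = 0, min_sites_error = 1)
  expect_length(fv1$values, 1)
  expect_equal(unname(fv1$values),
               f4("a", "b", "R1", "R2", cnt, bl)$est)

  fvA <- f4_vector("a", "b", c("R1", "R2", "R3", "R4"), cnt, bl,
                   min_sites_warn = 0, min_sites_error = 1)
  fvB <- f4_vector("a", "b", c("R1", "R4", "R3", "R2"), cnt, bl,
                   min_sites_warn = 0, min_sites_error = 1)
  expect_equal(unname(fvA$values), unname(fvB$values[c(3, 2, 1)]))
})

test_that("jackknife covariance equals the leave-one-block-out oracle", {
  set.seed(7)
  S <- 600
  fr <- matrix(runif(S * 5), S, 5,
               dimnames = list(NULL, c("a", "b", "R1", "R2", "R3")))
  bl <- synthetic_blocks(S)
  cnt <- list(freq = fr)
  fv <- f4_vector("a", "b", c("R1", "R2", "R3"), cnt, bl,
                  min_sites_warn = 0, min_sites_error = 1)
  cov_fast <- jackknife_cov(fv)

  # oracle: recompute the full vector from raw frequencies with each block
  # deleted, then apply the weighted-jackknife combination directly
  full_est <- function(rows) {
    ab <- fr[rows, "a"] - fr[rows, "b"]
    c(mean(ab * (fr[rows, "R1"] - fr[rows, "R2"])),
      mean(ab * (fr[rows, "R1"] - fr[rows, "R3"])))
  }
  blocks_u <- sort(unique(as.integer(bl)))
  m <- length(blocks_u)
  n_b <- vapply(blocks_u, function(b) sum(bl == b), numeric(1))
  n <- sum(n_b)
  est <- full_est(seq_len(S))
  loo <- t(vapply(blocks_u, function(b) full_est(which(bl != b)),
                  numeric(2)))
  h <- n / n_b
  est_j <- m * est - colSums((1 - 1 / h) * loo)
  tau <- outer(h, est) - (h - 1) * loo
  dev <- sweep(tau, 2, est_j)
  cov_oracle <- crossprod(dev / sqrt(h - 1)) / m
  expect_equal(unname(cov_fast), unname((cov_oracle + t(cov_oracle)) / 2),
               tolerance = 1e-10)

  # diagonal consistency with the single-f4 jackknife SE
  f1 <- f4("a", "b", "R1", "R2", cnt, bl)
  expect_equal(sqrt(cov_fast[1, 1]), f1$se, tolerance = 1e-12)

  # blocks with identical content -> zero between-block variance
  frc <- fr[rep(1:20, 30), ]
  bl_const <- structure(rep(1:30, each = 20), n_blocks = 30L)
  fvc <- f4_vector("a", "b", c("R1", "R2", "R3"), list(freq = frc),
                   bl_const, min_sites_warn = 0, min_sites_error = 1)
  expect_lt(max(abs(jackknife_cov(fvc))), 1e-12)
})

test_that("dissimilarity transform: d(0.05) = 1.3010, monotone, d(1) = 0", {
  expect_equal(dissimilarity(0.05), 1.3010, tolerance = 1e-4)
  expect_equal(dissimilarity(1), 0)
  p <- sort(runif(50))
  expect_true(all(diff(dissimilarity(p)) <= 0))
  expect_true(is.finite(dissimilarity(0)))   # floored at 1e-320
})

test_that("clade test is invariant to the choice of base reference", {
  set.seed(8)
  fr <- power_freqs(4000)$freqs
  pair <- pseudohaploidize(genotypes_from_freqs(fr[, "Leaf1"], 2), 0.1)
  cnt <- list(freq = cbind(a = pair[, 1] / 2, b = pair[, 2] / 2,
                           fr[, right_labels]))
  bl <- synthetic_blocks(4000)
  t1 <- one_component_test("a", "b", right_labels, cnt, bl,
                           min_sites_warn = 0)
  t2 <- one_component_test("a", "b", right_labels[c(4, 2, 3, 1, 5:8)], cnt,
                           bl, min_sites_warn = 0)
  expect_equal(t1$T, t2$T, tolerance = 1e-6)
  expect_equal(t1$df, t2$df)
})

test_that("clade test: null p-values are uniform, divergent pairs rejected", {
  set.seed(9)
  fr <- power_freqs(6000)$freqs
  bl <- synthetic_blocks(6000)
  # null: both individuals from one panmictic leaf
  pnull <- replicate(120, {
    pair <- pseudohaploidize(genotypes_from_freqs(fr[, "Leaf1"], 2), 0.2)
    cnt <- list(freq = cbind(a = pair[, 1] / 2, b = pair[, 2] / 2,
                             fr[, right_labels]))
    one_component_test("a", "b", right_labels, cnt, bl,
                       min_sites_warn = 0)$p
  })
  expect_gt(stats::ks.test(pnull, "punif")$p.value, 0.01)

  # power: individuals from strongly diverged leaves (opposite ancestry
  # components, leaf drift F = 0.05 each) are rejected hard
  fr50 <- power_freqs(50000, seed = 17)$freqs
  bl50 <- synthetic_blocks(50000)
  palt <- replicate(10, {
    a <- pseudohaploidize(genotypes_from_freqs(fr50[, "Leaf1"], 1), 0.2)
    b <- pseudohaploidize(genotypes_from_freqs(fr50[, "Leaf2"], 1), 0.2)
    cnt <- list(freq = cbind(a = a[, 1] / 2, b = b[, 1] / 2,
                             fr50[, right_labels]))
    one_component_test("a", "b", right_labels, cnt, bl50,
                       min_sites_warn = 0)$p
  })
  expect_gte(mean(palt < 1e-6), 0.95)
})

test_that("two-component fit recovers exact mixtures", {
  set.seed(10)
  S <- 20000
  am <- standard_ancestry_freqs(S, alphas = c(0, 1),
                                f_leaves = c(1e-6, 1e-6))
  fr <- am$freqs
  bl <- synthetic_blocks(S)
  # target constructed exactly as 0.3 * s1 + 0.7 * s2
  tgt <- 0.3 * fr[, "Leaf1"] + 0.7 * fr[, "Leaf2"]
  cnt <- list(freq = cbind(t = tgt, s1 = fr[, "Leaf1"],
                           s2 = fr[, "Leaf2"], fr[, right_labels]))
  fit <- two_component_fit("t", "s1", "s2", right_labels, cnt, bl,
                           min_sites_warn = 0)
  expect_equal(fit$alpha, 0.3, tolerance = 0.02)
  expect_gt(fit$p, 0.05)
  expect_equal(fit$df, 6)

  # degenerate mixture: target = s1
  cnt2 <- list(freq = cbind(t = fr[, "Leaf1"], s1 = fr[, "Leaf1"],
                            s2 = fr[, "Leaf2"], fr[, right_labels]))
  fit2 <- two_component_fit("t", "s1", "s2", right_labels, cnt2, bl,
                            min_sites_warn = 0)
  expect_equal(fit2$alpha, 1, tolerance = 0.02)

  # indistinguishable sources error
  cnt3 <- list(freq = cbind(t = tgt, s1 = fr[, "Leaf1"],
                            s2 = fr[, "Leaf1"], fr[, right_labels]))
  expect_error(two_component_fit("t", "s1", "s2", right_labels, cnt3, bl,
                                 min_sites_warn = 0),
               "indistinguishable")
})

test_that("usable-site thresholds warn and error as configured", {
  set.seed(11)
  fr <- matrix(runif(900 * 4), 900, 4,
               dimnames = list(NULL, c("a", "b", "R1", "R2")))
  bl <- synthetic_blocks(900)
  cnt <- list(freq = fr)
  expect_warning(
    one_component_test("a", "b", c("R1", "R2"), cnt, bl,
                       min_sites_warn = 5000, min_sites_error = 500),
    "usable sites")
  expect_error(
    one_component_test("a", "b", c("R1", "R2"), cnt, bl,
                       min_sites_warn = 5000, min_sites_error = 1000),
    "below minimum")
})
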