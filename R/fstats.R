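# f4-statistics with weighted block-jackknife covariance, the qpWave-style
# one-component (clade) test and the two-component admixture fit.
#
# All estimators work from per-group per-site allele counts as produced by
# group_allele_counts(); group frequencies of size-1 pseudohaploid samples
# are simply the 0/1 allele carried by that individual.

#' Assign sites to contiguous jackknife blocks
#'
#' Blocks are `block_size_bp` wide within each chromosome:
#' `floor((physpos - 1) / block_size_bp)`, re-indexed so block ids are never
#' shared across chromosomes.
#'
#' @param variants site table (columns `chrom`, `physpos`), sorted.
#' @param block_size_bp block width in bp (default 5e6).
#' @return integer vector of block ids (1-based, dense) per site, with
#'   attribute `n_blocks`.
#' @export
make_blocks <- function(variants, block_size_bp = 5e6) {
  stopifnot(block_size_bp > 0)
  raw <- paste(variants$chrom, (variants$physpos - 1) %/% block_size_bp)
  ids <- match(raw, unique(raw))
  nb <- length(unique(ids))
  if (nb < 2)
    stop("only ", nb, " nonempty block; choose a smaller block_size_bp ",
         "for the jackknife")
  structure(as.integer(ids), n_blocks = nb)
}

# frequencies for the named groups at usable sites; returns freq matrix
# restricted to sites where every listed group has >= 1 called allele.
.joint_usable <- function(counts, groups) {
  fr <- counts$freq[, groups, drop = FALSE]
  use <- rowSums(is.na(fr)) == 0L
  list(freq = fr, use = use)
}

#' Single f4-statistic with block-jackknife standard error
#'
#' `f4(A,B;C,D)` is the average over usable sites of
#' `(pA - pB) * (pC - pD)`; it is zero in expectation when (A,B) form a clade
#' relative to (C,D).  Sites missing (zero called alleles) in any of the four
#' groups are skipped.  The standard error comes from a weighted block
#' jackknife with block site counts as weights.
#'
#' @param a,b,c,d group labels (columns of `counts$freq`).
#' @param counts output of [group_allele_counts()].
#' @param blocks block assignment from [make_blocks()].
#' @return list with `est`, `se`, `z`, `n_snps_used`.
#' @export
f4 <- function(a, b, c, d, counts, blocks) {
  u <- .joint_usable(counts, c(a, b, c, d))
  if (!any(u$use)) stop("no usable sites for f4(", a, ",", b, ";", c, ",",
                        d, ")")
  fr <- u$freq[u$use, , drop = FALSE]
  bl <- blocks[u$use]
  prod <- (fr[, 1] - fr[, 2]) * (fr[, 3] - fr[, 4])
  bs <- rowsum(prod, bl)
  nb <- rowsum(rep(1, length(bl)), bl)
  jk <- .jackknife_moments(matrix(bs, ncol = 1), drop(nb))
  list(est = jk$est[1], se = sqrt(jk$cov[1, 1]),
       z = jk$est[1] / sqrt(jk$cov[1, 1]), n_snps_used = sum(u$use))
}

# Weighted block jackknife for a vector statistic that is a ratio-of-sums
# (here: mean over sites), following the standard weighted-jackknife
# combination with unequal block sizes.  block_sums: m x q matrix of
# per-block sums; block_n: per-block site counts.
.jackknife_moments <- function(block_sums, block_n) {
  keep <- block_n > 0
  block_sums <- block_sums[keep, , drop = FALSE]
  block_n <- block_n[keep]
  m <- length(block_n)
  if (m < 2) stop("need >= 2 nonempty blocks for the jackknife")
  n <- sum(block_n)
  tot <- colSums(block_sums)
  est <- tot / n
  # leave-one-block-out estimates, m x q
  loo <- sweep(-block_sums, 2, tot, "+") / (n - block_n)
  h <- n / block_n
  est_j <- m * est - colSums((1 - 1 / h) * loo)
  tau <- outer(h, est) - (h - 1) * loo          # pseudovalues, m x q
  dev <- sweep(tau, 2, est_j)
  covm <- crossprod(dev / sqrt(h - 1)) / m
  covm <- (covm + t(covm)) / 2
  if (any(!is.finite(covm))) stop("non-finite jackknife covariance")
  list(est = est, cov = covm, loo = loo, block_n = block_n, m = m)
}

#' f4-vector of a pair of groups against a reference panel
#'
#' For left groups `a`, `b` and right groups `rights = (base, r2, ..., rk)`,
#' computes `v_j = f4(a, b; base, r_j)` for every non-base right, on the
#' common set of sites usable in all involved groups (shared per-block
#' bookkeeping makes the jackknife covariance of the vector well defined).
#'
#' @param a,b left group labels.
#' @param rights character vector of >= 2 right-group labels; the first is
#'   the base.
#' @param counts output of [group_allele_counts()].
#' @param blocks block assignment from [make_blocks()].
#' @param min_sites_warn,min_sites_error usable-site thresholds: below the
#'   first a warning is emitted, below the second an error is thrown.
#' @return object of class `f4_vector`: list with `values`, `labels`,
#'   `block_sums` (m x (k-1)), `block_n`, `n_snps_used`.
#' @export
f4_vector <- function(a, b, rights, counts, blocks,
                      min_sites_warn = 5000, min_sites_error = 500) {
  if (length(rights) < 2) stop("need >= 2 right groups")
  for (g in rights)
    if (!g %in% colnames(counts$freq) || all(is.na(counts$freq[, g])))
      stop("right group with no usable sites: ", g)
  u <- .joint_usable(counts, c(a, b, rights))
  ns <- sum(u$use)
  if (ns < min_sites_error)
    stop("only ", ns, " usable sites for (", a, ", ", b,
         "); below minimum ", min_sites_error)
  if (ns < min_sites_warn)
    warning("only ", ns, " usable sites for (", a, ", ", b, ")")
  fr <- u$freq[u$use, , drop = FALSE]
  bl <- blocks[u$use]
  ab <- fr[, 1] - fr[, 2]
  base <- fr[, 3]
  other <- fr[, -(1:3), drop = FALSE]
  prods <- ab * (base - other)                 # ns x (k-1)
  bs <- rowsum(prods, bl)
  nb <- drop(rowsum(rep(1, length(bl)), bl))
  jk <- .jackknife_moments(bs, nb)
  structure(list(values = jk$est, labels = list(a = a, b = b,
                                                base = rights[1],
                                                rights = rights[-1]),
                 block_sums = bs, block_n = jk$block_n,
                 n_snps_used = ns),
            class = "f4_vector")
}

#' Weighted block-jackknife covariance of an f4-vector
#'
#' @param fv an [f4_vector()].
#' @return symmetric positive-semidefinite (k-1) x (k-1) covariance matrix.
#' @export
jackknife_cov <- function(fv) {
  stopifnot(inherits(fv, "f4_vector"))
  .jackknife_moments(fv$block_sums, fv$block_n)$cov
}

# Moore-Penrose pseudoinverse via SVD with relative tolerance; also reports
# the numerical rank used as effective degrees of freedom.
.pinv <- function(m, rtol = 1e-8) {
  s <- svd(m)
  keep <- s$d > rtol * max(s$d, 0)
  rank <- sum(keep)
  if (rank == 0) stop("covariance matrix numerically zero")
  inv <- s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
  list(inv = inv, rank = rank)
}

#' Dissimilarity from a clade-test p-value
#'
#' `d = -log10(max(p, p_floor))`: the scale on which individuals are
#' clustered.  The conventional cutoff d = 1.3 corresponds to a nominal
#' p of 0.05; d is monotone non-increasing in p and d(1) = 0.
#'
#' @param p p-value(s) in (0, 1].
#' @param p_floor lower bound keeping d finite (default 1e-320).
#' @return dissimilarity value(s).
#' @export
dissimilarity <- function(p, p_floor = 1e-320) {
  -log10(pmax(pmin(p, 1), p_floor))
}

#' One-component (clade) test of two groups against a reference panel
#'
#' Tests the null hypothesis that `a` and `b` form a clade relative to the
#' right groups, i.e. that the whole f4-vector is zero:
#' `T = v' Sigma^-1 v` with Sigma the block-jackknife covariance, compared to
#' a chi-square with df = k-1 (or the effective rank if Sigma is degenerate).
#' The dissimilarity is `d = -log10(max(p, 1e-320))`, so the conventional
#' clustering cutoff d = 1.3 corresponds to p = 0.05.
#'
#' @inheritParams f4_vector
#' @param p_floor lower bound applied to p before taking log10.
#' @return object of class `clade_test`: list with `T`, `df`, `p`, `d`,
#'   `n_snps_used`, `f4` (the underlying vector).
#' @export
one_component_test <- function(a, b, rights, counts, blocks,
                               min_sites_warn = 5000, min_sites_error = 500,
                               p_floor = 1e-320) {
  fv <- f4_vector(a, b, rights, counts, blocks, min_sites_warn,
                  min_sites_error)
  sig <- jackknife_cov(fv)
  pi <- .pinv(sig)
  v <- fv$values
  T <- drop(t(v) %*% pi$inv %*% v)
  T <- max(T, 0)
  p <- pchisq(T, df = pi$rank, lower.tail = FALSE)
  p <- min(max(p, p_floor), 1)
  structure(list(T = T, df = pi$rank, p = p,
                 d = dissimilarity(p, p_floor),
                 n_snps_used = fv$n_snps_used, f4 = fv),
            class = "clade_test")
}

#' @export
print.clade_test <- function(x, ...) {
  cat(sprintf("clade test: T = %.3f (df %d), p = %.3g, d = %.3f, %d SNPs\n",
              x$T, x$df, x$p, x$d, x$n_snps_used))
  invisible(x)
}

#' Two-component admixture fit
#'
#' Models `target` as a two-way mixture `alpha * s1 + (1 - alpha) * s2` via
#' generalized least squares on f4-statistics: with
#' `y_j = f4(target, s2; base, r_j)` and `X_j = f4(s1, s2; base, r_j)`,
#' `alpha = (X' S^-1 y) / (X' S^-1 X)` where S is the jackknife covariance of
#' y.  The residual statistic `T_resid = (y - alpha X)' S^-1 (y - alpha X)`
#' is compared to a chi-square with df = k-2.
#'
#' @param target,s1,s2 group labels: target and the two proposed sources.
#' @inheritParams f4_vector
#' @return list with `alpha`, `se_alpha`, `T_resid`, `df`, `p`,
#'   `n_snps_used`.
#' @export
two_component_fit <- function(target, s1, s2, rights, counts, blocks,
                              min_sites_warn = 5000, min_sites_error = 500) {
  if (length(rights) < 3)
    stop("two-component fit needs k >= 3 right groups (df = k - 2 >= 1)")
  u <- .joint_usable(counts, c(target, s1, s2, rights))
  ns <- sum(u$use)
  if (ns < min_sites_error) stop("only ", ns, " usable sites")
  if (ns < min_sites_warn) warning("only ", ns, " usable sites")
  fr <- u$freq[u$use, , drop = FALSE]
  bl <- blocks[u$use]
  base <- fr[, 4]
  rdiff <- base - fr[, -(1:4), drop = FALSE]   # (base - r_j), ns x (k-1)
  y_prod <- (fr[, 1] - fr[, 3]) * rdiff        # f4(target, s2; base, rj)
  x_prod <- (fr[, 2] - fr[, 3]) * rdiff        # f4(s1, s2; base, rj)
  nb <- drop(rowsum(rep(1, length(bl)), bl))
  jk_y <- .jackknife_moments(rowsum(y_prod, bl), nb)
  y <- jk_y$est
  X <- colSums(rowsum(x_prod, bl)) / sum(nb)
  pi <- .pinv(jk_y$cov)
  xtsx <- drop(t(X) %*% pi$inv %*% X)
  if (xtsx < 1e-12 || sum(X^2) < 1e-16)
    stop("sources indistinguishable: f4(s1, s2; base, rights) ~ 0")
  alpha <- drop(t(X) %*% pi$inv %*% y) / xtsx
  resid <- y - alpha * X
  T_resid <- max(drop(t(resid) %*% pi$inv %*% resid), 0)
  df <- length(rights) - 2
  p <- min(max(pchisq(T_resid, df = df, lower.tail = FALSE), 1e-320), 1)
  list(alpha = alpha, se_alpha = 1 / sqrt(xtsx), T_resid = T_resid,
       df = df, p = p, n_snps_used = ns)
}
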