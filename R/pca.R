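# Reference-space PCA with iterative outlier removal (smartpca-style) and
# least-squares projection of missing-data genomes; plain PCA for simulated
# genotypes.

#' PCA configuration
#'
#' @param n_pcs number of principal components (default 10).
#' @param n_outlier_iter outlier-removal rounds (default 5).
#' @param outlier_sigma removal threshold in per-PC standard deviations
#'   (default 6).
#' @param min_projected_sites minimum shared non-missing sites required to
#'   project a sample (default 1000).
#' @return list of class `pca_config`.
#' @export
pca_config <- function(n_pcs = 10, n_outlier_iter = 5, outlier_sigma = 6,
                       min_projected_sites = 1000) {
  stopifnot(n_pcs > 0, n_outlier_iter >= 0, outlier_sigma > 0,
            min_projected_sites > 0)
  structure(list(n_pcs = n_pcs, n_outlier_iter = n_outlier_iter,
                 outlier_sigma = outlier_sigma,
                 min_projected_sites = min_projected_sites),
            class = "pca_config")
}

# single PCA fit on a sites x samples dosage matrix (NA mean-imputed).
# Patterson normalization: center by site mean mu, scale by
# sqrt((mu/2)(1 - mu/2)).  Returns loadings (sites x n_pcs, column-
# orthonormal), scores (samples x n_pcs), eigenvalues, and the site stats.
.pca_fit_once <- function(calls, n_pcs) {
  mu <- rowMeans(calls, na.rm = TRUE)
  poly <- !is.na(mu) & mu > 0 & mu < 2
  calls <- calls[poly, , drop = FALSE]
  mu <- mu[poly]
  norm <- sqrt((mu / 2) * (1 - mu / 2))
  X <- (calls - mu) / norm
  X[is.na(X)] <- 0          # mean imputation of reference missingness
  n <- ncol(X)
  n_pcs <- min(n_pcs, n - 1)
  # samples x samples eigen-decomposition (sites >> samples)
  K <- crossprod(X) / nrow(X)
  eig <- eigen(K, symmetric = TRUE)
  ev <- pmax(eig$values[seq_len(n_pcs)], 0)
  U <- eig$vectors[, seq_len(n_pcs), drop = FALSE]
  # loadings: X u / ||X u||
  L <- X %*% U
  cn <- sqrt(colSums(L^2))
  cn[cn == 0] <- 1
  L <- sweep(L, 2, cn, "/")
  # deterministic sign: largest-|entry| loading positive per component
  for (k in seq_len(ncol(L))) {
    i <- which.max(abs(L[, k]))
    if (L[i, k] < 0) { L[, k] <- -L[, k]; U[, k] <- -U[, k] }
  }
  scores <- sweep(U, 2, cn, "*")   # = X' L, samples x n_pcs
  list(loadings = L, scores = scores, eigenvalues = ev, site_mean = mu,
       site_norm = norm, poly_sites = which(poly))
}

#' Fit a reference PCA model with iterative outlier removal
#'
#' Fits PCs on the reference samples (Patterson normalization; monomorphic
#' sites dropped; missing reference entries mean-imputed), then performs up
#' to `n_outlier_iter` rounds in which any reference whose score exceeds
#' `outlier_sigma` standard deviations (computed over currently retained
#' references) on any of the first `n_pcs` PCs is removed and the PCA refit.
#'
#' @param gm a [geno_matrix] of reference samples (low missingness).
#' @param config a [pca_config()].
#' @return object of class `pca_model`: loadings, eigenvalues, site ids,
#'   site means/normalizers, retained reference ids and scores, and the ids
#'   removed per iteration.
#' @export
fit_reference_pca <- function(gm, config = pca_config()) {
  stopifnot(inherits(gm, "geno_matrix"))
  calls <- gm$calls
  storage.mode(calls) <- "double"
  keep <- seq_along(gm$samples)
  removed <- list()
  fit <- NULL
  for (iter in seq_len(config$n_outlier_iter + 1)) {
    if (length(keep) < config$n_pcs)
      stop("fewer retained references (", length(keep),
           ") than requested PCs (", config$n_pcs, ")")
    fit <- .pca_fit_once(calls[, keep, drop = FALSE], config$n_pcs)
    if (iter > config$n_outlier_iter) break
    sds <- apply(fit$scores, 2, sd)
    sds[sds == 0] <- Inf
    out <- rowSums(abs(fit$scores) > config$outlier_sigma *
                     rep(sds, each = nrow(fit$scores))) > 0
    if (!any(out)) break
    removed[[length(removed) + 1]] <- gm$samples[keep][out]
    keep <- keep[!out]
  }
  structure(list(
    loadings = fit$loadings,
    eigenvalues = fit$eigenvalues,
    site_ids = gm$variants$id[fit$poly_sites],
    site_mean = fit$site_mean,
    site_norm = fit$site_norm,
    reference_ids = gm$samples[keep],
    reference_scores = fit$scores,
    removed = removed,
    config = config), class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat("pca_model: ", length(x$site_ids), " sites, ",
      length(x$reference_ids), " retained references, ",
      ncol(x$loadings), " PCs, ", length(unlist(x$removed)),
      " outliers removed\n", sep = "")
  invisible(x)
}

#' Least-squares projection of a sample onto a PCA model
#'
#' Restricted to the sample's non-missing sites shared with the model, the
#' coordinates minimize the squared error between the sample's normalized
#' dosages and the loadings-restricted reconstruction (normal-equations
#' solve).  With zero missingness this reduces exactly to the direct score
#' projection.  Pseudohaploid 0/2 calls are handled like any dosage.
#'
#' @param calls named numeric vector of dosages (names = site ids), or a
#'   [geno_matrix] (all its samples are projected).
#' @param model a `pca_model` from [fit_reference_pca()].
#' @param sample_id label used in error messages.
#' @return numeric matrix samples x n_pcs (with `n_sites_used` attribute),
#'   or a single coordinate vector for a single sample.
#' @export
lsq_project <- function(calls, model, sample_id = "sample") {
  if (inherits(calls, "geno_matrix")) {
    gm <- calls
    idx <- match(model$site_ids, gm$variants$id)
    out <- matrix(NA_real_, length(gm$samples), ncol(model$loadings),
                  dimnames = list(gm$samples, NULL))
    nuse <- integer(length(gm$samples))
    for (j in seq_along(gm$samples)) {
      x <- rep(NA_real_, length(model$site_ids))
      ok <- !is.na(idx)
      x[ok] <- gm$calls[idx[ok], j]
      names(x) <- model$site_ids
      co <- lsq_project(x, model, sample_id = gm$samples[j])
      out[j, ] <- co
      nuse[j] <- attr(co, "n_sites_used")
    }
    attr(out, "n_sites_used") <- nuse
    return(out)
  }
  idx <- match(names(calls), model$site_ids)
  obs <- !is.na(calls) & !is.na(idx)
  if (sum(obs) < model$config$min_projected_sites)
    stop("sample ", sample_id, ": only ", sum(obs),
         " usable sites shared with the PCA model (minimum ",
         model$config$min_projected_sites, ")")
  mi <- idx[obs]
  x <- (as.numeric(calls[obs]) - model$site_mean[mi]) / model$site_norm[mi]
  L <- model$loadings[mi, , drop = FALSE]
  coords <- drop(solve(crossprod(L), crossprod(L, x)))
  attr(coords, "n_sites_used") <- sum(obs)
  coords
}

#' Plain PCA of simulated genotypes with outlier removal
#'
#' Applies a dataset-wide MAF filter, then fits a plain PCA of all
#' individuals with the same iterative 6-SD outlier removal as the reference
#' fit, and returns the scores of retained individuals on the first
#' `n_pcs` PCs.
#'
#' @param gm a [geno_matrix] of simulated (complete, diploid) genotypes.
#' @param config a [pca_config()].
#' @param min_maf MAF filter threshold (default 0.01).
#' @return list with `scores` (retained samples x n_pcs), `removed` (ids per
#'   iteration), `model` (the underlying `pca_model`).
#' @export
pca_simulated <- function(gm, config = pca_config(), min_maf = 0.01) {
  gm <- apply_site_filters(gm, site_filter_spec(min_maf = min_maf))
  model <- fit_reference_pca(gm, config)
  scores <- model$reference_scores
  rownames(scores) <- model$reference_ids
  list(scores = scores, removed = model$removed, model = model)
}
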