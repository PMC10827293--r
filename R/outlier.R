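# The ancestry-outlier workflow: within-region pairwise clade tests ->
# UPGMA flat clusters -> size-based outlier candidacy -> period split ->
# within-region absorption -> cross-region source search -> model
# competition -> period prioritization -> migration-network summary.

#' Workflow configuration
#'
#' @param cluster_cutoff_d flat-clustering dissimilarity cutoff (default
#'   1.3, i.e. a nominal clade-test p of 0.05).
#' @param clade_p_threshold p-value above which a one-component model is
#'   "valid" (default 0.01; used for absorption, source search and model
#'   competition).
#' @param minority_fraction clusters below this fraction of the regional
#'   total are outlier candidates (strict `<`; default 0.05).
#' @param minority_max_n clusters of at most this many individuals are
#'   candidates regardless of fraction (default 2).
#' @param cluster_periods periods whose individuals enter the clustering
#'   (Copper Age up to, and excluding, Present-day).
#' @param time_window periods counted in regional denominators (Bronze Age
#'   up to, and excluding, Present-day).
#' @param min_sites_warn,min_sites_error usable-site thresholds passed to
#'   the clade tests.
#' @return list of class `workflow_config`.
#' @export
workflow_config <- function(cluster_cutoff_d = 1.3,
                            clade_p_threshold = 0.01,
                            minority_fraction = 0.05,
                            minority_max_n = 2,
                            cluster_periods = NULL,
                            time_window = NULL,
                            min_sites_warn = 5000,
                            min_sites_error = 500) {
  stopifnot(cluster_cutoff_d > 0, minority_fraction > 0,
            minority_fraction < 1)
  pt <- period_table()
  if (is.null(cluster_periods))
    cluster_periods <- pt$period[pt$period %in%
      c("Copper Age", "Bronze Age", "Iron Age",
        "Imperial Rome & Late Antiquity", "Medieval Ages & Early Modern")]
  if (is.null(time_window))
    time_window <- pt$period[pt$period %in%
      c("Bronze Age", "Iron Age", "Imperial Rome & Late Antiquity",
        "Medieval Ages & Early Modern")]
  structure(list(cluster_cutoff_d = cluster_cutoff_d,
                 clade_p_threshold = clade_p_threshold,
                 minority_fraction = minority_fraction,
                 minority_max_n = minority_max_n,
                 cluster_periods = cluster_periods,
                 time_window = time_window,
                 min_sites_warn = min_sites_warn,
                 min_sites_error = min_sites_error),
            class = "workflow_config")
}

#' Pairwise dissimilarity matrix from one-component tests
#'
#' Runs the clade test for every unordered pair of individuals and fills a
#' symmetric matrix of `d = -log10(p)` (diagonal 0).  Pairs that fail the
#' usable-site minimum are set NA with a warning and later imputed for
#' clustering.
#'
#' @param ids individual ids (each its own group of size 1).
#' @param rights right-group labels (first = base).
#' @param counts output of [group_allele_counts()] covering `ids` and
#'   `rights`.
#' @param blocks block assignment.
#' @param config a [workflow_config()].
#' @param log collect per-test records (pair, p, d, n_snps)?
#' @return matrix of d values; attribute `log` holds the test records.
#' @export
pairwise_dissimilarity <- function(ids, rights, counts, blocks,
                                   config = workflow_config(), log = TRUE) {
  n <- length(ids)
  if (n < 2) stop("need >= 2 individuals")
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  recs <- list()
  for (i in seq_len(n)) for (j in seq_len(i - 1)) {
    ct <- tryCatch(
      suppressWarnings(
        one_component_test(ids[i], ids[j], rights, counts, blocks,
                           min_sites_warn = config$min_sites_warn,
                           min_sites_error = config$min_sites_error)),
      error = function(e) e)
    if (inherits(ct, "error")) {
      warning("pair (", ids[i], ", ", ids[j],
              ") excluded from clustering: ", conditionMessage(ct))
      d[i, j] <- d[j, i] <- NA_real_
    } else {
      d[i, j] <- d[j, i] <- ct$d
      if (log)
        recs[[length(recs) + 1]] <- data.frame(
          a = ids[i], b = ids[j], T = ct$T, df = ct$df, p = ct$p,
          d = ct$d, n_snps = ct$n_snps_used)
    }
  }
  attr(d, "log") <- if (length(recs)) do.call(rbind, recs) else NULL
  d
}

#' UPGMA flat clusters at a dissimilarity cutoff
#'
#' Average-linkage hierarchical clustering of the dissimilarity matrix, cut
#' so that clusters are merged while the merge height is at most `cutoff`.
#' Missing entries (excluded pairs) are imputed as max(d) + 1 and flagged.
#'
#' @param d symmetric dissimilarity matrix.
#' @param cutoff flat-cluster cutoff (default 1.3).
#' @return integer cluster labels named by the matrix's rownames.
#' @export
upgma_flat_clusters <- function(d, cutoff = 1.3) {
  if (nrow(d) == 1) return(setNames(1L, rownames(d)))
  if (anyNA(d)) {
    warning("missing dissimilarities imputed as max(d) + 1")
    d[is.na(d)] <- max(d, na.rm = TRUE) + 1
  }
  hc <- hclust(as.dist(d), method = "average")
  setNames(cutree(hc, h = cutoff), rownames(d))
}

#' Classify clusters as majority or outlier candidate
#'
#' A cluster is an outlier candidate iff its size is strictly below
#' `minority_fraction` of the regional total (individuals in the configured
#' time window) OR at most `minority_max_n` individuals; otherwise it is a
#' majority cluster.
#'
#' @param sizes named integer vector of cluster sizes.
#' @param region_total regional denominator.
#' @param config a [workflow_config()].
#' @return character vector "majority" / "outlier_candidate" per cluster.
#' @export
classify_clusters <- function(sizes, region_total,
                              config = workflow_config()) {
  ifelse(sizes < config$minority_fraction * region_total |
           sizes <= config$minority_max_n,
         "outlier_candidate", "majority")
}

#' Split clusters by time period
#'
#' Each (region-level) cluster is split into homogeneous (region, period)
#' sub-clusters, retaining the parent cluster id and classification.
#'
#' @param members data.frame id, region, period, cluster, classification.
#' @return data.frame of region_period clusters: one row per individual with
#'   an added `rp_cluster` id `region_period_cluster`.
#' @export
split_by_period <- function(members) {
  period_order(members$period)   # validates labels
  members$rp_cluster <- paste(members$region, members$period,
                              members$cluster, sep = "|")
  members
}

# pooled pseudo-population counts for a set of member ids: member columns of
# the per-individual counts are summed (pooling allele counts, which gives
# the cluster more power than any individual-level test)
.pool_counts <- function(counts, ids, label) {
  sel <- intersect(ids, colnames(counts$derived))
  if (!length(sel)) stop("no counts available for cluster ", label)
  der <- rowSums(counts$derived[, sel, drop = FALSE])
  cal <- rowSums(counts$called[, sel, drop = FALSE])
  list(derived = cbind(der), called = cbind(cal))
}

# extend a counts object with pooled pseudo-populations for a list of
# clusters (named list label -> member ids)
pool_cluster_counts <- function(counts, clusters) {
  der <- counts$derived
  cal <- counts$called
  for (lab in names(clusters)) {
    pc <- .pool_counts(counts, clusters[[lab]], lab)
    der <- cbind(der, pc$derived)
    cal <- cbind(cal, pc$called)
    colnames(der)[ncol(der)] <- lab
    colnames(cal)[ncol(cal)] <- lab
  }
  freq <- der / cal
  freq[cal == 0] <- NA_real_
  list(derived = der, called = cal, freq = freq)
}

# cluster-level clade test between two pooled pseudo-populations already
# present in `counts`
.cluster_clade_p <- function(a, b, rights, counts, blocks, config) {
  ct <- tryCatch(
    suppressWarnings(
      one_component_test(a, b, rights, counts, blocks,
                         min_sites_warn = config$min_sites_warn,
                         min_sites_error = config$min_sites_error)),
    error = function(e) NULL)
  if (is.null(ct)) NA_real_ else ct$p
}

#' Run the full ancestry-outlier workflow
#'
#' @param gm a [geno_matrix] holding study individuals and reference
#'   individuals.
#' @param meta metadata (id, region, period, sex, role); reference samples
#'   have role "reference".
#' @param rights named vector id -> right-group label for the reference
#'   individuals; the first label is the f4 base group.
#' @param config a [workflow_config()].
#' @param block_size_bp jackknife block size.
#' @return object of class `outlier_result`: `clusters` (per-individual
#'   table with rp_cluster and classification), `outliers` (per
#'   region_period outlier cluster: sources before/after competition and
#'   prioritization), `network` (see [summarize_network()]), `d_matrices`,
#'   `test_log`.
#' @export
run_outlier_workflow <- function(gm, meta, rights,
                                 config = workflow_config(),
                                 block_size_bp = 5e6) {
  meta <- validate_metadata(meta)
  blocks <- make_blocks(gm$variants, block_size_bp)
  right_labels <- unique(unname(rights))
  study <- meta[meta$role != "reference" &
                  meta$period %in% config$cluster_periods, ]
  if (nrow(study) < 2) stop("fewer than 2 clusterable study individuals")
  groups <- c(setNames(study$id, study$id), rights)
  counts <- group_allele_counts(gm, groups)

  # 1) within-region pairwise d + UPGMA flat clusters
  d_mats <- list(); logs <- list(); assign <- list()
  for (rg in unique(study$region)) {
    ids <- study$id[study$region == rg]
    if (length(ids) < 2) {
      assign[[rg]] <- data.frame(id = ids, region = rg,
                                 cluster = paste0(rg, "_c1"))
      next
    }
    d <- pairwise_dissimilarity(ids, right_labels, counts, blocks, config)
    d_mats[[rg]] <- d
    logs[[rg]] <- attr(d, "log")
    cl <- upgma_flat_clusters(d, config$cluster_cutoff_d)
    assign[[rg]] <- data.frame(id = ids, region = rg,
                               cluster = paste0(rg, "_c", unname(cl)))
  }
  assign <- do.call(rbind, assign)
  assign$period <- meta$period[match(assign$id, meta$id)]
  assign$sex <- meta$sex[match(assign$id, meta$id)]

  # 2) classification on region-level clusters; denominators are the
  #    region's clustered individuals within the time window
  assign$classification <- NA_character_
  for (rg in unique(assign$region)) {
    sel <- assign$region == rg
    total <- sum(sel & assign$period %in% config$time_window)
    sizes <- table(assign$cluster[sel])
    cls <- classify_clusters(as.integer(sizes), total, config)
    names(cls) <- names(sizes)
    assign$classification[sel] <- cls[assign$cluster[sel]]
  }

  # 3) split by period
  assign <- split_by_period(assign)

  # pooled pseudo-populations for all region_period clusters
  rp_members <- split(assign$id, assign$rp_cluster)
  counts <- pool_cluster_counts(counts, rp_members)
  rp_info <- unique(assign[, c("rp_cluster", "region", "period", "cluster",
                               "classification")])
  majorities <- rp_info[rp_info$classification == "majority", ]
  candidates <- rp_info[rp_info$classification == "outlier_candidate", ]

  # 4) absorb candidates into same-region majorities (valid one-component
  #    model at p > threshold removes the candidate)
  absorbed <- character()
  for (i in seq_len(nrow(candidates))) {
    cand <- candidates$rp_cluster[i]
    maj <- majorities$rp_cluster[majorities$region == candidates$region[i]]
    for (m in maj) {
      p <- .cluster_clade_p(cand, m, right_labels, counts, blocks, config)
      if (!is.na(p) && p > config$clade_p_threshold) {
        absorbed <- c(absorbed, cand)
        break
      }
    }
  }
  assign$classification[assign$rp_cluster %in% absorbed] <- "majority"
  survivors <- candidates[!candidates$rp_cluster %in% absorbed, ]

  # 5) cross-region sources + 6) model competition + 7) period priority
  outliers <- list()
  for (i in seq_len(nrow(survivors))) {
    cand <- survivors$rp_cluster[i]
    other_maj <- majorities[majorities$region != survivors$region[i], ]
    src <- find_cross_region_sources(cand, other_maj, right_labels, counts,
                                     blocks, config)
    competed <- compete_sources(cand, src, right_labels, counts, blocks,
                                config)
    final <- prioritize_sources_by_period(
      data.frame(rp_cluster = competed,
                 period = rp_info$period[match(competed,
                                               rp_info$rp_cluster)]),
      survivors$period[i])
    outliers[[cand]] <- data.frame(
      rp_cluster = cand, region = survivors$region[i],
      period = survivors$period[i],
      n = sum(assign$rp_cluster == cand),
      n_sources_valid = length(src),
      n_sources_competed = length(competed),
      sources = paste(final, collapse = ";"),
      source_regions = paste(unique(rp_info$region[
        match(final, rp_info$rp_cluster)]), collapse = ";"),
      has_source = length(final) > 0,
      stringsAsFactors = FALSE)
  }
  outliers <- if (length(outliers)) do.call(rbind, c(outliers,
                                                     make.row.names = FALSE))
    else NULL
  if (!is.null(outliers)) {
    with_src <- outliers$rp_cluster[outliers$has_source]
    assign$classification[assign$rp_cluster %in% with_src] <-
      "outlier_with_source"
  }
  assign$classification[assign$classification == "outlier_candidate"] <-
    "outlier_without_source"

  network <- summarize_network(assign, outliers, config)
  structure(list(clusters = assign, outliers = outliers, network = network,
                 d_matrices = d_mats,
                 test_log = if (length(logs)) do.call(rbind, logs) else
                   NULL),
            class = "outlier_result")
}

#' Cross-region source search for an outlier candidate
#'
#' Tests the candidate's pooled pseudo-population against every majority
#' cluster across all other regions; majorities with a valid one-component
#' model (p above the threshold) are potential sources.
#'
#' @param cand candidate rp_cluster label (pooled counts present in
#'   `counts`).
#' @param other_majorities data.frame with column rp_cluster (majorities
#'   from other regions).
#' @param rights,counts,blocks,config as in [run_outlier_workflow()].
#' @return character vector of source rp_cluster labels (possibly empty:
#'   "outlier without source").
#' @export
find_cross_region_sources <- function(cand, other_majorities, rights,
                                      counts, blocks,
                                      config = workflow_config()) {
  src <- character()
  for (m in other_majorities$rp_cluster) {
    p <- .cluster_clade_p(cand, m, rights, counts, blocks, config)
    if (!is.na(p) && p > config$clade_p_threshold) src <- c(src, m)
  }
  src
}

#' Model competition among candidate sources
#'
#' For each potential source x, every rival source y is added (pooled) to
#' the right set in turn and the one-component model (candidate, x)
#' re-tested; if any rival rejects the model (p < threshold), x is
#' eliminated.  This only removes sub-optimal sources — it does not pick a
#' single best one.  If all sources are eliminated the candidate is demoted
#' to "outlier without source" (empty return, with a warning).
#'
#' @param cand candidate rp_cluster label.
#' @param sources character vector of potential source labels.
#' @param rights,counts,blocks,config as in [run_outlier_workflow()].
#' @return pruned character vector of sources.
#' @export
compete_sources <- function(cand, sources, rights, counts, blocks,
                            config = workflow_config()) {
  if (length(sources) < 2) return(sources)
  keep <- logical(length(sources))
  for (i in seq_along(sources)) {
    x <- sources[i]
    ok <- TRUE
    for (y in setdiff(sources, x)) {
      p <- .cluster_clade_p(cand, x, c(rights, y), counts, blocks, config)
      if (!is.na(p) && p < config$clade_p_threshold) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  if (!any(keep))
    warning("model competition eliminated every source for ", cand,
            "; demoted to outlier without source")
  sources[keep]
}

#' Prioritize sources by period
#'
#' Keeps same-period sources if any exist; otherwise the source(s) from the
#' nearest earlier period; remaining ties are considered equivalent and all
#' kept.  Sources only available from later periods are kept as-is.
#'
#' @param sources data.frame with columns rp_cluster, period.
#' @param target_period the outlier cluster's period.
#' @return character vector of prioritized source labels.
#' @export
prioritize_sources_by_period <- function(sources, target_period) {
  if (nrow(sources) == 0) return(character())
  ord <- period_order(sources$period)
  tgt <- period_order(target_period)
  if (any(ord == tgt)) return(sources$rp_cluster[ord == tgt])
  earlier <- ord[ord < tgt]
  if (length(earlier)) {
    best <- max(earlier)
    return(sources$rp_cluster[ord == best])
  }
  sources$rp_cluster
}

#' Migration network and outlier proportions
#'
#' Builds directed edges from source regions to outlier regions, per-region
#' proportions of outliers and outliers-with-source (denominator: clustered
#' individuals in the time window), and a chi-square test of sex against
#' \{non-outlier, outlier with source, outlier without source\} (df = 2).
#'
#' @param assign per-individual cluster table (from the workflow).
#' @param outliers per-outlier-cluster table (from the workflow).
#' @param config a [workflow_config()].
#' @return list of class `migration_network`: `nodes`, `edges` (data.frame
#'   source_region, outlier_region, count, clusters), `proportions`
#'   (region, n_total, n_outlier, n_outlier_with_source, prop_outlier,
#'   prop_outlier_with_source), `sex_bias` (statistic, df, p, table).
#' @export
summarize_network <- function(assign, outliers,
                              config = workflow_config()) {
  in_win <- assign$period %in% config$time_window
  props <- lapply(split(assign[in_win, ], assign$region[in_win]),
                  function(a) {
    data.frame(region = a$region[1], n_total = nrow(a),
               n_outlier = sum(a$classification %in%
                                 c("outlier_with_source",
                                   "outlier_without_source")),
               n_outlier_with_source =
                 sum(a$classification == "outlier_with_source"))
  })
  props <- do.call(rbind, c(props, make.row.names = FALSE))
  props$prop_outlier <- props$n_outlier / props$n_total
  props$prop_outlier_with_source <- props$n_outlier_with_source /
    props$n_total
  edges <- NULL
  if (!is.null(outliers) && any(outliers$has_source)) {
    el <- list()
    for (i in which(outliers$has_source)) {
      for (sr in strsplit(outliers$source_regions[i], ";")[[1]])
        el[[length(el) + 1]] <- data.frame(
          source_region = sr, outlier_region = outliers$region[i],
          cluster = outliers$rp_cluster[i], stringsAsFactors = FALSE)
    }
    el <- do.call(rbind, el)
    edges <- aggregate(cluster ~ source_region + outlier_region, el,
                       function(x) paste(unique(x), collapse = ";"))
    edges$count <- vapply(strsplit(edges$cluster, ";"), length, integer(1))
    names(edges)[names(edges) == "cluster"] <- "clusters"
  }
  # sex bias: sex x {non-outlier, outlier w/ source, outlier w/o source}
  status <- ifelse(assign$classification == "outlier_with_source",
                   "outlier_with_source",
            ifelse(assign$classification == "outlier_without_source",
                   "outlier_without_source", "non_outlier"))
  tab <- table(status, assign$sex)
  sex_bias <- NULL
  if (nrow(tab) >= 2 && ncol(tab) >= 2) {
    cs <- suppressWarnings(chisq.test(tab, correct = FALSE))
    sex_bias <- list(statistic = unname(cs$statistic),
                     df = unname(cs$parameter), p = cs$p.value, table = tab)
  }
  structure(list(nodes = unique(assign$region), edges = edges,
                 proportions = props, sex_bias = sex_bias),
            class = "migration_network")
}

#' @export
print.migration_network <- function(x, ...) {
  cat("migration network: ", length(x$nodes), " regions, ",
      if (is.null(x$edges)) 0 else nrow(x$edges), " edges\n", sep = "")
  print(x$proportions, row.names = FALSE)
  invisible(x)
}
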