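#' @useDynLib driftscape, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rbeta rbinom runif rnorm pchisq chisq.test lowess approx
#'   hclust cutree as.dist quantile cor.test sd prcomp setNames aggregate
#' @importFrom utils read.table write.table
"_PACKAGE"

# Missing genotype sentinel used throughout: NA_integer_ inside R matrices,
# written/read as '9' in EIGENSTRAT .geno payloads.

#' Historical period bins
#'
#' The seven period bins used to classify samples in time, with calendar
#' bounds in years CE (negative values are BCE).  The bins run from the
#' Mesolithic & Neolithic through Present-day; the ancestry-outlier workflow
#' clusters individuals from the Copper Age up to (but excluding) Present-day
#' and counts regional totals from the Bronze Age onward.
#'
#' @return A data.frame with columns `period`, `start_ce`, `end_ce`, `order`.
#' @export
period_table <- function() {
  data.frame(
    period = c("Mesolithic & Neolithic", "Copper Age", "Bronze Age",
               "Iron Age", "Imperial Rome & Late Antiquity",
               "Medieval Ages & Early Modern", "Present-day"),
    start_ce = c(-10000, -3500, -2300, -1000, 1, 700, 1900),
    end_ce   = c(-3500, -2300, -1000, 1, 700, 1900, Inf),
    order    = 1:7,
    stringsAsFactors = FALSE
  )
}

period_order <- function(periods, table = period_table()) {
  idx <- match(periods, table$period)
  if (anyNA(idx)) {
    bad <- unique(periods[is.na(idx)])
    stop("unknown period label(s): ", paste(bad, collapse = ", "),
         "; valid bins are: ", paste(table$period, collapse = "; "))
  }
  table$order[idx]
}

#' Construct a genotype matrix object
#'
#' A `geno_matrix` holds per-site diploid dosages (0/1/2) or pseudohaploid
#' calls (0/2) with `NA` for missing data, together with site annotations.
#' Pseudohaploid samples represent a single randomly drawn allele as a
#' homozygous call; they contribute one allele to frequency estimation,
#' diploid samples contribute two.
#'
#' @param calls integer matrix, sites x samples, values in \{0,1,2,NA\}.
#' @param variants data.frame with columns `id`, `chrom`, `genpos` (Morgans),
#'   `physpos` (bp, 1-based), `ref`, `alt`; one row per site, sorted by
#'   strictly increasing `physpos` within chromosome.
#' @param samples character vector of sample ids (column names of `calls`).
#' @param sample_ploidy per-sample ploidy, `"diploid"` or `"pseudohaploid"`;
#'   recycled if length 1.
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(calls, variants, samples,
                        sample_ploidy = "diploid") {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (nrow(calls) != nrow(variants))
    stop("calls has ", nrow(calls), " rows but variants has ",
         nrow(variants), " sites")
  if (ncol(calls) != length(samples))
    stop("calls has ", ncol(calls), " columns for ", length(samples),
         " samples")
  if (any(duplicated(samples)))
    stop("duplicated sample id: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  sample_ploidy <- rep_len(sample_ploidy, length(samples))
  if (!all(sample_ploidy %in% c("diploid", "pseudohaploid")))
    stop("sample_ploidy must be 'diploid' or 'pseudohaploid'")
  ok <- calls %in% c(0L, 1L, 2L) | is.na(calls)
  if (!all(ok)) stop("calls contain values outside {0,1,2,NA}")
  ph <- sample_ploidy == "pseudohaploid"
  if (any(ph) && any(calls[, ph, drop = FALSE] == 1L, na.rm = TRUE))
    stop("pseudohaploid samples admit only calls in {0,2,NA}")
  req <- c("id", "chrom", "genpos", "physpos", "ref", "alt")
  miss <- setdiff(req, names(variants))
  if (length(miss)) stop("variants lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (any(variants$physpos < 1)) stop("physpos must be >= 1")
  for (ch in unique(variants$chrom)) {
    pp <- variants$physpos[variants$chrom == ch]
    if (any(diff(pp) <= 0))
      stop("physpos not strictly increasing on chromosome ", ch)
  }
  rownames(calls) <- variants$id
  colnames(calls) <- samples
  structure(list(calls = calls, variants = variants,
                 samples = as.character(samples),
                 sample_ploidy = sample_ploidy),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  nmiss <- mean(is.na(x$calls))
  cat("geno_matrix: ", nrow(x$calls), " sites x ", length(x$samples),
      " samples (", sum(x$sample_ploidy == "pseudohaploid"),
      " pseudohaploid), ", sprintf("%.1f%%", 100 * nmiss), " missing\n",
      sep = "")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix by sites and/or samples
#' @param gm a `geno_matrix`.
#' @param sites logical/integer index over sites, or NULL for all.
#' @param samples character ids or index over samples, or NULL for all.
#' @return a `geno_matrix`.
#' @export
subset_geno <- function(gm, sites = NULL, samples = NULL) {
  if (is.null(sites)) sites <- seq_len(nrow(gm$calls))
  if (is.null(samples)) samples <- seq_along(gm$samples)
  if (is.character(samples)) {
    idx <- match(samples, gm$samples)
    if (anyNA(idx)) stop("unknown sample id(s): ",
                         paste(samples[is.na(idx)], collapse = ", "))
    samples <- idx
  }
  geno_matrix(gm$calls[sites, samples, drop = FALSE],
              gm$variants[sites, , drop = FALSE],
              gm$samples[samples], gm$sample_ploidy[samples])
}

#' Read plain-text EIGENSTRAT genotype files
#'
#' Reads the transparent (non-packed) EIGENSTRAT dialect: `.geno` has one row
#' per site and one digit per sample (9 = missing), `.snp` has columns id,
#' chromosome, genetic position (Morgans), physical position, ref, alt, and
#' `.ind` has id, sex, group.
#'
#' @param prefix path prefix; `<prefix>.geno`, `.snp`, `.ind` must exist.
#'   Alternatively pass explicit paths via `geno`, `snp`, `ind`.
#' @param geno,snp,ind explicit file paths (override `prefix`).
#' @param sample_ploidy per-sample ploidy; `"auto"` (default) marks a sample
#'   pseudohaploid iff it has no heterozygous call.
#' @return list with elements `geno` (a [geno_matrix]) and `ind`
#'   (data.frame id, sex, group).
#' @export
read_eigenstrat <- function(prefix = NULL, geno = NULL, snp = NULL,
                            ind = NULL, sample_ploidy = "auto") {
  if (!is.null(prefix)) {
    if (is.null(geno)) geno <- paste0(prefix, ".geno")
    if (is.null(snp))  snp  <- paste0(prefix, ".snp")
    if (is.null(ind))  ind  <- paste0(prefix, ".ind")
  }
  for (f in c(geno, snp, ind))
    if (!file.exists(f)) stop("file not found: ", f)
  indtab <- read.table(ind, header = FALSE, stringsAsFactors = FALSE,
                       col.names = c("id", "sex", "group"))
  snptab <- read.table(snp, header = FALSE, stringsAsFactors = FALSE,
                       col.names = c("id", "chrom", "genpos", "physpos",
                                     "ref", "alt"),
                       colClasses = c("character", "character", "numeric",
                                      "integer", "character", "character"))
  lines <- readLines(geno)
  nsamp <- nrow(indtab)
  if (length(lines) != nrow(snptab))
    stop(".geno has ", length(lines), " rows but .snp has ",
         nrow(snptab), " sites")
  nc <- nchar(lines)
  bad <- which(nc != nsamp)
  if (length(bad))
    stop("row ", bad[1], ": ", nc[bad[1]], " genotypes for ",
         nsamp, " samples")
  # char digits -> integers in one pass
  codes <- utf8ToInt(paste(lines, collapse = "")) - utf8ToInt("0")
  if (any(codes < 0 | codes > 9)) {
    pos <- which(codes < 0 | codes > 9)[1]
    stop("non-digit genotype character at site ",
         (pos - 1) %/% nsamp + 1, ", sample ", (pos - 1) %% nsamp + 1)
  }
  calls <- matrix(as.integer(codes), nrow = nsamp, ncol = length(lines))
  calls <- t(calls)
  calls[calls == 9L] <- NA_integer_
  if (any(!is.na(calls) & calls > 2L))
    stop("genotype digit > 2 (and not 9) found in .geno")
  if (identical(sample_ploidy, "auto")) {
    has_het <- apply(calls == 1L, 2, any, na.rm = TRUE)
    sample_ploidy <- ifelse(has_het, "diploid", "pseudohaploid")
  }
  list(geno = geno_matrix(calls, snptab, indtab$id, sample_ploidy),
       ind = indtab)
}

#' Write plain-text EIGENSTRAT genotype files
#'
#' @param gm a [geno_matrix].
#' @param out_prefix output path prefix (directories must exist).
#' @param ind optional data.frame with columns id, sex, group; defaults to
#'   sex "U" and group = sample id.
#' @return invisibly, the three file paths written.
#' @export
write_eigenstrat <- function(gm, out_prefix, ind = NULL) {
  stopifnot(inherits(gm, "geno_matrix"))
  calls <- gm$calls
  calls[is.na(calls)] <- 9L
  lines <- apply(calls, 1, paste, collapse = "")
  geno_path <- paste0(out_prefix, ".geno")
  writeLines(lines, geno_path)
  snp_path <- paste0(out_prefix, ".snp")
  v <- gm$variants
  write.table(data.frame(v$id, v$chrom, format(v$genpos, scientific = FALSE),
                         v$physpos, v$ref, v$alt),
              snp_path, quote = FALSE, row.names = FALSE, col.names = FALSE,
              sep = "\t")
  ind_path <- paste0(out_prefix, ".ind")
  if (is.null(ind))
    ind <- data.frame(id = gm$samples, sex = "U", group = gm$samples)
  write.table(ind[, c("id", "sex", "group")], ind_path, quote = FALSE,
              row.names = FALSE, col.names = FALSE, sep = "\t")
  invisible(c(geno = geno_path, snp = snp_path, ind = ind_path))
}

#' Read and validate a sample metadata table
#'
#' Tab-separated with header; required columns `id`, `lat`, `lon`, `region`,
#' `period`.  Optional columns `sex`, `group`, `date_ce`, `role`, `ploidy`
#' are passed through (with defaults filled in when absent).
#'
#' @param tsv_path path to the metadata TSV.
#' @param periods valid period table (default [period_table()]).
#' @return data.frame of validated sample records.
#' @export
read_metadata <- function(tsv_path, periods = period_table()) {
  if (!file.exists(tsv_path)) stop("file not found: ", tsv_path)
  md <- read.table(tsv_path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, quote = "", comment.char = "")
  validate_metadata(md, periods)
}

validate_metadata <- function(md, periods = period_table()) {
  req <- c("id", "lat", "lon", "region", "period")
  miss <- setdiff(req, names(md))
  if (length(miss)) stop("metadata lacks required column(s): ",
                         paste(miss, collapse = ", "))
  if (any(duplicated(md$id)))
    stop("duplicated sample id: ",
         paste(unique(md$id[duplicated(md$id)]), collapse = ", "))
  badlat <- md$lat < -90 | md$lat > 90
  if (any(badlat)) stop("latitude out of [-90,90] for sample ",
                        md$id[which(badlat)[1]])
  badlon <- md$lon < -180 | md$lon >= 180
  if (any(badlon)) stop("longitude out of [-180,180) for sample ",
                        md$id[which(badlon)[1]])
  period_order(md$period, periods)   # errors on unknown labels
  if (is.null(md$sex)) md$sex <- "U"
  if (is.null(md$role)) md$role <- "study"
  if (is.null(md$ploidy)) md$ploidy <- "diploid"
  md
}

#' Site filter specification
#'
#' @param min_maf minimum dataset-wide minor allele frequency in [0, 0.5];
#'   computed over non-missing calls across all samples.
#' @param exclusion_list character vector of site ids to drop (e.g. a
#'   precomputed list of transitions at CpG sites).
#' @param drop_transitions drop all A<->G and C<->T sites.
#' @return list of class `site_filter_spec`.
#' @export
site_filter_spec <- function(min_maf = 0.01, exclusion_list = character(),
                             drop_transitions = FALSE) {
  if (min_maf < 0 || min_maf > 0.5) stop("min_maf must be in [0, 0.5]")
  structure(list(min_maf = min_maf,
                 exclusion_list = as.character(exclusion_list),
                 drop_transitions = isTRUE(drop_transitions)),
            class = "site_filter_spec")
}

#' Apply site filters to a genotype matrix
#'
#' Keeps sites whose dataset-wide minor allele frequency (alleles counted
#' once per pseudohaploid call, twice per diploid call, missing excluded) is
#' at least `spec$min_maf`, that are not on the exclusion list, and — if
#' `drop_transitions` — are not A/G or C/T sites.  Idempotent.
#'
#' @param gm a [geno_matrix].
#' @param spec a [site_filter_spec()].
#' @return filtered `geno_matrix`; errors if no site survives.
#' @export
apply_site_filters <- function(gm, spec) {
  stopifnot(inherits(gm, "geno_matrix"), inherits(spec, "site_filter_spec"))
  cnt <- group_allele_counts(gm, setNames(rep("all", length(gm$samples)),
                                          gm$samples))
  der <- cnt$derived[, 1]; called <- cnt$called[, 1]
  freq <- ifelse(called > 0, der / called, 0)
  maf <- pmin(freq, 1 - freq)
  keep <- called > 0 & maf >= spec$min_maf
  keep <- keep & !(gm$variants$id %in% spec$exclusion_list)
  if (spec$drop_transitions) {
    pair <- paste0(pmin(gm$variants$ref, gm$variants$alt),
                   pmax(gm$variants$ref, gm$variants$alt))
    keep <- keep & !(pair %in% c("AG", "CT"))
  }
  if (!any(keep)) stop("site filters removed all sites")
  subset_geno(gm, sites = which(keep))
}

#' Per-group derived-allele counts
#'
#' For each site and group, counts derived alleles and called alleles.  Each
#' non-missing pseudohaploid call contributes one allele (0 -> 0/1, 2 ->
#' 1/1); each diploid call contributes two (dosage / 2).  Sites where a group
#' has zero called alleles are uninformative for that group (called = 0).
#'
#' @param gm a [geno_matrix].
#' @param groups named character vector mapping sample id -> group label.
#' @return list with matrices `derived` and `called` (sites x groups) and
#'   `freq` = derived/called (NA where called is 0).
#' @export
group_allele_counts <- function(gm, groups) {
  stopifnot(inherits(gm, "geno_matrix"))
  ids <- names(groups)
  if (is.null(ids)) stop("groups must be a named vector (id -> label)")
  idx <- match(ids, gm$samples)
  if (anyNA(idx)) stop("grouped sample(s) not in matrix: ",
                       paste(ids[is.na(idx)], collapse = ", "))
  labels <- unique(unname(groups))
  S <- nrow(gm$calls)
  der <- called <- matrix(0, S, length(labels),
                          dimnames = list(NULL, labels))
  for (lab in labels) {
    cols <- idx[groups == lab]
    if (!length(cols)) stop("empty group: ", lab)
    sub <- gm$calls[, cols, drop = FALSE]
    ph <- gm$sample_ploidy[cols] == "pseudohaploid"
    w_called <- ifelse(ph, 1, 2)           # alleles per non-missing call
    obs <- !is.na(sub)
    # derived alleles: pseudohaploid 2 -> 1; diploid dosage as-is
    dmat <- sub
    dmat[is.na(dmat)] <- 0L
    if (any(ph)) dmat[, ph] <- dmat[, ph, drop = FALSE] / 2L
    der[, lab] <- rowSums(dmat)
    called[, lab] <- obs %*% w_called
  }
  freq <- der / called
  freq[called == 0] <- NA_real_
  list(derived = der, called = called, freq = freq)
}
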