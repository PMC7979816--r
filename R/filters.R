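#' SNP and sample filters
#'
#' The filters mirror the study's pipeline: sites or accessions with more
#' than 20% missing calls are discarded (strictly greater; a missing rate of
#' exactly the threshold is retained), minor-allele-frequency filters use
#' allele counts over non-missing calls, singletons are sites whose minor
#' allele is observed exactly once, and distance thinning keeps SNPs at
#' least 20 kb apart by a greedy left-to-right scan per chromosome.
#'
#' Each filter returns a genotype_matrix with site/sample order preserved
#' and attaches a `filter_report` attribute row (name, sites and samples
#' before/after) so a chain of filters yields an auditable report.
#'
#' @name variant_filters
NULL

add_report <- function(out, gm, name) {
  prev <- attr(gm, "filter_report")
  row <- data.frame(filter = name,
                    sites_before = ncol(gm$geno), sites_after = ncol(out$geno),
                    samples_before = nrow(gm$geno), samples_after = nrow(out$geno),
                    stringsAsFactors = FALSE)
  attr(out, "filter_report") <- rbind(prev, row)
  out
}

#' @param gm genotype_matrix.
#' @param max_rate maximum tolerated missing fraction (default 0.2).
#' @return genotype_matrix with failing sites (or samples) removed.
#' @rdname variant_filters
#' @export
filter_site_missing <- function(gm, max_rate = 0.2) {
  miss <- colMeans(is.na(gm$geno))
  add_report(gm_subset(gm, sites = miss <= max_rate), gm, "site_missing")
}

#' @rdname variant_filters
#' @export
filter_sample_missing <- function(gm, max_rate = 0.2) {
  miss <- rowMeans(is.na(gm$geno))
  if (ncol(gm$geno) == 0L) miss <- rep(0, nrow(gm$geno))
  add_report(gm_subset(gm, samples = miss <= max_rate), gm, "sample_missing")
}

#' @param threshold MAF cut point in \[0, 0.5\].
#' @param comparator `"gt"` keeps sites with MAF strictly above the
#'   threshold, `"ge"` keeps MAF at or above it.
#' @rdname variant_filters
#' @export
filter_maf <- function(gm, threshold = 0.05, comparator = c("gt", "ge")) {
  comparator <- match.arg(comparator)
  stopifnot(threshold >= 0, threshold <= 0.5)
  maf <- site_maf(gm)
  keep <- if (comparator == "gt") maf > threshold else maf >= threshold
  add_report(gm_subset(gm, sites = keep), gm, paste0("maf_", comparator, "_", threshold))
}

#' @rdname variant_filters
#' @export
remove_singletons <- function(gm) {
  ac <- site_allele_counts(gm)
  minor <- pmin(ac[, "alt"], ac[, "total"] - ac[, "alt"])
  add_report(gm_subset(gm, sites = minor != 1L), gm, "singletons")
}

#' Classify SNPs relative to gene models
#'
#' Each site gets exactly one class with precedence exonic > intronic >
#' proximal > intergenic: `exonic` inside a CDS interval, `intronic` inside
#' the CDS envelope of a gene but outside its CDS intervals, `proximal`
#' within `window` bases of a gene's CDS envelope, otherwise `intergenic`.
#'
#' @param gm genotype_matrix.
#' @param ann gene_annotation (see [read_gff_cds()]).
#' @param window proximal flank in bases (default 2000, i.e. +/- 2 kb).
#' @return character vector, one class per site.
#' @export
classify_sites <- function(gm, ann, window = 2000) {
  sites <- gm$sites
  out <- rep("intergenic", nrow(sites))
  if (!nrow(ann) || !nrow(sites)) return(out)
  genes <- split(ann, ann$gene_id)
  env <- do.call(rbind, lapply(genes, function(d)
    data.frame(chrom = d$chrom[1], start = min(d$start), end = max(d$end))))
  for (ci in unique(sites$chrom)) {
    idx <- which(sites$chrom == ci)
    pos <- sites$pos[idx]
    a <- ann[ann$chrom == ci, , drop = FALSE]
    e <- env[env$chrom == ci, , drop = FALSE]
    if (!nrow(e)) next
    exonic <- outer(pos, a$start, ">=") & outer(pos, a$end, "<=")
    exonic <- rowSums(exonic) > 0
    inenv <- outer(pos, e$start, ">=") & outer(pos, e$end, "<=")
    inenv <- rowSums(inenv) > 0
    near <- outer(pos, e$start - window, ">=") & outer(pos, e$end + window, "<=")
    near <- rowSums(near) > 0
    cls <- ifelse(exonic, "exonic",
                  ifelse(inenv, "intronic",
                         ifelse(near, "proximal", "intergenic")))
    out[idx] <- cls
  }
  out
}

#' @param classes site classes aligned with `gm` (from [classify_sites()]).
#' @rdname variant_filters
#' @export
drop_genic <- function(gm, classes) {
  stopifnot(length(classes) == ncol(gm$geno))
  add_report(gm_subset(gm, sites = !(classes %in% c("exonic", "intronic"))),
             gm, "drop_genic")
}

#' @param min_gap minimum distance between retained SNPs in bases
#'   (default 20000). Input sites must be sorted by (chrom, pos); the scan
#'   is greedy left-to-right and restarts on each chromosome.
#' @rdname variant_filters
#' @export
thin_by_distance <- function(gm, min_gap = 20000) {
  sites <- gm$sites
  if (nrow(sites) > 1) {
    o <- order(sites$chrom, sites$pos)
    if (!identical(o, seq_len(nrow(sites))))
      stop("sites must be sorted by (chrom, pos) before thinning")
  }
  keep <- logical(nrow(sites))
  last_chrom <- NA_character_
  last_pos <- -Inf
  for (i in seq_len(nrow(sites))) {
    if (!identical(sites$chrom[i], last_chrom) || sites$pos[i] - last_pos >= min_gap) {
      keep[i] <- TRUE
      last_chrom <- sites$chrom[i]
      last_pos <- sites$pos[i]
    }
  }
  add_report(gm_subset(gm, sites = keep), gm, paste0("thin_", min_gap))
}

#' Retrieve the accumulated filter report
#'
#' @param gm genotype_matrix that went through one or more filters.
#' @return data.frame with one row per applied filter.
#' @export
filter_report <- function(gm) {
  rep <- attr(gm, "filter_report")
  if (is.null(rep))
    rep <- data.frame(filter = character(0), sites_before = integer(0),
                      sites_after = integer(0), samples_before = integer(0),
                      samples_after = integer(0))
  rep
}

#' Per-group SNP counts
#'
#' For each sample group: the number of sites polymorphic within the group
#' and the counts of sites with within-group MAF at or above 1% and 5%,
#' mirroring a diversity-panel summary table.
#'
#' @param gm genotype_matrix.
#' @param groups named list of sample-id vectors.
#' @return data.frame with columns `group`, `n_samples`, `polymorphic`,
#'   `maf_ge_1`, `maf_ge_5`.
#' @export
summarize_counts <- function(gm, groups) {
  stopifnot(is.list(groups), length(groups) > 0)
  rows <- lapply(names(groups), function(g) {
    ids <- groups[[g]]
    if (!length(ids)) stop("empty sample group: ", g)
    missing_ids <- setdiff(ids, gm$samples$sample_id)
    if (length(missing_ids))
      stop("group ", g, " names unknown sample(s): ",
           paste(missing_ids, collapse = ", "))
    sub <- gm_subset(gm, samples = match(ids, gm$samples$sample_id))
    maf <- site_maf(sub)
    data.frame(group = g, n_samples = length(ids),
               polymorphic = sum(maf > 0),
               maf_ge_1 = sum(maf >= 0.01 & maf > 0),
               maf_ge_5 = sum(maf >= 0.05),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
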