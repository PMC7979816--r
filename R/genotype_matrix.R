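#' Genotype matrix container
#'
#' Bundles a samples-by-sites grid of diploid alt-allele counts (0, 1, 2,
#' `NA` for missing) with per-sample and per-site metadata. This is the
#' substrate every filtering, structure, SFS and GWAS operation works on.
#'
#' @param geno integer matrix, samples in rows, sites in columns; entries in
#'   \{0, 1, 2, NA\}.
#' @param samples data.frame with columns `sample_id`, `subspecies`,
#'   `origin`, `population` (optional, `NA` allowed).
#' @param sites data.frame with columns `chrom`, `pos`, `ref`, `alt`; a
#'   `subgenome` column is derived from `chrom` if absent.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, samples, sites) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  samples <- validate_samples(samples)
  sites <- validate_sites(sites)
  if (nrow(geno) != nrow(samples))
    stop("geno has ", nrow(geno), " rows but ", nrow(samples), " samples")
  if (ncol(geno) != nrow(sites))
    stop("geno has ", ncol(geno), " columns but ", nrow(sites), " sites")
  bad <- geno[!is.na(geno)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stop("genotype codes must be 0, 1, 2 or NA")
  rownames(geno) <- samples$sample_id
  structure(list(geno = geno, samples = samples, sites = sites),
            class = "genotype_matrix")
}

SUBSPECIES_LEVELS <- c("aestivum", "spelta", "cross")
ORIGIN_LEVELS <- c("Asia", "CentralEurope", "Iberia", "Africa", "America", "other")

validate_samples <- function(samples) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need <- c("sample_id", "subspecies", "origin")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("samples table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stop("duplicated sample_id: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]), collapse = ", "))
  bad <- setdiff(stats::na.omit(unique(samples$subspecies)), SUBSPECIES_LEVELS)
  if (length(bad)) stop("unknown subspecies label(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(stats::na.omit(unique(samples$origin)), ORIGIN_LEVELS)
  if (length(bad)) stop("unknown origin label(s): ", paste(bad, collapse = ", "))
  if (is.null(samples$population)) samples$population <- NA_character_
  samples
}

validate_sites <- function(sites) {
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(sites))
  if (length(miss)) stop("sites table lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(sites)) {
    if (any(sites$pos < 1)) stop("positions are 1-based; pos >= 1 required")
    if (any(sites$ref == sites$alt)) stop("ref and alt alleles must differ")
  }
  sites$pos <- as.integer(sites$pos)
  if (is.null(sites$subgenome)) sites$subgenome <- subgenome_of(sites$chrom)
  sites
}

#' Derive the subgenome from a chromosome name
#'
#' The trailing alphabetic character of the chromosome name identifies the
#' wheat subgenome (`1A`..`7D`); anything else maps to `"unanchored"`. The
#' mapping is total: every string maps to exactly one class.
#'
#' @param chrom character vector of chromosome names.
#' @return character vector over \{"A","B","D","unanchored"\}.
#' @export
subgenome_of <- function(chrom) {
  last <- sub("^.*?([A-Za-z])$", "\\1", as.character(chrom))
  out <- ifelse(last %in% c("A", "B", "D"), last, "unanchored")
  out[is.na(chrom)] <- "unanchored"
  out
}

#' @export
print.genotype_matrix <- function(x, ...) {
  miss <- mean(is.na(x$geno))
  cat("genotype_matrix:", nrow(x$geno), "samples x", ncol(x$geno), "sites;",
      sprintf("%.1f%% missing\n", 100 * miss))
  tab <- table(factor(x$sites$subgenome, c("A", "B", "D", "unanchored")))
  cat("  subgenomes:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

#' Subset a genotype matrix by sites and/or samples
#'
#' @param gm genotype_matrix.
#' @param sites logical or integer index over sites.
#' @param samples logical or integer index over samples.
#' @return genotype_matrix restricted to the selection, order preserved.
#' @export
gm_subset <- function(gm, sites = NULL, samples = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  geno <- gm$geno
  st <- gm$sites
  sm <- gm$samples
  if (!is.null(sites)) {
    geno <- geno[, sites, drop = FALSE]
    st <- st[sites, , drop = FALSE]
  }
  if (!is.null(samples)) {
    geno <- geno[samples, , drop = FALSE]
    sm <- sm[samples, , drop = FALSE]
  }
  rownames(st) <- NULL
  rownames(sm) <- NULL
  genotype_matrix(geno, sm, st)
}

# per-site counts over non-missing calls: alt alleles, total alleles
site_allele_counts <- function(gm) {
  nonmiss <- colSums(!is.na(gm$geno))
  alt <- colSums(gm$geno, na.rm = TRUE)
  cbind(alt = alt, total = 2L * nonmiss)
}

#' Per-site minor allele frequency
#'
#' Computed over non-missing alleles; all-missing sites get MAF 0.
#'
#' @param gm genotype_matrix.
#' @return numeric vector in \[0, 0.5\].
#' @export
site_maf <- function(gm) {
  ac <- site_allele_counts(gm)
  f <- ifelse(ac[, "total"] > 0, ac[, "alt"] / ac[, "total"], 0)
  pmin(f, 1 - f)
}
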