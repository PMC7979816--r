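#' Read biallelic SNP genotypes from a VCF file
#'
#' Parses a VCF (via \pkg{vcfR}), keeps biallelic SNP records only (single
#' reference and alternate base), and converts diploid GT fields to
#' alt-allele counts: `0/0` to 0, `0/1` or `1/0` to 1, `1/1` to 2, `./.` to
#' missing. Phase separators (`|`) are accepted and ignored; GBS calls are
#' unphased. The number of retained records is reported with a message.
#'
#' @param path VCF file path.
#' @param samples optional sample metadata data.frame (`sample_id`,
#'   `subspecies`, `origin`, `population`) matched by sample id; VCF sample
#'   order wins.
#' @return genotype_matrix; zero sites (with a warning) when no biallelic
#'   SNP record survives.
#' @export
read_vcf <- function(path, samples = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  ids <- colnames(v@gt)[-1]
  if (nrow(fix) == 0L) {
    warning("no variant records in ", path)
    return(empty_gm(ids, samples))
  }
  keep <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T") &
    !is.na(fix$ALT)
  message(sum(keep), " of ", nrow(fix), " records retained as biallelic SNPs")
  if (!any(keep)) {
    warning("no biallelic SNP records retained from ", path)
    return(empty_gm(ids, samples))
  }
  gt <- vcfR::extract.gt(v[keep, ], element = "GT")
  codes <- gt_to_codes(gt) # sites x samples
  sites <- data.frame(chrom = fix$CHROM[keep], pos = as.integer(fix$POS[keep]),
                      ref = fix$REF[keep], alt = fix$ALT[keep],
                      stringsAsFactors = FALSE)
  genotype_matrix(t(codes), sample_frame(ids, samples), sites)
}

gt_to_codes <- function(gt) {
  core <- sub("^([^:]*).*$", "\\1", gt)
  core <- gsub("|", "/", core, fixed = TRUE)
  codes <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  codes[core == "0/0"] <- 0L
  codes[core %in% c("0/1", "1/0")] <- 1L
  codes[core == "1/1"] <- 2L
  unknown <- !is.na(core) & !(core %in% c("0/0", "0/1", "1/0", "1/1", "./.", "."))
  if (any(unknown))
    stop("unparseable GT value(s), e.g. ", core[unknown][1])
  codes
}

sample_frame <- function(ids, samples = NULL) {
  out <- data.frame(sample_id = ids, subspecies = NA_character_,
                    origin = NA_character_, population = NA_character_,
                    stringsAsFactors = FALSE)
  if (!is.null(samples)) {
    samples <- validate_samples(samples)
    m <- match(ids, samples$sample_id)
    for (col in c("subspecies", "origin", "population"))
      out[[col]] <- samples[[col]][m]
  }
  out
}

empty_gm <- function(ids, samples = NULL) {
  genotype_matrix(matrix(integer(0), nrow = length(ids), ncol = 0),
                  sample_frame(ids, samples),
                  data.frame(chrom = character(0), pos = integer(0),
                             ref = character(0), alt = character(0)))
}

#' Write a genotype matrix as plain-text VCF
#'
#' Emits a minimal VCF v4.2 with GT-only FORMAT; codes map back to `0/0`,
#' `0/1`, `1/1` and missing to `./.`, so `read_vcf(write_vcf(gm))`
#' round-trips codes, positions and alleles exactly.
#'
#' @param gm genotype_matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=speltpop",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", gm$samples$sample_id), collapse = "\t")),
             con)
  if (ncol(gm$geno) > 0L) {
    gtmap <- c("0/0", "0/1", "1/1")
    gt <- matrix("./.", nrow = ncol(gm$geno), ncol = nrow(gm$geno))
    idx <- !is.na(t(gm$geno))
    gt[idx] <- gtmap[t(gm$geno)[idx] + 1L]
    body <- cbind(gm$sites$chrom, gm$sites$pos, ".", gm$sites$ref,
                  gm$sites$alt, ".", "PASS", ".", "GT", gt)
    writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  }
  invisible(path)
}

#' Read phenotype, sample and gene-annotation tables
#'
#' @param phenotype_path tab-separated file with columns `sample_id`,
#'   `glume_color` (labels `red`, `white`, `missing`).
#' @param samples_path tab-separated file with columns `sample_id`,
#'   `subspecies`, `origin` and optionally `population`.
#' @param gff_path GFF3 file; CDS features are read and grouped by gene.
#' @return list with elements `phenotype` (named vector sample_id ->
#'   glume_color), `samples` (data.frame) and `annotation`
#'   (gene_annotation).
#' @export
read_tables <- function(phenotype_path, samples_path, gff_path) {
  list(phenotype = read_phenotype(phenotype_path),
       samples = validate_samples(read.delim(samples_path, stringsAsFactors = FALSE)),
       annotation = read_gff_cds(gff_path))
}

#' @rdname read_tables
#' @export
read_phenotype <- function(phenotype_path) {
  tab <- read.delim(phenotype_path, stringsAsFactors = FALSE)
  need <- c("sample_id", "glume_color")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("phenotype table lacks column(s): ", paste(miss, collapse = ", "))
  bad <- !(tab$glume_color %in% c("red", "white", "missing") | is.na(tab$glume_color))
  if (any(bad))
    stop("unknown glume_color label(s) in row(s) ",
         paste(which(bad), collapse = ", "), ": ",
         paste(unique(tab$glume_color[bad]), collapse = ", "))
  ph <- tab$glume_color
  ph[ph == "missing"] <- NA_character_
  setNames(ph, tab$sample_id)
}

#' Parse CDS intervals per gene from a GFF3 file
#'
#' Only `CDS` features are used. The gene id is taken from the `Parent`
#' attribute when present, otherwise `ID`. Overlapping CDS intervals of a
#' gene are merged so intervals are disjoint.
#'
#' @param gff_path GFF3 file path.
#' @return data.frame of class `gene_annotation` with columns `gene_id`,
#'   `chrom`, `strand`, `start`, `end` (1-based inclusive).
#' @export
read_gff_cds <- function(gff_path) {
  lines <- readLines(gff_path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) return(gene_annotation_frame(NULL))
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) != 9L)) stop("malformed GFF3: expected 9 tab-separated columns")
  f <- do.call(rbind, f)
  cds <- f[f[, 3] == "CDS", , drop = FALSE]
  if (!nrow(cds)) return(gene_annotation_frame(NULL))
  attr9 <- cds[, 9]
  gid <- gff_attr(attr9, "Parent")
  gid[is.na(gid)] <- gff_attr(attr9[is.na(gid)], "ID")
  if (anyNA(gid)) stop("CDS feature without Parent or ID attribute")
  ann <- data.frame(gene_id = gid, chrom = cds[, 1], strand = cds[, 7],
                    start = as.integer(cds[, 4]), end = as.integer(cds[, 5]),
                    stringsAsFactors = FALSE)
  if (any(ann$start > ann$end)) stop("CDS interval with start > end")
  gene_annotation_frame(merge_gene_intervals(ann))
}

gff_attr <- function(attrs, key) {
  pat <- paste0("(?:^|;)", key, "=([^;]+)")
  m <- regmatches(attrs, regexpr(pat, attrs, perl = TRUE))
  out <- rep(NA_character_, length(attrs))
  hit <- grepl(pat, attrs, perl = TRUE)
  out[hit] <- sub(pat, "\\1", m, perl = TRUE)
  out
}

merge_gene_intervals <- function(ann) {
  parts <- split(ann, ann$gene_id)
  out <- lapply(parts, function(d) {
    d <- d[order(d$start), , drop = FALSE]
    keep <- d[1, , drop = FALSE]
    if (nrow(d) > 1) {
      for (i in 2:nrow(d)) {
        j <- nrow(keep)
        if (d$start[i] <= keep$end[j] + 1L) {
          keep$end[j] <- max(keep$end[j], d$end[i])
        } else keep <- rbind(keep, d[i, ])
      }
    }
    keep
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

gene_annotation_frame <- function(ann) {
  if (is.null(ann))
    ann <- data.frame(gene_id = character(0), chrom = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}
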