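#' Candidate-gene allele with exon/intron structure
#'
#' @param allele_id allele name (e.g. `"Rg-B1b_h1"`).
#' @param assembly source assembly/cultivar name.
#' @param seq genomic sequence (character, ACGT).
#' @param exons two-column matrix of 1-based inclusive exon intervals on
#'   the genomic sequence, non-overlapping and ordered.
#' @param strand `"+"` or `"-"`; the CDS is the concatenated exon sequence,
#'   reverse-complemented on the minus strand.
#' @param insertions optional annotation of known insertions: data.frame
#'   with columns `intron`, `offset` (1-based position within the intron at
#'   which the insertion starts), `length`.
#' @return object of class `allele_sequence` with a derived `cds`; a CDS
#'   length not divisible by 3 is flagged (`frame_ok = FALSE`).
#' @export
allele_sequence <- function(allele_id, assembly, seq, exons, strand = "+",
                            insertions = NULL) {
  exons <- matrix(as.integer(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  stopifnot(all(exons[, 1] <= exons[, 2]), strand %in% c("+", "-"))
  if (nrow(exons) > 1) {
    if (any(diff(exons[, 1]) <= 0) || any(exons[-1, 1] <= exons[-nrow(exons), 2]))
      stop("exons must be ordered and non-overlapping")
  }
  if (max(exons) > nchar(seq)) stop("exon interval beyond sequence end")
  cds <- paste0(substring(seq, exons[, 1], exons[, 2]), collapse = "")
  if (strand == "-") cds <- revcomp(cds)
  structure(list(allele_id = allele_id, assembly = assembly, seq = seq,
                 exons = exons, strand = strand, cds = cds,
                 frame_ok = nchar(cds) %% 3L == 0L,
                 insertions = insertions),
            class = "allele_sequence")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

intron_seqs <- function(allele) {
  ex <- allele$exons
  if (nrow(ex) < 2) return(character(0))
  starts <- ex[-nrow(ex), 2] + 1L
  ends <- ex[-1, 1] - 1L
  substring(allele$seq, starts, ends)
}

as_cds <- function(x) {
  if (inherits(x, "allele_sequence")) x$cds else as.character(x)
}

#' Percent CDS identity from global alignment
#'
#' Needleman-Wunsch global alignment (match +2, mismatch -1, gap open -5,
#' gap extend -1); identity is the fraction of alignment columns with
#' identical bases, times 100. Symmetric by construction.
#'
#' @param a,b allele_sequence objects or character sequences.
#' @return percent identity in \[0, 100\].
#' @export
cds_identity <- function(a, b) {
  sa <- as_cds(a)
  sb <- as_cds(b)
  if (!nchar(sa) || !nchar(sb)) stop("empty CDS")
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(sa), Biostrings::DNAString(sb), type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -1),
    gapOpening = 5, gapExtension = 1)
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  100 * mean(pa == pb)
}

#' Pairwise identity matrix over alleles
#'
#' @param alleles list of allele_sequence objects.
#' @return symmetric percent-identity matrix with 100 on the diagonal.
#' @export
identity_matrix <- function(alleles) {
  ids <- vapply(alleles, `[[`, character(1), "allele_id")
  n <- length(alleles)
  M <- diag(100, n)
  dimnames(M) <- list(ids, ids)
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      M[i, j] <- M[j, i] <- cds_identity(alleles[[i]], alleles[[j]])
    }
  }
  M
}

#' Detect structural variants in introns relative to a reference
#'
#' Each intron of `allele` is globally aligned against the matching intron
#' of `reference`; gap runs are reported as insertions (present in the
#' allele, at least 50 bp) or deletions (absent from the allele, at least
#' 20 bp). Insertions are classed `"large"` (>= 1000 bp, MULE-like DNA
#' transposon scale) or `"small"` (< 1000 bp, SINE-like retrotransposon
#' scale); the size classes are this pipeline's convention.
#'
#' @param allele,reference allele_sequence objects with the same number of
#'   introns.
#' @param min_insertion,min_deletion reporting thresholds in bp.
#' @return data.frame with columns `intron`, `type`, `length`, `class`.
#' @export
detect_insertions <- function(allele, reference, min_insertion = 50,
                              min_deletion = 20) {
  ia <- intron_seqs(allele)
  ir <- intron_seqs(reference)
  if (length(ia) != length(ir))
    stop("intron count mismatch: ", length(ia), " vs ", length(ir))
  rows <- list()
  for (k in seq_along(ia)) {
    if (identical(ia[k], ir[k])) next
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(ir[k]), Biostrings::DNAString(ia[k]),
      type = "global",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 2, mismatch = -1),
      gapOpening = 5, gapExtension = 1)
    pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
    pb <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
    ins_len <- gap_runs(pa == "-") # gaps in reference = allele insertions
    del_len <- gap_runs(pb == "-") # gaps in allele = allele deletions
    for (L in ins_len[ins_len >= min_insertion])
      rows[[length(rows) + 1]] <- data.frame(
        intron = k, type = "insertion", length = L,
        class = if (L >= 1000) "large" else "small",
        stringsAsFactors = FALSE)
    for (L in del_len[del_len >= min_deletion])
      rows[[length(rows) + 1]] <- data.frame(
        intron = k, type = "deletion", length = L, class = NA_character_,
        stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(intron = integer(0), type = character(0),
                      length = integer(0), class = character(0)))
  do.call(rbind, rows)
}

gap_runs <- function(isgap) {
  r <- rle(isgap)
  r$lengths[r$values]
}

#' Translate a CDS and flag premature stops
#'
#' Standard-code translation up to the first stop codon. `premature_stop`
#' is `TRUE` when a reference protein length is supplied and the translated
#' protein is shorter; a CDS without any stop codon is flagged
#' unterminated.
#'
#' @param cds character CDS (or allele_sequence), must start with ATG.
#' @param reference_protein_length optional residue count of the intact
#'   reference protein.
#' @return list with `protein`, `n_residues`, `terminated`,
#'   `premature_stop`.
#' @export
orf_translate <- function(cds, reference_protein_length = NULL) {
  s <- toupper(as_cds(cds))
  if (substr(s, 1, 3) != "ATG") stop("CDS must start with ATG")
  n_codon <- nchar(s) %/% 3
  codons <- substring(s, 3 * seq_len(n_codon) - 2, 3 * seq_len(n_codon))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  stop_at <- which(aa == "*")[1]
  terminated <- !is.na(stop_at)
  prot <- if (terminated) aa[seq_len(stop_at - 1)] else aa
  list(protein = paste(prot, collapse = ""),
       n_residues = length(prot),
       terminated = terminated,
       premature_stop = !is.null(reference_protein_length) &&
         length(prot) < reference_protein_length)
}

#' Classify alleles into the five Rg-B1 haplotype groups
#'
#' Membership requires CDS identity to the reference strictly above
#' `id_threshold` (the study's >93% shortlist rule). Structural rules then
#' assign each member to exactly one group:
#' G1 large intron-2 insertion, intact ORF; G2 large intron-2 insertion
#' plus premature stop; G5 small intron-2 insertion; G3 no intron-2
#' insertion and a 40-60 bp intron-1 deletion; G4 no intron-2 insertion
#' and no such deletion. Alleles with conflicting features (both insertion
#' classes in intron 2) are left unassigned with a reason.
#'
#' Insertion features are detected against `baseline`, an insertion-free
#' template; by default it is the reference with its annotated insertions
#' excised (the reference itself, the Chinese Spring MYB allele, carries
#' the group-1 MULE).
#'
#' @param alleles list of allele_sequence objects.
#' @param reference allele_sequence used for identity and protein length.
#' @param id_threshold membership threshold in percent (default 93).
#' @param baseline insertion-free allele_sequence for feature detection.
#' @return data.frame with `allele_id`, `assembly`, `identity`, `group`
#'   (`G1`..`G5` or `NA`), `reason` for unassigned alleles.
#' @export
classify_alleles <- function(alleles, reference, id_threshold = 93,
                             baseline = strip_insertions(reference)) {
  ref_prot <- orf_translate(reference)$n_residues
  rows <- lapply(alleles, function(a) {
    idy <- cds_identity(a, reference)
    row <- data.frame(allele_id = a$allele_id, assembly = a$assembly,
                      identity = idy, group = NA_character_,
                      reason = NA_character_, stringsAsFactors = FALSE)
    if (idy <= id_threshold) {
      row$reason <- sprintf("identity %.1f%% below membership threshold", idy)
      return(row)
    }
    feats <- detect_insertions(a, baseline)
    i2 <- feats[feats$intron == 2 & feats$type == "insertion", , drop = FALSE]
    i1del <- feats[feats$intron == 1 & feats$type == "deletion", , drop = FALSE]
    has_large <- any(i2$class == "large")
    has_small <- any(i2$class == "small")
    if (has_large && has_small) {
      row$reason <- "conflicting intron-2 insertion classes"
      return(row)
    }
    premature <- orf_translate(a, ref_prot)$premature_stop
    row$group <- if (has_large) {
      if (premature) "G2" else "G1"
    } else if (has_small) {
      "G5"
    } else if (any(i1del$length >= 40 & i1del$length <= 60)) {
      "G3"
    } else "G4"
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Remove annotated insertions from an allele
#'
#' Uses the allele's `insertions` annotation (intron index, offset within
#' the intron, length) to excise the inserted sequence, yielding an
#' insertion-free template for feature detection.
#'
#' @param allele allele_sequence.
#' @return allele_sequence without the annotated insertions.
#' @export
strip_insertions <- function(allele) {
  ann <- allele$insertions
  if (is.null(ann) || !nrow(ann)) return(allele)
  ex <- allele$exons
  seq <- allele$seq
  # process from the end so earlier coordinates stay valid
  ann <- ann[order(-ann$intron, -ann$offset), , drop = FALSE]
  for (r in seq_len(nrow(ann))) {
    k <- ann$intron[r]
    ins_start <- ex[k, 2] + ann$offset[r]
    ins_end <- ins_start + ann$length[r] - 1L
    seq <- paste0(substr(seq, 1, ins_start - 1L),
                  substr(seq, ins_end + 1L, nchar(seq)))
    shift <- as.integer(ann$length[r])
    ex[ex[, 1] > ins_end, 1] <- ex[ex[, 1] > ins_end, 1] - shift
    ex[ex[, 2] > ins_end, 2] <- ex[ex[, 2] > ins_end, 2] - shift
  }
  allele_sequence(allele$allele_id, allele$assembly, seq, ex, allele$strand)
}

#' Neighbor-joining tree with bootstrap support
#'
#' Saitou-Nei agglomeration (via \pkg{ape}) on distance `100 - percent
#' identity`. Bootstrap support resamples columns of the CDS alignment
#' (`bootstrap_n` replicates; requires equal-length, substitution-only
#' CDS), rebuilds the tree, and reports for each internal edge the percent
#' of replicates containing the same bipartition. Deterministic under
#' `seed`.
#'
#' @param alleles list of at least 3 allele_sequence objects, or a
#'   precomputed distance matrix (then no bootstrap is run).
#' @param bootstrap_n bootstrap replicates (0 to skip).
#' @param seed integer seed.
#' @return list of class `nj_tree`: `tree` (ape phylo, support as node
#'   labels), `support` (per internal node, percent), `distances`.
#' @export
nj_tree <- function(alleles, bootstrap_n = 1000, seed = 1) {
  if (is.matrix(alleles)) {
    D <- alleles
    if (nrow(D) < 3) stop("need at least 3 taxa")
    tree <- ape::nj(as.dist(D))
    return(structure(list(tree = tree, support = NULL, distances = D),
                     class = "nj_tree"))
  }
  if (length(alleles) < 3) stop("need at least 3 alleles")
  D <- 100 - identity_matrix(alleles)
  tree <- ape::nj(as.dist(D))
  support <- NULL
  if (bootstrap_n > 0) {
    cds <- vapply(alleles, function(a) as_cds(a), "")
    L <- unique(nchar(cds))
    if (length(L) != 1)
      stop("bootstrap requires CDS of equal length (substitution-only alignment)")
    mat <- do.call(rbind, strsplit(cds, ""))
    rownames(mat) <- rownames(D)
    reps <- with_seed(seed, lapply(seq_len(bootstrap_n), function(b) {
      cols <- sample.int(L, L, replace = TRUE)
      m <- mat[, cols, drop = FALSE]
      d <- 100 * outer(seq_len(nrow(m)), seq_len(nrow(m)),
                       Vectorize(function(i, j) mean(m[i, ] != m[j, ])))
      dimnames(d) <- dimnames(D)
      ape::nj(as.dist(d))
    }))
    counts <- ape::prop.clades(tree, reps, rooted = FALSE)
    counts[is.na(counts)] <- 0
    support <- 100 * counts / bootstrap_n
    tree$node.label <- round(support, 1)
  }
  structure(list(tree = tree, support = support, distances = D),
            class = "nj_tree")
}

#' In-silico PCR
#'
#' Exact-match search of the forward primer on the plus strand and of the
#' reverse complement of the reverse primer downstream of it; every such
#' pairing within `max_len` is an amplicon. Lengths include both primer
#' sites.
#'
#' @param template allele_sequence or character sequence.
#' @param primers list with elements `forward` and `reverse` (5'->3'
#'   sequences, at least 15 bases each).
#' @param max_len maximum amplicon length (default 5000).
#' @param template_id label for reporting.
#' @return data.frame with `template_id`, `start`, `end`, `length`; zero
#'   rows when either primer finds no site.
#' @export
insilico_pcr <- function(template, primers, max_len = 5000,
                         template_id = NULL) {
  seq <- if (inherits(template, "allele_sequence")) template$seq
         else as.character(template)
  if (is.null(template_id))
    template_id <- if (inherits(template, "allele_sequence"))
      template$allele_id else "template"
  fwd <- toupper(primers$forward)
  rev <- toupper(primers$reverse)
  if (nchar(fwd) < 15 || nchar(rev) < 15)
    stop("primers must be at least 15 bases")
  f_hits <- exact_hits(seq, fwd)
  r_hits <- exact_hits(seq, revcomp(rev))
  out <- data.frame(template_id = character(0), start = integer(0),
                    end = integer(0), length = integer(0))
  for (f in f_hits) for (r in r_hits) {
    end <- r + nchar(rev) - 1L
    len <- end - f + 1L
    if (r >= f && len <= max_len)
      out <- rbind(out, data.frame(template_id = template_id, start = f,
                                   end = end, length = len,
                                   stringsAsFactors = FALSE))
  }
  out
}

exact_hits <- function(seq, pattern) {
  m <- gregexpr(pattern, seq, fixed = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}
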