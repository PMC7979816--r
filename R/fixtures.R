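#' Synthetic MYB allele fixtures for the five haplotype groups
#'
#' Builds a set of candidate-gene alleles realizing the five Rg-B1 groups,
#' sharing one gene architecture (three exons of 350/400/225 bp, CDS 975 bp
#' translating to 324 residues plus stop; intron 1 of 500 bp, intron 2 of
#' 400 bp before insertions):
#'
#' * `rg-B1a_h1` (reference, G1) and `rg-B1a_h2` (G1): 8100 bp MULE-like
#'   insertion in intron 2, intact ORF.
#' * `rg-B1a_h7` (G2): the same insertion plus a premature stop at codon
#'   259, truncating the protein by 66 residues.
#' * `Rg-B1b_h1` (G3): no intron-2 insertion, 47 bp deletion in intron 1,
#'   975 bp ORF.
#' * `rg-B1a_h9` (G4): no insertion, no intron-1 deletion.
#' * `rg-B1a_h10` (G5): 300 bp SINE-like insertion in intron 2, CDS
#'   identity to the reference tuned into 93-94%.
#' * `paralog_x`: a diverged paralog at ~90% identity that must fail the
#'   membership filter.
#'
#' The primer pair flanks the intron-1 InDel: 381 bp amplicon on templates
#' without the deletion, 334 bp on group-3 templates. All sequences are
#' synthetic and deterministic under `seed`.
#'
#' @param seed integer seed.
#' @return list with `alleles` (named list of allele_sequence), `primers`
#'   (forward/reverse), `reference_id`, and `truth` (data.frame of intended
#'   group per allele).
#' @export
make_allele_fixtures <- function(seed = 1) {
  with_seed(seed, {
    e_len <- c(350L, 400L, 225L)
    cds <- random_orf(sum(e_len))
    intron1 <- random_dna(500L)
    intron2 <- random_dna(400L)
    mule <- random_dna(8100L)
    sine <- random_dna(300L)
    del_at <- 250L # intron-1 deletion spans offsets 250..296 (47 bp)

    sub_sets <- list(h1 = draw_cds_subs(cds, 0),
                     h2 = draw_cds_subs(cds, 5),
                     h7 = draw_cds_subs(cds, 3),
                     g3 = draw_cds_subs(cds, 10),
                     g4 = draw_cds_subs(cds, 15),
                     g5 = draw_cds_subs(cds, 64),
                     para = draw_cds_subs(cds, 97))

    build <- function(id, assembly, subs, mule_ins = FALSE, sine_ins = FALSE,
                      i1_del = FALSE, stop_codon = NA) {
      v <- apply_cds_subs(cds, subs)
      if (!is.na(stop_codon)) {
        pos <- 3L * (stop_codon - 1L) + 1L
        substr(v, pos, pos + 2L) <- "TAA"
      }
      i1 <- if (i1_del) paste0(substr(intron1, 1, del_at - 1L),
                               substr(intron1, del_at + 47L, nchar(intron1)))
            else intron1
      ins <- NULL
      i2 <- intron2
      if (mule_ins) {
        i2 <- paste0(substr(intron2, 1, 200), mule, substr(intron2, 201, 400))
        ins <- data.frame(intron = 2L, offset = 201L, length = 8100L)
      } else if (sine_ins) {
        i2 <- paste0(substr(intron2, 1, 200), sine, substr(intron2, 201, 400))
        ins <- data.frame(intron = 2L, offset = 201L, length = 300L)
      }
      ex <- cds_exon_pieces(v, e_len)
      seq <- paste0(ex[1], i1, ex[2], i2, ex[3])
      s1 <- e_len[1]
      s2s <- s1 + nchar(i1) + 1L
      s2e <- s2s + e_len[2] - 1L
      s3s <- s2e + nchar(i2) + 1L
      exons <- rbind(c(1L, s1), c(s2s, s2e), c(s3s, s3s + e_len[3] - 1L))
      allele_sequence(id, assembly, seq, exons, "+", insertions = ins)
    }

    alleles <- list(
      `rg-B1a_h1` = build("rg-B1a_h1", "ChineseSpring", sub_sets$h1, mule_ins = TRUE),
      `rg-B1a_h2` = build("rg-B1a_h2", "CDCStanley", sub_sets$h2, mule_ins = TRUE),
      `rg-B1a_h7` = build("rg-B1a_h7", "Jagger", sub_sets$h7, mule_ins = TRUE,
                          stop_codon = 259L),
      `Rg-B1b_h1` = build("Rg-B1b_h1", "Norin61", sub_sets$g3, i1_del = TRUE),
      `rg-B1a_h9` = build("rg-B1a_h9", "Mace", sub_sets$g4),
      `rg-B1a_h10` = build("rg-B1a_h10", "PI190962", sub_sets$g5, sine_ins = TRUE),
      paralog_x = build("paralog_x", "PI190962", sub_sets$para))

    # primers flank the intron-1 InDel; the amplicon spans intron-1 offsets
    # 50..430 (381 bp without the deletion, 334 bp with it)
    primers <- list(forward = substr(intron1, 50, 69),
                    reverse = revcomp(substr(intron1, 411, 430)))

    truth <- data.frame(
      allele_id = names(alleles),
      group = c("G1", "G1", "G2", "G3", "G4", "G5", NA),
      stringsAsFactors = FALSE)
    list(alleles = alleles, primers = primers, reference_id = "rg-B1a_h1",
         truth = truth)
  })
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# in-frame ORF: ATG, sense codons, terminal TAA; no internal stop
random_orf <- function(len) {
  stopifnot(len %% 3 == 0)
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1, paste, collapse = "")
  sense <- setdiff(codons, c("TAA", "TAG", "TGA"))
  body <- sample(sense, len / 3 - 2, replace = TRUE)
  paste(c("ATG", body, "TAA"), collapse = "")
}

# positions (within codons 2..(n-1), i.e. sparing start and stop) where a
# substitution keeps the codon sense
draw_cds_subs <- function(cds, k) {
  n <- nchar(cds)
  bases <- c("A", "C", "G", "T")
  out <- list()
  used <- integer(0)
  while (length(out) < k) {
    pos <- sample(4:(n - 3), 1)
    if (pos %in% used) next
    codon_i <- (pos - 1) %/% 3
    cstart <- 3 * codon_i + 1
    codon <- substr(cds, cstart, cstart + 2)
    new <- sample(setdiff(bases, substr(cds, pos, pos)), 1)
    mutated <- codon
    substr(mutated, pos - cstart + 1, pos - cstart + 1) <- new
    if (mutated %in% c("TAA", "TAG", "TGA")) next
    used <- c(used, pos)
    out[[length(out) + 1]] <- c(pos = pos, base = new)
  }
  data.frame(pos = vapply(out, function(x) as.integer(x["pos"]), 1L),
             base = vapply(out, function(x) x["base"], ""))
}

apply_cds_subs <- function(cds, subs) {
  if (is.null(subs) || !NROW(subs)) return(cds)
  for (r in seq_len(nrow(subs)))
    substr(cds, subs$pos[r], subs$pos[r]) <- subs$base[r]
  cds
}

cds_exon_pieces <- function(cds, e_len) {
  ends <- cumsum(e_len)
  starts <- c(1L, head(ends, -1) + 1L)
  substring(cds, starts, ends)
}

#' Synthetic qPCR Ct fixture with known fold changes
#'
#' Three target genes with embedded true fold changes red vs white
#' (4, 1, 0.5), one reference gene, two groups (calibrator `white`) and
#' three biological replicates per group. Target dCt in the red group is
#' shifted by -log2(FC); replicate noise is Gaussian with sd 0.2 cycles,
#' and each sample gets a global Ct offset that the ddCt arithmetic must
#' cancel. Deterministic under `seed`.
#'
#' @param seed integer seed.
#' @return ct_table with attribute `true_fc` (named vector).
#' @export
make_qpcr_fixture <- function(seed = 1) {
  true_fc <- c(g1 = 4, g2 = 1, g3 = 0.5)
  with_seed(seed, {
    rows <- list()
    for (grp in c("red", "white")) {
      for (rep_i in 1:3) {
        sid <- paste0(toupper(substr(grp, 1, 1)), rep_i)
        shift <- runif(1, -1, 1) # per-sample offset, cancels in dCt
        ct_ref <- 20 + shift + rnorm(1, 0, 0.2)
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = sid, group = grp, gene = "ref", replicate = rep_i,
          ct = ct_ref, stringsAsFactors = FALSE)
        for (g in names(true_fc)) {
          dct <- 5 - if (grp == "red") log2(true_fc[[g]]) else 0
          rows[[length(rows) + 1]] <- data.frame(
            sample_id = sid, group = grp, gene = g, replicate = rep_i,
            ct = 20 + shift + dct + rnorm(1, 0, 0.2), stringsAsFactors = FALSE)
        }
      }
    }
    tab <- ct_table(do.call(rbind, rows), reference_gene = "ref",
                    calibrator = "white")
    attr(tab, "true_fc") <- true_fc
    tab
  })
}
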