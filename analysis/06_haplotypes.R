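#!/usr/bin/env Rscript
# Haplotype analysis of the candidate MYB alleles: pairwise CDS identity,
# rule-based assignment to groups G1-G5, a bootstrap neighbor-joining
# tree, in-silico validation of the group-3 marker, and ORF
# characterization of every allele.

library(speltpop)

out <- "results/haplotypes"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

fx <- make_allele_fixtures(2026)
alleles <- fx$alleles
ref <- alleles[[fx$reference_id]]

M <- identity_matrix(alleles)
write.table(round(M, 2), file.path(out, "cds_identity.tsv"), sep = "\t",
            quote = FALSE, col.names = NA)

cls <- classify_alleles(alleles, ref)
print(cls[, c("allele_id", "assembly", "identity", "group")])
write.table(cls, file.path(out, "haplotype_groups.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

members <- cls$allele_id[!is.na(cls$group)]
njt <- nj_tree(alleles[members], bootstrap_n = 1000, seed = 4)
ape::write.tree(njt$tree, file.path(out, "myb_nj.nwk"))
message("NJ tree with bootstrap support written (",
        length(members), " alleles, 1000 replicates)")

amps <- do.call(rbind, lapply(alleles, insilico_pcr, primers = fx$primers))
amps <- merge(amps, cls[, c("allele_id", "group")],
              by.x = "template_id", by.y = "allele_id")
print(amps)
write.table(amps, file.path(out, "marker_amplicons.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

ref_len <- orf_translate(ref)$n_residues
orfs <- do.call(rbind, lapply(alleles, function(a) {
  o <- orf_translate(a, ref_len)
  data.frame(allele_id = a$allele_id, cds_bp = nchar(a$cds),
             residues = o$n_residues, premature_stop = o$premature_stop)
}))
print(orfs, row.names = FALSE)
write.table(orfs, file.path(out, "orf_table.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
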