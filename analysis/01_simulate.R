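#!/usr/bin/env Rscript
# Generate the synthetic study inputs: a three-population spelt cohort
# genotyped at unlinked SNPs, a glume-color phenotype with a dominant
# causal locus, gene models for site classification, the MYB allele
# fixture set with its diagnostic primer pair, and a qPCR Ct table.
# Everything downstream (02-07) starts from the files written here.

library(speltpop)

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 2026

spec <- cohort_spec(n_diploid = c(asia = 18, ce = 40, ib = 18),
                    n_sites = 3000, missing_rate = 0.15, seed = seed)
gm <- simulate_cohort(spec)
message("cohort: ", nrow(gm$geno), " accessions x ", ncol(gm$geno), " SNPs, ",
        round(100 * mean(is.na(gm$geno)), 1), "% missing calls")
write_vcf(gm, file.path(out, "cohort.vcf"))
write.table(gm$samples, file.path(out, "samples.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(format(attr(gm, "n_loci"), digits = 15),
           file.path(out, "n_loci.txt"))

# dominant causal locus for glume color: a common SNP with few missing calls
maf <- site_maf(gm)
causal <- which(maf > 0.2 & maf < 0.45 & colMeans(is.na(gm$geno)) < 0.15)[1]
message("causal SNP: ", gm$sites$chrom[causal], ":", gm$sites$pos[causal],
        " (MAF ", round(maf[causal], 2), ")")
phen <- inject_phenotype(gm, pheno_spec(causal, penetrance = 0.95,
                                        phenocopy_rate = 0.02,
                                        seed = seed + 1))
write.table(data.frame(sample_id = names(phen), glume_color = phen),
            file.path(out, "phenotype.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
writeLines(paste(gm$sites$chrom[causal], gm$sites$pos[causal]),
           file.path(out, "causal_site.txt"))

# synthetic gene models: one gene every ~200 kb so site classes are mixed
set.seed(seed + 2)
genes <- do.call(rbind, lapply(unique(gm$sites$chrom), function(ch) {
  pos <- gm$sites$pos[gm$sites$chrom == ch]
  starts <- seq(min(pos), max(pos), by = 2e5)
  data.frame(chrom = ch, start = starts, end = starts + 3000,
             gene_id = paste0("gene_", ch, "_", seq_along(starts)))
}))
gff <- c("##gff-version 3",
         unlist(lapply(seq_len(nrow(genes)), function(i) with(genes[i, ], c(
           paste(chrom, "synth", "gene", start, end, ".", "+", ".",
                 paste0("ID=", gene_id), sep = "\t"),
           paste(chrom, "synth", "CDS", start, start + 1200, ".", "+", "0",
                 paste0("Parent=", gene_id), sep = "\t"),
           paste(chrom, "synth", "CDS", end - 1200, end, ".", "+", "0",
                 paste0("Parent=", gene_id), sep = "\t"))))))
writeLines(gff, file.path(out, "genes.gff3"))

# MYB allele fixtures and the co-dominant marker primers
fx <- make_allele_fixtures(seed)
fa <- unlist(lapply(fx$alleles, function(a)
  c(paste0(">", a$allele_id, " assembly=", a$assembly), a$seq)))
writeLines(fa, file.path(out, "myb_alleles.fasta"))
write.table(data.frame(name = "rgb1_group3_marker",
                       forward = fx$primers$forward,
                       reverse = fx$primers$reverse),
            file.path(out, "primers.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

# qPCR Ct table for flavonoid-pathway genes
qt <- make_qpcr_fixture(seed)
write.csv(as.data.frame(qt), file.path(out, "qpcr_ct.csv"), row.names = FALSE)

message("inputs written under ", out)
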