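#!/usr/bin/env Rscript
# SNP filtering and classification: read the cohort VCF back, apply the
# study's filter chain (missingness on both axes), classify sites against
# the gene models, and tabulate SNP counts per sample group.

library(speltpop)

dat <- "results/data"
out <- "results/filtering"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

tabs <- read_tables(file.path(dat, "phenotype.tsv"),
                    file.path(dat, "samples.tsv"),
                    file.path(dat, "genes.gff3"))
gm <- read_vcf(file.path(dat, "cohort.vcf"), samples = tabs$samples)

gm_f <- filter_site_missing(gm, 0.2)
gm_f <- filter_sample_missing(gm_f, 0.2)
rep <- filter_report(gm_f)
print(rep)
write.table(rep, file.path(out, "filter_report.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_vcf(gm_f, file.path(out, "cohort_filtered.vcf"))

classes <- classify_sites(gm_f, tabs$annotation, window = 2000)
message("site classes: ",
        paste(names(table(classes)), table(classes), collapse = ", ",
              sep = "="))
write.table(data.frame(chrom = gm_f$sites$chrom, pos = gm_f$sites$pos,
                       class = classes),
            file.path(out, "site_classes.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

groups <- c(list(All = gm_f$samples$sample_id),
            split(gm_f$samples$sample_id, gm_f$samples$population))
counts <- summarize_counts(gm_f, groups)
print(counts)
write.table(counts, file.path(out, "snp_counts_by_group.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# demography-ready panel: non-genic, singleton-free, 20 kb apart
gm_d <- drop_genic(gm_f, classes)
gm_d <- remove_singletons(gm_d)
gm_d <- thin_by_distance(gm_d, 20000)
print(filter_report(gm_d))
write_vcf(gm_d, file.path(out, "cohort_demography.vcf"))
message(ncol(gm_d$geno), " SNPs retained for demographic inference")
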