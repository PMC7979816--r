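#!/usr/bin/env Rscript
# Population structure: PCA of the filtered panel (whole genome and per
# subgenome), a sub-sampling robustness check, MDS coordinates for the
# GWAS, and k-means agreement with the three gene pools.

library(speltpop)

out <- "results/structure"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
tabs <- read_tables("results/data/phenotype.tsv", "results/data/samples.tsv",
                    "results/data/genes.gff3")
gm <- read_vcf("results/filtering/cohort_filtered.vcf",
               samples = tabs$samples)

p <- pca(gm, k = 2)
message(sprintf("whole genome: PC1+PC2 explain %.1f%% of variance",
                100 * sum(p$variance_explained)))
write.table(data.frame(sample_id = rownames(p$scores), p$scores,
                       population = gm$samples$population),
            file.path(out, "pca_scores.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

ve <- data.frame(panel = "whole", pc1 = p$variance_explained[1],
                 pc2 = p$variance_explained[2])
for (s in c("A", "B", "D")) {
  ps <- pca(subgenome_subset(gm, s), k = 2)
  ve <- rbind(ve, data.frame(panel = s, pc1 = ps$variance_explained[1],
                             pc2 = ps$variance_explained[2]))
}
# sub-sampling robustness: repeat on a random half of the panel
half <- subsample_sites(gm, ncol(gm$geno) %/% 2, seed = 11)
ph <- pca(half, k = 2)
ve <- rbind(ve, data.frame(panel = "subsampled_half",
                           pc1 = ph$variance_explained[1],
                           pc2 = ph$variance_explained[2]))
print(ve)
write.table(ve, file.path(out, "variance_explained.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

md <- mds_coordinates(gm)
write.table(data.frame(sample_id = rownames(md$coords), md$coords),
            file.path(out, "mds_coordinates.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

set.seed(1)
km <- kmeans(p$scores, centers = 3, nstart = 20)
tab <- table(cluster = km$cluster, population = gm$samples$population)
agree <- sum(apply(tab, 2, max)) / sum(tab)
message(sprintf("k-means vs gene pools: %.1f%% agreement", 100 * agree))
print(tab)
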