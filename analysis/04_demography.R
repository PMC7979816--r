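#!/usr/bin/env Rscript
# Demographic inference on folded 2D spectra: build the three pairwise
# spectra from the thinned non-genic panel, fit the three scenarios with
# the Asian gene pool as the ancestor, rank them by AIC, and attach
# parametric-bootstrap confidence intervals to the best model.
# Settings here are scaled for a workstation run of a few minutes; the
# study-scale settings (20 runs, 100k genealogies, 100 bootstraps) are
# exposed by the same functions.

library(speltpop)

out <- "results/demography"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
tabs <- read_tables("results/data/phenotype.tsv", "results/data/samples.tsv",
                    "results/data/genes.gff3")
gm <- read_vcf("results/filtering/cohort_demography.vcf",
               samples = tabs$samples)
n_loci <- as.numeric(readLines("results/data/n_loci.txt")) *
  ncol(gm$geno) / 3000 # rescale the mutational-target count to the panel

proj <- c(27, 60, 27) # ~3/4 of the haploid sample, as in projection use
obs <- observed_sfs_triple(gm, proj)
for (nm in names(obs)) write_sfs(obs[[nm]], file.path(out, paste0(nm, ".sfs")))

scen <- c("single_introduction", "independent_origins", "hybrid_geneflow")
fits <- lapply(scen, function(sc) {
  message("fitting ", sc, " ...")
  fit_model(obs, sc, "asian", proj, n_runs = 4, n_genealogies = 5000,
            seed = 7, n_loci = n_loci, eval_budget = 250, n_screen = 40)
})
rank <- select_model(fits)
print(rank)
write.table(rank, file.path(out, "model_ranking.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

best <- fits[[which(vapply(fits, `[[`, character(1), "model_id") ==
                      rank$model_id[1])]]
print(round(best$estimates))

message("parametric bootstrap (scaled: 10 replicates) ...")
boot <- suppressWarnings(parametric_bootstrap(
  best, proj, n_sites = ncol(gm$geno), n_boot = 10, n_runs = 2,
  n_genealogies = 2500, eval_budget = 60, seed = 99))
print(boot$table)
write.table(boot$table, file.path(out, "bootstrap_ci.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
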