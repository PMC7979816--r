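#!/usr/bin/env Rscript
# Relative expression of flavonoid-pathway genes by 2^-ddCt, red vs white
# glume groups, from the long-format Ct table written by 01_simulate.R.

library(speltpop)

out <- "results/expression"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

raw <- read.csv("results/data/qpcr_ct.csv", stringsAsFactors = FALSE)
tab <- ct_table(raw, reference_gene = "ref", calibrator = "white")

dd <- delta_delta_ct(tab)
print(dd$summary, row.names = FALSE)
write.table(dd$per_replicate, file.path(out, "fold_changes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(dd$summary, file.path(out, "group_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cmp <- group_compare(dd)
print(cmp, row.names = FALSE)
write.table(cmp, file.path(out, "red_vs_white.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
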