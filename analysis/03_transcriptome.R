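#!/usr/bin/env Rscript
# Expression analysis: CPM filtering, the poorly-induced-gene classifier,
# and the read-fraction accounting of the classified set.

suppressPackageStartupMessages(library(ecscreen))

de_wt <- read_de_table("results/scenario/de_wt.tsv")
de_mut <- read_de_table("results/scenario/de_mut.tsv")
cm <- read_count_matrix("results/scenario/counts.tsv",
                        "results/scenario/groups.tsv")

kept <- cpm_filter(cm)
cat(sprintf("CPM filter kept %d of %d genes\n", length(kept),
            nrow(cm$counts)))

poor <- classify_poorly_induced(de_wt, de_mut)
writeLines(poor, "results/poorly_induced_genes.txt")
cat(sprintf("%d genes classified poorly induced (induced in the reference on the glucose->ethanol shift, >= 2-fold less induced in the mutant)\n",
            length(poor)))

fr <- do.call(rbind, lapply(unique(cm$groups), function(g)
  data.frame(group = g, read_fraction_pct = read_fraction(cm, poor, g))))
ecscreen:::write_tsv_plain(fr, "results/read_fractions.tsv")
print(fr, row.names = FALSE)
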