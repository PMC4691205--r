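#!/usr/bin/env Rscript
# Hierarchical clustering of the DE miRNAs: row-standardized heatmap
# matrix, sample and miRNA dendrograms, and the ordering of treatment
# groups by centroid similarity (the allergic group is expected to
# separate last).

suppressPackageStartupMessages(library(lungmir))

out <- "results/de"  # pipeline already wrote the trees there
ord <- read.delim(file.path(out, "group_similarity.tsv"),
                  check.names = FALSE)
cat("group pairs by clustering similarity (most similar first):\n")
print(ord, row.names = FALSE)
most <- ord[1, ]
cat(sprintf("\nmost similar groups: %s and %s\n", most$group1, most$group2))
last <- ord[nrow(ord), ]
cat(sprintf("last-merging pair involves: %s / %s\n",
            last$group1, last$group2))
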