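#!/usr/bin/env Rscript
# Stage 4: average-linkage clustering (1 - Pearson correlation) of the
# standardized 12-condition profiles within each set, cut to 2 / 2 / 4
# clusters and labelled by expression pattern (Ch-up, Te-up, LT-down,
# LT-up, and the four line x cold combinations).

library(coldcascade)

data_dir <- "results/data"
out <- "results"
design <- read_design(file.path(data_dir, "design.tsv"))
counts <- read_counts(file.path(data_dir, "counts.tsv"), design)
cl <- read.delim(file.path(out, "classification.tsv"))
class(cl) <- c("gene_classification", "data.frame")

subsets <- cluster_patterns(cl, normalize_counts(counts), design)
write_tsv(subsets, file.path(out, "subsets.tsv"))
for (set in names(attr(subsets, "trees")))
  write_tsv(attr(subsets, "trees")[[set]],
            file.path(out, paste0("tree_", set, ".tsv")))

cat("subset sizes:\n")
print(table(subsets$set_label, subsets$subset_label))

truth <- read.delim(file.path(data_dir, "truth.tsv"))
rec <- recovery_report(truth, cl, subsets)
cat("subset-label recovery among correctly-set genes:",
    sprintf("%.1f%%", 100 * rec$subset_recovery$overall), "\n")
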