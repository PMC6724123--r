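#!/usr/bin/env Rscript
# Stage 2: normalize, test the nine condition contrasts, and apply the
# selection filters (testability, total normalized count > 48,
# adjusted p <= 0.02 in >= 1 contrast, best-hit E-value <= 9e-4).

library(coldcascade)

data_dir <- "results/data"
out <- "results"
design <- read_design(file.path(data_dir, "design.tsv"))
counts <- read_counts(file.path(data_dir, "counts.tsv"), design)
bundle <- annotation_bundle(
  best_hit = read.delim(file.path(data_dir, "best_hit.tsv")),
  tf_family = read.delim(file.path(data_dir, "tf_family.tsv")),
  kinase_family = read.delim(file.path(data_dir, "kinase_family.tsv")),
  go_terms = read_gene_sets(file.path(data_dir, "go_sets.gmt")))

sf <- size_factors(counts)
cat("size factors:", paste(round(range(sf), 3), collapse = " - "), "\n")

freport <- filter_report(counts, design, bundle = bundle)
write_tsv(freport, file.path(out, "filter_report.tsv"))
write_tsv(attr(freport, "contrasts"), file.path(out, "contrast_table.tsv"))

cat("genes:            ", nrow(freport), "\n")
cat("testable:         ", sum(freport$testable), "\n")
cat("> 48 norm counts: ", sum(freport$passed_count_filter), "\n")
cat("DEGs (p_adj<=.02):", sum(freport$passed_deg_filter), "\n")
cat("annotated DEGs:   ", sum(freport$passed_annotation_filter), "\n")
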