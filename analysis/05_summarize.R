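#!/usr/bin/env Rscript
# Stage 5: functional summary tables — per-subset kinase / TF /
# cold-GO tallies and percentages, the cold-GO incidence matrix, and
# hypergeometric GO enrichment of each subset against the annotated
# DEG background.

library(coldcascade)

data_dir <- "results/data"
out <- "results"
subsets <- read.delim(file.path(out, "subsets.tsv"))
bundle <- annotation_bundle(
  best_hit = read.delim(file.path(data_dir, "best_hit.tsv")),
  tf_family = read.delim(file.path(data_dir, "tf_family.tsv")),
  kinase_family = read.delim(file.path(data_dir, "kinase_family.tsv")),
  go_terms = read_gene_sets(file.path(data_dir, "go_sets.gmt")))

sm <- summarize_sets(subsets, bundle)
write_tsv(sm, file.path(out, "functional_summary.tsv"))
cg <- cold_go_matrix(subsets, bundle)
write_tsv(cg$totals, file.path(out, "cold_go_totals.tsv"))

background <- subsets$gene_id
enr <- do.call(rbind, lapply(unique(subsets$subset_label), function(s) {
  res <- hypergeom_enrichment(
    subsets$gene_id[subsets$subset_label == s],
    bundle$go_terms, background)
  res$subset_label <- s
  res
}))
write_tsv(enr, file.path(out, "go_enrichment.tsv"))

cat("functional summary (counts):\n")
print(sm[, c("set_label", "subset_label", "n_genes", "n_kinases",
             "n_tf", "n_cold_go")])
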