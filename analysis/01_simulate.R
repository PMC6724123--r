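#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study — a 24-sample factorial count
# matrix (2 lines x 2 treatments x 3 times x 2 replicates) with
# planted expression archetypes, plus annotation sidecars and a paired
# qPCR table. All downstream stages read only the files written here.

library(coldcascade)

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

design <- canonical_design()
cfg <- simulation_config(seed = 42)   # 1000 null + 100 per archetype
sim <- simulate_counts(cfg, design)
bundle <- simulate_annotation(sim$truth, annotated_fraction = 1.0,
                              evalue_range = c(1e-50, 1e-5), seed = 42)
qpcr <- simulate_qpcr(sim$truth, n_transcripts = 33, noise_sd = 0.5,
                      seed = 42)

write_design(design, file.path(out, "design.tsv"))
write_counts(sim$counts, file.path(out, "counts.tsv"))
write_tsv(sim$truth, file.path(out, "truth.tsv"))
write_tsv(bundle$best_hit, file.path(out, "best_hit.tsv"))
write_tsv(bundle$tf_family, file.path(out, "tf_family.tsv"))
write_tsv(bundle$kinase_family, file.path(out, "kinase_family.tsv"))
write_tsv(qpcr, file.path(out, "qpcr_ratios.tsv"))
gmt <- vapply(names(bundle$go_terms), function(id)
  paste(c(id, "cold-related", bundle$go_terms[[id]]), collapse = "\t"),
  character(1))
writeLines(gmt, file.path(out, "go_sets.gmt"))

cat("samples:", nrow(design), "\n")
cat("genes:  ", nrow(sim$counts), "\n")
cat("planted non-null genes:", sum(sim$truth$archetype != "NULL"), "\n")
cat("written to", out, "\n")
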