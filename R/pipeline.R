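# End-to-end orchestration: simulate (or load) -> normalise -> nine
# contrasts -> filters -> ANOVA cascade -> pattern clustering ->
# functional summaries, with a run report recording the gene count at
# every stage and the thresholds and seed used.

#' Run configuration
#'
#' Houses the selection thresholds (with the study's values as
#' defaults), the per-set cluster counts, the seed and the simulation
#' settings.
#'
#' @param sim A [simulation_config()] (used when no counts are given).
#' @param count_threshold Total normalized-count filter (default 48).
#' @param deg_alpha Adjusted-p DEG threshold (default 0.02).
#' @param annot_evalue Annotation E-value threshold (default 9e-4).
#' @param anova_alpha Per-factor cascade threshold (default 0.05).
#' @param k_per_set Cluster counts per set (LR 2, TCR 2, TLSR 4).
#' @param seed Integer seed; flows to every random stage.
#' @return List of class `run_config`.
#' @export
run_config <- function(sim = simulation_config(seed = seed),
                       count_threshold = 48, deg_alpha = 0.02,
                       annot_evalue = 9e-4, anova_alpha = 0.05,
                       k_per_set = c(LR = 2, TCR = 2, TLSR = 4),
                       seed = 42) {
  if (count_threshold < 0 || deg_alpha < 0 || annot_evalue < 0 ||
      anova_alpha < 0)
    stop("thresholds must be non-negative")
  if (any(k_per_set < 1)) stop("cluster counts must be >= 1")
  structure(list(sim = sim, count_threshold = count_threshold,
                 deg_alpha = deg_alpha, annot_evalue = annot_evalue,
                 anova_alpha = anova_alpha, k_per_set = k_per_set,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full cascade pipeline
#'
#' Stages: (1) simulate or accept counts under the factorial design;
#' (2) size factors and normalization; (3) testability, total-count
#' filter, nine NB Wald contrasts, BH adjustment, DEG selection, and
#' (when an annotation bundle is present) the annotation filter;
#' (4) line x treatment ANOVA cascade into LR / TCR / TLSR / NS;
#' (5) per-set average-linkage pattern clustering and subset labels;
#' (6) functional summaries. Identical config and seed give identical
#' outputs.
#'
#' @param config A [run_config()].
#' @param counts Optional count matrix (otherwise simulated).
#' @param design Sample design (default [canonical_design()]).
#' @param bundle Optional `annotation_bundle`; when NULL and counts are
#'   simulated, no annotation filter is applied.
#' @param out_dir Optional directory; when given, all stage tables and
#'   the report are written there as tab-separated text.
#' @return List of class `cascade_run`: counts, truth (if simulated),
#'   filter report, contrast table, anova table, classification,
#'   subsets, summary, report.
#' @export
run_pipeline <- function(config = run_config(), counts = NULL,
                         design = canonical_design(), bundle = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  truth <- NULL
  if (is.null(counts)) {
    sim <- simulate_counts(config$sim, design)
    counts <- sim$counts
    truth <- sim$truth
  }
  norm <- normalize_counts(counts)
  freport <- filter_report(counts, design, bundle = bundle,
                           count_threshold = config$count_threshold,
                           deg_alpha = config$deg_alpha,
                           evalue_max = config$annot_evalue)
  contrasts <- attr(freport, "contrasts")
  degs <- freport$gene_id[freport$passed_annotation_filter]

  if (length(degs) > 0) {
    lg <- log_transform(norm)
    anova <- anova_table(lg[degs, , drop = FALSE], design)
    classification <- classify_cascade(anova, degs,
                                       alpha = config$anova_alpha)
    subsets <- cluster_patterns(classification, norm, design,
                                k_per_set = config$k_per_set)
    summary_tab <- if (!is.null(bundle))
      summarize_sets(subsets, bundle) else NULL
  } else {
    anova <- NULL
    classification <- data.frame(gene_id = character(0),
                                 set_label = character(0))
    subsets <- data.frame(gene_id = character(0),
                          set_label = character(0),
                          cluster_id = integer(0),
                          subset_label = character(0))
    summary_tab <- NULL
  }

  counts_stage <- cascade_set_counts(
    if (nrow(classification) > 0) classification else
      list(n_total = 0L, n_lr = 0L, n_tcr = 0L, n_tlsr = 0L, n_ns = 0L))
  report <- list(
    seed = config$seed,
    thresholds = list(count_total = config$count_threshold,
                      deg_alpha = config$deg_alpha,
                      annot_evalue = config$annot_evalue,
                      anova_alpha = config$anova_alpha),
    n_genes = nrow(counts),
    n_testable = sum(freport$testable),
    n_pass_count_filter = sum(freport$passed_count_filter),
    n_deg = sum(freport$passed_deg_filter),
    n_deg_annotated = sum(freport$passed_annotation_filter),
    set_counts = counts_stage,
    subset_counts = as.list(table(subsets$subset_label)))
  run <- structure(list(counts = counts, truth = truth, design = design,
                        norm = norm, filter_report = freport,
                        contrasts = contrasts, anova = anova,
                        classification = classification,
                        subsets = subsets, summary = summary_tab,
                        report = report),
                   class = "cascade_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.cascade_run <- function(x, ...) {
  r <- x$report
  cat("cascade run (seed ", r$seed, ")\n", sep = "")
  cat("  genes:          ", r$n_genes, "\n")
  cat("  testable:       ", r$n_testable, "\n")
  cat("  > count filter: ", r$n_pass_count_filter, "\n")
  cat("  DEGs:           ", r$n_deg, "\n")
  cat("  DEGs annotated: ", r$n_deg_annotated, "\n")
  sc <- r$set_counts
  cat("  LR / TCR / TLSR / NS: ", sc$n_lr, "/", sc$n_tcr, "/",
      sc$n_tlsr, "/", sc$n_ns, "\n")
  invisible(x)
}

#' Write all stage tables of a run
#'
#' @param run A `cascade_run`.
#' @param out_dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_counts(run$counts, p("counts.tsv"))
  write_design(run$design, p("design.tsv"))
  if (!is.null(run$truth)) write_tsv(run$truth, p("truth.tsv"))
  write_tsv(run$filter_report, p("filter_report.tsv"))
  write_tsv(run$contrasts, p("contrast_table.tsv"))
  if (!is.null(run$anova)) write_tsv(run$anova, p("anova_table.tsv"))
  write_tsv(as.data.frame(run$classification), p("classification.tsv"))
  write_tsv(run$subsets, p("subsets.tsv"))
  if (!is.null(run$summary)) write_tsv(run$summary, p("summary.tsv"))
  trees <- attr(run$subsets, "trees")
  for (set in names(trees))
    write_tsv(trees[[set]], p(paste0("tree_", set, ".tsv")))
  rep_lines <- c(
    paste0("# seed\t", run$report$seed),
    paste0("n_genes\t", run$report$n_genes),
    paste0("n_testable\t", run$report$n_testable),
    paste0("n_pass_count_filter\t", run$report$n_pass_count_filter),
    paste0("n_deg\t", run$report$n_deg),
    paste0("n_deg_annotated\t", run$report$n_deg_annotated),
    paste0("n_lr\t", run$report$set_counts$n_lr),
    paste0("n_tcr\t", run$report$set_counts$n_tcr),
    paste0("n_tlsr\t", run$report$set_counts$n_tlsr),
    paste0("n_ns\t", run$report$set_counts$n_ns))
  writeLines(rep_lines, p("report.tsv"))
  invisible(out_dir)
}

#' Compare planted truth with the recovered classification
#'
#' Maps archetype labels to their expected set (LR_* -> LR, TCR_* ->
#' TCR, TLSR_* -> TLSR) and subset (LR_CH_UP -> LRa, LR_TE_UP -> LRb,
#' TCR_DOWN -> TCRa, TCR_UP -> TCRb, TLSR_A..D -> TLSRa..d) and
#' reports per-class sensitivity and the confusion table.
#'
#' @param truth Truth table from [simulate_counts()].
#' @param classification A `gene_classification`.
#' @param subsets Subset assignment from [cluster_patterns()].
#' @return List: `set_recovery` (overall + per-class fractions),
#'   `subset_recovery`, `confusion` (table), `lr_to_tcr_leakage`.
#' @export
recovery_report <- function(truth, classification, subsets = NULL) {
  expected_set <- c(LR_CH_UP = "LR", LR_TE_UP = "LR",
                    TCR_DOWN = "TCR", TCR_UP = "TCR",
                    TLSR_A = "TLSR", TLSR_B = "TLSR",
                    TLSR_C = "TLSR", TLSR_D = "TLSR")
  expected_subset <- c(LR_CH_UP = "LRa", LR_TE_UP = "LRb",
                       TCR_DOWN = "TCRa", TCR_UP = "TCRb",
                       TLSR_A = "TLSRa", TLSR_B = "TLSRb",
                       TLSR_C = "TLSRc", TLSR_D = "TLSRd")
  nn <- truth[truth$archetype != "NULL", ]
  got <- setNames(classification$set_label, classification$gene_id)
  obs <- got[nn$gene_id]
  obs[is.na(obs)] <- "missing"
  exp_set <- expected_set[nn$archetype]
  confusion <- table(planted = nn$archetype, recovered = obs)
  per_class <- tapply(obs == exp_set, nn$archetype, mean)
  overall <- mean(obs == exp_set)
  lr <- nn$archetype %in% c("LR_CH_UP", "LR_TE_UP")
  lr_to_tcr <- mean(obs[lr] == "TCR")
  out <- list(set_recovery = list(overall = overall,
                                  per_class = per_class),
              confusion = confusion, lr_to_tcr_leakage = lr_to_tcr)
  if (!is.null(subsets)) {
    sub_got <- setNames(subsets$subset_label, subsets$gene_id)
    correct_set <- nn$gene_id[obs == exp_set]
    sub_obs <- sub_got[correct_set]
    sub_exp <- expected_subset[nn$archetype[match(correct_set,
                                                  nn$gene_id)]]
    ok <- !is.na(sub_obs) & sub_obs == sub_exp
    out$subset_recovery <- list(
      overall = mean(ok),
      per_class = tapply(ok, nn$archetype[match(correct_set, nn$gene_id)],
                         mean))
  }
  out
}
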