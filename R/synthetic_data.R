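# Synthetic count generator with planted expression archetypes.
#
# Mean model (log2 scale), per gene g and sample s:
#   log2 mu_gs = log2(base_mean) + offset_g * (+1/2 if Ch, -1/2 if Te)
#              + slope_g * step(time_s) * [treatment_s == LT] * gate
# step(T0, T1, T2) = 0, 1, 2.  Counts ~ NB(mean = sf_s * mu_gs,
# variance = mu + dispersion * mu^2).  Control (N) samples never see
# the slope, so LT0 columns are distributionally identical to N
# columns of the same line.

ARCHETYPES <- c("NULL", "LR_CH_UP", "LR_TE_UP", "TCR_DOWN", "TCR_UP",
                "TLSR_A", "TLSR_B", "TLSR_C", "TLSR_D")

# signs of (line offset, LT slope) per non-null archetype
archetype_effects <- function(label, offset, slope) {
  switch(label,
    "NULL"     = c(0, 0),
    "LR_CH_UP" = c(+offset, 0),
    "LR_TE_UP" = c(-offset, 0),
    "TCR_DOWN" = c(0, -slope),
    "TCR_UP"   = c(0, +slope),
    "TLSR_A"   = c(+offset, -slope),
    "TLSR_B"   = c(+offset, +slope),
    "TLSR_C"   = c(-offset, -slope),
    "TLSR_D"   = c(-offset, +slope),
    stop("unknown archetype: ", label))
}

#' Simulation configuration
#'
#' Default configuration: 1000 null genes and 100 genes per non-null
#' archetype, base mean 100, negative-binomial dispersion 0.05, line
#' offset 1.5 log2 units, cold-response slope 1.0 log2 units per LT
#' time step, unit library size factors, seed 42.
#'
#' @param n_genes_per_archetype Named integer vector over the archetype
#'   labels (`NULL` genes use the name `"NULL"`).
#' @param base_mean Expected count at the reference condition.
#' @param dispersion NB dispersion alpha in variance = mu + alpha mu^2.
#' @param effect_offset Absolute line offset (log2, Ch minus Te).
#' @param effect_slope Absolute LT slope (log2 per time step).
#' @param library_size_factors Per-sample positive reals, recycled to
#'   the design size.
#' @param line_specific_slope If TRUE, TLSR archetypes apply their
#'   slope in the Ch line only; by default the slope acts in both
#'   lines, the lines differing by the offset (the pattern shown by
#'   the study's line-specific subsets).
#' @param seed Integer RNG seed.
#' @return List of class `sim_config`.
#' @export
simulation_config <- function(n_genes_per_archetype = NULL,
                              base_mean = 100, dispersion = 0.05,
                              effect_offset = 1.5, effect_slope = 1.0,
                              library_size_factors = 1,
                              line_specific_slope = FALSE,
                              seed = 42) {
  if (is.null(n_genes_per_archetype)) {
    n_genes_per_archetype <- setNames(c(1000L, rep(100L, 8)), ARCHETYPES)
  }
  unknown <- setdiff(names(n_genes_per_archetype), ARCHETYPES)
  if (length(unknown) > 0)
    stop("unknown archetype name(s): ", paste(unknown, collapse = ", "))
  if (any(n_genes_per_archetype < 0)) stop("negative gene count")
  if (base_mean <= 0) stop("base_mean must be positive")
  if (dispersion <= 0) stop("dispersion must be positive")
  if (any(library_size_factors <= 0)) stop("size factors must be positive")
  structure(list(n_genes_per_archetype = n_genes_per_archetype,
                 base_mean = base_mean, dispersion = dispersion,
                 effect_offset = effect_offset, effect_slope = effect_slope,
                 library_size_factors = library_size_factors,
                 line_specific_slope = line_specific_slope,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a count matrix with planted gene classes
#'
#' @param config A [simulation_config()].
#' @param design A `sample_design` (defaults to [canonical_design()]).
#' @return List with `counts` (integer matrix genes x samples) and
#'   `truth` (data frame: gene_id, archetype, line_offset, lt_slope).
#' @export
simulate_counts <- function(config, design = canonical_design()) {
  stopifnot(inherits(config, "sim_config"))
  n_per <- config$n_genes_per_archetype
  labels <- rep(names(n_per), n_per)
  n_genes <- length(labels)
  if (n_genes == 0) stop("no genes requested")
  gene_ids <- sprintf("gene%05d", seq_len(n_genes))

  eff <- t(vapply(labels, archetype_effects, numeric(2),
                  offset = config$effect_offset,
                  slope = config$effect_slope))
  truth <- data.frame(gene_id = gene_ids, archetype = labels,
                      line_offset = eff[, 1], lt_slope = eff[, 2],
                      stringsAsFactors = FALSE)

  n_samp <- nrow(design)
  sf <- rep_len(config$library_size_factors, n_samp)
  step <- as.integer(design$time) - 1L                 # T0,T1,T2 -> 0,1,2
  is_lt <- design$treatment == "LT"
  line_sign <- ifelse(design$line == "Ch", +0.5, -0.5)
  # slope gate: 1 where the slope acts (LT samples; optionally Ch only
  # for TLSR archetypes)
  slope_gate <- matrix(rep(as.numeric(is_lt), each = n_genes),
                       n_genes, n_samp)
  if (isTRUE(config$line_specific_slope)) {
    tlsr <- grepl("^TLSR", labels)
    gate_te <- outer(tlsr, design$line == "Te" & is_lt, FUN = "&")
    slope_gate[gate_te] <- 0
  }
  log2mu <- log2(config$base_mean) +
    outer(truth$line_offset, line_sign) +
    sweep(truth$lt_slope * slope_gate, 2, step, `*`)
  mu <- sweep(2^log2mu, 2, sf, `*`)

  set.seed(config$seed)
  counts <- matrix(stats::rnbinom(n_genes * n_samp, mu = as.vector(mu),
                                  size = 1 / config$dispersion),
                   n_genes, n_samp)
  dimnames(counts) <- list(gene_ids, design$sample_id)
  storage.mode(counts) <- "integer"
  list(counts = counts, truth = truth)
}

#' Simulate annotation sidecars for a simulated gene set
#'
#' A configurable fraction of genes receive a best hit whose E-value is
#' drawn log-uniformly over `evalue_range`; configurable fractions
#' receive transcription-factor family, kinase family, and cold-related
#' GO labels. Family labels are drawn from small fixed vocabularies of
#' plant TF and kinase families.
#'
#' @param truth Truth table from [simulate_counts()].
#' @param annotated_fraction Fraction of genes with a best hit.
#' @param evalue_range Length-2 positive range for the log-uniform
#'   E-value draw (default straddles the 9e-4 annotation threshold).
#' @param tf_fraction,kinase_fraction,cold_go_fraction Label fractions.
#' @param seed Integer RNG seed.
#' @return An [annotation_bundle()].
#' @export
simulate_annotation <- function(truth, annotated_fraction = 1.0,
                                evalue_range = c(1e-10, 1e-1),
                                tf_fraction = 0.08,
                                kinase_fraction = 0.04,
                                cold_go_fraction = 0.03,
                                seed = 42) {
  if (nrow(truth) == 0) stop("truth table is empty")
  fracs <- c(annotated_fraction, tf_fraction, kinase_fraction,
             cold_go_fraction)
  if (any(fracs < 0 | fracs > 1)) stop("fraction outside [0, 1]")
  if (any(evalue_range <= 0) || evalue_range[1] > evalue_range[2])
    stop("invalid evalue_range")
  set.seed(seed)
  genes <- truth$gene_id
  n <- length(genes)

  annotated <- genes[stats::runif(n) < annotated_fraction]
  lr <- log(evalue_range)
  ev <- exp(stats::runif(length(annotated), lr[1], lr[2]))
  best_hit <- data.frame(gene_id = annotated,
                         subject_id = sprintf("AT%d", seq_along(annotated)),
                         evalue = ev, stringsAsFactors = FALSE)

  tf_families <- c("AP2-EREBP", "bHLH", "MYB", "WRKY", "C2H2", "NAC",
                   "C3H", "C2C2-CO-like", "bZIP", "GRAS")
  kin_families <- c("RLK-Pelle", "CAMK", "CMGC", "STE", "TKL", "AGC")
  tf_genes <- genes[stats::runif(n) < tf_fraction]
  kin_genes <- genes[stats::runif(n) < kinase_fraction]
  tf_family <- data.frame(gene_id = tf_genes,
                          family = sample(tf_families, length(tf_genes),
                                          replace = TRUE),
                          stringsAsFactors = FALSE)
  kinase_family <- data.frame(gene_id = kin_genes,
                              family = sample(kin_families, length(kin_genes),
                                              replace = TRUE),
                              stringsAsFactors = FALSE)

  cold_ids <- c("GO:0009409", "GO:0009631", "GO:0070417")
  cold_genes <- genes[stats::runif(n) < cold_go_fraction]
  go_terms <- lapply(cold_ids, function(id) {
    members <- cold_genes[stats::runif(length(cold_genes)) < 1 / 2]
    unique(members)
  })
  names(go_terms) <- cold_ids
  # guarantee every cold gene carries at least one of the three ids
  orphan <- setdiff(cold_genes, unique(unlist(go_terms)))
  if (length(orphan) > 0)
    go_terms[["GO:0009409"]] <- union(go_terms[["GO:0009409"]], orphan)

  annotation_bundle(best_hit = best_hit, tf_family = tf_family,
                    kinase_family = kinase_family, go_terms = go_terms)
}

#' Simulate a paired qPCR / RNA-seq log-ratio table
#'
#' For each chosen non-null transcript and LT time point T1 and T2, the
#' RNA-seq log2 ratio relative to T0 is taken from the planted truth
#' (slope x step) and the qPCR log2 ratio equals that truth plus
#' Gaussian noise, emulating an independent measurement of the same
#' regulation.
#'
#' @param truth Truth table from [simulate_counts()].
#' @param n_transcripts Number of non-null transcripts to pair.
#' @param noise_sd Standard deviation of the qPCR measurement noise.
#' @param seed Integer RNG seed.
#' @return Data frame: transcript, timepoint (T1/T2), rnaseq_log2_ratio,
#'   qpcr_log2_ratio.
#' @export
simulate_qpcr <- function(truth, n_transcripts = 33, noise_sd = 0.5,
                          seed = 42) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  nn <- truth[truth$archetype != "NULL" & truth$lt_slope != 0, ]
  if (n_transcripts > nrow(nn))
    stop("n_transcripts exceeds the number of cold-responsive genes")
  set.seed(seed)
  chosen <- nn[sample.int(nrow(nn), n_transcripts), ]
  out <- do.call(rbind, lapply(1:2, function(step) {
    data.frame(transcript = chosen$gene_id,
               timepoint = paste0("T", step),
               rnaseq_log2_ratio = chosen$lt_slope * step,
               stringsAsFactors = FALSE)
  }))
  out$qpcr_log2_ratio <- out$rnaseq_log2_ratio +
    stats::rnorm(nrow(out), 0, noise_sd)
  rownames(out) <- NULL
  out
}
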