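# Normalisation, negative-binomial contrast testing, and the three
# selection filters that define the DEG universe:
#   (1) testability (enough reads for the statistical test),
#   (2) total normalized count > 48 over the 24 samples,
#   (3) adjusted p <= 0.02 in >= 1 of the nine condition contrasts,
# plus the annotation filter (best-hit E-value <= 9e-4).

#' The nine condition contrasts
#'
#' Each contrast compares two of the twelve (line, treatment, time)
#' conditions: the T0 line comparison under control, and the T1/T2
#' versus T0 comparisons within each line and treatment.
#'
#' @return Character vector of nine `"A:B"` contrast names.
#' @export
nine_contrasts <- function() {
  c("ChNT0:TeNT0",
    "ChNT0:ChNT1", "ChNT0:ChNT2",
    "ChLT0:ChLT1", "ChLT0:ChLT2",
    "TeNT0:TeNT1", "TeNT0:TeNT2",
    "TeLT0:TeLT1", "TeLT0:TeLT2")
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over reference genes
#' of the ratio of the gene's count in the sample to the gene's
#' geometric mean across all samples. Reference genes are those with no
#' zero count; when no such gene exists, genes with zeros in at most
#' `fallback_zero_frac` of samples are used, their zeros excluded from
#' the geometric mean. Factors are returned unscaled (no re-centring).
#'
#' @param counts Integer count matrix, genes x samples.
#' @param fallback_zero_frac Maximum fraction of zero samples a gene
#'   may have to enter the fallback reference set.
#' @return Named numeric vector of positive size factors.
#' @export
size_factors <- function(counts, fallback_zero_frac = 0.2) {
  counts <- as.matrix(counts)
  n_zero <- rowSums(counts == 0)
  ref <- n_zero == 0
  if (!any(ref)) {
    ref <- n_zero <= fallback_zero_frac * ncol(counts) & n_zero < ncol(counts)
    if (!any(ref))
      stop("no usable reference gene: every gene has zeros in more than ",
           round(100 * fallback_zero_frac), "% of samples; supply more ",
           "genes or raise fallback_zero_frac")
  }
  refc <- counts[ref, , drop = FALSE]
  log_gm <- apply(refc, 1, function(x) mean(log(x[x > 0])))
  log_ratio <- log(refc) - log_gm          # -Inf where count is 0
  sf <- apply(log_ratio, 2, function(lr) exp(stats::median(lr[is.finite(lr)])))
  if (any(!is.finite(sf) | sf <= 0))
    stop("non-positive size factor estimated; matrix too sparse")
  setNames(sf, colnames(counts))
}

#' Normalize counts by size factors
#'
#' @param counts Count matrix.
#' @param sf Size factors (defaults to [size_factors()] of `counts`).
#' @return List of class `normalized_matrix` with elements `values`
#'   (genes x samples reals) and `size_factors`.
#' @export
normalize_counts <- function(counts, sf = size_factors(counts)) {
  stopifnot(length(sf) == ncol(counts), all(sf > 0))
  values <- sweep(as.matrix(counts), 2, sf, `/`)
  structure(list(values = values, size_factors = sf),
            class = "normalized_matrix")
}

#' Testability flags
#'
#' A gene is testable when its counts suffice for the contrast test:
#' nonzero in at least two samples.
#'
#' @param counts Count matrix.
#' @return Named logical vector per gene.
#' @export
testable_flags <- function(counts) {
  setNames(rowSums(as.matrix(counts) > 0) >= 2, rownames(counts))
}

#' Low-total-count filter
#'
#' Genes whose normalized counts sum to `threshold` or less over all
#' samples are discarded (flag FALSE); the boundary value itself is
#' discarded.
#'
#' @param norm A `normalized_matrix`.
#' @param threshold Total normalized-count threshold (default 48).
#' @return Named logical vector: TRUE = kept.
#' @export
low_count_filter <- function(norm, threshold = 48) {
  tot <- rowSums(norm$values)
  setNames(tot > threshold, rownames(norm$values))
}

#' Per-gene NB dispersion by method of moments
#'
#' Within-cell mean and variance of normalized counts are pooled over
#' the design cells (line x treatment x time), giving
#' alpha = max((s2 - mu) / mu^2, 1e-8). With `shrink` > 0 the per-gene
#' estimate is shrunk toward the across-gene mean with weight
#' `shrink` pseudo-cells, stabilising the Wald denominator under the
#' two-replicate design.
#'
#' @param norm A `normalized_matrix`.
#' @param design Matching `sample_design`.
#' @param shrink Shrinkage weight in pseudo-cells (0 = none).
#' @return Named numeric vector of dispersions (>= 1e-8).
#' @export
estimate_dispersions <- function(norm, design, shrink = 12) {
  v <- norm$values
  cell <- interaction(design$line, design$treatment, design$time, drop = TRUE)
  cells <- levels(cell)
  n_cells <- length(cells)
  cell_means <- vapply(cells, function(cl)
    rowMeans(v[, cell == cl, drop = FALSE]), numeric(nrow(v)))
  cell_vars <- vapply(cells, function(cl)
    apply(v[, cell == cl, drop = FALSE], 1, stats::var), numeric(nrow(v)))
  mu_bar <- rowMeans(cell_means)
  s2 <- rowMeans(cell_vars)
  raw <- ifelse(mu_bar > 0, (s2 - mu_bar) / mu_bar^2, 0)
  raw <- pmax(raw, 1e-8)
  if (shrink > 0) {
    trend <- mean(raw)
    raw <- (n_cells * raw + shrink * trend) / (n_cells + shrink)
  }
  setNames(pmax(raw, 1e-8), rownames(v))
}

# Wald test for one two-group contrast, vectorised over genes.
# Normalized group means m_A, m_B; shared per-gene dispersion alpha.
# Var(log mean) ~ (1/(n m) + alpha/n) by the delta method on NB means.
wald_contrast <- function(norm, idx_a, idx_b, dispersions) {
  v <- norm$values
  n_a <- length(idx_a); n_b <- length(idx_b)
  m_a <- rowMeans(v[, idx_a, drop = FALSE])
  m_b <- rowMeans(v[, idx_b, drop = FALSE])
  testable <- m_a > 0 & m_b > 0
  lfc <- ifelse(testable, log2(m_b) - log2(m_a), 0)
  var_log <- ifelse(testable,
                    (1 / m_a + dispersions) / n_a +
                    (1 / m_b + dispersions) / n_b, Inf)
  z <- ifelse(testable & m_a != m_b,
              (log(m_b) - log(m_a)) / sqrt(var_log), 0)
  p <- ifelse(testable & m_a != m_b,
              2 * stats::pnorm(-abs(z)), 1)
  data.frame(log2_fold_change = lfc, p_raw = p, testable = testable)
}

#' Negative-binomial Wald test for one contrast
#'
#' Fits the two-group NB mean model on normalized counts with a shared
#' per-gene dispersion and tests the log2 fold change against zero
#' with a normal-reference Wald statistic. Groups with zero mean in
#' either arm are untestable for the contrast (p = 1, fold change 0);
#' exactly equal group means give statistic 0 and p = 1.
#'
#' @param counts Count matrix.
#' @param design Matching `sample_design`.
#' @param contrast `"A:B"` string over condition labels (see
#'   [condition_labels()]), or length-2 character vector.
#' @param norm Optional precomputed `normalized_matrix`.
#' @param dispersions Optional precomputed dispersion vector.
#' @return Data frame: gene_id, log2_fold_change, p_raw, testable.
#' @export
nb_contrast_test <- function(counts, design, contrast,
                             norm = normalize_counts(counts),
                             dispersions = estimate_dispersions(norm, design)) {
  if (length(contrast) == 1) contrast <- strsplit(contrast, ":")[[1]]
  stopifnot(length(contrast) == 2)
  cond <- as.character(condition_labels(design))
  idx_a <- which(cond == contrast[1])
  idx_b <- which(cond == contrast[2])
  if (length(idx_a) == 0 || length(idx_b) == 0)
    stop("empty contrast group: ", paste(contrast, collapse = ":"))
  res <- wald_contrast(norm, idx_a, idx_b, dispersions)
  cbind(data.frame(gene_id = rownames(norm$values),
                   stringsAsFactors = FALSE), res)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity
#' enforcement; inputs outside [0, 1] are an error.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values, elementwise >= the input.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Build the full contrast table
#'
#' Runs [nb_contrast_test()] for all nine contrasts and BH-adjusts
#' p-values per contrast across genes.
#'
#' @param counts Count matrix.
#' @param design Matching `sample_design`.
#' @param contrasts Contrast names (default [nine_contrasts()]).
#' @return Long data frame: gene_id, contrast, log2_fold_change,
#'   p_raw, p_adj, testable.
#' @export
contrast_table <- function(counts, design, contrasts = nine_contrasts()) {
  norm <- normalize_counts(counts)
  disp <- estimate_dispersions(norm, design)
  out <- do.call(rbind, lapply(contrasts, function(cn) {
    res <- nb_contrast_test(counts, design, cn, norm = norm,
                            dispersions = disp)
    res$p_adj <- bh_adjust(res$p_raw)
    res$contrast <- cn
    res
  }))
  out[, c("gene_id", "contrast", "log2_fold_change", "p_raw", "p_adj",
          "testable")]
}

#' DEG selection from a contrast table
#'
#' A gene is selected when its minimum adjusted p-value over the
#' contrasts is `alpha` or less (the boundary is retained).
#'
#' @param contrasts Long contrast table from [contrast_table()].
#' @param alpha Adjusted-p threshold (default 0.02).
#' @return Named logical vector per gene.
#' @export
deg_selection <- function(contrasts, alpha = 0.02) {
  split_p <- split(contrasts$p_adj, contrasts$gene_id)
  min_p <- vapply(split_p, min, numeric(1))
  (min_p <= alpha)[unique(contrasts$gene_id)]
}

#' Annotation significance filter
#'
#' A gene passes when it has a best hit with E-value at most
#' `evalue_max`; the boundary passes, genes without a hit fail.
#'
#' @param bundle An `annotation_bundle`.
#' @param genes Genes to flag.
#' @param evalue_max E-value threshold (default 9e-4).
#' @return Named logical vector over `genes`.
#' @export
annotation_filter <- function(bundle, genes, evalue_max = 9e-4) {
  hit <- bundle$best_hit
  ev <- setNames(hit$evalue, hit$gene_id)[genes]
  setNames(!is.na(ev) & ev <= evalue_max, genes)
}

#' Per-gene filter report
#'
#' Collects the testability flag, total normalized count and count
#' filter, minimum adjusted p and DEG filter, and (when a bundle is
#' supplied) best E-value and annotation filter, with the implication
#' chain deg => count filter => testable enforced.
#'
#' @param counts Count matrix.
#' @param design Matching `sample_design`.
#' @param bundle Optional `annotation_bundle`.
#' @param count_threshold,deg_alpha,evalue_max Filter thresholds.
#' @param contrasts Optional precomputed [contrast_table()].
#' @return Data frame, one row per gene, plus the contrast table in
#'   attribute `"contrasts"`.
#' @export
filter_report <- function(counts, design, bundle = NULL,
                          count_threshold = 48, deg_alpha = 0.02,
                          evalue_max = 9e-4, contrasts = NULL) {
  norm <- normalize_counts(counts)
  testable <- testable_flags(counts)
  total_norm <- rowSums(norm$values)
  pass_count <- testable & low_count_filter(norm, count_threshold)
  if (is.null(contrasts)) contrasts <- contrast_table(counts, design)
  min_p <- tapply(contrasts$p_adj, contrasts$gene_id, min)[rownames(counts)]
  pass_deg <- pass_count & !is.na(min_p) & min_p <= deg_alpha
  rep <- data.frame(gene_id = rownames(counts), testable = testable,
                    total_normalized_count = total_norm,
                    passed_count_filter = pass_count,
                    min_adj_p = as.numeric(min_p),
                    passed_deg_filter = pass_deg,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(bundle)) {
    ev <- setNames(bundle$best_hit$evalue, bundle$best_hit$gene_id)
    rep$best_evalue <- as.numeric(ev[rep$gene_id])
    rep$passed_annotation_filter <- pass_deg &
      annotation_filter(bundle, rep$gene_id, evalue_max)
  } else {
    rep$best_evalue <- NA_real_
    rep$passed_annotation_filter <- pass_deg
  }
  attr(rep, "contrasts") <- contrasts
  rep
}
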