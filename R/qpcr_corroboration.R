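# Corroboration of the RNA-seq fold changes against an earlier qPCR
# experiment: unigenes are linked to the qPCR ESTs through stringent
# BLAST-hit thresholds, the RNA-seq T0/T1/T2 samples are matched to
# the qPCR T0/T6/T10 samplings, and the agreement is summarised by the
# uncentered (cosine) correlation of the paired log2 ratios.

#' Time mapping between RNA-seq and qPCR samplings
#'
#' @return Named character vector: RNA-seq time -> qPCR time
#'   (T0 -> T0, T1 -> T6, T2 -> T10).
#' @export
qpcr_time_map <- function() c(T0 = "T0", T1 = "T6", T2 = "T10")

#' Filter BLAST hits to qPCR links
#'
#' Keeps hits with E-value <= `evalue_max` AND alignment length >=
#' `min_len` AND percent identity >= `min_identity` (all boundaries
#' inclusive), then retains the best hit per (query, subject) pair by
#' lowest E-value, ties broken by highest bit score.
#'
#' @param hits Data frame from [read_blast_tab()].
#' @param evalue_max,min_len,min_identity Link thresholds (defaults
#'   1e-25, 200 bp, 95 percent).
#' @return Filtered hit data frame, one row per retained link.
#' @export
link_filter <- function(hits, evalue_max = 1e-25, min_len = 200,
                        min_identity = 95) {
  keep <- hits$evalue <= evalue_max &
    hits$alignment_length >= min_len &
    hits$percent_identity >= min_identity
  kept <- hits[keep, , drop = FALSE]
  if (nrow(kept) == 0) return(kept)
  ord <- order(kept$query_id, kept$subject_id, kept$evalue,
               -kept$bit_score)
  kept <- kept[ord, , drop = FALSE]
  first <- !duplicated(kept[, c("query_id", "subject_id")])
  out <- kept[first, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Uncentered (cosine) correlation
#'
#' R = sum(x y) / sqrt(sum(x^2) sum(y^2)). Unlike Pearson's r the
#' vectors are not centred, matching the corroboration statistic as
#' reported; `centered = TRUE` gives Pearson's r for comparison.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @param centered Use the centred (Pearson) form instead.
#' @return Correlation in [-1, 1].
#' @export
uncentered_correlation <- function(x, y, centered = FALSE) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least 2 pairs")
  if (centered) return(stats::cor(x, y))
  den <- sqrt(sum(x^2) * sum(y^2))
  if (den == 0) stop("zero denominator: a vector is all-zero")
  sum(x * y) / den
}

#' Assemble paired ratios and the corroboration R
#'
#' Joins the RNA-seq and qPCR log2-ratio tables through the link list
#' and the time mapping, and computes the uncentered correlation over
#' all pairs.
#'
#' @param rnaseq_ratios Data frame: transcript (unigene id), timepoint
#'   (RNA-seq times), log2_ratio.
#' @param qpcr_ratios Data frame: transcript (EST id), timepoint (qPCR
#'   times), log2_ratio.
#' @param links Data frame from [link_filter()] with `query_id`
#'   (unigene) and `subject_id` (EST).
#' @param time_map Named vector RNA-seq time -> qPCR time.
#' @return List: `pairs` (unigene, est, timepoint, rnaseq_log2_ratio,
#'   qpcr_log2_ratio), `R`.
#' @export
corroborate <- function(rnaseq_ratios, qpcr_ratios, links,
                        time_map = qpcr_time_map()) {
  if (nrow(links) == 0) stop("no links between unigenes and ESTs")
  pairs <- NULL
  for (i in seq_len(nrow(links))) {
    uni <- links$query_id[i]; est <- links$subject_id[i]
    rs <- rnaseq_ratios[rnaseq_ratios$transcript == uni, , drop = FALSE]
    for (j in seq_len(nrow(rs))) {
      tp <- rs$timepoint[j]
      qp_time <- time_map[[tp]]
      qp <- qpcr_ratios[qpcr_ratios$transcript == est &
                        qpcr_ratios$timepoint == qp_time, , drop = FALSE]
      if (nrow(qp) == 1)
        pairs <- rbind(pairs, data.frame(
          unigene = uni, est = est, timepoint = tp,
          rnaseq_log2_ratio = rs$log2_ratio[j],
          qpcr_log2_ratio = qp$log2_ratio[1], stringsAsFactors = FALSE))
    }
  }
  if (is.null(pairs) || nrow(pairs) < 2)
    stop("fewer than 2 linked ratio pairs; cannot compute R")
  R <- uncentered_correlation(pairs$qpcr_log2_ratio,
                              pairs$rnaseq_log2_ratio)
  list(pairs = pairs, R = R)
}
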