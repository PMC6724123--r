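# Three-way partition of the DEG universe by a line x treatment ANOVA
# cascade:
#   line significant only        -> LR   (Line Response)
#   treatment significant only   -> TCR  (Temperature Common Response)
#   both significant             -> TLSR (Temperature Line-Specific Response)
#   neither                      -> NS
# The serial two-factor / one-way procedure of the original analysis is
# realised as this simultaneous decision rule on the two factor
# p-values; time points and replicates are pooled as within-cell
# replication (n = 6 per cell on the canonical design).

#' Log2 transform of normalized counts
#'
#' @param norm A `normalized_matrix` (or plain matrix).
#' @param pseudocount Positive offset added before the log (default 1).
#' @return Real matrix log2(value + pseudocount).
#' @export
log_transform <- function(norm, pseudocount = 1) {
  if (pseudocount <= 0) stop("pseudocount must be positive")
  v <- if (inherits(norm, "normalized_matrix")) norm$values else as.matrix(norm)
  log2(v + pseudocount)
}

# p-value used when an effect is perfectly separated with zero residual
P_DEGENERATE <- .Machine$double.xmin

#' Two-factor fixed-effects ANOVA for one gene
#'
#' Classical line x treatment ANOVA (with interaction) on a balanced
#' layout, fitted by `stats::lm`/`stats::anova` on the log-transformed
#' expression vector. Fully constant genes report all p = 1; zero
#' residual variance with a nonzero effect reports the machine-minimum
#' p with `degenerate = TRUE`.
#'
#' @param expr Numeric expression vector over the design's samples.
#' @param design Matching `sample_design`.
#' @return One-row data frame: F and p for line, treatment and
#'   interaction, degrees of freedom, and a `degenerate` flag.
#' @export
two_way_anova <- function(expr, design) {
  stopifnot(length(expr) == nrow(design))
  cell_n <- table(design$line, design$treatment)
  if (length(unique(as.integer(cell_n))) != 1)
    stop("unbalanced line x treatment layout")
  if (stats::var(expr) == 0) {
    return(data.frame(F_line = 0, p_line = 1, F_treatment = 0,
                      p_treatment = 1, F_interaction = 0, p_interaction = 1,
                      df_effect = c(1), df_residual = length(expr) - 4,
                      degenerate = FALSE))
  }
  fit <- stats::lm(expr ~ line * treatment, data = design)
  # degenerate fits are handled below; silence the perfect-fit warning
  tab <- suppressWarnings(stats::anova(fit))
  rss <- tab["Residuals", "Sum Sq"]
  degenerate <- rss <= .Machine$double.eps * sum(expr^2)
  pv <- function(row) {
    if (degenerate) {
      if (tab[row, "Sum Sq"] > .Machine$double.eps * sum(expr^2))
        P_DEGENERATE else 1
    } else tab[row, "Pr(>F)"]
  }
  fv <- function(row) if (is.finite(tab[row, "F value"]))
    tab[row, "F value"] else Inf
  data.frame(F_line = fv("line"), p_line = pv("line"),
             F_treatment = fv("treatment"), p_treatment = pv("treatment"),
             F_interaction = fv("line:treatment"),
             p_interaction = pv("line:treatment"),
             df_effect = tab["line", "Df"],
             df_residual = tab["Residuals", "Df"],
             degenerate = degenerate)
}

#' One-way fixed-effects ANOVA
#'
#' Classical one-way F test via `stats::lm`/`stats::anova`; with two
#' levels the F statistic equals the squared pooled-variance t
#' statistic. Groups with fewer than two samples are an error;
#' constant data reports p = 1; zero residual variance with a real
#' effect reports the machine-minimum p.
#'
#' @param expr Numeric vector.
#' @param grouping Factor with >= 2 levels.
#' @return p-value of the F test.
#' @export
one_way_anova <- function(expr, grouping) {
  grouping <- droplevels(as.factor(grouping))
  if (nlevels(grouping) < 2) stop("grouping needs >= 2 levels")
  if (any(table(grouping) < 2)) stop("every group needs >= 2 samples")
  if (stats::var(expr) == 0) return(1)
  tab <- suppressWarnings(stats::anova(stats::lm(expr ~ grouping)))
  rss <- tab["Residuals", "Sum Sq"]
  if (rss <= .Machine$double.eps * sum(expr^2)) return(P_DEGENERATE)
  tab[1, "Pr(>F)"]
}

#' ANOVA table over a gene set
#'
#' Applies [two_way_anova()] to every row of the log-transformed
#' matrix and BH-adjusts the line, treatment and interaction p-values
#' across genes.
#'
#' @param log_expr Log2-transformed matrix (genes x samples), e.g. from
#'   [log_transform()].
#' @param design Matching `sample_design`.
#' @return Data frame with one row per gene: F statistics, raw and
#'   BH-adjusted p-values.
#' @export
anova_table <- function(log_expr, design) {
  rows <- lapply(seq_len(nrow(log_expr)), function(i)
    two_way_anova(log_expr[i, ], design))
  out <- do.call(rbind, rows)
  out <- cbind(data.frame(gene_id = rownames(log_expr),
                          stringsAsFactors = FALSE), out)
  out$p_line_adj <- bh_adjust(out$p_line)
  out$p_treatment_adj <- bh_adjust(out$p_treatment)
  out$p_interaction_adj <- bh_adjust(out$p_interaction)
  rownames(out) <- NULL
  out
}

#' Cascade classification of the DEG universe
#'
#' With `s_line = p_line_adj <= alpha` and
#' `s_treat = p_treatment_adj <= alpha`:
#' LR when line only, TCR when treatment only, TLSR when both, NS when
#' neither. With `adjust = FALSE` the raw p-values are thresholded
#' instead. `require_interaction` additionally demands a significant
#' interaction for the TLSR label (off by default; genes failing it
#' fall back to TCR).
#'
#' @param anova An [anova_table()] covering all DEGs.
#' @param degs Character vector of DEG ids (default: all rows).
#' @param alpha Per-factor significance threshold (default 0.05).
#' @param adjust Use BH-adjusted p-values (default TRUE).
#' @param require_interaction See above.
#' @return Data frame of class `gene_classification`: gene_id,
#'   set_label in {LR, TCR, TLSR, NS}, the p-values used, provenance.
#' @export
classify_cascade <- function(anova, degs = anova$gene_id, alpha = 0.05,
                             adjust = TRUE, require_interaction = FALSE) {
  missing <- setdiff(degs, anova$gene_id)
  if (length(missing) > 0)
    stop("missing ANOVA row for DEG(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  anova <- anova[match(degs, anova$gene_id), ]
  p_line <- if (adjust) anova$p_line_adj else anova$p_line
  p_treat <- if (adjust) anova$p_treatment_adj else anova$p_treatment
  p_int <- if (adjust) anova$p_interaction_adj else anova$p_interaction
  s_line <- p_line <= alpha
  s_treat <- p_treat <= alpha
  label <- ifelse(s_line & s_treat, "TLSR",
           ifelse(s_line, "LR",
           ifelse(s_treat, "TCR", "NS")))
  if (require_interaction)
    label[label == "TLSR" & p_int > alpha] <- "TCR"
  out <- data.frame(gene_id = degs, set_label = label,
                    p_line = p_line, p_treatment = p_treat,
                    p_interaction = p_int,
                    provenance = paste0("line=", ifelse(s_line, "sig", "ns"),
                                        ";treatment=",
                                        ifelse(s_treat, "sig", "ns")),
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_classification", "data.frame")
  out
}

#' Stage counts of the cascade
#'
#' Reports the set sizes and the subtraction identities of the serial
#' procedure: `remaining_after_lr = n_total - n_lr` is the input to the
#' treatment stage, and `n_total - n_lr - n_tcr = n_tlsr + n_ns`.
#'
#' @param classification A `gene_classification`, or a named vector /
#'   list with elements `n_total`, `n_lr`, `n_tcr` (and optionally
#'   `n_tlsr`, `n_ns`) for worked arithmetic.
#' @return Named list: n_total, n_lr, n_tcr, n_tlsr, n_ns,
#'   remaining_after_lr, remaining_after_tcr.
#' @export
cascade_set_counts <- function(classification) {
  if (inherits(classification, "gene_classification") ||
      (is.data.frame(classification) && "set_label" %in% names(classification))) {
    tab <- table(factor(classification$set_label,
                        levels = c("LR", "TCR", "TLSR", "NS")))
    n_total <- nrow(classification)
    n_lr <- as.integer(tab["LR"]); n_tcr <- as.integer(tab["TCR"])
    n_tlsr <- as.integer(tab["TLSR"]); n_ns <- as.integer(tab["NS"])
  } else {
    cl <- as.list(classification)
    n_total <- cl$n_total; n_lr <- cl$n_lr; n_tcr <- cl$n_tcr
    n_ns <- if (!is.null(cl$n_ns)) cl$n_ns else 0L
    n_tlsr <- if (!is.null(cl$n_tlsr)) cl$n_tlsr else
      n_total - n_lr - n_tcr - n_ns
  }
  stopifnot(n_total == n_lr + n_tcr + n_tlsr + n_ns)
  list(n_total = n_total, n_lr = n_lr, n_tcr = n_tcr, n_tlsr = n_tlsr,
       n_ns = n_ns,
       remaining_after_lr = n_total - n_lr,
       remaining_after_tcr = n_total - n_lr - n_tcr)
}
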