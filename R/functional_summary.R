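# Functional summary tables over the classified gene sets: per-subset
# kinase / transcription-factor / cold-GO tallies with percentages,
# the cold-GO incidence matrix, and a hypergeometric GO-enrichment
# test. Percentages are stored unrounded; display helpers round to
# one decimal (set-level style) or two decimals (ratio style).

#' The three cold-related GO identifiers
#'
#' "response to cold" (GO:0009409), "cold acclimation" (GO:0009631),
#' "cellular response to cold" (GO:0070417).
#'
#' @return Character vector of the three GO ids.
#' @export
cold_go_ids <- function() c("GO:0009409", "GO:0009631", "GO:0070417")

#' Percentage of a count within a subset
#'
#' @param count,n Non-negative integers, `count <= n`.
#' @param digits Rounding digits for display (NULL = unrounded).
#' @return 100 * count / n, rounded when `digits` is given; 0 for an
#'   empty subset.
#' @export
subset_percent <- function(count, n, digits = NULL) {
  p <- ifelse(n > 0, 100 * count / n, 0)
  if (!is.null(digits)) p <- round(p, digits)
  p
}

#' Per-subset functional summary
#'
#' For every pattern subset (and per-set totals): number of genes,
#' kinase count and percentage, TF count, percentage and most
#' represented family, and count/percentage of genes carrying any
#' cold-related GO id. A gene labelled both TF and kinase counts in
#' both tallies.
#'
#' @param subsets Data frame with columns `gene_id`, `set_label`,
#'   `subset_label` (from [cluster_patterns()]), or any assignment of
#'   genes to subsets.
#' @param bundle An `annotation_bundle`.
#' @return Data frame, one row per subset plus one per set, with an
#'   `emptiness` flag for empty subsets.
#' @export
summarize_sets <- function(subsets, bundle) {
  stopifnot(all(c("gene_id", "set_label", "subset_label") %in%
                names(subsets)))
  if (anyDuplicated(subsets$gene_id))
    stop("gene assigned to more than one subset")
  kin <- setNames(bundle$kinase_family$family, bundle$kinase_family$gene_id)
  tf <- setNames(bundle$tf_family$family, bundle$tf_family$gene_id)
  cold <- unique(unlist(bundle$go_terms[intersect(names(bundle$go_terms),
                                                  cold_go_ids())]))
  one_row <- function(label, genes, set) {
    n <- length(genes)
    n_kin <- sum(genes %in% names(kin))
    n_tf <- sum(genes %in% names(tf))
    n_cold <- sum(genes %in% cold)
    mrf <- most_represented_family(genes, tf)
    data.frame(set_label = set, subset_label = label, n_genes = n,
               n_kinases = n_kin,
               pct_kinases = subset_percent(n_kin, n),
               n_tf = n_tf, pct_tf = subset_percent(n_tf, n),
               most_represented_tf_family =
                 if (length(mrf$family) > 0)
                   paste0(mrf$family, " (", mrf$count, ")", collapse = ", ")
                 else "",
               n_cold_go = n_cold,
               pct_cold_go = subset_percent(n_cold, n),
               empty = n == 0, stringsAsFactors = FALSE)
  }
  rows <- list()
  for (set in unique(subsets$set_label)) {
    in_set <- subsets[subsets$set_label == set, ]
    # factor subset labels keep declared-but-empty subsets in the output
    subs_here <- if (is.factor(in_set$subset_label))
      levels(in_set$subset_label) else unique(in_set$subset_label)
    for (sub in subs_here)
      rows[[paste(set, sub)]] <-
        one_row(sub, in_set$gene_id[in_set$subset_label == sub], set)
    rows[[paste(set, "total")]] <- one_row("total", in_set$gene_id, set)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cold-GO incidence matrix
#'
#' Per-(gene, subset) incidence of the three cold-related GO ids, with
#' per-subset totals and the ratio row (100 * total / subset size).
#'
#' @param subsets Assignment data frame as in [summarize_sets()].
#' @param bundle An `annotation_bundle`.
#' @return List: `incidence` (long data frame gene_id, subset_label,
#'   go_id), `totals` (per subset: n_genes, n_cold, ratio_pct).
#' @export
cold_go_matrix <- function(subsets, bundle) {
  ids <- intersect(names(bundle$go_terms), cold_go_ids())
  inc <- do.call(rbind, lapply(ids, function(id) {
    hit <- subsets[subsets$gene_id %in% bundle$go_terms[[id]], ,
                   drop = FALSE]
    if (nrow(hit) == 0) return(NULL)
    data.frame(gene_id = hit$gene_id, subset_label = hit$subset_label,
               go_id = id, stringsAsFactors = FALSE)
  }))
  if (is.null(inc))
    inc <- data.frame(gene_id = character(0), subset_label = character(0),
                      go_id = character(0))
  cold <- unique(inc$gene_id)
  totals <- do.call(rbind, lapply(unique(subsets$subset_label),
    function(sub) {
      genes <- subsets$gene_id[subsets$subset_label == sub]
      n_cold <- sum(genes %in% cold)
      data.frame(subset_label = sub, n_genes = length(genes),
                 n_cold = n_cold,
                 ratio_pct = subset_percent(n_cold, length(genes)),
                 stringsAsFactors = FALSE)
    }))
  list(incidence = inc, totals = totals)
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric (urn) probability P(X >= overlap) for each
#' term against the background, BH-adjusted across terms.
#'
#' @param subset_genes Character vector, must be contained in
#'   `background`.
#' @param gene_sets Named list term -> gene vector; members are
#'   intersected with the background.
#' @param background Character vector of background genes.
#' @return Data frame: term, overlap, term_size, subset_size,
#'   background_size, p, p_adj.
#' @export
hypergeom_enrichment <- function(subset_genes, gene_sets, background) {
  if (!all(subset_genes %in% background))
    stop("subset is not contained in the background")
  subset_genes <- unique(subset_genes)
  background <- unique(background)
  n_bg <- length(background)
  n_sub <- length(subset_genes)
  rows <- lapply(names(gene_sets), function(term) {
    members <- intersect(gene_sets[[term]], background)
    m <- length(members)
    ov <- length(intersect(members, subset_genes))
    p <- stats::phyper(ov - 1, m, n_bg - m, n_sub, lower.tail = FALSE)
    data.frame(term = term, overlap = ov, term_size = m,
               subset_size = n_sub, background_size = n_bg, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term = character(0), overlap = integer(0),
                      term_size = integer(0), subset_size = integer(0),
                      background_size = integer(0), p = numeric(0),
                      p_adj = numeric(0)))
  out$p_adj <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}

#' Most represented family among a gene set
#'
#' @param genes Character vector of gene ids.
#' @param family_map Named character vector gene -> family (or a data
#'   frame with `gene_id`, `family`).
#' @return List with `family` (character vector; ties reported
#'   together, alphabetical) and `count`; empty vectors when no gene
#'   is labelled.
#' @export
most_represented_family <- function(genes, family_map) {
  if (is.data.frame(family_map))
    family_map <- setNames(family_map$family, family_map$gene_id)
  fams <- family_map[intersect(genes, names(family_map))]
  if (length(fams) == 0)
    return(list(family = character(0), count = integer(0)))
  tab <- table(fams)
  top <- max(tab)
  list(family = sort(names(tab)[tab == top]), count = as.integer(top))
}
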