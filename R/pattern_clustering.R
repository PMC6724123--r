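# Expression-pattern clustering: per-gene profiles over the twelve
# condition means are standardized and clustered by agglomerative
# average linkage (UPGMA) on 1 - Pearson correlation, then cut to a
# fixed number of clusters per set (LR: 2, TCR: 2, TLSR: 4) and each
# cluster is labelled by the sign of its line and cold-response
# summaries.

#' Per-gene condition means
#'
#' Mean of log2(normalized + pseudocount) over replicates for each of
#' the twelve (line, treatment, time) conditions, columns in the
#' display order ChNT0..ChNT2, ChLT0..ChLT2, TeNT0..TeNT2,
#' TeLT0..TeLT2.
#'
#' @param norm A `normalized_matrix`.
#' @param design Matching `sample_design`.
#' @param pseudocount Offset for the log transform (default 1).
#' @return Real matrix, genes x 12 conditions.
#' @export
condition_means <- function(norm, design, pseudocount = 1) {
  lg <- log_transform(norm, pseudocount)
  cond <- condition_labels(design)
  if (any(table(cond) == 0))
    stop("empty condition: ",
         paste(names(which(table(cond) == 0)), collapse = ", "))
  out <- vapply(condition_order(), function(cl)
    rowMeans(lg[, cond == cl, drop = FALSE]), numeric(nrow(lg)))
  out <- matrix(out, nrow = nrow(lg),
                dimnames = list(rownames(lg), condition_order()))
  out
}

#' Standardize expression profiles
#'
#' Per-gene mean-centring and unit-variance scaling. Constant profiles
#' cannot be standardized; they are flagged in the `"constant"`
#' attribute and must be excluded from clustering.
#'
#' @param profiles Genes x conditions real matrix.
#' @return Standardized matrix with logical attribute `"constant"`.
#' @export
standardize <- function(profiles) {
  m <- rowMeans(profiles)
  s <- apply(profiles, 1, stats::sd)
  const <- s == 0 | !is.finite(s)
  out <- (profiles - m) / ifelse(const, 1, s)
  out[const, ] <- 0
  attr(out, "constant") <- setNames(const, rownames(profiles))
  out
}

# Average-linkage agglomeration on a distance matrix, with ties in the
# minimum-distance pair broken by the smallest (i, j) pair of lowest
# original indices. Returns an hclust-style merge encoding: negative
# entries are leaves, positive entries earlier merges.
upgma_merge <- function(d) {
  n <- nrow(d)
  members <- as.list(seq_len(n))     # original leaf indices per cluster
  id <- -seq_len(n)                  # hclust coding of each active cluster
  sizes <- rep(1L, n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  # canonical key for tie-breaking: smallest leaf index in each cluster
  min_leaf <- seq_len(n)
  for (step in seq_len(n - 1)) {
    k <- n - step + 1
    D <- d
    D[lower.tri(D, diag = TRUE)] <- Inf
    best_d <- min(D)
    cand <- which(D <= best_d + 1e-12, arr.ind = TRUE)
    key1 <- pmin(min_leaf[cand[, 1]], min_leaf[cand[, 2]])
    key2 <- pmax(min_leaf[cand[, 1]], min_leaf[cand[, 2]])
    pick <- order(key1, key2)[1]
    a <- cand[pick, 1]; b <- cand[pick, 2]
    best_d <- d[a, b]
    merge[step, ] <- sort(c(id[a], id[b]))
    height[step] <- best_d
    # average-linkage update: size-weighted mean of distances
    new_d <- (sizes[a] * d[a, ] + sizes[b] * d[b, ]) / (sizes[a] + sizes[b])
    keep <- setdiff(seq_len(k), c(a, b))
    nd <- matrix(0, k - 1, k - 1)
    if (length(keep) > 0) {
      nd[seq_along(keep), seq_along(keep)] <- d[keep, keep]
      nd[k - 1, seq_along(keep)] <- new_d[keep]
      nd[seq_along(keep), k - 1] <- new_d[keep]
    }
    d <- nd
    members[[a]] <- c(members[[a]], members[[b]])
    new_members <- members[c(keep, a)]
    new_sizes <- c(sizes[keep], sizes[a] + sizes[b])
    new_id <- c(id[keep], step)
    new_min <- c(min_leaf[keep], min(min_leaf[a], min_leaf[b]))
    members <- new_members; sizes <- new_sizes; id <- new_id
    min_leaf <- new_min
  }
  list(merge = merge, height = height)
}

# cut an hclust-style merge list to k clusters; returns integer vector
# of cluster memberships over the n leaves, numbered by first leaf.
cut_merge <- function(merge, n, k) {
  if (k < 1 || k > n) stop("k must lie in [1, n]")
  cl <- seq_len(n)
  reps <- seq_len(n)                  # representative leaf per merge node
  if (n - k >= 1) {
    for (step in seq_len(n - k)) {
      pick <- function(x) if (x < 0) -x else reps[n + x]
      i <- pick(merge[step, 1]); j <- pick(merge[step, 2])
      cl[cl == cl[j]] <- cl[i]
      reps[n + step] <- i
    }
  } else {
    reps <- c(reps, rep(NA_integer_, n - 1))
  }
  # renumber 1..k in order of first appearance
  as.integer(factor(cl, levels = unique(cl)))
}

#' Average-linkage clustering on Pearson correlation distance
#'
#' Agglomerative (UPGMA) clustering of standardized profiles with
#' distance 1 - Pearson correlation, deterministic tie-breaking by
#' lowest original gene index, and the tree cut to exactly `k`
#' clusters.
#'
#' @param profiles Standardized genes x conditions matrix (constant
#'   rows must already be removed).
#' @param k Number of clusters.
#' @return List: `cluster` (named integer vector), `merge` (hclust
#'   coding), `height` (merge heights), `merge_table` (data frame
#'   child1, child2, height, size).
#' @export
hcl_average_pearson <- function(profiles, k) {
  n <- nrow(profiles)
  if (k < 1 || k > n) stop("k must lie in [1, number of profiles]")
  s <- apply(profiles, 1, stats::sd)
  if (any(s == 0)) stop("constant profile cannot be clustered; ",
                        "standardize() flags these")
  d <- 1 - stats::cor(t(profiles))
  diag(d) <- 0
  tree <- upgma_merge(d)
  cl <- cut_merge(tree$merge, n, k)
  sizes <- integer(n - 1)
  size_of <- function(x) if (x < 0) 1L else sizes[x]
  for (st in seq_len(max(n - 1, 0)))
    sizes[st] <- size_of(tree$merge[st, 1]) + size_of(tree$merge[st, 2])
  merge_table <- data.frame(child1 = tree$merge[, 1],
                            child2 = tree$merge[, 2],
                            height = tree$height, size = sizes)
  list(cluster = setNames(cl, rownames(profiles)),
       merge = tree$merge, height = tree$height,
       merge_table = merge_table)
}

#' Pattern label of a cluster mean profile
#'
#' Two signed summaries of the 12-condition mean profile decide the
#' label: `d_line` = mean(Ch conditions) - mean(Te conditions) and
#' `d_lt` = mean(LT at T1, T2) - mean(LT at T0), averaged over lines.
#' LR clusters: d_line > 0 -> LRa (Ch up) else LRb (Te up). TCR:
#' d_lt < 0 -> TCRa (down under LT) else TCRb (up). TLSR: the four
#' sign combinations (+,-) -> TLSRa, (+,+) -> TLSRb, (-,-) -> TLSRc,
#' (-,+) -> TLSRd. A summary of exactly zero is a tie error.
#'
#' @param mean_profile Numeric 12-vector named by [condition_order()].
#' @param set_label One of "LR", "TCR", "TLSR".
#' @return Subset label string.
#' @export
pattern_label <- function(mean_profile, set_label) {
  co <- condition_order()
  if (is.null(names(mean_profile))) names(mean_profile) <- co
  ch <- grepl("^Ch", co); lt <- grepl("LT", co)
  t0 <- grepl("0$", co)
  d_line <- mean(mean_profile[ch]) - mean(mean_profile[!ch])
  d_lt <- mean(mean_profile[lt & !t0]) - mean(mean_profile[lt & t0])
  tie <- function(x, what)
    if (x == 0) stop("tied ", what, " summary (exactly 0); inspect cluster")
  switch(set_label,
    LR = { tie(d_line, "line")
           if (d_line > 0) "LRa" else "LRb" },
    TCR = { tie(d_lt, "cold-response")
            if (d_lt < 0) "TCRa" else "TCRb" },
    TLSR = { tie(d_line, "line"); tie(d_lt, "cold-response")
             if (d_line > 0) { if (d_lt < 0) "TLSRa" else "TLSRb" }
             else            { if (d_lt < 0) "TLSRc" else "TLSRd" } },
    stop("unknown set label: ", set_label))
}

#' Cluster each gene set into its pattern subsets
#'
#' Runs [hcl_average_pearson()] within each of the LR (k = 2), TCR
#' (k = 2) and TLSR (k = 4) sets on standardized condition-mean
#' profiles and labels every cluster with [pattern_label()] applied to
#' its mean profile.
#'
#' @param classification A `gene_classification`.
#' @param norm A `normalized_matrix` covering the classified genes.
#' @param design Matching `sample_design`.
#' @param k_per_set Named integer vector of cluster counts.
#' @param pseudocount Offset for the log transform.
#' @return Data frame: gene_id, set_label, cluster_id, subset_label;
#'   the per-set merge tables in attribute `"trees"`.
#' @export
cluster_patterns <- function(classification, norm, design,
                             k_per_set = c(LR = 2, TCR = 2, TLSR = 4),
                             pseudocount = 1) {
  prof <- condition_means(norm, design, pseudocount)
  std <- standardize(prof)
  const <- attr(std, "constant")
  out <- NULL
  trees <- list()
  for (set in c("LR", "TCR", "TLSR")) {
    genes <- classification$gene_id[classification$set_label == set]
    genes <- genes[!const[genes]]
    if (length(genes) == 0) next
    k <- min(k_per_set[[set]], length(genes))
    hc <- hcl_average_pearson(std[genes, , drop = FALSE], k)
    trees[[set]] <- hc$merge_table
    labels <- vapply(seq_len(k), function(ci) {
      mp <- colMeans(std[genes[hc$cluster == ci], , drop = FALSE])
      pattern_label(mp, set)
    }, character(1))
    out <- rbind(out, data.frame(gene_id = genes, set_label = set,
                                 cluster_id = as.integer(hc$cluster),
                                 subset_label = labels[hc$cluster],
                                 stringsAsFactors = FALSE))
  }
  if (is.null(out))
    out <- data.frame(gene_id = character(0), set_label = character(0),
                      cluster_id = integer(0), subset_label = character(0))
  attr(out, "trees") <- trees
  out
}
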