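# Shared fixtures and independent oracles, built in code.

# write a design data frame as a tab-delimited file, return the path
write_design_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

# small count fixture: n_genes x design, constant-ish values
toy_counts <- function(n_genes = 10, design = canonical_design(),
                       base = 50, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * nrow(design), base), n_genes)
  dimnames(m) <- list(sprintf("g%03d", seq_len(n_genes)),
                      design$sample_id)
  m
}

# brute-force Benjamini-Hochberg step-up oracle
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  scaled <- p[o] * n / seq_len(n)
  adj_sorted <- pmin(rev(cummin(rev(scaled))), 1)
  out <- numeric(n)
  out[o] <- adj_sorted
  out
}

# exhaustive average-linkage agglomeration oracle: at every step,
# recompute all cross-cluster mean distances from the ORIGINAL matrix
# and merge the closest pair (ties: smallest pair of lowest original
# indices). Returns list of merged member sets and heights.
upgma_oracle <- function(d0) {
  n <- nrow(d0)
  clusters <- lapply(seq_len(n), identity)
  merges <- list()
  heights <- numeric(0)
  while (length(clusters) > 1) {
    k <- length(clusters)
    best <- NULL; best_d <- Inf
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      dd <- mean(d0[clusters[[a]], clusters[[b]]])
      key <- sort(c(min(clusters[[a]]), min(clusters[[b]])))
      if (dd < best_d - 1e-12) {
        best_d <- dd; best <- c(a, b); best_key <- key
      } else if (abs(dd - best_d) <= 1e-12 &&
                 (key[1] < best_key[1] ||
                  (key[1] == best_key[1] && key[2] < best_key[2]))) {
        best <- c(a, b); best_key <- key
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    merges[[length(merges) + 1]] <-
      list(a = sort(clusters[[best[1]]]), b = sort(clusters[[best[2]]]))
    heights <- c(heights, best_d)
    clusters <- c(clusters[-best], list(merged))
  }
  list(merges = merges, heights = heights)
}

# decode an hclust-style merge matrix into per-step member sets
decode_merges <- function(merge) {
  sets <- list()
  out <- list()
  for (i in seq_len(nrow(merge))) {
    get <- function(x) if (x < 0) -x else sets[[x]]
    a <- sort(get(merge[i, 1])); b <- sort(get(merge[i, 2]))
    sets[[i]] <- sort(c(a, b))
    out[[i]] <- list(a = a, b = b)
  }
  out
}

# two-way balanced ANOVA from-scratch sums-of-squares oracle
# (line x treatment with interaction)
anova2_oracle <- function(y, line, treatment) {
  line <- factor(line); treatment <- factor(treatment)
  gm <- mean(y)
  ml <- tapply(y, line, mean); mt <- tapply(y, treatment, mean)
  mc <- tapply(y, interaction(line, treatment), mean)
  nl <- table(line); nt <- table(treatment)
  nc <- table(interaction(line, treatment))
  ss_line <- sum(nl * (ml - gm)^2)
  ss_treat <- sum(nt * (mt - gm)^2)
  cell_line <- tapply(as.integer(line), interaction(line, treatment),
                      function(i) levels(line)[i[1]])
  cell_treat <- tapply(as.integer(treatment),
                       interaction(line, treatment),
                       function(i) levels(treatment)[i[1]])
  ss_cells <- sum(nc * (mc - gm)^2)
  ss_int <- ss_cells - ss_line - ss_treat
  fitted <- mc[as.character(interaction(line, treatment))]
  ss_res <- sum((y - fitted)^2)
  df_l <- nlevels(line) - 1; df_t <- nlevels(treatment) - 1
  df_i <- df_l * df_t
  df_r <- length(y) - nlevels(line) * nlevels(treatment)
  ms <- function(ss, df) ss / df
  f_l <- ms(ss_line, df_l) / ms(ss_res, df_r)
  f_t <- ms(ss_treat, df_t) / ms(ss_res, df_r)
  f_i <- ms(ss_int, df_i) / ms(ss_res, df_r)
  list(F_line = f_l, p_line = pf(f_l, df_l, df_r, lower.tail = FALSE),
       F_treatment = f_t,
       p_treatment = pf(f_t, df_t, df_r, lower.tail = FALSE),
       F_interaction = f_i,
       p_interaction = pf(f_i, df_i, df_r, lower.tail = FALSE))
}

# bundle with exact label counts planted over given gene vectors
planted_bundle <- function(kinase_genes = character(0),
                           tf_genes = character(0),
                           tf_families = NULL,
                           cold_genes = character(0),
                           cold_ids = NULL) {
  tf_fam <- if (is.null(tf_families))
    rep("bHLH", length(tf_genes)) else tf_families
  go <- list()
  if (length(cold_genes) > 0) {
    if (is.null(cold_ids)) cold_ids <- rep("GO:0009409", length(cold_genes))
    for (id in unique(cold_ids))
      go[[id]] <- cold_genes[cold_ids == id]
  }
  annotation_bundle(
    tf_family = data.frame(gene_id = tf_genes, family = tf_fam,
                           stringsAsFactors = FALSE),
    kinase_family = data.frame(gene_id = kinase_genes,
                               family = rep("RLK-Pelle",
                                            length(kinase_genes)),
                               stringsAsFactors = FALSE),
    go_terms = go)
}

# subset-assignment fixture: named vector subset_label -> n genes,
# set label inferred from the subset prefix
make_subsets <- function(sizes) {
  genes <- unlist(lapply(names(sizes), function(s)
    sprintf("%s_%d", s, seq_len(sizes[[s]]))))
  data.frame(gene_id = as.character(genes),
             set_label = sub("(LR|TCR|TLSR).*", "\\1",
                             rep(names(sizes), sizes)),
             subset_label = rep(names(sizes), sizes),
             stringsAsFactors = FALSE)
}
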