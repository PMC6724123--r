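test_that("condition means average replicates in the display order", {
  d <- canonical_design()
  m <- toy_counts(5, d, seed = 61)
  norm <- normalize_counts(m, sf = rep(1, 24))
  cm <- condition_means(norm, d)
  expect_equal(colnames(cm), condition_order())
  # replicate values 2 and 4 (raw 3 and 15 after log2(x+1)) -> mean
  m2 <- matrix(0L, 1, 24, dimnames = list("g", d$sample_id))
  m2[1, which(condition_labels(d) == "ChNT0")] <- c(3L, 15L)
  cm2 <- condition_means(normalize_counts(m2, sf = rep(1, 24)), d)
  expect_equal(cm2["g", "ChNT0"], 3)       # mean(log2(4), log2(16))
  # identical replicates equal the replicate value
  expect_equal(cm["g001", "TeLT2"],
               mean(log2(m["g001", condition_labels(d) == "TeLT2"] + 1)))
})

test_that("standardize centres, scales, flags constants, is idempotent", {
  p <- rbind(a = 1:12, b = rep(5, 12), c = rnorm(12))
  s <- standardize(p)
  expect_equal(unname(rowMeans(s)[c("a", "c")]), c(0, 0))
  expect_equal(unname(apply(s, 1, sd)[c("a", "c")]), c(1, 1))
  expect_true(attr(s, "constant")[["b"]])
  expect_false(attr(s, "constant")[["a"]])
  s2 <- standardize(s[c("a", "c"), ])
  expect_equal(unname(s2), unname(s[c("a", "c"), ]), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("clustering recovers exact groups and matches the oracle", {
  base1 <- sin(seq_len(12)); base2 <- cos(seq_len(12))
  prof <- standardize(rbind(matrix(rep(base1, 5), 5, byrow = TRUE),
                            matrix(rep(base2, 5), 5, byrow = TRUE)))
  rownames(prof) <- paste0("g", 1:10)
  hc <- hcl_average_pearson(prof, 2)
  expect_equal(unname(hc$cluster), rep(c(1L, 2L), each = 5))

  # merge order equals the exhaustive re-agglomeration oracle on
  # random 5-gene toys
  set.seed(67)
  for (i in 1:10) {
    p5 <- standardize(matrix(rnorm(60), 5,
                             dimnames = list(paste0("g", 1:5), NULL)))
    d0 <- 1 - cor(t(p5)); diag(d0) <- 0
    oracle <- upgma_oracle(d0)
    got <- hcl_average_pearson(p5, 1)
    got_steps <- decode_merges(got$merge)
    for (s in seq_along(oracle$merges)) {
      o <- oracle$merges[[s]]; g <- got_steps[[s]]
      expect_setequal(c(list(o$a), list(o$b)), c(list(g$a), list(g$b)))
    }
    expect_equal(got$height, oracle$heights, tolerance = 1e-12)
  }
})

test_that("clustering agrees with hclust on tie-free data", {
  set.seed(71)
  p <- standardize(matrix(rnorm(30 * 12), 30,
                          dimnames = list(sprintf("g%02d", 1:30), NULL)))
  d <- as.dist(1 - cor(t(p)))
  ref <- cutree(hclust(d, method = "average"), k = 4)
  got <- hcl_average_pearson(p, 4)$cluster
  expect_equal(length(unique(paste(ref, got))), 4)  # same partition
})

test_that("distances are invariant to positive affine rescaling", {
  set.seed(73)
  p <- matrix(rnorm(5 * 12), 5, dimnames = list(paste0("g", 1:5), NULL))
  hc1 <- hcl_average_pearson(standardize(p), 2)
  p2 <- p; p2[3, ] <- 2.5 * p[3, ] + 7
  hc2 <- hcl_average_pearson(standardize(p2), 2)
  expect_equal(hc1$height, hc2$height, tolerance = 1e-12)
  expect_equal(hc1$cluster, hc2$cluster)
})

test_that("gene order does not change cluster memberships", {
  set.seed(79)
  p <- standardize(matrix(rnorm(20 * 12), 20,
                          dimnames = list(sprintf("g%02d", 1:20), NULL)))
  c1 <- hcl_average_pearson(p, 3)$cluster
  perm <- sample(20)
  c2 <- hcl_average_pearson(p[perm, ], 3)$cluster[rownames(p)]
  expect_equal(length(unique(paste(c1, c2))), 3)
})

test_that("merge heights are non-decreasing", {
  set.seed(83)
  p <- standardize(matrix(rnorm(25 * 12), 25,
                          dimnames = list(sprintf("g%02d", 1:25), NULL)))
  hc <- hcl_average_pearson(p, 1)
  expect_true(all(diff(hc$height) >= -1e-9))
})

test_that("pattern labels follow the two signed summaries", {
  co <- condition_order()
  ch <- grepl("^Ch", co); lt <- grepl("LT", co); t0 <- grepl("0$", co)
  flat_line <- ifelse(ch, 1, -1)
  expect_equal(pattern_label(setNames(flat_line, co), "LR"), "LRa")
  expect_equal(pattern_label(setNames(-flat_line, co), "LR"), "LRb")
  rising_lt <- ifelse(lt, c(0, 1, 2)[as.integer(sub(".*(\\d)$", "\\1",
                                                    co)) + 1], 0)
  expect_equal(pattern_label(setNames(rising_lt, co), "TCR"), "TCRb")
  expect_equal(pattern_label(setNames(-rising_lt, co), "TCR"), "TCRa")
  # TLSR: (line sign, LT slope sign) -> a, b, c, d
  expect_equal(pattern_label(setNames(flat_line - rising_lt, co),
                             "TLSR"), "TLSRa")
  expect_equal(pattern_label(setNames(flat_line + rising_lt, co),
                             "TLSR"), "TLSRb")
  expect_equal(pattern_label(setNames(-flat_line - rising_lt, co),
                             "TLSR"), "TLSRc")
  expect_equal(pattern_label(setNames(-flat_line + rising_lt, co),
                             "TLSR"), "TLSRd")
  expect_error(pattern_label(setNames(rep(0, 12), co), "LR"), "tie")
})

test_that("planted archetypes map onto their subsets", {
  run <- run_pipeline(run_config(seed = 42))
  rec <- recovery_report(run$truth, run$classification, run$subsets)
  expect_gte(rec$subset_recovery$overall, 0.85)
})
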