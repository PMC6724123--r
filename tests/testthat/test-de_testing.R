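test_that("size factors match the median-of-ratios oracle", {
  # identical columns -> all factors 1
  m <- matrix(rep(c(10L, 30L, 7L), 24), nrow = 3)
  colnames(m) <- paste0("s", 1:24)
  expect_equal(unname(size_factors(m)), rep(1, 24))

  # hand-computed 2x2 oracle: geometric means (sqrt(200), sqrt(1800)),
  # per-sample ratio medians 1/sqrt(2) and sqrt(2)
  m2 <- matrix(c(10L, 30L, 20L, 60L), nrow = 2,
               dimnames = list(c("g1", "g2"), c("a", "b")))
  expect_equal(unname(size_factors(m2)), c(1 / sqrt(2), sqrt(2)))

  # scaled copies of one column recover the scaling constants
  base <- c(5L, 80L, 13L, 200L, 44L)
  sc <- c(1, 2, 4, 0.5)
  m3 <- vapply(sc, function(s) as.integer(round(base * s)), integer(5))
  colnames(m3) <- paste0("s", 1:4)
  sf <- size_factors(m3)
  expect_equal(unname(sf / sf[1]), sc, tolerance = 0.05)

  # every gene has a zero -> error
  m4 <- diag(5L); colnames(m4) <- paste0("s", 1:5)
  expect_error(size_factors(m4), "reference gene")
})

test_that("size factors agree with the DESeq2 reference on a zero-free matrix", {
  set.seed(21)
  m <- matrix(rnbinom(200 * 24, mu = 100, size = 20), 200, 24)
  m <- m + 1L  # ensure zero-free
  colnames(m) <- paste0("s", 1:24)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(size_factors(m)), unname(ref), tolerance = 1e-6)
})

test_that("testability flags follow the two-sample rule", {
  m <- rbind(all_zero = rep(0L, 24),
             one = c(5L, rep(0L, 23)),
             two = c(5L, 3L, rep(0L, 22)))
  colnames(m) <- paste0("s", 1:24)
  expect_equal(unname(testable_flags(m)), c(FALSE, FALSE, TRUE))
})

test_that("the 48-count filter discards the boundary total", {
  d <- canonical_design()
  m <- rbind(at48 = rep(2L, 24),    # total normalized = 48 exactly
             just_above = c(rep(2L, 23), 3L),
             zero = rep(0L, 24),
             big = rep(100L, 24))
  colnames(m) <- d$sample_id
  norm <- normalize_counts(m, sf = rep(1, 24))
  keep <- low_count_filter(norm)
  expect_false(keep[["at48"]])
  expect_true(keep[["just_above"]])
  expect_false(keep[["zero"]])
  expect_equal(sum(norm$values["at48", ]), 48)
})

test_that("bh_adjust matches the step-up oracle and its properties", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03, 0.02)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(10)
  for (i in 1:50) {
    p <- runif(sample(1:30, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p))
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
  }
})

test_that("exact-null genes give LFC 0 and p 1; zero groups are untestable", {
  d <- canonical_design()
  m <- matrix(10L, 2, 24,
              dimnames = list(c("g1", "g2"), d$sample_id))
  m["g2", condition_labels(d) == "ChNT0"] <- 0L
  res <- nb_contrast_test(m, d, "ChNT0:TeNT0",
                          norm = normalize_counts(m, sf = rep(1, 24)),
                          dispersions = c(g1 = 0.05, g2 = 0.05))
  expect_equal(res$log2_fold_change[1], 0)
  expect_equal(res$p_raw[1], 1)
  expect_false(res$testable[2])
  expect_equal(res$p_raw[2], 1)
})

test_that("the Wald test has power on strong planted differences", {
  # 8-fold line difference, low dispersion, 2 vs 2 samples, on a
  # majority-null background so normalization stays anchored
  cfg <- simulation_config(
    n_genes_per_archetype = c("NULL" = 1500L, LR_CH_UP = 500L),
    base_mean = 100, dispersion = 0.01, effect_offset = 3, seed = 13)
  d <- canonical_design()
  sim <- simulate_counts(cfg, d)
  res <- nb_contrast_test(sim$counts, d, "TeNT0:ChNT0")
  lr <- sim$truth$archetype == "LR_CH_UP"
  expect_gte(mean(res$p_raw[lr] <= 0.02), 0.90)
  expect_gt(median(res$log2_fold_change[lr]), 2.5)
})

test_that("null p-values are calibrated and uniform under permutation", {
  d <- canonical_design()
  cfg <- simulation_config(n_genes_per_archetype = c("NULL" = 2000L),
                           seed = 17)
  sim <- simulate_counts(cfg, d)
  tab <- contrast_table(sim$counts, d)
  frac <- mean(tab$p_raw <= 0.05)
  expect_gte(frac, 0.03); expect_lte(frac, 0.07)
  # permuted group labels: compare two arbitrary null halves of ChN vs TeLT
  ks <- suppressWarnings(
    ks.test(tab$p_raw[tab$contrast == "ChNT0:TeNT0"], "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("deg_selection keeps the 0.02 boundary and is monotone in alpha", {
  tab <- data.frame(
    gene_id = rep(c("a", "b", "c"), each = 2),
    contrast = rep(c("c1", "c2"), 3),
    p_adj = c(0.02, 1, 1, 1, 0.019, 0.5))
  sel <- deg_selection(tab, alpha = 0.02)
  expect_true(sel[["a"]])      # boundary retained
  expect_false(sel[["b"]])
  expect_true(sel[["c"]])
  for (a2 in c(0.05, 0.2, 1)) {
    expect_true(all(deg_selection(tab, 0.02) <= deg_selection(tab, a2)))
  }
})

test_that("annotation filter keeps the 9e-4 boundary and drops hitless genes", {
  bundle <- annotation_bundle(best_hit = data.frame(
    gene_id = c("g1", "g2"), subject_id = c("h1", "h2"),
    evalue = c(9e-4, 1e-3)))
  flags <- annotation_filter(bundle, c("g1", "g2", "g3"))
  expect_true(flags[["g1"]])
  expect_false(flags[["g2"]])
  expect_false(flags[["g3"]])
})

test_that("filter_report enforces the implication chain", {
  d <- canonical_design()
  cfg <- simulation_config(n_genes_per_archetype =
                             c("NULL" = 150L, LR_CH_UP = 50L), seed = 23)
  sim <- simulate_counts(cfg, d)
  sim$counts[1, ] <- 0L   # untestable gene
  rep <- filter_report(sim$counts, d)
  expect_true(all(!rep$passed_deg_filter | rep$passed_count_filter))
  expect_true(all(!rep$passed_count_filter | rep$testable))
  expect_false(rep$testable[1])
})
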