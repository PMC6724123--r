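test_that("log transform is exact and monotone", {
  m <- matrix(c(0, 3, 7, 1), 2)
  lt <- log_transform(m, 1)
  expect_equal(lt[1, 1], 0)
  expect_equal(lt[2, 1], 2)
  expect_true(all(diff(log_transform(matrix(0:10, 1))[1, ]) > 0))
  expect_error(log_transform(m, 0), "pseudocount")
})

test_that("two-way ANOVA matches the from-scratch sums-of-squares oracle", {
  d <- canonical_design()
  set.seed(31)
  for (i in 1:20) {
    y <- rnorm(24, mean = 2 * (d$line == "Ch") + (d$treatment == "LT"))
    got <- two_way_anova(y, d)
    oracle <- anova2_oracle(y, d$line, d$treatment)
    expect_equal(got$F_line, oracle$F_line, tolerance = 1e-10)
    expect_equal(got$p_line, oracle$p_line, tolerance = 1e-10)
    expect_equal(got$F_treatment, oracle$F_treatment, tolerance = 1e-10)
    expect_equal(got$p_treatment, oracle$p_treatment, tolerance = 1e-10)
    expect_equal(got$p_interaction, oracle$p_interaction,
                 tolerance = 1e-10)
  }
})

test_that("two-way ANOVA handles constant and degenerate genes", {
  d <- canonical_design()
  const <- two_way_anova(rep(3, 24), d)
  expect_equal(const$p_line, 1)
  expect_equal(const$p_treatment, 1)
  # perfect separation with zero residual: line effect, no noise
  sep <- two_way_anova(as.numeric(d$line == "Ch"), d)
  expect_true(sep$degenerate)
  expect_lt(sep$p_line, 1e-300)
  expect_equal(sep$p_treatment, 1)
  expect_error(two_way_anova(rnorm(23), d))
})

test_that("two-way ANOVA separates strong line effects from treatment", {
  d <- canonical_design()
  set.seed(37)
  hits <- replicate(200, {
    y <- (d$line == "Ch") * 1 + rnorm(24, sd = 0.1)
    r <- two_way_anova(y, d)
    c(r$p_line < 1e-4, r$p_treatment > 0.05)
  })
  expect_gte(mean(hits[1, ]), 0.95)
  expect_gte(mean(hits[2, ]), 0.95)
})

test_that("null two-way p-values are uniform", {
  d <- canonical_design()
  set.seed(41)
  p <- vapply(1:2000, function(i) two_way_anova(rnorm(24), d)$p_line,
              numeric(1))
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("one-way F equals pooled t-squared on 2-level groupings", {
  set.seed(43)
  for (i in 1:20) {
    g <- factor(rep(c("a", "b"), each = 6))
    y <- rnorm(12, mean = (g == "b") * runif(1, 0, 2))
    p_f <- one_way_anova(y, g)
    tt <- t.test(y ~ g, var.equal = TRUE)
    expect_equal(p_f, tt$p.value, tolerance = 1e-12)
  }
  # null calibration over repeats
  p0 <- replicate(500, one_way_anova(rnorm(12), rep(c("a", "b"), 6)))
  expect_gt(ks.test(p0, "punif")$p.value, 0.01)
  # degenerate: identical within, different between
  expect_lt(one_way_anova(rep(c(0, 1), each = 3),
                          rep(c("a", "b"), each = 3)), 1e-300)
  expect_error(one_way_anova(rnorm(3), factor(c("a", "a", "b"))),
               ">= 2 samples")
})

test_that("cascade labels follow the two significance flags", {
  mk <- function(pl, pt) data.frame(
    gene_id = "g", p_line = pl, p_treatment = pt, p_interaction = 0.5,
    p_line_adj = pl, p_treatment_adj = pt, p_interaction_adj = 0.5)
  expect_equal(classify_cascade(mk(0.001, 0.9))$set_label, "LR")
  expect_equal(classify_cascade(mk(0.9, 0.001))$set_label, "TCR")
  expect_equal(classify_cascade(mk(0.001, 0.001))$set_label, "TLSR")
  expect_equal(classify_cascade(mk(0.9, 0.9))$set_label, "NS")
  # boundary alpha retained
  expect_equal(classify_cascade(mk(0.05, 0.9))$set_label, "LR")
  expect_error(classify_cascade(mk(0.5, 0.5), degs = c("g", "h")),
               "missing ANOVA row")
})

test_that("classification partitions the DEG universe", {
  d <- canonical_design()
  sim <- simulate_counts(simulation_config(seed = 47), d)
  norm <- normalize_counts(sim$counts)
  lg <- log_transform(norm)
  degs <- sample(rownames(sim$counts), 300)
  at <- anova_table(lg[degs, ], d)
  cl <- classify_cascade(at, degs)
  expect_equal(sort(cl$gene_id), sort(degs))
  expect_true(all(cl$set_label %in% c("LR", "TCR", "TLSR", "NS")))
  cc <- cascade_set_counts(cl)
  expect_equal(cc$n_lr + cc$n_tcr + cc$n_tlsr + cc$n_ns, cc$n_total)
  expect_equal(cc$remaining_after_lr, cc$n_total - cc$n_lr)
  expect_equal(cc$remaining_after_tcr, cc$n_tlsr + cc$n_ns)
})

test_that("stage counts reproduce serial-subtraction arithmetic", {
  cc <- cascade_set_counts(list(n_total = 4981, n_lr = 2487,
                                n_tcr = 1403, n_ns = 0))
  expect_identical(cc$remaining_after_lr, 2494)
  expect_identical(cc$n_tlsr, 1091)
  empty <- cascade_set_counts(data.frame(gene_id = character(0),
                                         set_label = character(0)))
  expect_equal(empty$n_total, 0)
  expect_equal(empty$n_tlsr, 0)
})

test_that("pure-null DEG universes are mostly labelled NS", {
  d <- canonical_design()
  sim <- simulate_counts(simulation_config(
    n_genes_per_archetype = c("NULL" = 1000L), seed = 53), d)
  lg <- log_transform(normalize_counts(sim$counts))
  at <- anova_table(lg, d)
  cl <- classify_cascade(at, alpha = 0.05)
  frac_non_ns <- mean(cl$set_label != "NS")
  expect_lte(frac_non_ns, 2 * 0.05)
})
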