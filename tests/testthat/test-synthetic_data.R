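test_that("simulation is reproducible under a fixed seed", {
  cfg <- simulation_config(n_genes_per_archetype = c("NULL" = 100L),
                           seed = 7)
  a <- simulate_counts(cfg)
  b <- simulate_counts(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
})

test_that("null-gene moments match the NB parameterization", {
  cfg <- simulation_config(n_genes_per_archetype = c("NULL" = 2000L),
                           base_mean = 100, dispersion = 0.05, seed = 11)
  sim <- simulate_counts(cfg)
  x <- as.numeric(sim$counts)
  expect_lt(abs(mean(x) - 100) / 100, 0.02)
  expect_lt(abs(var(x) - 600) / 600, 0.15)
})

test_that("planted effects follow the mean model and gate on treatment", {
  cfg <- simulation_config(
    n_genes_per_archetype = c(TCR_UP = 400L), base_mean = 200,
    dispersion = 0.01, effect_slope = 2, seed = 3)
  d <- canonical_design()
  sim <- simulate_counts(cfg, d)
  cond <- as.character(condition_labels(d))
  cm <- function(cl) mean(sim$counts[, cond == cl])
  # slope 2 log2/step: T1 = 4x T0, T2 = 16x T0, in both lines under LT
  expect_lt(abs(cm("ChLT1") / cm("ChLT0") - 4) / 4, 0.1)
  expect_lt(abs(cm("ChLT2") / cm("ChLT0") - 16) / 16, 0.1)
  expect_lt(abs(cm("TeLT2") / cm("TeLT0") - 16) / 16, 0.1)
  # control columns stay flat
  expect_lt(abs(cm("ChNT2") / cm("ChNT0") - 1), 0.1)
  expect_lt(abs(cm("TeNT1") / cm("TeNT0") - 1), 0.1)
})

test_that("line offset splits symmetrically around the base mean", {
  cfg <- simulation_config(
    n_genes_per_archetype = c(LR_CH_UP = 500L), base_mean = 100,
    dispersion = 0.01, effect_offset = 2, seed = 5)
  d <- canonical_design()
  sim <- simulate_counts(cfg, d)
  ch <- mean(sim$counts[, d$line == "Ch"])
  te <- mean(sim$counts[, d$line == "Te"])
  expect_lt(abs(ch / te - 4) / 4, 0.1)          # offset 2 log2 = 4x
  expect_lt(abs(sqrt(ch * te) - 100) / 100, 0.05)  # geometric centre
})

test_that("N-treatment columns of slope archetypes match null behaviour", {
  d <- canonical_design()
  cfg_t <- simulation_config(n_genes_per_archetype = c(TCR_UP = 1000L),
                             seed = 9)
  cfg_0 <- simulation_config(n_genes_per_archetype = c("NULL" = 1000L),
                             seed = 9)
  st <- simulate_counts(cfg_t, d)
  s0 <- simulate_counts(cfg_0, d)
  n_cols <- d$treatment == "N"
  m_t <- mean(st$counts[, n_cols]); m_0 <- mean(s0$counts[, n_cols])
  expect_lt(abs(m_t - m_0) / m_0, 0.05)
})

test_that("annotation fractions and the log-uniform E-value tail behave", {
  truth <- simulate_counts(simulation_config(
    n_genes_per_archetype = c("NULL" = 10000L), seed = 2))$truth
  full <- simulate_annotation(truth, annotated_fraction = 1.0, seed = 2)
  expect_equal(nrow(full$best_hit), nrow(truth))
  none <- simulate_annotation(truth, annotated_fraction = 0.0, seed = 2)
  expect_equal(nrow(none$best_hit), 0)
  expect_error(simulate_annotation(truth, annotated_fraction = 1.5),
               "fraction")

  # log-uniform tail: P(E <= 9e-4) over (1e-10, 1e-1)
  expected <- (log(9e-4) - log(1e-10)) / (log(1e-1) - log(1e-10))
  observed <- mean(full$best_hit$evalue <= 9e-4)
  se <- sqrt(expected * (1 - expected) / nrow(truth))
  expect_lt(abs(observed - expected), 4 * se)
})

test_that("qPCR tables pair truth with configurable noise", {
  truth <- simulate_counts(simulation_config(seed = 4))$truth
  noiseless <- simulate_qpcr(truth, n_transcripts = 33, noise_sd = 0,
                             seed = 4)
  expect_equal(uncentered_correlation(noiseless$qpcr_log2_ratio,
                                      noiseless$rnaseq_log2_ratio), 1)
  again <- simulate_qpcr(truth, n_transcripts = 33, noise_sd = 0,
                         seed = 4)
  expect_identical(noiseless, again)
  expect_error(simulate_qpcr(truth, n_transcripts = 33, noise_sd = -1),
               "noise_sd")
  expect_error(simulate_qpcr(truth, n_transcripts = 1e6), "exceeds")

  # attenuation: R decreases as noise grows
  rs <- vapply(c(0.1, 1, 10, 100), function(sd) {
    tab <- simulate_qpcr(truth, n_transcripts = 33, noise_sd = sd,
                         seed = 8)
    uncentered_correlation(tab$qpcr_log2_ratio, tab$rnaseq_log2_ratio)
  }, numeric(1))
  expect_true(all(diff(rs) < 0))
  expect_lt(rs[4], 0.3)
})
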