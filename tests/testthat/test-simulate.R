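test_that("the same seed reproduces the dataset exactly", {
  cfg <- cohort_sim_config(seed = 99)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  c2 <- simulate_cohort(cfg, seed = 100)
  expect_false(identical(a$subjects, c2$subjects))
})

test_that("group sizes and survival placement follow the configuration", {
  co <- simulate_cohort(cohort_sim_config(seed = 3))
  expect_equal(sum(co$subjects$status == "case"), 231)
  expect_equal(sum(co$subjects$status == "control"), 240)
  expect_true(all(is.na(co$subjects$time[co$subjects$status == "control"])))
  expect_true(all(!is.na(co$subjects$time[co$subjects$status == "case"])))
  expect_true(all(co$subjects$time >= 0, na.rm = TRUE))
  expect_lte(max(co$subjects$time, na.rm = TRUE), 10)
  ## missingness applied at roughly the configured rate
  miss <- mean(is.na(as.matrix(co$subjects[co$snps$snp_id])))
  expect_gt(miss, 0.01); expect_lt(miss, 0.08)
})

test_that("a null disease model leaves case and control MAFs equal", {
  cfg <- cohort_sim_config(seed = 17, n_cases = 2500, n_controls = 2500,
                           disease_model = list(intercept = -1, carrier = 0,
                                                tc = 0, carrier_tc = 0,
                                                tc_threshold = 5),
                           missing_rate = 0)
  co <- simulate_cohort(cfg)
  for (s in co$snps$snp_id) {
    gc <- genotype_counts(co, s)
    p1 <- gc$allele_counts["case", 2] / sum(gc$allele_counts["case", ])
    p0 <- gc$allele_counts["control", 2] / sum(gc$allele_counts["control", ])
    n1 <- sum(gc$allele_counts["case", ]); n0 <- sum(gc$allele_counts["control", ])
    se <- sqrt(p0 * (1 - p0) * (1 / n1 + 1 / n0))
    expect_lt(abs(p1 - p0), 3 * se)
  }
})

test_that("EM on simulated diplotypes recovers the generating pool", {
  pool <- c(0.584, 0.036, 0.050, 0.330)
  cfg <- cohort_sim_config(seed = 23, n_cases = 1000, n_controls = 1000,
                           haplotype_pool = pool,
                           disease_model = list(intercept = -1, carrier = 0,
                                                tc = 0, carrier_tc = 0,
                                                tc_threshold = 5),
                           missing_rate = 0)
  co <- simulate_cohort(cfg)
  em <- em_haplotypes(co, cfg$linked_snps$snp_id)
  expect_lt(max(abs(em$frequencies - pool)), 0.02)
})

test_that("generated control genotypes sit in Hardy-Weinberg equilibrium", {
  ## genotype-independent risk: the genotype machinery itself must give HWE
  ## (with genotype effects, case-control selection perturbs control
  ## frequencies away from HWE by design)
  ok <- 0L
  for (seed in 1:100) {
    cfg <- cohort_sim_config(seed = seed, n_cases = 20, n_controls = 2000,
                             disease_model = list(intercept = -1.5, carrier = 0,
                                                  tc = 0.2, carrier_tc = 0,
                                                  tc_threshold = 5))
    co <- simulate_cohort(cfg)
    p <- vapply(co$snps$snp_id, function(s)
      hwe_test(genotype_counts(co, s), group = "control")$p_value, 0)
    if (all(p > 0.001)) ok <- ok + 1L
  }
  expect_gte(ok / 100, 0.99)
})

test_that("a generative genotype effect is recovered by logistic regression", {
  cfg <- cohort_sim_config(seed = 41, n_cases = 2000, n_controls = 2000,
                           disease_model = list(intercept = -1.5, carrier = 0.5,
                                                tc = 0, carrier_tc = 0,
                                                tc_threshold = 5),
                           missing_rate = 0)
  co <- simulate_cohort(cfg)
  fit <- logistic_fit(co, genotypes = c(rs3825807 = "major_carrier"))
  co_row <- fit$coefficients[2, ]
  expect_lt(abs(co_row$estimate - 0.5), 3 * co_row$se)
})

test_that("an infeasible disease model exhausts the attempt budget", {
  cfg <- cohort_sim_config(seed = 5, n_cases = 100, n_controls = 10,
                           disease_model = list(intercept = -20, carrier = 0,
                                                tc = 0, carrier_tc = 0,
                                                tc_threshold = 5))
  expect_error(simulate_cohort(cfg, max_attempts = 5L), "attempt budget")
})

test_that("the Friedewald formula computes and guards its validity domain", {
  expect_equal(friedewald_ldl(5.0, 1.0, 2.2), 3.0)
  expect_equal(friedewald_ldl(4.0, 4.0, 0), 0)
  expect_error(friedewald_ldl(5.0, 1.0, 4.5), "4.5")
  expect_equal(friedewald_ldl(c(5, 6), c(1, 1.5), c(2.2, 1.1)),
               c(3.0, 4.0))
})

test_that("mean simulated synergy tracks the generative interaction", {
  ## generative model: carrier x high-TC log-OR = log(2.2); the RERI implied
  ## by the three generative ORs is OR11 - OR10 - OR01 + 1 with
  ## OR10 = 1.3, OR01 = 1.5, OR11 = 1.3 * 1.5 * 2.2
  set.seed(404)
  reris <- numeric(200)
  for (r in seq_len(200)) {
    cfg <- cohort_sim_config(seed = sample.int(1e7, 1), n_cases = 1000,
                             n_controls = 1000, missing_rate = 0)
    co <- simulate_cohort(cfg)
    tb <- build_4x2(co, "rs3825807", carrier = "major_carrier",
                    exposure = "tc", threshold = 5)
    reris[r] <- interaction_measures(tb)$reri$estimate
  }
  implied <- 1.3 * 1.5 * 2.2 - 1.3 - 1.5 + 1
  expect_lt(abs(mean(reris) - implied) / implied, 0.15)
})
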