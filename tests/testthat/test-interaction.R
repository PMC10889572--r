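test_that("the 4x2 table equals direct cross-tabulation", {
  d <- make_small_cohort()
  tb <- build_4x2(d, "rs1", carrier = "minor_carrier", exposure = "smoking")
  s <- d$subjects[!is.na(d$subjects$rs1), ]
  for (g in c(TRUE, FALSE)) for (e in c(TRUE, FALSE)) for (st in c("case", "control")) {
    row <- paste0("g", as.integer(g), "e", as.integer(e))
    expect_equal(tb$counts[row, st],
                 sum((s$rs1 >= 1) == g & s$smoking == e & s$status == st))
  }
  expect_equal(tb$n_excluded, 1)
})

test_that("a numeric exposure threshold is inclusive at the cut-point", {
  d <- make_small_cohort()
  tb <- build_4x2(d, "rs1", carrier = "minor_carrier", exposure = "tc",
                  threshold = 5.0)
  ## subject s04 has tc exactly 5.0 but a missing genotype; s06 tc = 5.2 carrier
  s <- d$subjects[!is.na(d$subjects$rs1), ]
  expect_equal(sum(tb$counts[c("g1e1", "g0e1"), ]), sum(s$tc >= 5.0))
  d$subjects$tc[7] <- 5.0  # control carrier, now exactly at the threshold
  tb2 <- build_4x2(d, "rs1", carrier = "minor_carrier", exposure = "tc",
                   threshold = 5.0)
  expect_equal(tb2$counts["g1e1", "control"] - tb$counts["g1e1", "control"], 1)
})

test_that("carrier rules accept allele letters and reject foreign alleles", {
  d <- make_small_cohort()
  t_allele <- build_4x2(d, "rs1", carrier = "T", exposure = "smoking")
  t_rule <- build_4x2(d, "rs1", carrier = "minor_carrier", exposure = "smoking")
  expect_identical(t_allele$counts, t_rule$counts)
  expect_error(build_4x2(d, "rs1", carrier = "G", exposure = "smoking"),
               "not an allele")
})

test_that("interaction identities hold to 1e-12 on random tables", {
  set.seed(55)
  for (i in 1:40) {
    w <- matrix(sample(0:30, 8, replace = TRUE), 4, 2,
                dimnames = list(c("g1e1", "g1e0", "g0e1", "g0e0"),
                                c("case", "control")))
    if (all(w["g0e0", ] == 0)) next
    m <- interaction_measures(w)
    o11 <- m$or11$or; o10 <- m$or10$or; o01 <- m$or01$or
    expect_equal(m$reri$estimate, o11 - o10 - o01 + 1, tolerance = 1e-12)
    expect_equal(m$ap$estimate, m$reri$estimate / o11, tolerance = 1e-12)
    expect_equal(m$sim$estimate, o11 / (o01 * o10), tolerance = 1e-12)
    if (!is.na(m$si$estimate))
      expect_equal(m$si$estimate, (o11 - 1) / ((o01 - 1) + (o10 - 1)),
                   tolerance = 1e-12)
    if (m$or01$or + m$or10$or >= 1) expect_lte(m$ap$estimate, 1)
  }
})

test_that("worked substitutions give the textbook interaction measures", {
  m <- interaction_measures(table_with_ors(2, 2, 4))
  expect_equal(m$or01$or, 2); expect_equal(m$or10$or, 2); expect_equal(m$or11$or, 4)
  expect_equal(m$reri$estimate, 1)
  expect_equal(m$ap$estimate, 0.25)
  expect_equal(m$si$estimate, 1.5)
  expect_equal(m$sim$estimate, 1)

  m2 <- interaction_measures(table_with_ors(2, 2, 3))  # exact additivity
  expect_equal(m2$reri$estimate, 0, tolerance = 1e-12)
  expect_equal(m2$ap$estimate, 0, tolerance = 1e-12)
  expect_equal(m2$si$estimate, 1)
  expect_equal(m2$sim$estimate, 0.75)
})

test_that("the full null flags SI as undefined but returns the rest", {
  m <- interaction_measures(table_with_ors(1, 1, 1))
  expect_equal(m$reri$estimate, 0, tolerance = 1e-12)
  expect_equal(m$ap$estimate, 0, tolerance = 1e-12)
  expect_equal(m$sim$estimate, 1, tolerance = 1e-12)
  expect_true(is.na(m$si$estimate))
  expect_match(paste(m$flags, collapse = " "), "SI undefined")
})

test_that("RERI > 0, SI > 1 and AP > 0 co-occur when SI is interpretable", {
  set.seed(66)
  for (i in 1:30) {
    w <- matrix(sample(5:60, 8, replace = TRUE), 4, 2,
                dimnames = list(c("g1e1", "g1e0", "g0e1", "g0e0"),
                                c("case", "control")))
    m <- interaction_measures(w)
    o01 <- m$or01$or; o10 <- m$or10$or
    if (is.na(m$si$estimate) || o01 + o10 <= 2) next
    expect_equal(m$reri$estimate > 0, m$si$estimate > 1)
    expect_equal(m$reri$estimate > 0, m$ap$estimate > 0)
  }
})

test_that("MOVER and bootstrap SI intervals agree at large n", {
  w <- table_with_ors(1.8, 1.6, 4.2, scale = 1250)  # n = 5000 per margin
  m <- interaction_measures(w)
  bs <- si_bootstrap_ci(w, n_boot = 2000, seed = 42)
  for (k in 1:2) {
    expect_lt(abs(m$si$ci[k] - bs[k]) / (bs[2] - bs[1]), 0.10)
  }
})

test_that("delta, MOVER and bootstrap RERI intervals are mutually consistent", {
  w <- table_with_ors(1.5, 1.4, 2.8, scale = 500)
  ci_d <- interaction_measures(w, "delta")$reri$ci
  ci_m <- interaction_measures(w, "mover")$reri$ci
  ci_b <- interaction_measures(w, "bootstrap", seed = 9)$reri$ci
  for (ci in list(ci_m, ci_b)) {
    expect_lt(abs(ci[1] - ci_d[1]), 0.35)
    expect_lt(abs(ci[2] - ci_d[2]), 0.35)
  }
})

test_that("the scan ranks a true synergistic pair first in most replicates", {
  set.seed(314)
  hits <- 0L
  reps <- 200
  for (r in seq_len(reps)) {
    cfg <- cohort_sim_config(seed = sample.int(1e7, 1), n_cases = 1000,
                             n_controls = 1000)
    co <- simulate_cohort(cfg)
    sc <- interaction_scan(co, exposures = list(tc = 5, smoking = NULL))
    top <- sc$snp_id[1]
    ## the generative synergy acts on the rs3825807 A-carrier x cholesterol
    ## pair; its block partner tags the same signal through LD
    if (sc$exposure[1] == "tc >= 5" && top %in% c("rs3825807", "rs1994016"))
      hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.90)
})

test_that("degenerate scans behave: empty exposures, constant exposure", {
  d <- make_small_cohort()
  sc0 <- interaction_scan(d, exposures = list())
  expect_s3_class(sc0, "gxe_scan")
  expect_equal(nrow(sc0), 0)
  d$subjects$always <- TRUE
  expect_warning(sc1 <- interaction_scan(d, snps = "rs1",
                                         exposures = list(always = NULL)),
                 "constant")
  expect_equal(nrow(sc1), 0)
})
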