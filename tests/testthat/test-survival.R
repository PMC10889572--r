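test_that("with no events the survivor function is 1 everywhere", {
  km <- km_estimate(data.frame(time = c(1, 2, 5), event = FALSE))
  expect_equal(nrow(km$table), 0)
  expect_equal(predict(km, c(0, 3, 10)), c(1, 1, 1))
})

test_that("the product-limit estimate matches the hand computation", {
  km <- km_estimate(data.frame(time = 1:3, event = TRUE))
  expect_equal(km$table$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km$table$n_risk, c(3, 2, 1))
})

test_that("a horizon censors later events administratively", {
  rec <- data.frame(time = c(1, 3, 7), event = c(TRUE, FALSE, TRUE))
  km5 <- km_estimate(rec, horizon = 5)
  equiv <- data.frame(time = c(1, 3, 5), event = c(TRUE, FALSE, FALSE))
  km_eq <- km_estimate(equiv)
  expect_equal(km5$table, km_eq$table)
  expect_equal(km5$n_events, 1)
})

test_that("without censoring KM equals the empirical survivor function", {
  set.seed(11)
  for (i in 1:5) {
    t <- round(stats::rexp(60, 0.2), 2)
    km <- km_estimate(data.frame(time = t, event = TRUE))
    for (tt in km$table$time)
      expect_equal(predict(km, tt), mean(t > tt), tolerance = 1e-12)
  }
})

test_that("Greenwood variance is zero until the first event", {
  km <- km_estimate(data.frame(time = c(1, 2, 3, 4), event = c(FALSE, FALSE, TRUE, TRUE)))
  expect_equal(predict(km, 2.5), 1)
  expect_gt(km$table$greenwood_var[1], 0)
})

test_that("events used at horizon 5 never exceed those at horizon 10", {
  set.seed(13)
  rec <- data.frame(time = stats::rexp(100, 0.15),
                    event = stats::runif(100) < 0.7)
  expect_lte(km_estimate(rec, horizon = 5)$n_events,
             km_estimate(rec, horizon = 10)$n_events)
})

test_that("identical groups give z = 0 and label swap negates z", {
  g <- data.frame(time = c(1, 2, 3, 4, 6), event = c(TRUE, TRUE, FALSE, TRUE, FALSE))
  lr <- logrank_2group(g, g)
  expect_equal(lr$z, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1, tolerance = 1e-12)

  set.seed(4)
  a <- data.frame(time = stats::rexp(40, 0.1), event = stats::runif(40) < 0.8)
  b <- data.frame(time = stats::rexp(40, 0.2), event = stats::runif(40) < 0.8)
  l1 <- logrank_2group(a, b); l2 <- logrank_2group(b, a)
  expect_equal(l1$z, -l2$z, tolerance = 1e-12)
  expect_equal(l1$p_value, l2$p_value, tolerance = 1e-12)
})

test_that("the k-sample statistic reduces to z-squared at k = 2", {
  set.seed(6)
  a <- data.frame(time = stats::rexp(50, 0.1), event = stats::runif(50) < 0.7)
  b <- data.frame(time = stats::rexp(50, 0.25), event = stats::runif(50) < 0.7)
  lr2 <- logrank_2group(a, b)
  lrk <- logrank_ksample(list(a, b))
  expect_equal(lrk$chi2, lr2$z^2, tolerance = 1e-10)
  expect_equal(lrk$df, 1L)
})

test_that("three identical groups give a null k-sample statistic", {
  g <- data.frame(time = c(1, 2, 3, 5, 8), event = c(TRUE, FALSE, TRUE, TRUE, FALSE))
  lr <- logrank_ksample(list(g, g, g))
  expect_equal(lr$chi2, 0, tolerance = 1e-10)
  expect_equal(lr$df, 2L)
})

test_that("no events at all is an explicit error", {
  g <- data.frame(time = c(1, 2), event = FALSE)
  expect_error(logrank_2group(g, g), "no events")
})

test_that("KM and log-rank match the reference survival package", {
  skip_if_not_installed("survival")
  set.seed(2718)
  for (i in 1:100) {
    n <- sample(10:60, 1)
    t <- round(stats::rexp(n, 0.2), 3)
    ev <- stats::runif(n) < 0.75
    if (sum(ev) == 0) ev[1] <- TRUE
    km <- km_estimate(data.frame(time = t, event = ev))
    sf <- survival::survfit(survival::Surv(t, ev) ~ 1)
    at <- km$table$time
    ref_surv <- summary(sf, times = at)$surv
    expect_equal(km$table$surv, ref_surv, tolerance = 1e-8)
    g <- rep(1:2, length.out = n)
    if (sum(ev[g == 1]) + sum(ev[g == 2]) == 0) next
    lr <- try(logrank_2group(data.frame(time = t[g == 1], event = ev[g == 1]),
                             data.frame(time = t[g == 2], event = ev[g == 2])),
              silent = TRUE)
    if (inherits(lr, "try-error")) next
    sd <- survival::survdiff(survival::Surv(t, ev) ~ g)
    expect_equal(lr$chi2, sd$chisq, tolerance = 1e-8)
  }
})

test_that("two-group power under hazard ratio 2 matches Schoenfeld", {
  set.seed(1001)
  reps <- 1000
  rej <- logical(reps)
  for (b in seq_len(reps)) {
    a <- data.frame(time = stats::rexp(200, 0.03), event = TRUE)
    d <- data.frame(time = stats::rexp(200, 0.06), event = TRUE)
    rej[b] <- logrank_2group(a, d, horizon = 5)$p_value < 0.05
  }
  d_expected <- 200 * (1 - exp(-0.15)) + 200 * (1 - exp(-0.3))
  approx <- logrank_power_schoenfeld(2, d_expected)
  expect_lt(abs(mean(rej) - approx), 0.03)
})

test_that("k-sample test has power under distinct proportional hazards", {
  set.seed(1002)
  reps <- 500
  hit <- logical(reps)
  for (b in seq_len(reps)) {
    gs <- lapply(c(0.04, 0.06, 0.09), function(r)
      data.frame(time = stats::rexp(300, r), event = TRUE))
    hit[b] <- logrank_ksample(gs, horizon = 5)$p_value < 0.05
  }
  expect_gte(mean(hit), 0.80)
})
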