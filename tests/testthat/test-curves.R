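test_that("preprocessing sorts, clamps, monotonises and anchors at (0, 1)", {
  # sorting only
  cv <- preprocess_curve(rbind(c(0, 1.0), c(3, 0.8), c(2, 0.9)))
  expect_equal(cv$time, c(0, 2, 3))
  expect_equal(cv$survival, c(1.0, 0.9, 0.8))
  # running-minimum monotonicity + (0, 1) prepend
  cv <- preprocess_curve(rbind(c(1, 0.95), c(2, 0.97), c(3, 0.90)))
  expect_equal(cv$time, c(0, 1, 2, 3))
  expect_equal(cv$survival, c(1.0, 0.95, 0.95, 0.90))
  # clamping to [0, 1]
  cv <- preprocess_curve(rbind(c(0, 1.02), c(5, -0.01)))
  expect_equal(cv$survival, c(1.0, 0.0))
  # duplicate times collapse to the lower survival
  cv <- preprocess_curve(rbind(c(0, 1), c(2, 0.8), c(2, 0.7), c(4, 0.5)))
  expect_equal(cv$time, c(0, 2, 4))
  expect_equal(cv$survival, c(1, 0.7, 0.5))
  expect_error(preprocess_curve(rbind(c(1, 0.5))), "at least two")
})

test_that("reconstruction handles single-drop and flat curves exactly", {
  cv <- preprocess_curve(rbind(c(0, 1.0), c(5, 0.5)))
  ipd <- reconstruct_ipd(cv, risk_table(c(0, 5), c(10, 5)), 10)
  expect_equal(nrow(ipd), 10)
  expect_equal(sum(ipd$event == 1 & ipd$time == 5), 5)
  expect_equal(sum(ipd$event == 0 & ipd$time == 5), 5)

  flat <- preprocess_curve(rbind(c(0, 1.0), c(12, 1.0)))
  ipd <- reconstruct_ipd(flat, risk_table(c(0, 12), c(8, 8)), 8)
  expect_equal(sum(ipd$event), 0)
  expect_equal(ipd$time, rep(12, 8))
})

test_that("reconstruction recovers per-interval event counts from an exact KM curve", {
  # 40 subjects with known event/censor times; the oracle is the generating
  # list itself plus a survfit-computed curve and risk table.  Censoring is
  # confined to event-free intervals so that the interval event counts are
  # identifiable from the curve and risk table alone.
  set.seed(11)
  true <- data.frame(
    time = c(sort(runif(12, 0.5, 2.9)),   # events in (0, 3]
             sort(runif(8, 3.1, 5.9)),    # censored in (3, 6]
             sort(runif(10, 6.1, 8.9)),   # events in (6, 9]
             sort(runif(10, 9.1, 12))),   # censored after 9
    event = c(rep(1L, 12), rep(0L, 8), rep(1L, 10), rep(0L, 10)))
  km <- survfit_curve(true)
  rt_times <- c(0, 3, 6, 9)
  rt <- risk_table(rt_times, vapply(rt_times, function(r) sum(true$time >= r), numeric(1)))
  cv <- preprocess_curve(cbind(c(km$time, max(true$time)),
                               c(km$survival, min(km$survival))))
  rec <- reconstruct_ipd(cv, rt, 40)
  expect_equal(nrow(rec), 40)
  breaks <- c(rt_times, Inf)
  for (j in seq_len(length(breaks) - 1)) {
    expected <- sum(true$event == 1 & true$time > breaks[j] & true$time <= breaks[j + 1])
    got <- sum(rec$event == 1 & rec$time > breaks[j] & rec$time <= breaks[j + 1])
    expect_equal(got, expected)
  }
})

test_that("product-limit estimator matches survfit and ignores record order", {
  # no censoring: S drops 1 -> 2/3 -> 1/3 -> 0
  km <- km_estimator(data.frame(time = c(1, 2, 3), event = c(1, 1, 1)))
  expect_equal(km$survival, c(1, 2/3, 1/3, 0))
  # censoring between events: only one subject at risk at t = 3
  d <- data.frame(time = c(1, 2, 3), event = c(1, 0, 1))
  km <- km_estimator(d)
  oracle <- survfit_curve(d)
  expect_equal(km$survival, oracle$survival)
  expect_equal(surv_step(km, 1), 2/3)
  # all censored: S identically 1
  km <- km_estimator(data.frame(time = c(1, 2, 5), event = c(0, 0, 0)))
  expect_equal(km$survival, 1)
  # order invariance and survfit agreement on a larger random sample
  set.seed(7)
  d <- data.frame(time = rexp(200) + 0.01, event = rbinom(200, 1, 0.7))
  km1 <- km_estimator(d)
  km2 <- km_estimator(d[sample(nrow(d)), ])
  expect_identical(km1$survival, km2$survival)
  expect_equal(km1$survival, survfit_curve(d)$survival, tolerance = 1e-12)
})

test_that("round-trip KM -> IPD -> KM stays within 0.02 sup-norm at n >= 200", {
  for (s in c(21, 22, 23)) {
    ipd <- simulate_ipd(0.05, 1.2, 250, censor_rate = 0.25, max_follow = 30,
                        seed = s)
    km <- km_estimator(ipd)
    rt_times <- seq(0, 29, length.out = 6)
    rt <- risk_table(rt_times,
                     vapply(rt_times, function(r) sum(ipd$time >= r), numeric(1)))
    cv <- preprocess_curve(cbind(km$time, km$survival))
    rec <- reconstruct_ipd(cv, rt, 250)
    expect_equal(nrow(rec), 250)
    expect_lt(curve_supnorm(km, km_estimator(rec), at = km$time), 0.02)
  }
})

test_that("reconstruction validates its inputs", {
  cv <- preprocess_curve(rbind(c(0, 1), c(5, 0.5)))
  expect_error(reconstruct_ipd(cv, risk_table(c(0, 5), c(20, 5)), 10),
               "exceeds")
  raw <- digitized_curve(c(1, 3), c(0.9, 0.8))
  expect_error(reconstruct_ipd(raw, NULL, 10), "preprocessed")
  expect_error(reconstruct_ipd(cv, NULL, 0), "positive integer")
})

test_that("curve and risk-table CSV round-trips preserve the data", {
  dir <- withr::local_tempdir()
  ipd <- simulate_ipd(0.1, 1.2, 60, 0.2, 24, seed = 5, arm = "AVE",
                      endpoint = "PFS")
  dig <- digitize_curve(ipd, n_points = 20, jitter = 0, seed = 1)
  df <- data.frame(time_months = dig$curve$time, survival = dig$curve$survival,
                   arm = "AVE", endpoint = "PFS")
  write.csv(df, file.path(dir, "curves.csv"), row.names = FALSE)
  curves <- read_curves_csv(file.path(dir, "curves.csv"))
  expect_named(curves, "AVE_PFS")
  expect_equal(max(abs(curves$AVE_PFS$survival - cummin(dig$curve$survival))), 0)
  rt_df <- data.frame(time_months = dig$risk$time, n_at_risk = dig$risk$n_at_risk,
                      arm = "AVE", endpoint = "PFS")
  write.csv(rt_df, file.path(dir, "risk.csv"), row.names = FALSE)
  rts <- read_risk_tables_csv(file.path(dir, "risk.csv"))
  expect_equal(rts$AVE_PFS$n_at_risk, dig$risk$n_at_risk)
  write_ipd_csv(ipd, file.path(dir, "ipd.csv"))
  back <- read.csv(file.path(dir, "ipd.csv"))
  expect_equal(back$time_months, ipd$time)
  expect_equal(back$event, ipd$event)
})
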