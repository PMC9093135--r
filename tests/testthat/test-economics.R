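test_that("utility and currency helpers evaluate their formulas", {
  expect_equal(utility_from_qlqc30(0), 0)
  expect_equal(utility_from_qlqc30(126), 1)
  expect_equal(utility_from_qlqc30(100.8), 0.8)
  expect_error(utility_from_qlqc30(130), "\\[0, 126\\]")
  expect_equal(cny_to_usd(6.36), 1)
  expect_equal(cny_to_usd(0), 0)
  expect_equal(cny_to_usd(1000), 1000 / 6.36)
  expect_error(cny_to_usd(10, rate = 0), "> 0")
})

test_that("discount factors compound the annual rate per cycle", {
  expect_equal(discount_factor(0, 0:40), rep(1, 41))
  expect_equal(discount_factor(0.03, 12), 1 / 1.03)
  expect_equal(discount_factor(0.05, 0), 1)
  expect_equal(discount_factor(0.05, 30), (1.05)^(-30 / 12))
})

test_that("QALY accrual matches hand calculations on simple traces", {
  spec <- model_spec(horizon = 1, arm = "AVE")
  res <- accrue(all_pfs_trace(1), zero_inputs(utility_pfs = 0.84),
                default_cost_schedule(), spec)
  expect_equal(res$qalys, 0.84 / 12)
  expect_equal(res$cost, 0)
  # all utilities and costs zero -> zero result
  res <- accrue(all_pfs_trace(12), zero_inputs(),
                default_cost_schedule(), model_spec(horizon = 12, arm = "CON"))
  expect_equal(res$qalys, 0)
  expect_equal(res$cost, 0)
})

test_that("a constant PFS cost reproduces the discounted annuity closed form", {
  H <- 120; c_m <- 1000; r <- 0.03
  spec <- model_spec(horizon = H, arm = "AVE")
  res <- accrue(all_pfs_trace(H),
                zero_inputs(cost_bsc_ave_monthly = c_m, discount_rate = r),
                default_cost_schedule(), spec)
  annuity <- sum(c_m * (1 + r)^(-(0:(H - 1)) / 12))
  expect_equal(res$cost, annuity, tolerance = 1e-9)
  # discounted totals never exceed undiscounted ones and decrease in the rate
  res0 <- accrue(all_pfs_trace(H), zero_inputs(cost_bsc_ave_monthly = c_m),
                 default_cost_schedule(), spec)
  res5 <- accrue(all_pfs_trace(H),
                 zero_inputs(cost_bsc_ave_monthly = c_m, discount_rate = 0.05),
                 default_cost_schedule(), spec)
  expect_gt(res0$cost, res$cost)
  expect_gt(res$cost, res5$cost)
})

test_that("accrual is linear in utilities and cost items", {
  set.seed(55)
  series <- random_transition_series(24)
  trace <- run_cohort(series)
  spec <- model_spec(horizon = 24, arm = "AVE")
  sched <- default_cost_schedule()
  for (item in c("utility_pfs", "utility_pd", "cost_pd_monthly",
                 "cost_drug_monthly", "cost_ae_ave")) {
    args1 <- list(); args1[[item]] <- 1
    args3 <- list(); args3[[item]] <- 3
    r1 <- accrue(trace, do.call(zero_inputs, args1), sched, spec)
    r3 <- accrue(trace, do.call(zero_inputs, args3), sched, spec)
    expect_equal(3 * (r1$cost + r1$qalys), r3$cost + r3$qalys,
                 tolerance = 1e-12)
  }
  # superposition across two items
  ra <- accrue(trace, zero_inputs(cost_pd_monthly = 100), sched, spec)
  rb <- accrue(trace, zero_inputs(cost_imaging = 50), sched, spec)
  rab <- accrue(trace, zero_inputs(cost_pd_monthly = 100, cost_imaging = 50),
                sched, spec)
  expect_equal(rab$cost, ra$cost + rb$cost, tolerance = 1e-12)
})

test_that("the treatment-duration stop rule caps drug cost accrual fractionally", {
  H <- 12
  spec <- model_spec(horizon = H, arm = "AVE")
  sched <- default_cost_schedule(treat_duration_ave_months = 2.5)
  res <- accrue(all_pfs_trace(H), zero_inputs(cost_drug_monthly = 1200),
                sched, spec)
  expect_equal(res$cost, 1200 * 2.5)    # 2 full cycles + half a cycle
  # the comparator arm never accrues drug cost
  res_con <- accrue(all_pfs_trace(H), zero_inputs(cost_drug_monthly = 1200),
                    sched, model_spec(horizon = H, arm = "CON"))
  expect_equal(res_con$cost, 0)
})

test_that("ICER reproduces the published incremental arithmetic", {
  for (country in c("US", "China")) {
    for (pop in c("overall", "PD-L1-positive")) {
      ref <- reference_arm_results(country, pop)
      ic <- icer(ref$ave, ref$con)
      expect_equal(ic$icer, ref$icer, tolerance = 0.005 / ref$icer)
      expect_equal(ic$icer, ic$delta_cost / ic$delta_qalys)
    }
  }
})

test_that("dominance taxonomy covers every quadrant", {
  expect_equal(icer(arm_result(10, 2), arm_result(20, 1))$status, "dominant")
  expect_equal(icer(arm_result(20, 1), arm_result(10, 2))$status, "dominated")
  sw <- icer(arm_result(10, 1), arm_result(20, 2))
  expect_equal(sw$status, "southwest")
  expect_equal(sw$icer, (10 - 20) / (1 - 2))
  same <- icer(arm_result(10, 1), arm_result(10, 1))
  expect_equal(same$status, "undefined")
  expect_true(is.na(same$icer))
  expect_equal(icer(arm_result(20, 1), arm_result(10, 1))$status, "undefined")
})

test_that("net monetary benefit is consistent with the ICER decision rule", {
  a <- arm_result(1971.13, 0.21)
  expect_equal(net_monetary_benefit(a, 0), -1971.13)
  expect_equal(net_monetary_benefit(a, 150000), 150000 * 0.21 - 1971.13)
  expect_equal(net_monetary_benefit(a, 150000), 29528.87)
  set.seed(77)
  for (i in 1:50) {
    ave <- arm_result(runif(1, 0, 1e5), runif(1, 0.1, 2))
    con <- arm_result(runif(1, 0, 1e5), runif(1, 0.1, 2))
    wtp <- runif(1, 1e3, 3e5)
    ic <- icer(ave, con)
    if (ic$delta_qalys > 0) {
      nmb_better <- net_monetary_benefit(ave, wtp) > net_monetary_benefit(con, wtp)
      icer_below <- ic$delta_cost / ic$delta_qalys < wtp
      expect_equal(nmb_better, icer_below)
    }
  }
  expect_error(net_monetary_benefit(a, -1), ">= 0")
})

test_that("parameter tables carry valid ranges and the scenario structure", {
  for (country in c("US", "China")) {
    for (pop in c("overall", "PD-L1-positive")) {
      p <- table1_parameters(country, pop)
      expect_true(all(p$low <= p$base & p$base <= p$high))
      expect_true(all(p$dist[grepl("^utility", p$name)] == "beta"))
      expect_true(all(p$dist[grepl("^cost", p$name)] == "gamma"))
      sched <- default_cost_schedule()
      expect_setequal(sched$item, p$name[grepl("^cost", p$name)])
    }
  }
  expect_equal(table1_parameters("US")$base[
    table1_parameters("US")$name == "discount_rate"], 0.03)
  expect_equal(table1_parameters("China")$base[
    table1_parameters("China")$name == "discount_rate"], 0.05)
})
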