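# a transparent toy model: ICER = (C0 + p) / E with overridable p
toy_model <- function(C0 = 100, E = 0.5, base = c(p = 20, unused = 7)) {
  function(overrides = NULL) {
    vals <- base
    if (!is.null(overrides)) vals[names(overrides)] <- overrides
    icer(arm_result(C0 + vals[["p"]], E + 1), arm_result(0, 1))
  }
}

toy_params <- function() {
  data.frame(name = c("p", "unused"), base = c(20, 7), low = c(10, 7),
             high = c(30, 7), dist = c("gamma", "fixed"),
             stringsAsFactors = FALSE)
}

test_that("gamma moment matching reproduces mean and SE analytically", {
  mm <- moment_match_gamma(100, 80, 120)
  expect_equal(mm$se, 40 / 3.92)
  expect_equal(mm$se, 10.2041, tolerance = 1e-4)
  expect_equal(mm$shape, 96.04, tolerance = 1e-10)
  expect_equal(mm$rate, 0.9604, tolerance = 1e-10)
  expect_equal(mm$shape / mm$rate, 100)                  # mean
  expect_equal(sqrt(mm$shape) / mm$rate, mm$se)          # SE
  # scale equivariance: doubling everything halves the rate, keeps the shape
  mm2 <- moment_match_gamma(200, 160, 240)
  expect_equal(mm2$shape, mm$shape)
  expect_equal(mm2$rate, mm$rate / 2)
  # Monte-Carlo check
  set.seed(13)
  x <- rgamma(1e5, shape = mm$shape, rate = mm$rate)
  expect_lt(abs(mean(x) - 100), 3 * mm$se / sqrt(1e5))
})

test_that("beta moment matching reproduces mean and SE analytically", {
  mm <- moment_match_beta(0.84, 0.68, 1.00)
  expect_equal(mm$se, 0.32 / 3.92)
  expect_equal(mm$se, 0.08163, tolerance = 1e-4)
  m <- mm$alpha / (mm$alpha + mm$beta)
  v <- mm$alpha * mm$beta / ((mm$alpha + mm$beta)^2 * (mm$alpha + mm$beta + 1))
  expect_equal(m, 0.84, tolerance = 1e-12)
  expect_equal(sqrt(v), mm$se, tolerance = 1e-12)
  # symmetric case: alpha = beta
  mm_s <- moment_match_beta(0.5, 0.3, 0.7)
  expect_equal(mm_s$alpha, mm_s$beta)
  # upper bound clamped to 1 before the SE is formed
  mm_c <- moment_match_beta(0.84, 0.68, 1.2)
  expect_equal(mm_c$se, mm$se)
  expect_error(moment_match_beta(0.5, -3, 4), "infeasible")
  # Monte-Carlo check
  set.seed(14)
  x <- rbeta(1e5, mm$alpha, mm$beta)
  expect_lt(abs(mean(x) - 0.84), 3 * mm$se / sqrt(1e5))
})

test_that("one-way DSA has the closed-form width and sorts unused last", {
  tor <- one_way_dsa(toy_model(), toy_params())
  expect_s3_class(tor, "tornado")
  p_row <- tor[tor$parameter == "p", ]
  expect_equal(p_row$icer_low, 110 / 0.5)
  expect_equal(p_row$icer_high, 130 / 0.5)
  expect_equal(p_row$width, 20 / 0.5)
  expect_equal(tor$parameter[nrow(tor)], "unused")
  expect_equal(tor$width[nrow(tor)], 0)
  # ordering invariant to parameter listing order
  tor_rev <- one_way_dsa(toy_model(), toy_params()[2:1, ])
  expect_equal(tor$parameter, tor_rev$parameter)
  expect_equal(tor$width, tor_rev$width)
})

test_that("DSA flags dominance at an endpoint instead of emitting NaN", {
  # low p makes the intervention cost-saving -> dominant at that endpoint
  model <- function(overrides = NULL) {
    p <- if (!is.null(overrides) && "p" %in% names(overrides)) overrides[["p"]] else 5
    icer(arm_result(max(0, p - 10) , 2), arm_result(1, 1))
  }
  params <- data.frame(name = "p", base = 5, low = 0, high = 50,
                       dist = "gamma", stringsAsFactors = FALSE)
  tor <- one_way_dsa(model, params, wtp = 1000)
  expect_true(tor$flag[1] != "")
  expect_false(any(is.nan(tor$width)))
})

test_that("PSA draws are reproducible and degenerate when all parameters are fixed", {
  params <- toy_params()
  d1 <- run_psa(toy_model(), params, n_draws = 200, seed = 99)
  d2 <- run_psa(toy_model(), params, n_draws = 200, seed = 99)
  expect_identical(d1, d2)
  fixed <- params; fixed$dist <- "fixed"
  d0 <- run_psa(toy_model(), fixed, n_draws = 50, seed = 1)
  expect_equal(unique(d0$delta_cost), 120)
  expect_equal(unique(d0$delta_qalys), 0.5)
})

test_that("sampled utilities reproduce the specified mean over 1000 draws", {
  params <- table1_parameters("US", "overall")
  set.seed(2024)
  draws <- replicate(1000, maintcea:::draw_params(params))
  u <- draws["utility_pfs", ]
  mm <- moment_match_beta(0.84, 0.68, 1.00)
  expect_lt(abs(mean(u) - 0.84), 3 * mm$se / sqrt(1000))
  expect_equal(unique(draws["discount_rate", ]), 0.03)  # fixed stays fixed
})

test_that("CEAC probabilities follow the NMB rule and its limits", {
  # dominance: all draws gain QALYs and save cost
  dom <- data.frame(delta_cost = c(-5, -1), delta_qalys = c(0.1, 0.2))
  expect_true(all(ceac(dom, c(0, 1e4, 3e5))$probability == 1))
  # hand enumeration: 2 of 4 draws cost-effective at wtp = 100
  draws <- data.frame(delta_cost = c(50, 150, 90, 500),
                      delta_qalys = c(1, 1, 1, 1))
  expect_equal(ceac(draws, 100)$probability, 0.5)
  # exact tie counts as not cost-effective
  tie <- data.frame(delta_cost = 100, delta_qalys = 1)
  expect_equal(ceac(tie, 100)$probability, 0)
  # limits on the draw set
  set.seed(3)
  rnd <- data.frame(delta_cost = rnorm(500, 10, 40),
                    delta_qalys = rnorm(500, 0.1, 0.3))
  cc <- ceac(rnd, c(0, 1e9))
  expect_equal(cc$probability[1], mean(rnd$delta_cost < 0))
  expect_equal(cc$probability[2], mean(rnd$delta_qalys > 0))
})

test_that("the default WTP grid contains both decision thresholds", {
  g <- default_wtp_grid()
  expect_true(all(c(150000, 30447.09) %in% g))
  expect_false(is.unsorted(g))
})
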