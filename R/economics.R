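# Discounted cost and QALY accrual over the cohort trace, and incremental
# cost-effectiveness statistics.

#' Utility from a QLQ-C30 score
#'
#' Health-state utilities in this analysis derive from the EORTC
#' Quality of Life Questionnaire Core 30 by dividing the score by 126, so
#' that 1 is perfect health and 0 is death.
#'
#' @param score QLQ-C30 score in `[0, 126]`.
#' @return utility in `[0, 1]`.
#' @export
utility_from_qlqc30 <- function(score) {
  if (any(score < 0) || any(score > 126)) {
    stop("QLQ-C30 score must be in [0, 126]", call. = FALSE)
  }
  score / 126
}

#' Convert Chinese yuan to US dollars
#'
#' All Chinese costs in the model are stored in USD, converted at the
#' 2022 exchange rate of 6.36 CNY per USD; this helper is for ingesting
#' new CNY prices.
#'
#' @param amount amount in CNY, >= 0.
#' @param rate CNY per USD (default 6.36).
#' @return amount in USD.
#' @export
cny_to_usd <- function(amount, rate = 6.36) {
  if (any(amount < 0)) stop("`amount` must be >= 0", call. = FALSE)
  if (rate <= 0) stop("`rate` must be > 0", call. = FALSE)
  amount / rate
}

#' Per-cycle discount factor
#'
#' Discounting is applied at cycle start with an annual rate compounded
#' per cycle: `(1 + annual_rate)^(-cycle_index / cycles_per_year)`.
#'
#' @param annual_rate annual discount rate (0.03 US, 0.05 China).
#' @param cycle_index cycle number, 0-based (vectorized).
#' @param cycles_per_year cycles per year (12 for monthly cycles).
#' @return discount factors.
#' @export
discount_factor <- function(annual_rate, cycle_index, cycles_per_year = 12) {
  if (annual_rate < 0) stop("`annual_rate` must be >= 0", call. = FALSE)
  if (any(cycle_index < 0)) stop("`cycle_index` must be >= 0", call. = FALSE)
  (1 + annual_rate)^(-cycle_index / cycles_per_year)
}

#' Model input parameters by country and population
#'
#' Returns the cost and utility inputs of the analysis as one row per
#' parameter with its base value, range and sampling distribution: beta
#' for utilities, gamma for costs, fixed for the discount rate.  Monetary
#' values are USD; Chinese prices were converted at 6.36 CNY/USD.
#' Utilities are shared by both arms and both countries; drug and best
#' supportive care costs differ by population because the PD-L1-positive
#' analysis prices a different usage mix.
#'
#' @param country `"US"` or `"China"`.
#' @param population `"overall"` or `"PD-L1-positive"`.
#' @return a data frame with columns `name`, `base`, `low`, `high`, `dist`.
#' @export
table1_parameters <- function(country = c("US", "China"),
                              population = c("overall", "PD-L1-positive")) {
  country <- match.arg(country)
  population <- match.arg(population)
  p <- function(name, base, low, high, dist) {
    data.frame(name = name, base = base, low = low, high = high, dist = dist,
               stringsAsFactors = FALSE)
  }
  shared <- rbind(
    p("utility_pfs", 0.84, 0.68, 1.00, "beta"),
    p("utility_pd",  0.80, 0.64, 0.96, "beta"))
  if (country == "US") {
    fixed_costs <- rbind(
      p("cost_pdl1_test",    431.28,  345.03,  517.54, "gamma"),
      p("cost_pretreatment",   6.96,    5.57,    8.35, "gamma"),
      p("cost_ae_con",        74.89,   59.91,   89.87, "gamma"),
      p("cost_ae_ave",       111.68,   89.34,  134.02, "gamma"),
      p("cost_imaging",     1137.67,  910.14, 1365.20, "gamma"),
      p("cost_pd_monthly",  2396.70, 1917.36, 2876.04, "gamma"))
    pop_costs <- if (population == "overall") rbind(
      p("cost_drug_monthly",    22022.59, 17618.07, 26427.11, "gamma"),
      p("cost_bsc_ave_monthly",  4324.24,  3387.39,  5081.09, "gamma"),
      p("cost_bsc_con_monthly",  4113.40,  3290.72,  4936.08, "gamma"))
    else rbind(
      p("cost_drug_monthly",    14295.37, 11436.30, 17154.44, "gamma"),
      p("cost_bsc_ave_monthly",  2754.38,  2203.50,  3305.26, "gamma"),
      p("cost_bsc_con_monthly",  3917.52,  3134.02,  4701.02, "gamma"))
    disc <- p("discount_rate", 0.03, 0.03, 0.03, "fixed")
  } else {
    fixed_costs <- rbind(
      p("cost_pdl1_test",    157.23, 125.78, 188.68, "gamma"),
      p("cost_pretreatment",   1.57,   1.26,   1.88, "gamma"),
      p("cost_ae_con",        29.73,  23.78,  35.68, "gamma"),
      p("cost_ae_ave",        51.33,  41.06,  61.60, "gamma"),
      p("cost_imaging",      163.96, 131.17, 196.75, "gamma"),
      p("cost_pd_monthly",   376.83, 301.46, 452.20, "gamma"))
    pop_costs <- if (population == "overall") rbind(
      p("cost_drug_monthly",    172637.26, 138109.81, 207164.71, "gamma"),
      p("cost_bsc_ave_monthly",   2726.00,   2180.80,   3271.20, "gamma"),
      p("cost_bsc_con_monthly",   2642.93,   2114.34,   3171.52, "gamma"))
    else rbind(
      p("cost_drug_monthly",    112062.00, 89649.60, 134474.40, "gamma"),
      p("cost_bsc_ave_monthly",   2754.38,  2203.50,   3305.26, "gamma"),
      p("cost_bsc_con_monthly",   3917.52,  3134.02,   4701.02, "gamma"))
    disc <- p("discount_rate", 0.05, 0.05, 0.05, "fixed")
  }
  rbind(shared, fixed_costs, pop_costs, disc)
}

#' Willingness-to-pay threshold by country
#'
#' @param country `"US"` (150,000 USD/QALY) or `"China"` (30,447.09
#'   USD/QALY, three times per-capita GDP converted to USD).
#' @return the WTP threshold in USD per QALY.
#' @export
wtp_threshold <- function(country = c("US", "China")) {
  switch(match.arg(country), US = 150000, China = 30447.09)
}

#' Default cost schedule
#'
#' The published input table does not state when each cost item is
#' incurred, so the schedule is explicit and configurable.  Defaults:
#' PD-L1 testing, pretreatment and adverse-event management are one-time
#' costs at model entry; drug acquisition and best supportive care accrue
#' per cycle while in PFS, the drug additionally stopping at the median
#' treatment duration (24.9 weeks); imaging accrues per PFS cycle at its
#' monthly equivalent of an every-8-weeks examination; the progressed
#' disease cost is per patient per month in PD.
#'
#' @param treat_duration_ave_months months of avelumab dosing before the
#'   treatment-duration stop rule halts drug cost accrual (default
#'   `weeks_to_months(24.9)`; `Inf` disables the cap).
#' @param imaging_interval_weeks interval between imaging examinations
#'   (default 8 weeks); the per-cycle multiplier is
#'   `weeks-per-month / interval`.
#' @return a data frame of class `cost_schedule`, one row per cost item,
#'   with columns `item`, `timing` (`one_time_at_entry` | `per_cycle`),
#'   `state` (`PFS` | `PD` | `both`), `arm` (`AVE` | `CON` | `both`),
#'   `stop_months` (NA = no stop rule) and `multiplier`.
#' @export
default_cost_schedule <- function(treat_duration_ave_months = weeks_to_months(24.9),
                                  imaging_interval_weeks = 8) {
  s <- function(item, timing, state, arm, stop_months = NA_real_, multiplier = 1) {
    data.frame(item = item, timing = timing, state = state, arm = arm,
               stop_months = stop_months, multiplier = multiplier,
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    s("cost_pdl1_test",       "one_time_at_entry", "both", "both"),
    s("cost_pretreatment",    "one_time_at_entry", "both", "both"),
    s("cost_ae_ave",          "one_time_at_entry", "both", "AVE"),
    s("cost_ae_con",          "one_time_at_entry", "both", "CON"),
    s("cost_drug_monthly",    "per_cycle", "PFS", "AVE",
      stop_months = treat_duration_ave_months),
    s("cost_bsc_ave_monthly", "per_cycle", "PFS", "AVE"),
    s("cost_bsc_con_monthly", "per_cycle", "PFS", "CON"),
    s("cost_imaging",         "per_cycle", "PFS", "both",
      multiplier = WEEKS_PER_MONTH / imaging_interval_weeks),
    s("cost_pd_monthly",      "per_cycle", "PD", "both"))
  class(out) <- c("cost_schedule", "data.frame")
  out
}

#' Accrue discounted costs and QALYs over a cohort trace
#'
#' QALYs: `sum_t [occ_PFS(t)*u_PFS + occ_PD(t)*u_PD] * cycle_length/12 *
#' discount_factor(t)`.  Costs: one-time items at cycle 0 plus per-cycle
#' items times applicable state occupancy, multiplier and discount factor,
#' honouring each item's stop rule (treatment-duration caps apply
#' fractionally within the cycle in which they fall).
#'
#' @param trace a `cohort_trace`.
#' @param inputs a named list/vector of parameter values (as in
#'   `table1_parameters()$base` named by `name`): utilities, cost items,
#'   `discount_rate`.
#' @param schedule a [default_cost_schedule()]-style `cost_schedule`.
#' @param spec the arm's [model_spec] (`arm` selects applicable items).
#' @return an object of class `arm_result`: list with `cost` (discounted
#'   USD), `qalys` (discounted QALYs) and `arm`.
#' @export
accrue <- function(trace, inputs, schedule, spec) {
  stopifnot(inherits(spec, "model_spec"))
  inputs <- as.list(inputs)
  H <- spec$horizon; cl <- spec$cycle_length
  m <- unclass(trace)
  if (nrow(m) < H + 1) stop("trace shorter than the model horizon", call. = FALSE)
  occ <- m[seq_len(H), , drop = FALSE]           # cycle-start occupancy
  df <- discount_factor(inputs$discount_rate, seq_len(H) - 1,
                        cycles_per_year = 12 / cl)
  ly <- cl / 12
  qalys <- sum((occ[, "PFS"] * inputs$utility_pfs +
                occ[, "PD"] * inputs$utility_pd) * ly * df)
  cost <- 0
  cycle_start <- (seq_len(H) - 1) * cl
  for (i in seq_len(nrow(schedule))) {
    row <- schedule[i, ]
    if (!(row$arm %in% c("both", spec$arm))) next
    amount <- inputs[[row$item]]
    if (is.null(amount)) {
      stop(sprintf("cost schedule item `%s` missing from inputs", row$item),
           call. = FALSE)
    }
    if (row$timing == "one_time_at_entry") {
      cost <- cost + amount
    } else {
      s_occ <- switch(row$state,
                      PFS = occ[, "PFS"],
                      PD = occ[, "PD"],
                      both = occ[, "PFS"] + occ[, "PD"])
      w <- if (is.na(row$stop_months)) 1 else
        pmin(1, pmax(0, (row$stop_months - cycle_start) / cl))
      cost <- cost + amount * row$multiplier * sum(s_occ * w * df)
    }
  }
  structure(list(cost = cost, qalys = qalys, arm = spec$arm),
            class = "arm_result")
}

#' Construct an arm result directly
#'
#' Useful for injecting published per-arm totals into [icer()] without
#' running the trace.
#'
#' @param cost discounted total cost in USD.
#' @param qalys discounted total QALYs.
#' @param arm arm label.
#' @return an `arm_result`.
#' @export
arm_result <- function(cost, qalys, arm = NA_character_) {
  if (cost < 0 || qalys < 0) stop("cost and QALYs must be >= 0", call. = FALSE)
  structure(list(cost = cost, qalys = qalys, arm = arm), class = "arm_result")
}

#' Incremental cost-effectiveness ratio
#'
#' `delta_cost / delta_qalys` of the intervention versus the comparator,
#' with the standard dominance taxonomy instead of a silent division:
#' `icer` status when both increments are positive; `dominant` when the
#' intervention gains QALYs at no extra (or lower) cost; `dominated` when
#' it loses QALYs at no saving; `southwest` (cheaper and less effective)
#' reports the ratio but flags it; zero incremental QALYs give status
#' `undefined` and no division.
#'
#' @param ave intervention `arm_result`.
#' @param con comparator `arm_result`.
#' @return an object of class `icer_result`: `delta_cost`, `delta_qalys`,
#'   `icer` (NA when not a ratio) and `status`.
#' @export
icer <- function(ave, con) {
  dc <- ave$cost - con$cost
  de <- ave$qalys - con$qalys
  if (!is.finite(dc) || !is.finite(de)) {
    stop("arm results must be finite", call. = FALSE)
  }
  if (de == 0) {
    status <- "undefined"; ratio <- NA_real_
  } else if (de > 0 && dc > 0) {
    status <- "icer"; ratio <- dc / de
  } else if (de > 0) {
    status <- "dominant"; ratio <- NA_real_
  } else if (dc >= 0) {
    status <- "dominated"; ratio <- NA_real_
  } else {
    status <- "southwest"; ratio <- dc / de
  }
  structure(list(delta_cost = dc, delta_qalys = de, icer = ratio,
                 status = status),
            class = "icer_result")
}

#' @export
print.icer_result <- function(x, ...) {
  cat(sprintf("<icer_result> dCost = %.2f USD, dQALY = %.4f, %s\n",
              x$delta_cost, x$delta_qalys,
              if (x$status %in% c("icer", "southwest"))
                sprintf("ICER = %.2f USD/QALY%s", x$icer,
                        if (x$status == "southwest") " (southwest)" else "")
              else x$status))
  invisible(x)
}

#' Net monetary benefit
#'
#' `wtp * total_qalys - total_cost`; the intervention has higher NMB than
#' the comparator exactly when its ICER is below `wtp` (for positive
#' incremental QALYs).
#'
#' @param arm an `arm_result`.
#' @param wtp willingness-to-pay threshold in USD/QALY, >= 0.
#' @return NMB in USD.
#' @export
net_monetary_benefit <- function(arm, wtp) {
  if (wtp < 0) stop("`wtp` must be >= 0", call. = FALSE)
  wtp * arm$qalys - arm$cost
}

#' Published base-case per-arm totals
#'
#' The discounted per-arm cost and QALY totals reported in the original
#' avelumab maintenance cost-effectiveness analysis, by country and
#' population.  They are used to validate the incremental arithmetic
#' (ICER, incremental cost) rather than being recomputed: the absolute
#' totals depend on the original study's digitized curves and unpublished
#' cost-timing conventions.
#'
#' @param country `"US"` or `"China"`.
#' @param population `"overall"` or `"PD-L1-positive"`.
#' @return a list with `ave` and `con` (each an `arm_result`) and the
#'   published `icer`.
#' @export
reference_arm_results <- function(country = c("US", "China"),
                                  population = c("overall", "PD-L1-positive")) {
  country <- match.arg(country)
  population <- match.arg(population)
  key <- paste(country, population)
  vals <- switch(key,
    "US overall" = list(ave = c(1971.13, 0.21), con = c(436.35, 0.17),
                        icer = 38369.50),
    "US PD-L1-positive" = list(ave = c(1597.66, 0.25), con = c(467.14, 0.18),
                               icer = 16150.29),
    "China overall" = list(ave = c(9794.48, 0.21), con = c(130.07, 0.17),
                           icer = 241610.25),
    "China PD-L1-positive" = list(ave = c(7171.91, 0.25), con = c(134.93, 0.18),
                                  icer = 100528.29))
  list(ave = arm_result(vals$ave[1], vals$ave[2], "AVE"),
       con = arm_result(vals$con[1], vals$con[2], "CON"),
       icer = vals$icer)
}
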