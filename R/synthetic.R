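# Synthetic trial generator: Weibull event times calibrated to the
# published survival medians, independent censoring, emulated figure
# digitization, and a Gompertz-shaped life table.  Everything the pipeline
# consumes can be produced here, so all stages run without downloads.

# exponential censoring hazard giving the requested non-event fraction
# for Weibull(lambda, gamma) event times with administrative censoring at
# max_follow; returns 0 when the admin floor already exceeds the target.
censoring_hazard <- function(lambda, gamma, censor_rate, max_follow = Inf) {
  if (censor_rate < 0 || censor_rate >= 1) {
    stop("`censor_rate` must be in [0, 1)", call. = FALSE)
  }
  if (censor_rate == 0) return(0)
  f_t <- function(t) lambda * gamma * t^(gamma - 1) * exp(-lambda * t^gamma)
  p_censored <- function(lc) {
    # P(non-event) = 1 - P(T <= min(C, max_follow))
    upper <- if (is.finite(max_follow)) max_follow else Inf
    1 - stats::integrate(function(t) f_t(t) * exp(-lc * t), 0, upper,
                         rel.tol = 1e-10)$value
  }
  if (p_censored(1e-12) >= censor_rate) return(0)   # admin censoring suffices
  stats::uniroot(function(lc) p_censored(lc) - censor_rate,
                 lower = 1e-12, upper = 100, tol = 1e-12)$root
}

#' Simulate right-censored Weibull trial data
#'
#' Event times are drawn by inversion, `T = (-log U / lambda)^(1/gamma)`;
#' independent exponential censoring is tuned so the expected non-event
#' fraction equals `censor_rate` (allowing for administrative censoring at
#' `max_follow`).
#'
#' @param lambda,gamma Weibull cumulative-hazard parameters.
#' @param n number of subjects.
#' @param censor_rate target fraction of non-events, in `[0, 1)`.
#' @param max_follow administrative censoring time in months (`Inf` for
#'   none).
#' @param seed RNG seed; the output is reproducible given the seed.
#' @param arm,endpoint labels carried on the records.
#' @return an `ipd` data frame with columns `time`, `event`, `arm`,
#'   `endpoint`.
#' @export
simulate_ipd <- function(lambda, gamma, n, censor_rate = 0, max_follow = Inf,
                         seed = 1L, arm = NA_character_,
                         endpoint = NA_character_) {
  if (lambda <= 0 || gamma <= 0) stop("invalid Weibull parameters", call. = FALSE)
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  lc <- censoring_hazard(lambda, gamma, censor_rate, max_follow)
  set.seed(seed)
  u <- stats::runif(n)
  T_ev <- (-log(u) / lambda)^(1 / gamma)
  C <- if (lc > 0) stats::rexp(n, rate = lc) else rep(Inf, n)
  C <- pmin(C, max_follow)
  time <- pmin(T_ev, C)
  event <- as.integer(T_ev <= C)
  structure(
    data.frame(time = time, event = event, arm = arm, endpoint = endpoint,
               stringsAsFactors = FALSE),
    class = c("ipd", "data.frame")
  )
}

#' Emulate figure digitization of a Kaplan-Meier curve
#'
#' Digitizers trace a published Kaplan-Meier plot by clicking at the
#' visible step corners, so the extracted time coordinates coincide with
#' (a subset of) the event times.  This emulation therefore samples the
#' exact product-limit step function of `ipd` at `n_points` coordinates
#' consisting of time zero, the end of follow-up and an even thinning of
#' the distinct event times; uniform survival jitter of the given
#' amplitude is added to the interior points (pixel noise; the time-zero
#' point is known to be 1).  Numbers at risk are tabulated at
#' `n_risk_times` evenly spaced times.
#'
#' @param ipd an `ipd` data frame.
#' @param n_points number of digitized coordinates (>= 4).
#' @param jitter uniform jitter amplitude on the survival axis (< 0.02).
#' @param seed RNG seed for the jitter.
#' @param n_risk_times number of risk-table rows (default 6).
#' @return a list with `curve` (a raw, unpreprocessed [digitized_curve])
#'   and `risk` (a [risk_table]).
#' @export
digitize_curve <- function(ipd, n_points = 120, jitter = 0, seed = 1L,
                           n_risk_times = 6) {
  if (n_points < 4) stop("`n_points` must be >= 4", call. = FALSE)
  if (jitter < 0 || jitter >= 0.02) {
    stop("`jitter` must be in [0, 0.02)", call. = FALSE)
  }
  km <- km_estimator(ipd)
  t_max <- max(ipd$time)
  ev <- sort(unique(ipd$time[ipd$event == 1]))
  if (length(ev) > 0) {
    idx <- unique(round(seq(1, length(ev),
                            length.out = min(n_points - 2, length(ev)))))
    t_grid <- sort(unique(c(0, ev[idx], t_max)))
  } else {
    t_grid <- seq(0, t_max, length.out = n_points)
  }
  s <- surv_step(km, t_grid)
  n_points <- length(t_grid)
  if (jitter > 0) {
    set.seed(seed)
    s[-1] <- s[-1] + stats::runif(n_points - 1, -jitter, jitter)
  }
  # numbers at risk on a grid strictly below t_max so the last interval
  # stays unconstrained (as in published figures, where follow-up ends
  # after the last printed risk time)
  r_grid <- seq(0, t_max, length.out = n_risk_times + 1)[seq_len(n_risk_times)]
  n_at <- vapply(r_grid, function(r) sum(ipd$time >= r), numeric(1))
  list(curve = digitized_curve(t_grid, s, arm = ipd$arm[1],
                               endpoint = ipd$endpoint[1]),
       risk = risk_table(r_grid, n_at))
}

#' Synthetic life table (Gompertz mortality)
#'
#' A stand-in for a national period life table:
#' `qx(age) = min(1, 5e-5 * exp(0.09 * age))` over ages 40 to 110 — the
#' classical Gompertz shape with parameters giving roughly 2% annual
#' mortality at age 68, typical of a general elderly population.
#'
#' @return a [life_table].
#' @export
make_life_table_fixture <- function() {
  age <- 40:110
  life_table(age, pmin(1, 5e-5 * exp(0.09 * age)))
}

# medians (months) used to calibrate the synthetic scenarios; overall
# medians are the published trial values, the PD-L1-positive ones are
# synthetic choices consistent with the reported stronger subgroup effect
# (subgroup medians were not published; AVE-arm OS was not reached).
fixture_medians <- function(population) {
  if (population == "overall") {
    list(AVE = list(PFS = 3.7, OS = 21.4), CON = list(PFS = 2.0, OS = 14.3))
  } else {
    list(AVE = list(PFS = 5.7, OS = 26.0), CON = list(PFS = 2.0, OS = 13.5))
  }
}

#' Build the complete synthetic base-case input bundle
#'
#' Generates a two-arm trial (350 subjects per arm, as in the maintenance
#' trial) with Weibull event times of shape `gamma = 1.2` (mildly
#' increasing hazard) and scales solved so the median survival matches the
#' published medians per arm and endpoint
#' (`lambda = log(2) / median^gamma`), 20% independent censoring,
#' administrative censoring at 36 months; then emulates figure
#' digitization of all four curves and bundles the synthetic life table.
#'
#' @param seed RNG seed; two calls with the same seed produce identical
#'   bundles.
#' @param population `"overall"` (published medians 3.7/2.0 PFS, 21.4/14.3
#'   OS months) or `"PD-L1-positive"` (synthetic subgroup medians).
#' @param n subjects per arm (default 350).
#' @param gamma_shape Weibull shape for all curves (default 1.2).
#' @param censor_rate target censoring fraction (default 0.2).
#' @param max_follow administrative censoring time in months (default 36).
#' @param n_points digitized coordinates per curve (default 120,
#'   typical of step-tracing curve extraction tools).
#' @param jitter digitization jitter amplitude (default 0.005).
#' @return a list of class `cea_fixture` with elements `scenario`
#'   (true parameters per arm/endpoint), `ipd`, `curves`, `risk_tables`
#'   (named `ARM_ENDPOINT`) and `life_table`.
#' @export
make_base_case_fixture <- function(seed = 1L, population = "overall",
                                   n = 350, gamma_shape = 1.2,
                                   censor_rate = 0.2, max_follow = 36,
                                   n_points = 120, jitter = 0.005) {
  med <- fixture_medians(population)
  scenario <- list()
  ipd <- list(); curves <- list(); risk_tables <- list()
  k <- 0L
  for (arm in c("AVE", "CON")) {
    for (endpoint in c("PFS", "OS")) {
      k <- k + 1L
      lam <- log(2) / med[[arm]][[endpoint]]^gamma_shape
      key <- paste(arm, endpoint, sep = "_")
      scenario[[key]] <- list(lambda = lam, gamma = gamma_shape,
                              median = med[[arm]][[endpoint]])
      dat <- simulate_ipd(lam, gamma_shape, n, censor_rate, max_follow,
                          seed = seed + 1000L * k, arm = arm,
                          endpoint = endpoint)
      dig <- digitize_curve(dat, n_points = n_points, jitter = jitter,
                            seed = seed + 1000L * k + 500L)
      ipd[[key]] <- dat
      curves[[key]] <- dig$curve
      risk_tables[[key]] <- dig$risk
    }
  }
  structure(list(scenario = scenario, ipd = ipd, curves = curves,
                 risk_tables = risk_tables,
                 life_table = make_life_table_fixture(),
                 population = population, n_per_arm = n, seed = seed),
            class = "cea_fixture")
}

#' Write a fixture bundle to disk
#'
#' Emits `curves.csv`, `risk_tables.csv`, `life_table.csv` and
#' `config.yaml` in the exact formats the pipeline readers consume.
#'
#' @param dir destination directory (created if missing).
#' @param seed RNG seed forwarded to [make_base_case_fixture()].
#' @param population passed to [make_base_case_fixture()].
#' @param country country block written into `config.yaml`.
#' @return `dir`, invisibly.
#' @export
write_fixture_bundle <- function(dir, seed = 1L, population = "overall",
                                 country = "US") {
  fx <- make_base_case_fixture(seed = seed, population = population)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  curves <- do.call(rbind, lapply(fx$curves, function(cv) {
    data.frame(time_months = cv$time, survival = cv$survival,
               arm = cv$arm, endpoint = cv$endpoint)
  }))
  utils::write.csv(curves, file.path(dir, "curves.csv"),
                   row.names = FALSE, quote = FALSE)
  risks <- do.call(rbind, lapply(names(fx$risk_tables), function(key) {
    rt <- fx$risk_tables[[key]]
    parts <- strsplit(key, "_")[[1]]
    data.frame(time_months = rt$time, n_at_risk = rt$n_at_risk,
               arm = parts[1], endpoint = parts[2])
  }))
  utils::write.csv(risks, file.path(dir, "risk_tables.csv"),
                   row.names = FALSE, quote = FALSE)
  lt <- fx$life_table
  utils::write.csv(data.frame(age = lt$age, qx = lt$qx),
                   file.path(dir, "life_table.csv"),
                   row.names = FALSE, quote = FALSE)
  cfg <- list(
    country = country, population = population,
    total_n = fx$n_per_arm, seed = seed,
    paths = list(curves = "curves.csv", risk_tables = "risk_tables.csv",
                 life_table = "life_table.csv"),
    model = list(cycle_length = 1, horizon = 120, starting_age = 68),
    sensitivity = list(n_draws = 1000, seed = seed,
                       wtp = wtp_threshold(country)),
    parameters = lapply(split(table1_parameters(country, population),
                              seq_len(nrow(table1_parameters(country, population)))),
                        as.list)
  )
  names(cfg$parameters) <- table1_parameters(country, population)$name
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}
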