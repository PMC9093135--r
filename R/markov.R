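# Three-state Markov cohort engine: per-cycle transition matrices built
# from the Weibull fits and the life table, and the cohort trace.

STATES <- c("PFS", "PD", "Death")

#' Model specification for one arm
#'
#' @param cycle_length cycle length in months (base case: 1).
#' @param horizon number of cycles (base case: 120, i.e. 10 years).
#' @param starting_age cohort age in years at model entry.  The trial does
#'   not report a cohort starting age; 68 (a typical metastatic urothelial
#'   carcinoma population) is the package default and is configurable.
#' @param arm arm label (`"AVE"` or `"CON"`).
#' @param population `"overall"` or `"PD-L1-positive"`.
#' @param country `"US"` or `"China"`.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(cycle_length = 1, horizon = 120, starting_age = 68,
                       arm = NA_character_, population = "overall",
                       country = "US") {
  if (cycle_length <= 0) stop("`cycle_length` must be > 0", call. = FALSE)
  horizon <- as.integer(horizon)
  if (is.na(horizon) || horizon < 1) stop("`horizon` must be >= 1", call. = FALSE)
  structure(list(cycle_length = cycle_length, horizon = horizon,
                 starting_age = starting_age, arm = arm,
                 population = population, country = country),
            class = "model_spec")
}

#' Build the per-cycle transition matrices
#'
#' For cycle `t` (model time `t*cl` to `(t+1)*cl` months, cohort age
#' `starting_age + t*cl/12`):
#'
#' * `p(PFS -> death)` is the age-specific background mortality from the
#'   life table;
#' * the total probability of leaving PFS is the PFS fit's conditional
#'   transition probability for the cycle, and
#'   `p(PFS -> PD) = max(0, p_exit - p_background)` (subtraction rule);
#' * `p(PD -> death)` is the OS fit's conditional transition probability,
#'   floored at background mortality;
#' * residual probability mass stays in the current state; death is
#'   absorbing and there is no PD -> PFS backflow.
#'
#' Which fitted curve feeds the PD -> death transition is a modelling
#' choice (see the methods vignette); pass a different `os_fit` to explore
#' alternatives.
#'
#' @param pfs_fit,os_fit [weibull_fit] objects for the arm's PFS and OS.
#' @param table a [life_table].
#' @param spec a [model_spec].
#' @return an object of class `transition_series`: a `horizon x 3 x 3`
#'   array of row-stochastic matrices over (PFS, PD, Death).
#' @export
build_transition_series <- function(pfs_fit, os_fit, table, spec) {
  stopifnot(inherits(spec, "model_spec"))
  H <- spec$horizon; cl <- spec$cycle_length
  a <- array(0, dim = c(H, 3, 3),
             dimnames = list(NULL, STATES, STATES))
  for (t in seq_len(H) - 1L) {
    age <- spec$starting_age + t * cl / 12
    p_bg <- monthly_background_mortality(table, age, months = cl)
    p_exit <- transition_probability(pfs_fit, t * cl, (t + 1) * cl)
    p_pfs_pd <- max(0, p_exit - p_bg)
    p_pd_death <- max(transition_probability(os_fit, t * cl, (t + 1) * cl),
                      p_bg)
    row_pfs <- c(1 - p_pfs_pd - p_bg, p_pfs_pd, p_bg)
    row_pd <- c(0, 1 - p_pd_death, p_pd_death)
    if (any(c(row_pfs, row_pd) < -1e-12) || any(c(row_pfs, row_pd) > 1 + 1e-12)) {
      stop(sprintf("transition probabilities outside [0, 1] at cycle %d", t),
           call. = FALSE)
    }
    a[t + 1L, 1, ] <- row_pfs
    a[t + 1L, 2, ] <- row_pd
    a[t + 1L, 3, ] <- c(0, 0, 1)
  }
  structure(a, class = "transition_series")
}

#' Validate a transition series
#'
#' Checks that every matrix is row-stochastic within `1e-12`, entries lie
#' in `[0, 1]`, the death row is `(0, 0, 1)` and there is no PD -> PFS
#' backflow.
#'
#' @param series a `transition_series` (or plain `H x 3 x 3` array).
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_transition_series <- function(series) {
  a <- unclass(series)
  stopifnot(length(dim(a)) == 3, dim(a)[2] == 3, dim(a)[3] == 3)
  for (t in seq_len(dim(a)[1])) {
    M <- a[t, , ]
    if (any(M < -1e-12) || any(M > 1 + 1e-12)) {
      stop(sprintf("entries outside [0, 1] at cycle %d", t - 1), call. = FALSE)
    }
    if (any(abs(rowSums(M) - 1) > 1e-12)) {
      stop(sprintf("rows do not sum to 1 at cycle %d", t - 1), call. = FALSE)
    }
    if (any(abs(M[3, ] - c(0, 0, 1)) > 0)) {
      stop(sprintf("death is not absorbing at cycle %d", t - 1), call. = FALSE)
    }
    if (M[2, 1] != 0) {
      stop(sprintf("PD -> PFS backflow at cycle %d", t - 1), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Run the cohort trace
#'
#' The whole cohort starts in PFS; occupancy is propagated by
#' `occ(t+1) = occ(t) %*% M(t)`.
#'
#' @param series a `transition_series` of length `horizon`.
#' @param spec a [model_spec]; its `horizon` must match the series.
#' @return an object of class `cohort_trace`: a `(horizon + 1) x 3` matrix
#'   of state occupancies, rows indexed by cycle start `0..horizon`.
#' @export
run_cohort <- function(series, spec = NULL) {
  a <- unclass(series)
  H <- dim(a)[1]
  if (!is.null(spec)) {
    stopifnot(inherits(spec, "model_spec"))
    if (spec$horizon != H) {
      stop(sprintf("series has %d cycles but spec$horizon is %d",
                   H, spec$horizon), call. = FALSE)
    }
  }
  trace <- matrix(0, nrow = H + 1, ncol = 3,
                  dimnames = list(NULL, STATES))
  trace[1, ] <- c(1, 0, 0)
  for (t in seq_len(H)) {
    trace[t + 1, ] <- trace[t, ] %*% a[t, , ]
  }
  structure(trace, class = c("cohort_trace", "matrix"))
}

#' Export a cohort trace or transition series as a long data frame
#'
#' @param x a `cohort_trace` or `transition_series`.
#' @return a data frame in `(cycle, state, value)` form (traces) or
#'   `(cycle, from, to, value)` form (series), suitable for CSV audit
#'   output.
#' @export
as_long_df <- function(x) {
  if (inherits(x, "cohort_trace")) {
    m <- unclass(x)
    data.frame(cycle = rep(seq_len(nrow(m)) - 1L, times = 3),
               state = rep(STATES, each = nrow(m)),
               value = as.vector(m))
  } else if (inherits(x, "transition_series")) {
    a <- unclass(x)
    H <- dim(a)[1]
    grid <- expand.grid(cycle = seq_len(H) - 1L, from = STATES, to = STATES,
                        stringsAsFactors = FALSE)
    grid$value <- as.vector(a)
    grid
  } else {
    stop("`x` must be a cohort_trace or transition_series", call. = FALSE)
  }
}
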