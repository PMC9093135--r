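# One-way deterministic sensitivity analysis with tornado ordering, and
# probabilistic sensitivity analysis with cost-effectiveness acceptability
# curves.

#' Moment-match a gamma distribution to a base value and range
#'
#' The published ranges are interpreted as 95% intervals, so
#' `SE = (high - low) / (2 * 1.96)`; then `shape = mean^2/SE^2`,
#' `rate = mean/SE^2`, which reproduces the mean and SE exactly.
#'
#' @param mean base value, > 0.
#' @param low,high range bounds, `high > low`.
#' @return named list with `shape`, `rate`, `se`.
#' @export
moment_match_gamma <- function(mean, low, high) {
  if (mean <= 0) stop("`mean` must be > 0", call. = FALSE)
  se <- (high - low) / (2 * 1.96)
  if (se <= 0) stop("range gives a non-positive SE", call. = FALSE)
  list(shape = mean^2 / se^2, rate = mean / se^2, se = se)
}

#' Moment-match a beta distribution to a base value and range
#'
#' As [moment_match_gamma()] but for utilities: the upper bound is clamped
#' to 1 before the SE is formed, and
#' `alpha = mean * (mean*(1-mean)/SE^2 - 1)`,
#' `beta = (1-mean) * (mean*(1-mean)/SE^2 - 1)`.
#'
#' @param mean base value in (0, 1).
#' @param low,high range bounds.
#' @return named list with `alpha`, `beta`, `se`.
#' @export
moment_match_beta <- function(mean, low, high) {
  if (mean <= 0 || mean >= 1) stop("`mean` must be in (0, 1)", call. = FALSE)
  se <- (min(high, 1) - low) / (2 * 1.96)
  if (se <= 0) stop("range gives a non-positive SE", call. = FALSE)
  v <- se^2
  if (v >= mean * (1 - mean)) {
    stop(sprintf("variance %.4g infeasible for a beta with mean %.3g",
                 v, mean), call. = FALSE)
  }
  k <- mean * (1 - mean) / v - 1
  list(alpha = mean * k, beta = (1 - mean) * k, se = se)
}

# one PSA draw of every non-fixed parameter (named vector)
draw_params <- function(params) {
  vals <- params$base
  for (i in seq_len(nrow(params))) {
    vals[i] <- switch(params$dist[i],
      beta = {
        mm <- moment_match_beta(params$base[i], params$low[i], params$high[i])
        stats::rbeta(1, mm$alpha, mm$beta)
      },
      gamma = {
        mm <- moment_match_gamma(params$base[i], params$low[i], params$high[i])
        stats::rgamma(1, shape = mm$shape, rate = mm$rate)
      },
      fixed = params$base[i],
      stop(sprintf("unknown distribution `%s` for parameter `%s`",
                   params$dist[i], params$name[i]), call. = FALSE))
  }
  stats::setNames(vals, params$name)
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Evaluates the model's ICER with each parameter at its low and high
#' bound, all others at base, and orders the entries by descending bar
#' width `|icer_high - icer_low|`.  When an endpoint does not yield a
#' plain ratio (dominance), the entry is flagged and the incremental net
#' monetary benefit at `wtp` is recorded in its place so nothing is
#' silently dropped; flagged entries sort by their NMB-based width.
#'
#' @param model a function taking a named vector of parameter overrides
#'   and returning an `icer_result` (see [build_cea_model()]).
#' @param params parameter data frame as from [table1_parameters()].
#' @param wtp willingness-to-pay used for the NMB fallback on dominant or
#'   dominated endpoints.
#' @return a data frame of class `tornado`, sorted by descending `width`:
#'   columns `parameter`, `low`, `high`, `icer_low`, `icer_high`, `width`,
#'   `flag`.
#' @export
one_way_dsa <- function(model, params, wtp = 150000) {
  eval_at <- function(overrides) {
    res <- model(overrides)
    list(icer = res$icer, status = res$status,
         inmb = wtp * res$delta_qalys - res$delta_cost)
  }
  rows <- lapply(seq_len(nrow(params)), function(i) {
    lo <- eval_at(stats::setNames(params$low[i], params$name[i]))
    hi <- eval_at(stats::setNames(params$high[i], params$name[i]))
    flagged <- !(lo$status %in% c("icer")) || !(hi$status %in% c("icer"))
    width <- if (!flagged) abs(hi$icer - lo$icer) else abs(hi$inmb - lo$inmb)
    data.frame(parameter = params$name[i],
               low = params$low[i], high = params$high[i],
               icer_low = lo$icer, icer_high = hi$icer,
               width = width,
               flag = if (flagged) paste(lo$status, hi$status, sep = "/")
                      else "", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$width, out$parameter), ]
  rownames(out) <- NULL
  class(out) <- c("tornado", "data.frame")
  out
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n_draws` parameter vectors (beta for utilities, gamma for costs,
#' fixed parameters at base), evaluates the model for each, and returns
#' the incremental cost and QALY pairs.  Draws whose model evaluation
#' fails (e.g. a sampled configuration violating a probability constraint)
#' are rejected and resampled; the count is recorded in the `rejections`
#' attribute.
#'
#' @param model as in [one_way_dsa()].
#' @param params parameter data frame.
#' @param n_draws number of Monte Carlo draws (published analysis: 1,000).
#' @param seed RNG seed; results are bitwise reproducible given the seed.
#' @return a data frame of class `psa_draws`: `draw`, `delta_cost`,
#'   `delta_qalys`, with attribute `rejections`.
#' @export
run_psa <- function(model, params, n_draws = 1000, seed = 1L) {
  set.seed(seed)
  dc <- numeric(n_draws); de <- numeric(n_draws)
  rejections <- 0L
  for (i in seq_len(n_draws)) {
    repeat {
      vals <- draw_params(params)
      res <- tryCatch(model(vals), error = function(e) NULL)
      if (!is.null(res)) break
      rejections <- rejections + 1L
      if (rejections > 100 * n_draws) {
        stop("PSA rejection rate implausibly high; check parameter specs",
             call. = FALSE)
      }
    }
    dc[i] <- res$delta_cost
    de[i] <- res$delta_qalys
  }
  out <- data.frame(draw = seq_len(n_draws), delta_cost = dc, delta_qalys = de)
  attr(out, "rejections") <- rejections
  class(out) <- c("psa_draws", "data.frame")
  out
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the probability that the
#' intervention is cost-effective is the fraction of PSA draws with
#' positive incremental net monetary benefit `wtp * dQALY - dCost > 0`
#' (exact ties count as not cost-effective).
#'
#' @param draws a `psa_draws` data frame (or any data frame with
#'   `delta_cost` and `delta_qalys`).
#' @param wtp_grid vector of WTP values in USD/QALY.
#' @return a data frame with columns `wtp` and `probability`.
#' @export
ceac <- function(draws, wtp_grid = default_wtp_grid()) {
  if (NROW(draws) == 0) stop("no PSA draws", call. = FALSE)
  probability <- vapply(wtp_grid, function(w) {
    mean(w * draws$delta_qalys - draws$delta_cost > 0)
  }, numeric(1))
  data.frame(wtp = wtp_grid, probability = probability)
}

#' Default willingness-to-pay grid
#'
#' 0 to 300,000 USD/QALY in steps of 5,000, always including the two
#' decision thresholds used in the analysis (150,000 US; 30,447.09 China).
#'
#' @return sorted numeric vector of WTP values.
#' @export
default_wtp_grid <- function() {
  sort(unique(c(seq(0, 300000, by = 5000),
                wtp_threshold("US"), wtp_threshold("China"))))
}
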