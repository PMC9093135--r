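# Right-censored Weibull maximum likelihood on the cumulative-hazard scale
# H(t) = lambda * t^gamma, and the per-cycle transition probability derived
# from it.

#' Construct a Weibull fit object
#'
#' Parameterization is fixed to the cumulative hazard
#' `H(t) = lambda * t^gamma` so that the per-cycle transition probability is
#' literally `1 - exp(lambda*t^gamma - lambda*(t+1)^gamma)`.  This differs
#' from the location-scale form used by [stats::dweibull()] /
#' `survival::survreg`; see [weibull_from_shape_scale()] for conversion.
#'
#' @param lambda scale of the cumulative hazard (per month^gamma), > 0.
#' @param gamma dimensionless shape, > 0; `gamma > 1` means increasing
#'   hazard.
#' @param loglik log-likelihood at `(lambda, gamma)` (NA when constructed
#'   directly).
#' @param n_obs number of observations behind the fit.
#' @param arm,endpoint optional labels.
#' @return an object of class `weibull_fit`.
#' @export
weibull_fit <- function(lambda, gamma, loglik = NA_real_, n_obs = NA_integer_,
                        arm = NA_character_, endpoint = NA_character_) {
  if (!is.finite(lambda) || lambda <= 0) stop("`lambda` must be > 0", call. = FALSE)
  if (!is.finite(gamma) || gamma <= 0) stop("`gamma` must be > 0", call. = FALSE)
  structure(list(lambda = lambda, gamma = gamma, loglik = loglik,
                 n_obs = n_obs, arm = arm, endpoint = endpoint),
            class = "weibull_fit")
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf(
    "<weibull_fit> H(t) = %.6g * t^%.4g  (median %.2f months, n = %s, logLik = %s)\n",
    x$lambda, x$gamma, median_survival(x),
    ifelse(is.na(x$n_obs), "?", x$n_obs),
    ifelse(is.na(x$loglik), "?", sprintf("%.3f", x$loglik))))
  invisible(x)
}

# log-likelihood and gradient in theta = (log lambda, log gamma)
weibull_loglik <- function(theta, time, event) {
  lambda <- exp(theta[1]); gamma <- exp(theta[2])
  lt <- log(time)
  tg <- exp(gamma * lt)                 # t^gamma
  sum(event) * (theta[1] + theta[2]) + (gamma - 1) * sum(lt[event == 1]) -
    lambda * sum(tg)
}

weibull_grad <- function(theta, time, event) {
  lambda <- exp(theta[1]); gamma <- exp(theta[2])
  lt <- log(time)
  tg <- exp(gamma * lt)
  D <- sum(event)
  c(D - lambda * sum(tg),
    D + gamma * sum(lt[event == 1]) - lambda * gamma * sum(tg * lt))
}

weibull_hessian <- function(theta, time, event) {
  lambda <- exp(theta[1]); gamma <- exp(theta[2])
  lt <- log(time)
  tg <- exp(gamma * lt)
  T0 <- sum(tg); T1 <- sum(tg * lt); T2 <- sum(tg * lt^2)
  Se <- sum(lt[event == 1])
  h_aa <- -lambda * T0
  h_ab <- -lambda * gamma * T1
  h_bb <- gamma * Se - lambda * (gamma * T1 + gamma^2 * T2)
  matrix(c(h_aa, h_ab, h_ab, h_bb), 2, 2)
}

#' Fit a Weibull survival model to right-censored IPD
#'
#' Maximizes the right-censored Weibull log-likelihood
#' `sum_events log(lambda*gamma*t^(gamma-1)) - sum_all lambda*t^gamma`
#' over `(log lambda, log gamma)` by BFGS with analytic gradients,
#' started from the exponential (`gamma = 1`) closed-form fit plus two
#' perturbed starts.
#'
#' @param ipd data frame with columns `time` (> 0) and `event` (0/1), or
#'   pass `time`/`event` vectors directly.
#' @param time,event alternative vector interface.
#' @param gamma_fixed optionally pin the shape (e.g. `gamma_fixed = 1` for
#'   the exponential submodel, whose MLE is events / total follow-up).
#' @return a [weibull_fit] with the MLE, its log-likelihood and `n_obs`.
#' @export
fit_weibull <- function(ipd = NULL, time = NULL, event = NULL,
                        gamma_fixed = NULL) {
  if (!is.null(ipd)) {
    time <- as.numeric(ipd$time); event <- as.integer(ipd$event)
    arm <- if (!is.null(ipd$arm)) as.character(ipd$arm[1]) else NA_character_
    endpoint <- if (!is.null(ipd$endpoint)) as.character(ipd$endpoint[1]) else NA_character_
  } else {
    event <- as.integer(event)
    arm <- NA_character_; endpoint <- NA_character_
  }
  if (length(time) < 2) stop("need at least two records", call. = FALSE)
  if (any(time <= 0) || any(!is.finite(time))) {
    stop("all times must be finite and > 0", call. = FALSE)
  }
  D <- sum(event)
  if (D < 1) {
    stop("no events: Weibull parameters are not identifiable", call. = FALSE)
  }
  lambda_exp <- D / sum(time)           # exponential MLE
  if (!is.null(gamma_fixed)) {
    gamma <- gamma_fixed
    lambda <- D / sum(time^gamma)       # profile MLE for fixed gamma
    ll <- weibull_loglik(log(c(lambda, gamma)), time, event)
    return(weibull_fit(lambda, gamma, loglik = ll, n_obs = length(time),
                       arm = arm, endpoint = endpoint))
  }
  starts <- list(c(log(lambda_exp), 0),
                 c(log(lambda_exp), log(1.5)),
                 c(log(lambda_exp), log(0.7)))
  best <- NULL
  for (th0 in starts) {
    opt <- tryCatch(
      stats::optim(th0, fn = weibull_loglik, gr = weibull_grad,
                   time = time, event = event, method = "BFGS",
                   control = list(fnscale = -1, maxit = 500, reltol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value > best$value)) best <- opt
  }
  if (is.null(best)) stop("Weibull fit failed to converge", call. = FALSE)
  # Newton polish with the analytic Hessian: quadratic convergence to a
  # machine-precision stationary point
  th <- best$par
  ll <- best$value
  for (i in 1:100) {
    g <- weibull_grad(th, time, event)
    if (sqrt(sum(g^2)) <= 1e-10) break
    step <- tryCatch(solve(weibull_hessian(th, time, event), g),
                     error = function(e) NULL)
    if (is.null(step)) break
    th_new <- th - step
    ll_new <- weibull_loglik(th_new, time, event)
    # fall back to damped steps if the full Newton step overshoots
    damp <- 1
    while (!is.finite(ll_new) || ll_new < ll - 1e-9) {
      damp <- damp / 2
      if (damp < 1e-6) break
      th_new <- th - damp * step
      ll_new <- weibull_loglik(th_new, time, event)
    }
    if (!is.finite(ll_new) || max(abs(th_new - th)) < 1e-15) break
    th <- th_new; ll <- ll_new
  }
  best <- list(par = th, value = ll)
  g <- weibull_grad(th, time, event)
  if (sqrt(sum(g^2)) > 1e-6) {
    stop(sprintf("Weibull fit did not converge: |grad| = %.3g at lambda = %.4g, gamma = %.4g",
                 sqrt(sum(g^2)), exp(th[1]), exp(th[2])), call. = FALSE)
  }
  ll_exp <- weibull_loglik(log(c(lambda_exp, 1)), time, event)
  if (best$value < ll_exp - 1e-8) {
    stop("Weibull fit converged below the exponential submodel; optimisation failed",
         call. = FALSE)
  }
  weibull_fit(exp(th[1]), exp(th[2]), loglik = best$value,
              n_obs = length(time), arm = arm, endpoint = endpoint)
}

#' Survivor function of a Weibull fit
#'
#' @param fit a [weibull_fit].
#' @param t time in months, >= 0 (vectorized).
#' @return `exp(-lambda * t^gamma)`.
#' @export
survival_at <- function(fit, t) {
  stopifnot(inherits(fit, "weibull_fit"))
  if (any(t < 0)) stop("`t` must be >= 0", call. = FALSE)
  exp(-fit$lambda * t^fit$gamma)
}

#' Per-cycle conditional transition probability
#'
#' The probability of the event occurring in `(cycle_start, cycle_end]`
#' given survival to `cycle_start`:
#' `1 - exp(lambda * cycle_start^gamma - lambda * cycle_end^gamma)`,
#' identical to `1 - S(cycle_end)/S(cycle_start)`.
#'
#' @param fit a [weibull_fit].
#' @param cycle_start,cycle_end interval bounds in months,
#'   `0 <= cycle_start < cycle_end` (vectorized).
#' @return a probability in `[0, 1)`.
#' @export
transition_probability <- function(fit, cycle_start, cycle_end) {
  stopifnot(inherits(fit, "weibull_fit"))
  if (any(cycle_start < 0) || any(cycle_end <= cycle_start)) {
    stop("need 0 <= cycle_start < cycle_end", call. = FALSE)
  }
  1 - exp(fit$lambda * cycle_start^fit$gamma - fit$lambda * cycle_end^fit$gamma)
}

#' Median survival time of a Weibull fit
#'
#' @param fit a [weibull_fit].
#' @return `(ln 2 / lambda)^(1/gamma)` in months.
#' @export
median_survival <- function(fit) {
  stopifnot(inherits(fit, "weibull_fit"))
  (log(2) / fit$lambda)^(1 / fit$gamma)
}

#' Convert between cumulative-hazard and shape/scale parameterizations
#'
#' Survival packages usually parameterize the Weibull as
#' `S(t) = exp(-(t/scale)^shape)`.  The correspondence with
#' `H(t) = lambda * t^gamma` is `gamma = shape`,
#' `lambda = scale^(-shape)`.
#'
#' @param shape,scale location-scale Weibull parameters.
#' @return [weibull_from_shape_scale()]: a [weibull_fit];
#'   [weibull_to_shape_scale()]: a named list with `shape` and `scale`.
#' @export
weibull_from_shape_scale <- function(shape, scale) {
  weibull_fit(lambda = scale^(-shape), gamma = shape)
}

#' @rdname weibull_from_shape_scale
#' @param fit a [weibull_fit].
#' @export
weibull_to_shape_scale <- function(fit) {
  stopifnot(inherits(fit, "weibull_fit"))
  list(shape = fit$gamma, scale = fit$lambda^(-1 / fit$gamma))
}

#' Serialize Weibull fits to JSON
#'
#' @param fits a list of [weibull_fit] objects.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_fits_json <- function(fits, path) {
  payload <- lapply(fits, function(f) {
    list(endpoint = f$endpoint, arm = f$arm, lambda = f$lambda,
         gamma = f$gamma, loglik = f$loglik, n = f$n_obs)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
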