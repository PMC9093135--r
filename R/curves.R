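# Digitized Kaplan-Meier curves, numbers-at-risk tables, and deterministic
# Guyot-style pseudo-IPD reconstruction.

#' Construct a digitized survival curve
#'
#' Holds ordered `(time, survival)` coordinates read off a published
#' Kaplan-Meier plot for one endpoint (PFS or OS) and one trial arm.
#' Use [preprocess_curve()] to clean raw digitizer output before
#' reconstruction.
#'
#' @param time times in months, non-negative.
#' @param survival survival probabilities in `[0, 1]`.
#' @param arm arm label (e.g. `"AVE"`, `"CON"`).
#' @param endpoint endpoint label (`"PFS"` or `"OS"`).
#' @return an object of class `digitized_curve` with fields `time`,
#'   `survival`, `arm`, `endpoint`.
#' @export
digitized_curve <- function(time, survival, arm = NA_character_,
                            endpoint = NA_character_) {
  time <- as.numeric(time)
  survival <- as.numeric(survival)
  if (length(time) != length(survival)) {
    stop("`time` and `survival` must have the same length", call. = FALSE)
  }
  if (length(time) == 0) stop("curve has no points", call. = FALSE)
  if (any(!is.finite(time)) || any(time < 0)) {
    stop("curve times must be finite and >= 0", call. = FALSE)
  }
  structure(
    list(time = time, survival = survival,
         arm = as.character(arm), endpoint = as.character(endpoint)),
    class = "digitized_curve"
  )
}

#' @export
print.digitized_curve <- function(x, ...) {
  cat(sprintf("<digitized_curve> %s / %s: %d points over [%g, %g] months\n",
              x$arm, x$endpoint, length(x$time), min(x$time), max(x$time)))
  invisible(x)
}

#' Clean raw digitized Kaplan-Meier coordinates
#'
#' Digitizer output carries pixel noise: points can be slightly out of
#' order, exceed 1 or dip below 0, or tick upward where the true curve is
#' flat.  This normalises the coordinates into a valid survival step
#' function:
#' points are sorted by time, survival is clamped to `[0, 1]`, duplicate
#' times are collapsed to their lowest survival, `(0, 1)` is prepended when
#' no time-zero point exists, and monotonicity is enforced by a running
#' minimum.
#'
#' @param points a 2-column matrix or data frame of `(time, survival)`, or a
#'   `digitized_curve`.
#' @param arm,endpoint labels attached to the result (defaults taken from
#'   `points` when it is already a `digitized_curve`).
#' @return a `digitized_curve` whose points satisfy: strictly increasing
#'   times, survival in `[0, 1]` and non-increasing, first point `(0, 1)`
#'   unless a clamped time-zero point was supplied.
#' @examples
#' preprocess_curve(rbind(c(0, 1), c(3, 0.8), c(2, 0.9)))
#' @export
preprocess_curve <- function(points, arm = NULL, endpoint = NULL) {
  if (inherits(points, "digitized_curve")) {
    if (is.null(arm)) arm <- points$arm
    if (is.null(endpoint)) endpoint <- points$endpoint
    points <- cbind(points$time, points$survival)
  }
  points <- as.matrix(points)
  if (nrow(points) < 2) {
    stop("need at least two digitized points", call. = FALSE)
  }
  if (is.null(arm)) arm <- NA_character_
  if (is.null(endpoint)) endpoint <- NA_character_
  tm <- as.numeric(points[, 1])
  sv <- as.numeric(points[, 2])
  if (any(!is.finite(tm)) || any(tm < 0)) {
    stop("digitized times must be finite and >= 0", call. = FALSE)
  }
  sv <- pmin(1, pmax(0, sv))
  ord <- order(tm, sv)       # ties: lower survival first
  tm <- tm[ord]; sv <- sv[ord]
  # collapse duplicate times to the lower survival
  keep <- !duplicated(tm)
  tm <- tm[keep]; sv <- sv[keep]
  if (tm[1] > 0) {
    tm <- c(0, tm)
    sv <- c(1, sv)
  }
  sv <- cummin(sv)
  digitized_curve(tm, sv, arm = arm, endpoint = endpoint)
}

#' Construct a numbers-at-risk table
#'
#' @param time times in months at which numbers at risk are printed under
#'   the published plot; strictly increasing, first entry usually 0.
#' @param n_at_risk non-negative, non-increasing integers; the first entry
#'   is the arm size at time zero.
#' @return an object of class `risk_table`.
#' @export
risk_table <- function(time, n_at_risk) {
  time <- as.numeric(time)
  n_at_risk <- as.numeric(n_at_risk)
  if (length(time) != length(n_at_risk) || length(time) == 0) {
    stop("`time` and `n_at_risk` must be non-empty and of equal length",
         call. = FALSE)
  }
  if (is.unsorted(time, strictly = TRUE)) {
    stop("risk-table times must be strictly increasing", call. = FALSE)
  }
  if (any(n_at_risk < 0) || any(n_at_risk != round(n_at_risk))) {
    stop("`n_at_risk` must be non-negative integers", call. = FALSE)
  }
  if (is.unsorted(rev(n_at_risk))) {
    stop("`n_at_risk` must be non-increasing", call. = FALSE)
  }
  structure(list(time = time, n_at_risk = as.integer(n_at_risk)),
            class = "risk_table")
}

# Apportion a fractional vector to integers summing to `total`
# (largest-remainder method; deterministic, ties broken by position).
largest_remainder <- function(x, total) {
  x <- pmax(0, x)
  base <- floor(x)
  rem <- as.integer(round(total - sum(base)))
  if (rem > 0) {
    frac <- x - base
    take <- order(frac, decreasing = TRUE)[seq_len(min(rem, length(x)))]
    base[take] <- base[take] + 1
    rem <- rem - length(take)
    while (rem > 0) {            # total exceeds sum(ceiling(x)): spread evenly
      k <- min(rem, length(x))
      base[seq_len(k)] <- base[seq_len(k)] + 1
      rem <- rem - k
    }
  } else if (rem < 0) {
    # round() of the total fell below sum(floor); trim from smallest fractions
    frac <- x - base
    for (i in order(frac)) {
      if (rem == 0) break
      drop <- min(base[i], -rem)
      base[i] <- base[i] - drop
      rem <- rem + drop
    }
  }
  as.integer(base)
}

# Solve one inter-risk-table interval (L, R]: choose censoring count and
# per-drop event counts so the product-limit estimate of the output tracks
# the digitized curve while matching the number at risk at R.
# `n_end = NA` means unconstrained (no interval censoring assumed).
solve_interval <- function(L, R, n_avail, n_end, drop_t, drop_s, S_enter) {
  m <- length(drop_t)
  if (!is.na(n_end) && n_end > n_avail) {
    stop(sprintf(
      "reconstruction infeasible in interval (%g, %g]: %d at risk entering but %d required at exit",
      L, R, n_avail, n_end), call. = FALSE)
  }
  frac_pass <- function(c_hat) {
    cens_t <- if (c_hat > 0) L + seq_len(c_hat) * (R - L) / (c_hat + 1) else numeric(0)
    n <- n_avail; S <- S_enter; ci <- 1L
    d_frac <- numeric(m)
    for (k in seq_len(m)) {
      while (ci <= c_hat && cens_t[ci] < drop_t[k]) {
        n <- n - 1; ci <- ci + 1L
      }
      dk <- if (S <= 0 || n <= 0) 0 else n * (1 - drop_s[k] / S)
      dk <- max(0, min(dk, n))
      d_frac[k] <- dk
      if (n > 0) S <- S * (1 - dk / n)
      n <- n - dk
    }
    d_frac
  }
  c_hat <- 0L
  d_frac <- frac_pass(c_hat)
  D <- as.integer(round(sum(d_frac)))
  if (!is.na(n_end)) {
    seen <- integer(0)
    repeat {
      c_new <- max(0L, as.integer(n_avail - n_end) - D)
      if (c_new == c_hat || c_new %in% seen) break
      seen <- c(seen, c_hat)
      c_hat <- c_new
      d_frac <- frac_pass(c_hat)
      D <- as.integer(round(sum(d_frac)))
    }
    if (D > n_avail) {
      stop(sprintf(
        "reconstruction infeasible in interval (%g, %g]: curve implies %d events but only %d at risk",
        L, R, D, n_avail), call. = FALSE)
    }
    # curve implies more exits than the risk table allows: cap events
    D <- min(D, as.integer(n_avail - n_end) - c_hat)
    D <- max(D, 0L)
    c_hat <- as.integer(n_avail - n_end) - D
  } else if (D > n_avail) {
    D <- n_avail
  }
  d_int <- largest_remainder(d_frac, D)
  cens_t <- if (c_hat > 0) L + seq_len(c_hat) * (R - L) / (c_hat + 1) else numeric(0)
  # integer walk: enforce d <= n at risk, update the running KM level
  n <- n_avail; S <- S_enter; ci <- 1L
  carry <- 0L
  for (k in seq_len(m)) {
    while (ci <= c_hat && cens_t[ci] < drop_t[k]) {
      n <- n - 1L; ci <- ci + 1L
    }
    d_int[k] <- d_int[k] + carry
    carry <- 0L
    if (d_int[k] > n) {
      carry <- d_int[k] - n
      d_int[k] <- n
    }
    if (n > 0 && d_int[k] > 0) S <- S * (1 - d_int[k] / n)
    n <- n - d_int[k]
  }
  list(events_t = drop_t, events_d = d_int, censor_t = cens_t,
       S_exit = S, n_exit = as.integer(n_avail - sum(d_int) - c_hat))
}

#' Reconstruct pseudo individual patient data from a digitized curve
#'
#' Deterministic variant of the Guyot reconstruction algorithm.  Within
#' each interval between consecutive risk-table times, the number censored
#' is estimated from the drop in the number at risk not explained by
#' curve-implied events, censoring times are placed on a uniform grid over
#' the interval, and events are assigned at the curve's drop times with
#' non-integer implied counts resolved by largest-remainder rounding.  The
#' result has exactly `total_n` records and its product-limit estimate
#' tracks the input curve.
#'
#' Without a risk table, no censoring is assumed before the last observed
#' time and all survivors are censored at the final coordinate.
#'
#' @param curve a preprocessed [digitized_curve].
#' @param risk_tab optional [risk_table] for the same arm/endpoint.
#' @param total_n total arm size (>= first risk-table entry).
#' @return a data frame of class `ipd` with columns `time` (months, > 0),
#'   `event` (1 = event, 0 = censored), `arm`, `endpoint`.
#' @references Guyot P, Ades AE, Ouwens MJ, Welton NJ. Enhanced secondary
#'   analysis of survival data: reconstructing the data from published
#'   Kaplan-Meier survival curves. BMC Med Res Methodol. 2012;12:9.
#' @export
reconstruct_ipd <- function(curve, risk_tab = NULL, total_n) {
  stopifnot(inherits(curve, "digitized_curve"))
  total_n <- as.integer(total_n)
  if (is.na(total_n) || total_n < 1) {
    stop("`total_n` must be a positive integer", call. = FALSE)
  }
  tm <- curve$time; sv <- curve$survival
  if (tm[1] != 0 || sv[1] != 1 || is.unsorted(tm, strictly = TRUE) ||
      is.unsorted(rev(sv))) {
    stop("curve must be preprocessed (see `preprocess_curve()`)", call. = FALSE)
  }
  t_last <- tm[length(tm)]
  if (!is.null(risk_tab)) {
    stopifnot(inherits(risk_tab, "risk_table"))
    if (risk_tab$n_at_risk[1] > total_n) {
      stop("first risk-table entry exceeds `total_n`", call. = FALSE)
    }
    bounds <- risk_tab$time
    n_at <- risk_tab$n_at_risk
    if (bounds[1] != 0) {
      bounds <- c(0, bounds)
      n_at <- c(total_n, n_at)
    }
    ends <- c(bounds[-1], if (t_last > bounds[length(bounds)]) t_last else NULL)
    n_targets <- c(n_at[-1], if (t_last > bounds[length(bounds)]) NA else NULL)
    starts <- bounds[seq_along(ends)]
  } else {
    starts <- 0; ends <- t_last; n_targets <- NA
  }

  events_t <- numeric(0); events_d <- integer(0); censor_t <- numeric(0)
  n_cur <- total_n
  S_run <- 1
  for (j in seq_along(ends)) {
    L <- starts[j]; R <- ends[j]
    in_int <- which(tm > L & tm <= R)
    sol <- solve_interval(L, R, n_cur, n_targets[j],
                          tm[in_int], sv[in_int], S_run)
    events_t <- c(events_t, sol$events_t)
    events_d <- c(events_d, sol$events_d)
    censor_t <- c(censor_t, sol$censor_t)
    S_run <- sol$S_exit
    n_cur <- sol$n_exit
  }
  out_t <- c(rep(events_t, events_d), censor_t, rep(t_last, n_cur))
  out_e <- c(rep(1L, sum(events_d)), rep(0L, length(censor_t) + n_cur))
  ord <- order(out_t, -out_e)
  structure(
    data.frame(time = out_t[ord], event = out_e[ord],
               arm = curve$arm, endpoint = curve$endpoint,
               stringsAsFactors = FALSE),
    class = c("ipd", "data.frame")
  )
}

#' Product-limit (Kaplan-Meier) estimator
#'
#' Standard product-limit estimate used to validate round-trips through
#' [reconstruct_ipd()]: the returned step function is sampled at the
#' distinct event times, with `S(0) = 1`.
#'
#' @param ipd a data frame with columns `time` (> 0) and `event` (0/1),
#'   e.g. the output of [reconstruct_ipd()] or [simulate_ipd()].
#' @return a [digitized_curve] with one point at time 0 and one per
#'   distinct event time.
#' @export
km_estimator <- function(ipd) {
  if (NROW(ipd) == 0) stop("`ipd` is empty", call. = FALSE)
  time <- as.numeric(ipd$time); event <- as.integer(ipd$event)
  if (any(time <= 0) || any(!event %in% c(0L, 1L))) {
    stop("`ipd` must have times > 0 and event in {0, 1}", call. = FALSE)
  }
  ev_times <- sort(unique(time[event == 1L]))
  S <- 1
  surv <- numeric(length(ev_times))
  for (k in seq_along(ev_times)) {
    tk <- ev_times[k]
    n_k <- sum(time >= tk)          # censored at tk still at risk at tk
    d_k <- sum(time == tk & event == 1L)
    S <- S * (1 - d_k / n_k)
    surv[k] <- S
  }
  curve <- digitized_curve(c(0, ev_times), c(1, surv),
                           arm = if (!is.null(ipd$arm)) ipd$arm[1] else NA,
                           endpoint = if (!is.null(ipd$endpoint)) ipd$endpoint[1] else NA)
  attr(curve, "max_time") <- max(time)
  curve
}

#' Evaluate a survival curve as a right-continuous step function
#'
#' @param curve a [digitized_curve] (assumed sorted by time).
#' @param t times at which to evaluate; values before the first point give 1.
#' @return survival probabilities at `t`.
#' @export
surv_step <- function(curve, t) {
  idx <- findInterval(t, curve$time)
  ifelse(idx == 0, 1, curve$survival[pmax(idx, 1)])
}

#' Sup-norm distance between two survival step functions
#'
#' @param a,b `digitized_curve` objects.
#' @param at times at which to compare; defaults to the union of both
#'   curves' jump times.
#' @return the maximum absolute difference.
#' @export
curve_supnorm <- function(a, b, at = NULL) {
  if (is.null(at)) at <- sort(unique(c(a$time, b$time)))
  max(abs(surv_step(a, at) - surv_step(b, at)))
}

# ---- CSV interfaces ----------------------------------------------------

#' Read digitized curves from CSV
#'
#' Expected columns: `time_months`, `survival`, `arm`, `endpoint`.  One
#' curve is returned per `arm` x `endpoint` combination, already passed
#' through [preprocess_curve()].
#'
#' @param path CSV file path.
#' @return a named list of `digitized_curve` objects, names `ARM_ENDPOINT`.
#' @export
read_curves_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  req <- c("time_months", "survival", "arm", "endpoint")
  if (!all(req %in% names(df))) {
    stop("curve CSV must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  out <- list()
  for (key in unique(paste(df$arm, df$endpoint, sep = "_"))) {
    sub <- df[paste(df$arm, df$endpoint, sep = "_") == key, ]
    out[[key]] <- preprocess_curve(cbind(sub$time_months, sub$survival),
                                   arm = sub$arm[1], endpoint = sub$endpoint[1])
  }
  out
}

#' Read numbers-at-risk tables from CSV
#'
#' Expected columns: `time_months`, `n_at_risk`, `arm`, `endpoint`.
#'
#' @param path CSV file path.
#' @return a named list of `risk_table` objects, names `ARM_ENDPOINT`.
#' @export
read_risk_tables_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  req <- c("time_months", "n_at_risk", "arm", "endpoint")
  if (!all(req %in% names(df))) {
    stop("risk-table CSV must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  out <- list()
  for (key in unique(paste(df$arm, df$endpoint, sep = "_"))) {
    sub <- df[paste(df$arm, df$endpoint, sep = "_") == key, ]
    sub <- sub[order(sub$time_months), ]
    out[[key]] <- risk_table(sub$time_months, sub$n_at_risk)
  }
  out
}

#' Write reconstructed IPD to CSV
#'
#' Columns written: `time_months`, `event`, `arm`, `endpoint`.
#'
#' @param ipd an `ipd` data frame.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_ipd_csv <- function(ipd, path) {
  out <- data.frame(time_months = ipd$time, event = ipd$event,
                    arm = ipd$arm, endpoint = ipd$endpoint)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
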