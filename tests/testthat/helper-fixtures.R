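# Small deterministic fixtures and independent oracles shared across tests.

# a 6-record toy dataset with a mix of events and censorings
toy_ipd <- function() {
  data.frame(time = c(1.2, 2.5, 3.1, 4.8, 6.0, 7.5),
             event = c(1L, 1L, 0L, 1L, 1L, 0L))
}

# independent product-limit oracle via the survival package
survfit_curve <- function(ipd) {
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = ipd)
  digitized_curve(c(0, sf$time[sf$n.event > 0]),
                  c(1, sf$surv[sf$n.event > 0]))
}

# brute-force grid maximiser of the right-censored Weibull log-likelihood,
# independent of the package's optimiser: repeated 61x61 grid refinement
grid_weibull <- function(time, event, n_refine = 6) {
  ll <- function(lambda, gamma) {
    sum(event) * (log(lambda) + log(gamma)) +
      (gamma - 1) * sum(log(time)[event == 1]) - lambda * sum(time^gamma)
  }
  lam_rng <- c(1e-4, 2); gam_rng <- c(0.1, 6)
  for (r in seq_len(n_refine)) {
    lam <- exp(seq(log(lam_rng[1]), log(lam_rng[2]), length.out = 61))
    gam <- exp(seq(log(gam_rng[1]), log(gam_rng[2]), length.out = 61))
    vals <- outer(lam, gam, Vectorize(ll))
    ix <- which(vals == max(vals), arr.ind = TRUE)[1, ]
    i <- ix[1]; j <- ix[2]
    lam_rng <- lam[c(max(1, i - 1), min(61, i + 1))]
    gam_rng <- gam[c(max(1, j - 1), min(61, j + 1))]
  }
  c(lambda = lam[i], gamma = gam[j])
}

# a random valid transition series (death absorbing, no PD->PFS backflow)
random_transition_series <- function(H) {
  a <- array(0, dim = c(H, 3, 3), dimnames = list(NULL, NULL, NULL))
  for (t in seq_len(H)) {
    p1 <- runif(1, 0, 0.4); p2 <- runif(1, 0, 0.1)
    q1 <- runif(1, 0, 0.5)
    a[t, 1, ] <- c(1 - p1 - p2, p1, p2)
    a[t, 2, ] <- c(0, 1 - q1, q1)
    a[t, 3, ] <- c(0, 0, 1)
  }
  structure(a, class = "transition_series")
}

# a trace that stays fully in PFS for H cycles
all_pfs_trace <- function(H) {
  m <- matrix(rep(c(1, 0, 0), each = H + 1), ncol = 3,
              dimnames = list(NULL, c("PFS", "PD", "Death")))
  structure(m, class = c("cohort_trace", "matrix"))
}

# inputs list with every schedule item zeroed except named overrides
zero_inputs <- function(...) {
  base <- list(utility_pfs = 0, utility_pd = 0, cost_pdl1_test = 0,
               cost_pretreatment = 0, cost_ae_con = 0, cost_ae_ave = 0,
               cost_imaging = 0, cost_pd_monthly = 0, cost_drug_monthly = 0,
               cost_bsc_ave_monthly = 0, cost_bsc_con_monthly = 0,
               discount_rate = 0)
  ov <- list(...)
  base[names(ov)] <- ov
  base
}
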