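# Configuration and scenario drivers tying the stages together across the
# four analysis scenarios (US/China x overall/PD-L1-positive).

#' Read / write a run configuration
#'
#' The configuration mirrors the model's input table: file paths (or a
#' fixture directory), country, population, model settings and the
#' sensitivity block.  YAML is the native format; JSON is accepted.
#'
#' @param path configuration file.
#' @return a named list.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$country) || is.null(cfg$population)) {
    stop("config must set `country` and `population`", call. = FALSE)
  }
  cfg
}

#' @rdname read_run_config
#' @param cfg configuration list.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Reconstruct IPD for every curve in a bundle
#'
#' Runs [preprocess_curve()] and [reconstruct_ipd()] over all
#' arm/endpoint curves and reports round-trip fidelity (sup-norm between
#' each input curve and the product-limit estimate of its reconstruction).
#' When a curve has no risk table, reconstruction falls back to the
#' no-censoring assumption with a warning.
#'
#' @param curves named list of `digitized_curve` objects
#'   (`ARM_ENDPOINT`), raw or preprocessed.
#' @param risk_tables named list of `risk_table` objects with matching
#'   names (entries may be missing).
#' @param total_n subjects per arm.
#' @param out_dir optional directory: reconstructed IPD CSVs and a
#'   fidelity report are written there.
#' @return a list with `ipd` (named list) and `fidelity` (data frame:
#'   `curve`, `supnorm`).
#' @export
cea_reconstruct <- function(curves, risk_tables = list(), total_n,
                            out_dir = NULL) {
  ipd <- list()
  fid <- data.frame(curve = character(0), supnorm = numeric(0))
  for (key in names(curves)) {
    cv <- preprocess_curve(curves[[key]])
    rt <- risk_tables[[key]]
    if (is.null(rt)) {
      warning(sprintf("no risk table for %s: assuming no censoring before last follow-up", key),
              call. = FALSE)
    }
    rec <- reconstruct_ipd(cv, rt, total_n)
    sn <- curve_supnorm(cv, km_estimator(rec), at = cv$time)
    ipd[[key]] <- rec
    fid <- rbind(fid, data.frame(curve = key, supnorm = sn))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (key in names(ipd)) {
      write_ipd_csv(ipd[[key]], file.path(out_dir, paste0("ipd_", key, ".csv")))
    }
    utils::write.csv(fid, file.path(out_dir, "reconstruction_fidelity.csv"),
                     row.names = FALSE)
  }
  list(ipd = ipd, fidelity = fid)
}

#' Fit Weibull models to every reconstructed curve
#'
#' @param ipd named list of `ipd` data frames (`ARM_ENDPOINT`).
#' @return named list of [weibull_fit] objects.
#' @export
fit_all <- function(ipd) {
  lapply(ipd, fit_weibull)
}

#' Build the cost-effectiveness model closure for one scenario
#'
#' Precomputes the two arms' cohort traces (which depend only on the
#' survival fits and the life table, not on the economic parameters) and
#' returns a function mapping a named vector of economic parameter
#' overrides to an `icer_result`.  This closure is what the DSA and PSA
#' machinery evaluate.
#'
#' @param fits named list of [weibull_fit]s (`AVE_PFS`, `AVE_OS`,
#'   `CON_PFS`, `CON_OS`).
#' @param table a [life_table].
#' @param country,population scenario selectors.
#' @param schedule a `cost_schedule` (default [default_cost_schedule()]).
#' @param cycle_length,horizon,starting_age model settings (defaults: 1
#'   month, 120 cycles, age 68).
#' @return a function `f(overrides = NULL) -> icer_result`, with
#'   attributes `params` (the scenario's [table1_parameters()]),
#'   `traces`, `specs` and `arm_results(overrides)` accessible via
#'   `attr(f, "arm_results")`.
#' @export
build_cea_model <- function(fits, table, country = "US",
                            population = "overall",
                            schedule = default_cost_schedule(),
                            cycle_length = 1, horizon = 120,
                            starting_age = 68) {
  params <- table1_parameters(country, population)
  base <- stats::setNames(params$base, params$name)
  specs <- list(); traces <- list()
  for (arm in c("AVE", "CON")) {
    sp <- model_spec(cycle_length = cycle_length, horizon = horizon,
                     starting_age = starting_age, arm = arm,
                     population = population, country = country)
    series <- build_transition_series(fits[[paste0(arm, "_PFS")]],
                                      fits[[paste0(arm, "_OS")]],
                                      table, sp)
    specs[[arm]] <- sp
    traces[[arm]] <- run_cohort(series, sp)
  }
  arm_results <- function(overrides = NULL) {
    vals <- base
    if (!is.null(overrides)) {
      unknown <- setdiff(names(overrides), names(vals))
      if (length(unknown)) {
        stop("unknown parameter override(s): ", paste(unknown, collapse = ", "),
             call. = FALSE)
      }
      vals[names(overrides)] <- overrides
    }
    inputs <- as.list(vals)
    list(ave = accrue(traces$AVE, inputs, schedule, specs$AVE),
         con = accrue(traces$CON, inputs, schedule, specs$CON))
  }
  model <- function(overrides = NULL) {
    res <- arm_results(overrides)
    icer(res$ave, res$con)
  }
  attr(model, "params") <- params
  attr(model, "traces") <- traces
  attr(model, "specs") <- specs
  attr(model, "arm_results") <- arm_results
  model
}

#' Run the base case for one scenario
#'
#' @param model a closure from [build_cea_model()].
#' @return a list with per-arm results, the `icer_result`, the country
#'   WTP, incremental net monetary benefit at that WTP, and a
#'   cost-effectiveness verdict.
#' @export
run_base_case <- function(model) {
  res <- attr(model, "arm_results")()
  ic <- icer(res$ave, res$con)
  country <- attr(model, "specs")$AVE$country
  wtp <- wtp_threshold(country)
  inmb <- net_monetary_benefit(res$ave, wtp) - net_monetary_benefit(res$con, wtp)
  verdict <- if (ic$status == "dominant") {
    "cost-effective (dominant)"
  } else if (ic$status == "icer" && ic$icer < wtp) {
    "cost-effective"
  } else {
    "not cost-effective"
  }
  list(ave = res$ave, con = res$con, icer = ic, wtp = wtp,
       inmb = inmb, verdict = verdict)
}

#' Run DSA for one scenario
#'
#' @param model a closure from [build_cea_model()].
#' @return a `tornado` data frame (see [one_way_dsa()]).
#' @export
run_dsa <- function(model) {
  country <- attr(model, "specs")$AVE$country
  one_way_dsa(model, attr(model, "params"), wtp = wtp_threshold(country))
}

#' Run PSA and CEAC for one scenario
#'
#' @param model a closure from [build_cea_model()].
#' @param n_draws Monte Carlo draws (default 1000).
#' @param seed RNG seed.
#' @param wtp_grid WTP grid for the CEAC.
#' @return a list with `draws` (a `psa_draws`), `ceac`, and
#'   `prob_ce_at_wtp` — the acceptability at the country threshold.
#' @export
run_psa_scenario <- function(model, n_draws = 1000, seed = 1L,
                             wtp_grid = default_wtp_grid()) {
  draws <- run_psa(model, attr(model, "params"), n_draws = n_draws,
                   seed = seed)
  cc <- ceac(draws, wtp_grid)
  country <- attr(model, "specs")$AVE$country
  wtp <- wtp_threshold(country)
  list(draws = draws, ceac = cc,
       prob_ce_at_wtp = cc$probability[match(wtp, cc$wtp)])
}

#' Run the full four-scenario batch on the synthetic base case
#'
#' For each population, generates the synthetic bundle, reconstructs IPD
#' from the digitized curves, fits the Weibull models, and evaluates the
#' base case (plus optionally DSA and PSA) for both countries.
#'
#' @param seed master RNG seed; sub-seeds are derived from it.
#' @param n_draws PSA draws per scenario (0 skips the PSA).
#' @param dsa also run the tornado analysis.
#' @param out_dir optional directory for CSV/JSON outputs; every file
#'   carries a header with the seed for audit.
#' @return a named list of scenario results (`US_overall`,
#'   `US_PD-L1-positive`, `China_overall`, `China_PD-L1-positive`), each
#'   with `base`, and optionally `dsa`, `psa`; plus `fidelity` and `fits`
#'   per population.
#' @export
run_scenarios <- function(seed = 1L, n_draws = 1000, dsa = TRUE,
                          out_dir = NULL) {
  out <- list()
  for (population in c("overall", "PD-L1-positive")) {
    fx <- make_base_case_fixture(seed = seed, population = population)
    rec <- cea_reconstruct(fx$curves, fx$risk_tables, total_n = fx$n_per_arm)
    fits <- fit_all(rec$ipd)
    for (country in c("US", "China")) {
      key <- paste(country, population, sep = "_")
      model <- build_cea_model(fits, fx$life_table, country = country,
                               population = population)
      res <- list(base = run_base_case(model))
      if (dsa) res$dsa <- run_dsa(model)
      if (n_draws > 0) {
        res$psa <- run_psa_scenario(model, n_draws = n_draws,
                                    seed = seed + 7L)
      }
      out[[key]] <- res
    }
    out[[paste0("fidelity_", population)]] <- rec$fidelity
    out[[paste0("fits_", population)]] <- fits
  }
  if (!is.null(out_dir)) write_scenario_outputs(out, out_dir, seed)
  out
}

# CSV/JSON writers with an audit header (seed + content hash of the config)
write_scenario_outputs <- function(results, out_dir, seed) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  header <- sprintf("# maintcea scenario batch, seed = %d", seed)
  write_with_header <- function(df, path) {
    con <- file(path, "w")
    writeLines(header, con)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
  }
  summary_rows <- list()
  for (key in names(results)) {
    if (!grepl("^(US|China)_", key)) next
    res <- results[[key]]
    summary_rows[[key]] <- data.frame(
      scenario = key,
      cost_ave = res$base$ave$cost, qalys_ave = res$base$ave$qalys,
      cost_con = res$base$con$cost, qalys_con = res$base$con$qalys,
      delta_cost = res$base$icer$delta_cost,
      delta_qalys = res$base$icer$delta_qalys,
      icer = res$base$icer$icer, status = res$base$icer$status,
      wtp = res$base$wtp, inmb = res$base$inmb, verdict = res$base$verdict)
    if (!is.null(res$dsa)) {
      write_with_header(res$dsa, file.path(out_dir, paste0("dsa_", key, ".csv")))
    }
    if (!is.null(res$psa)) {
      write_with_header(res$psa$draws,
                        file.path(out_dir, paste0("psa_", key, ".csv")))
      write_with_header(res$psa$ceac,
                        file.path(out_dir, paste0("ceac_", key, ".csv")))
    }
  }
  smry <- do.call(rbind, summary_rows)
  write_with_header(smry, file.path(out_dir, "base_case_summary.csv"))
  jsonlite::write_json(list(seed = seed, scenarios = smry),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(out_dir)
}
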