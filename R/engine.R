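#' Define an intervention scenario
#'
#' A scenario is a National Health Service Corps budget trajectory: an
#' annual budget growth rate applied to dental-practitioner awards
#' (0 = status quo, flat awards), an optional one-year extension of the
#' service commitment, a simulation horizon, and a discount rate.
#'
#' @param label scenario name.
#' @param growth annual budget growth fraction (>= 0).
#' @param commitment_extension extra commitment years for all award
#'   types (0 or 1 in the packaged analyses).
#' @param horizon simulated years (default 10).
#' @param start_year first calendar year (default 2022; informational).
#' @param discount annual discount rate; `NULL` uses the parameter set's.
#' @return An object of class `caries_scenario`.
#' @export
scenario_config <- function(label = "status quo", growth = 0,
                            commitment_extension = 0, horizon = 10,
                            start_year = 2022, discount = NULL) {
  stopifnot(horizon >= 1, growth >= 0, commitment_extension >= 0)
  structure(list(label = label, growth = growth,
                 commitment_extension = commitment_extension,
                 horizon = horizon, start_year = start_year,
                 discount = discount),
            class = "caries_scenario")
}

#' Run one scenario over the simulated horizon
#'
#' Executes `horizon` annual cycles.  The scenario's incremental dentist
#' FTE (relative to flat status-quo awards) is converted each year into
#' a dentist-density change for whole- and partial-HPSA strata, whose
#' utilization and caries-risk effects apply to HPSA residents only.
#' Disease randomness is drawn from `(disease_seed, cycle, slot)`
#' streams, so two scenarios run with the same population and
#' `disease_seed` are compared under common random numbers.
#'
#' Outcome definitions: `prevalence` is ever-had-caries at horizon end
#' among surviving children (age <= 19); `incidence` is the weighted
#' count of carious-tooth events accrued during the simulation; costs
#' and QALYs are discounted, weighted totals, with the scenario's own
#' discounted NHSC program cost reported separately
#' (`program_cost`) and attributed to the HPSA population in
#' `hpsa$cost_total`.
#'
#' @param pop population with baseline states assigned.
#' @param params a calibrated `caries_params` object.
#' @param scenario a `caries_scenario`.
#' @param disease_seed integer master seed for disease randomness.
#' @param require_calibrated error if `params$calibrated` is not TRUE
#'   (set FALSE for experiments on uncalibrated models).
#' @return An object of class `caries_result`: aggregates `overall`,
#'   `hpsa`, `non_hpsa` (each with prevalence, incidence,
#'   cost_treatment, qaly), `by_stratum`, `by_year`,
#'   `age_band_prevalence`, `program_cost`, and bookkeeping fields used
#'   by [incremental()].
#' @export
run_scenario <- function(pop, params, scenario, disease_seed,
                         require_calibrated = TRUE) {
  if (require_calibrated && !isTRUE(params$calibrated)) {
    stop("parameter set is not calibrated; run calibrate_model() first ",
         "(or pass require_calibrated = FALSE)")
  }
  if (!all(c("ever_caries", "alive") %in% names(pop))) {
    stop("population has no baseline states; run assign_baseline_states()")
  }
  rate <- if (is.null(scenario$discount)) params$econ$discount else
    scenario$discount
  H <- scenario$horizon

  sched <- NULL
  if (scenario$growth > 0 || scenario$commitment_extension > 0) {
    sched <- supply_schedule(params, scenario$growth, H,
                             scenario$commitment_extension)
  }
  res <- simulate_cohort(pop, params, H, disease_seed,
                         shift_schedule = sched, discount_rate = rate)

  aw <- project_awards(params$program, scenario$growth, H,
                       compound = budget_compound(params$program))
  res$program_cost <- sum(program_cost(aw, params$program$cost_per_award,
                                       rate, amortize = TRUE,
                                       commitment = params$program$commitment))
  res$hpsa$cost_total <- res$hpsa$cost_treatment + res$program_cost
  res$overall$cost_total <- res$overall$cost_treatment + res$program_cost
  res$scenario <- scenario
  res$fingerprint <- attr(pop, "fingerprint")
  res$disease_seed <- disease_seed
  class(res) <- "caries_result"
  res
}

#' @export
print.caries_result <- function(x, ...) {
  cat("<caries_result>", x$scenario$label, "\n")
  cat(sprintf("  HPSA child prevalence at horizon end: %.1f%%\n",
              100 * x$hpsa$prevalence))
  cat(sprintf("  non-HPSA child prevalence:            %.1f%%\n",
              100 * x$non_hpsa$prevalence))
  cat(sprintf("  cumulative decayed teeth (HPSA):      %.2f million\n",
              x$hpsa$incidence / 1e6))
  cat(sprintf("  discounted cost (HPSA, incl. program): $%.1f million\n",
              x$hpsa$cost_total / 1e6))
  cat(sprintf("  discounted QALYs (HPSA):              %.2f million\n",
              x$hpsa$qaly / 1e6))
  invisible(x)
}

#' Incremental outcomes of a scenario against a status-quo baseline
#'
#' Element-wise differences of the HPSA-resident aggregates of two runs
#' that share the same population and disease seed (enforced through the
#' population fingerprint).  Reports the change in caries prevalence in
#' percentage points, the change in cumulative decayed-tooth incidence,
#' incremental QALYs and incremental cost (treatment plus incremental
#' program cost), the ICER (flagged "dominant (cost-saving)" when QALYs
#' are gained at negative incremental cost), and net monetary benefit
#' `NMB = WTP x dQALY - dcost`.
#'
#' @param result scenario `caries_result`.
#' @param baseline status-quo `caries_result`.
#' @param wtp willingness to pay per QALY (default 50000 USD).
#' @return A list of class `caries_incremental`.
#' @export
incremental <- function(result, baseline, wtp = 50000) {
  if (!identical(result$fingerprint, baseline$fingerprint)) {
    stop("results come from different populations (fingerprint mismatch)")
  }
  if (!identical(result$disease_seed, baseline$disease_seed)) {
    stop("results do not share common random numbers (disease seeds differ)")
  }
  d_prev_pp <- 100 * (result$hpsa$prevalence - baseline$hpsa$prevalence)
  d_incidence <- result$hpsa$incidence - baseline$hpsa$incidence
  d_qaly <- result$hpsa$qaly - baseline$hpsa$qaly
  d_cost <- result$hpsa$cost_total - baseline$hpsa$cost_total
  dominant <- is.finite(d_qaly) && is.finite(d_cost) &&
    d_qaly > 0 && d_cost < 0
  icer <- if (d_qaly == 0 && d_cost == 0) NA_real_ else d_cost / d_qaly
  structure(list(
    label = result$scenario$label,
    d_prevalence_pp = d_prev_pp,
    d_incidence = d_incidence,
    d_qaly = d_qaly,
    d_cost = d_cost,
    icer = icer,
    dominant = dominant,
    wtp = wtp,
    nmb = wtp * d_qaly - d_cost
  ), class = "caries_incremental")
}

#' @export
print.caries_incremental <- function(x, ...) {
  cat("<caries_incremental>", x$label, "\n")
  cat(sprintf("  d prevalence: %+.2f pp\n", x$d_prevalence_pp))
  cat(sprintf("  d decayed teeth: %+.2f million\n", x$d_incidence / 1e6))
  cat(sprintf("  d QALYs: %+.2f thousand\n", x$d_qaly / 1e3))
  cat(sprintf("  d cost: %+.2f $ million\n", x$d_cost / 1e6))
  cat("  ICER:", if (x$dominant) "dominant (cost-saving)" else
    format(x$icer, digits = 4), "\n")
  cat(sprintf("  NMB at $%s/QALY: $%.1f million\n",
              format(x$wtp, big.mark = ","), x$nmb / 1e6))
  invisible(x)
}

#' Write Table-style incremental results for a set of scenarios
#'
#' One row per scenario: change in prevalence (percentage points),
#' change in cumulative incidence (millions of decayed teeth),
#' incremental QALYs (thousands), incremental cost ($ millions).
#'
#' @param increments list of `caries_incremental` objects.
#' @param path CSV file path (optional).
#' @return The data frame, invisibly if written.
#' @export
incremental_table <- function(increments, path = NULL) {
  df <- do.call(rbind, lapply(increments, function(x) data.frame(
    scenario = x$label,
    d_prevalence_pp = x$d_prevalence_pp,
    d_incidence_millions = x$d_incidence / 1e6,
    d_qaly_thousands = x$d_qaly / 1e3,
    d_cost_millions = x$d_cost / 1e6,
    stringsAsFactors = FALSE
  )))
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}
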