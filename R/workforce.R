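#' Project NHSC award streams under a budget growth rate
#'
#' With `compound = TRUE` (default), awards in year `t` (0-based) equal
#' the baseline award count times `(1 + growth)^t`, separately for each
#' program type (scholarship, loan repayment, student-to-service).  With
#' `compound = FALSE` the budget ramps linearly, `baseline * (1 +
#' growth * t)` — the packaged analysis uses the linear ramp, which is
#' what makes incremental outcomes scale proportionally with the growth
#' rate (see the methods vignette).  Awards are kept continuous; a
#' growth rate of 0 reproduces the baseline every year.
#'
#' @param program the `program` component of a `caries_params` object.
#' @param growth annual budget growth fraction (> -1).
#' @param years number of projected years (>= 1).
#' @param compound compound (`(1+g)^t`) or linear (`1+g*t`) growth.
#' @return A `years` x type matrix of award counts; row `t+1` is year `t`.
#' @export
#' @examples
#' pr <- default_parameters()$program
#' project_awards(pr, 0.10, 3)
project_awards <- function(program, growth, years, compound = TRUE) {
  if (growth <= -1) stop("growth rate must exceed -100%")
  stopifnot(years >= 1, all(program$awards >= 0))
  t_ <- seq_len(years) - 1L
  fac <- if (compound) (1 + growth)^t_ else pmax(1 + growth * t_, 0)
  out <- outer(fac, program$awards)
  dimnames(out) <- list(year = t_, type = names(program$awards))
  out
}

#' Convert award streams to serving dentist FTE by calendar year
#'
#' Each award cohort of type `j` contributes `(1 - default_rate)` FTE
#' per award during its commitment period (optionally extended), then
#' decays geometrically through the post-service retention profile:
#' `(1 - default_rate) * retention^k` in the `k`-th year after the
#' commitment ends, for up to `retention_years` years.  Yearly FTE is
#' the sum over all active cohorts.
#'
#' @param awards matrix from [project_awards()].
#' @param program program constants (commitment, default_rate, retention,
#'   retention_years).
#' @param commitment_extension additional commitment years applied to all
#'   types (0 or 1 in the packaged scenarios).
#' @param years_out length of the returned FTE vector; defaults to
#'   `nrow(awards)` (cohort tails beyond the horizon are then dropped).
#' @return Numeric vector of FTE per year (0-based years).
#' @export
awards_to_fte <- function(awards, program, commitment_extension = 0,
                          years_out = nrow(awards)) {
  stopifnot(all(awards >= 0), commitment_extension >= 0)
  d <- program$default_rate
  ret <- program$retention
  rt_years <- program$retention_years
  fte <- numeric(years_out)
  for (j in seq_len(ncol(awards))) {
    cl <- program$commitment[[colnames(awards)[j]]] + commitment_extension
    profile <- c(rep(1 - d, cl), (1 - d) * ret^seq_len(rt_years))
    for (t0 in seq_len(nrow(awards))) {
      idx <- t0 - 1L + seq_along(profile) # 1-based years t0-1, t0, ...
      sel <- idx <= years_out
      if (!any(sel)) next
      fte[idx[sel]] <- fte[idx[sel]] + awards[t0, j] * profile[sel]
    }
  }
  fte
}

# Closed-form total FTE-years contributed by an award matrix over an
# unbounded horizon; used as the conservation ledger.
fte_ledger_total <- function(awards, program, commitment_extension = 0) {
  d <- program$default_rate
  per_award <- vapply(colnames(awards), function(ty) {
    cl <- program$commitment[[ty]] + commitment_extension
    (1 - d) * (cl + sum(program$retention^seq_len(program$retention_years)))
  }, numeric(1))
  sum(colSums(awards) * per_award)
}

#' Dentist-density change per 1,000 children
#'
#' @param fte FTE vector (or scalar) serving a population.
#' @param population children served (persons, > 0).
#' @return `1000 * fte / population`.
#' @export
#' @examples
#' density_delta(1470, 14.7e6)  # 0.1 dentists per 1,000 children
density_delta <- function(fte, population) {
  if (!is.numeric(population) || any(population <= 0)) {
    stop("population must be positive")
  }
  1000 * fte / population
}

# budget ramp shape used by the scenario pipeline; "linear" unless the
# program config says otherwise
budget_compound <- function(program) {
  identical(program$budget_ramp, "compound")
}

# Split incremental FTE between whole- and partial-county HPSA strata
# proportionally to their child populations, down-weighting partial
# counties (only part of their population faces the shortage).
allocate_fte <- function(fte, pop_whole, pop_partial, partial_weight = 0.5) {
  denom <- pop_whole + partial_weight * pop_partial
  list(whole = fte * pop_whole / denom,
       partial = fte * partial_weight * pop_partial / denom)
}

#' Translate a dentist-density change into utilization and risk effects
#'
#' The utilization effect is linear: each additional dentist per 10,000
#' children raises the fraction of children using preventive dental care
#' by `util_slope` (default 0.0167, i.e. 1.67 percentage points); the
#' result is clamped to `[0, 1]`.  The caries effect is log-linear: the
#' per-1,000-children odds ratio (default 0.46) is raised to the
#' fractional density power, i.e. the log-odds shift is
#' `delta * log(caries_or)`.
#'
#' @param delta dentist-density change per 1,000 children (>= 0; scalar
#'   or vector).
#' @param effect the `supply` component of a `caries_params` object.
#' @param baseline_util baseline utilization fraction(s).
#' @return List with `utilization` (shifted, clamped fraction) and
#'   `log_or_shift` (additive caries log-odds change, <= 0 for a
#'   protective odds ratio).
#' @export
#' @examples
#' eff <- default_parameters()$supply
#' apply_supply_effect(0.1, eff, 0.40)  # +1 per 10,000: util 0.4167
apply_supply_effect <- function(delta, effect, baseline_util) {
  stopifnot(all(delta >= 0), effect$caries_or > 0)
  util <- pmin(pmax(baseline_util + effect$util_slope * (delta * 10), 0), 1)
  list(utilization = util, log_or_shift = delta * log(effect$caries_or))
}

# Per-year, per-HPSA-stratum utilization and log-odds shifts of a budget
# scenario relative to the flat-award status quo.
supply_schedule <- function(params, growth, horizon,
                            commitment_extension = 0) {
  prog <- params$program
  aw_base <- project_awards(prog, 0, horizon, compound = budget_compound(prog))
  aw_sc <- project_awards(prog, growth, horizon,
                          compound = budget_compound(prog))
  fte_base <- awards_to_fte(aw_base, prog)
  fte_sc <- awards_to_fte(aw_sc, prog, commitment_extension)
  dfte <- fte_sc - fte_base

  st <- params$demography$strata
  tot <- params$demography$total_population
  pop_whole <- tot * sum(st$proportion[st$hpsa == "whole"])
  pop_partial <- tot * sum(st$proportion[st$hpsa == "partial"])
  al <- allocate_fte(dfte, pop_whole, pop_partial,
                     params$supply$partial_weight)
  sched <- rbind(
    data.frame(year = seq_len(horizon) - 1L, hpsa = "whole",
               delta = density_delta(al$whole, pop_whole)),
    data.frame(year = seq_len(horizon) - 1L, hpsa = "partial",
               delta = density_delta(al$partial, pop_partial))
  )
  eff <- apply_supply_effect(sched$delta, params$supply, 0)
  sched$util_shift <- eff$utilization          # baseline 0 => pure shift
  sched$logor_shift <- eff$log_or_shift
  sched
}
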