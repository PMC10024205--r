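#' Discount a value accrued in a future year
#'
#' Present value of `value` accrued `year` years from the start:
#' `value / (1 + rate)^year`; year 0 is undiscounted.  Costs and QALYs
#' use the same annual rate (default 3% in the packaged parameters).
#'
#' @param value currency or QALY amount(s).
#' @param year 0-based year index (>= 0).
#' @param rate annual discount rate (> -1).
#' @return Discounted value(s).
#' @export
#' @examples
#' discount(103, 1, 0.03)  # 100
discount <- function(value, year, rate) {
  if (any(rate <= -1)) stop("discount rate must exceed -100%")
  if (any(year < 0)) stop("year index must be >= 0")
  value / (1 + rate)^year
}

#' Health-care costs accrued by each individual in one cycle
#'
#' Sums unit costs over the cycle's events: a preventive visit if care
#' was utilized, restorative treatment per carious event treated this
#' cycle (newly treated events and previously untreated caries converted
#' to treated at a visit), an abscess episode, and an extraction per
#' tooth lost.  Zero if nothing happened.
#'
#' @param events per-cycle event counts as returned by
#'   [step_population()] (`utilized`, `treated_now`, `new_abscess`,
#'   `new_loss`).
#' @param econ the `econ` component of a `caries_params` object.
#' @return USD vector, one entry per individual.
#' @export
cycle_costs <- function(events, econ) {
  events$utilized * econ$cost_preventive +
    events$treated_now * econ$cost_restorative +
    events$new_abscess * econ$cost_abscess +
    events$new_loss * econ$cost_extraction
}

#' Quality-adjusted life-year accrual for one cycle
#'
#' Utility is 1 minus the sum of disutility weights of the states held
#' during the cycle (untreated caries, treated caries, an abscess
#' episode this cycle, and a permanent per-tooth decrement for teeth
#' lost), floored at 0.  Individuals who do not survive the cycle accrue
#' 0.
#'
#' @param state data frame with columns `alive`, `untreated`, `treated`,
#'   `abscess_now` (logical) and `teeth_lost` (count).
#' @param econ the `econ` component of a `caries_params` object.
#' @return QALY vector in `[0, 1]`, one entry per individual.
#' @export
cycle_qaly <- function(state, econ) {
  q <- 1 - econ$du_untreated * state$untreated -
    econ$du_treated * state$treated -
    econ$du_abscess * state$abscess_now -
    econ$du_tooth_loss * state$teeth_lost
  q <- pmax(q, 0)
  q[!state$alive] <- 0
  q
}

#' Discounted NHSC program cost stream
#'
#' Multiplies each year's awards by the per-award cost of its program
#' type and discounts the yearly totals.  In incremental analyses only
#' the award stream *difference* between a scenario and the status quo
#' enters incremental cost; program cost is accrued at the aggregate
#' level and attributed to the HPSA population.
#'
#' With `amortize = FALSE` (default) the full award cost accrues in the
#' award year.  With `amortize = TRUE`, each award's cost is disbursed
#' evenly over its commitment years (the loan-repayment contract
#' structure), truncated at the end of the award horizon, which keeps
#' the timing of program outlays aligned with the timing of service.
#'
#' @param awards matrix from [project_awards()].
#' @param cost_per_award named vector of USD per award by type.
#' @param rate annual discount rate.
#' @param amortize spread each award's cost over its commitment years?
#' @param commitment named vector of commitment years by type (required
#'   when `amortize = TRUE`).
#' @return Vector of discounted USD per year; `sum()` gives the total.
#' @export
program_cost <- function(awards, cost_per_award, rate, amortize = FALSE,
                         commitment = NULL) {
  stopifnot(all(awards >= 0))
  if (!amortize) {
    yearly <- as.numeric(awards %*% cost_per_award[colnames(awards)])
    return(discount(yearly, seq_along(yearly) - 1, rate))
  }
  stopifnot(!is.null(commitment))
  H <- nrow(awards)
  yearly <- numeric(H)
  for (j in seq_len(ncol(awards))) {
    ty <- colnames(awards)[j]
    cl <- commitment[[ty]]
    per_year <- cost_per_award[[ty]] / cl
    for (t0 in seq_len(H)) {
      idx <- t0 - 1L + seq_len(cl)
      idx <- idx[idx <= H]
      yearly[idx] <- yearly[idx] + awards[t0, j] * per_year
    }
  }
  discount(yearly, seq_along(yearly) - 1, rate)
}
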