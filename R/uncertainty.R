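#' Default uncertainty distributions for model parameters
#'
#' One row per uncertain parameter: dotted path into the parameter set,
#' distribution family by domain (beta for probabilities and fractions,
#' gamma for costs, lognormal for odds ratios and rates), central value,
#' and low/high bounds for one-way analysis.  Dispersion for
#' probabilistic sampling defaults to a 95% interval of +/-20% around
#' the central value (multiplicative for lognormal).  The `one_way`
#' flag marks the nine parameters swept in the packaged tornado
#' analysis: treatment and visit costs, the two dentist-supply effect
#' sizes, untreated-caries and abscess probabilities, the untreated
#' disutility, and the NHSC retention and default rates.
#'
#' @param params a `caries_params` object supplying central values.
#' @return A data frame with columns `name`, `path`, `family`,
#'   `central`, `low`, `high`, `one_way`.
#' @export
param_distributions <- function(params = default_parameters()) {
  row <- function(name, path, family, low, high, one_way = TRUE) {
    data.frame(name = name, path = path, family = family,
               central = as.numeric(get_param(params, path)),
               low = low, high = high, one_way = one_way,
               stringsAsFactors = FALSE)
  }
  # the nine one-way rows follow the categories named in the packaged
  # tornado analysis: treatment cost, the two dentist-supply effects,
  # untreated-caries and abscess pathways, disutility weights, and NHSC
  # program characteristics
  rbind(
    row("Caries treatment cost", "econ.cost_restorative", "gamma", 750, 2250),
    row("Abscess episode cost", "econ.cost_abscess", "gamma", 750, 2250),
    row("Supply effect on caries (OR per 1,000)", "supply.caries_or",
        "lognormal", 0.30, 0.90),
    row("Supply effect on utilization", "supply.util_slope", "beta",
        0.008, 0.033),
    row("Probability of untreated caries", "risk.p_untreated_no_care",
        "beta", 0.20, 0.60),
    row("Probability of tooth abscess", "risk.p_abscess", "beta",
        0.06, 0.24),
    row("Disutility of untreated caries", "econ.du_untreated", "beta",
        0.0175, 0.07),
    row("NHSC post-service retention", "program.retention", "beta",
        0.30, 0.95),
    row("NHSC default rate", "program.default_rate", "beta", 0.01, 0.15),
    row("Extraction cost", "econ.cost_extraction", "gamma", 175, 525,
        one_way = FALSE),
    row("Probability of tooth loss", "risk.p_tooth_loss", "beta",
        0.025, 0.10, one_way = FALSE),
    row("Disutility of treated caries", "econ.du_treated", "beta",
        0.0025, 0.01, one_way = FALSE),
    row("Disutility of abscess", "econ.du_abscess", "beta", 0.04, 0.16,
        one_way = FALSE),
    row("Disutility of tooth loss", "econ.du_tooth_loss", "beta",
        0.005, 0.02, one_way = FALSE),
    row("Probability untreated despite care", "risk.p_untreated_care",
        "beta", 0.05, 0.20, one_way = FALSE)
  )
}

# domain of a parameter implied by its distribution family
check_bounds <- function(dists) {
  for (i in seq_len(nrow(dists))) {
    d <- dists[i, ]
    bad <- switch(d$family,
      beta = d$low < 0 || d$high > 1,
      gamma = d$low < 0,
      lognormal = d$low <= 0,
      fixed = FALSE, # degenerate: always the central value
      stop("unknown distribution family: ", d$family))
    if (is.na(bad) || bad || d$low > d$high) {
      stop("bounds outside domain for parameter '", d$name, "'")
    }
  }
  invisible(dists)
}

# One Monte-Carlo draw of every distribution row.  Dispersion: sd equal
# to 20%/1.96 of the central value (sdlog = log(1.2)/1.96 for
# lognormal); beta and gamma are moment-matched.
sample_distribution_row <- function(d) {
  m <- d$central
  if (identical(d$family, "fixed") || m == 0) return(m)
  s <- 0.2 * m / 1.96
  switch(d$family,
    gamma = {
      shape <- (m / s)^2
      stats::rgamma(1, shape = shape, rate = shape / m)
    },
    beta = {
      v <- s^2
      ab <- m * (1 - m) / v - 1
      if (ab <= 0) return(m) # dispersion impossible, degenerate
      stats::rbeta(1, ab * m, ab * (1 - m))
    },
    lognormal = stats::rlnorm(1, meanlog = log(m),
                              sdlog = log(1.2) / 1.96))
}

#' Draw parameter sets for probabilistic sensitivity analysis
#'
#' @param params central `caries_params` object.
#' @param dists distribution table from [param_distributions()].
#' @param n_draws number of parameter sets.
#' @param seed master seed; draw `d` uses a derived child seed.
#' @return A list of `n_draws` modified parameter sets.
#' @export
sample_params <- function(params, dists, n_draws, seed) {
  check_bounds(dists)
  lapply(seq_len(n_draws), function(d) {
    with_local_seed(derive_seed(seed, 1000, d), {
      p <- params
      for (i in seq_len(nrow(dists))) {
        p <- set_param(p, dists$path[i],
                       sample_distribution_row(dists[i, ]))
      }
      p
    })
  })
}

# Paired (status quo, scenario) incremental run under one parameter set.
paired_increment <- function(params, pop, scenario, disease_seed,
                             wtp = 50000) {
  base <- run_scenario(pop, params, scenario_config(
    "status quo", growth = 0, horizon = scenario$horizon), disease_seed,
    require_calibrated = FALSE)
  sc <- run_scenario(pop, params, scenario, disease_seed,
                     require_calibrated = FALSE)
  incremental(sc, base, wtp = wtp)
}

#' One-way (tornado) sensitivity analysis
#'
#' Evaluates the incremental outcomes of the target scenario at the low
#' and high bound of each swept parameter, holding every other parameter
#' at its central value, under common random numbers (same population
#' and disease seed for all runs, and for the status-quo arm inside each
#' run).  Both incremental endpoints are re-simulated because a
#' parameter change moves the status quo too.
#'
#' @param params calibrated central `caries_params` object.
#' @param dists distribution table; rows with `one_way = TRUE` are swept.
#' @param scenario target scenario (default: 10% annual budget growth).
#' @param pop population to simulate; default generates `n` individuals.
#' @param n population size when `pop` is NULL (default 5000).
#' @param pop_seed,disease_seed seeds.
#' @param outcome designated outcome for ranking: `"d_cost"` or
#'   `"d_qaly"`.
#' @return A data frame sorted by decreasing `|spread|` on the
#'   designated outcome, with the low/high parameter values and both
#'   incremental outcomes at each endpoint.
#' @export
one_way <- function(params, dists = param_distributions(params),
                    scenario = scenario_config("base case", growth = 0.10),
                    pop = NULL, n = 5000, pop_seed = 21,
                    disease_seed = 301, outcome = c("d_cost", "d_qaly")) {
  outcome <- match.arg(outcome)
  check_bounds(dists)
  sw <- dists[dists$one_way, , drop = FALSE]
  if (is.null(pop)) {
    pop <- generate_population(n, params$demography, pop_seed)
    pop <- assign_baseline_states(pop, params, derive_seed(pop_seed, 2))
  }
  rows <- lapply(seq_len(nrow(sw)), function(i) {
    ends <- lapply(c(low = sw$low[i], high = sw$high[i]), function(v) {
      paired_increment(set_param(params, sw$path[i], v), pop, scenario,
                       disease_seed)
    })
    data.frame(
      name = sw$name[i], path = sw$path[i],
      low = sw$low[i], high = sw$high[i],
      d_cost_low = ends$low$d_cost, d_cost_high = ends$high$d_cost,
      d_qaly_low = ends$low$d_qaly, d_qaly_high = ends$high$d_qaly,
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  tab$spread <- if (outcome == "d_cost") {
    tab$d_cost_high - tab$d_cost_low
  } else {
    tab$d_qaly_high - tab$d_qaly_low
  }
  tab[order(-abs(tab$spread)), , drop = FALSE]
}

#' Probabilistic sensitivity analysis
#'
#' Repeats the paired status-quo/intervention comparison under `n_draws`
#' Monte-Carlo draws from the parameter distributions.  Within a draw
#' the two arms share a disease seed (common random numbers); across
#' draws the disease seed is refreshed from `(seed, draw)` unless
#' `vary_disease_seed = FALSE`, which isolates parameter uncertainty
#' from simulation noise.  Credible intervals are empirical 2.5th and
#' 97.5th percentiles (inverse-ECDF order statistics).
#'
#' @param params calibrated central `caries_params` object.
#' @param dists distribution table from [param_distributions()].
#' @param n_draws parameter draws (packaged default 1000; the source
#'   analysis scale is 10000).
#' @param seed master seed.
#' @param scenario target scenario (default 10% growth).
#' @param n individuals simulated per draw (default 5000; a desk-scale
#'   reduction, see the methods vignette).
#' @param pop_seed population seed.
#' @param wtp_grid willingness-to-pay grid for the acceptability curve.
#' @param vary_disease_seed refresh disease randomness each draw?
#' @return An object of class `caries_psa`: `draws` (one row per draw:
#'   d_prevalence_pp, d_incidence, d_qaly, d_cost), `summary` (mean and
#'   95% credible interval per outcome), and `ceac`.
#' @export
psa <- function(params, dists = param_distributions(params),
                n_draws = 1000, seed = 1,
                scenario = scenario_config("base case", growth = 0.10),
                n = 5000, pop_seed = 31,
                wtp_grid = seq(0, 150000, by = 25000),
                vary_disease_seed = TRUE) {
  stopifnot(n_draws >= 2)
  draws_params <- sample_params(params, dists, n_draws, seed)
  pop <- generate_population(n, params$demography, pop_seed)
  pop <- assign_baseline_states(pop, params, derive_seed(pop_seed, 2))
  rows <- lapply(seq_len(n_draws), function(d) {
    ds <- if (vary_disease_seed) derive_seed(seed, 2000, d) else
      derive_seed(seed, 2000, 0)
    inc <- paired_increment(draws_params[[d]], pop, scenario, ds)
    data.frame(draw = d, d_prevalence_pp = inc$d_prevalence_pp,
               d_incidence = inc$d_incidence, d_qaly = inc$d_qaly,
               d_cost = inc$d_cost)
  })
  draws <- do.call(rbind, rows)
  qlo <- function(x) stats::quantile(x, 0.025, type = 1, names = FALSE)
  qhi <- function(x) stats::quantile(x, 0.975, type = 1, names = FALSE)
  outs <- c("d_prevalence_pp", "d_incidence", "d_qaly", "d_cost")
  summary <- data.frame(
    outcome = outs,
    mean = vapply(draws[outs], mean, numeric(1)),
    lo = vapply(draws[outs], qlo, numeric(1)),
    hi = vapply(draws[outs], qhi, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(draws = draws, summary = summary,
                 ceac = ceac(draws, wtp_grid), n = n, n_draws = n_draws),
            class = "caries_psa")
}

#' @export
print.caries_psa <- function(x, ...) {
  cat("<caries_psa>", x$n_draws, "draws x", x$n, "individuals\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value `w`, the fraction of PSA draws in
#' which the intervention has positive net monetary benefit,
#' `w * dQALY - dcost > 0`.  Monotone nondecreasing in `w` whenever all
#' draws gain QALYs.
#'
#' @param draws data frame with columns `d_qaly` and `d_cost` (e.g.
#'   `psa(...)$draws`).
#' @param wtp_grid vector of willingness-to-pay values (USD/QALY).
#' @return Data frame with columns `wtp` and `prob_cost_effective`.
#' @export
ceac <- function(draws, wtp_grid) {
  if (is.null(draws) || nrow(draws) == 0) stop("empty draw set")
  data.frame(
    wtp = wtp_grid,
    prob_cost_effective = vapply(wtp_grid, function(w) {
      mean(w * draws$d_qaly - draws$d_cost > 0)
    }, numeric(1))
  )
}
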