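#' Generate a seeded synthetic population
#'
#' Allocates `n` simulated children to the demographic strata of `demo`
#' using deterministic largest-remainder quotas, so that stratum counts
#' differ from the exact quotas `n * proportion` by at most one and the
#' total sampling weight of every represented stratum equals its
#' configured population exactly.  The leftover units after flooring the
#' quotas are assigned to strata in order of descending fractional
#' remainder, with ties broken by a seeded random permutation.  Ages
#' within an age group are drawn uniformly over the group's integer
#' years.
#'
#' @param n number of simulated individuals (>= 1).
#' @param demo a `caries_demography` object.
#' @param seed integer master seed; identical `(n, demo, seed)` give
#'   byte-identical populations.
#' @return A data frame with one row per individual: `id`, `stratum`,
#'   demographic columns, integer `age`, and sampling `weight`
#'   (persons represented per simulated individual).
#' @export
#' @examples
#' pop <- generate_population(500, default_demography(), seed = 1)
#' sum(pop$weight)   # ~ total child population
generate_population <- function(n, demo, seed) {
  stopifnot(n >= 1)
  validate_demography(demo)
  st <- demo$strata
  quota <- n * st$proportion
  count <- floor(quota)
  rem <- n - sum(count)
  if (rem > 0) {
    frac <- quota - count
    ord <- with_local_seed(derive_seed(seed, 1), {
      jitter <- sample.int(nrow(st)) # seeded tie-break only
      order(-frac, jitter)
    })
    count[ord[seq_len(rem)]] <- count[ord[seq_len(rem)]] + 1
  }
  keep <- count > 0
  idx <- rep(which(keep), count[keep])
  pop <- st[idx, c("stratum", "age_group", "sex", "race", "income",
                   "residence", "hpsa")]
  rownames(pop) <- NULL
  pop$id <- seq_len(nrow(pop))
  pop <- pop[, c("id", setdiff(names(pop), "id"))]

  age_lo <- c("0-5" = 0L, "6-12" = 6L, "13-19" = 13L)
  age_hi <- c("0-5" = 5L, "6-12" = 12L, "13-19" = 19L)
  lo <- age_lo[pop$age_group]
  hi <- age_hi[pop$age_group]
  u <- crn_uniforms(seed, 0, 2, nrow(pop))
  pop$age <- as.integer(lo + floor(u * (hi - lo + 1L)))
  pop$age0 <- pop$age # age at cohort entry; fixes the birth cohort

  stratum_pop <- demo$total_population * st$proportion
  pop$weight <- (stratum_pop / count)[idx]
  attr(pop, "fingerprint") <- derive_seed(n, seed, nrow(st))
  attr(pop, "pop_seed") <- seed
  pop
}

#' Assign baseline oral-health states
#'
#' Seeds each individual's ever-had-caries status from the packaged
#' baseline prevalence curve (by single year of age), adjusted on the
#' odds scale by race/ethnicity and HPSA-status odds ratios; a configured
#' share of prevalent cases start with currently untreated caries.
#' Baseline-prevalent individuals enter with one recorded carious-tooth
#' event; the simulation's cumulative-incidence outcome counts only
#' events accrued during simulated cycles.
#'
#' @param pop population from [generate_population()].
#' @param params a `caries_params` object (uses the `baseline` section).
#' @param seed integer seed for the baseline draws.
#' @return `pop` with state columns added: `ever_caries`,
#'   `caries_events`, `events_sim`, `untreated`, `abscesses`,
#'   `teeth_lost`, `alive`.
#' @export
assign_baseline_states <- function(pop, params, seed) {
  bl <- params$baseline
  curve <- bl$prevalence_curve
  if (any(bad <- !(as.character(pop$age) %in% names(curve)))) {
    stop("no baseline prevalence target for age ", pop$age[which(bad)[1]])
  }
  if (any(bad <- !(pop$race %in% names(bl$race_or)))) {
    stop("no baseline odds ratio for race stratum ", pop$race[which(bad)[1]])
  }
  if (any(curve < 0 | curve > 1)) stop("baseline targets must be in [0, 1]")
  p0 <- unname(curve[as.character(pop$age)])
  odds <- p0 / (1 - p0) * bl$race_or[pop$race] * bl$hpsa_or[pop$hpsa]
  p <- ifelse(p0 >= 1, 1, odds / (1 + odds))

  u1 <- crn_uniforms(seed, 0, 11, nrow(pop))
  u2 <- crn_uniforms(seed, 0, 12, nrow(pop))
  ever <- u1 < p
  pop$ever_caries <- ever
  pop$caries_events <- as.integer(ever)
  pop$events_sim <- 0L
  pop$untreated <- ever & (u2 < bl$untreated_share)
  pop$abscesses <- 0L
  pop$teeth_lost <- 0L
  pop$alive <- TRUE
  pop
}

#' Write or read a population as CSV
#'
#' One row per individual; all columns are plain atomic types, so the
#' round trip is lossless apart from the population fingerprint
#' attributes.
#'
#' @param pop a population data frame.
#' @param path CSV file path.
#' @return `write_population()` returns `path` invisibly;
#'   `read_population()` returns the data frame.
#' @export
write_population <- function(pop, path) {
  utils::write.csv(pop, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# Baseline fraction of children with a preventive dental visit per year,
# by stratum (additive adjustments on the probability scale, clamped).
baseline_utilization <- function(pop, params) {
  u <- params$utilization
  p <- u$base + u$income[pop$income] + u$hpsa[pop$hpsa] +
    u$residence[pop$residence]
  pmin(pmax(unname(p), 0.05), 0.95)
}
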