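#' Default demographic configuration
#'
#' Builds the packaged joint demographic structure of US children aged
#' 0-19: age group (0-5, 6-12, 13-19) x sex x race/ethnicity (Hispanic,
#' non-Hispanic Black, non-Hispanic White) x household income relative to
#' the federal poverty level (low, below 130% FPL; middle, 130-300% FPL;
#' high, above 300% FPL) x urban/rural residence x county dental-HPSA
#' designation (whole, partial, none).
#'
#' National race/ethnicity margins follow published NHANES 2011-2016
#' weighted percentages (26.4% Hispanic, 15.7% non-Hispanic Black, 57.9%
#' non-Hispanic White).  The HPSA child population is fixed at 14.7
#' million out of a total child population of 80 million; conditional
#' income, residence, and race distributions inside shortage areas are
#' documented assumptions (shortage-area children skew lower-income, more
#' rural, and more Hispanic/Black), since the restricted county-linked
#' tabulations behind them are not public.
#'
#' @param total_population total number of represented children (persons).
#' @param hpsa_share fraction of children living in whole- or
#'   partial-county dental HPSAs; default 14.7e6 / 80e6.
#' @return An object of class `caries_demography`: a list with `strata`
#'   (data frame with one row per stratum and its `proportion`) and
#'   `total_population`.
#' @export
default_demography <- function(total_population = 80e6,
                               hpsa_share = 14.7e6 / 80e6) {
  age_group <- c("0-5" = 0.30, "6-12" = 0.35, "13-19" = 0.35)
  sex <- c(female = 0.49, male = 0.51)
  hpsa <- c(whole = 0.40 * hpsa_share, partial = 0.60 * hpsa_share,
            none = 1 - hpsa_share)
  # conditional distributions given HPSA status (assumptions, see vignette)
  race_by_hpsa <- list(
    whole   = c(Hispanic = 0.32, Black = 0.20, White = 0.48),
    partial = c(Hispanic = 0.29, Black = 0.18, White = 0.53),
    none    = c(Hispanic = 0.25, Black = 0.15, White = 0.60)
  )
  income_by_hpsa <- list(
    whole   = c(low = 0.42, middle = 0.37, high = 0.21),
    partial = c(low = 0.34, middle = 0.37, high = 0.29),
    none    = c(low = 0.22, middle = 0.34, high = 0.44)
  )
  residence_by_hpsa <- list(
    whole   = c(urban = 0.45, rural = 0.55),
    partial = c(urban = 0.65, rural = 0.35),
    none    = c(urban = 0.85, rural = 0.15)
  )

  grid <- expand.grid(
    age_group = names(age_group), sex = names(sex),
    race = names(race_by_hpsa$none), income = names(income_by_hpsa$none),
    residence = c("urban", "rural"), hpsa = names(hpsa),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  prop <- age_group[grid$age_group] * sex[grid$sex] * hpsa[grid$hpsa] *
    mapply(function(r, h) race_by_hpsa[[h]][[r]], grid$race, grid$hpsa) *
    mapply(function(i, h) income_by_hpsa[[h]][[i]], grid$income, grid$hpsa) *
    mapply(function(u, h) residence_by_hpsa[[h]][[u]], grid$residence, grid$hpsa)
  grid$proportion <- as.numeric(prop / sum(prop))
  grid$stratum <- do.call(paste, c(grid[c("age_group", "sex", "race",
                                          "income", "residence", "hpsa")],
                                   sep = "|"))
  demo <- structure(
    list(strata = grid[, c("stratum", "age_group", "sex", "race", "income",
                           "residence", "hpsa", "proportion")],
         total_population = total_population),
    class = "caries_demography"
  )
  validate_demography(demo)
  demo
}

#' Validate a demographic configuration
#'
#' Checks that stratum proportions are nonnegative and sum to one within
#' 1e-9, that stratum keys are unique, and that the represented population
#' is positive.  Errors name the offending stratum.
#'
#' @param demo a `caries_demography` object.
#' @return `demo`, invisibly, if valid.
#' @export
validate_demography <- function(demo) {
  st <- demo$strata
  if (any(bad <- st$proportion < 0)) {
    stop("negative proportion for stratum ", st$stratum[which(bad)[1]])
  }
  if (abs(sum(st$proportion) - 1) > 1e-9) {
    stop("stratum proportions sum to ", format(sum(st$proportion), digits = 12),
         ", not 1")
  }
  if (anyDuplicated(st$stratum)) {
    stop("duplicated stratum key: ", st$stratum[duplicated(st$stratum)][1])
  }
  if (!is.numeric(demo$total_population) || demo$total_population <= 0) {
    stop("total_population must be positive")
  }
  invisible(demo)
}

#' HPSA child population represented by a demographic configuration
#' @param demo a `caries_demography` object.
#' @return Persons in whole- or partial-HPSA strata.
#' @export
hpsa_population <- function(demo) {
  st <- demo$strata
  demo$total_population * sum(st$proportion[st$hpsa != "none"])
}

# Ever-had-caries baseline fraction by single year of age (population
# average before race/HPSA odds adjustments).  Anchored so the band
# averages over ages 2-5, 6-12 and 13-19 reproduce NHANES-style
# cross-sectional prevalences of 21.3% / 52.1% / 56.8%, while remaining
# monotone in age (the mid-band jump at age 6 reflects mixed dentition:
# primary-tooth caries plus first permanent molars).
# Within the two older bands the curve is nearly flat: band prevalence
# is mostly established around band entry (mixed/permanent dentition
# transitions), which is also what keeps a closed-cohort run consistent
# with flat cross-sectional band prevalences.
baseline_prevalence_curve <- function() {
  c("0" = 0.00, "1" = 0.04, "2" = 0.13, "3" = 0.19, "4" = 0.25, "5" = 0.29,
    "6" = 0.500, "7" = 0.510, "8" = 0.515, "9" = 0.520, "10" = 0.525,
    "11" = 0.530, "12" = 0.535,
    "13" = 0.555, "14" = 0.560, "15" = 0.565, "16" = 0.568, "17" = 0.572,
    "18" = 0.576, "19" = 0.580)
}

#' Default model parameter set
#'
#' Assembles the full parameter set for the microsimulation: demographic
#' configuration, annual caries risk model (logistic-additive in age
#' group, sex, race/ethnicity, income, residence, HPSA status, plus
#' per-age-group calibration multipliers), baseline-state assignment
#' targets, baseline preventive-care utilization, NHSC program constants,
#' dentist-supply effect sizes, and cost/disutility values (2022 USD).
#'
#' Where source values sit in restricted or supplementary tables that are
#' not public, the packaged defaults are documented assumptions (see the
#' methods vignette); the two supply effect sizes are taken from the
#' published literature: +1 dentist per 10,000 children raises the
#' fraction of children using preventive dental care by 1.67 percentage
#' points, and +1 dentist per 1,000 children lowers caries risk to an
#' odds ratio of 0.46.
#'
#' @param demo a `caries_demography` object.
#' @return A list of class `caries_params` with components `demography`,
#'   `risk`, `baseline`, `utilization`, `program`, `supply`, `econ`,
#'   `targets`, and a `calibrated` flag (FALSE until [calibrate_model()]
#'   has been run).
#' @export
default_parameters <- function(demo = default_demography()) {
  p <- list(
    demography = demo,
    risk = list(
      # annual caries log-odds, reference: male / White / high income /
      # urban / non-HPSA child of the given age group
      intercept = c("0-5" = stats::qlogis(0.055),
                    "6-12" = stats::qlogis(0.070),
                    "13-19" = stats::qlogis(0.020)),
      sex = c(female = -0.05, male = 0),
      race = c(Hispanic = 0.35, Black = 0.15, White = 0),
      income = c(low = 0.40, middle = 0.15, high = 0),
      residence = c(urban = 0, rural = 0.10),
      hpsa = c(whole = 0.20, partial = 0.10, none = 0),
      calibration = c("0-5" = 0, "6-12" = 0, "13-19" = 0),
      hpsa_calibration = 0,
      # secular decline in caries risk across birth cohorts (log-odds per
      # birth year relative to the oldest cohort, born start_year - 19);
      # lets a closed cohort match flat cross-sectional band prevalences
      # without driving adolescent incidence to zero
      secular_trend = -0.03,
      # fixed within-group age profile of the caries log-odds (single
      # years 0..19), reflecting tooth-eruption timing: risk rises as
      # primary teeth erupt, peaks at first-permanent-molar eruption
      # (6-8 y) and again moderately at second-molar eruption (13-14 y),
      # declining toward band exit.  Not touched by calibration.
      age_shape = c(-1.5, -0.8, -0.3, 0, 0.1, 0.1,
                    0.9, 0.6, 0.2, -0.1, -0.45, -0.8, -1.1,
                    0.4, 0.2, 0, -0.2, -0.4, -0.6, -0.8),
      # reference annual caries probability for cohort members past age
      # 19 (young-adult incidence persists after the child age bands;
      # not touched by calibration)
      p_caries_adult = 0.04,
      p_untreated_no_care = 0.40,
      p_untreated_care = 0.10,
      # per-cycle progression hazards of prevalent untreated caries;
      # pulpal involvement (pufa-type lesions) is reported in a third to
      # a half of untreated carious teeth in children
      p_abscess = 0.12,
      p_tooth_loss = 0.05,
      # all-cause annual mortality by single year of age 0..29 (CDC-style
      # life-table magnitudes; deaths are rare and nearly outcome-neutral)
      mortality = c(0.0055, rep(0.00025, 4), rep(0.00014, 8),
                    rep(0.00045, 7), rep(0.0008, 10))
    ),
    baseline = list(
      prevalence_curve = baseline_prevalence_curve(),
      race_or = c(Hispanic = 1.30, Black = 1.10, White = 0.85),
      hpsa_or = c(whole = 1.20, partial = 1.10, none = 0.95),
      untreated_share = 0.25
    ),
    utilization = list(
      base = 0.52,
      income = c(low = -0.12, middle = -0.05, high = 0),
      hpsa = c(whole = -0.12, partial = -0.06, none = 0),
      residence = c(urban = 0, rural = -0.04)
    ),
    program = list(
      # annual oral-health awards by program type; loan repayment
      # dominates NHSC award volume, with scholarships comparatively
      # rare; scale consistent with recent NHSC field-strength reports
      # (assumption, see vignette)
      awards = c(scholarship = 30, loan_repayment = 1150,
                 student_to_service = 40),
      cost_per_award = c(scholarship = 120000, loan_repayment = 50000,
                         student_to_service = 120000),
      commitment = c(scholarship = 2, loan_repayment = 2,
                     student_to_service = 3),
      default_rate = 0.05,
      # annual continuation probability in HPSA practice after the
      # commitment ends; NHSC alumni surveys report >80% short-term
      # retention in underserved practice
      retention = 0.85,
      retention_years = 8,
      # budget trajectory shape for growth scenarios: "linear"
      # (baseline * (1 + g*t)) or "compound" (baseline * (1+g)^t).
      # Linear ramping makes incremental outcomes scale proportionally
      # with the growth rate across the 5-30% sweep.
      budget_ramp = "linear"
    ),
    supply = list(
      util_slope = 0.0167,   # fraction per +1 dentist / 10,000 children
      caries_or = 0.46,      # odds ratio per +1 dentist / 1,000 children
      partial_weight = 0.5   # partial-county share weight in FTE allocation
    ),
    econ = list(
      # preventive-visit fee.  The packaged default is 0: the costed
      # item set mirrors the source analysis (caries treatment,
      # complications, and NHSC program costs); utilization is a
      # mediator of treatment status, not a costed service.  Set a
      # positive fee to put preventive visits on the payer ledger.
      cost_preventive = 0,
      cost_restorative = 1500,  # per decayed tooth, 10-y comprehensive mgmt
      cost_abscess = 1500,      # abscess episode incl. urgent/definitive care
      cost_extraction = 350,
      du_untreated = 0.035,
      du_treated = 0.005,
      du_abscess = 0.08,
      du_tooth_loss = 0.01,     # per missing tooth per year
      discount = 0.03
    ),
    targets = list(
      age_bands = data.frame(
        band = c("2-5", "6-12", "13-19"),
        lo = c(2, 6, 13), hi = c(5, 12, 19),
        target = c(0.213, 0.521, 0.568),
        stringsAsFactors = FALSE
      ),
      hpsa = 0.566,
      non_hpsa = 0.525
    ),
    calibrated = FALSE
  )
  class(p) <- "caries_params"
  p
}

#' Read or write a parameter set as JSON or YAML
#'
#' The on-disk layout mirrors the in-memory list.  YAML support requires
#' the optional `yaml` package; JSON uses `jsonlite`.
#'
#' @param params a `caries_params` object.
#' @param path file path ending in `.json`, `.yaml`, or `.yml`.
#' @return `read_params()` returns a `caries_params` object;
#'   `write_params()` returns `path` invisibly.
#' @export
write_params <- function(params, path) {
  x <- unclass(params)
  x$demography <- list(strata = x$demography$strata,
                       total_population = x$demography$total_population)
  # named vectors become maps on disk so names survive the round trip
  for (sec in c("risk", "baseline", "utilization", "program", "supply",
                "econ")) {
    x[[sec]] <- lapply(x[[sec]], function(v) {
      if (is.atomic(v) && !is.null(names(v))) as.list(v) else v
    })
  }
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required to write YAML configs")
    }
    yaml::write_yaml(x, path, precision = 15)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  }
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required to read YAML configs")
    }
    x <- yaml::read_yaml(path)
  } else {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
  }
  as_caries_params(x)
}

# Rebuild typed structure (named numeric vectors, demography class) from a
# plain nested list as returned by JSON/YAML parsers.
as_caries_params <- function(x) {
  num <- function(v) {
    out <- unlist(v)
    storage.mode(out) <- "double"
    out
  }
  tpl <- default_parameters()
  for (sec in c("risk", "baseline", "utilization", "program", "supply",
                "econ")) {
    for (nm in names(x[[sec]])) {
      v <- x[[sec]][[nm]]
      if (is.character(v) || is.character(unlist(v))) {
        x[[sec]][[nm]] <- as.character(unlist(v))
      } else {
        x[[sec]][[nm]] <- if (is.list(v) || length(v) > 1) num(v) else
          as.numeric(v)
      }
    }
    miss <- setdiff(names(tpl[[sec]]), names(x[[sec]]))
    x[[sec]][miss] <- tpl[[sec]][miss]
  }
  st <- as.data.frame(x$demography$strata, stringsAsFactors = FALSE)
  x$demography <- structure(
    list(strata = st, total_population = as.numeric(x$demography$total_population)),
    class = "caries_demography"
  )
  validate_demography(x$demography)
  x$targets$age_bands <- as.data.frame(x$targets$age_bands,
                                       stringsAsFactors = FALSE)
  x$calibrated <- isTRUE(x$calibrated)
  class(x) <- "caries_params"
  x
}

# Dotted-path access into a parameter set, e.g. "econ.cost_restorative"
# or "risk.p_abscess".  Used by the sensitivity machinery.
get_param <- function(params, path) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  v <- params
  for (k in keys) v <- v[[k]]
  v
}

set_param <- function(params, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (length(keys) == 1) {
    params[[keys]] <- value
  } else if (length(keys) == 2) {
    params[[keys[1]]][[keys[2]]] <- value
  } else {
    params[[keys[1]]][[keys[2]]][[keys[3]]] <- value
  }
  params
}

#' @export
print.caries_params <- function(x, ...) {
  cat("<caries_params>\n")
  cat("  strata:", nrow(x$demography$strata),
      "| children represented:", format(x$demography$total_population,
                                        big.mark = ","), "\n")
  cat("  HPSA child population:", format(hpsa_population(x$demography),
                                         big.mark = ","), "\n")
  cat("  calibrated:", x$calibrated, "\n")
  invisible(x)
}
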