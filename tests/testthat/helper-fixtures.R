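# Shared fixtures, all built in code.

# single- or few-stratum demography for focused tests
make_demography <- function(props, total_population = 1e6,
                            age_group = "6-12", hpsa = "none") {
  n <- length(props)
  st <- data.frame(
    stratum = paste0("s", seq_len(n)),
    age_group = rep_len(age_group, n),
    sex = rep_len(c("female", "male"), n),
    race = rep_len(c("White", "Hispanic", "Black"), n),
    income = rep_len(c("high", "low", "middle"), n),
    residence = rep_len(c("urban", "rural"), n),
    hpsa = rep_len(hpsa, n),
    proportion = props,
    stringsAsFactors = FALSE
  )
  structure(list(strata = st, total_population = total_population),
            class = "caries_demography")
}

# a risk model with every term zeroed (annual caries prob = plogis(0) = 0.5
# for children; adult reference set separately)
zero_risk <- function() {
  list(
    intercept = c("0-5" = 0, "6-12" = 0, "13-19" = 0),
    sex = c(female = 0, male = 0),
    race = c(Hispanic = 0, Black = 0, White = 0),
    income = c(low = 0, middle = 0, high = 0),
    residence = c(urban = 0, rural = 0),
    hpsa = c(whole = 0, partial = 0, none = 0),
    calibration = c("0-5" = 0, "6-12" = 0, "13-19" = 0),
    hpsa_calibration = 0,
    secular_trend = 0,
    age_shape = rep(0, 20),
    p_caries_adult = 0.5,
    p_untreated_no_care = 0.5,
    p_untreated_care = 0.1,
    p_abscess = 0,
    p_tooth_loss = 0,
    mortality = rep(0, 30)
  )
}

# parameter set with controllable disease mechanics and no mortality
test_params <- function(intercepts = c(-60, -60, -60), p_untreated = 0,
                        p_abscess = 0, p_tooth_loss = 0,
                        baseline_prev = 0, untreated_share = 0) {
  p <- default_parameters()
  p$risk <- zero_risk()
  p$risk$intercept[] <- intercepts
  p$risk$p_caries_adult <- stats::plogis(intercepts[3])
  p$risk$p_untreated_no_care <- p_untreated
  p$risk$p_untreated_care <- p_untreated
  p$risk$p_abscess <- p_abscess
  p$risk$p_tooth_loss <- p_tooth_loss
  p$baseline$prevalence_curve[] <- baseline_prev
  p$baseline$race_or[] <- 1
  p$baseline$hpsa_or[] <- 1
  p$baseline$untreated_share <- untreated_share
  p
}

make_pop <- function(n, params = default_parameters(), seed = 1,
                     baseline = TRUE) {
  pop <- generate_population(n, params$demography, seed)
  if (baseline) pop <- assign_baseline_states(pop, params, seed + 1000)
  pop
}

# mark a parameter set calibrated without running the (slow) search;
# used by engine tests that exercise structure, not calibration
mark_calibrated <- function(params) {
  params$calibrated <- TRUE
  params
}

# minimal caries_result stubs for incremental() arithmetic tests
fake_result <- function(qaly, cost, prevalence = 0.5, incidence = 0,
                        fingerprint = 1L, disease_seed = 1L,
                        label = "fake") {
  structure(list(
    hpsa = list(prevalence = prevalence, incidence = incidence,
                cost_treatment = cost, qaly = qaly, cost_total = cost),
    scenario = list(label = label),
    fingerprint = fingerprint, disease_seed = disease_seed
  ), class = "caries_result")
}
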