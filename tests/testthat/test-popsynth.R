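test_that("degenerate demography puts everyone in the single stratum", {
  demo <- make_demography(1)
  pop <- generate_population(10000, demo, seed = 1)
  expect_equal(nrow(pop), 10000)
  expect_true(all(pop$stratum == "s1"))
  expect_true(all(pop$age >= 6 & pop$age <= 12))
})

test_that("largest-remainder quotas track proportions within one unit", {
  demo <- make_demography(c(0.3, 0.7))
  pop <- generate_population(100000, demo, seed = 7)
  counts <- table(pop$stratum)
  # deterministic quotas are tighter than the binomial 3-SD bound
  expect_lte(abs(counts[["s1"]] - 30000), 1)
  expect_lte(abs(counts[["s2"]] - 70000), 1)
  expect_lte(abs(counts[["s1"]] - 30000), 3 * sqrt(100000 * 0.3 * 0.7))
})

test_that("weights conserve the configured populations", {
  demo <- default_demography()
  pop <- generate_population(20000, demo, seed = 3)
  expect_equal(sum(pop$weight), demo$total_population, tolerance = 1e-9)
  w_hpsa <- sum(pop$weight[pop$hpsa != "none"])
  expect_equal(w_hpsa, 14.7e6, tolerance = 1e-9)
  expect_equal(hpsa_population(demo), 14.7e6, tolerance = 1e-9)
})

test_that("generation is byte-identical under a repeated seed", {
  demo <- default_demography()
  expect_identical(generate_population(5000, demo, seed = 9),
                   generate_population(5000, demo, seed = 9))
  p1 <- generate_population(5000, demo, seed = 9)
  p2 <- generate_population(5000, demo, seed = 10)
  expect_false(identical(p1$age, p2$age))
})

test_that("invalid demography is rejected with the offending stratum named", {
  demo <- make_demography(c(0.5, 0.5))
  demo$strata$proportion <- c(-0.1, 1.1)
  expect_error(generate_population(100, demo, 1), "s1")
  demo2 <- make_demography(c(0.5, 0.4))
  expect_error(validate_demography(demo2), "sum")
  demo3 <- make_demography(c(0.5, 0.5))
  demo3$strata$stratum <- c("a", "a")
  expect_error(validate_demography(demo3), "duplicated")
})

test_that("ages are uniform integers over the group's years", {
  demo <- make_demography(1, age_group = "0-5")
  pop <- generate_population(30000, demo, seed = 2)
  tab <- table(factor(pop$age, levels = 0:5))
  expect_true(all(tab > 0))
  # each year should hold about 1/6 of the draws
  expect_lt(max(abs(tab / 30000 - 1 / 6)), 0.02)
})

test_that("baseline assignment honours degenerate targets", {
  params0 <- test_params(baseline_prev = 0)
  pop <- make_pop(2000, params0, seed = 4, baseline = FALSE)
  pop0 <- assign_baseline_states(pop, params0, seed = 5)
  expect_true(all(!pop0$ever_caries))
  expect_true(all(pop0$caries_events == 0L))

  params1 <- test_params(baseline_prev = 1, untreated_share = 1)
  pop1 <- assign_baseline_states(pop, params1, seed = 5)
  expect_true(all(pop1$ever_caries))
  expect_true(all(pop1$untreated))
  expect_true(all(pop1$caries_events == 1L))
})

test_that("baseline prevalence matches its Poisson-binomial oracle", {
  params <- default_parameters()
  pop <- make_pop(50000, params, seed = 6, baseline = FALSE)
  pop <- assign_baseline_states(pop, params, seed = 60)
  sel <- pop$age >= 2 & pop$age <= 5
  # oracle: recompute each child's assignment probability directly
  bl <- params$baseline
  p0 <- unname(bl$prevalence_curve[as.character(pop$age[sel])])
  odds <- p0 / (1 - p0) * bl$race_or[pop$race[sel]] * bl$hpsa_or[pop$hpsa[sel]]
  p <- odds / (1 + odds)
  observed <- sum(pop$ever_caries[sel])
  expect_lt(abs(observed - sum(p)), 3 * sqrt(sum(p * (1 - p))))
  # and the packaged curve itself averages to the 2-5y prevalence target
  expect_equal(mean(bl$prevalence_curve[as.character(2:5)]), 0.213,
               tolerance = 0.01)
})

test_that("baseline assignment rejects missing targets", {
  params <- default_parameters()
  params$baseline$prevalence_curve <-
    params$baseline$prevalence_curve[as.character(0:18)]
  demo19 <- make_demography(1, age_group = "13-19")
  pop <- generate_population(200, demo19, 1)
  expect_error(assign_baseline_states(pop, params, 1), "age 19")
})

test_that("populations survive a CSV round trip", {
  pop <- make_pop(200, seed = 8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_population(pop, path)
  back <- read_population(path)
  expect_equal(back$age, pop$age)
  expect_equal(back$weight, pop$weight)
  expect_equal(back$ever_caries, pop$ever_caries)
})

test_that("parameter sets survive JSON and YAML round trips", {
  params <- default_parameters()
  for (ext in c(".json", ".yaml")) {
    path <- withr::local_tempfile(fileext = ext)
    write_params(params, path)
    back <- read_params(path)
    expect_equal(back$risk$intercept, params$risk$intercept)
    expect_equal(back$econ$cost_restorative, params$econ$cost_restorative)
    expect_equal(back$program$awards, params$program$awards)
    expect_identical(back$program$budget_ramp, "linear")
    expect_equal(back$demography$strata$proportion,
                 params$demography$strata$proportion)
  }
})
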