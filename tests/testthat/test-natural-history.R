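test_that("annual caries probability is the inverse-logit of the linear predictor", {
  pop <- data.frame(age = 8L, age0 = 8L, sex = "male", race = "White",
                    income = "high", residence = "urban", hpsa = "none")
  risk <- zero_risk()
  expect_equal(annual_caries_prob(pop, risk), 0.5)

  risk$intercept[] <- stats::qlogis(0.2)
  expect_equal(annual_caries_prob(pop, risk), 0.2)

  # protective supply shift of ln(0.46): hand-computed logit arithmetic
  expected <- 1 / (1 + exp(-(stats::qlogis(0.2) + log(0.46))))
  expect_equal(annual_caries_prob(pop, risk, supply_shift = log(0.46)),
               expected)
  expect_lt(expected, 0.2)
  # monotone decreasing in the (protective) shift
  shifts <- seq(0, -2, by = -0.25)
  ps <- vapply(shifts, function(s) annual_caries_prob(pop, risk, s),
               numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("a zero-risk cycle only advances age", {
  params <- test_params() # all probabilities 0
  pop <- make_pop(500, params, seed = 1)
  st <- step_population(pop, params, cycle = 0, seed = 9)
  expect_equal(st$pop$age, pop$age + 1L)
  expect_identical(st$pop$caries_events, pop$caries_events)
  expect_identical(st$pop$untreated, pop$untreated)
  expect_identical(st$pop$abscesses, pop$abscesses)
  expect_true(all(st$pop$alive))
  expect_equal(sum(st$events$new_event), 0)
})

test_that("forced transitions follow the published event order", {
  params <- test_params(intercepts = c(60, 60, 60), p_untreated = 1,
                        p_abscess = 1, p_tooth_loss = 1)
  pop <- make_pop(300, params, seed = 2)
  st <- step_population(pop, params, cycle = 0, seed = 9)
  expect_true(all(st$pop$caries_events == pop$caries_events + 1L))
  expect_true(all(st$pop$untreated))
  # complications are drawn on prevalent untreated caries after assignment
  expect_true(all(st$pop$abscesses == 1L))
  expect_true(all(st$pop$teeth_lost == 1L))
})

test_that("incidence matches its binomial oracle", {
  params <- test_params(intercepts = rep(stats::qlogis(0.3), 3))
  pop <- make_pop(10000, params, seed = 3)
  st <- step_population(pop, params, cycle = 0, seed = 11)
  observed <- sum(st$events$new_event)
  expect_lt(abs(observed - 10000 * 0.3), 3 * sqrt(10000 * 0.3 * 0.7))
})

test_that("counters are monotone and bounded over many cycles", {
  params <- test_params(intercepts = rep(stats::qlogis(0.25), 3),
                        p_untreated = 0.6, p_abscess = 0.3,
                        p_tooth_loss = 0.4, baseline_prev = 0.3,
                        untreated_share = 0.5)
  pop <- make_pop(1000, params, seed = 4)
  for (t in 0:19) {
    st <- step_population(pop, params, cycle = t, seed = 21)
    expect_true(all(st$pop$caries_events >= pop$caries_events))
    expect_true(all(st$pop$abscesses >= pop$abscesses))
    expect_true(all(st$pop$teeth_lost >= pop$teeth_lost))
    expect_true(all(st$pop$teeth_lost <= st$pop$caries_events))
    expect_true(all(st$pop$abscesses <= st$pop$caries_events))
    pop <- st$pop
  }
})

test_that("a protective supply shift never increases incidence under CRN", {
  params <- test_params(intercepts = rep(stats::qlogis(0.2), 3))
  pop0 <- make_pop(2000, params, seed = 5)
  totals <- vapply(1:20, function(s) {
    run <- function(shift) {
      pop <- pop0
      for (t in 0:4) {
        pop <- step_population(pop, params, t, derive_seed(500, s),
                               supply_shift = shift)$pop
      }
      sum(pop$events_sim)
    }
    c(run(0), run(-0.5))
  }, numeric(2))
  # per-seed threshold coupling makes the comparison individually monotone
  expect_true(all(totals[2, ] <= totals[1, ]))
  expect_lt(mean(totals[2, ]), mean(totals[1, ]))
})

test_that("zero shifts reproduce the status-quo trajectory exactly", {
  params <- mark_calibrated(default_parameters())
  pop <- make_pop(1500, params, seed = 6)
  a <- cariesim:::simulate_cohort(pop, params, 5, disease_seed = 31,
                                  shift_schedule = NULL)
  sched0 <- data.frame(year = rep(0:4, 2),
                       hpsa = rep(c("whole", "partial"), each = 5),
                       util_shift = 0, logor_shift = 0)
  b <- cariesim:::simulate_cohort(pop, params, 5, disease_seed = 31,
                                  shift_schedule = sched0)
  expect_identical(a$overall, b$overall)
  expect_identical(a$by_year, b$by_year)
})

test_that("calibration is a fixed point at self-consistent targets", {
  params <- default_parameters()
  fit1 <- calibrate_model(params, n = 4000, horizon = 5, pop_seed = 41,
                          disease_seed = 42, tol = 0.004, max_residual = 0.2)
  rep1 <- attr(fit1, "calibration_report")
  # re-target the model at exactly what it achieves: multipliers stay put
  fit1$targets$age_bands$target <- rep1$achieved[1:3]
  fit1$targets$hpsa <- rep1$achieved[4]
  fit1$targets$non_hpsa <- rep1$achieved[5]
  fit2 <- calibrate_model(fit1, n = 4000, horizon = 5, pop_seed = 41,
                          disease_seed = 42, tol = 0.004, max_residual = 0.2)
  expect_equal(attr(fit2, "calibration_delta"), 0)
  expect_equal(fit2$risk$calibration, fit1$risk$calibration,
               tolerance = 0.15)
  expect_equal(attr(fit2, "calibration_report")$achieved, rep1$achieved,
               tolerance = 0.005)
})

test_that("calibration rejects unreachable targets with diagnostics", {
  params <- default_parameters()
  params$targets$age_bands$target <- c(0.9995, 0.9995, 0.9995)
  params$targets$hpsa <- 0.9995
  params$targets$non_hpsa <- 0.0005
  expect_error(
    calibrate_model(params, n = 1500, horizon = 3, tol = 0.003,
                    max_iter = 12, outer = 1, balance = FALSE),
    "did not converge"
  )
})
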