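mini_dists <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(name = r[[1]], path = r[[2]], family = r[[3]],
               central = as.numeric(r[[4]]), low = as.numeric(r[[5]]),
               high = as.numeric(r[[6]]), one_way = TRUE,
               stringsAsFactors = FALSE)
  }))
}

test_that("the packaged distribution table has nine one-way parameters", {
  d <- param_distributions()
  expect_equal(sum(d$one_way), 9)
  expect_true(all(d$family %in% c("beta", "gamma", "lognormal")))
  expect_true(all(d$low <= d$central & d$central <= d$high))
})

test_that("bounds outside a parameter's domain are rejected by name", {
  bad <- mini_dists(list("Retention", "program.retention", "beta", 0.6,
                         0.2, 1.4))
  expect_error(cariesim:::check_bounds(bad), "Retention")
  badlog <- mini_dists(list("OR", "supply.caries_or", "lognormal", 0.46,
                            0, 0.9))
  expect_error(cariesim:::check_bounds(badlog), "OR")
})

test_that("sampled parameters respect their domains", {
  params <- default_parameters()
  d <- param_distributions(params)
  draws <- sample_params(params, d, 60, seed = 2)
  for (i in seq_len(nrow(d))) {
    vals <- vapply(draws, function(p) cariesim:::get_param(p, d$path[i]),
                   numeric(1))
    if (d$family[i] == "beta") expect_true(all(vals >= 0 & vals <= 1))
    if (d$family[i] == "gamma") expect_true(all(vals >= 0))
    if (d$family[i] == "lognormal") expect_true(all(vals > 0))
    # dispersion roughly the intended +/-20% scale, and not degenerate
    if (d$central[i] > 0) {
      expect_gt(stats::sd(vals) / d$central[i], 0.02)
      expect_lt(stats::sd(vals) / d$central[i], 0.35)
    }
  }
  expect_identical(sample_params(params, d, 3, seed = 9),
                   sample_params(params, d, 3, seed = 9))
})

params_cal <- mark_calibrated(default_parameters())
pop_small <- make_pop(1500, params_cal, seed = 61)
sc_fast <- scenario_config("g10", growth = 0.10, horizon = 4)

test_that("degenerate one-way bounds give zero spread", {
  d <- mini_dists(list("Fixed cost", "econ.cost_restorative", "gamma",
                       1500, 1500, 1500))
  tab <- one_way(params_cal, d, scenario = sc_fast, pop = pop_small,
                 disease_seed = 71)
  expect_equal(tab$spread, 0)
  expect_equal(tab$d_cost_low, tab$d_cost_high)
})

test_that("cost parameters cannot move QALYs under common random numbers", {
  d <- mini_dists(
    list("Caries treatment cost", "econ.cost_restorative", "gamma",
         1500, 750, 2250),
    list("Abscess episode cost", "econ.cost_abscess", "gamma",
         1500, 750, 2250)
  )
  tab <- one_way(params_cal, d, scenario = sc_fast, pop = pop_small,
                 disease_seed = 71)
  expect_equal(tab$d_qaly_low, tab$d_qaly_high)
  # treatment cost must move incremental cost (abscess may see no
  # incremental episodes at this small scale)
  rest <- tab$path == "econ.cost_restorative"
  expect_false(tab$d_cost_low[rest] == tab$d_cost_high[rest])
  # and the table is sorted by |spread| on the designated outcome
  expect_true(all(diff(abs(tab$spread)) <= 0))
})

test_that("one-way analysis is reproducible and covers the nine parameters", {
  d <- param_distributions(params_cal)
  t1 <- one_way(params_cal, d, scenario = sc_fast, pop = pop_small,
                disease_seed = 72)
  t2 <- one_way(params_cal, d, scenario = sc_fast, pop = pop_small,
                disease_seed = 72)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 9)
  expect_true(all(is.finite(t1$d_cost_low) & is.finite(t1$d_cost_high)))
})

test_that("PSA is reproducible and summarizes draws by sort-based percentiles", {
  d <- param_distributions(params_cal)
  ps1 <- psa(params_cal, d, n_draws = 12, seed = 4, scenario = sc_fast,
             n = 800, pop_seed = 62)
  ps2 <- psa(params_cal, d, n_draws = 12, seed = 4, scenario = sc_fast,
             n = 800, pop_seed = 62)
  expect_identical(ps1$draws, ps2$draws)
  # percentile oracle: plain sort of the draws
  x <- ps1$draws$d_cost
  n <- length(x)
  expect_equal(ps1$summary$lo[ps1$summary$outcome == "d_cost"],
               sort(x)[ceiling(0.025 * n)])
  expect_equal(ps1$summary$hi[ps1$summary$outcome == "d_cost"],
               sort(x)[ceiling(0.975 * n)])
  expect_true(all(ps1$summary$lo <= ps1$summary$mean &
                    ps1$summary$mean <= ps1$summary$hi))
})

test_that("degenerate distributions with fixed disease seeds collapse the interval", {
  d <- param_distributions(params_cal)
  d$family <- "fixed"
  ps <- psa(params_cal, d, n_draws = 6, seed = 5, scenario = sc_fast,
            n = 600, pop_seed = 63, vary_disease_seed = FALSE)
  expect_equal(ps$summary$hi - ps$summary$lo, rep(0, 4))
  expect_equal(stats::sd(ps$draws$d_cost), 0)
})

test_that("the acceptability curve equals its counting oracle", {
  draws <- data.frame(d_qaly = c(0, 0), d_cost = c(-1, 1))
  expect_equal(ceac(draws, 0)$prob_cost_effective, 0.5)

  saving <- data.frame(d_qaly = c(1, 2, 3), d_cost = c(-5, -1, -10))
  expect_equal(ceac(saving, c(0, 1e5))$prob_cost_effective, c(1, 1))

  set.seed(88)
  arb <- data.frame(d_qaly = rnorm(400), d_cost = rnorm(400))
  grid <- c(0, 1, 2, 5)
  got <- ceac(arb, grid)$prob_cost_effective
  oracle <- vapply(grid, function(w) {
    hits <- 0
    for (i in seq_len(nrow(arb))) {
      if (w * arb$d_qaly[i] - arb$d_cost[i] > 0) hits <- hits + 1
    }
    hits / nrow(arb)
  }, numeric(1))
  expect_equal(got, oracle)

  gains <- data.frame(d_qaly = abs(rnorm(200)), d_cost = rnorm(200))
  curve <- ceac(gains, seq(0, 2e5, by = 2.5e4))$prob_cost_effective
  expect_true(all(diff(curve) >= 0))
  expect_error(ceac(gains[0, ], 0), "empty")
})
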