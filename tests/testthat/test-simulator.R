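test_that("the published model reproduces its printed constants", {
  pm <- publishedModel()
  phi <- data.frame(AGE = c(0.2, 0.61, 1), SEX = c(-0.5, 0.5, -0.5),
                    T = c(0, 0.4, 1))
  # constant DKD-to-both map
  f34 <- evalExpression(pm$maps[["3->4"]], phi)
  expect_equal(f34, rep(sigm(-5.88), 3))
  expect_equal(f34[1], 0.0027870, tolerance = 1e-4)
  # state-4 death map at T = 0, AGE = 0
  f45 <- evalExpression(pm$maps[["4->5"]], data.frame(AGE = 0, SEX = 0.5, T = 0))
  expect_equal(f45, sigm(-12.8))
  expect_equal(f45, 2.76e-6, tolerance = 1e-2)
  # both-comorbidity entry map at AGE = 1
  f24 <- evalExpression(pm$maps[["2->4"]], data.frame(AGE = 1, SEX = -0.5, T = 0))
  expect_equal(f24, sigm(-13.69 + 9.08))
  # state-2 death map with the T*AGE interaction
  f25 <- evalExpression(pm$maps[["2->5"]], data.frame(AGE = 0.5, SEX = 0, T = 0.5))
  expect_equal(f25, sigm(-11.64 + 5.87 * 0.5 + 5.56 * 0.25))
  # every map stays inside (0,1) over the covariate box
  withr::local_seed(1)
  grid <- data.frame(AGE = stats::runif(200, 0.17, 1),
                     SEX = sample(c(-0.5, 0.5), 200, TRUE),
                     T = stats::runif(200, 0, 1))
  for (k in names(pm$maps)) {
    v <- evalExpression(pm$maps[[k]], grid)
    expect_true(all(v > 0 & v < 1))
  }
})

test_that("simulation is deterministic and respects absorbing dynamics", {
  pm <- publishedModel()
  cfg <- simulationConfig(n_patients = 150, horizon_months = 36, seed = 9)
  c1 <- simulateCohort(pm, cfg)
  c2 <- simulateCohort(pm, cfg)
  expect_identical(c1$events, c2$events)
  expect_identical(c1$patients, c2$patients)
  # no transitions out of death; event months within horizon
  expect_true(all(c1$events$from_state != 5))
  expect_true(all(c1$events$event_month < 36))
  # a model that never transitions keeps everyone in state 1
  frozen <- pm
  for (k in names(frozen$maps))
    frozen$maps[[k]] <- snnmarkov:::new_expression(quote(sigm(-745)),
                                                   pm$input_names)
  c0 <- simulateCohort(frozen, cfg)
  expect_identical(nrow(c0$events), 0L)
  expect_true(all(c0$final_state == 1L))
})

test_that("monthly exit rates match the generating hazard", {
  # constant monthly death probability of 0.1 and no other transitions:
  # pooled over all at-risk patient-months, the empirical exit fraction is a
  # binomial proportion with success probability 0.1
  pm <- publishedModel()
  const <- pm
  for (k in names(const$maps))
    const$maps[[k]] <- snnmarkov:::new_expression(quote(sigm(-745)), pm$input_names)
  const$maps[["1->5"]] <- snnmarkov:::new_expression(
    substitute(sigm(q), list(q = stats::qlogis(0.1))), pm$input_names)
  cfg <- simulationConfig(n_patients = 1200, horizon_months = 30, seed = 2)
  cohort <- simulateCohort(const, cfg)
  deaths <- cohort$events
  at_risk <- 1200
  exits <- 0; months <- 0
  for (t in 0:29) {
    d_t <- sum(deaths$event_month == t)
    exits <- exits + d_t
    months <- months + at_risk
    at_risk <- at_risk - d_t
  }
  expect_gt(months, 10000)
  p_hat <- exits / months
  se <- sqrt(0.1 * 0.9 / months)
  expect_lt(abs(p_hat - 0.1), 3 * se)
})

test_that("state-5 occupancy is nondecreasing in simulated cohorts", {
  pm <- publishedModel()
  cohort <- simulateCohort(pm, simulationConfig(n_patients = 400,
                                                horizon_months = 60, seed = 11))
  deaths <- cohort$events[cohort$events$to_state == 5, ]
  cum_dead <- vapply(0:59, function(t) sum(deaths$event_month <= t), 0)
  expect_true(all(diff(cum_dead) >= 0))
})

test_that("censoring converts events per the assessment schedule", {
  pm <- publishedModel()
  cfg <- simulationConfig(n_patients = 250, horizon_months = 48,
                          assessment_interval = 12L, seed = 13)
  cohort <- simulateCohort(pm, cfg)
  ds <- applyCensoring(cohort, cfg, pm)
  obs <- ds$observations
  # death exact, morbidity interval, censoring open
  expect_true(all(obs$obs_kind[!is.na(obs$to_state) & obs$to_state == 5] == "exact"))
  expect_true(all(obs$obs_kind[!is.na(obs$to_state) & obs$to_state != 5] == "interval"))
  # intervals bracket the true event month
  truth <- cohort$events
  iv <- obs[obs$obs_kind == "interval", ]
  for (i in seq_len(nrow(iv))) {
    tr <- truth[truth$patient_id == iv$patient_id[i] &
                  truth$entry_month == iv$entry_month[i], ]
    k_e <- tr$event_month - tr$entry_month
    expect_gte(k_e, iv$k1_star[i])
    expect_lte(k_e, iv$k2_star[i])
    expect_lte(iv$k2_star[i] - iv$k1_star[i], 12)
  }
  # a dataset produced by censoring always validates
  expect_s3_class(ds, "snnm_dataset")
})

test_that("monthly assessments degenerate intervals to a single month", {
  pm <- publishedModel()
  cfg <- simulationConfig(n_patients = 300, horizon_months = 36,
                          assessment_interval = 1L, seed = 14)
  ds <- simulateDataset(pm, cfg)
  iv <- ds$observations[ds$observations$obs_kind == "interval", ]
  expect_gt(nrow(iv), 0)
  expect_true(all(iv$k1_star == iv$k2_star))
})

test_that("censoring beyond the horizon leaves the event set unchanged", {
  pm <- publishedModel()
  far <- censoringMixture(0, 1 / 30, gamma_shape = 50, gamma_scale = 1000)
  cfg <- simulationConfig(n_patients = 200, horizon_months = 36,
                          censoring = far, seed = 15)
  cohort <- simulateCohort(pm, cfg)
  ds <- applyCensoring(cohort, cfg, pm)
  n_events_obs <- sum(!is.na(ds$observations$to_state))
  expect_identical(n_events_obs, nrow(cohort$events))
})

test_that("the censored fraction matches the competing-risk expectation", {
  # exponential-only censoring, rate 1/24, against a constant death hazard:
  # censoring escapes death when the exponential clock fires first
  pm <- publishedModel()
  lam <- 0.05
  const <- pm
  for (k in names(const$maps))
    const$maps[[k]] <- snnmarkov:::new_expression(quote(sigm(-745)), pm$input_names)
  const$maps[["1->5"]] <- snnmarkov:::new_expression(
    substitute(sigm(q), list(q = stats::qlogis(lam))), pm$input_names)
  cfg <- simulationConfig(n_patients = 4000, horizon_months = 2000,
                          censoring = censoringMixture(1, 1 / 24, 1, 1),
                          seed = 16)
  ds <- simulateDataset(const, cfg)
  obs <- ds$observations
  censored <- is.na(obs$to_state)
  # P(censored) = E[(1-lam)^floor(C)] over C ~ Exp(1/24)
  pc <- integrate(function(c) (1 - lam)^floor(c) * dexp(c, 1 / 24),
                  0, Inf, subdivisions = 2000)$value
  se <- sqrt(pc * (1 - pc) / nrow(obs))
  expect_lt(abs(mean(censored) - pc), 3 * se)
})

test_that("simulated datasets round-trip through the data model", {
  pm <- publishedModel()
  ds <- simulateDataset(pm, simulationConfig(n_patients = 60,
                                             horizon_months = 24, seed = 17))
  dir <- withr::local_tempdir()
  writeDataset(ds, dir)
  ds2 <- readDataset(dir)
  expect_equal(ds2$observations, ds$observations)
  expect_equal(ds2$covariates, ds$covariates)
})
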