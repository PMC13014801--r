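# Uncensored cohort with exact (monthly-assessed) morbidity events, for
# oracle comparisons against empirical state fractions.
uncensored_dataset <- function(n = 200, horizon = 40, seed = 21) {
  pm <- publishedModel()
  far <- censoringMixture(0, 1 / 30, gamma_shape = 50, gamma_scale = 1000)
  cfg <- simulationConfig(n_patients = n, horizon_months = horizon,
                          censoring = far, assessment_interval = 1L,
                          seed = seed)
  simulateDataset(pm, cfg)
}

empirical_occupancy <- function(ds, grid) {
  truth <- attr(ds, "truth")
  t(vapply(grid, function(t) {
    s <- vapply(ds$patients$patient_id, function(id) {
      tr <- truth[truth$patient_id == id & truth$event_month < t, ]
      if (!nrow(tr)) 1L else tr$to_state[nrow(tr)]
    }, 1L)
    tabulate(s, 5) / length(s)
  }, numeric(5)))
}

test_that("Aalen-Johansen equals empirical proportions without censoring", {
  ds <- uncensored_dataset(n = 200)
  grid <- seq(0, 40, by = 4)
  aj <- aalenJohansen(ds, grid)
  expect_equal(aj$pstate, empirical_occupancy(ds, grid), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("a cohort that never leaves state 1 has constant occupancy", {
  obs <- data.frame(patient_id = sprintf("s%03d", 1:40), from_state = 1L,
                    to_state = NA_integer_, obs_kind = "censored",
                    k_star = 60L, k1_star = NA_integer_, k2_star = NA_integer_,
                    entry_month = 0L)
  pats <- data.frame(patient_id = obs$patient_id, AGE = 60, SEX = "Man")
  ds <- normalizeDataset(pats, default_specs(), obs)
  aj <- aalenJohansen(ds, c(0, 12, 24, 48))
  expect_equal(aj$pstate[, 1], rep(1, 4))
  expect_equal(rowSums(aj$pstate), rep(1, 4))
})

test_that("censoring at the origin is non-informative for the estimator", {
  ds <- uncensored_dataset(n = 120, seed = 23)
  grid <- seq(0, 36, by = 6)
  aj_full <- aalenJohansen(ds, grid)
  # add a shadow cohort censored at month 0
  extra <- data.frame(patient_id = sprintf("z%03d", 1:120), from_state = 1L,
                      to_state = NA_integer_, obs_kind = "censored",
                      k_star = 0L, k1_star = NA_integer_, k2_star = NA_integer_,
                      entry_month = 0L)
  pats2 <- rbind(ds$patients,
                 data.frame(patient_id = extra$patient_id, AGE = 50, SEX = "Man"))
  ds2 <- normalizeDataset(pats2, ds$specs, rbind(ds$observations, extra),
                          max_state_times = ds$max_state_times)
  aj2 <- aalenJohansen(ds2, grid)
  expect_equal(aj2$pstate, aj_full$pstate, tolerance = 1e-12)
})

test_that("EM recovers the censoring mixture and increases the likelihood", {
  withr::local_seed(31)
  truth <- censoringMixture(0.4, 1 / 12, gamma_shape = 4, gamma_scale = 10)
  x <- rCensoring(5000, truth)
  fit <- fitCensoringMixture(x)
  expect_lt(abs(fit$weight - 0.4) / 0.4, 0.1)
  expect_lt(abs(fit$exp_rate - 1 / 12) / (1 / 12), 0.1)
  expect_lt(abs(fit$gamma_shape - 4) / 4, 0.1)
  expect_lt(abs(fit$gamma_scale - 10) / 10, 0.1)
  ll <- attr(fit, "loglik")
  expect_true(all(diff(ll) > -1e-8))
})

test_that("pure exponential censoring data pushes the weight toward one", {
  withr::local_seed(32)
  x <- stats::rexp(3000, 1 / 20)
  fit <- fitCensoringMixture(x)
  # either the exponential component dominates or the gamma component mimics
  # an exponential (shape near 1)
  expect_true(fit$weight > 0.8 || abs(fit$gamma_shape - 1) < 0.25)
  expect_error(fitCensoringMixture(x[1:5]), "at least 10")
})

test_that("Brier score reproduces closed-form toy values", {
  # perfect, half-right and maximally wrong one-hot predictions
  y <- c(1, 0, 0, 0, 0)
  expect_equal(sum((y - c(1, 0, 0, 0, 0))^2), 0)
  expect_equal(sum((y - c(0.5, 0.5, 0, 0, 0))^2), 0.5)
  expect_equal(sum((y - c(0, 1, 0, 0, 0))^2), 2)
  # and the dataset-level implementation stays within [0, 2]
  ds <- uncensored_dataset(n = 60, horizon = 24, seed = 25)
  bs <- brierScore(publishedModel(), ds, t = 12)
  expect_true(all(bs$per_individual$brier >= 0 & bs$per_individual$brier <= 2))
  expect_equal(bs$mean, mean(bs$per_individual$brier))
  expect_identical(bs$n_excluded, 0L)
})

test_that("pseudo-observations follow the jackknife identity", {
  expect_equal(drop(pseudoObservations(rep(0.5, 5),
                                       matrix(0.45, 10, 5))[1, ]),
               rep(10 * 0.5 - 9 * 0.45, 5))
  # loo equal to full -> every pseudo-observation equals the full estimate
  loo <- matrix(rep(c(0.7, 0.1, 0.1, 0.05, 0.05), each = 8), 8, 5)
  ps <- pseudoObservations(c(0.7, 0.1, 0.1, 0.05, 0.05), loo)
  expect_equal(ps, loo)
  # without censoring the pseudo-observations average back exactly
  ds <- uncensored_dataset(n = 80, horizon = 24, seed = 26)
  jk <- jackknifeOccupancy(ds, 12)
  ps2 <- pseudoObservations(jk$full, jk$loo)
  expect_equal(colMeans(ps2), jk$full, tolerance = 1e-10)
})

test_that("KL divergence matches closed forms and flags impossible support", {
  P <- rbind(c(1, 0, 0, 0, 0), c(1, 0, 0, 0, 0), c(0.2, 0.2, 0.2, 0.2, 0.2))
  Q <- rbind(c(1, 0, 0, 0, 0) * 0.5 + c(0, 1, 0, 0, 0) * 0.5,
             rep(0.2, 5), rep(0.2, 5))
  kl <- klDivergence(P, Q)
  expect_equal(kl$per_individual[1], log(2), tolerance = 1e-12)
  expect_equal(kl$per_individual[2], log(5), tolerance = 1e-12)
  expect_equal(kl$per_individual[3], 0, tolerance = 1e-12)
  expect_identical(kl$n_clamped, 0L)
  # zero predicted mass where pseudo-mass exists
  kl2 <- klDivergence(rbind(c(1, 0, 0, 0, 0)), rbind(c(0, 1, 0, 0, 0)))
  expect_identical(kl2$per_individual[1], Inf)
  # clamping counts out-of-range pseudo-observations
  kl3 <- klDivergence(rbind(c(1.1, -0.1, 0, 0, 0)), rbind(rep(0.2, 5)))
  expect_identical(kl3$n_clamped, 2L)
})

test_that("an evaluation report assembles both metrics", {
  ds <- uncensored_dataset(n = 50, horizon = 24, seed = 27)
  rep <- evalReport(publishedModel(), ds, t = 12)
  expect_s3_class(rep, "snnm_eval_report")
  expect_true(rep$brier$mean >= 0 && rep$brier$mean <= 2)
  expect_true(is.finite(rep$kl$mean))
  expect_output(print(rep), "Brier")
})

test_that("a single-replicate VPC band collapses to that replicate's curve", {
  pm <- publishedModel()
  ds <- simulateDataset(pm, simulationConfig(n_patients = 80,
                                             horizon_months = 24, seed = 28))
  vpc <- simulateVpc(pm, ds, time_grid = seq(0, 24, by = 6), n_sim = 1,
                     n_boot = 10, seed = 3)
  expect_equal(vpc$band_min, vpc$band_max)
  expect_equal(vpc$band_lower, vpc$band_upper)
})

test_that("censoring mass far beyond the horizon leaves VPC bands unchanged", {
  pm <- publishedModel()
  ds <- simulateDataset(pm, simulationConfig(n_patients = 60,
                                             horizon_months = 24, seed = 29))
  far1 <- censoringMixture(0, 1, gamma_shape = 50, gamma_scale = 1000)
  far2 <- censoringMixture(0, 1, gamma_shape = 500, gamma_scale = 1000)
  grid <- seq(0, 24, by = 6)
  v1 <- simulateVpc(pm, ds, grid, n_sim = 5, mixture = far1, n_boot = 5, seed = 7)
  v2 <- simulateVpc(pm, ds, grid, n_sim = 5, mixture = far2, n_boot = 5, seed = 7)
  expect_equal(v1$band_min, v2$band_min)
  expect_equal(v1$band_max, v2$band_max)
})
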