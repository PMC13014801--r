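obs_exact <- function(k) list(obs_kind = "exact", k_star = k)
obs_cens <- function(k) list(obs_kind = "censored", k_star = k)
obs_int <- function(k1, k2) list(obs_kind = "interval", k1_star = k1, k2_star = k2)

test_that("constant-hazard log-likelihoods match hand evaluations", {
  expect_equal(sojournLoglikConst(0.1, 0.1, obs_exact(3)),
               log(0.1) + 3 * log(0.9))
  expect_equal(sojournLoglikConst(0.1, 0.1, obs_exact(3)), -2.61867,
               tolerance = 1e-5)
  expect_equal(sojournLoglikConst(0.1, 0.1, obs_int(1, 2)),
               log(0.09 + 0.081))
  expect_equal(sojournLoglikConst(0.1, 0.1, obs_int(1, 2)), -1.76609,
               tolerance = 1e-5)
  expect_identical(sojournLoglikConst(0.1, 0.1, obs_cens(0)), 0)
})

test_that("time-varying log-likelihoods match hand evaluations", {
  expect_equal(sojournLoglikTv(c(0.1, 0.2), c(0.1, 0.2), obs_exact(1)),
               log(0.2) + log(0.9))
  expect_equal(sojournLoglikTv(c(0.1, 0.2), c(0.1, 0.2), obs_exact(1)),
               -1.71480, tolerance = 1e-5)
  expect_equal(sojournLoglikTv(c(0.1, 0.1), c(0.1, 0.1), obs_int(0, 1)),
               log(0.1 + 0.09))
  expect_equal(sojournLoglikTv(c(0.1, 0.1), c(0.1, 0.1), obs_int(0, 1)),
               -1.66073, tolerance = 1e-5)
})

test_that("time-varying likelihood reduces to the constant form on constant paths", {
  withr::local_seed(10)
  for (i in 1:1000) {
    rs <- stats::runif(1, 0.01, 0.9)
    lam <- stats::runif(1, 0.001, 1) * rs
    kind <- sample(c("exact", "censored", "interval"), 1)
    if (kind == "interval") {
      k1 <- sample(0:10, 1); k2 <- k1 + sample(0:8, 1)
      obs <- obs_int(k1, k2); n <- k2 + 1
    } else {
      k <- sample(0:15, 1)
      obs <- if (kind == "exact") obs_exact(k) else obs_cens(k)
      n <- max(k + 1, 1)
    }
    expect_equal(sojournLoglikTv(rep(lam, n), rep(rs, n), obs),
                 sojournLoglikConst(lam, rs, obs), tolerance = 1e-12)
  }
})

test_that("an exact event equals a degenerate interval", {
  withr::local_seed(11)
  for (i in 1:50) {
    rs <- stats::runif(1, 0.05, 0.6)
    lam <- stats::runif(1, 0.1, 1) * rs
    k <- sample(0:12, 1)
    n <- k + 1
    path_l <- stats::runif(n, 0.01, 0.3)
    path_rs <- pmin(path_l + stats::runif(n, 0, 0.3), 0.95)
    expect_equal(sojournLoglikTv(path_l, path_rs, obs_exact(k)),
                 sojournLoglikTv(path_l, path_rs, obs_int(k, k)),
                 tolerance = 1e-12)
  }
})

test_that("probabilities of all possible outcomes sum to one", {
  # destinations at each month k <= K plus survival past K exhaust the sample
  # space of one sojourn under any valid hazard path
  withr::local_seed(12)
  for (rep in 1:20) {
    K <- sample(3:12, 1)
    lam1 <- stats::runif(K + 1, 0.01, 0.25)
    lam2 <- stats::runif(K + 1, 0.01, 0.25)
    rs <- lam1 + lam2
    total <- 0
    for (k in 0:K) {
      total <- total + exp(sojournLoglikTv(lam1, rs, obs_exact(k)))
      total <- total + exp(sojournLoglikTv(lam2, rs, obs_exact(k)))
    }
    surv <- sum(log1p(-rs))
    total <- total + exp(surv)
    expect_equal(total, 1, tolerance = 1e-10)
  }
})

test_that("degenerate zero-probability events are flagged with -Inf", {
  expect_warning(ll <- sojournLoglikTv(c(0, 0), c(0.1, 0.1), obs_exact(1)),
                 "degenerate")
  expect_identical(ll, -Inf)
})

test_that("dataset likelihood decomposes into per-observation closed forms", {
  ds <- single_map_dataset(60, seed = 21, b0 = -2.5, b1 = 3)
  model <- publishedModel()
  # replace the state-4 map by a known constant-in-T expression
  model$maps[["4->5"]] <- snnmarkov:::new_expression(
    quote(sigm(-2.5 + 3 * AGE)), model$input_names)
  got <- datasetNegLoglik(model, ds)
  lam <- sigm(-2.5 + 3 * ds$covariates[ds$observations$patient_id, "AGE"])
  # age advances within the sojourn, so use the full path per observation
  manual <- 0
  for (i in seq_len(nrow(ds$observations))) {
    o <- ds$observations[i, ]
    age0 <- ds$patients$AGE[match(o$patient_id, ds$patients$patient_id)]
    n <- if (o$obs_kind == "exact") o$k_star + 1 else max(o$k_star, 1)
    kk <- seq_len(n) - 1
    path <- sigm(-2.5 + 3 * (age0 + kk / 12) / 102.07)
    manual <- manual - sojournLoglikTv(path, path, o)
  }
  expect_equal(got, manual, tolerance = 1e-10)
})

test_that("maximum likelihood recovers a scalar monthly hazard", {
  # 50,000 geometric sojourns at lambda = 0.05, fit by minimizing the loss
  withr::local_seed(13)
  n <- 50000
  k <- stats::rgeom(n, 0.05)
  nll <- function(lam) -sum(log(lam) + k * log(1 - lam))
  fit <- stats::optimize(nll, c(1e-4, 0.5))
  se <- sqrt(0.05^2 * (1 - 0.05) / n)  # asymptotic SE of the geometric MLE
  expect_lt(abs(fit$minimum - 0.05), 3 * se)
})

test_that("C++ gradient matches central finite differences away from kinks", {
  withr::local_seed(14)
  pm <- publishedModel()
  ds <- simulateDataset(pm, simulationConfig(n_patients = 150,
                                             horizon_months = 36, seed = 3))
  model <- suppressWarnings(initTransitionModel(inputNames(ds), seed = 5,
                                                scale = 0.05))
  # keep the power-unit base away from |z|=0 and rows away from the bound
  for (k in names(model$maps)) {
    m <- model$maps[[k]]
    m$params$b1[4] <- 1
    m$params$b3 <- -2
    model$maps[[k]] <- m
  }
  layout <- suppressWarnings(snnmarkov:::build_layout(model, ds))
  dsg <- snnmarkov:::attach_offsets(
    snnmarkov:::prepare_likelihood_data(ds, model$input_names), layout)
  theta <- layout$theta * layout$mask
  g <- snnmarkov:::.cpp_negloglik_grad(theta, dsg)
  expect_equal(g$loss, snnmarkov:::.cpp_negloglik(theta, dsg))
  fd <- vapply(seq_along(theta), function(k) {
    h <- 1e-4 * max(1, abs(theta[k]))
    tp <- theta; tp[k] <- tp[k] + h
    tm <- theta; tm[k] <- tm[k] - h
    (snnmarkov:::.cpp_negloglik(tp, dsg) - snnmarkov:::.cpp_negloglik(tm, dsg)) / (2 * h)
  }, 0)
  expect_lt(max(abs(fd - g$grad) / (abs(fd) + 1)), 1e-5)
})
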