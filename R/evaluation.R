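# Model evaluation: nonparametric state occupancy (Aalen-Johansen via the
# survival package), censoring-distribution fitting, visual predictive
# checks, Brier score and Kullback-Leibler divergence on jackknife
# pseudo-observations.

# Resolve a dataset's sojourn records to continuous-time multistate rows
# (id, tstart, tstop, istate, to) usable by survival::survfit. Within each
# patient, sojourns are chained so intervals never overlap: an exact event at
# within-sojourn month k ends the sojourn at duration k + 1; a right
# censoring at k ends it at duration k (dropped when zero); an interval event
# is placed at the interval midpoint (or right endpoint).
resolve_records <- function(dataset, interval_placement = c("midpoint", "right")) {
  interval_placement <- match.arg(interval_placement)
  obs <- dataset$observations
  obs <- obs[order(obs$patient_id, obs$entry_month), , drop = FALSE]
  dur <- ifelse(obs$obs_kind == "exact", obs$k_star + 1,
         ifelse(obs$obs_kind == "censored", obs$k_star,
                (if (interval_placement == "midpoint")
                   floor((obs$k1_star + obs$k2_star) / 2)
                 else obs$k2_star) + 1))
  out <- data.frame(id = obs$patient_id, istate = obs$from_state,
                    to = ifelse(is.na(obs$to_state), "censor",
                                as.character(obs$to_state)),
                    dur = dur, stringsAsFactors = FALSE)
  # chain durations within patient
  first <- !duplicated(out$id)
  tstart <- numeric(nrow(out))
  for (i in seq_len(nrow(out)))
    tstart[i] <- if (first[i]) 0 else tstart[i - 1] + out$dur[i - 1]
  out$tstart <- tstart
  out$tstop <- tstart + out$dur
  out[out$dur > 0, c("id", "tstart", "tstop", "istate", "to"), drop = FALSE]
}

aj_from_records <- function(records, time_grid) {
  states <- as.character(1:5)
  out <- matrix(0, length(time_grid), 5, dimnames = list(NULL, states))
  if (!any(records$to != "censor")) {
    # no events at all: occupancy stays at the initial-state distribution
    first <- records[!duplicated(records$id), ]
    out[, ] <- rep(tabulate(first$istate, 5) / nrow(first),
                   each = length(time_grid))
    return(out)
  }
  ev <- factor(records$to, levels = c("censor", states))
  istate <- factor(as.character(records$istate), levels = states)
  fit <- survival::survfit(
    survival::Surv(records$tstart, records$tstop, ev) ~ 1,
    id = records$id, istate = istate)
  sm <- summary(fit, times = time_grid, extend = TRUE)
  ps <- sm$pstate
  colnames(ps) <- fit$states
  out[, intersect(states, colnames(ps))] <- ps[, intersect(states, colnames(ps))]
  out
}

#' Aalen-Johansen state occupancy curves
#'
#' Nonparametric occupancy probabilities over the five states, computed with
#' the multistate product-integral estimator of the survival package.
#' Interval-censored morbidity events are placed at the interval midpoint by
#' default (configurable to the right endpoint).
#'
#' @param dataset A `snnm_dataset`.
#' @param time_grid Months at which occupancy is evaluated.
#' @param interval_placement `"midpoint"` or `"right"`.
#' @return A `snnm_aj` object: list with `time` and the `pstate` matrix
#'   (time points x 5 states).
#' @export
aalenJohansen <- function(dataset, time_grid,
                          interval_placement = c("midpoint", "right")) {
  records <- resolve_records(dataset, match.arg(interval_placement))
  structure(list(time = time_grid, pstate = aj_from_records(records, time_grid)),
            class = "snnm_aj")
}

#' @export
print.snnm_aj <- function(x, ...) {
  cat("<snnm_aj> occupancy at", length(x$time), "time points\n")
  print(utils::head(cbind(time = x$time, round(x$pstate, 4))))
  invisible(x)
}

# --- censoring mixture fit --------------------------------------------------

#' Fit an exponential + gamma mixture to censoring times
#'
#' Expectation-maximization for the two-component mixture used to inject
#' right censoring into simulated datasets. The log-likelihood is
#' nondecreasing across iterations; non-convergence within `max_em_iter`
#' returns the best fit with `converged = FALSE`.
#'
#' @param censor_times Positive censoring times (months); at least 10.
#' @param max_em_iter Maximum EM iterations.
#' @param tol Absolute log-likelihood improvement below which EM stops.
#' @param seed Unused source of randomness kept for interface stability (the
#'   fit is deterministic from moment-based initialization).
#' @return A [censoringMixture()] with attributes `loglik` (trace) and
#'   `converged`.
#' @export
fitCensoringMixture <- function(censor_times, max_em_iter = 500L, tol = 1e-8,
                                seed = 1L) {
  x <- as.numeric(censor_times)
  if (length(x) < 10) stopf("need at least 10 censoring times")
  if (any(x <= 0)) stopf("censoring times must be positive")
  w <- 0.5
  rate <- 1 / mean(x)
  v <- stats::var(x); mu <- mean(x)
  shape <- max(mu^2 / v, 0.1); scale <- max(v / mu, 1e-8)
  ll_trace <- numeric(0)
  for (it in seq_len(max_em_iter)) {
    fe <- w * stats::dexp(x, rate)
    fg <- (1 - w) * stats::dgamma(x, shape = shape, scale = scale)
    tot <- fe + fg
    tot[tot == 0] <- 1e-300
    ll <- sum(log(tot))
    ll_trace <- c(ll_trace, ll)
    if (it > 1 && ll - ll_trace[it - 1] < tol) break
    r <- fe / tot
    sr <- sum(r)
    if (sr > 1e-10) {
      w <- sr / length(x)
      rate <- sr / sum(r * x)
    } else w <- 0
    sg <- sum(1 - r)
    if (sg > 1e-10) {
      mw <- sum((1 - r) * x) / sg
      ml <- sum((1 - r) * log(x)) / sg
      gap <- log(mw) - ml
      if (gap > 1e-12) {
        f <- function(s) log(s) - digamma(s) - gap
        shape <- stats::uniroot(f, c(1e-3, 1e6), extendInt = "downX")$root
      }
      scale <- mw / shape
    }
  }
  out <- censoringMixture(w, rate, shape, scale)
  attr(out, "loglik") <- ll_trace
  attr(out, "converged") <- length(ll_trace) < max_em_iter
  out
}

# --- predictive metrics -----------------------------------------------------

# Observed state of each patient at month t from resolved records; NA when
# the patient is censored before t.
observed_state_at <- function(records, t) {
  ids <- unique(records$id)
  vapply(ids, function(id) {
    rr <- records[records$id == id, , drop = FALSE]
    last <- rr[nrow(rr), ]
    if (last$to != "censor") {
      # absorbed: death time is last$tstop
      if (t >= last$tstop && last$to == "5") return(5L)
    } else if (t > last$tstop) {
      return(NA_integer_)  # censored before t
    }
    hit <- which(rr$tstart <= t & t < rr$tstop)
    if (length(hit)) return(rr$istate[hit[1]])
    if (t <= rr$tstop[nrow(rr)]) return(rr$istate[nrow(rr)])
    NA_integer_
  }, 1L, USE.NAMES = TRUE)
}

#' Brier score at a landmark time
#'
#' Mean squared distance between the one-hot observed state indicator and the
#' model's predicted occupancy at month `t`, over patients whose state at `t`
#' is observable; censored-before-`t` patients are excluded and counted.
#'
#' @param model A `snnm_model`.
#' @param dataset A `snnm_dataset`.
#' @param t Landmark month (default 12, one year after diagnosis).
#' @param interval_placement Passed to the record resolution.
#' @return List with `per_individual` (data frame), `mean`, `n_used`,
#'   `n_excluded`.
#' @export
brierScore <- function(model, dataset, t = 12,
                       interval_placement = c("midpoint", "right")) {
  records <- resolve_records(dataset, match.arg(interval_placement))
  ys <- observed_state_at(records, t)
  ys <- ys[!is.na(ys)]
  if (!length(ys)) stopf("no patient has an observable state at t = %g", t)
  terms <- vapply(names(ys), function(id) {
    pi_t <- occupancyCurve(model, id, dataset, t)[t, ]
    y <- numeric(5); y[ys[[id]]] <- 1
    sum((y - pi_t)^2)
  }, 0)
  list(per_individual = data.frame(patient_id = names(ys),
                                   state = unname(ys), brier = unname(terms)),
       mean = mean(terms), n_used = length(ys),
       n_excluded = length(unique(records$id)) - length(ys))
}

#' Jackknife occupancy estimates at a landmark time
#'
#' Full-sample and leave-one-out Aalen-Johansen occupancy at month `t`, the
#' ingredients of pseudo-observations.
#'
#' @inheritParams brierScore
#' @return List with `full` (length-5 vector), `loo` (patients x 5 matrix)
#'   and `ids`.
#' @export
jackknifeOccupancy <- function(dataset, t,
                               interval_placement = c("midpoint", "right")) {
  records <- resolve_records(dataset, match.arg(interval_placement))
  ids <- unique(records$id)
  full <- aj_from_records(records, t)[1, ]
  loo <- t(vapply(ids, function(id)
    aj_from_records(records[records$id != id, , drop = FALSE], t)[1, ],
    numeric(5)))
  rownames(loo) <- ids
  list(full = full, loo = loo, ids = ids)
}

#' Pseudo-observations from jackknife occupancy estimates
#'
#' Per individual and state, `N * full - (N - 1) * loo`: a surrogate outcome
#' whose average reproduces the full-sample estimate, usable for
#' per-individual metrics under right censoring.
#'
#' @param aj_full Length-5 occupancy vector from the full sample.
#' @param aj_loo Patients x 5 matrix of leave-one-out estimates.
#' @return Patients x 5 matrix of pseudo-observations.
#' @export
pseudoObservations <- function(aj_full, aj_loo) {
  N <- nrow(aj_loo)
  out <- matrix(rep(N * aj_full, each = N), N, 5) - (N - 1) * aj_loo
  rownames(out) <- rownames(aj_loo)
  out
}

#' Kullback-Leibler divergence of predictions from pseudo-observations
#'
#' Per individual, `sum_s P_s log(P_s / pi_s)` with the convention
#' `0 log 0 = 0`. Jackknife pseudo-observations can fall outside `[0, 1]`,
#' where the divergence is undefined; out-of-range entries are clamped back
#' to `[0, 1]` (a negative pseudo-probability contributes nothing, like an
#' exact zero) and the number of clamped entries is reported. Summaries
#' include the mean, median and mode (kernel-density peak) across
#' individuals.
#'
#' @param pseudo Patients x 5 matrix of pseudo-observations.
#' @param model_occupancy Patients x 5 matrix of predicted occupancies.
#' @return List with `per_individual`, `mean`, `median`, `mode`,
#'   `n_clamped`.
#' @export
klDivergence <- function(pseudo, model_occupancy) {
  if (!all(dim(pseudo) == dim(model_occupancy)))
    stopf("pseudo and model occupancy must have matching dimensions")
  n_clamped <- sum(pseudo < -1e-12 | pseudo > 1 + 1e-12)
  P <- pmin(pmax(pseudo, 0), 1)
  kl <- vapply(seq_len(nrow(P)), function(i) {
    p <- P[i, ]; q <- model_occupancy[i, ]
    if (any(q == 0 & p > 0)) return(Inf)
    sum(ifelse(p > 0, p * log(p / q), 0))
  }, 0)
  list(per_individual = kl, mean = mean(kl), median = stats::median(kl),
       mode = density_mode(kl), n_clamped = n_clamped)
}

density_mode <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(x[1])
  d <- stats::density(x)
  d$x[which.max(d$y)]
}

#' Evaluation report: Brier score and KL divergence at a landmark time
#'
#' @param model A `snnm_model`.
#' @param dataset A `snnm_dataset` (typically validation data).
#' @param t Landmark month.
#' @param interval_placement Interval-event placement for the nonparametric
#'   estimates.
#' @return A `snnm_eval_report`: list with `brier`, `kl`, `t`.
#' @export
evalReport <- function(model, dataset, t = 12,
                       interval_placement = c("midpoint", "right")) {
  interval_placement <- match.arg(interval_placement)
  bs <- brierScore(model, dataset, t, interval_placement)
  jk <- jackknifeOccupancy(dataset, t, interval_placement)
  pseudo <- pseudoObservations(jk$full, jk$loo)
  occ <- t(vapply(jk$ids, function(id)
    occupancyCurve(model, id, dataset, t)[t, ], numeric(5)))
  kl <- klDivergence(pseudo, occ)
  structure(list(t = t, brier = bs, kl = kl), class = "snnm_eval_report")
}

#' @export
print.snnm_eval_report <- function(x, ...) {
  cat(sprintf("<snnm_eval_report> at t = %g months\n", x$t))
  cat(sprintf("  Brier: mean %.4g (n = %d, excluded %d)\n",
              x$brier$mean, x$brier$n_used, x$brier$n_excluded))
  cat(sprintf("  KL: mean %.4g, median %.4g, mode %.4g (clamped %d)\n",
              x$kl$mean, x$kl$median, x$kl$mode, x$kl$n_clamped))
  invisible(x)
}

# --- visual predictive check -----------------------------------------------

#' Visual predictive check of state occupancy
#'
#' Simulates `n_sim` replicate datasets from the model using the observed
#' cohort's covariates, injects right censoring drawn from the mixture
#' (events after the censoring time are removed) and interval-censors
#' morbidity events at the scheduled assessments, then compares the observed
#' nonparametric occupancy curves (with a patient-bootstrap confidence band)
#' to the spread of the replicates' curves.
#'
#' @param model A `snnm_model`.
#' @param dataset Observed `snnm_dataset`.
#' @param time_grid Months at which curves are evaluated.
#' @param n_sim Number of simulation replicates.
#' @param mixture A [censoringMixture()] for simulated censoring times;
#'   `NULL` fits one to the dataset's censoring times when available,
#'   falling back to [defaultCensoringMixture()].
#' @param assessment_interval Months between morbidity assessments in the
#'   replicates.
#' @param n_boot Bootstrap resamples for the observed-curve confidence band.
#' @param quantiles Lower/upper band quantiles across replicates.
#' @param seed Integer seed.
#' @return A `snnm_vpc`: list with `time`, `observed`, `obs_lower`,
#'   `obs_upper`, `band_lower`, `band_upper`, `band_min`, `band_max` (all
#'   time x 5 matrices) and `n_sim`.
#' @export
simulateVpc <- function(model, dataset, time_grid = seq(0, 60, by = 3),
                        n_sim = 1000L, mixture = NULL,
                        assessment_interval = 12L, n_boot = 1000L,
                        quantiles = c(0.025, 0.975), seed = 1L) {
  if (is.null(mixture)) {
    cens <- dataset$observations
    ct <- cens$k_star[is.na(cens$to_state)] + cens$entry_month[is.na(cens$to_state)]
    ct <- ct[ct > 0]
    mixture <- if (length(ct) >= 10) fitCensoringMixture(ct)
               else defaultCensoringMixture()
  }
  horizon <- max(time_grid)
  if (horizon < 1) stopf("time grid must extend past 0")
  records <- resolve_records(dataset)
  observed <- aj_from_records(records, time_grid)

  old <- .Random.seed_exists(); on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))

  # patient bootstrap of the observed curve
  ids <- unique(records$id)
  by_id <- split(seq_len(nrow(records)), records$id)
  boot <- array(NA_real_, c(n_boot, length(time_grid), 5))
  for (b in seq_len(n_boot)) {
    pick <- sample(ids, length(ids), replace = TRUE)
    rows <- data.frame(
      idx = unlist(by_id[pick], use.names = FALSE),
      bid = rep(seq_along(pick), vapply(by_id[pick], length, 1L)))
    rec_b <- records[rows$idx, , drop = FALSE]
    rec_b$id <- rows$bid
    boot[b, , ] <- aj_from_records(rec_b, time_grid)
  }
  obs_lower <- apply(boot, c(2, 3), stats::quantile, probs = quantiles[1])
  obs_upper <- apply(boot, c(2, 3), stats::quantile, probs = quantiles[2])

  # model replicates with the observed covariates
  pats <- dataset$patients
  sims <- array(NA_real_, c(n_sim, length(time_grid), 5))
  for (r in seq_len(n_sim)) {
    cfg <- simulationConfig(n_patients = nrow(pats),
                            horizon_months = max(horizon, 1),
                            assessment_interval = assessment_interval,
                            censoring = mixture,
                            seed = sub_seed(seed, paste0("vpc", r)))
    cohort <- simulateCohort(model, cfg, patients = pats)
    drep <- applyCensoring(cohort, cfg, model)
    sims[r, , ] <- aj_from_records(resolve_records(drep), time_grid)
  }
  structure(list(
    time = time_grid, observed = observed,
    obs_lower = obs_lower, obs_upper = obs_upper,
    band_lower = apply(sims, c(2, 3), stats::quantile, probs = quantiles[1]),
    band_upper = apply(sims, c(2, 3), stats::quantile, probs = quantiles[2]),
    band_min = apply(sims, c(2, 3), min),
    band_max = apply(sims, c(2, 3), max),
    n_sim = n_sim), class = "snnm_vpc")
}

#' Fraction of grid points where the observed curve lies inside the band
#'
#' @param vpc A `snnm_vpc`.
#' @param band `"quantile"` (the configured quantile band) or `"range"`
#'   (min/max across replicates).
#' @return Fraction in `[0, 1]` over all states and time points.
#' @export
vpcCoverage <- function(vpc, band = c("quantile", "range")) {
  band <- match.arg(band)
  lo <- if (band == "quantile") vpc$band_lower else vpc$band_min
  hi <- if (band == "quantile") vpc$band_upper else vpc$band_max
  mean(vpc$observed >= lo - 1e-12 & vpc$observed <= hi + 1e-12)
}
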