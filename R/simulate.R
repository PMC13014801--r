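# Synthetic cohort generation: monthly transitions among the five states
# drawn from any covariate model, followed by the censoring scheme of a
# registry — right censoring from an exponential+gamma mixture and interval
# censoring of morbidity events at scheduled assessment times. Death times
# stay exact.

#' Exponential + gamma censoring-time mixture
#'
#' @param weight Mixing weight of the exponential component, in `[0, 1]`.
#' @param exp_rate Exponential rate (1/months).
#' @param gamma_shape,gamma_scale Gamma component parameters (months scale).
#' @return A `snnm_censoring_mixture` object.
#' @export
censoringMixture <- function(weight, exp_rate, gamma_shape, gamma_scale) {
  if (weight < 0 || weight > 1) stopf("weight must be in [0, 1]")
  if (exp_rate <= 0 || gamma_shape <= 0 || gamma_scale <= 0)
    stopf("rate, shape and scale must be positive")
  structure(list(weight = weight, exp_rate = exp_rate,
                 gamma_shape = gamma_shape, gamma_scale = gamma_scale),
            class = "snnm_censoring_mixture")
}

#' Default censoring mixture of the cohort generator
#'
#' Chosen once to reproduce the follow-up spread of the registry cohort the
#' generator emulates (median 3.22 years, range roughly 0 to 10 years): a 35%
#' exponential component with mean 30 months plus a gamma component with
#' shape 3.5 and scale 14.5 months.
#'
#' @return A [censoringMixture()].
#' @export
defaultCensoringMixture <- function() {
  censoringMixture(weight = 0.35, exp_rate = 1 / 30,
                   gamma_shape = 3.5, gamma_scale = 14.5)
}

#' Draw censoring times from a mixture
#'
#' @param n Number of draws.
#' @param mixture A [censoringMixture()].
#' @return Numeric vector of censoring times (months, continuous).
#' @export
rCensoring <- function(n, mixture) {
  is_exp <- stats::runif(n) < mixture$weight
  out <- numeric(n)
  out[is_exp] <- stats::rexp(sum(is_exp), rate = mixture$exp_rate)
  out[!is_exp] <- stats::rgamma(sum(!is_exp), shape = mixture$gamma_shape,
                                scale = mixture$gamma_scale)
  out
}

# Mixture density and distribution, used by the EM fit and its tests.
dmixture <- function(x, mixture, log = FALSE) {
  v <- mixture$weight * stats::dexp(x, mixture$exp_rate) +
    (1 - mixture$weight) * stats::dgamma(x, shape = mixture$gamma_shape,
                                         scale = mixture$gamma_scale)
  if (log) log(v) else v
}

#' Cohort simulation settings
#'
#' Defaults emulate the registry cohort the published model was developed on:
#' baseline age uniform over 18-99 years, male fraction 22715/41517, monthly
#' transitions over a horizon of 118 months (the longest observed follow-up,
#' 9.86 years), annual morbidity assessments, and right censoring from
#' [defaultCensoringMixture()].
#'
#' @param n_patients Cohort size.
#' @param horizon_months Months of simulation (administrative censoring).
#' @param age_range Baseline age range (years), sampled uniformly.
#' @param p_male Probability of the level coded -0.5.
#' @param assessment_interval Months between scheduled morbidity assessments.
#' @param censoring A [censoringMixture()].
#' @param seed Integer seed.
#' @return A `snnm_simulation_config` list.
#' @export
simulationConfig <- function(n_patients = 1000L, horizon_months = 118L,
                             age_range = c(18, 99), p_male = 22715 / 41517,
                             assessment_interval = 12L,
                             censoring = defaultCensoringMixture(),
                             seed = 1L) {
  stopifnot(horizon_months >= 1, assessment_interval >= 1,
            n_patients >= 1, age_range[1] < age_range[2])
  structure(list(n_patients = as.integer(n_patients),
                 horizon_months = as.integer(horizon_months),
                 age_range = age_range, p_male = p_male,
                 assessment_interval = as.integer(assessment_interval),
                 censoring = censoring, seed = as.integer(seed)),
            class = "snnm_simulation_config")
}

#' Simulate uncensored disease trajectories
#'
#' Every patient starts in state 1 at month 0. Each month, the covariate
#' vector (age advancing monthly, time-in-state resetting at every entry) is
#' mapped to the current state's transition probabilities, the row bound is
#' applied, and one categorical draw over stay-or-move resolves competing
#' destinations. Trajectories end at death or at the horizon.
#'
#' @param model A `snnm_model`.
#' @param config A [simulationConfig()].
#' @param patients Optional baseline table (`patient_id`, `AGE` in raw years,
#'   `SEX` as `"Man"`/`"Woman"`) to simulate for fixed covariates, e.g. when
#'   generating predictive-check replicates; when `NULL`, a cohort is drawn
#'   from the config's baseline distributions.
#' @return List with `patients` (raw baseline table) and `events` (one row
#'   per transition: patient, from, to, calendar event month, entry month of
#'   the sojourn).
#' @export
simulateCohort <- function(model, config = simulationConfig(), patients = NULL) {
  old <- .Random.seed_exists(); on.exit(restore_rng(old), add = TRUE)
  set.seed(config$seed)
  if (is.null(patients)) {
    n <- config$n_patients
    age0 <- stats::runif(n, config$age_range[1], config$age_range[2])
    sex_lab <- ifelse(stats::runif(n) < config$p_male, "Man", "Woman")
    ids <- sprintf("P%05d", seq_len(n))
  } else {
    n <- nrow(patients)
    age0 <- patients$AGE
    sex_lab <- as.character(patients$SEX)
    ids <- as.character(patients$patient_id)
  }
  sex_code <- ifelse(sex_lab == "Man", -0.5, 0.5)
  age_norm <- model$normalization$age_norm
  maxT <- model$normalization$max_state_times
  dests <- state_destinations()

  state <- rep(1L, n); entry <- rep(0L, n)
  events <- list()
  for (t in 0:(config$horizon_months - 1L)) {
    for (m in 1:4) {
      idx <- which(state == m)
      if (!length(idx)) next
      Phi <- cbind(AGE = (age0[idx] + t / 12) / age_norm,
                   SEX = sex_code[idx],
                   T = (t - entry[idx]) / maxT[[as.character(m)]])
      dst <- dests[[as.character(m)]]
      lam <- vapply(dst, function(nn)
        map_forward(model$maps[[paste0(m, "->", nn)]], Phi, model$input_names),
        numeric(length(idx)))
      if (!is.matrix(lam)) lam <- matrix(lam, ncol = length(dst))
      lam <- row_bound_matrix(pmin(pmax(lam, 0), 1 - 1e-12))
      u <- stats::runif(length(idx))
      cs <- lam
      if (ncol(cs) > 1)
        for (d in 2:ncol(cs)) cs[, d] <- cs[, d - 1] + lam[, d]
      cum <- cbind(0, cs)
      for (d in seq_along(dst)) {
        hit <- idx[u >= cum[, d] & u < cum[, d + 1]]
        if (!length(hit)) next
        events[[length(events) + 1L]] <- data.frame(
          patient_id = hit, from_state = m, to_state = dst[d],
          event_month = t, entry_month = entry[hit])
        state[hit] <- dst[d]
        entry[hit] <- t + 1L
      }
    }
  }
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(patient_id = integer(), from_state = integer(),
               to_state = integer(), event_month = integer(),
               entry_month = integer())
  ev <- ev[order(ev$patient_id, ev$event_month), , drop = FALSE]
  rownames(ev) <- NULL
  ev$patient_id <- ids[ev$patient_id]
  list(
    patients = data.frame(patient_id = ids, AGE = age0, SEX = sex_lab,
                          stringsAsFactors = FALSE),
    events = ev,
    config = config,
    final_state = state
  )
}

#' Censor simulated trajectories into an observation dataset
#'
#' Per patient, a censoring time is drawn from the mixture and truncated at
#' the horizon; all events from the censoring month onward are removed and
#' the patient is right-censored in the state occupied at that month. Death
#' transitions keep their exact month; morbidity transitions are converted to
#' interval observations bounded by the last scheduled assessment showing the
#' old state and the first assessment showing the new one.
#'
#' @param cohort Output of [simulateCohort()].
#' @param config The [simulationConfig()] used (defaults to the cohort's).
#' @param model Model supplying normalization constants for the dataset.
#' @return A `snnm_dataset`.
#' @export
applyCensoring <- function(cohort, config = cohort$config,
                           model = publishedModel()) {
  old <- .Random.seed_exists(); on.exit(restore_rng(old), add = TRUE)
  set.seed(sub_seed(config$seed, "censor"))
  pats <- cohort$patients
  n <- nrow(pats)
  A <- config$assessment_interval
  cmonth <- pmin(floor(rCensoring(n, config$censoring)), config$horizon_months)
  names(cmonth) <- pats$patient_id

  obs <- list()
  for (i in seq_len(n)) {
    id <- pats$patient_id[i]
    ci <- cmonth[[i]]
    ev <- cohort$events[cohort$events$patient_id == id, , drop = FALSE]
    ev <- ev[ev$event_month < ci, , drop = FALSE]
    for (j in seq_len(nrow(ev))) {
      e <- ev[j, ]
      k_e <- e$event_month - e$entry_month
      if (e$to_state == 5L) {
        obs[[length(obs) + 1L]] <- data.frame(
          patient_id = id, from_state = e$from_state, to_state = e$to_state,
          obs_kind = "exact", k_star = k_e, k1_star = NA_integer_,
          k2_star = NA_integer_, entry_month = e$entry_month)
      } else {
        a_prev <- A * (e$event_month %/% A)
        a_next <- A * ceiling((e$event_month + 1) / A)
        obs[[length(obs) + 1L]] <- data.frame(
          patient_id = id, from_state = e$from_state, to_state = e$to_state,
          obs_kind = "interval",
          k_star = NA_integer_,
          k1_star = max(a_prev, e$entry_month) - e$entry_month,
          k2_star = (a_next - 1L) - e$entry_month,
          entry_month = e$entry_month)
      }
    }
    # open sojourn at censoring (unless the patient already died)
    died <- nrow(ev) && ev$to_state[nrow(ev)] == 5L
    if (!died) {
      cur_state <- if (nrow(ev)) ev$to_state[nrow(ev)] else 1L
      cur_entry <- if (nrow(ev)) ev$event_month[nrow(ev)] + 1L else 0L
      if (ci >= cur_entry) {
        obs[[length(obs) + 1L]] <- data.frame(
          patient_id = id, from_state = cur_state, to_state = NA_integer_,
          obs_kind = "censored", k_star = ci - cur_entry,
          k1_star = NA_integer_, k2_star = NA_integer_,
          entry_month = cur_entry)
      }
    }
  }
  obs <- do.call(rbind, obs)
  rownames(obs) <- NULL
  specs <- list(
    covariateSpec("AGE", "continuous",
                  norm_constant = model$normalization$age_norm),
    covariateSpec("SEX", "binary", levels = c("Man", "Woman"))
  )
  ds <- normalizeDataset(pats, specs, obs,
                         max_state_times = model$normalization$max_state_times,
                         age_covariate = "AGE")
  attr(ds, "censor_months") <- cmonth
  ds
}

#' Simulate a censored observation dataset in one call
#'
#' [simulateCohort()] followed by [applyCensoring()]; the uncensored event
#' table is attached as attribute `"truth"` for oracle checks.
#'
#' @param model A `snnm_model`.
#' @param config A [simulationConfig()].
#' @return A `snnm_dataset`.
#' @export
simulateDataset <- function(model, config = simulationConfig()) {
  cohort <- simulateCohort(model, config)
  ds <- applyCensoring(cohort, config, model)
  attr(ds, "truth") <- cohort$events
  ds
}
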