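# Censored-data likelihood for monthly sojourn observations.
#
# Within a sojourn, the month index k is 0-based: an event at k = 0 happened
# during the first month in the state, with no survival factor (empty
# product). Three observation kinds contribute:
#   exact event at k*:      log lambda(k*) + sum_{j<k*} log(1 - rowsum(j))
#   right censored at k*:   sum_{j<k*} log(1 - rowsum(j))
#   interval [k1*, k2*]:    log sum_{k=k1*}^{k2*} lambda(k) prod_{j<k}(1 - rowsum(j))
# where rowsum(j) is the total probability of leaving the state in month j
# (after the row bound). Interval sums are accumulated in the log domain.

obs_kind_code <- function(kind) match(kind, obs_kinds) - 1L  # 0 exact, 1 cens, 2 interval

#' Sojourn log-likelihood under a constant hazard
#'
#' @param lambda_target Probability of the observed transition per month
#'   (ignored for censored observations; pass any value).
#' @param lambda_row_sum Total probability of leaving the state per month
#'   (must satisfy `lambda_target <= lambda_row_sum < 1`).
#' @param obs A list or one-row data frame with `obs_kind` and `k_star` (or
#'   `k1_star`, `k2_star` for interval observations).
#' @return The log-probability of the observation.
#' @export
sojournLoglikConst <- function(lambda_target, lambda_row_sum, obs) {
  kind <- as.character(obs$obs_kind)
  K <- switch(kind,
    exact = obs$k_star, censored = obs$k_star, interval = obs$k2_star,
    stopf("unknown obs_kind '%s'", kind))
  n <- if (kind == "censored") max(K, 1L) else K + 1L
  sojournLoglikTv(rep(lambda_target, n), rep(lambda_row_sum, n), obs)
}

#' Sojourn log-likelihood under a time-varying hazard
#'
#' Generalizes [sojournLoglikConst()] to a per-month hazard path; with a
#' constant path the two agree exactly.
#'
#' @param lambda_path Vector of per-month transition probabilities for the
#'   observed destination, for months `k = 0, 1, ...` of the sojourn.
#' @param row_sum_path Vector of per-month total leaving probabilities (same
#'   length).
#' @param obs As in [sojournLoglikConst()].
#' @return The log-probability of the observation.
#' @export
sojournLoglikTv <- function(lambda_path, row_sum_path, obs) {
  if (length(lambda_path) != length(row_sum_path))
    stopf("hazard paths must have equal length")
  if (any(row_sum_path < 0 | row_sum_path >= 1))
    stopf("row sums must lie in [0, 1)")
  if (any(lambda_path < 0 | lambda_path > row_sum_path + 1e-15))
    stopf("need 0 <= lambda <= row sum")
  kind <- as.character(obs$obs_kind)
  lsurv <- log1p(-row_sum_path)
  csurv <- c(0, cumsum(lsurv))  # csurv[k+1] = sum_{j<k} log(1 - rowsum(j))
  if (kind == "exact") {
    k <- obs$k_star
    if (length(lambda_path) < k + 1) stopf("hazard path shorter than k*")
    if (lambda_path[k + 1] == 0) {
      warnf("observed event with zero transition probability (degenerate)")
      return(-Inf)
    }
    log(lambda_path[k + 1]) + csurv[k + 1]
  } else if (kind == "censored") {
    k <- obs$k_star
    if (k == 0) return(0)
    if (length(lambda_path) < k) stopf("hazard path shorter than k*")
    csurv[k + 1]
  } else if (kind == "interval") {
    k1 <- obs$k1_star; k2 <- obs$k2_star
    if (length(lambda_path) < k2 + 1) stopf("hazard path shorter than k2*")
    ks <- k1:k2
    if (all(lambda_path[ks + 1] == 0)) {
      warnf("observed event with zero transition probability (degenerate)")
      return(-Inf)
    }
    logsumexp(log(lambda_path[ks + 1]) + csurv[ks + 1])
  } else stopf("unknown obs_kind '%s'", kind)
}

# ---------------------------------------------------------------------------
# Dataset-level likelihood: build per-from-state covariate designs once, run
# every mapping on them, apply the row bound and accumulate.

# Rows needed per observation: exact k* -> k = 0..k*; censored k* -> 0..k*-1;
# interval [k1,k2] -> 0..k2.
obs_row_count <- function(obs) {
  ifelse(obs$obs_kind == "exact", obs$k_star + 1L,
         ifelse(obs$obs_kind == "censored", obs$k_star, obs$k2_star + 1L))
}

# Build the (observation, month) design for one from-state.
# Returns NULL when the state has no observations.
state_design <- function(dataset, m, input_names) {
  obs <- dataset$observations
  obs <- obs[obs$from_state == m, , drop = FALSE]
  if (!nrow(obs)) return(NULL)
  len <- obs_row_count(obs)
  dst <- state_destinations()[[as.character(m)]]
  idx <- rep(seq_len(nrow(obs)), len)
  kk <- sequence(len) - 1L
  pi_rows <- match(obs$patient_id, rownames(dataset$covariates))
  Phi <- dataset$covariates[pi_rows[idx], , drop = FALSE]
  agec <- dataset$age_covariate
  age0 <- dataset$patients[[agec]][match(obs$patient_id, dataset$patients$patient_id)]
  norm <- dataset$specs[[agec]]$norm_constant
  Phi[, agec] <- (age0[idx] + (obs$entry_month[idx] + kk) / 12) / norm
  Phi <- cbind(Phi, T = kk / dataset$max_state_times[[as.character(m)]])
  rownames(Phi) <- NULL
  list(
    state = m,
    Phi = Phi[, input_names, drop = FALSE],
    obs_ptr = c(0L, cumsum(len)),                 # 0-based CSR offsets
    kind = obs_kind_code(obs$obs_kind),
    dest_idx = ifelse(is.na(obs$to_state), -1L, match(obs$to_state, dst) - 1L),
    kstar = ifelse(is.na(obs$k_star), -1L, obs$k_star),
    k1 = ifelse(is.na(obs$k1_star), -1L, obs$k1_star),
    k2 = ifelse(is.na(obs$k2_star), -1L, obs$k2_star),
    dests = dst,
    patient_id = obs$patient_id
  )
}

prepare_likelihood_data <- function(dataset, input_names) {
  designs <- lapply(1:4, function(m) state_design(dataset, m, input_names))
  designs <- designs[!vapply(designs, is.null, TRUE)]
  structure(list(designs = designs, n_obs = nrow(dataset$observations),
                 input_names = input_names),
            class = "snnm_likdata")
}

# Vectorized stick-breaking row bound over a matrix of raw probabilities
# (rows x destinations, ascending destination order).
row_bound_matrix <- function(lam) {
  s <- rowSums(lam)
  hit <- which(s >= 1)
  if (length(hit)) {
    acc <- rep(1, length(hit))
    for (d in seq_len(ncol(lam))) {
      raw <- lam[hit, d]
      lam[hit, d] <- raw * acc
      acc <- acc * (1 - raw)
    }
  }
  lam
}

# Per-observation log-likelihood contributions for one prepared design,
# given the bounded hazard matrix for its rows.
design_loglik <- function(des, lam) {
  rs <- rowSums(lam)
  lsurv <- log1p(-rs)
  cs <- c(0, cumsum(lsurv))
  nObs <- length(des$kind)
  out <- numeric(nObs)
  for (i in seq_len(nObs)) {
    r0 <- des$obs_ptr[i]          # 0-based offset of this obs's k = 0 row
    base <- cs[r0 + 1]            # cumulative log-survival before the sojourn
    if (des$kind[i] == 0L) {      # exact
      k <- des$kstar[i]
      out[i] <- log(lam[r0 + k + 1, des$dest_idx[i] + 1]) + (cs[r0 + k + 1] - base)
    } else if (des$kind[i] == 1L) {  # censored
      k <- des$kstar[i]
      out[i] <- cs[r0 + k + 1] - base
    } else {                      # interval
      ks <- des$k1[i]:des$k2[i]
      out[i] <- logsumexp(log(lam[r0 + ks + 1, des$dest_idx[i] + 1]) +
                            (cs[r0 + ks + 1] - base))
    }
  }
  out
}

#' Negative log-likelihood of a dataset under a covariate model
#'
#' Evaluates every transition mapping on the per-month covariate vectors of
#' each sojourn, applies the row-sum bound, and accumulates the censored-data
#' log-likelihood over all observations.
#'
#' @param model A `snnm_model` (network or expression maps).
#' @param dataset A `snnm_dataset`.
#' @param normalize Divide by the number of observations (the reported
#'   loss scale).
#' @param per_observation Also return the per-observation contributions.
#' @return The (optionally normalized) negative log-likelihood; with
#'   `per_observation = TRUE`, a list with `value` and `contributions`.
#' @export
datasetNegLoglik <- function(model, dataset, normalize = FALSE,
                             per_observation = FALSE) {
  lik <- prepare_likelihood_data(dataset, model$input_names)
  total <- 0
  contrib <- list()
  for (des in lik$designs) {
    lam_raw <- vapply(des$dests, function(n)
      map_forward(model$maps[[paste0(des$state, "->", n)]], des$Phi,
                  model$input_names),
      numeric(nrow(des$Phi)))
    if (!is.matrix(lam_raw)) lam_raw <- matrix(lam_raw, ncol = length(des$dests))
    lam_raw <- pmin(pmax(lam_raw, 1e-300), 1 - 1e-12)
    lam <- row_bound_matrix(lam_raw)
    ll <- design_loglik(des, lam)
    bad <- !is.finite(ll)
    if (any(bad))
      stopf("non-finite likelihood contribution for patient(s): %s",
            paste(unique(des$patient_id[bad]), collapse = ", "))
    total <- total + sum(ll)
    contrib[[as.character(des$state)]] <-
      data.frame(patient_id = des$patient_id, from_state = des$state, loglik = ll)
  }
  value <- -total
  if (normalize && lik$n_obs > 0) value <- value / lik$n_obs
  if (per_observation)
    return(list(value = value, contributions = do.call(rbind, unname(contrib))))
  value
}
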