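# Shared fixtures: small in-code datasets and generators used across tests.

default_specs <- function() {
  list(covariateSpec("AGE", "continuous", norm_constant = 102.07),
       covariateSpec("SEX", "binary", levels = c("Man", "Woman")))
}

# A tiny hand-written dataset with all three observation kinds.
tiny_dataset <- function() {
  pats <- data.frame(patient_id = c("a", "b", "c"),
                     AGE = c(62, 45, 80), SEX = c("Man", "Woman", "Man"),
                     stringsAsFactors = FALSE)
  obs <- data.frame(
    patient_id = c("a", "a", "b", "c"),
    from_state = c(1L, 2L, 1L, 1L),
    to_state = c(2L, 5L, NA_integer_, 3L),
    obs_kind = c("interval", "exact", "censored", "interval"),
    k_star = c(NA, 7L, 30L, NA),
    k1_star = c(12L, NA, NA, 0L),
    k2_star = c(23L, NA, NA, 11L),
    entry_month = c(0L, 24L, 0L, 0L))
  normalizeDataset(pats, default_specs(), obs)
}

# Sojourn data from a single transient state (4 -> 5) with a constant-in-time
# hazard lambda = sigm(b0 + b1 * AGE_normalized); exact deaths, administrative
# censoring at `horizon` months.
single_map_dataset <- function(n, seed, b0 = -3.5, b1 = 4, horizon = 48L) {
  withr::local_seed(seed)
  age <- stats::runif(n, 25, 100)
  sex <- ifelse(stats::runif(n) < 0.5, "Man", "Woman")
  lam <- sigm(b0 + b1 * age / 102.07)
  k <- stats::rgeom(n, lam)
  cens <- k > horizon
  obs <- data.frame(
    patient_id = sprintf("q%05d", seq_len(n)), from_state = 4L,
    to_state = ifelse(cens, NA_integer_, 5L),
    obs_kind = ifelse(cens, "censored", "exact"),
    k_star = pmin(k, horizon), k1_star = NA_integer_, k2_star = NA_integer_,
    entry_month = 0L)
  normalizeDataset(
    data.frame(patient_id = obs$patient_id, AGE = age, SEX = sex,
               stringsAsFactors = FALSE),
    default_specs(), obs)
}

# A valid random transition matrix with small off-diagonal entries.
random_transition_matrix <- function() {
  off <- stats::setNames(stats::runif(8, 0, 0.2),
                         apply(allowedTransitions(), 1, paste, collapse = "->"))
  assembleTransitionMatrix(off)
}

published_input_ranges <- function() {
  list(AGE = c(0.2, 1), SEX = c(-0.5, 0.5), T = c(0, 1))
}
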