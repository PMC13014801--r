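# Dataset representation: covariate specs, normalization, time-varying
# covariate construction and patient-level train/test splitting.
#
# A dataset couples one row per patient of baseline covariates with a table of
# sojourn observations. Each observation is one stay in one state, recorded as
# an exact transition month, a right-censoring month, or an interval of months
# in which the transition is known to have occurred. Month indices are 0-based
# within the sojourn: an event at k = 0 happened during the first month in the
# state.

#' Allowed transitions of the five-state progression model
#'
#' The irreversible structure: from diagnosis (state 1) to macrovascular
#' complications (state 2), diabetic kidney disease (state 3), both
#' comorbidities (state 4) and death (state 5, absorbing).
#'
#' @return A two-column integer matrix of (from, to) pairs.
#' @export
allowedTransitions <- function() {
  cbind(
    from = c(1L, 1L, 1L, 2L, 2L, 3L, 3L, 4L),
    to   = c(2L, 3L, 5L, 4L, 5L, 4L, 5L, 5L)
  )
}

#' Published maximum state occupation times
#'
#' Training-set maxima (months) used to normalize time-in-state for states
#' 1 to 4: 114, 95, 97 and 78 months.
#'
#' @return Named numeric vector of length 4.
#' @export
publishedMaxStateTimes <- function() {
  c(`1` = 114, `2` = 95, `3` = 97, `4` = 78)
}

#' Published age normalization constant
#'
#' Highest age (years) achieved in the original training data; continuous age
#' is divided by this constant so normalized age lies in (0, 1] on training
#' data.
#'
#' @return A single number, 102.07.
#' @export
publishedAgeNorm <- function() 102.07

#' Describe one covariate
#'
#' @param name Covariate name (column in the raw covariate table).
#' @param kind `"continuous"` (divided by `norm_constant`) or `"binary"`
#'   (two raw levels coded -0.5 / +0.5).
#' @param norm_constant Positive normalization constant for continuous
#'   covariates, in the units of the raw value. `NULL` means "estimate as the
#'   training-set maximum" when the dataset is normalized.
#' @param levels For binary covariates, the two raw levels, in the order
#'   (level coded -0.5, level coded +0.5).
#' @param codes Numeric codes for the two binary levels; fixed at
#'   `c(-0.5, 0.5)`.
#' @return A `snnm_covariate_spec` object.
#' @export
covariateSpec <- function(name, kind = c("continuous", "binary"),
                          norm_constant = NULL, levels = NULL,
                          codes = c(-0.5, 0.5)) {
  kind <- match.arg(kind)
  if (kind == "continuous") {
    if (!is.null(norm_constant) && (!is.numeric(norm_constant) || norm_constant <= 0))
      stopf("norm_constant for '%s' must be a positive number", name)
  } else {
    if (is.null(levels) || length(levels) != 2L)
      stopf("binary covariate '%s' needs exactly two levels", name)
    if (!identical(as.numeric(codes), c(-0.5, 0.5)))
      stopf("binary codes are fixed at (-0.5, +0.5)")
  }
  structure(
    list(name = name, kind = kind, norm_constant = norm_constant,
         levels = levels, codes = c(-0.5, 0.5)),
    class = "snnm_covariate_spec"
  )
}

obs_kinds <- c("exact", "censored", "interval")

validate_observations <- function(obs, patient_ids) {
  req <- c("patient_id", "from_state", "to_state", "obs_kind",
           "k_star", "k1_star", "k2_star", "entry_month")
  miss <- setdiff(req, names(obs))
  if (length(miss)) stopf("observations table lacks columns: %s", paste(miss, collapse = ", "))
  if (!all(obs$patient_id %in% patient_ids))
    stopf("observations refer to unknown patient ids")
  if (!all(obs$obs_kind %in% obs_kinds))
    stopf("obs_kind must be one of: %s", paste(obs_kinds, collapse = ", "))
  if (!all(obs$from_state %in% 1:4))
    stopf("from_state must be in 1..4")
  ev <- !is.na(obs$to_state)
  if (any(ev)) {
    allowed <- paste(allowedTransitions()[, 1], allowedTransitions()[, 2])
    bad <- !(paste(obs$from_state[ev], obs$to_state[ev]) %in% allowed)
    if (any(bad)) stopf("disallowed transition(s), e.g. %d->%d",
                        obs$from_state[ev][bad][1], obs$to_state[ev][bad][1])
  }
  if (any(obs$obs_kind %in% c("exact", "censored") & is.na(obs$k_star)))
    stopf("exact/censored observations need k_star")
  iv <- obs$obs_kind == "interval"
  if (any(iv & (is.na(obs$k1_star) | is.na(obs$k2_star))))
    stopf("interval observations need k1_star and k2_star")
  if (any(iv & !is.na(obs$k1_star) & !is.na(obs$k2_star) &
          (obs$k1_star > obs$k2_star | obs$k1_star < 0)))
    stopf("intervals must satisfy 0 <= k1_star <= k2_star")
  if (any(!iv & (!is.na(obs$k1_star) | !is.na(obs$k2_star))))
    stopf("exact/censored observations must not carry an interval")
  if (any(iv & !is.na(obs$k_star)))
    stopf("interval observations must not carry k_star")
  if (any(obs$obs_kind == "censored" & !is.na(obs$to_state)))
    stopf("censored observations must have no to_state")
  if (any(obs$obs_kind != "censored" & is.na(obs$to_state)))
    stopf("event observations need a to_state")
  invisible(obs)
}

#' Build a normalized dataset from raw tables
#'
#' Continuous covariates are divided by their normalization constant (the
#' training-set maximum when the spec leaves it `NULL`); binary covariates are
#' mapped to -0.5 / +0.5. The resolved constants are stored in the returned
#' dataset so they can be reused verbatim on unseen (validation) data.
#'
#' @param raw_table Data frame with one row per patient: `patient_id` plus one
#'   column per raw covariate named in `specs`.
#' @param specs List of [covariateSpec()] objects.
#' @param observations Sojourn observation table (may have zero rows); see
#'   package docs for the column contract.
#' @param max_state_times Months of maximum state occupancy for states 1..4,
#'   used to normalize time-in-state.
#' @param age_covariate Name of the continuous covariate treated as age
#'   (advances by 1/12 per month); must appear in `specs`.
#' @param guard Emit a warning when a normalized continuous value exceeds this
#'   bound (suggests applying the wrong constants to new data).
#' @return A `snnm_dataset` object.
#' @export
normalizeDataset <- function(raw_table, specs,
                             observations = empty_observations(),
                             max_state_times = publishedMaxStateTimes(),
                             age_covariate = "AGE",
                             guard = 1.5) {
  if (!"patient_id" %in% names(raw_table)) stopf("raw_table needs a patient_id column")
  if (any(duplicated(raw_table$patient_id))) stopf("duplicated patient ids")
  if (inherits(specs, "snnm_covariate_spec")) specs <- list(specs)
  nm <- vapply(specs, `[[`, "", "name")
  names(specs) <- nm
  miss <- setdiff(nm, names(raw_table))
  if (length(miss)) stopf("unknown covariate name(s): %s", paste(miss, collapse = ", "))
  if (!age_covariate %in% nm) stopf("age covariate '%s' not among specs", age_covariate)
  if (length(max_state_times) != 4L || any(max_state_times <= 0))
    stopf("max_state_times must be 4 positive values")

  n <- nrow(raw_table)
  covmat <- matrix(NA_real_, n, length(specs), dimnames = list(raw_table$patient_id, nm))
  for (s in specs) {
    x <- raw_table[[s$name]]
    if (s$kind == "continuous") {
      if (!is.numeric(x)) stopf("covariate '%s' must be numeric", s$name)
      if (any(x < 0, na.rm = TRUE)) stopf("continuous covariate '%s' has negative values", s$name)
      if (is.null(s$norm_constant)) {
        s$norm_constant <- max(x, na.rm = TRUE)
        specs[[s$name]]$norm_constant <- s$norm_constant
      }
      v <- x / s$norm_constant
      if (any(v > guard, na.rm = TRUE))
        warnf("covariate '%s': normalized values exceed %.2f; check norm_constant",
              s$name, guard)
      covmat[, s$name] <- v
    } else {
      bad <- !(as.character(x) %in% as.character(s$levels))
      if (any(bad)) stopf("covariate '%s': value '%s' not among declared levels",
                          s$name, as.character(x)[bad][1])
      covmat[, s$name] <- ifelse(as.character(x) == as.character(s$levels[2]), 0.5, -0.5)
    }
  }
  observations <- as.data.frame(observations)
  validate_observations(observations, raw_table$patient_id)
  structure(
    list(
      patients = as.data.frame(raw_table),
      covariates = covmat,
      observations = observations,
      specs = specs,
      max_state_times = stats::setNames(as.numeric(max_state_times), as.character(1:4)),
      age_covariate = age_covariate
    ),
    class = "snnm_dataset"
  )
}

empty_observations <- function() {
  data.frame(patient_id = character(), from_state = integer(), to_state = integer(),
             obs_kind = character(), k_star = integer(), k1_star = integer(),
             k2_star = integer(), entry_month = integer())
}

#' @export
print.snnm_dataset <- function(x, ...) {
  cat(sprintf("<snnm_dataset> %d patients, %d observations\n",
              nrow(x$patients), nrow(x$observations)))
  cat("  covariates:", paste(colnames(x$covariates), collapse = ", "), "\n")
  tb <- table(x$observations$obs_kind)
  if (length(tb)) cat("  observation kinds:",
                      paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  invisible(x)
}

#' Names of the model input vector
#'
#' The covariate vector fed to every transition mapping: all declared
#' covariates in spec order followed by `"T"`, the normalized time spent in
#' the current state. The same input shape is used for every mapping; mappings
#' that do not need `T` are free to give it zero weight.
#'
#' @param dataset A `snnm_dataset`.
#' @return Character vector of input names.
#' @export
inputNames <- function(dataset) c(colnames(dataset$covariates), "T")

#' Covariate vector for a patient at a within-sojourn month
#'
#' All covariates are fixed at their normalized baseline values except age,
#' which advances by one month per time step
#' (`AGE = (baseline_age + elapsed_months/12) / norm_constant` with elapsed
#' months counted from study start), and `T = k / max_state_time[state]`, the
#' normalized time already spent in the current state.
#'
#' @param patient_id Patient identifier.
#' @param state Current state (1..4).
#' @param k Months spent in the state so far (0-based).
#' @param dataset A `snnm_dataset`.
#' @param entry_month Months since study start at state entry, so that the
#'   elapsed time driving age is `entry_month + k`.
#' @return Named numeric vector over [inputNames()].
#' @export
covariateVectorAt <- function(patient_id, state, k, dataset, entry_month = 0) {
  if (!state %in% 1:4) stopf("state must be in 1..4")
  if (any(k < 0)) stopf("k must be >= 0")
  i <- match(patient_id, rownames(dataset$covariates))
  if (is.na(i)) stopf("unknown patient '%s'", patient_id)
  phi <- dataset$covariates[i, ]
  agec <- dataset$age_covariate
  spec <- dataset$specs[[agec]]
  age0 <- dataset$patients[[agec]][match(patient_id, dataset$patients$patient_id)]
  phi[agec] <- (age0 + (entry_month + k) / 12) / spec$norm_constant
  c(phi, T = k / dataset$max_state_times[[as.character(state)]])
}

#' Stratified patient-level train/test split
#'
#' Patients are stratified by their observed event profile (the multiset of
#' transitions they experienced, or "censored only") and allocated to the test
#' set proportionally within each stratum, so event-type proportions in the
#' test data track the full data. Deterministic given `seed`.
#'
#' @param dataset A `snnm_dataset`.
#' @param test_fraction Fraction of patients assigned to the test set
#'   (0 < f < 1).
#' @param seed Integer seed.
#' @return List with elements `train` and `test`, both `snnm_dataset`.
#' @export
splitTrainTest <- function(dataset, test_fraction = 0.1, seed = 1L) {
  if (test_fraction <= 0 || test_fraction >= 1) stopf("test_fraction must be in (0,1)")
  obs <- dataset$observations
  ids <- dataset$patients$patient_id
  ev <- obs[!is.na(obs$to_state), c("patient_id", "from_state", "to_state")]
  prof <- vapply(ids, function(id) {
    tr <- ev[ev$patient_id == id, , drop = FALSE]
    if (!nrow(tr)) return("censored")
    paste(sort(paste0(tr$from_state, ">", tr$to_state)), collapse = ",")
  }, "")
  strata <- split(ids, prof)
  n_test_tot <- round(length(ids) * test_fraction)
  if (n_test_tot < 1 || n_test_tot >= length(ids))
    stopf("too few patients for a %.0f%% test split", 100 * test_fraction)

  old <- .Random.seed_exists()
  set.seed(as.integer(seed))
  on.exit(restore_rng(old), add = TRUE)

  test_ids <- character()
  for (s in names(strata)) {
    grp <- strata[[s]]
    n_s <- round(length(grp) * test_fraction)
    # every multi-patient stratum should appear in both splits
    if (n_s == 0 && length(grp) >= 2) n_s <- 1L
    if (n_s >= length(grp) && length(grp) >= 2) n_s <- length(grp) - 1L
    if (n_s > 0) test_ids <- c(test_ids, sample(grp, n_s))
  }
  if (!length(test_ids)) stopf("stratified split produced an empty test set")
  subset_ids <- function(keep) {
    d <- dataset
    ki <- dataset$patients$patient_id %in% keep
    d$patients <- dataset$patients[ki, , drop = FALSE]
    d$covariates <- dataset$covariates[ki, , drop = FALSE]
    d$observations <- obs[obs$patient_id %in% keep, , drop = FALSE]
    rownames(d$patients) <- NULL
    rownames(d$observations) <- NULL
    d
  }
  list(train = subset_ids(setdiff(ids, test_ids)), test = subset_ids(test_ids))
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Write a dataset to a directory of plain-text files
#'
#' Emits `covariates.csv` (raw values), `observations.csv`, and `config.json`
#' (covariate specs with resolved normalization constants, max state times).
#'
#' @param dataset A `snnm_dataset`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeDataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(dataset$patients, file.path(dir, "covariates.csv"), row.names = FALSE)
  utils::write.csv(dataset$observations, file.path(dir, "observations.csv"), row.names = FALSE)
  cfg <- list(
    specs = lapply(unname(dataset$specs), function(s)
      list(name = s$name, kind = s$kind, norm_constant = s$norm_constant,
           levels = s$levels)),
    max_state_times = unname(dataset$max_state_times),
    age_covariate = dataset$age_covariate
  )
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}

#' Read a dataset written by [writeDataset()]
#'
#' Normalization constants stored in `config.json` are reused as-is; they are
#' never re-estimated from the data being read.
#'
#' @param dir Directory containing `covariates.csv`, `observations.csv` and
#'   `config.json`.
#' @return A `snnm_dataset`.
#' @export
readDataset <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"))
  specs <- lapply(cfg$specs, function(s)
    covariateSpec(s$name, s$kind,
                  norm_constant = s$norm_constant,
                  levels = if (!is.null(s$levels)) unlist(s$levels)))
  pats <- utils::read.csv(file.path(dir, "covariates.csv"),
                          colClasses = c(patient_id = "character"))
  obs <- utils::read.csv(file.path(dir, "observations.csv"),
                         colClasses = c(patient_id = "character"))
  for (col in c("to_state", "k_star", "k1_star", "k2_star"))
    if (!col %in% names(obs)) obs[[col]] <- NA_integer_
  normalizeDataset(pats, specs, obs,
                   max_state_times = unlist(cfg$max_state_times),
                   age_covariate = cfg$age_covariate %||% "AGE")
}
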