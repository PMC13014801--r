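# Covariate model container: one mapping per allowed transition, either a
# symbolic neural network (during training) or a closed-form expression
# (after extraction, or for the published reference model).

transition_keys <- function() {
  a <- allowedTransitions()
  paste0(a[, 1], "->", a[, 2])
}

#' Create a transition covariate model
#'
#' @param maps Named list over the 8 allowed transitions (`"1->2"`, ...,
#'   `"4->5"`); each element a `snnm_snn_params` network or a
#'   `snnm_expression`.
#' @param input_names Names of the covariate input vector the mappings expect
#'   (covariates followed by `"T"`).
#' @param normalization List with `age_norm` (years) and `max_state_times`
#'   (months, states 1..4) used to normalize inputs.
#' @return A `snnm_model` object.
#' @export
transitionModel <- function(maps, input_names,
                            normalization = list(
                              age_norm = publishedAgeNorm(),
                              max_state_times = publishedMaxStateTimes())) {
  miss <- setdiff(transition_keys(), names(maps))
  if (length(miss)) stopf("missing transition map(s): %s", paste(miss, collapse = ", "))
  ok <- vapply(maps, function(m)
    inherits(m, "snnm_snn_params") || inherits(m, "snnm_expression"), TRUE)
  if (!all(ok)) stopf("each map must be a network or an expression")
  structure(list(maps = maps[transition_keys()], input_names = input_names,
                 normalization = normalization),
            class = "snnm_model")
}

#' Initialize a model of dense symbolic networks
#'
#' One independent network per allowed transition (no weight sharing), with
#' seeded small-uniform weights.
#'
#' @param input_names Covariate input names (ending in `"T"`).
#' @param seed Integer seed; each transition gets a distinct derived stream.
#' @param scale Half-width of the uniform weight initialization.
#' @inheritParams transitionModel
#' @return A `snnm_model` whose maps are all dense networks.
#' @export
initTransitionModel <- function(input_names, seed = 1L, scale = 0.1,
                                normalization = list(
                                  age_norm = publishedAgeNorm(),
                                  max_state_times = publishedMaxStateTimes())) {
  cfg <- snnConfig(length(input_names))
  maps <- lapply(seq_along(transition_keys()), function(i)
    snnInit(cfg, seed = sub_seed(seed, paste0("init", i)), scale = scale))
  names(maps) <- transition_keys()
  transitionModel(maps, input_names, normalization)
}

# Evaluate one map on a covariate matrix (columns named by input).
map_forward <- function(map, Phi, input_names) {
  if (inherits(map, "snnm_snn_params")) {
    snnForward(map, Phi[, input_names, drop = FALSE])
  } else {
    evalExpression(map, as.data.frame(Phi))
  }
}

#' Evaluate the covariate model as a transition matrix
#'
#' Builds, for each transient state, the covariate vector of the patient at
#' time `k`, runs the per-transition mappings, applies the row-sum bound and
#' assembles the full matrix. Time-in-state for every row is measured from
#' study start (exact for state 1, where all patients begin; the marginal
#' propagation of Eq.-style occupancy products uses the same clock for the
#' other states).
#'
#' @param model A `snnm_model`.
#' @param patient_id Patient identifier in `dataset`.
#' @param k Months since study start.
#' @param dataset A `snnm_dataset` supplying covariates and normalization.
#' @return A 5x5 `snnm_transition_matrix`.
#' @export
evaluateCovariateModel <- function(model, patient_id, k, dataset) {
  dests <- state_destinations()
  off <- numeric(0)
  for (m in 1:4) {
    phi <- covariateVectorAt(patient_id, m, k, dataset, entry_month = 0)
    Phi <- matrix(phi, 1, dimnames = list(NULL, names(phi)))
    dst <- dests[[as.character(m)]]
    lam <- vapply(dst, function(n)
      map_forward(model$maps[[paste0(m, "->", n)]], Phi, model$input_names), 0)
    lam <- enforceRowBound(lam)
    names(lam) <- paste0(m, "->", dst)
    off <- c(off, lam)
  }
  assembleTransitionMatrix(off)
}

#' Per-individual state occupancy curve
#'
#' Propagates the initial occupancy (all mass in state 1) through the
#' individual's time-varying transition matrices for months `1..t_max`.
#'
#' @param model A `snnm_model`.
#' @param patient_id Patient identifier.
#' @param dataset A `snnm_dataset`.
#' @param t_max Months to propagate.
#' @return Matrix `t_max` x 5; row t is the occupancy at month t.
#' @export
occupancyCurve <- function(model, patient_id, dataset, t_max) {
  mats <- lapply(0:(t_max - 1), function(k)
    evaluateCovariateModel(model, patient_id, k, dataset))
  propagateOccupancy(c(1, 0, 0, 0, 0), mats)
}

#' Extract readable expressions for every transition mapping
#'
#' @param model A `snnm_model`.
#' @return Named list of `snnm_expression`, one per transition (expression
#'   maps are passed through unchanged).
#' @export
modelExpressions <- function(model) {
  lapply(model$maps, function(m) {
    if (inherits(m, "snnm_expression")) m
    else extractExpression(m, model$input_names)
  })
}

#' Active parameter count per transition mapping
#'
#' @param model A `snnm_model`.
#' @return Named integer vector (NA for closed-form expression maps).
#' @export
modelActiveCounts <- function(model) {
  vapply(model$maps, function(m) {
    if (inherits(m, "snnm_snn_params")) countActiveParameters(m) else NA_integer_
  }, 1L)
}

#' @export
print.snnm_model <- function(x, ...) {
  cat("<snnm_model> inputs:", paste(x$input_names, collapse = ", "), "\n")
  for (key in names(x$maps)) {
    m <- x$maps[[key]]
    if (inherits(m, "snnm_expression")) {
      cat(sprintf("  f%s = %s\n", gsub("->", "", key), formatExpression(m)))
    } else {
      cat(sprintf("  f%s : network, %d active parameters\n",
                  gsub("->", "", key), countActiveParameters(m)))
    }
  }
  invisible(x)
}

#' The published type 2 diabetes progression covariate model
#'
#' The final pruned model reported for the five-state type 2 diabetes
#' progression data, as closed-form maps over normalized age (`AGE`, years
#' divided by 102.07) and normalized time-in-state (`T`, months divided by the
#' per-state maxima 114, 95, 97, 78). The printed rendering of the maps for
#' transitions 1->3, 1->5 and 3->5 is typographically ambiguous; this factory
#' encodes one documented reading of each (see the methods vignette) and no
#' downstream computation in this package depends on their exact form. The
#' map for 3->4 is a constant, `sigm(-5.88)`.
#'
#' @return A `snnm_model` with expression maps over inputs `AGE`, `SEX`, `T`
#'   (`SEX` is carried in the input vector but unused by the published maps).
#' @export
publishedModel <- function() {
  ins <- c("AGE", "SEX", "T")
  ex <- function(lang) new_expression(lang, ins)
  maps <- list(
    "1->2" = ex(quote(sigm(-7.35 + 3.34 * AGE^2))),
    "1->3" = ex(quote(sigm(-3.77 - 4.41 * (1.61 * AGE)^(2.26 * AGE)))),
    "1->5" = ex(quote(sigm(-5.1 + 2.93 * T + 3.96 * AGE - 3.67 * AGE^(-1.32 * AGE)))),
    "2->4" = ex(quote(sigm(-13.69 + 9.08 * AGE))),
    "2->5" = ex(quote(sigm(-11.64 + 5.87 * AGE + 5.56 * T * AGE))),
    "3->4" = ex(quote(sigm(-5.88))),
    "3->5" = ex(quote(sigm(-4.33 + (0.34 * T + 0.79 * AGE)^1.98 + 0.33))),
    "4->5" = ex(quote(sigm(-12.8 + 4.28 * T + 8.47 * AGE)))
  )
  transitionModel(maps, ins)
}

# --- model serialization ---------------------------------------------------

#' Serialize a model to JSON
#'
#' Network maps are stored as weight/bias/mask arrays; expression maps as
#' expression trees. Normalization constants and input names travel with the
#' bundle.
#'
#' @param model A `snnm_model`.
#' @param path Optional file path; when given, the JSON is written there.
#' @return The JSON string, invisibly when `path` is given.
#' @export
modelToJson <- function(model, path = NULL) {
  ser_map <- function(m) {
    if (inherits(m, "snnm_snn_params")) {
      list(type = "snn", n_inputs = m$config$n_inputs,
           params = lapply(m$params, function(x) if (is.matrix(x)) x else as.numeric(x)),
           mask = lapply(m$mask, function(x) if (is.matrix(x)) x else as.numeric(x)))
    } else {
      list(type = "expression", inputs = m$inputs, tree = expr_to_tree(m$expr))
    }
  }
  obj <- list(input_names = model$input_names,
              normalization = model$normalization,
              maps = lapply(model$maps, ser_map))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Rebuild a model serialized by [modelToJson()]
#'
#' @param json JSON string, or a file path to one.
#' @return A `snnm_model`.
#' @export
modelFromJson <- function(json) {
  if (length(json) == 1L && file.exists(json)) json <- paste(readLines(json), collapse = "")
  obj <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  input_names <- unlist(obj$input_names)
  de_map <- function(m) {
    if (m$type == "snn") {
      cfg <- snnConfig(m$n_inputs)
      # matrices arrive as JSON arrays of rows
      as_shape <- function(x, ref) {
        if (is.matrix(ref)) do.call(rbind, lapply(x, function(r) unlist(r)))
        else as.numeric(unlist(x))
      }
      proto <- snnInit(cfg, seed = 1L)
      params <- mapply(as_shape, m$params, proto$params, SIMPLIFY = FALSE)
      mask <- mapply(as_shape, m$mask, proto$mask, SIMPLIFY = FALSE)
      structure(list(params = params, mask = mask, config = cfg),
                class = "snnm_snn_params")
    } else {
      new_expression(tree_to_expr(m$tree), unlist(m$inputs))
    }
  }
  norm <- obj$normalization
  transitionModel(lapply(obj$maps, de_map), input_names,
                  normalization = list(
                    age_norm = norm$age_norm,
                    max_state_times = stats::setNames(unlist(norm$max_state_times),
                                                      as.character(1:4))))
}
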