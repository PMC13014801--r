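# Gradient training with test-loss early stopping, parameter salience,
# sampled diagonal Hessians, and the iterative prune-retrain loop.

#' Training and pruning configuration
#'
#' Defaults follow the reference protocol: Adam with learning rate 0.001;
#' convergence when the (per-observation) test loss fails to improve by more
#' than 0.01 for 35 consecutive iterations before the first prune and 25
#' during pruning; a pruning schedule removing 20, 10, 5, 5 parameters in the
#' first four pruning iterations and one per iteration thereafter; and a hard
#' cap of 10 active parameters per transition mapping.
#'
#' @param learning_rate Adam step size.
#' @param min_improvement Minimum test-loss improvement (per-observation
#'   scale) that resets the patience counter.
#' @param patience_initial Patience (iterations) for the initial training.
#' @param patience_pruning Patience during prune-retrain cycles.
#' @param prune_schedule Parameters removed in the first pruning iterations.
#' @param prune_tail Parameters removed per iteration once the schedule is
#'   exhausted.
#' @param max_params_per_map Hard cap of active parameters per mapping.
#' @param loss_degradation Relative test-loss increase over the running best
#'   that terminates pruning (once every mapping is within the cap).
#' @param max_iter Safety cap on training iterations per convergence run.
#' @param max_prune_iter Safety cap on pruning iterations.
#' @param hessian_sample_threshold Use the sampled Hessian for mappings whose
#'   from-state has more observations than this; exact full-data diagonal
#'   otherwise.
#' @param hessian_batches,per_transition,per_censored Sampling plan of the
#'   batched Hessian: number of batches, observed transitions of each type
#'   per batch, right-censored observations per batch.
#' @param fd_step Relative step of the central-difference diagonal Hessian.
#' @param seed Integer seed for Hessian batch sampling.
#' @return A `snnm_training_config` list.
#' @export
trainingConfig <- function(learning_rate = 0.001,
                           min_improvement = 0.01,
                           patience_initial = 35L,
                           patience_pruning = 25L,
                           prune_schedule = c(20L, 10L, 5L, 5L),
                           prune_tail = 1L,
                           max_params_per_map = 10L,
                           loss_degradation = 0.01,
                           max_iter = 20000L,
                           max_prune_iter = 1000L,
                           hessian_sample_threshold = 5000L,
                           hessian_batches = 10L,
                           per_transition = 30L,
                           per_censored = 30L,
                           fd_step = 1e-3,
                           seed = 1L) {
  cfg <- list(learning_rate = learning_rate, min_improvement = min_improvement,
              patience_initial = as.integer(patience_initial),
              patience_pruning = as.integer(patience_pruning),
              prune_schedule = as.integer(prune_schedule),
              prune_tail = as.integer(prune_tail),
              max_params_per_map = as.integer(max_params_per_map),
              loss_degradation = loss_degradation,
              max_iter = as.integer(max_iter),
              max_prune_iter = as.integer(max_prune_iter),
              hessian_sample_threshold = as.integer(hessian_sample_threshold),
              hessian_batches = as.integer(hessian_batches),
              per_transition = as.integer(per_transition),
              per_censored = as.integer(per_censored),
              fd_step = fd_step, seed = as.integer(seed))
  stopifnot(cfg$learning_rate > 0, cfg$min_improvement >= 0,
            all(diff(cfg$prune_schedule) <= 0))
  structure(cfg, class = "snnm_training_config")
}

# --- flat parameter layout across trained mappings -------------------------

# Mappings are trainable when they are networks and their from-state has at
# least one observation; others are frozen (with a warning for event-less
# states).
build_layout <- function(model, dataset) {
  states_obs <- sort(unique(dataset$observations$from_state))
  keys <- transition_keys()
  from <- as.integer(sub("->.*", "", keys))
  is_net <- vapply(model$maps, inherits, TRUE, "snnm_snn_params")
  trained <- is_net & from %in% states_obs
  if (!any(trained)) stopf("no trainable mapping has observations")
  skipped <- keys[is_net & !trained]
  if (length(skipped))
    warnf("no observations for from-state of mapping(s) %s; frozen",
          paste(skipped, collapse = ", "))
  lens <- integer(0); offs <- integer(0); off <- 0L
  theta <- numeric(0); mask <- numeric(0); exempt <- logical(0)
  labels <- character(0); keyv <- character(0); locidx <- integer(0)
  for (key in keys[trained]) {
    m <- model$maps[[key]]
    v <- flattenSnn(m$params)
    w <- flattenSnn(m$mask)
    L <- length(v)
    offs <- c(offs, off); lens <- c(lens, L); off <- off + L
    theta <- c(theta, v); mask <- c(mask, w)
    ex <- rep(FALSE, L); ex[L] <- TRUE   # sigmoid-head bias b3 never pruned
    exempt <- c(exempt, ex)
    labels <- c(labels, snnParamLabels(m$config))
    keyv <- c(keyv, rep(key, L)); locidx <- c(locidx, seq_len(L))
  }
  list(keys = keys[trained], offsets = stats::setNames(offs, keys[trained]),
       lengths = stats::setNames(lens, keys[trained]),
       theta = theta, mask = mask, exempt = exempt,
       label = labels, key = keyv, local_index = locidx)
}

# Attach global parameter offsets to prepared designs; every mapping of an
# included from-state must be trainable.
attach_offsets <- function(likdata, layout) {
  designs <- lapply(likdata$designs, function(des) {
    k <- paste0(des$state, "->", des$dests)
    if (!all(k %in% layout$keys))
      stopf("state %d has observations but untrained mapping(s)", des$state)
    des$map_off <- as.integer(layout$offsets[k])
    des
  })
  designs
}

apply_theta <- function(model, layout, theta, mask = NULL) {
  for (key in layout$keys) {
    o <- layout$offsets[[key]]; L <- layout$lengths[[key]]
    m <- model$maps[[key]]
    m$params <- unflattenSnn(theta[(o + 1):(o + L)], m$config)
    if (!is.null(mask)) {
      flat_mask <- mask[(o + 1):(o + L)]
      m$mask <- unflattenSnn(flat_mask, m$config)
    }
    model$maps[[key]] <- m
  }
  model
}

#' Train a model to convergence on the censored-data likelihood
#'
#' Full-batch Adam on the training negative log-likelihood; after every
#' iteration the per-observation test loss is evaluated, and training stops
#' once it has failed to improve by more than `min_improvement` for
#' `patience` consecutive iterations. The parameters achieving the best test
#' loss are returned. Masked parameters stay exactly zero throughout.
#'
#' @param model A `snnm_model` whose trainable maps are networks.
#' @param train,test Training and test `snnm_dataset`s.
#' @param config A [trainingConfig()].
#' @param patience Patience override (defaults to `config$patience_initial`).
#' @param trace_file Optional CSV path receiving per-iteration losses.
#' @return List with `model` (at the best test loss), `test_loss`,
#'   `train_loss`, `iterations` and the loss `trace` data frame.
#' @export
trainUntilConvergence <- function(model, train, test,
                                  config = trainingConfig(),
                                  patience = config$patience_initial,
                                  trace_file = NULL) {
  layout <- build_layout(model, train)
  dtrain <- attach_offsets(prepare_likelihood_data(train, model$input_names), layout)
  dtest <- attach_offsets(prepare_likelihood_data(test, model$input_names), layout)
  n_tr <- nrow(train$observations); n_te <- nrow(test$observations)

  theta <- layout$theta * layout$mask
  m1 <- numeric(length(theta)); m2 <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; epsA <- 1e-8; lr <- config$learning_rate

  test_loss <- .cpp_negloglik(theta, dtest) / n_te
  best_loss <- test_loss; best_theta <- theta; best_iter <- 0L
  ref_loss <- test_loss; stall <- 0L; it <- 0L
  trace <- vector("list", 0L)
  train_loss <- NA_real_
  while (it < config$max_iter) {
    it <- it + 1L
    g <- .cpp_negloglik_grad(theta, dtrain)
    if (!is.finite(g$loss))
      stopf("training diverged at iteration %d (non-finite loss)", it)
    grad <- g$grad * layout$mask
    m1 <- b1 * m1 + (1 - b1) * grad
    m2 <- b2 * m2 + (1 - b2) * grad^2
    mh <- m1 / (1 - b1^it); vh <- m2 / (1 - b2^it)
    theta <- theta - lr * mh / (sqrt(vh) + epsA)
    theta <- theta * layout$mask
    train_loss <- g$loss / n_tr
    test_loss <- .cpp_negloglik(theta, dtest) / n_te
    trace[[it]] <- c(iteration = it, train_loss = train_loss, test_loss = test_loss)
    if (test_loss < best_loss) { best_loss <- test_loss; best_theta <- theta; best_iter <- it }
    if (test_loss < ref_loss - config$min_improvement) {
      ref_loss <- test_loss; stall <- 0L
    } else {
      stall <- stall + 1L
    }
    if (stall >= patience) break
  }
  trace <- as.data.frame(do.call(rbind, trace))
  if (!is.null(trace_file))
    utils::write.csv(trace, trace_file, row.names = FALSE)
  list(model = apply_theta(model, layout, best_theta),
       test_loss = best_loss, train_loss = train_loss,
       iterations = it, best_iteration = best_iter, trace = trace,
       layout = layout)
}

#' Parameter salience
#'
#' Importance of a parameter as its squared value times the corresponding
#' diagonal element of the loss Hessian. Negative curvature gives negative
#' salience, which ranks lowest for removal.
#'
#' @param gamma Parameter value(s).
#' @param hessian_diag Matching diagonal Hessian element(s).
#' @return `gamma^2 * hessian_diag`, vectorized.
#' @export
parameterSalience <- function(gamma, hessian_diag) gamma^2 * hessian_diag

#' Central-difference diagonal Hessian of a scalar function
#'
#' Generic second-difference estimator
#' `(f(x + h e_k) - 2 f(x) + f(x - h e_k)) / h^2` with a per-coordinate step
#' `h * max(1, |x_k|)`.
#'
#' @param f Scalar function of a parameter vector.
#' @param theta Evaluation point.
#' @param idx Coordinates to differentiate (default: all).
#' @param h Relative step.
#' @return Numeric vector of diagonal Hessian estimates for `idx`.
#' @export
hessianDiagFD <- function(f, theta, idx = seq_along(theta), h = 1e-3) {
  f0 <- f(theta)
  vapply(idx, function(k) {
    hk <- h * max(1, abs(theta[k]))
    tp <- theta; tp[k] <- tp[k] + hk
    tm <- theta; tm[k] <- tm[k] - hk
    (f(tp) - 2 * f0 + f(tm)) / hk^2
  }, 0)
}

# Sample one Hessian batch: per_transition observed events of every observed
# transition type plus per_censored right-censored observations (with
# replacement when a stratum is smaller than requested).
sample_batch_obs <- function(obs, per_transition, per_censored) {
  ev <- which(!is.na(obs$to_state))
  type <- paste0(obs$from_state, "->", obs$to_state)[ev]
  pick <- integer(0)
  for (ty in unique(type)) {
    rows <- ev[type == ty]
    pick <- c(pick, if (length(rows) >= per_transition) sample(rows, per_transition)
              else sample(rows, per_transition, replace = TRUE))
  }
  cens <- which(is.na(obs$to_state))
  if (length(cens))
    pick <- c(pick, if (length(cens) >= per_censored) sample(cens, per_censored)
              else sample(cens, per_censored, replace = TRUE))
  sort(pick)
}

subset_observations <- function(dataset, rows) {
  d <- dataset
  d$observations <- dataset$observations[rows, , drop = FALSE]
  rownames(d$observations) <- NULL
  d
}

#' Sampled diagonal Hessian of the loss
#'
#' Draws `n_batches` observation batches (each with `per_transition` observed
#' events of every transition type and `per_censored` right-censored
#' observations), computes the diagonal Hessian of the batch loss for every
#' active parameter, and returns the elementwise median across batches.
#'
#' @param model A `snnm_model` with network maps.
#' @param dataset A `snnm_dataset`.
#' @param n_batches,per_transition,per_censored Sampling plan.
#' @param seed Integer seed.
#' @param fd_step Relative finite-difference step.
#' @return Data frame with one row per active parameter: mapping key,
#'   parameter label, value and the median batch Hessian `H`.
#' @export
sampledHessian <- function(model, dataset, n_batches = 10L,
                           per_transition = 30L, per_censored = 30L,
                           seed = 1L, fd_step = 1e-3) {
  layout <- build_layout(model, dataset)
  theta <- layout$theta * layout$mask
  active <- which(layout$mask > 0)
  old <- .Random.seed_exists(); on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  Hb <- matrix(NA_real_, length(active), n_batches)
  for (b in seq_len(n_batches)) {
    rows <- sample_batch_obs(dataset$observations, per_transition, per_censored)
    batch <- subset_observations(dataset, rows)
    dsg <- attach_offsets(prepare_likelihood_data(batch, model$input_names), layout)
    Hb[, b] <- .cpp_hessian_diag(theta, dsg, as.integer(active - 1L), fd_step)
  }
  H <- apply(Hb, 1, stats::median, na.rm = TRUE)
  data.frame(key = layout$key[active], label = layout$label[active],
             local_index = layout$local_index[active],
             gamma = theta[active], H = H, stringsAsFactors = FALSE)
}

# Exact diagonal Hessian on the full dataset for the active parameters.
exact_hessian <- function(model, dataset, layout, fd_step = 1e-3) {
  theta <- layout$theta * layout$mask
  active <- which(layout$mask > 0)
  dsg <- attach_offsets(prepare_likelihood_data(dataset, model$input_names), layout)
  H <- .cpp_hessian_diag(theta, dsg, as.integer(active - 1L), fd_step)
  data.frame(key = layout$key[active], label = layout$label[active],
             local_index = layout$local_index[active],
             gamma = theta[active], H = H, stringsAsFactors = FALSE)
}

#' Salience report for every active parameter
#'
#' Uses the sampled Hessian for mappings whose from-state has more
#' observations than `config$hessian_sample_threshold` and the exact
#' full-data diagonal Hessian otherwise; salience is
#' [parameterSalience()] of each active parameter. The sigmoid-head bias of
#' each mapping is marked exempt so every mapping retains at least a
#' constant.
#'
#' @param model A `snnm_model`.
#' @param dataset Training `snnm_dataset`.
#' @param config A [trainingConfig()].
#' @param seed Seed for batch sampling.
#' @return Data frame: key, label, local_index, gamma, H, S, exempt.
#' @export
salienceReport <- function(model, dataset, config = trainingConfig(),
                           seed = config$seed) {
  layout <- build_layout(model, dataset)
  counts <- table(dataset$observations$from_state)
  exact <- exact_hessian(model, dataset, layout, config$fd_step)
  rep <- exact
  from <- as.integer(sub("->.*", "", rep$key))
  big <- as.integer(names(counts))[counts > config$hessian_sample_threshold]
  if (length(big)) {
    samp <- sampledHessian(model, dataset, config$hessian_batches,
                           config$per_transition, config$per_censored,
                           seed = seed, fd_step = config$fd_step)
    sel <- from %in% big
    stopifnot(identical(samp$label, rep$label), identical(samp$key, rep$key))
    rep$H[sel] <- samp$H[sel]
  }
  active <- which(layout$mask > 0)
  rep$S <- parameterSalience(rep$gamma, rep$H)
  rep$exempt <- layout$exempt[active]
  rep
}

#' Remove the least-salient parameters
#'
#' Sets the `n_remove` lowest-salience active, non-exempt parameters to zero
#' and masks them. Ties are broken by the stable enumeration order
#' (transition pair, then parameter position).
#'
#' @param model A `snnm_model`.
#' @param n_remove Number of parameters to remove.
#' @param salience A [salienceReport()] data frame.
#' @param restrict_keys Optional mapping keys to which removal is confined
#'   (used to enforce the per-mapping cap).
#' @return The pruned `snnm_model`.
#' @export
pruneStep <- function(model, n_remove, salience, restrict_keys = NULL) {
  if (n_remove == 0) return(model)
  cand <- salience[!salience$exempt, , drop = FALSE]
  if (!is.null(restrict_keys)) cand <- cand[cand$key %in% restrict_keys, , drop = FALSE]
  if (!nrow(cand)) stopf("no prunable parameters remain")
  n_remove <- min(n_remove, nrow(cand))
  cand <- cand[order(cand$S, cand$key, cand$local_index), , drop = FALSE]
  drop <- cand[seq_len(n_remove), , drop = FALSE]
  for (i in seq_len(nrow(drop))) {
    key <- drop$key[i]; li <- drop$local_index[i]
    m <- model$maps[[key]]
    fm <- flattenSnn(m$mask); fp <- flattenSnn(m$params)
    fm[li] <- 0; fp[li] <- 0
    m$mask <- unflattenSnn(fm, m$config)
    m$params <- unflattenSnn(fp, m$config)
    model$maps[[key]] <- m
  }
  model
}

#' Alternate pruning and retraining until the loss degrades
#'
#' Starting from a trained model, repeatedly removes the least-salient
#' parameters (20, 10, 5, 5 in the first four iterations, then
#' `prune_tail` per iteration) and retrains to convergence with the pruning
#' patience. While any mapping exceeds the per-mapping cap, removal is
#' confined to the over-cap mappings and loss degradation does not stop the
#' loop; once every mapping is within the cap, a retrained test loss
#' exceeding the running best by more than `loss_degradation` (relative)
#' reverts the last prune and terminates. Exhausting all prunable parameters
#' also terminates cleanly.
#'
#' @param model A trained `snnm_model`.
#' @param train,test Training and test datasets.
#' @param config A [trainingConfig()].
#' @param quiet Suppress per-iteration messages.
#' @return List with `model`, `history` (per-iteration losses and active
#'   counts) and `stopped` (reason).
#' @export
runPruningLoop <- function(model, train, test, config = trainingConfig(),
                           quiet = TRUE) {
  layout <- build_layout(model, train)
  dtest <- attach_offsets(prepare_likelihood_data(test, model$input_names), layout)
  n_te <- nrow(test$observations)
  theta <- layout$theta * layout$mask
  best_loss <- .cpp_negloglik(theta, dtest) / n_te
  best_model <- model
  history <- list()
  stopped <- "max_prune_iter"
  for (i in seq_len(config$max_prune_iter)) {
    n_rm <- if (i <= length(config$prune_schedule)) config$prune_schedule[i]
            else config$prune_tail
    counts <- modelActiveCounts(model)[layout$keys]
    over <- names(counts)[counts > config$max_params_per_map]
    sal <- salienceReport(model, train, config, seed = sub_seed(config$seed, i))
    cand <- sal[!sal$exempt, , drop = FALSE]
    if (length(over)) cand <- cand[cand$key %in% over, , drop = FALSE]
    if (!nrow(cand)) { stopped <- "exhausted"; break }
    prev_model <- model
    model <- pruneStep(model, n_rm, sal,
                       restrict_keys = if (length(over)) over else NULL)
    fit <- trainUntilConvergence(model, train, test, config,
                                 patience = config$patience_pruning)
    model <- fit$model
    counts_after <- modelActiveCounts(model)[layout$keys]
    history[[i]] <- data.frame(
      iteration = i, n_removed = min(n_rm, nrow(cand)),
      test_loss = fit$test_loss, train_loss = fit$train_loss,
      n_active = sum(counts_after), max_per_map = max(counts_after))
    if (!quiet)
      message(sprintf("prune %d: removed %d, test loss %.4f, active %d (max/map %d)",
                      i, min(n_rm, nrow(cand)), fit$test_loss,
                      sum(counts_after), max(counts_after)))
    cap_ok <- all(counts_after <= config$max_params_per_map)
    if (cap_ok && fit$test_loss > best_loss * (1 + config$loss_degradation)) {
      prev_ok <- all(modelActiveCounts(prev_model)[layout$keys] <=
                       config$max_params_per_map)
      if (prev_ok) {
        # revert the final prune; the cap stays satisfied
        model <- prev_model
        stopped <- "loss_degradation"
      } else {
        # the prune that crossed the cap cannot be reverted: the cap is hard
        stopped <- "loss_degradation_capped"
      }
      break
    }
    if (fit$test_loss < best_loss) { best_loss <- fit$test_loss; best_model <- model }
  }
  list(model = model, best_model = best_model, best_loss = best_loss,
       history = do.call(rbind, history), stopped = stopped)
}

#' Train and prune in one call
#'
#' Initial training to convergence with `patience_initial`, followed by
#' [runPruningLoop()].
#'
#' @inheritParams runPruningLoop
#' @return As [runPruningLoop()], plus `initial_fit`.
#' @export
fitPruneModel <- function(model, train, test, config = trainingConfig(),
                          quiet = TRUE) {
  fit <- trainUntilConvergence(model, train, test, config,
                               patience = config$patience_initial)
  if (!quiet) message(sprintf("initial training: %d iterations, test loss %.4f",
                              fit$iterations, fit$test_loss))
  out <- runPruningLoop(fit$model, train, test, config, quiet = quiet)
  out$initial_fit <- fit[c("test_loss", "train_loss", "iterations")]
  out
}
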