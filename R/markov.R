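# Transition structure, row-stochastic matrix assembly with the boundary
# rescaling rule, and state-occupancy propagation.

#' Structure mask of the progression model
#'
#' @return List with `allowed` (two-column matrix of permitted transitions),
#'   `n_states` and `absorbing`.
#' @export
structureMask <- function() {
  list(allowed = allowedTransitions(), n_states = 5L, absorbing = 5L)
}

# Destinations reachable from each transient state, ascending.
state_destinations <- function() {
  list(`1` = c(2L, 3L, 5L), `2` = c(4L, 5L), `3` = c(4L, 5L), `4` = 5L)
}

#' Rescale one row of off-diagonal transition probabilities
#'
#' Raw per-transition probabilities come from independent sigmoid mappings, so
#' within a row they may sum to 1 or more. When they do, the row is rescaled
#' by stick-breaking in ascending destination order, using the original
#' values: the first entry is kept, and the n-th is multiplied by the product
#' of (1 - original earlier entries). The rescaled sum is
#' `1 - prod(1 - lambda) < 1`. Rows already summing below 1 are returned
#' unchanged.
#'
#' @param off_diag Numeric vector of raw probabilities in `[0, 1)`, ordered by
#'   ascending destination state.
#' @return Numeric vector of the same length with sum < 1.
#' @export
enforceRowBound <- function(off_diag) {
  if (any(off_diag < 0 | off_diag >= 1)) stopf("row entries must lie in [0, 1)")
  if (sum(off_diag) < 1) return(off_diag)
  off_diag * cumprod(c(1, 1 - off_diag[-length(off_diag)]))
}

#' Assemble a full transition probability matrix
#'
#' Off-diagonal entries are placed at their allowed positions, each diagonal
#' element is the complement `1 - sum(off-diagonals of the row)`, disallowed
#' entries are exactly zero and the absorbing death state has probability one
#' of remaining. The per-row sum bound ([enforceRowBound()]) is assumed to
#' have been applied already.
#'
#' @param off_diag_by_pair Named numeric vector; names like `"1->2"` for the
#'   allowed pairs present. Missing pairs default to zero.
#' @return A 5x5 row-stochastic matrix of class `snnm_transition_matrix`.
#' @export
assembleTransitionMatrix <- function(off_diag_by_pair) {
  allowed <- allowedTransitions()
  keys <- paste0(allowed[, 1], "->", allowed[, 2])
  bad <- setdiff(names(off_diag_by_pair), keys)
  if (length(bad)) stopf("transition(s) outside the structure mask: %s",
                         paste(bad, collapse = ", "))
  P <- matrix(0, 5, 5)
  for (nm in names(off_diag_by_pair)) {
    mn <- as.integer(strsplit(nm, "->", fixed = TRUE)[[1]])
    v <- off_diag_by_pair[[nm]]
    if (v < 0 || v >= 1) stopf("probability for %s outside [0, 1)", nm)
    P[mn[1], mn[2]] <- v
  }
  for (m in 1:4) {
    s <- sum(P[m, -m])
    if (s >= 1) stopf("row %d sums to %.4f >= 1; apply enforceRowBound first", m, s)
    P[m, m] <- 1 - s
  }
  P[5, 5] <- 1
  structure(P, class = c("snnm_transition_matrix", "matrix", "array"))
}

validate_transition_matrix <- function(P, tol = 1e-12) {
  if (!is.matrix(P) || any(dim(P) != 5)) stopf("transition matrix must be 5x5")
  if (any(P < -tol | P > 1 + tol)) stopf("transition probabilities outside [0, 1]")
  if (any(abs(rowSums(P) - 1) > tol)) stopf("transition matrix rows must sum to 1")
  allowed <- allowedTransitions()
  ok <- diag(5) > 0
  ok[allowed] <- TRUE
  if (any(P[!ok] != 0)) stopf("nonzero entry at a disallowed transition")
  invisible(P)
}

#' Propagate state occupancy through a sequence of transition matrices
#'
#' Left-multiplies the occupancy row vector by each matrix in order
#' (`pi(t) = pi0 %*% P(0) %*% ... %*% P(t-1)`), returning the occupancy after
#' each step.
#'
#' @param pi0 Initial occupancy, a length-5 probability vector (default: all
#'   mass in state 1).
#' @param matrices List of 5x5 transition matrices, in time order.
#' @return Matrix with one row per step (plus attribute-free base row omitted),
#'   `length(matrices)` rows and 5 columns; row t is the occupancy after t
#'   steps.
#' @export
propagateOccupancy <- function(pi0 = c(1, 0, 0, 0, 0), matrices) {
  if (!length(matrices)) stopf("need at least one transition matrix")
  if (length(pi0) != 5 || any(pi0 < 0) || abs(sum(pi0) - 1) > 1e-12)
    stopf("pi0 must be a length-5 probability vector")
  out <- matrix(NA_real_, length(matrices), 5)
  v <- matrix(pi0, 1, 5)
  for (i in seq_along(matrices)) {
    validate_transition_matrix(matrices[[i]])
    v <- v %*% matrices[[i]]
    out[i, ] <- v
  }
  out
}
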