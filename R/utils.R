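# Internal numerical helpers shared across modules.

#' Logistic (sigmoid) function
#'
#' Numerically stable evaluation of `1 / (1 + exp(-x))`, the output head of
#' every transition mapping.
#'
#' @param x Numeric vector of logits.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
sigm <- function(x) {
  out <- ifelse(x >= 0, 1 / (1 + exp(-x)), exp(x) / (1 + exp(x)))
  out
}

# log(sum(exp(x))) without overflow; x may contain -Inf.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Derive a reproducible 32-bit sub-seed from a base seed and a stream label.
sub_seed <- function(seed, stream) {
  (as.integer(seed) %% 1009L) * 104729L %% 2147483647L +
    (sum(utf8ToInt(as.character(stream))) * 7919L) %% 1048573L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
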