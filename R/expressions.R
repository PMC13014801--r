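# Extraction of closed-form expressions from (pruned) symbolic networks.
#
# Expressions are stored as R language objects over the input symbols, the
# arithmetic grammar of the network (+, *, the guarded power
# (|.| + eps)^(.), the bounded division ./(|.|+1)) and the sigmoid head, and
# are wrapped in a light S3 container that remembers the input names.
# Extraction is exact: constants are folded at full precision, so the
# expression and the network agree pointwise to floating-point accuracy.

new_expression <- function(lang, inputs) {
  structure(list(expr = lang, inputs = inputs), class = "snnm_expression")
}

is_const <- function(e) is.numeric(e) && length(e) == 1L

expr_has_symbols <- function(e) {
  if (is.name(e)) return(TRUE)
  if (is.call(e)) return(any(vapply(as.list(e)[-1], expr_has_symbols, TRUE)))
  FALSE
}

fold_expr <- function(e) {
  if (!is.call(e)) return(e)
  args <- lapply(as.list(e)[-1], fold_expr)
  e <- as.call(c(e[[1]], args))
  if (!expr_has_symbols(e))
    return(eval(e, envir = list(sigm = sigm), enclos = baseenv()))
  e
}

e_add <- function(a, b) {
  if (is_const(a) && a == 0) return(b)
  if (is_const(b) && b == 0) return(a)
  if (is_const(a) && is_const(b)) return(a + b)
  if (is_const(b) && b < 0) return(call("-", a, -b))
  call("+", a, b)
}

e_mul <- function(a, b) {
  if ((is_const(a) && a == 0) || (is_const(b) && b == 0)) return(0)
  if (is_const(a) && a == 1) return(b)
  if (is_const(b) && b == 1) return(a)
  if (is_const(a) && is_const(b)) return(a * b)
  call("*", a, b)
}

# Affine combination sum_j w_j * terms_j + b with zero-weight terms dropped.
e_affine <- function(w, b, terms) {
  out <- if (b != 0) b else 0
  for (j in seq_along(terms)) {
    if (w[j] == 0) next
    out <- e_add(out, e_mul(w[j], terms[[j]]))
  }
  out
}

# The guarded power unit (|base| + eps)^expo.
e_power <- function(base, expo) {
  guarded <- if (is_const(base)) abs(base) + POWER_EPS
             else call("+", call("abs", base), POWER_EPS)
  if (is_const(expo)) {
    if (expo == 0) return(1)
    if (expo == 1) return(guarded)
  }
  if (is_const(guarded) && is_const(expo)) return(guarded^expo)
  call("^", guarded, expo)
}

# The bounded division unit num / (|den| + 1).
e_div <- function(num, den) {
  if (is_const(num) && num == 0) return(0)
  dd <- if (is_const(den)) abs(den) + 1 else call("+", call("abs", den), 1)
  if (is_const(dd) && dd == 1) return(num)
  if (is_const(num) && is_const(dd)) return(num / dd)
  call("/", num, dd)
}

#' Extract the closed-form expression computed by a network
#'
#' Composes the affine layers and activation units symbolically, dropping
#' masked/zero-weight terms and folding constant subexpressions at full
#' precision. Works on dense or pruned networks; the result and
#' [snnForward()] agree pointwise.
#'
#' @param snn A `snnm_snn_params` object.
#' @param input_names Names of the covariate inputs, in order.
#' @return A `snnm_expression`.
#' @export
extractExpression <- function(snn, input_names) {
  if (length(input_names) != snn$config$n_inputs)
    stopf("need %d input names", snn$config$n_inputs)
  p <- snn$params; m <- snn$mask
  syms <- lapply(input_names, as.name)
  W1 <- p$W1 * m$W1; b1 <- p$b1 * m$b1
  W2 <- p$W2 * m$W2; b2 <- p$b2 * m$b2
  W3 <- p$W3 * m$W3; b3 <- p$b3 * m$b3
  z1 <- lapply(1:5, function(i) e_affine(W1[i, ], b1[i], syms))
  x2 <- list(z1[[1]], e_mul_sym(z1[[2]], z1[[3]]), e_power(z1[[4]], z1[[5]]))
  z2 <- lapply(1:5, function(i) e_affine(W2[i, ], b2[i], x2))
  x3 <- list(z2[[1]], e_mul_sym(z2[[2]], z2[[3]]), e_div(z2[[4]], z2[[5]]))
  head <- e_affine(W3, b3, x3)
  # fold constants inside the logit but keep the sigmoid head symbolic, so a
  # bias-only network reads as sigm(b) rather than a bare probability
  lang <- as.call(list(as.name("sigm"), fold_expr(head)))
  new_expression(lang, input_names)
}

# Product unit: symbolic product of two subexpressions (not weight * term).
e_mul_sym <- function(a, b) {
  if ((is_const(a) && a == 0) || (is_const(b) && b == 0)) return(0)
  if (is_const(a) && is_const(b)) return(a * b)
  if (is_const(a) && a == 1) return(b)
  if (is_const(b) && b == 1) return(a)
  call("*", if (is.call(a) && !is_wrapped(a)) call("(", a) else a,
            if (is.call(b) && !is_wrapped(b)) call("(", b) else b)
}

is_wrapped <- function(e) {
  is.call(e) && (identical(e[[1]], as.name("(")) ||
                 identical(e[[1]], as.name("abs")) ||
                 identical(e[[1]], as.name("sigm")))
}

#' Evaluate a symbolic expression on covariate values
#'
#' @param expr A `snnm_expression` (or a bare language object).
#' @param phi Named numeric vector, or a list/data frame of equal-length
#'   vectors, supplying every input symbol.
#' @return Numeric vector of expression values.
#' @export
evalExpression <- function(expr, phi) {
  lang <- if (inherits(expr, "snnm_expression")) expr$expr else expr
  if (is.matrix(phi)) phi <- as.data.frame(phi)
  env <- list2env(as.list(phi), parent = asNamespace("snnmarkov"))
  v <- eval(lang, envir = env)
  if (is_const(lang) || !expr_has_symbols(lang)) {
    n <- if (is.data.frame(phi)) nrow(phi) else 1L
    v <- rep(as.numeric(v), n)
  }
  v
}

#' Symbols appearing in an expression
#'
#' @param expr A `snnm_expression` or bare language object.
#' @return Character vector of distinct input symbols used.
#' @export
expressionSymbols <- function(expr) {
  lang <- if (inherits(expr, "snnm_expression")) expr$expr else expr
  found <- character()
  walk <- function(e) {
    if (is.name(e)) found[[length(found) + 1L]] <<- as.character(e)
    else if (is.call(e)) lapply(as.list(e)[-1], walk)
    invisible(NULL)
  }
  walk(lang)
  unique(found)
}

#' Inputs an expression effectively depends on
#'
#' A pruned network can retain an input symbol in a functionally inert way:
#' with binary covariates coded -0.5/+0.5, a term like `(|w * SEX| + eps)^c`
#' is constant across both levels. Covariate selection is therefore judged by
#' functional dependence: an input is effective when varying it over its
#' range (other inputs held at sampled base points) changes the expression
#' value by more than `tol`.
#'
#' @param expr A `snnm_expression`.
#' @param ranges Named list giving, for each input, a numeric range
#'   `c(lo, hi)` (sampled continuously), or — for inputs named in
#'   `discrete` — the finite set of values the input takes.
#' @param discrete Names of inputs whose `ranges` entry is a finite value set
#'   (binary covariates coded -0.5/+0.5 must be probed at exactly those two
#'   values).
#' @param n Number of random base points.
#' @param n_var Number of probe values per varied continuous input.
#' @param tol Spread above which an input counts as effective.
#' @param seed Seed for the base-point draw.
#' @return Character vector of effective input names.
#' @export
effectiveInputs <- function(expr, ranges, discrete = character(),
                            n = 24, n_var = 7, tol = 1e-8, seed = 1L) {
  inputs <- expr$inputs
  miss <- setdiff(inputs, names(ranges))
  if (length(miss)) stopf("no range given for input(s): %s", paste(miss, collapse = ", "))
  old <- .Random.seed_exists(); on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  draw <- function(nm, k) {
    r <- ranges[[nm]]
    if (!nm %in% discrete) stats::runif(k, r[1], r[2])
    else r[sample.int(length(r), k, replace = TRUE)]
  }
  probes <- function(nm) {
    r <- ranges[[nm]]
    if (!nm %in% discrete) seq(r[1], r[2], length.out = n_var) else r
  }
  base <- as.data.frame(stats::setNames(lapply(inputs, draw, k = n), inputs))
  eff <- character(0)
  for (nm in inputs) {
    vals <- probes(nm)
    out <- vapply(vals, function(v) {
      b <- base; b[[nm]] <- v
      evalExpression(expr, b)
    }, numeric(n))
    spread <- max(apply(out, 1, function(x) diff(range(x))))
    if (spread > tol) eff <- c(eff, nm)
  }
  eff
}

#' Format an expression for display
#'
#' Coefficients are rounded for printing only; the stored expression keeps
#' full precision.
#'
#' @param expr A `snnm_expression` or bare language object.
#' @param digits Significant decimal places for displayed constants.
#' @return A single character string.
#' @export
formatExpression <- function(expr, digits = 2) {
  lang <- if (inherits(expr, "snnm_expression")) expr$expr else expr
  rounded <- round_consts(lang, digits)
  paste(deparse(rounded, width.cutoff = 500L), collapse = " ")
}

round_consts <- function(e, digits) {
  if (is_const(e)) {
    r <- signif(e, max(digits + 1, ceiling(log10(abs(e) + 1e-300)) + digits))
    return(round(r, digits = max(digits, -floor(log10(abs(e) + 1e-300)) + digits)))
  }
  if (is.call(e)) {
    args <- lapply(as.list(e)[-1], round_consts, digits = digits)
    return(as.call(c(e[[1]], args)))
  }
  e
}

#' @export
print.snnm_expression <- function(x, ...) {
  cat(formatExpression(x), "\n")
  invisible(x)
}

# --- JSON serialization of expression trees -------------------------------

expr_to_tree <- function(e) {
  if (is_const(e)) return(list(constant = as.numeric(e)))
  if (is.name(e)) return(list(symbol = as.character(e)))
  if (is.call(e)) {
    if (identical(e[[1]], as.name("("))) return(expr_to_tree(e[[2]]))
    return(list(op = as.character(e[[1]]),
                args = lapply(as.list(e)[-1], expr_to_tree)))
  }
  stopf("unsupported expression node")
}

tree_to_expr <- function(t) {
  if (!is.null(t$constant)) return(as.numeric(t$constant))
  if (!is.null(t$symbol)) return(as.name(t$symbol))
  as.call(c(as.name(t$op), lapply(t$args, tree_to_expr)))
}

#' Serialize an expression to a JSON tree
#'
#' @param expr A `snnm_expression`.
#' @return A JSON string with node types `constant`, `symbol`, `op/args`.
#' @export
expressionToJson <- function(expr) {
  jsonlite::toJSON(list(inputs = expr$inputs, tree = expr_to_tree(expr$expr)),
                   auto_unbox = TRUE, digits = NA)
}

#' Rebuild an expression from its JSON tree
#'
#' @param json JSON string produced by [expressionToJson()].
#' @return A `snnm_expression`.
#' @export
expressionFromJson <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  new_expression(tree_to_expr(obj$tree), unlist(obj$inputs))
}
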