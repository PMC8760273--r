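#' @useDynLib actinet, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats runif rbinom
NULL

# Global probability floor applied before any logarithm.  The variational
# expressions are undefined at exact 0/1; a single package-wide floor keeps
# every module consistent.
.ACTINET_EPS <- 1e-9

# Clip ratio used before inverse-sigmoid transforms of conditional ratios
# (synaptic fixed points diverge at 0/1).
.ACTINET_RATIO_EPS <- 1e-6

#' Logistic (sigmoid) function and its inverse
#'
#' `sig()` maps membrane potentials to firing rates in (0, 1); `sig_inv()`
#' is the logit, mapping probabilities to synaptic-strength space.
#' `sig_inv()` clips its argument to `(eps, 1 - eps)` first.
#'
#' @param u numeric vector or matrix.
#' @param p numeric vector or matrix of probabilities.
#' @param eps clipping bound for `sig_inv`.
#' @return numeric object of the same shape.
#' @export
sig <- function(u) 1 / (1 + exp(-u))

#' @rdname sig
#' @export
sig_inv <- function(p, eps = .ACTINET_RATIO_EPS) {
  p <- pmin(pmax(p, eps), 1 - eps)
  log(p) - log1p(-p)
}

# Floored natural log: log(max(p, eps)).
ln_floor <- function(p, eps = .ACTINET_EPS) log(pmax(p, eps))

# Per-factor two-way softmax: given logits for the "=1" and "=0" components,
# return the probability of the "=1" component.  Numerically stable.
softmax_pair <- function(u1, u0) {
  m <- pmax(u1, u0)
  e1 <- exp(u1 - m)
  e0 <- exp(u0 - m)
  e1 / (e1 + e0)
}

# Enumerate joint binary assignments of n factors as a (2^n) x n matrix with
# entries in {1, 0}.  Row 1 is all ones; factor 1 varies fastest.  This fixes
# the assignment ordering used by expand_mapping() and the exact-enumeration
# oracles in the tests.
enumerate_assignments <- function(n) {
  stopifnot(n >= 1)
  k <- 2L^n
  out <- matrix(1L, k, n)
  for (j in seq_len(n)) {
    out[, j] <- 1L - bitwAnd(bitwShiftR(seq_len(k) - 1L, j - 1L), 1L)
  }
  out
}

# Deterministic 31-bit polynomial hash of a character scalar, as 8 hex
# digits.  Used to stamp run directories and config snapshots without
# external dependencies (not cryptographic).
string_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 5381
  for (b in utf8ToInt(x)) {
    h <- (h * 31 + b) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
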