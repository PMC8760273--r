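#' Dirichlet concentration array for a factorised mapping
#'
#' Concentration parameters with the same `(2, 2, n_out, n_in)` layout as the
#' mapping they parameterise: each column (input component, factor pair) is
#' an independent two-component Dirichlet over the output components.
#'
#' @param conc nonnegative numeric array `(2, 2, n_out, n_in)`, or a scalar
#'   replicated to that shape via `n_out`, `n_in`.
#' @param n_out,n_in factor counts when `conc` is scalar.
#' @return numeric array of class `dirichlet_array`.
#' @export
dirichlet_array <- function(conc, n_out = NULL, n_in = NULL) {
  if (length(conc) == 1L) {
    stopifnot(!is.null(n_out), !is.null(n_in))
    conc <- array(conc, c(2, 2, n_out, n_in))
  }
  stopifnot(is.array(conc), length(dim(conc)) == 4L, all(dim(conc)[1:2] == 2L))
  if (any(conc <= 0)) stop("dirichlet_array: concentrations must be positive")
  structure(conc, class = "dirichlet_array")
}

#' Dirichlet bank for the three mapping posteriors
#'
#' Holds concentration arrays for the likelihood (a), transition (b) and
#' policy (c) mappings together with frozen prior copies, supporting the
#' count-based parameter learning rule with delayed risk modulation.
#'
#' @param a,b,c `dirichlet_array` objects (or arrays) for A, B, C.
#' @return object of class `dirichlet_bank` with fields `a`, `b`, `c` and
#'   prior copies `a0`, `b0`, `c0`.
#' @export
dirichlet_bank <- function(a, b, c) {
  a <- dirichlet_array(unclass(a)); b <- dirichlet_array(unclass(b))
  c <- dirichlet_array(unclass(c))
  structure(list(a = a, b = b, c = c, a0 = a, b0 = b, c0 = c),
            class = "dirichlet_bank")
}

#' Posterior expectations of a categorical mapping under a Dirichlet belief
#'
#' Returns the mean mapping and the expected log mapping.  The exact log
#' expectation uses the digamma function; the `"log-ratio"` mode replaces it
#' by the logarithm of the mean, the large-concentration approximation whose
#' error is of order one over the column concentration total (this is the
#' regime in which the network/Bayes dictionary is an identity).
#'
#' @param conc a `dirichlet_array` (or plain array) of concentrations.
#' @param mode `"digamma"` (default, exact) or `"log-ratio"`.
#' @return list with `mean` (array, columns summing to 1) and `logmean`.
#' @export
dirichlet_expectations <- function(conc, mode = c("digamma", "log-ratio")) {
  mode <- match.arg(mode)
  conc <- unclass(conc)
  if (any(conc <= 0)) stop("dirichlet_expectations: nonpositive concentration")
  tot <- conc[1, , , , drop = FALSE] + conc[2, , , , drop = FALSE]
  tot2 <- conc
  tot2[1, , , ] <- tot; tot2[2, , , ] <- tot
  mean_ <- conc / tot2
  logmean <- if (mode == "digamma") digamma(conc) - digamma(tot2) else log(mean_)
  list(mean = mean_, logmean = logmean)
}

# Per-pair transpose of a concentration array: the bank for the inverse
# mapping orientation.  inv[c_in, c_out, j, i] = conc[c_out, c_in, i, j].
# Normalising the transposed bank's columns yields the co-occurrence-ratio
# inverse mapping that the network's synapses encode.
transpose_concentrations <- function(conc) {
  conc <- unclass(conc)
  d <- dim(conc)
  aperm(conc, c(2, 1, 4, 3))
}

# Wrap a mean array as a factorized_mapping of the given kind.
mean_as_mapping <- function(mean_arr, kind) {
  factorized_mapping(kind, mean_arr)
}

#' Accumulate Dirichlet parameter updates from a history
#'
#' Implements the count-based parameter posteriors: the likelihood
#' concentrations gain `o_tau (x) s_tau`, the transition concentrations gain
#' `s_tau (x) s_{tau-1}`, and the policy concentrations gain the
#' risk-modulated decision/state co-occurrences, with the present-time
#' decision entering unmodulated.  Anti-Hebbian histories can drive policy
#' concentrations nonpositive; those entries are clamped at `floor` with a
#' warning.
#'
#' @param bank a `dirichlet_bank`.
#' @param o matrix `n_o x T` of observed 1-components (binary or graded).
#' @param s matrix `n_s x T` of state posterior 1-components.
#' @param s_prev matrix `n_s x T`; column `tau` holds the belief about the
#'   state one step earlier (column 1 is the initial belief).
#' @param delta matrix `n_d x T` of decision 1-components (realized decisions
#'   as one-hot columns).
#' @param Gamma_t scalar risk in `[0, 1]` attached to the whole history
#'   (columns before the last are modulated by `1 - 2 Gamma_t`).
#' @param floor clamp value for nonpositive concentrations.
#' @return the updated `dirichlet_bank`.
#' @export
update_parameters <- function(bank, o, s, s_prev, delta, Gamma_t,
                              floor = 1e-6) {
  stopifnot(inherits(bank, "dirichlet_bank"))
  o <- as.matrix(o); s <- as.matrix(s)
  s_prev <- as.matrix(s_prev); delta <- as.matrix(delta)
  T_ <- ncol(o)
  if (T_ == 0L) stop("update_parameters: empty history")
  stopifnot(ncol(s) == T_, ncol(s_prev) == T_, ncol(delta) == T_,
            Gamma_t >= 0, Gamma_t <= 1)

  pair_counts <- function(post, pre, w = NULL) {
    # 2 x 2 x n_out x n_in array of weighted co-occurrence sums over time
    postc <- 1 - post
    if (!is.null(w)) {
      post <- sweep(post, 2, w, "*")
      postc <- sweep(postc, 2, w, "*")
    }
    out <- array(0, c(2, 2, nrow(post), nrow(pre)))
    out[1, 1, , ] <- tcrossprod(post, pre)
    out[1, 2, , ] <- tcrossprod(post, 1 - pre)
    out[2, 1, , ] <- tcrossprod(postc, pre)
    out[2, 2, , ] <- tcrossprod(postc, 1 - pre)
    out
  }

  # likelihood: o (x) s
  bank$a <- dirichlet_array(unclass(bank$a) + pair_counts(o, s))
  # transition: s (x) s_prev
  bank$b <- dirichlet_array(unclass(bank$b) + pair_counts(s, s_prev))
  # policy: modulated past + unmodulated present
  w <- c(rep(1 - 2 * Gamma_t, max(T_ - 1L, 0L)), 1)
  cc <- unclass(bank$c) + pair_counts(delta, s_prev, w)
  n_clamped <- sum(cc <= 0)
  if (n_clamped > 0) {
    warning(sprintf(
      "update_parameters: %d policy concentration(s) clamped at %g",
      n_clamped, floor))
    cc[cc <= 0] <- floor
  }
  bank$c <- dirichlet_array(cc)
  bank
}
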