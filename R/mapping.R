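#' Factorised stochastic mapping
#'
#' A categorical mapping between two binary-factorised spaces, stored as one
#' 2 x 2 column-stochastic submatrix per (output factor, input factor) pair,
#' with the usual outer-product expansion rule.  The likelihood mapping A,
#' decision-averaged transition mapping B and policy mapping C all take this
#' form, as do their (column-stochastic) Bayes inverses.
#'
#' Component index 1 corresponds to the factor taking value 1, index 2 to
#' value 0, matching the ones-then-zeros block-vector convention.
#'
#' @param kind label, e.g. "A", "B", "C", "Binv", "Cinv".
#' @param sub numeric array of dimension `c(2, 2, n_out, n_in)`;
#'   `sub[, c, i, j]` is the distribution of output factor i's component
#'   given input factor j at component c.
#' @param normalized if `TRUE` (default) every submatrix column must sum to 1.
#' @return object of class `factorized_mapping`.
#' @export
factorized_mapping <- function(kind, sub, normalized = TRUE) {
  stopifnot(is.array(sub), length(dim(sub)) == 4L, all(dim(sub)[1:2] == 2L))
  n_out <- dim(sub)[3]
  n_in <- dim(sub)[4]
  if (any(sub < -1e-12)) stop("factorized_mapping: negative entries")
  if (normalized) {
    colsums <- sub[1, , , , drop = FALSE] + sub[2, , , , drop = FALSE]
    if (any(abs(colsums - 1) > 1e-12)) {
      stop("factorized_mapping: submatrix columns must sum to 1")
    }
  }
  structure(list(kind = kind, sub = sub, n_out = n_out, n_in = n_in,
                 normalized = normalized),
            class = "factorized_mapping")
}

#' @export
print.factorized_mapping <- function(x, ...) {
  cat("<factorized_mapping> kind=", x$kind, " ", x$n_out, " out x ",
      x$n_in, " in factor(s)", if (!x$normalized) " (unnormalized)", "\n",
      sep = "")
  invisible(x)
}

#' Convenience constructors for factorised mappings
#'
#' `fm_uniform()` gives maximally ambiguous submatrices (all entries 1/2);
#' `fm_identity()` gives near-identity diagonal pairs (mixing `rho` identity
#' with `1 - rho` uniform) and uniform off-diagonal pairs; `fm_random()`
#' draws each submatrix column from a symmetric Dirichlet via `rbeta`.
#'
#' @param kind mapping label.
#' @param n_out,n_in factor counts.
#' @param n factor count for square mappings.
#' @param rho diagonal identity weight in `[0, 1]`.
#' @param alpha Beta/Dirichlet concentration for random columns.
#' @return a `factorized_mapping`.
#' @export
fm_uniform <- function(kind, n_out, n_in) {
  factorized_mapping(kind, array(0.5, c(2, 2, n_out, n_in)))
}

#' @rdname fm_uniform
#' @export
fm_identity <- function(kind, n, rho = 1) {
  sub <- array(0.5, c(2, 2, n, n))
  d1 <- rho + (1 - rho) * 0.5
  for (i in seq_len(n)) {
    sub[, , i, i] <- matrix(c(d1, 1 - d1, 1 - d1, d1), 2, 2)
  }
  factorized_mapping(kind, sub)
}

#' @rdname fm_uniform
#' @export
fm_random <- function(kind, n_out, n_in, alpha = 1) {
  p <- array(stats::rbeta(2 * n_out * n_in, alpha, alpha),
             c(2, n_out, n_in))
  sub <- array(0, c(2, 2, n_out, n_in))
  sub[1, 1, , ] <- p[1, , ]
  sub[2, 1, , ] <- 1 - p[1, , ]
  sub[1, 2, , ] <- p[2, , ]
  sub[2, 2, , ] <- 1 - p[2, , ]
  factorized_mapping(kind, sub)
}

#' Expand a factorised mapping to its full joint block matrix
#'
#' The entry for (output assignment, input assignment) is the product over
#' factor pairs of submatrix entries, normalised per output factor, i.e.
#' `P(out_i = 1 | in) = prod_j sub[1, in_j, i, j] / (prod_j sub[1, ...] +
#' prod_j sub[0, ...])` and joint outputs multiply across i.  Assignments are
#' enumerated by [enumerate_assignments()] (all-ones first, factor 1 fastest).
#'
#' @param m a `factorized_mapping`.
#' @return a `2^n_out` x `2^n_in` column-stochastic matrix.
#' @export
expand_mapping <- function(m) {
  stopifnot(inherits(m, "factorized_mapping"))
  outs <- enumerate_assignments(m$n_out)
  ins <- enumerate_assignments(m$n_in)
  full <- matrix(0, nrow(outs), nrow(ins))
  for (col in seq_len(nrow(ins))) {
    lin <- ins[col, ]
    # per-output-factor probability of component 1, normalised
    p1 <- vapply(seq_len(m$n_out), function(i) {
      num <- prod(vapply(seq_len(m$n_in), function(j) {
        m$sub[1, 2 - lin[j], i, j]
      }, numeric(1)))
      den0 <- prod(vapply(seq_len(m$n_in), function(j) {
        m$sub[2, 2 - lin[j], i, j]
      }, numeric(1)))
      num / (num + den0)
    }, numeric(1))
    for (row in seq_len(nrow(outs))) {
      lout <- outs[row, ]
      full[row, col] <- prod(ifelse(lout == 1L, p1, 1 - p1))
    }
  }
  full
}

#' Recover submatrices from an expanded mapping
#'
#' Marginalises the full joint matrix per output factor, reading each input
#' factor's columns at the reference assignment (all other factors at
#' component 1).  Exact for single-input-factor mappings (any number of
#' output factors); for multiple input factors the normalised expansion
#' determines the submatrices only up to a per-pair odds gauge, and the
#' contraction returns one representative.
#'
#' @param full expanded matrix as returned by [expand_mapping()].
#' @param n_out,n_in factor counts.
#' @param kind label for the reconstructed mapping.
#' @return a `factorized_mapping`.
#' @export
contract_mapping <- function(full, n_out, n_in, kind = "A") {
  outs <- enumerate_assignments(n_out)
  ins <- enumerate_assignments(n_in)
  sub <- array(0, c(2, 2, n_out, n_in))
  for (j in seq_len(n_in)) {
    for (cc in 1:2) {                       # component 1 then 0
      want <- rep(1L, n_in)
      want[j] <- 2L - cc
      col <- which(apply(ins, 1, function(r) all(r == want)))
      for (i in seq_len(n_out)) {
        p1 <- sum(full[outs[, i] == 1L, col])
        sub[1, cc, i, j] <- p1
        sub[2, cc, i, j] <- 1 - p1
      }
    }
  }
  factorized_mapping(kind, sub)
}

#' Bayes inversion of a mapping under a prior
#'
#' Implements the inverse mapping `M^dagger = M' diag[prior]^{-1}` (transpose
#' scaled by the reciprocal prior over the forward mapping's output space),
#' per factor pair.  With `normalize = TRUE` the columns of the inverse are
#' renormalised to 1, yielding the proper conditional
#' `P(input | output)` that the network's synapses encode; the prior then
#' cancels and re-enters the inference once through the threshold terms.
#'
#' @param m a `factorized_mapping` (forward direction).
#' @param prior a `belief_block` over the output factors of `m` (state prior
#'   D for B, decision prior E for C); entries must be strictly positive.
#' @param normalize renormalise inverse columns (default `FALSE`, the literal
#'   matrix identity `M^dagger diag[prior] = M'`).
#' @return a `factorized_mapping` of kind `<kind>inv` whose output factors
#'   are `m`'s input factors and vice versa.
#' @export
bayes_invert <- function(m, prior, normalize = FALSE) {
  stopifnot(inherits(m, "factorized_mapping"), inherits(prior, "belief_block"))
  if (prior$n != m$n_out) {
    stop("bayes_invert: prior length must match the mapping's output factors")
  }
  pr <- rbind(prior$p1, prior$p0)
  bad <- which(pr <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "bayes_invert: zero prior entry at factor %d (component %s)",
      bad[1, 2], c("1", "0")[bad[1, 1]]))
  }
  inv <- array(0, c(2, 2, m$n_in, m$n_out))
  for (i in seq_len(m$n_out)) {
    for (j in seq_len(m$n_in)) {
      # inv[c_in, c_out, j, i] = sub[c_out, c_in, i, j] / prior_i[c_out]
      blk <- t(m$sub[, , i, j]) / rep(pr[, i], each = 2)
      if (normalize) blk <- sweep(blk, 2, colSums(blk), "/")
      inv[, , j, i] <- blk
    }
  }
  factorized_mapping(paste0(m$kind, "inv"), inv, normalized = normalize)
}

#' Elementwise floored logarithm of a mapping's submatrix array
#'
#' Returns the array of log submatrix entries (floored at `eps`), the form
#' consumed by [infer_state()], [infer_decision()] and [free_energy()] as an
#' expected log mapping.
#'
#' @param m a `factorized_mapping`.
#' @param eps probability floor applied before the logarithm.
#' @return numeric array `(2, 2, n_out, n_in)` of logs.
#' @export
log_mapping <- function(m, eps = .ACTINET_EPS) {
  stopifnot(inherits(m, "factorized_mapping"))
  ln_floor(m$sub, eps)
}

# "Push" a log mapping through an input belief: (ln M) b in the block custom.
# Returns a 2 x n_out matrix of log-weights over output components.
log_push <- function(logsub, b) {
  d <- dim(logsub)
  n_out <- d[3]; n_in <- d[4]
  stopifnot(inherits(b, "belief_block"), b$n == n_in)
  u <- matrix(0, 2, n_out)
  for (cc in 1:2) {
    # sum_j logsub[cc, 1, i, j] p1_j + logsub[cc, 2, i, j] p0_j
    m1 <- matrix(logsub[cc, 1, , ], n_out, n_in)
    m0 <- matrix(logsub[cc, 2, , ], n_out, n_in)
    u[cc, ] <- as.numeric(m1 %*% b$p1 + m0 %*% b$p0)
  }
  u
}

# "Pull" a log mapping against an output belief: ln M . b (transpose custom).
# Returns a 2 x n_in matrix of log-weights over input components.
log_pull <- function(logsub, b) {
  d <- dim(logsub)
  n_out <- d[3]; n_in <- d[4]
  stopifnot(inherits(b, "belief_block"), b$n == n_out)
  u <- matrix(0, 2, n_in)
  for (cc in 1:2) {
    m1 <- matrix(logsub[1, cc, , ], n_out, n_in)
    m0 <- matrix(logsub[2, cc, , ], n_out, n_in)
    u[cc, ] <- as.numeric(crossprod(m1, b$p1) + crossprod(m0, b$p0))
  }
  u
}

#' Fictive decision log-likelihood
#'
#' The risk-switched mixture over the policy mapping reduces (after dropping
#' the normaliser) to the modulated term `(1 - 2 Gamma) ln(C s_prev)`, the
#' log-weight each decision receives from the previous state belief.  At
#' `Gamma = 0.5` the modulation factor vanishes; `Gamma = 1` negates the
#' `Gamma = 0` weights.
#'
#' @param C policy `factorized_mapping` (states to decisions).
#' @param s_prev `belief_block` over the previous state's factors.
#' @param Gamma scalar risk in `[0, 1]`.
#' @return a 2 x n_decision matrix of log-weights (components 1 and 0).
#' @export
fictive_decision_loglik <- function(C, s_prev, Gamma) {
  stopifnot(inherits(C, "factorized_mapping"),
            inherits(s_prev, "belief_block"),
            length(Gamma) == 1L, Gamma >= 0, Gamma <= 1)
  (1 - 2 * Gamma) * log_push(log_mapping(C), s_prev)
}
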