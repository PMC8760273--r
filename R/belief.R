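#' Belief block over N binary factors
#'
#' The common currency for states, decisions and network activity: a block
#' vector pairing the "feature = 1" probabilities with their complements,
#' following the (x(t)', xbar(t)')' stacking convention (all 1-components
#' first, then all 0-components).
#'
#' @param p1 numeric vector of "=1" probabilities, one per factor.
#' @param p0 optional complements; defaults to `1 - p1`.
#' @return an object of class `belief_block` with fields `p1`, `p0`, `n`.
#' @examples
#' b <- belief_block(c(0.2, 0.9))
#' as_block_vector(b)
#' @export
belief_block <- function(p1, p0 = NULL) {
  p1 <- as.numeric(p1)
  if (is.null(p0)) p0 <- 1 - p1
  p0 <- as.numeric(p0)
  stopifnot(length(p1) == length(p0))
  if (any(p1 < -1e-12) || any(p1 > 1 + 1e-12)) {
    stop("belief_block: probabilities must lie in [0, 1]")
  }
  if (any(abs(p1 + p0 - 1) > 1e-12)) {
    stop("belief_block: p1 + p0 must equal 1 elementwise")
  }
  structure(list(p1 = pmin(pmax(p1, 0), 1), p0 = pmin(pmax(p0, 0), 1),
                 n = length(p1)),
            class = "belief_block")
}

#' @rdname belief_block
#' @param x a `belief_block`.
#' @export
as_block_vector <- function(x) {
  stopifnot(inherits(x, "belief_block"))
  c(x$p1, x$p0)
}

#' @rdname belief_block
#' @param v a stacked block vector of length 2N.
#' @export
block_vector_to_belief <- function(v) {
  n <- length(v) %/% 2L
  belief_block(v[seq_len(n)], v[n + seq_len(n)])
}

#' @export
print.belief_block <- function(x, ...) {
  cat("<belief_block> ", x$n, " binary factor(s)\n", sep = "")
  print(rbind(p1 = x$p1, p0 = x$p0))
  invisible(x)
}

# One-hot belief from realized binary vector (entries in {0,1}).
one_hot_belief <- function(bits) belief_block(as.numeric(bits))

#' Sample a binary realization from a belief block
#'
#' Draws each factor independently with its "=1" probability.
#'
#' @param b a `belief_block`.
#' @return integer vector of 0/1 draws, one per factor.
#' @export
sample_belief <- function(b) {
  stopifnot(inherits(b, "belief_block"))
  as.integer(runif(b$n) < b$p1)
}
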