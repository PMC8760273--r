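#' Forward sampler of the generative process
#'
#' Draws a trajectory from the factorised POMDP: the initial state from the
#' state prior, observations through the likelihood mapping and state
#' transitions through the (optionally decision-conditioned) transition
#' mapping.  Used as the independent oracle input for the inference tests.
#'
#' @param A likelihood `factorized_mapping` (states to observations).
#' @param B transition `factorized_mapping`, or a list of mappings indexed by
#'   decision when transitions are decision-dependent.
#' @param D `belief_block` state prior.
#' @param policy `NULL` (no decisions recorded), or a function
#'   `policy(tau, s_bits)` returning the decision index used to select
#'   `B[[index]]` (and recorded in the trajectory).
#' @param T_steps number of time steps (>= 1).
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return object of class `trajectory_sample`: list with integer matrices
#'   `o` (`n_o x T`), `s` (`n_s x T`) and optional vector `delta`.
#' @export
sample_generative_process <- function(A, B, D, policy = NULL, T_steps,
                                      seed = 1L) {
  stopifnot(inherits(A, "factorized_mapping"), inherits(D, "belief_block"),
            T_steps >= 1)
  b_list <- if (inherits(B, "factorized_mapping")) list(B) else B
  stopifnot(all(vapply(b_list, inherits, logical(1), "factorized_mapping")))
  if (!is.null(policy) && !is.function(policy)) {
    stop("sample_generative_process: policy must be NULL or a function(tau, s)")
  }
  n_s <- D$n
  n_o <- A$n_out
  set.seed(as.integer(seed))
  o <- matrix(0L, n_o, T_steps)
  s <- matrix(0L, n_s, T_steps)
  delta <- integer(T_steps)

  emit <- function(s_bits) {
    # per-observation-factor P(o_i = 1 | joint s), normalised product rule
    p1 <- vapply(seq_len(n_o), function(i) {
      num <- prod(ifelse(s_bits == 1L, A$sub[1, 1, i, ], A$sub[1, 2, i, ]))
      den <- prod(ifelse(s_bits == 1L, A$sub[2, 1, i, ], A$sub[2, 2, i, ]))
      num / (num + den)
    }, numeric(1))
    as.integer(runif(n_o) < p1)
  }
  transit <- function(Bm, s_bits) {
    p1 <- vapply(seq_len(n_s), function(j) {
      num <- prod(ifelse(s_bits == 1L, Bm$sub[1, 1, j, ], Bm$sub[1, 2, j, ]))
      den <- prod(ifelse(s_bits == 1L, Bm$sub[2, 1, j, ], Bm$sub[2, 2, j, ]))
      num / (num + den)
    }, numeric(1))
    as.integer(runif(n_s) < p1)
  }

  s[, 1] <- as.integer(runif(n_s) < D$p1)
  o[, 1] <- emit(s[, 1])
  for (tau in seq_len(T_steps)[-1]) {
    k <- if (is.null(policy)) 1L else as.integer(policy(tau, s[, tau - 1]))
    if (k < 1L || k > length(b_list)) {
      stop("sample_generative_process: policy returned an invalid index")
    }
    delta[tau] <- k
    s[, tau] <- transit(b_list[[k]], s[, tau - 1])
    o[, tau] <- emit(s[, tau])
  }
  structure(list(o = o, s = s, delta = delta, T_steps = T_steps, seed = seed),
            class = "trajectory_sample")
}
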