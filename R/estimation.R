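#' Estimate implicit priors from activity time averages
#'
#' When threshold adaptation is slow relative to the observation window, the
#' threshold perturbations are estimated as the logarithms of the average
#' firing rates: `psi_hat = ln(<y>, <1 - y>)` and `phi_hat = ln(<x>,
#' <1 - x>)`, pooled (concatenated) over the supplied session logs.  The
#' exponential-sum constraints hold exactly by construction.  The implied
#' decision prior is the exponential of `psi_hat`, with the one-components
#' renormalised to sum to 1.
#'
#' @param logs a `session_log` or list of them, recorded from the agent
#'   whose priors are to be estimated (ten distinct mazes by convention).
#' @param floor clamp applied to average rates of exactly 0 or 1 before the
#'   logarithm (flagged in the result).
#' @return object of class `prior_estimate` with fields `psi1`, `psi0`,
#'   `phi1`, `phi0`, `E_hat` (normalised), `D_hat`, `n_periods` and
#'   per-element binomial standard errors `se_y`, `se_x`.
#' @export
estimate_thresholds <- function(logs, floor = .ACTINET_EPS) {
  if (inherits(logs, "session_log")) logs <- list(logs)
  stopifnot(length(logs) >= 1,
            all(vapply(logs, inherits, logical(1), "session_log")))
  n_per <- sum(vapply(logs, function(l) l$stats$n_periods, numeric(1)))
  if (n_per == 0) stop("estimate_thresholds: zero-length logs")
  sum_y <- Reduce(`+`, lapply(logs, function(l) l$stats$S_y))
  sum_x <- Reduce(`+`, lapply(logs, function(l) l$stats$S_x))
  mean_y <- sum_y / n_per
  mean_x <- sum_x / n_per
  clamped <- any(mean_y <= 0) || any(mean_y >= 1) ||
    any(mean_x <= 0) || any(mean_x >= 1)
  mean_y <- pmin(pmax(mean_y, floor), 1 - floor)
  mean_x <- pmin(pmax(mean_x, floor), 1 - floor)
  E_hat <- mean_y / sum(mean_y)
  structure(list(
    psi1 = log(mean_y), psi0 = log1p(-mean_y),
    phi1 = log(mean_x), phi0 = log1p(-mean_x),
    E_hat = E_hat, D_hat = mean_x,
    mean_y = mean_y, mean_x = mean_x,
    se_y = sqrt(mean_y * (1 - mean_y) / n_per),
    se_x = sqrt(mean_x * (1 - mean_x) / n_per),
    n_periods = n_per, n_logs = length(logs), clamped = clamped
  ), class = "prior_estimate")
}

#' @export
print.prior_estimate <- function(x, ...) {
  cat("<prior_estimate> from ", x$n_logs, " log(s), ", x$n_periods,
      " periods\n", sep = "")
  cat("  E_hat range:", format(range(x$E_hat)), "\n")
  invisible(x)
}

#' Serialise a prior estimate to JSON
#'
#' @param est a `prior_estimate`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
prior_estimate_to_json <- function(est, path) {
  stopifnot(inherits(est, "prior_estimate"))
  jsonlite::write_json(
    list(element = seq_along(est$psi1) - 1L,
         psi1 = est$psi1, psi0 = est$psi0,
         E_hat = est$E_hat, se = est$se_y,
         n_periods = est$n_periods),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Collect activity logs for prior estimation
#'
#' Runs plain action phases (no plasticity) of the given agent on each maze
#' and returns the session logs.
#'
#' @param agent a `maze_agent`.
#' @param mazes list of `maze_grid`s (ten by convention).
#' @param T step budget per session.
#' @param seed integer seed.
#' @return list of `session_log`s.
#' @export
collect_activity_logs <- function(agent, mazes, T = 20000L, seed = 1L) {
  if (inherits(mazes, "maze_grid")) mazes <- list(mazes)
  set.seed(as.integer(seed))
  lapply(mazes, function(m) run_action_phase(agent, m, T = T, seed = NULL))
}

#' Reconstruct an agent from an estimated decision prior and predict learning
#'
#' Builds a naive agent whose output thresholds carry the estimated decision
#' prior (weights at their standard initialisations), trains it with the
#' standard protocol on fresh mazes, and returns its training curve as the
#' prediction for the original agent's learning.  The prediction uses only
#' the estimate and the known task/risk structure, never the original
#' agent's activity or behaviour logs.
#'
#' @param estimate a `prior_estimate` (its `E_hat` is used), or a numeric
#'   decision-prior vector.
#' @param fresh_mazes list of `maze_grid`s unseen by the source agent.
#' @param n_sessions,T training protocol parameters.
#' @param seed integer seed for the predicted run.
#' @param ... further arguments passed to [maze_agent()] (architecture and
#'   risk parameters, assumed known).
#' @return a `training_curve` for the reconstructed agent.
#' @export
reconstruct_and_predict <- function(estimate, fresh_mazes,
                                    n_sessions = 100L, T = 20000L,
                                    seed = 1L, ...) {
  E <- if (inherits(estimate, "prior_estimate")) estimate$E_hat
       else as.numeric(estimate)
  agent <- maze_agent(E = E, ...)
  train(agent, fresh_mazes, n_sessions = n_sessions, T = T, seed = seed)
}
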