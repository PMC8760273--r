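#' Maze-solving canonical network agent
#'
#' Constructs the two-layer network agent for the maze task: the middle
#' layer encodes beliefs about the cells of the observation window (the
#' likelihood mapping is initialised near the identity), the recurrent and
#' output synapses are initialised uniform, and the firing-threshold
#' perturbations encode the state prior and the 256-way decision prior.
#' Plasticity follows the gradient rules on session-averaged statistics,
#' one step per session, with per-family rates `1 / lambda` (the `lambda`
#' factors are the inverse learning rates of the weight/posterior
#' dictionary).  The sensory/recurrent rate sits far below the policy rate:
#' each middle-layer logit sums over all 121 inputs, so even a uniform
#' drift of the likelihood or recurrent weights is amplified by the input
#' count, and a rate within two orders of the policy rate corrupts the
#' state representation over a hundred-session run.
#'
#' @param window odd observation window side (default 11; 121 input cells).
#' @param n_steps actions per decision (default 4; 256 decision options).
#' @param E decision prior: either a full vector of length `4^n_steps`, or
#'   `NULL` to build it from `E_dirs`.
#' @param E_dirs named per-direction prior values (`right`, `left`, `up`,
#'   `down`); a decision's prior is the value of its first action.
#' @param D state prior 1-component (scalar or length `window^2`).
#' @param rho_A identity mixing weight of the initial likelihood mapping.
#' @param lambda named list of prior masses (inverse learning rates) for
#'   `W`, `K`, `V`.
#' @param risk a [risk_params()] object.  The agent default sets the
#'   displacement threshold to one cell per period: with four-step decisions
#'   and single-cell barrier doors, net rightward progress of one cell is
#'   the reliable signature of a good period, and zero-risk periods remain
#'   frequent enough to drive the modulated plasticity.
#' @param modulation `"delayed"` (risk scores the period that produced it)
#'   or `"immediate"` (ablation: the modulator scales the plasticity of the
#'   period during which it arrives).
#' @param learn named logical list enabling plasticity per synapse family.
#' @return object of class `maze_agent`.
#' @export
maze_agent <- function(window = 11L, n_steps = 4L, E = NULL,
                       E_dirs = c(right = 1, left = 1, up = 1, down = 1) / 256,
                       D = 0.5, rho_A = 0.95,
                       lambda = list(W = 1e5, K = 1e5, V = 10),
                       risk = risk_params(d_star = 1L),
                       modulation = c("delayed", "immediate"),
                       learn = list(W = TRUE, K = TRUE, V = TRUE)) {
  modulation <- match.arg(modulation)
  n_o <- as.integer(window)^2
  n_x <- n_o
  n_y <- 4L^n_steps
  if (is.null(E)) {
    first <- (seq_len(n_y) - 1L) %/% (4L^(n_steps - 1L))  # 0 up,1 down,2 left,3 right
    E <- unname(c(E_dirs["up"], E_dirs["down"], E_dirs["left"],
                  E_dirs["right"])[first + 1L])
  }
  stopifnot(length(E) == n_y, all(E > 0), all(E < 1))
  if (length(D) == 1L) D <- rep(D, n_x)
  stopifnot(length(D) == n_x, all(D > 0), all(D < 1))

  # initial likelihood mapping: rho_A identity + (1 - rho_A) uniform;
  # recurrent synapses start at the uniform mapping (weight 0); output
  # synapses start at the prior policy (excitatory and inhibitory parts
  # cancel, so the initial decision beliefs equal the prior E)
  d1 <- rho_A + (1 - rho_A) * 0.5
  A1 <- matrix(0.5, n_x, n_o); A0 <- matrix(0.5, n_x, n_o)
  diag(A1) <- d1; diag(A0) <- 1 - d1
  Vbase <- matrix(sig_inv(E), n_y, n_x)
  weights <- synaptic_weights(
    W1 = sig_inv(A1), W0 = sig_inv(A0),
    K1 = matrix(0, n_x, n_x), K0 = matrix(0, n_x, n_x),
    V1 = Vbase, V0 = Vbase,
    lambda = lambda)
  agent <- structure(list(
    window = as.integer(window), n_steps = as.integer(n_steps),
    n_o = n_o, n_x = n_x, n_y = n_y,
    D = D, E = E, risk = risk, modulation = modulation,
    lambda = lambda, learn = learn, weights = weights,
    # discounted modulated decision/context co-occurrence statistics
    vstats = list(M = matrix(0, n_y, n_x))
  ), class = "maze_agent")
  agent_refresh_weights(agent)
}

#' Recompute adaptive thresholds and cached drives from the weights
#'
#' The firing thresholds are functions of the synaptic strengths (log
#' complement sums) plus the fixed perturbations `phi = ln D`,
#' `psi = ln E`; they are refreshed after every plasticity step.
#'
#' @param agent a `maze_agent`.
#' @return the agent with updated `tspec`, `thresholds` and the cached
#'   difference matrices used by the fast simulation path.
#' @export
agent_refresh_weights <- function(agent) {
  tspec <- threshold_spec(log(agent$D), log1p(-agent$D),
                          log(agent$E), log1p(-agent$E))
  th <- compute_thresholds(agent$weights, tspec)
  agent$tspec <- tspec
  agent$thresholds <- th
  agent$net <- list(dW = agent$weights$W1 - agent$weights$W0,
                    dK = agent$weights$K1 - agent$weights$K0,
                    dV = agent$weights$V1 - agent$weights$V0,
                    hd = th$h1 - th$h0, md = th$m1 - th$m0)
  agent
}

#' Run one action phase in a maze
#'
#' Loops observe / infer state / infer decision / act for up to `T` steps
#' (grouped in decision periods), with delayed risk evaluation per period.
#' Decisions are sampled with probability proportional to the output-layer
#' rates, renormalised over the one-hot block.  The run is deterministic
#' given the RNG state (pass `seed` to fix it).
#'
#' @param agent a `maze_agent`.
#' @param maze a `maze_grid`.
#' @param T step budget for the session.
#' @param seed optional integer seed (otherwise the current RNG state).
#' @param log_activity record per-period activity and per-step positions.
#' @return object of class `session_log`: success flag, duration in steps,
#'   per-period decision indices (0-based), risks, column trace, plasticity
#'   sufficient statistics and (optionally) activity matrices.
#' @export
run_action_phase <- function(agent, maze, T = 20000L, seed = NULL,
                             log_activity = FALSE) {
  stopifnot(inherits(agent, "maze_agent"), inherits(maze, "maze_grid"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  res <- .action_phase_cpp(
    maze$cells, maze$start[1], maze$start[2],
    agent$net$dW, agent$net$dK, agent$net$dV,
    agent$net$hd, agent$net$md,
    x0 = rep(0.5, agent$n_x),
    T = as.integer(T), window = agent$window,
    period_len = agent$n_steps,
    d_star = agent$risk$d_star,
    g_success = agent$risk$Gamma_success,
    g_partial = agent$risk$Gamma_partial,
    g_fail = agent$risk$Gamma_fail,
    immediate_mod = identical(agent$modulation, "immediate"),
    log_activity = log_activity)
  vec_stats <- c("S_d", "S_o", "S_x", "S_xp", "S_xp_w", "S_y")
  res$stats[vec_stats] <- lapply(res$stats[vec_stats], as.numeric)
  res$x_final <- as.numeric(res$x_final)
  res$T <- as.integer(T)
  res$seed <- seed
  class(res) <- "session_log"
  res
}

#' @export
print.session_log <- function(x, ...) {
  cat("<session_log> ", if (x$success) "success" else "failure",
      ", duration ", x$duration, " steps (", x$n_periods, " periods)\n",
      sep = "")
  invisible(x)
}

#' Apply the session's plasticity updates
#'
#' One gradient step per synapse family on the session-averaged statistics:
#' Hebbian co-activation (risk-modulated for the output synapses, where each
#' period's decision/context product is weighted by `1 - 2 Gamma` of the
#' period that evaluates it in delayed mode, or of the preceding period in
#' the immediate ablation) minus the activity-dependent homeostatic term,
#' applied with rate `1 / lambda` per family.  The realized one-hot
#' decisions serve as the output-layer postsynaptic signal.
#'
#' @param agent a `maze_agent`.
#' @param log a `session_log` from [run_action_phase()].
#' @return the updated agent (thresholds refreshed).
#' @export
run_learning_phase <- function(agent, log) {
  stopifnot(inherits(agent, "maze_agent"), inherits(log, "session_log"))
  st <- log$stats
  P <- st$n_periods
  if (P == 0L) return(agent)
  w <- agent$weights

  if (isTRUE(agent$learn$V)) {
    # The one-hot decision block is a single categorical factor: the
    # risk-modulated decision/context counts are normalised across
    # decisions per context cell, yielding the risk-weighted policy
    # mapping the excitatory output synapses encode; the inhibitory
    # partners hold the prior-policy baseline.  Session statistics enter
    # as a discounted running sum (rate 1/lambda_V per session) and the
    # prior contributes lambda_V pseudo-counts shaped like E, so rarely
    # chosen decisions relax back to the prior and anti-Hebbian episodes
    # are forgotten on the same timescale they were learned.
    rV <- 1 / agent$lambda$V
    agent$vstats$M <- (1 - rV) * agent$vstats$M + st$S_dxm
    pos <- pmax(agent$vstats$M, 0)
    colmass <- colSums(pos)
    pm <- agent$lambda$V
    Ptilde <- sweep(pos, 2, colmass + pm, "/") +
      outer(agent$E, pm / (colmass + pm))
    w$V1 <- sig_inv(Ptilde, .ACTINET_RATIO_EPS)
  }
  if (isTRUE(agent$learn$W)) {
    rW <- 1 / agent$lambda$W
    w$W1 <- w$W1 + rW * (st$S_xo / P - (st$S_x / P) * sig(w$W1))
    hebW0 <- (matrix(st$S_o, agent$n_x, agent$n_o, byrow = TRUE) -
                st$S_xo) / P
    w$W0 <- w$W0 + rW * (hebW0 - (1 - st$S_x / P) * sig(w$W0))
  }
  if (isTRUE(agent$learn$K)) {
    rK <- 1 / agent$lambda$K
    w$K1 <- w$K1 + rK * (st$S_xxp / P - (st$S_x / P) * sig(w$K1))
    xpm <- matrix(st$S_xp, agent$n_x, agent$n_x, byrow = TRUE)
    w$K0 <- w$K0 + rK * ((xpm - st$S_xxp) / P -
                           (1 - st$S_x / P) * sig(w$K0))
  }
  agent$weights <- w
  agent_refresh_weights(agent)
}
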