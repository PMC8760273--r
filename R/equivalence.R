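#' Map Bayesian beliefs to network weights and thresholds
#'
#' The weight/posterior dictionary: sensory synapses are the inverse sigmoid
#' of the likelihood-mapping posterior means, recurrent and output synapses
#' the inverse sigmoid of the (column-stochastic) inverse transition and
#' policy posterior means, and the threshold perturbations are the log state
#' and decision priors.  Full thresholds follow from [compute_thresholds()],
#' so that `phi = ln D` and `psi = ln E` hold by construction.
#'
#' @param bank `dirichlet_bank` with concentrations for A, B, C.
#' @param D,E `belief_block` priors (strictly positive entries).
#' @param lambda inverse-learning-rate list passed to [synaptic_weights()].
#' @return list with `weights` (`synaptic_weights`), `tspec`
#'   (`threshold_spec`) and `thresholds` (computed `h`/`m` lists).
#' @export
beliefs_to_weights <- function(bank, D, E,
                               lambda = list(W = 1000, K = 1000, V = 10)) {
  stopifnot(inherits(bank, "dirichlet_bank"))
  if (any(c(D$p1, D$p0, E$p1, E$p0) <= 0)) {
    stop("beliefs_to_weights: priors must be strictly positive (log needed)")
  }
  amean <- dirichlet_expectations(bank$a)$mean
  binv <- dirichlet_expectations(transpose_concentrations(bank$b))$mean
  cinv <- dirichlet_expectations(transpose_concentrations(bank$c))$mean
  n_o <- dim(amean)[3]; n_s <- dim(amean)[4]; n_d <- dim(cinv)[4]

  # sig(W_l)[j, i] = P(o_i = 1 | s_j = l); likewise for the inverses.
  W1 <- t(matrix(amean[1, 1, , ], n_o, n_s))
  W0 <- t(matrix(amean[1, 2, , ], n_o, n_s))
  K1 <- t(matrix(binv[1, 1, , ], n_s, n_s))
  K0 <- t(matrix(binv[1, 2, , ], n_s, n_s))
  V1 <- t(matrix(cinv[1, 1, , ], n_s, n_d))
  V0 <- t(matrix(cinv[1, 2, , ], n_s, n_d))
  weights <- synaptic_weights(sig_inv(W1), sig_inv(W0), sig_inv(K1),
                              sig_inv(K0), sig_inv(V1), sig_inv(V0),
                              lambda = lambda)
  tspec <- threshold_spec(log(D$p1), log(D$p0), log(E$p1), log(E$p0))
  list(weights = weights, tspec = tspec,
       thresholds = compute_thresholds(weights, tspec))
}

#' Recover Bayesian quantities from network weights and thresholds
#'
#' Inverse of [beliefs_to_weights()] on its domain: mapping means are the
#' sigmoids of the synaptic strengths, priors are the exponentials of the
#' threshold perturbations.
#'
#' @param weights `synaptic_weights`.
#' @param tspec `threshold_spec`.
#' @return list with mapping means `A`, `Binv`, `Cinv`
#'   (`factorized_mapping`s) and priors `D`, `E` (`belief_block`s).
#' @export
weights_to_beliefs <- function(weights, tspec) {
  stopifnot(inherits(weights, "synaptic_weights"),
            inherits(tspec, "threshold_spec"))
  n_o <- weights$n_o; n_s <- weights$n_x; n_d <- weights$n_y
  pack <- function(M1, M0, n_out, n_in) {
    sub <- array(0, c(2, 2, n_out, n_in))
    sub[1, 1, , ] <- t(sig(M1)); sub[2, 1, , ] <- 1 - t(sig(M1))
    sub[1, 2, , ] <- t(sig(M0)); sub[2, 2, , ] <- 1 - t(sig(M0))
    sub
  }
  list(
    A = factorized_mapping("A", pack(weights$W1, weights$W0, n_o, n_s)),
    Binv = factorized_mapping("Binv", pack(weights$K1, weights$K0, n_s, n_s)),
    Cinv = factorized_mapping("Cinv", pack(weights$V1, weights$V0, n_s, n_d)),
    D = belief_block(exp(tspec$phi1), exp(tspec$phi0)),
    E = belief_block(exp(tspec$psi1), exp(tspec$psi0))
  )
}

# Random Dirichlet bank for a model of given factor counts.
random_bank <- function(n_o, n_s, n_d, conc_min = 1, conc_max = 20) {
  r <- function(n_out, n_in) {
    dirichlet_array(array(runif(4 * n_out * n_in, conc_min, conc_max),
                          c(2, 2, n_out, n_in)))
  }
  dirichlet_bank(r(n_o, n_s), r(n_s, n_s), r(n_d, n_s))
}

# Random strictly positive belief block.
random_prior <- function(n, lo = 0.1, hi = 0.9) {
  belief_block(runif(n, lo, hi))
}

#' Verify the network/Bayes correspondence numerically
#'
#' Drives the network recursion (steady-state activity from weights and
#' thresholds) and the variational updates (state/decision posteriors from
#' expected log mappings) with the same observation sequence and mapped
#' initial conditions, and reports (i) the maximal per-step activity
#' discrepancy, (ii) the per-step gap between the network cost and
#' variational free energy (parameter complexity and the order-one weight
#' residual excluded), and (iii) the gap between the closed-form synaptic
#' fixed point and the count-based Dirichlet mean on the same history.
#'
#' In `"log-ratio"` expectation mode the dictionary is an identity and all
#' gaps vanish to machine precision; in `"digamma"` mode the gaps are
#' bounded by the reciprocal column concentration and shrink as
#' concentrations grow.
#'
#' @param n_s,n_o,n_d factor counts of the random model.
#' @param T_steps number of driven steps.
#' @param seed RNG seed.
#' @param mode Dirichlet log-expectation mode for the Bayesian side.
#' @param conc_range concentration range of the random bank.
#' @param Gamma_t risk value used for the cost comparison.
#' @param perturb_psi optional additive perturbation of the output threshold
#'   (negative control: a broken mapping must yield a nonzero discrepancy).
#' @param json_path optional path; when given the report is written as JSON.
#' @return list report (class `equivalence_report`).
#' @export
verify_equivalence <- function(n_s = 3, n_o = 3, n_d = 4, T_steps = 200,
                               seed = 1L, mode = c("log-ratio", "digamma"),
                               conc_range = c(1, 20), Gamma_t = 0.3,
                               perturb_psi = 0, json_path = NULL) {
  mode <- match.arg(mode)
  set.seed(as.integer(seed))
  bank <- random_bank(n_o, n_s, n_d, conc_range[1], conc_range[2])
  D <- random_prior(n_s)
  E <- random_prior(n_d)

  A_log <- dirichlet_expectations(bank$a, mode)$logmean
  Binv_log <- dirichlet_expectations(transpose_concentrations(bank$b),
                                     mode)$logmean
  Cinv_log <- dirichlet_expectations(transpose_concentrations(bank$c),
                                     mode)$logmean

  nw <- beliefs_to_weights(bank, D, E)
  th <- nw$thresholds
  th$m1 <- th$m1 + perturb_psi

  o <- matrix(as.integer(runif(n_o * T_steps) < 0.5), n_o, T_steps)
  s_prev <- belief_block(rep(0.5, n_s))
  x_del <- rep(0.5, n_s)
  X <- matrix(0, n_s, T_steps); Y <- matrix(0, n_d, T_steps)
  S <- matrix(0, n_s, T_steps); Dl <- matrix(0, n_d, T_steps)
  Sprev <- matrix(0, n_s, T_steps); Xdel <- matrix(0, n_s, T_steps)
  max_dx <- 0; max_dy <- 0
  for (tt in seq_len(T_steps)) {
    s_t <- infer_state(o[, tt], s_prev, A_log, Binv_log, D)
    d_t <- infer_decision(s_prev, Cinv_log, E)
    fp <- activity_fixed_point(o[, tt], x_del, nw$weights, th)
    max_dx <- max(max_dx, max(abs(fp$x - s_t$p1)))
    max_dy <- max(max_dy, max(abs(fp$y - d_t$p1)))
    S[, tt] <- s_t$p1; Dl[, tt] <- d_t$p1
    Sprev[, tt] <- s_prev$p1
    X[, tt] <- fp$x; Y[, tt] <- fp$y; Xdel[, tt] <- x_del
    s_prev <- s_t
    x_del <- fp$x
  }

  fe <- free_energy(o, S, Sprev, Dl,
                    maps = list(A = A_log, Binv = Binv_log, Cinv = Cinv_log),
                    D = D, E = E, Gamma_t = Gamma_t,
                    form = "inverse", initial = FALSE)
  L <- cost_L(list(o = o, x = X, x_delayed = Xdel, y = Y),
              nw$weights, th, Gamma = Gamma_t, Delta = 1L)
  cost_gap <- abs(L - fe$total) / T_steps

  # plasticity fixed point vs count-based Dirichlet mean on the same
  # unmodulated history: sig(W1*) = <x o'>/<x> must equal the Dirichlet mean
  # P(o_i = 1 | s_j = 1) computed from the o (x) s counts (priors -> 0)
  hist_ <- list(o = o, x = X, x_delayed = Xdel, y = Y)
  fpW1 <- synaptic_fixed_point(hist_, 0, "W1")
  tiny <- dirichlet_bank(dirichlet_array(1e-12, n_o, n_s),
                         dirichlet_array(1e-12, n_s, n_s),
                         dirichlet_array(1e-12, n_d, n_s))
  tiny <- update_parameters(tiny, o, X, Xdel, Y, Gamma_t = 0)
  aa <- unclass(tiny$a)
  cond <- t(matrix(aa[1, 1, , ] / (aa[1, 1, , ] + aa[2, 1, , ]), n_o, n_s))
  plast_gap <- max(abs(sig(fpW1) - cond))

  report <- list(
    mode = mode, n_s = n_s, n_o = n_o, n_d = n_d, T_steps = T_steps,
    seed = seed, Gamma_t = Gamma_t, perturb_psi = perturb_psi,
    max_activity_discrepancy_x = max_dx,
    max_activity_discrepancy_y = max_dy,
    cost_gap_per_step = cost_gap,
    plasticity_gap = plast_gap,
    free_energy_total = fe$total, cost_total = L
  )
  class(report) <- "equivalence_report"
  if (!is.null(json_path)) {
    jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.equivalence_report <- function(x, ...) {
  cat("<equivalence_report> mode=", x$mode, " T=", x$T_steps, "\n", sep = "")
  cat("  max |x - s1| :", format(x$max_activity_discrepancy_x), "\n")
  cat("  max |y - d1| :", format(x$max_activity_discrepancy_y), "\n")
  cat("  |L - F| / T  :", format(x$cost_gap_per_step), "\n")
  invisible(x)
}
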