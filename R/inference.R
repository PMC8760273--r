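#' Posterior belief about the current hidden state
#'
#' The coordinate-wise minimiser of variational free energy with respect to
#' the present state belief: a per-factor two-way softmax of the summed
#' log-evidence from the observation (through the expected log likelihood
#' mapping), the previous state (through the expected log inverse transition
#' mapping) and the log state prior.  Past state beliefs are never revisited
#' (Bayesian filter).
#'
#' @param o_t observation: binary vector or `belief_block` over o-factors.
#' @param s_prev `belief_block` over the previous state.
#' @param A_log expected log likelihood mapping, array `(2, 2, n_o, n_s)`.
#' @param Binv_log expected log inverse transition mapping, array
#'   `(2, 2, n_s, n_s)` (output factors = previous state).
#' @param D `belief_block` state prior.
#' @return `belief_block` over the current state.
#' @export
infer_state <- function(o_t, s_prev, A_log, Binv_log, D) {
  if (!inherits(o_t, "belief_block")) o_t <- one_hot_belief(o_t)
  stopifnot(inherits(s_prev, "belief_block"), inherits(D, "belief_block"))
  u <- log_pull(A_log, o_t) + log_pull(Binv_log, s_prev) +
    rbind(ln_floor(D$p1), ln_floor(D$p0))
  belief_block(softmax_pair(u[1, ], u[2, ]))
}

#' Posterior belief about the current decision
#'
#' Per-factor softmax of the expected log inverse policy mapping applied to
#' the previous state belief plus the log decision prior.  With a flat policy
#' mapping and uniform prior over a one-hot decision space every element of
#' the result equals the uniform prior value.
#'
#' @param s_prev `belief_block` over the previous state.
#' @param Cinv_log expected log inverse policy mapping, array
#'   `(2, 2, n_s, n_d)` (output factors = previous state, input = decisions).
#' @param E `belief_block` decision prior.
#' @return `belief_block` over decisions.
#' @export
infer_decision <- function(s_prev, Cinv_log, E) {
  stopifnot(inherits(s_prev, "belief_block"), inherits(E, "belief_block"))
  u <- log_pull(Cinv_log, s_prev) + rbind(ln_floor(E$p1), ln_floor(E$p0))
  belief_block(softmax_pair(u[1, ], u[2, ]))
}

#' Variational free energy of a history of beliefs
#'
#' Evaluates the accuracy-plus-complexity decomposition of variational free
#' energy for a sequence of observations and posterior beliefs, with the
#' risk-modulated decision term (the modulation factor `1 - 2 Gamma_t`
#' applies to every time point except the most recent, which is always
#' unmodulated).  Two algebraically related forms are provided: the
#' `"inverse"` form written with the inverse mappings and explicit log priors
#' (the form the network cost realises), and the `"forward"` form written
#' with the forward mappings.  The parameter-complexity term (of order
#' `ln t`) is included only on request.
#'
#' @param o matrix `n_o x T` of observation 1-components.
#' @param s matrix `n_s x T` of state posterior 1-components.
#' @param s_prev matrix `n_s x T`, column `tau` holding the belief one step
#'   earlier (column 1 = initial belief; ignored when `initial = TRUE`).
#' @param delta matrix `n_d x T` of decision posterior 1-components.
#' @param maps list of expected log mappings: for the `"inverse"` form,
#'   `A`, `Binv`, `Cinv`; for `"forward"`, `A`, `B`, `C` (arrays of logs).
#' @param D,E `belief_block` priors over states and decisions.
#' @param Gamma_t scalar risk attached to the history.
#' @param form `"inverse"` (default) or `"forward"`.
#' @param initial when `TRUE`, the first column is treated as time 1 and its
#'   transition/policy log-evidence is replaced by the priors alone; when
#'   `FALSE`, every column uses `s_prev` (the mid-run convention used when
#'   comparing against the network cost with a running recurrent input).
#' @param bank optional `dirichlet_bank` for the parameter-complexity term.
#' @param include_parameter_complexity add the Dirichlet complexity term.
#' @return object of class `free_energy_report`: list with `total`, the
#'   three reported parts and `per_time` contributions (nats).
#' @export
free_energy <- function(o, s, s_prev, delta, maps, D, E, Gamma_t,
                        form = c("inverse", "forward"), initial = TRUE,
                        bank = NULL, include_parameter_complexity = FALSE) {
  form <- match.arg(form)
  o <- as.matrix(o); s <- as.matrix(s)
  s_prev <- as.matrix(s_prev); delta <- as.matrix(delta)
  T_ <- ncol(o)
  stopifnot(T_ >= 1, ncol(s) == T_, ncol(s_prev) == T_, ncol(delta) == T_)
  lnD <- rbind(ln_floor(D$p1), ln_floor(D$p0))
  lnE <- rbind(ln_floor(E$p1), ln_floor(E$p0))

  state_pt <- numeric(T_)
  dec_pt <- numeric(T_)
  for (tau in seq_len(T_)) {
    sb <- belief_block(s[, tau])
    spb <- belief_block(s_prev[, tau])
    db <- belief_block(delta[, tau])
    ob <- belief_block(o[, tau])
    gam <- if (tau == T_) 0 else Gamma_t

    ent_s <- sum(s[, tau] * ln_floor(s[, tau]) +
                   (1 - s[, tau]) * ln_floor(1 - s[, tau]))
    ent_d <- sum(delta[, tau] * ln_floor(delta[, tau]) +
                   (1 - delta[, tau]) * ln_floor(1 - delta[, tau]))
    uA <- log_pull(maps$A, ob)
    acc <- sum(uA[1, ] * sb$p1 + uA[2, ] * sb$p0)

    if (tau == 1L && initial) {
      trans <- sum(lnD[1, ] * sb$p1 + lnD[2, ] * sb$p0)
      pol <- sum(lnE[1, ] * db$p1 + lnE[2, ] * db$p0)
    } else if (form == "inverse") {
      uB <- log_pull(maps$Binv, spb)
      trans <- sum((uB[1, ] + lnD[1, ]) * sb$p1 +
                     (uB[2, ] + lnD[2, ]) * sb$p0)
      uC <- log_pull(maps$Cinv, spb)
      # The modulator scales only the state-dependent log-ratio evidence
      # (the synaptic-input term of the network cost); the log-complement
      # offsets stay unmodulated in the thresholds, like the prior.
      n_sp <- dim(maps$Cinv)[3]; n_dd <- dim(maps$Cinv)[4]
      offs <- rbind(colSums(matrix(maps$Cinv[2, 1, , ], n_sp, n_dd)),
                    colSums(matrix(maps$Cinv[2, 2, , ], n_sp, n_dd)))
      pol <- (1 - 2 * gam) * sum(uC[1, ] * db$p1 + uC[2, ] * db$p0) +
        2 * gam * sum(offs[1, ] * db$p1 + offs[2, ] * db$p0) +
        sum(lnE[1, ] * db$p1 + lnE[2, ] * db$p0)
    } else {
      uB <- log_push(maps$B, spb)
      trans <- sum(uB[1, ] * sb$p1 + uB[2, ] * sb$p0)
      uC <- log_push(maps$C, spb)
      pol <- (1 - 2 * gam) * sum(uC[1, ] * db$p1 + uC[2, ] * db$p0)
    }
    state_pt[tau] <- ent_s - acc - trans
    dec_pt[tau] <- ent_d - pol
  }

  param_cx <- 0
  if (include_parameter_complexity) {
    if (is.null(bank)) stop("free_energy: bank needed for parameter complexity")
    param_cx <- sum(vapply(c("a", "b", "c"), function(nm) {
      conc <- unclass(bank[[nm]])
      prior <- unclass(bank[[paste0(nm, "0")]])
      lm <- dirichlet_expectations(conc)$logmean
      tot1 <- conc[1, , , ] + conc[2, , , ]
      lbeta_ <- lgamma(conc[1, , , ]) + lgamma(conc[2, , , ]) - lgamma(tot1)
      sum((conc - prior) * lm) - sum(lbeta_)
    }, numeric(1)))
  }

  structure(list(
    total = sum(state_pt) + sum(dec_pt) + param_cx,
    accuracy_state_term = sum(state_pt),
    decision_term = sum(dec_pt),
    parameter_complexity = param_cx,
    per_time = state_pt + dec_pt
  ), class = "free_energy_report")
}

#' @export
print.free_energy_report <- function(x, ...) {
  cat("<free_energy_report> total =", format(x$total), "nats\n")
  cat("  state term     :", format(x$accuracy_state_term), "\n")
  cat("  decision term  :", format(x$decision_term), "\n")
  cat("  parameter cx   :", format(x$parameter_complexity), "\n")
  invisible(x)
}

#' Export a free-energy report to a tidy data frame / TSV
#'
#' @param x a `free_energy_report`.
#' @param path optional file; when given, writes tab-separated columns
#'   `time`, `term`, `value`.
#' @return data frame (invisibly when writing).
#' @export
free_energy_to_tsv <- function(x, path = NULL) {
  stopifnot(inherits(x, "free_energy_report"))
  df <- data.frame(time = seq_along(x$per_time), term = "per_time",
                   value = x$per_time)
  df <- rbind(df, data.frame(
    time = NA_integer_,
    term = c("total", "accuracy_state_term", "decision_term",
             "parameter_complexity"),
    value = c(x$total, x$accuracy_state_term, x$decision_term,
              x$parameter_complexity)))
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
    return(invisible(df))
  }
  df
}
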