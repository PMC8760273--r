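#' Synaptic weight set of the canonical two-layer network
#'
#' Six real matrices: sensory afferents `W1`, `W0` (excitatory/inhibitory,
#' `n_x x n_o`), recurrent `K1`, `K0` (`n_x x n_x`) and output `V1`, `V0`
#' (`n_y x n_x`), together with inverse-learning-rate factors (prior mass per
#' synapse) and frozen initial copies used by the weight/Dirichlet-prior
#' correspondence.
#'
#' @param W1,W0,K1,K0,V1,V0 numeric matrices of consistent shapes.
#' @param lambda named list of inverse learning rates for `W`, `K`, `V`.
#' @return object of class `synaptic_weights`.
#' @export
synaptic_weights <- function(W1, W0, K1, K0, V1, V0,
                             lambda = list(W = 1000, K = 1000, V = 10)) {
  n_x <- nrow(W1); n_o <- ncol(W1); n_y <- nrow(V1)
  stopifnot(all(dim(W0) == c(n_x, n_o)),
            all(dim(K1) == c(n_x, n_x)), all(dim(K0) == c(n_x, n_x)),
            all(dim(V1) == c(n_y, n_x)), all(dim(V0) == c(n_y, n_x)))
  w <- list(W1 = W1, W0 = W0, K1 = K1, K0 = K0, V1 = V1, V0 = V0,
            lambda = lambda, n_x = n_x, n_o = n_o, n_y = n_y)
  w$init <- list(W1 = W1, W0 = W0, K1 = K1, K0 = K0, V1 = V1, V0 = V0)
  structure(w, class = "synaptic_weights")
}

#' Firing-threshold specification
#'
#' The threshold perturbations `phi` (middle layer) and `psi` (output layer)
#' encode the log state and decision priors; the components of each pair
#' satisfy `exp(phi1) + exp(phi0) = 1` elementwise.  Full adaptive thresholds
#' `h_l`, `m_l` are functions of the weights and are computed by
#' [compute_thresholds()].
#'
#' @param phi1,phi0 numeric vectors (length `n_x`).
#' @param psi1,psi0 numeric vectors (length `n_y`).
#' @return object of class `threshold_spec`.
#' @export
threshold_spec <- function(phi1, phi0, psi1, psi0) {
  stopifnot(length(phi1) == length(phi0), length(psi1) == length(psi0))
  if (any(abs(exp(phi1) + exp(phi0) - 1) > 1e-9) ||
      any(abs(exp(psi1) + exp(psi0) - 1) > 1e-9)) {
    stop("threshold_spec: exp(.1) + exp(.0) must equal 1 elementwise")
  }
  structure(list(phi1 = phi1, phi0 = phi0, psi1 = psi1, psi0 = psi0),
            class = "threshold_spec")
}

#' @rdname threshold_spec
#' @param weights a `synaptic_weights`.
#' @param tspec a `threshold_spec`.
#' @return for `compute_thresholds()`: list with `h1`, `h0`, `m1`, `m0`.
#' @export
compute_thresholds <- function(weights, tspec) {
  stopifnot(inherits(weights, "synaptic_weights"),
            inherits(tspec, "threshold_spec"))
  l1m <- function(M) log1p(-sig(M))       # ln(1 - sig(M)), elementwise
  list(
    h1 = rowSums(l1m(weights$W1)) + rowSums(l1m(weights$K1)) + tspec$phi1,
    h0 = rowSums(l1m(weights$W0)) + rowSums(l1m(weights$K0)) + tspec$phi0,
    m1 = rowSums(l1m(weights$V1)) + tspec$psi1,
    m0 = rowSums(l1m(weights$V0)) + tspec$psi0
  )
}

#' Network state
#'
#' Middle- and output-layer firing rates together with the delayed copy of
#' the middle layer that feeds the recurrent and output synapses.
#'
#' @param x,y rate vectors in `(0, 1)`.
#' @param x_delayed middle-layer rates one delay period earlier.
#' @return object of class `network_state`.
#' @export
network_state <- function(x, y, x_delayed = x) {
  stopifnot(all(x > 0 & x < 1), all(y > 0 & y < 1))
  structure(list(x = x, y = y, x_delayed = x_delayed),
            class = "network_state")
}

# Net drives entering the sigmoid, shared by the fixed point and the ODE.
.net_drive <- function(o_t, x_delayed, weights, th) {
  list(
    x = as.numeric((weights$W1 - weights$W0) %*% o_t +
                     (weights$K1 - weights$K0) %*% x_delayed) +
      th$h1 - th$h0,
    y = as.numeric((weights$V1 - weights$V0) %*% x_delayed) + th$m1 - th$m0
  )
}

#' Steady-state network activity
#'
#' The fixed point of the rate dynamics: a sigmoid of the summed synaptic
#' input and adaptive threshold, for both layers.  This is the per-step
#' update used in simulations (activity converges quickly relative to the
#' observation stream).
#'
#' @param o_t observation vector (binary or graded), length `n_o`.
#' @param x_delayed middle-layer rates one delay period earlier.
#' @param weights `synaptic_weights`.
#' @param thresholds list `h1, h0, m1, m0` from [compute_thresholds()].
#' @return list with rate vectors `x` and `y`.
#' @export
activity_fixed_point <- function(o_t, x_delayed, weights, thresholds) {
  dr <- .net_drive(o_t, x_delayed, weights, thresholds)
  list(x = sig(dr$x), y = sig(dr$y))
}

#' One explicit Euler step of the rate dynamics
#'
#' Integrates the leaky rate equations (logit leak plus synaptic drive and
#' threshold) with step `step_size`; rates leaving `(0, 1)` are clipped to
#' the probability floor with a warning.  Iterated to stationarity this
#' converges to [activity_fixed_point()].
#'
#' @param state a `network_state`.
#' @param o_t observation vector.
#' @param weights `synaptic_weights`.
#' @param thresholds threshold list.
#' @param step_size positive Euler step (in units of the time constant).
#' @return updated `network_state` (with `x_delayed` unchanged).
#' @export
activity_ode_step <- function(state, o_t, weights, thresholds,
                              step_size = 0.1) {
  stopifnot(inherits(state, "network_state"), step_size > 0)
  dr <- .net_drive(o_t, state$x_delayed, weights, thresholds)
  x_new <- state$x + step_size * (-sig_inv(state$x, .ACTINET_EPS) + dr$x)
  y_new <- state$y + step_size * (-sig_inv(state$y, .ACTINET_EPS) + dr$y)
  clip <- function(v) {
    if (any(v <= 0 | v >= 1)) {
      warning("activity_ode_step: rate left (0,1); clipped to the floor")
      v <- pmin(pmax(v, .ACTINET_EPS), 1 - .ACTINET_EPS)
    }
    v
  }
  network_state(clip(x_new), clip(y_new), state$x_delayed)
}

# Instantaneous integrand of the network cost at one time step.
cost_L_step <- function(o_t, x_t, x_delayed, y_t, weights, thresholds,
                        Gamma_win = 0) {
  xb <- c(x_t, 1 - x_t)
  yb <- c(y_t, 1 - y_t)
  ub_x <- c(
    as.numeric(weights$W1 %*% o_t + weights$K1 %*% x_delayed) + thresholds$h1,
    as.numeric(weights$W0 %*% o_t + weights$K0 %*% x_delayed) + thresholds$h0)
  ub_y <- (1 - 2 * Gamma_win) *
    c(as.numeric(weights$V1 %*% x_delayed),
      as.numeric(weights$V0 %*% x_delayed)) + c(thresholds$m1, thresholds$m0)
  sum(xb * (ln_floor(xb) - ub_x)) + sum(yb * (ln_floor(yb) - ub_y))
}

#' Network cost function over a history
#'
#' Evaluates the two cost integrals as sums over recorded steps.  The
#' modulator enters through the window rule: steps inside the most recent
#' delay window are unmodulated (`Gamma(t, tau) = 0`), earlier steps carry
#' the current `Gamma(t)`.  The order-one weight-dependent residual is
#' excluded (it is an additive constant in the optimised activities).
#'
#' @param history list of matrices `o` (`n_o x T`), `x` (`n_x x T`),
#'   `x_delayed` (`n_x x T`), `y` (`n_y x T`).
#' @param weights `synaptic_weights`.
#' @param thresholds threshold list from [compute_thresholds()].
#' @param Gamma scalar modulator value `Gamma(t)`, or a vector of length `T`
#'   giving `Gamma(t, tau)` directly (the window rule is then the caller's).
#' @param Delta delay window in steps (last `Delta` steps unmodulated).
#' @return scalar cost (nats).
#' @export
cost_L <- function(history, weights, thresholds, Gamma = 0, Delta = 1L) {
  T_ <- ncol(history$o)
  if (is.null(T_) || T_ == 0L) return(0)
  stopifnot(ncol(history$x) == T_, ncol(history$x_delayed) == T_,
            ncol(history$y) == T_)
  gam <- if (length(Gamma) == T_) Gamma else {
    ifelse(seq_len(T_) > T_ - Delta, 0, Gamma)
  }
  tot <- 0
  for (tau in seq_len(T_)) {
    tot <- tot + cost_L_step(history$o[, tau], history$x[, tau],
                             history$x_delayed[, tau], history$y[, tau],
                             weights, thresholds, gam[tau])
  }
  tot
}

# Time averages <post pre'> and <post> used by the plasticity rules.
.hebb_stats <- function(post, pre, w = NULL) {
  T_ <- ncol(post)
  if (!is.null(w)) post <- sweep(post, 2, w, "*")
  list(heb = tcrossprod(post, pre) / T_, act = rowSums(post) / T_)
}

#' Middle-layer plasticity step
#'
#' Gradient-descent plasticity for the sensory and recurrent synapses:
#' Hebbian co-activation minus the activity-dependent homeostatic term
#' (`<post> * sig(omega)`), applied with rate `learning_rate`.
#'
#' @param weights `synaptic_weights`.
#' @param history list with matrices `o`, `x`, `x_delayed` (columns = steps).
#' @param learning_rate positive scalar.
#' @return updated `synaptic_weights`.
#' @export
plasticity_step_middle <- function(weights, history, learning_rate = 1e-3) {
  stopifnot(ncol(history$o) >= 1)
  upd <- function(M, post, pre) {
    st <- .hebb_stats(post, pre)
    M + learning_rate * (st$heb - st$act * sig(M))
  }
  weights$W1 <- upd(weights$W1, history$x, history$o)
  weights$W0 <- upd(weights$W0, 1 - history$x, history$o)
  weights$K1 <- upd(weights$K1, history$x, history$x_delayed)
  weights$K0 <- upd(weights$K0, 1 - history$x, history$x_delayed)
  weights
}

#' Output-layer plasticity step (risk-modulated)
#'
#' As [plasticity_step_middle()] but with the Hebbian term scaled by
#' `1 - 2 Gamma`: a modulator below one half potentiates co-active
#' connections (Hebbian), above one half depresses them (anti-Hebbian); the
#' homeostatic term is unmodulated.
#'
#' @param weights `synaptic_weights`.
#' @param history list with matrices `y`, `x_delayed`.
#' @param Gamma scalar modulator, or vector of per-step values.
#' @param learning_rate positive scalar.
#' @return updated `synaptic_weights`.
#' @export
plasticity_step_output <- function(weights, history, Gamma,
                                   learning_rate = 0.1) {
  T_ <- ncol(history$y)
  stopifnot(T_ >= 1, all(Gamma >= 0), all(Gamma <= 1))
  w <- rep(1 - 2 * Gamma, length.out = T_)
  upd <- function(M, post) {
    stw <- .hebb_stats(post, history$x_delayed, w)
    st <- .hebb_stats(post, history$x_delayed)
    M + learning_rate * (stw$heb - st$act * sig(M))
  }
  weights$V1 <- upd(weights$V1, history$y)
  weights$V0 <- upd(weights$V0, 1 - history$y)
  weights
}

#' Summarise a weight change for convergence monitoring
#'
#' One row per synaptic matrix with the Frobenius norm of the change and
#' the maximal absolute entry change; written with a session column this
#' forms the weight-trajectory TSV used for convergence plots.
#'
#' @param w_old,w_new `synaptic_weights` of identical shapes.
#' @param session optional session index recorded in the output.
#' @return data frame with columns `session`, `matrix`, `frobenius`,
#'   `max_abs_change`.
#' @export
weights_delta_summary <- function(w_old, w_new, session = NA_integer_) {
  stopifnot(inherits(w_old, "synaptic_weights"),
            inherits(w_new, "synaptic_weights"))
  nms <- c("W1", "W0", "K1", "K0", "V1", "V0")
  do.call(rbind, lapply(nms, function(nm) {
    d <- w_new[[nm]] - w_old[[nm]]
    data.frame(session = session, matrix = nm,
               frobenius = sqrt(sum(d^2)), max_abs_change = max(abs(d)))
  }))
}

#' Closed-form synaptic fixed point
#'
#' The stationary point of the plasticity rules: the inverse sigmoid of the
#' conditional co-activation ratio `<post pre'> / <post>`, with the
#' `(1 - 2 Gamma)` factor inside the average for the output synapses.
#' Ratios are clipped to `(eps, 1 - eps)` before the inverse sigmoid; rows
#' with zero postsynaptic activity are undefined and returned as `NA` with a
#' warning.
#'
#' @param history list with matrices `o`, `x`, `x_delayed`, `y` as needed.
#' @param Gamma_trace per-step modulator values (used for `V1`, `V0`).
#' @param which one of `"W1"`, `"W0"`, `"K1"`, `"K0"`, `"V1"`, `"V0"`.
#' @param eps ratio clip.
#' @return weight matrix at the fixed point.
#' @export
synaptic_fixed_point <- function(history, Gamma_trace = 0, which = "W1",
                                 eps = .ACTINET_RATIO_EPS) {
  which <- match.arg(which, c("W1", "W0", "K1", "K0", "V1", "V0"))
  post <- switch(which,
    W1 = history$x, W0 = 1 - history$x,
    K1 = history$x, K0 = 1 - history$x,
    V1 = history$y, V0 = 1 - history$y)
  pre <- switch(which,
    W1 = history$o, W0 = history$o,
    K1 = history$x_delayed, K0 = history$x_delayed,
    V1 = history$x_delayed, V0 = history$x_delayed)
  T_ <- ncol(post)
  modulated <- which %in% c("V1", "V0")
  w <- if (modulated) rep(1 - 2 * Gamma_trace, length.out = T_) else NULL
  num <- .hebb_stats(post, pre, w)$heb
  den <- .hebb_stats(post, pre)$act
  bad <- den <= 0
  ratio <- num / den
  if (any(bad)) {
    warning(sprintf(
      "synaptic_fixed_point: %d row(s) with zero postsynaptic activity",
      sum(bad)))
    ratio[bad, ] <- NA_real_
  }
  out <- sig_inv(ratio, eps)
  out[is.na(ratio)] <- NA_real_
  out
}
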