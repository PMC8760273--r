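make_net <- function(n_o = 3, n_x = 3, n_y = 4, seed = 1, scale = 0.8) {
  set.seed(seed)
  w <- synaptic_weights(
    W1 = matrix(rnorm(n_x * n_o, 0, scale), n_x, n_o),
    W0 = matrix(rnorm(n_x * n_o, 0, scale), n_x, n_o),
    K1 = matrix(rnorm(n_x * n_x, 0, scale), n_x, n_x),
    K0 = matrix(rnorm(n_x * n_x, 0, scale), n_x, n_x),
    V1 = matrix(rnorm(n_y * n_x, 0, scale), n_y, n_x),
    V0 = matrix(rnorm(n_y * n_x, 0, scale), n_y, n_x))
  D <- runif(n_x, 0.2, 0.8); E <- runif(n_y, 0.2, 0.8)
  ts <- threshold_spec(log(D), log1p(-D), log(E), log1p(-E))
  list(w = w, ts = ts, th = compute_thresholds(w, ts))
}

test_that("threshold pairs must be log-complementary", {
  expect_error(threshold_spec(c(0), c(0), log(0.5), log(0.5)), "equal 1")
  ts <- threshold_spec(log(0.3), log(0.7), log(0.9), log(0.1))
  expect_s3_class(ts, "threshold_spec")
})

test_that("the steady state is symmetric under zero drive", {
  n <- 2
  w <- synaptic_weights(matrix(0, n, n), matrix(0, n, n), matrix(0, n, n),
                        matrix(0, n, n), matrix(0, n, n), matrix(0, n, n))
  ts <- threshold_spec(rep(log(0.5), n), rep(log(0.5), n),
                       rep(log(0.5), n), rep(log(0.5), n))
  th <- compute_thresholds(w, ts)
  fp <- activity_fixed_point(rep(0, n), rep(0.5, n), w, th)
  expect_equal(fp$x, rep(0.5, n), tolerance = 1e-12)
  expect_equal(fp$y, rep(0.5, n), tolerance = 1e-12)

  # saturation: +10 net input drives the rate above 0.9999
  th2 <- th
  th2$h1[1] <- th2$h1[1] + 10
  fp2 <- activity_fixed_point(rep(0, n), rep(0.5, n), w, th2)
  expect_gt(fp2$x[1], 0.9999)
})

test_that("Euler integration converges to the analytic fixed point", {
  net <- make_net(seed = 5)
  o_t <- c(1, 0, 1)
  x_del <- runif(3, 0.2, 0.8)
  fp <- activity_fixed_point(o_t, x_del, net$w, net$th)
  st <- network_state(rep(0.5, 3), rep(0.5, 4), x_del)
  for (i in 1:3000) st <- activity_ode_step(st, o_t, net$w, net$th, 0.05)
  expect_equal(st$x, fp$x, tolerance = 1e-8)
  expect_equal(st$y, fp$y, tolerance = 1e-8)

  # a state already at the fixed point stays there
  st_fp <- network_state(fp$x, fp$y, x_del)
  st2 <- activity_ode_step(st_fp, o_t, net$w, net$th, 0.1)
  expect_equal(st2$x, fp$x, tolerance = 1e-10)

  # zero drive at x = 0.5 has zero derivative
  n <- 2
  w0 <- synaptic_weights(matrix(0, n, n), matrix(0, n, n), matrix(0, n, n),
                         matrix(0, n, n), matrix(0, n, n), matrix(0, n, n))
  ts0 <- threshold_spec(rep(log(0.5), n), rep(log(0.5), n),
                        rep(log(0.5), n), rep(log(0.5), n))
  st0 <- network_state(rep(0.5, n), rep(0.5, n), rep(0.5, n))
  st0b <- activity_ode_step(st0, rep(0, n), w0, compute_thresholds(w0, ts0), 0.2)
  expect_equal(st0b$x, rep(0.5, n), tolerance = 1e-12)
})

test_that("the cost gradient equals the negative activity drift", {
  # finite differences of the instantaneous integrand against the ODE drift
  net <- make_net(seed = 7)
  o_t <- c(0, 1, 1)
  x_del <- runif(3, 0.2, 0.8)
  x <- runif(3, 0.2, 0.8); y <- runif(4, 0.2, 0.8)
  h <- 1e-6
  drift_x <- -sig_inv(x) +
    as.numeric((net$w$W1 - net$w$W0) %*% o_t +
                 (net$w$K1 - net$w$K0) %*% x_del) + net$th$h1 - net$th$h0
  drift_y <- -sig_inv(y) +
    as.numeric((net$w$V1 - net$w$V0) %*% x_del) + net$th$m1 - net$th$m0
  for (i in 1:3) {
    xp <- x; xm <- x
    xp[i] <- x[i] + h; xm[i] <- x[i] - h
    g <- (actinet:::cost_L_step(o_t, xp, x_del, y, net$w, net$th, 0) -
            actinet:::cost_L_step(o_t, xm, x_del, y, net$w, net$th, 0)) / (2 * h)
    expect_equal(g, -drift_x[i], tolerance = 1e-5)
  }
  for (i in 1:4) {
    yp <- y; ym <- y
    yp[i] <- y[i] + h; ym[i] <- y[i] - h
    g <- (actinet:::cost_L_step(o_t, x, x_del, yp, net$w, net$th, 0) -
            actinet:::cost_L_step(o_t, x, x_del, ym, net$w, net$th, 0)) / (2 * h)
    expect_equal(g, -drift_y[i], tolerance = 1e-5)
  }
})

test_that("the cost is zero on an empty history and minimal at the fixed point", {
  net <- make_net(seed = 9)
  expect_equal(cost_L(list(o = matrix(0, 3, 0), x = matrix(0, 3, 0),
                           x_delayed = matrix(0, 3, 0),
                           y = matrix(0, 4, 0)), net$w, net$th), 0)
  o_t <- c(1, 1, 0)
  x_del <- runif(3, 0.2, 0.8)
  fp <- activity_fixed_point(o_t, x_del, net$w, net$th)
  f_of <- function(xv) {
    cost_L(list(o = matrix(o_t, 3, 1), x = matrix(xv, 3, 1),
                x_delayed = matrix(x_del, 3, 1), y = matrix(fp$y, 4, 1)),
           net$w, net$th, Gamma = 0)
  }
  h <- 1e-6
  for (i in 1:3) {
    xp <- fp$x; xm <- fp$x
    xp[i] <- xp[i] + h; xm[i] <- xm[i] - h
    expect_lt(abs((f_of(xp) - f_of(xm)) / (2 * h)), 1e-5)
  }
})

test_that("middle-layer plasticity obeys its closed-form behaviour", {
  n <- 2
  w <- synaptic_weights(matrix(0.3, n, n), matrix(-0.2, n, n),
                        matrix(0.1, n, n), matrix(0, n, n),
                        matrix(0.2, n, n), matrix(0, n, n))
  # silent postsynaptic units leave the weights unchanged
  hist0 <- list(o = matrix(1, n, 5), x = matrix(0, n, 5),
                x_delayed = matrix(0.5, n, 5))
  w2 <- plasticity_step_middle(w, hist0, learning_rate = 0.5)
  expect_equal(w2$W1, w$W1, tolerance = 1e-12)
  expect_equal(w2$K1, w$K1, tolerance = 1e-12)
  # saturating case: post = pre = 1 gives increment 1 - sig(w)
  hist1 <- list(o = matrix(1, n, 5), x = matrix(1, n, 5),
                x_delayed = matrix(1, n, 5))
  w3 <- plasticity_step_middle(w, hist1, learning_rate = 1)
  expect_equal(w3$W1, w$W1 + (1 - sig(w$W1)), tolerance = 1e-12)
})

test_that("iterated plasticity converges to the synaptic fixed point", {
  set.seed(31)
  n_o <- 2; n_x <- 2
  T_ <- 10000
  o <- matrix(as.numeric(runif(n_o * T_) < 0.4), n_o, T_)
  x <- matrix(as.numeric(runif(n_x * T_) < 0.6), n_x, T_)
  hist_ <- list(o = o, x = x, x_delayed = x)
  fpW1 <- synaptic_fixed_point(hist_, 0, "W1")
  w <- synaptic_weights(matrix(0, n_x, n_o), matrix(0, n_x, n_o),
                        matrix(0, n_x, n_x), matrix(0, n_x, n_x),
                        matrix(0, 1, n_x), matrix(0, 1, n_x))
  for (i in 1:400) w <- plasticity_step_middle(w, hist_, learning_rate = 0.3)
  expect_lt(max(abs(sig(w$W1) - sig(fpW1))), 0.05)
})

test_that("output plasticity is modulated with slope minus two in Gamma", {
  net <- make_net(seed = 13)
  hist_ <- list(y = matrix(runif(4 * 6), 4, 6),
                x_delayed = matrix(runif(3 * 6), 3, 6))
  w_half <- plasticity_step_output(net$w, hist_, Gamma = 0.5,
                                   learning_rate = 1)
  # at Gamma = 0.5 only the homeostatic term acts
  stats_act <- rowMeans(hist_$y)
  expect_equal(w_half$V1, net$w$V1 - stats_act * sig(net$w$V1),
               tolerance = 1e-12)
  # Gamma = 0 and Gamma = 1 Hebbian contributions are exact negatives
  w0 <- plasticity_step_output(net$w, hist_, Gamma = 0, learning_rate = 1)
  w1 <- plasticity_step_output(net$w, hist_, Gamma = 1, learning_rate = 1)
  heb0 <- w0$V1 - w_half$V1
  heb1 <- w1$V1 - w_half$V1
  expect_equal(heb0, -heb1, tolerance = 1e-12)
  # affine in Gamma with slope -2 on the Hebbian term
  w03 <- plasticity_step_output(net$w, hist_, Gamma = 0.3, learning_rate = 1)
  expect_equal(w03$V1 - w_half$V1, (1 - 2 * 0.3) * heb0, tolerance = 1e-12)
})

test_that("synaptic fixed points reproduce conditional ratios and edge cases", {
  # conditional ratio exactly one half gives weight zero
  hist_ <- list(o = matrix(c(1, 0, 1, 0), 1, 4),
                x = matrix(1, 1, 4), x_delayed = matrix(1, 1, 4),
                y = matrix(1, 1, 4))
  expect_equal(synaptic_fixed_point(hist_, 0, "W1")[1, 1], 0,
               tolerance = 1e-12)
  # pre always equal to post saturates at the documented clip
  hist2 <- list(o = matrix(1, 1, 4), x = matrix(1, 1, 4),
                x_delayed = matrix(1, 1, 4), y = matrix(1, 1, 4))
  expect_equal(synaptic_fixed_point(hist2, 0, "W1")[1, 1], sig_inv(1),
               tolerance = 1e-12)
  # zero postsynaptic activity is reported as NA with a warning
  hist3 <- list(o = matrix(1, 1, 4), x = matrix(0, 1, 4),
                x_delayed = matrix(1, 1, 4), y = matrix(1, 1, 4))
  expect_warning(fp <- synaptic_fixed_point(hist3, 0, "W1"), "zero")
  expect_true(is.na(fp[1, 1]))
})

test_that("sig of the fixed point equals the count-based Dirichlet mean", {
  # shared counts: Hebbian ratio <x o'>/<x> against the posterior mean of
  # P(o = 1 | s-component active) from the same one-hot history
  set.seed(41)
  n_o <- 2; n_x <- 2; T_ <- 500
  o <- matrix(as.numeric(runif(n_o * T_) < 0.5), n_o, T_)
  x <- matrix(as.numeric(runif(n_x * T_) < 0.5), n_x, T_)
  hist_ <- list(o = o, x = x, x_delayed = x, y = x)
  fpW1 <- synaptic_fixed_point(hist_, 0, "W1")
  bank <- dirichlet_bank(dirichlet_array(1e-12, n_o, n_x),
                         dirichlet_array(1e-12, n_x, n_x),
                         dirichlet_array(1e-12, n_x, n_x))
  bank <- update_parameters(bank, o, x, x, x, Gamma_t = 0)
  aa <- unclass(bank$a)
  cond <- t(matrix(aa[1, 1, , ] / (aa[1, 1, , ] + aa[2, 1, , ]), n_o, n_x))
  expect_lt(max(abs(sig(fpW1) - cond)), 1e-9)
})

test_that("homeostatic decay pulls weights down without correlation", {
  # constant post, zero pre correlation: only the homeostatic term acts
  n <- 2
  w <- synaptic_weights(matrix(2, n, n), matrix(2, n, n), matrix(0, n, n),
                        matrix(0, n, n), matrix(0, 1, n), matrix(0, 1, n))
  hist_ <- list(o = matrix(0, n, 10), x = matrix(1, n, 10),
                x_delayed = matrix(0, n, 10))
  w2 <- plasticity_step_middle(w, hist_, learning_rate = 1)
  expect_true(all(w2$W1 < w$W1))
})

test_that("weight changes summarise into a trajectory table", {
  net <- make_net(seed = 17)
  w2 <- net$w
  w2$V1 <- w2$V1 + 0.5
  df <- weights_delta_summary(net$w, w2, session = 3L)
  expect_equal(nrow(df), 6L)
  expect_equal(df$max_abs_change[df$matrix == "V1"], 0.5, tolerance = 1e-12)
  expect_equal(df$frobenius[df$matrix == "W1"], 0, tolerance = 1e-12)
  expect_true(all(df$session == 3L))
})
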