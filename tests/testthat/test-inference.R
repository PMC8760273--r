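test_that("state inference reduces to symmetric beliefs on zero logits", {
  zero <- array(0, c(2, 2, 1, 1))
  s <- infer_state(c(1), belief_block(0.5), zero, zero, belief_block(0.5))
  expect_equal(s$p1, 0.5, tolerance = 1e-12)
})

test_that("identity likelihood concentrates the state belief", {
  A <- fm_identity("A", 1, rho = 1)
  Binv <- fm_uniform("Binv", 1, 1)
  s <- infer_state(c(1), belief_block(0.5), log_mapping(A),
                   log_mapping(Binv), belief_block(0.5))
  # the observed state dominates up to the probability floor
  expect_gt(s$p1, 1 - 1e-6)
})

test_that("state inference matches brute-force Bayes on a 2-state chain", {
  # with a realized (one-hot) previous state, the variational update is the
  # exact filtered posterior: p(s_t | o_t, s_{t-1}) ~ A[o, s] B[s, s_prev]
  for (seed in 1:5) {
    mod <- one_factor_model(seed)
    logs <- literal_inverse_logs(mod)
    for (s_prev_bit in 0:1) {
      for (o_bit in 0:1) {
        sp <- one_hot_belief(s_prev_bit)
        post <- infer_state(o_bit, sp, logs$A, logs$Binv, mod$D)
        A <- mod$A$sub[, , 1, 1]; B <- mod$B$sub[, , 1, 1]
        co <- 2 - o_bit; cp <- 2 - s_prev_bit
        w1 <- A[co, 1] * B[1, cp]
        w0 <- A[co, 2] * B[2, cp]
        expect_equal(post$p1, w1 / (w1 + w0), tolerance = 1e-9)
      }
    }
  }
})

test_that("decision inference under flat mappings returns the prior element", {
  # flat policy mapping and uniform prior over a 256-way one-hot space
  n_d <- 256
  Cinv <- fm_uniform("Cinv", 4, n_d)
  E <- belief_block(rep(1 / 256, n_d))
  d <- infer_decision(belief_block(rep(0.5, 4)), log_mapping(Cinv), E)
  expect_equal(d$p1, rep(1 / 256, n_d), tolerance = 1e-9)
  expect_equal(round(d$p1[1], 4), 0.0039)

  # zero logits with two options
  zero <- array(0, c(2, 2, 1, 2))
  d2 <- infer_decision(belief_block(0.5), zero, belief_block(c(0.5, 0.5)))
  expect_equal(d2$p1, c(0.5, 0.5), tolerance = 1e-12)
})

test_that("decision inference matches enumeration for a realized state", {
  for (seed in 1:5) {
    mod <- one_factor_model(seed + 40)
    logs <- literal_inverse_logs(mod)
    for (s_bit in 0:1) {
      d <- infer_decision(one_hot_belief(s_bit), logs$Cinv, mod$E)
      C <- mod$C$sub[, , 1, 1]
      expect_equal(d$p1, C[1, 2 - s_bit], tolerance = 1e-9)
    }
  }
})

test_that("free energy at the exact posterior equals the negative log evidence", {
  # single step: F = -ln sum_s A[o, s] D_s exactly, and any perturbed
  # posterior is strictly worse (upper-bound property)
  for (seed in 1:5) {
    mod <- one_factor_model(seed + 10)
    logs <- literal_inverse_logs(mod)
    o_bit <- seed %% 2
    # at time 1 there is no transition evidence: zero out the inverse term
    no_trans <- array(0, c(2, 2, 1, 1))
    post <- infer_state(o_bit, belief_block(0.5), logs$A, no_trans, mod$D)
    dpost <- belief_block(mod$E$p1)         # decision prior minimises its term
    fe <- free_energy(o = matrix(o_bit, 1, 1), s = matrix(post$p1, 1, 1),
                      s_prev = matrix(0.5, 1, 1),
                      delta = matrix(dpost$p1, 1, 1),
                      maps = logs, D = mod$D, E = mod$E, Gamma_t = 0)
    A <- mod$A$sub[, , 1, 1]
    evidence <- A[2 - o_bit, 1] * mod$D$p1 + A[2 - o_bit, 2] * mod$D$p0
    expect_equal(fe$total, -log(evidence), tolerance = 1e-9)

    for (eps in c(-0.1, 0.07)) {
      pert <- belief_block(min(max(post$p1 + eps, 1e-6), 1 - 1e-6))
      fe_p <- free_energy(o = matrix(o_bit, 1, 1),
                          s = matrix(pert$p1, 1, 1),
                          s_prev = matrix(0.5, 1, 1),
                          delta = matrix(dpost$p1, 1, 1),
                          maps = logs, D = mod$D, E = mod$E, Gamma_t = 0)
      expect_gt(fe_p$total, fe$total)
    }
  }
})

test_that("coordinate updates never increase free energy", {
  set.seed(99)
  for (rep in 1:100) {
    mod <- one_factor_model(rep + 100)
    logs <- literal_inverse_logs(mod)
    o_bits <- as.integer(runif(3) < 0.5)
    s_prev <- belief_block(runif(1, 0.05, 0.95))
    # random beliefs at the final step, then one coordinate update each
    s_rand <- runif(1, 0.05, 0.95)
    d_rand <- runif(1, 0.05, 0.95)
    sp_mat <- matrix(s_prev$p1, 1, 1)
    fe_before <- free_energy(matrix(o_bits[1], 1, 1), matrix(s_rand, 1, 1),
                             sp_mat, matrix(d_rand, 1, 1), logs,
                             mod$D, mod$E, Gamma_t = 0, initial = FALSE)
    s_new <- infer_state(o_bits[1], s_prev, logs$A, logs$Binv, mod$D)
    fe_s <- free_energy(matrix(o_bits[1], 1, 1), matrix(s_new$p1, 1, 1),
                        sp_mat, matrix(d_rand, 1, 1), logs,
                        mod$D, mod$E, Gamma_t = 0, initial = FALSE)
    expect_lte(fe_s$total, fe_before$total + 1e-12)
    d_new <- infer_decision(s_prev, logs$Cinv, mod$E)
    fe_d <- free_energy(matrix(o_bits[1], 1, 1), matrix(s_new$p1, 1, 1),
                        sp_mat, matrix(d_new$p1, 1, 1), logs,
                        mod$D, mod$E, Gamma_t = 0, initial = FALSE)
    expect_lte(fe_d$total, fe_s$total + 1e-12)
  }
})

test_that("the report decomposition is additive and exports to TSV", {
  mod <- one_factor_model(3)
  logs <- literal_inverse_logs(mod)
  o <- matrix(c(1, 0, 1), 1, 3)
  s <- matrix(c(0.7, 0.3, 0.6), 1, 3)
  s_prev <- matrix(c(0.5, 0.7, 0.3), 1, 3)
  delta <- matrix(c(0.5, 0.2, 0.9), 1, 3)
  bank <- dirichlet_bank(dirichlet_array(2, 1, 1), dirichlet_array(2, 1, 1),
                         dirichlet_array(2, 1, 1))
  fe <- free_energy(o, s, s_prev, delta, logs, mod$D, mod$E, Gamma_t = 0.3,
                    initial = FALSE, bank = bank,
                    include_parameter_complexity = TRUE)
  expect_equal(fe$total,
               fe$accuracy_state_term + fe$decision_term +
                 fe$parameter_complexity, tolerance = 1e-9)
  tsv <- tempfile(fileext = ".tsv")
  on.exit(unlink(tsv), add = TRUE)
  free_energy_to_tsv(fe, tsv)
  expect_true(file.exists(tsv))
  expect_equal(nrow(utils::read.delim(tsv)), 3 + 4)
})

test_that("stationarity: numerical gradient of F vanishes at the minimiser", {
  mod <- one_factor_model(17)
  logs <- literal_inverse_logs(mod)
  s_prev <- belief_block(0.35)
  s_star <- infer_state(1, s_prev, logs$A, logs$Binv, mod$D)
  f_of <- function(p) {
    free_energy(matrix(1, 1, 1), matrix(p, 1, 1),
                matrix(s_prev$p1, 1, 1), matrix(mod$E$p1, 1, 1),
                logs, mod$D, mod$E, Gamma_t = 0, initial = FALSE)$total
  }
  h <- 1e-6
  grad <- (f_of(s_star$p1 + h) - f_of(s_star$p1 - h)) / (2 * h)
  expect_lt(abs(grad), 1e-6)
})

test_that("forward and inverse free-energy forms agree at zero risk", {
  # one-factor model with the literal Bayes inverses: the two algebraic
  # forms of the objective coincide when the inversion identities hold
  for (seed in 1:5) {
    mod <- one_factor_model(seed + 60)
    maps <- c(literal_inverse_logs(mod),
              list(B = log_mapping(mod$B), C = log_mapping(mod$C)))
    set.seed(seed)
    T_ <- 4
    o <- matrix(as.numeric(runif(T_) < 0.5), 1, T_)
    s <- matrix(runif(T_, 0.1, 0.9), 1, T_)
    s_prev <- matrix(runif(T_, 0.1, 0.9), 1, T_)
    delta <- matrix(runif(T_, 0.1, 0.9), 1, T_)
    fi <- free_energy(o, s, s_prev, delta, maps, mod$D, mod$E,
                      Gamma_t = 0, form = "inverse", initial = FALSE)
    ff <- free_energy(o, s, s_prev, delta, maps, mod$D, mod$E,
                      Gamma_t = 0, form = "forward", initial = FALSE)
    expect_equal(fi$total, ff$total, tolerance = 1e-9)
  }
})
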