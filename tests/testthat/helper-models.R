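# Shared fixture builders.  Everything is generated in code under fixed
# seeds; no stored data files.

# Random one-factor POMDP pieces (2-state chain with binary observation).
one_factor_model <- function(seed = 1) {
  set.seed(seed)
  list(A = fm_random("A", 1, 1), B = fm_random("B", 1, 1),
       C = fm_random("C", 1, 1), D = random_prior(1), E = random_prior(1))
}

# Log arrays of the literal (unnormalised) Bayes inverses of a model, the
# form under which the reduced single-step updates are exact Bayes rule.
literal_inverse_logs <- function(mod) {
  list(A = log_mapping(mod$A),
       Binv = log_mapping(bayes_invert(mod$B, mod$D)),
       Cinv = log_mapping(bayes_invert(mod$C, mod$E)))
}

# Hand-rolled vertical-barrier maze used by behavioural tests (independent
# of the package generator so maze bugs cannot hide).
tiny_open_maze <- function(H = 7, W = 9) {
  cells <- matrix(0L, H, W)
  cells[2:(H - 1), 2:W] <- 1L
  cells[4, 1] <- 1L
  maze_grid(cells, c(4L, 1L))
}

# Random history matrices (graded beliefs / binary observations) for
# plasticity and free-energy checks.
random_history <- function(n_o, n_x, n_y, T_, seed = 1) {
  set.seed(seed)
  list(o = matrix(as.numeric(runif(n_o * T_) < 0.5), n_o, T_),
       x = matrix(runif(n_x * T_, 0.05, 0.95), n_x, T_),
       x_delayed = matrix(runif(n_x * T_, 0.05, 0.95), n_x, T_),
       y = matrix(runif(n_y * T_, 0.05, 0.95), n_y, T_))
}
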