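# Minimal session log with hand-set sufficient statistics, for exercising
# the learning phase without running a maze.
fake_log <- function(agent, P, S_dxm = NULL, S_d = NULL) {
  n_y <- agent$n_y; n_x <- agent$n_x
  st <- list(
    S_xo = matrix(0, n_x, n_x), S_xxp = matrix(0, n_x, n_x),
    S_dxm = if (is.null(S_dxm)) matrix(0, n_y, n_x) else S_dxm,
    S_dx = matrix(0, n_y, n_x),
    S_d = if (is.null(S_d)) rep(0, n_y) else S_d,
    S_o = rep(0, n_x), S_x = rep(P / 2, n_x), S_xp = rep(P / 2, n_x),
    S_xp_w = rep(0, n_x), S_y = rep(P / 256, n_y), S_w = 0, n_periods = P)
  structure(list(success = FALSE, duration = 4L * P, n_periods = P,
                 decisions = integer(0), gamma = numeric(0),
                 col_trace = integer(0), stats = st, T = 4L * P),
            class = "session_log")
}

test_that("an agent starting on the rightmost column succeeds immediately", {
  cells <- matrix(1L, 3, 1)
  m <- maze_grid(cells, c(2L, 1L))
  a <- maze_agent(window = 3L, n_steps = 2L)
  lg <- run_action_phase(a, m, T = 100, seed = 1)
  expect_true(lg$success)
  expect_equal(lg$duration, 0L)
  expect_equal(lg$n_periods, 0L)
})

test_that("action phases are reproducible bit-for-bit from the seed", {
  m <- generate_barrier_maze(11, 15, seed = 3)
  a <- maze_agent(window = 5L, n_steps = 2L)
  l1 <- run_action_phase(a, m, T = 2000, seed = 7, log_activity = TRUE)
  l2 <- run_action_phase(a, m, T = 2000, seed = 7, log_activity = TRUE)
  expect_identical(l1$decisions, l2$decisions)
  expect_identical(l1$positions, l2$positions)
  expect_equal(l1$X, l2$X, tolerance = 0)
})

test_that("time is conserved: steps equal four per period plus remainder", {
  m <- generate_barrier_maze(21, 41, seed = 5)
  a <- maze_agent()
  lg <- run_action_phase(a, m, T = 4000, seed = 2)
  if (lg$success) {
    expect_gte(lg$duration, 4L * lg$n_periods)
    expect_lte(lg$duration, 4L * (lg$n_periods + 1L))
  } else {
    expect_equal(lg$duration, 4L * lg$n_periods)
  }
})

test_that("untrained decisions have uniform first-action marginals", {
  m <- generate_barrier_maze(21, 41, seed = 9)
  a <- maze_agent(learn = list(W = FALSE, K = FALSE, V = FALSE))
  dec <- integer(0)
  set.seed(11)
  while (length(dec) < 10000) {
    lg <- run_action_phase(a, m, T = 20000)
    dec <- c(dec, lg$decisions)
  }
  firsts <- dec[seq_len(10000)] %/% 64L
  tab <- tabulate(firsts + 1L, 4L)
  chi <- stats::chisq.test(tab, p = rep(0.25, 4))
  expect_gt(chi$p.value, 0.01)
})

test_that("learning-phase branches behave as the modulation dictates", {
  a <- maze_agent(window = 3L, n_steps = 2L)
  P <- 50L
  # all periods at Gamma = 0.5: modulated statistics vanish, V unchanged
  a1 <- run_learning_phase(a, fake_log(a, P))
  expect_equal(a1$weights$V1, a$weights$V1, tolerance = 1e-12)
  # alternating Gamma = 0 / 1 on identical activity cancels exactly
  ctx <- rep(0.5, a$n_x)
  S_pos <- outer(c(1, rep(0, a$n_y - 1)), ctx) * 10
  a2 <- run_learning_phase(a, fake_log(a, P, S_dxm = S_pos - S_pos,
                                       S_d = c(20, rep(0, a$n_y - 1))))
  expect_equal(a2$weights$V1, a$weights$V1, tolerance = 1e-10)
  # pure Hebbian branch (all Gamma = 0): chosen decision potentiated in its
  # context relative to the others
  a3 <- run_learning_phase(a, fake_log(a, P, S_dxm = S_pos,
                                       S_d = c(20, rep(0, a$n_y - 1))))
  expect_true(all(a3$weights$V1[1, ] > a$weights$V1[1, ]))
  expect_true(all(a3$weights$V1[-1, ] <= a$weights$V1[-1, ] + 1e-12))
})

test_that("training records sessions and a single session changes weights", {
  m <- generate_barrier_maze(11, 15, seed = 1)
  a <- maze_agent(window = 5L, n_steps = 2L)
  cv <- train(a, m, n_sessions = 1, T = 400, seed = 3)
  expect_equal(nrow(cv$sessions), 1L)
  if (cv$sessions$duration[1] > 0) {
    expect_false(isTRUE(all.equal(cv$agent$weights$V1, a$weights$V1)))
  }
  expect_true(all(rolling_failure_probability(cv) >= 0 &
                    rolling_failure_probability(cv) <= 1))
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  training_curve_to_tsv(cv, path)
  expect_equal(nrow(utils::read.delim(path)), 1L)
})

test_that("decision priors direct early behaviour (prior sensitivity)", {
  # before any learning, a stronger rightward prior carries the agent
  # further right within the session: the furthest column reached orders
  # strictly with E_right across ten seeds per condition (session
  # durations saturate at the step budget early on, so progress is the
  # discriminating early-session statistic)
  conds <- c(0.0023, 0.0039, 0.0055)
  mean_prog <- vapply(conds, function(er) {
    p <- c()
    for (s in 1:10) {
      m <- generate_barrier_maze(21, 41, seed = 500 + s)
      a <- maze_agent(E_dirs = decision_prior(E_right = er),
                      learn = list(W = FALSE, K = FALSE, V = FALSE))
      lg <- run_action_phase(a, m, T = 20000, seed = s)
      p <- c(p, max(lg$col_trace))
    }
    mean(p)
  }, numeric(1))
  expect_true(mean_prog[1] < mean_prog[2] && mean_prog[2] < mean_prog[3])
})
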