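#' Direction-based decision priors
#'
#' Builds the per-direction prior values used in the prior-sensitivity
#' experiments: the rightward value is free, the leftward value is its
#' complement within the left/right mass `lr_mass`, and the vertical values
#' stay at the uniform element.
#'
#' @param E_right prior element for decisions starting rightward.
#' @param lr_mass combined first-step right + left mass (default `2/256`).
#' @param E_vertical prior element for up/down first steps.
#' @return named vector with entries `right`, `left`, `up`, `down`.
#' @export
decision_prior <- function(E_right = 1 / 256, lr_mass = 2 / 256,
                           E_vertical = 1 / 256) {
  stopifnot(E_right > 0, E_right < lr_mass)
  c(right = E_right, left = lr_mass - E_right,
    up = E_vertical, down = E_vertical)
}

#' Train an agent over alternating action and learning phases
#'
#' Runs `n_sessions` cycles of action phase (one maze session, at most `T`
#' steps) and learning phase (session-batch plasticity).  Mazes are cycled
#' session by session when several are supplied.  The whole run is
#' deterministic given `seed`.
#'
#' @param agent a `maze_agent`.
#' @param mazes a `maze_grid` or list of them.
#' @param n_sessions number of training sessions.
#' @param T step budget per session.
#' @param seed integer seed for the whole run.
#' @return object of class `training_curve`: data frame `sessions` with
#'   columns `session`, `duration`, `success`, `maze`, `mean_gamma`, plus
#'   the trained `agent`.
#' @export
train <- function(agent, mazes, n_sessions = 100L, T = 20000L, seed = 1L) {
  stopifnot(inherits(agent, "maze_agent"), n_sessions >= 1)
  if (inherits(mazes, "maze_grid")) mazes <- list(mazes)
  stopifnot(all(vapply(mazes, inherits, logical(1), "maze_grid")))
  set.seed(as.integer(seed))
  n <- as.integer(n_sessions)
  duration <- integer(n); success <- logical(n)
  maze_id <- integer(n); mean_gamma <- numeric(n)
  for (s in seq_len(n)) {
    mid <- ((s - 1L) %% length(mazes)) + 1L
    log_ <- run_action_phase(agent, mazes[[mid]], T = T, seed = NULL)
    agent <- run_learning_phase(agent, log_)
    duration[s] <- log_$duration
    success[s] <- log_$success
    maze_id[s] <- mid
    mean_gamma[s] <- if (length(log_$gamma)) mean(log_$gamma) else NA_real_
  }
  structure(list(
    sessions = data.frame(session = seq_len(n), duration = duration,
                          success = success, maze = maze_id,
                          mean_gamma = mean_gamma),
    agent = agent, T = as.integer(T), seed = as.integer(seed)
  ), class = "training_curve")
}

#' @export
print.training_curve <- function(x, ...) {
  n <- nrow(x$sessions)
  cat("<training_curve> ", n, " sessions; failure probability ",
      sprintf("%.2f", mean(!x$sessions$success)), " overall\n", sep = "")
  invisible(x)
}

#' Failure probability over session windows
#'
#' @param curve a `training_curve` (or its `sessions` data frame).
#' @param sessions integer vector of session indices to average over.
#' @return scalar failure probability in `[0, 1]`.
#' @export
failure_probability <- function(curve, sessions = NULL) {
  df <- if (inherits(curve, "training_curve")) curve$sessions else curve
  if (!is.null(sessions)) df <- df[df$session %in% sessions, ]
  mean(!df$success)
}

#' @rdname failure_probability
#' @param window window length for the running average (ten sessions by
#'   convention).
#' @return `rolling_failure_probability()`: vector of windowed averages
#'   (entry `i` covers sessions `i - window + 1` to `i`).
#' @export
rolling_failure_probability <- function(curve, window = 10L) {
  df <- if (inherits(curve, "training_curve")) curve$sessions else curve
  f <- as.numeric(!df$success)
  n <- length(f)
  vapply(seq_len(n), function(i) {
    mean(f[max(1L, i - window + 1L):i])
  }, numeric(1))
}

#' Export a training curve to TSV
#'
#' @param curve a `training_curve`.
#' @param path output file.
#' @return the data frame, invisibly.
#' @export
training_curve_to_tsv <- function(curve, path) {
  stopifnot(inherits(curve, "training_curve"))
  utils::write.table(curve$sessions, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(curve$sessions)
}

#' Export a session log to TSV (one row per period)
#'
#' @param log a `session_log`.
#' @param path output file.
#' @return the data frame, invisibly.
#' @export
session_log_to_tsv <- function(log, path) {
  stopifnot(inherits(log, "session_log"))
  np <- length(log$decisions)
  df <- data.frame(period = seq_len(np),
                   decision = log$decisions,
                   gamma = log$gamma[seq_len(np)],
                   col = log$col_trace[seq_len(np)])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(df)
}
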