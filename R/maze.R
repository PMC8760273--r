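#' Maze grid
#'
#' A discrete grid of pathway and wall cells.  The agent starts at a pathway
#' cell in the leftmost column and succeeds on first arrival at any pathway
#' cell of the rightmost column.  Every generated maze carries a
#' breadth-first-search certificate of solvability.
#'
#' @param cells integer or logical matrix, 1/`TRUE` = pathway, 0 = wall.
#' @param start length-2 integer `(row, col)` with `col = 1`.
#' @return object of class `maze_grid`.
#' @export
maze_grid <- function(cells, start) {
  cells <- matrix(as.integer(cells != 0), nrow(cells), ncol(cells))
  stopifnot(length(start) == 2, start[2] == 1L,
            cells[start[1], start[2]] == 1L)
  m <- structure(list(cells = cells, start = as.integer(start),
                      H = nrow(cells), W = ncol(cells)),
                 class = "maze_grid")
  if (!maze_solvable(m)) stop("maze_grid: no path from start to right edge")
  m
}

#' @rdname maze_grid
#' @param maze a `maze_grid`.
#' @return `maze_solvable()`: `TRUE` if a pathway connects the start to the
#'   rightmost column (4-neighbourhood breadth-first search).
#' @export
maze_solvable <- function(maze) {
  cells <- maze$cells
  H <- maze$H; W <- maze$W
  seen <- matrix(FALSE, H, W)
  queue <- matrix(maze$start, ncol = 2)
  seen[maze$start[1], maze$start[2]] <- TRUE
  while (nrow(queue) > 0) {
    cur <- queue[1, , drop = TRUE]
    queue <- queue[-1, , drop = FALSE]
    if (cur[2] == W) return(TRUE)
    for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      nr <- cur[1] + d[1]; nc <- cur[2] + d[2]
      if (nr >= 1 && nr <= H && nc >= 1 && nc <= W &&
          cells[nr, nc] == 1L && !seen[nr, nc]) {
        seen[nr, nc] <- TRUE
        queue <- rbind(queue, c(nr, nc))
      }
    }
  }
  FALSE
}

#' Generate a random solvable maze
#'
#' Randomised depth-first (recursive backtracker) corridor carving on an
#' odd-dimensioned grid, plus a configurable density of extra openings that
#' create loops, an opened start cell on the left edge and goal cells on the
#' right edge.  Regenerates (bounded retries) until solvable; deterministic
#' per seed.
#'
#' @param height,width odd integers `>= 5`.
#' @param seed integer seed.
#' @param extra_openings fraction of interior walls (with pathway on both
#'   sides) that are additionally opened.
#' @param max_retries retry budget for the solvability guarantee.
#' @return a `maze_grid`.
#' @export
generate_maze <- function(height = 21, width = 41, seed = 1L,
                          extra_openings = 0.2, max_retries = 20L) {
  stopifnot(height >= 5, width >= 5, height %% 2 == 1, width %% 2 == 1)
  set.seed(as.integer(seed))
  for (attempt in seq_len(max_retries)) {
    cells <- matrix(0L, height, width)
    nodes_r <- seq(2L, height - 1L, by = 2L)
    nodes_c <- seq(2L, width - 1L, by = 2L)
    nr <- length(nodes_r); nc <- length(nodes_c)
    visited <- matrix(FALSE, nr, nc)
    # iterative depth-first carving over the node lattice
    stack <- matrix(c(sample.int(nr, 1), sample.int(nc, 1)), ncol = 2)
    visited[stack[1, 1], stack[1, 2]] <- TRUE
    cells[nodes_r[stack[1, 1]], nodes_c[stack[1, 2]]] <- 1L
    while (nrow(stack) > 0) {
      cur <- stack[nrow(stack), ]
      nbrs <- rbind(cur + c(-1L, 0L), cur + c(1L, 0L),
                    cur + c(0L, -1L), cur + c(0L, 1L))
      ok <- nbrs[, 1] >= 1 & nbrs[, 1] <= nr & nbrs[, 2] >= 1 &
        nbrs[, 2] <= nc
      nbrs <- nbrs[ok, , drop = FALSE]
      nbrs <- nbrs[!visited[nbrs], , drop = FALSE]
      if (nrow(nbrs) == 0) {
        stack <- stack[-nrow(stack), , drop = FALSE]
        next
      }
      nxt <- nbrs[sample.int(nrow(nbrs), 1), ]
      visited[nxt[1], nxt[2]] <- TRUE
      cells[nodes_r[nxt[1]], nodes_c[nxt[2]]] <- 1L
      cells[(nodes_r[cur[1]] + nodes_r[nxt[1]]) %/% 2L,
            (nodes_c[cur[2]] + nodes_c[nxt[2]]) %/% 2L] <- 1L
      stack <- rbind(stack, nxt)
    }
    # extra openings: interior walls flanked by two pathways
    if (extra_openings > 0) {
      wall_idx <- which(cells[2:(height - 1), 2:(width - 1)] == 0L)
      for (w in wall_idx) {
        rr <- ((w - 1) %% (height - 2)) + 2L
        cc <- ((w - 1) %/% (height - 2)) + 2L
        open_lr <- cells[rr, cc - 1] == 1L && cells[rr, cc + 1] == 1L
        open_ud <- cells[rr - 1, cc] == 1L && cells[rr + 1, cc] == 1L
        if ((open_lr || open_ud) && runif(1) < extra_openings) {
          cells[rr, cc] <- 1L
        }
      }
    }
    # start on the left edge, goals on the right edge
    srow <- sample(nodes_r, 1)
    cells[srow, 1L] <- 1L
    for (rr in nodes_r) if (cells[rr, width - 1L] == 1L) cells[rr, width] <- 1L
    m <- tryCatch(maze_grid(cells, c(srow, 1L)), error = function(e) NULL)
    if (!is.null(m)) return(m)
  }
  stop("generate_maze: retry budget exhausted without a solvable maze")
}

#' Generate a vertical-barrier maze
#'
#' A maze of full-height wall barriers at regular column spacing, each
#' pierced by a small number of randomly placed doors, with open corridors
#' between.  Rightward progress requires threading the doors in sequence,
#' which defeats an undirected random walker within the step budget, while
#' a context-sensitive rightward policy passes each barrier quickly — the
#' regime in which delayed-risk policy learning is expressible.  (Depth-first
#' corridor mazes, by contrast, contain right-leading dead-end pockets that
#' make a rightward preference counterproductive.)
#'
#' @param height,width grid dimensions (odd, `>= 7`).
#' @param seed integer seed; generation is deterministic per seed.
#' @param spacing barrier-to-barrier column distance (default 2).
#' @param doors pathway cells per barrier (default 1).
#' @return a `maze_grid`.
#' @export
generate_barrier_maze <- function(height = 21, width = 41, seed = 1L,
                                  spacing = 2L, doors = 1L) {
  stopifnot(height >= 7, width >= 7, spacing >= 2, doors >= 1)
  set.seed(as.integer(seed))
  cells <- matrix(0L, height, width)
  cells[2:(height - 1), 2:width] <- 1L
  for (cc in seq(3L, width - 2L, by = spacing)) {
    cells[, cc] <- 0L
    cells[sample(2:(height - 1), doors), cc] <- 1L
  }
  srow <- sample(2:(height - 1), 1)
  cells[srow, 1L] <- 1L
  maze_grid(cells, c(srow, 1L))
}

#' Read and write mazes as plain text
#'
#' One row per line: `#` wall, `.` pathway, `S` the start cell.  The
#' reader/writer pair round-trips exactly.
#'
#' @param maze a `maze_grid`.
#' @param path file path.
#' @return `read_maze()`: a `maze_grid`; `write_maze()`: the path,
#'   invisibly.
#' @export
write_maze <- function(maze, path) {
  stopifnot(inherits(maze, "maze_grid"))
  ch <- matrix(ifelse(maze$cells == 1L, ".", "#"), maze$H, maze$W)
  ch[maze$start[1], maze$start[2]] <- "S"
  writeLines(apply(ch, 1, paste0, collapse = ""), path)
  invisible(path)
}

#' @rdname write_maze
#' @export
read_maze <- function(path) {
  lines <- readLines(path)
  ch <- do.call(rbind, strsplit(lines, ""))
  start <- which(ch == "S", arr.ind = TRUE)
  if (nrow(start) != 1) stop("read_maze: expected exactly one start cell 'S'")
  cells <- matrix(as.integer(ch != "#"), nrow(ch), ncol(ch))
  maze_grid(cells, as.integer(start[1, ]))
}

#' @export
print.maze_grid <- function(x, ...) {
  cat("<maze_grid> ", x$H, " x ", x$W, ", start (", x$start[1], ",",
      x$start[2], ")\n", sep = "")
  invisible(x)
}

#' Windowed observation of the maze
#'
#' The binary contents of the square window centred on the agent, row-major
#' (window rows read left to right, top to bottom), 1 = pathway, 0 = wall;
#' cells outside the grid read as wall.
#'
#' @param maze a `maze_grid`.
#' @param position length-2 `(row, col)`; must be a pathway cell.
#' @param window odd window side (default 11, i.e. a length-121 vector).
#' @return integer vector of length `window^2`.
#' @export
observe <- function(maze, position, window = 11L) {
  stopifnot(inherits(maze, "maze_grid"), window %% 2 == 1)
  r <- position[1]; c <- position[2]
  if (maze$cells[r, c] != 1L) stop("observe: position is on a wall")
  half <- window %/% 2
  out <- integer(window * window)
  idx <- 1L
  for (dr in -half:half) {
    for (dc in -half:half) {
      rr <- r + dr; cc <- c + dc
      out[idx] <- if (rr >= 1 && rr <= maze$H && cc >= 1 && cc <= maze$W) {
        maze$cells[rr, cc]
      } else 0L
      idx <- idx + 1L
    }
  }
  out
}

# Action codes: 0 up, 1 down, 2 left, 3 right (the printed order).
.ACTION_NAMES <- c("up", "down", "left", "right")

#' Decision coding: four-step action sequences
#'
#' Each decision is a base-4 positional code over the actions (up, down,
#' left, right), most significant digit first, giving `4^4 = 256` one-hot
#' options.  `encode_decision(decode_decision(i)) == i` for all indices.
#'
#' @param index integer in `[0, 255]`.
#' @param actions character vector of four action names.
#' @return `decode_decision()`: character vector of four actions;
#'   `encode_decision()`: the integer index.
#' @export
decode_decision <- function(index, n_steps = 4L) {
  stopifnot(index >= 0, index < 4^n_steps)
  digits <- integer(n_steps)
  code <- as.integer(index)
  for (i in n_steps:1) {
    digits[i] <- code %% 4L
    code <- code %/% 4L
  }
  .ACTION_NAMES[digits + 1L]
}

#' @rdname decode_decision
#' @param n_steps actions per decision (default 4).
#' @export
encode_decision <- function(actions, n_steps = length(actions)) {
  digits <- match(actions, .ACTION_NAMES) - 1L
  if (anyNA(digits)) stop("encode_decision: unknown action name")
  sum(digits * 4L^((n_steps - 1L):0))
}

#' Execute one action with wall rejection
#'
#' Moves one cell in the given direction if the target is a pathway cell
#' inside the grid; otherwise the position is unchanged (the rejected move
#' still consumes the step).
#'
#' @param maze a `maze_grid`.
#' @param position length-2 `(row, col)`.
#' @param action one of `"up"`, `"down"`, `"left"`, `"right"`.
#' @return the new position.
#' @export
maze_step <- function(maze, position, action) {
  d <- switch(action, up = c(-1L, 0L), down = c(1L, 0L),
              left = c(0L, -1L), right = c(0L, 1L),
              stop("maze_step: unknown action"))
  nr <- position[1] + d[1]; nc <- position[2] + d[2]
  if (nr >= 1 && nr <= maze$H && nc >= 1 && nc <= maze$W &&
      maze$cells[nr, nc] == 1L) c(nr, nc) else position
}

#' Risk parameters of the delayed evaluation
#'
#' Risk levels attached to the rightward displacement achieved over one
#' evaluation period: zero risk for moving right at least `d_star` cells,
#' 0.45 for moving right but less than `d_star`, 0.55 for not moving right.
#'
#' @param Gamma_success,Gamma_partial,Gamma_fail risk levels in `[0, 1]`.
#' @param d_star displacement threshold (cells per period).
#' @return list of class `risk_params`.
#' @export
risk_params <- function(Gamma_success = 0, Gamma_partial = 0.45,
                        Gamma_fail = 0.55, d_star = 2L) {
  stopifnot(Gamma_success >= 0, Gamma_success <= 1,
            Gamma_partial >= 0, Gamma_partial <= 1,
            Gamma_fail >= 0, Gamma_fail <= 1, d_star >= 1)
  structure(list(Gamma_success = Gamma_success, Gamma_partial = Gamma_partial,
                 Gamma_fail = Gamma_fail, d_star = as.integer(d_star)),
            class = "risk_params")
}

#' @rdname risk_params
#' @param Gamma scalar risk level in `[0, 1]`.
#' @return `sample_risk()`: list with the risk level `Gamma` and a binary
#'   draw `gamma` with `Prob[gamma = 1] = Gamma`.
#' @export
sample_risk <- function(Gamma) {
  stopifnot(Gamma >= 0, Gamma <= 1)
  list(Gamma = Gamma, gamma = as.integer(runif(1) < Gamma))
}

#' @rdname risk_params
#' @param x_displacement signed rightward displacement over the period.
#' @param params a `risk_params`.
#' @return `evaluate_risk()`: the scalar risk level.
#' @export
evaluate_risk <- function(x_displacement, params = risk_params()) {
  if (x_displacement >= params$d_star) {
    params$Gamma_success
  } else if (x_displacement > 0) {
    params$Gamma_partial
  } else {
    params$Gamma_fail
  }
}
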