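#' Run configuration
#'
#' Central configuration for reproducible runs: dimensions, priors, risk
#' parameters, learning rates (as prior masses), budgets, seeds and mode
#' flags.  Unknown keys are rejected; every run directory embeds the
#' configuration together with its hash.
#'
#' @param ... overrides of the default fields.
#' @return object of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    window = 11L, n_steps = 4L,
    maze_style = "barriers", barrier_spacing = 2L, doors_per_wall = 1L,
    maze_height = 21L, maze_width = 41L, extra_openings = 0.2,
    E_right = 1 / 256, lr_mass = 2 / 256, E_vertical = 1 / 256,
    Gamma_success = 0, Gamma_partial = 0.45, Gamma_fail = 0.55, d_star = 1L,
    lambda_W = 1e5, lambda_K = 1e5, lambda_V = 10,
    T = 20000L, n_sessions = 100L, n_mazes = 1L,
    seed = 1L, maze_seed = 1L,
    modulation = "delayed", expectation_mode = "log-ratio"
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(defaults))
  if (length(unknown) > 0) {
    stop("run_config: unknown key(s): ", paste(unknown, collapse = ", "))
  }
  defaults[names(ov)] <- ov
  structure(defaults, class = "run_config")
}

#' @rdname run_config
#' @param path YAML file with configuration keys.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' @rdname run_config
#' @param config a `run_config`.
#' @export
config_hash <- function(config) {
  string_hash(as.character(jsonlite::toJSON(unclass(config),
                                            auto_unbox = TRUE, digits = NA)))
}

#' @rdname run_config
#' @param dir output directory (created if needed).
#' @export
write_config <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- c(unclass(config), list(config_hash = config_hash(config)))
  jsonlite::write_json(out, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(config)
}

# Build the experiment pieces implied by a configuration.
config_agent <- function(config) {
  maze_agent(
    window = config$window, n_steps = config$n_steps,
    E_dirs = decision_prior(config$E_right, config$lr_mass,
                            config$E_vertical),
    lambda = list(W = config$lambda_W, K = config$lambda_K,
                  V = config$lambda_V),
    risk = risk_params(config$Gamma_success, config$Gamma_partial,
                       config$Gamma_fail, config$d_star),
    modulation = config$modulation)
}

config_mazes <- function(config) {
  lapply(seq_len(config$n_mazes), function(i) {
    if (identical(config$maze_style, "barriers")) {
      generate_barrier_maze(config$maze_height, config$maze_width,
                            seed = config$maze_seed + i - 1L,
                            spacing = config$barrier_spacing,
                            doors = config$doors_per_wall)
    } else {
      generate_maze(config$maze_height, config$maze_width,
                    seed = config$maze_seed + i - 1L,
                    extra_openings = config$extra_openings)
    }
  })
}

#' Serialise mappings, banks and weights as CSV archives
#'
#' A portable array archive: one CSV per component matrix (entry `[i, j]` of
#' file `c<out><in>.csv` is the submatrix element for output component
#' `<out>` and input component `<in>` of factor pair `(i, j)`), with a JSON
#' sidecar recording the kind, factor counts and the ones-then-zeros block
#' ordering convention.
#'
#' @param x a `factorized_mapping`, `dirichlet_array` or `synaptic_weights`.
#' @param dir archive directory (created).
#' @return `dir`, invisibly.
#' @export
write_mapping_archive <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(m, name) {
    utils::write.table(m, file.path(dir, paste0(name, ".csv")),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  if (inherits(x, "synaptic_weights")) {
    for (nm in c("W1", "W0", "K1", "K0", "V1", "V0")) wcsv(x[[nm]], nm)
    meta <- list(type = "synaptic_weights", n_x = x$n_x, n_o = x$n_o,
                 n_y = x$n_y, lambda = x$lambda,
                 block_ordering = "ones-then-zeros")
  } else {
    sub <- if (inherits(x, "factorized_mapping")) x$sub else unclass(x)
    d <- dim(sub)
    for (oc in 1:2) for (ic in 1:2) {
      wcsv(matrix(sub[oc, ic, , ], d[3], d[4]),
           sprintf("c%d%d", 2 - oc, 2 - ic))
    }
    meta <- list(
      type = if (inherits(x, "factorized_mapping")) "factorized_mapping"
             else "dirichlet_array",
      kind = if (inherits(x, "factorized_mapping")) x$kind else NULL,
      normalized = if (inherits(x, "factorized_mapping")) x$normalized
                   else NULL,
      n_out = d[3], n_in = d[4], block_ordering = "ones-then-zeros")
  }
  jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))],
                       file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_mapping_archive
#' @export
read_mapping_archive <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  rcsv <- function(name) {
    as.matrix(utils::read.table(file.path(dir, paste0(name, ".csv")),
                                sep = ",", header = FALSE))
  }
  if (identical(meta$type, "synaptic_weights")) {
    mats <- lapply(setNames(nm = c("W1", "W0", "K1", "K0", "V1", "V0")), rcsv)
    mats <- lapply(mats, unname)
    return(synaptic_weights(mats$W1, mats$W0, mats$K1, mats$K0,
                            mats$V1, mats$V0, lambda = as.list(meta$lambda)))
  }
  sub <- array(0, c(2, 2, meta$n_out, meta$n_in))
  for (oc in 1:2) for (ic in 1:2) {
    sub[oc, ic, , ] <- unname(rcsv(sprintf("c%d%d", 2 - oc, 2 - ic)))
  }
  if (identical(meta$type, "factorized_mapping")) {
    factorized_mapping(meta$kind, sub, normalized = isTRUE(meta$normalized))
  } else {
    dirichlet_array(sub)
  }
}

#' Deterministic fixture bundle for tests and examples
#'
#' Small enumerable POMDPs (one- and two-factor), a hand-built 5 x 5 maze
#' and canned activity logs from a miniature agent, all regenerated
#' deterministically from the seed.
#'
#' @param seed integer seed.
#' @return named list with `pomdp1`, `pomdp2`, `maze5`, `logs`.
#' @export
make_fixtures <- function(seed = 1L) {
  set.seed(as.integer(seed))
  pomdp1 <- list(A = fm_random("A", 1, 1), B = fm_random("B", 1, 1),
                 C = fm_random("C", 1, 1), D = random_prior(1),
                 E = random_prior(1))
  pomdp2 <- list(A = fm_random("A", 2, 2), B = fm_random("B", 2, 2),
                 C = fm_random("C", 2, 2), D = random_prior(2),
                 E = random_prior(2))
  rows <- c("#####",
            "S....",
            "#.#.#",
            "#...#",
            "#####")
  ch <- do.call(rbind, strsplit(rows, ""))
  maze5 <- maze_grid(matrix(as.integer(ch != "#"), 5, 5), c(2L, 1L))
  tiny <- maze_agent(window = 3L, n_steps = 2L,
                     E_dirs = c(right = 1, left = 1, up = 1, down = 1) / 16)
  logs <- collect_activity_logs(tiny, maze5, T = 200L, seed = seed)
  list(pomdp1 = pomdp1, pomdp2 = pomdp2, maze5 = maze5, logs = logs,
       tiny_agent = tiny)
}

#' Command-line entry point
#'
#' Thin dispatcher over the package functions, used by the
#' `inst/cli/actinet.R` script.  Subcommands: `generate-maze`, `train`,
#' `evaluate`, `estimate-priors`, `predict`, `verify`.  Options are given as
#' `--key value` pairs matching [run_config()] fields plus `--out`.
#'
#' @param args character vector of command-line arguments.
#' @return exit status (0 on success), invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    cat("usage: actinet <generate-maze|train|evaluate|estimate-priors|",
        "predict|verify> [--key value ...]\n", sep = "")
    return(invisible(1L))
  }
  cmd <- args[1]
  opts <- list()
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    opts[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  out <- opts$out %||% "actinet-run"
  opts$out <- NULL
  num_keys <- setdiff(names(opts), c("modulation", "expectation_mode",
                                     "config", "estimate"))
  opts[num_keys] <- lapply(opts[num_keys], function(v) {
    x <- suppressWarnings(as.numeric(v))
    if (is.na(x)) v else if (x == round(x)) as.integer(x) else x
  })
  status <- tryCatch({
    unknown <- setdiff(names(opts), c(names(run_config()), "config",
                                      "estimate"))
    if (length(unknown) > 0) {
      stop("unknown option(s): ", paste(unknown, collapse = ", "))
    }
    cfg <- if (!is.null(opts$config)) {
      read_config(opts$config)
    } else {
      cfg_keys <- intersect(names(opts), names(run_config()))
      do.call(run_config, opts[cfg_keys])
    }
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    write_config(cfg, out)
    switch(cmd,
      "generate-maze" = {
        write_maze(config_mazes(cfg)[[1]], file.path(out, "maze.txt"))
      },
      "train" = {
        curve <- train(config_agent(cfg), config_mazes(cfg),
                       n_sessions = cfg$n_sessions, T = cfg$T,
                       seed = cfg$seed)
        training_curve_to_tsv(curve, file.path(out, "curve.tsv"))
        write_mapping_archive(curve$agent$weights,
                              file.path(out, "weights"))
      },
      "evaluate" = {
        log_ <- run_action_phase(config_agent(cfg), config_mazes(cfg)[[1]],
                                 T = cfg$T, seed = cfg$seed)
        session_log_to_tsv(log_, file.path(out, "session.tsv"))
      },
      "estimate-priors" = {
        logs <- collect_activity_logs(config_agent(cfg), config_mazes(cfg),
                                      T = cfg$T, seed = cfg$seed)
        prior_estimate_to_json(estimate_thresholds(logs),
                               file.path(out, "priors.json"))
      },
      "predict" = {
        if (is.null(opts$estimate)) stop("predict: --estimate <json> needed")
        est <- jsonlite::read_json(opts$estimate, simplifyVector = TRUE)
        curve <- reconstruct_and_predict(
          as.numeric(est$E_hat), config_mazes(cfg),
          n_sessions = cfg$n_sessions, T = cfg$T, seed = cfg$seed,
          window = cfg$window, n_steps = cfg$n_steps)
        training_curve_to_tsv(curve, file.path(out, "predicted_curve.tsv"))
      },
      "verify" = {
        verify_equivalence(seed = cfg$seed,
                           mode = cfg$expectation_mode,
                           json_path = file.path(out, "equivalence.json"))
      },
      stop("unknown subcommand: ", cmd))
    0L
  }, error = function(e) {
    message("actinet: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
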