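#' Experiment configuration
#'
#' A validated, fully serializable description of a simulation experiment:
#' which simulator to run (`reduced`, `full` or `plastic`), its network
#' and protocol settings, integrator settings, seed and label. Configs
#' round-trip losslessly through YAML or JSON.
#'
#' @param simulator One of `"reduced"`, `"full"`, `"plastic"`.
#' @param label Experiment label (used in output file names).
#' @param duration Simulated time (seconds).
#' @param dt Integrator step (seconds); `NULL` for the simulator default.
#' @param record_dt Trajectory sampling interval (seconds).
#' @param seed Integer seed for all stochastic inputs.
#' @param velocity List describing the velocity profile (fields of
#'   [make_velocity_profile()]; `kind`, `mean_v`, optional `pauses`, ...).
#' @param visual List with `k_star` and optional `landmark_off_intervals`.
#' @param network Named list of overrides for [network_params()] /
#'   [plastic_params()].
#' @param reduced For the reduced simulator: list with `k0`, `beta_amp`,
#'   optional `rule` (list: `type` = "linear", "velocity_biased", "cubic"
#'   or "sign_flipped", plus `mu`, `eta`).
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(simulator = c("reduced", "full", "plastic"),
                              label = "experiment",
                              duration = 60, dt = NULL, record_dt = 0.1,
                              seed = 1L,
                              velocity = list(kind = "constant", mean_v = 1),
                              visual = list(k_star = 1),
                              network = list(),
                              reduced = list(k0 = 1, beta_amp = 0.66)) {
  simulator <- match.arg(simulator)
  if (!is.null(velocity$pauses)) {
    # normalize to a list of (start, end) pairs, whatever the source
    # format (R list, YAML sequence, JSON matrix)
    pz <- velocity$pauses
    if (is.matrix(pz) || is.data.frame(pz)) {
      pz <- lapply(seq_len(nrow(pz)), function(i) as.numeric(pz[i, ]))
    } else {
      pz <- lapply(pz, as.numeric)
    }
    velocity$pauses <- pz
  }
  cfg <- list(simulator = simulator, label = label, duration = duration,
              dt = dt, record_dt = record_dt, seed = as.integer(seed),
              velocity = velocity, visual = visual, network = network,
              reduced = reduced)
  validate_config(cfg)
  structure(cfg, class = "experiment_config")
}

validate_config <- function(cfg) {
  fail <- function(path, msg) stop(sprintf("config$%s: %s", path, msg))
  if (!cfg$simulator %in% c("reduced", "full", "plastic"))
    fail("simulator", "must be 'reduced', 'full' or 'plastic'")
  if (!is.numeric(cfg$duration) || cfg$duration <= 0)
    fail("duration", "must be a positive number")
  if (!is.null(cfg$dt) && (!is.numeric(cfg$dt) || cfg$dt <= 0))
    fail("dt", "must be a positive number")
  if (!is.list(cfg$velocity) || is.null(cfg$velocity$kind))
    fail("velocity.kind", "is required")
  if (!cfg$velocity$kind %in% c("constant", "pause_resume", "smoothed_random"))
    fail("velocity.kind", "unknown kind")
  if (!is.list(cfg$visual) || is.null(cfg$visual$k_star))
    fail("visual.k_star", "is required")
  if (cfg$simulator == "reduced") {
    if (is.null(cfg$reduced$k0)) fail("reduced.k0", "is required")
    if (is.null(cfg$reduced$beta_amp) || cfg$reduced$beta_amp <= 0)
      fail("reduced.beta_amp", "must be > 0")
    if (!is.null(cfg$reduced$rule) &&
        !cfg$reduced$rule$type %in%
          c("linear", "velocity_biased", "cubic", "sign_flipped"))
      fail("reduced.rule.type", "unknown rule type")
  }
  invisible(TRUE)
}

#' Read / write experiment configurations
#'
#' YAML (`.yml`, `.yaml`) or JSON (`.json`), chosen by file extension.
#'
#' @param path File path.
#' @return `read_experiment_config` returns an `experiment_config`;
#'   `write_experiment_config` returns `path` invisibly.
#' @export
read_experiment_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yml", "yaml")) yaml::read_yaml(path)
  else if (ext == "json") jsonlite::fromJSON(path, simplifyVector = TRUE)
  else stop("read_experiment_config: unknown extension: ", ext)
  do.call(experiment_config, cfg)
}

#' @rdname read_experiment_config
#' @param config An `experiment_config`.
#' @export
write_experiment_config <- function(config, path) {
  ext <- tolower(tools::file_ext(path))
  x <- unclass(config)
  if (ext %in% c("yml", "yaml")) yaml::write_yaml(x, path)
  else if (ext == "json")
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  else stop("write_experiment_config: unknown extension: ", ext)
  invisible(path)
}

# Build the velocity profile described in a config.
config_velocity <- function(cfg) {
  v <- cfg$velocity
  args <- list(kind = v$kind, duration = cfg$duration,
               mean_v = if (is.null(v$mean_v)) 1 else v$mean_v,
               seed = cfg$seed)
  if (!is.null(v$pauses)) args$pauses <- v$pauses
  if (!is.null(v$dt)) args$dt <- v$dt
  do.call(make_velocity_profile, args)
}

config_visual <- function(cfg) {
  off <- cfg$visual$landmark_off_intervals
  make_visual_protocol(k_star = cfg$visual$k_star,
                       landmark_off_intervals =
                         if (is.null(off)) list() else off)
}

config_rule <- function(r) {
  if (is.null(r)) return(NULL)
  switch(r$type,
         linear = gain_rule_linear(r$mu),
         velocity_biased = gain_rule_velocity_biased(r$mu, r$eta),
         cubic = gain_rule_cubic(r$mu),
         sign_flipped = gain_rule_sign_flipped(r$mu))
}

#' Run a configured experiment
#'
#' Dispatches an [experiment_config] to the reduced, full or plastic
#' simulator; optionally writes the trajectory (CSV), a JSON summary and
#' the config used. All randomness flows through `config$seed`.
#'
#' @param config An `experiment_config` (or a path to one on disk).
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return List with `trajectory`, `summary` (see
#'   [summarize_trajectory()]), and `files` (paths written, if any).
#' @export
run_experiment <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_experiment_config(config)
  stopifnot(inherits(config, "experiment_config"))
  vp <- config_velocity(config)
  proto <- config_visual(config)
  t_start <- Sys.time()
  if (config$simulator == "reduced") {
    dt <- if (is.null(config$dt)) 0.01 else config$dt
    traj <- simulate_reduced(
      reduced_state(k0 = config$reduced$k0),
      vp, proto, beta_sinusoidal(config$reduced$beta_amp),
      rule = config_rule(config$reduced$rule),
      duration = config$duration, dt = dt,
      record_dt = config$record_dt)
  } else if (config$simulator == "full") {
    params <- do.call(network_params, config$network)
    dt <- if (is.null(config$dt)) params$tau_c / 20 else config$dt
    traj <- simulate_network(params, vp, proto,
                             duration = config$duration, dt = dt,
                             record_dt = config$record_dt)
  } else {
    params <- do.call(plastic_params, config$network)
    dt <- if (is.null(config$dt)) params$tau_c / 10 else config$dt
    rr <- run_recalibration_protocol(params,
                                     k_star = config$visual$k_star,
                                     duration = config$duration,
                                     velocity = vp, dt = dt,
                                     record_dt = config$record_dt)
    traj <- rr$trajectory
    attr(traj, "gains") <- rr$gains
  }
  summ <- summarize_trajectory(traj)
  summ$label <- config$label
  summ$seed <- config$seed
  summ$elapsed_s <- as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    base <- file.path(out_dir, config$label)
    write_trajectory(traj, paste0(base, "_trajectory.csv"))
    jsonlite::write_json(summ, paste0(base, "_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_experiment_config(config, paste0(base, "_config.json"))
    files <- paste0(base, c("_trajectory.csv", "_summary.json",
                            "_config.json"))
  }
  list(trajectory = traj, summary = summ, files = files)
}

#' Summary statistics of a trajectory
#'
#' Steady-state (trailing-window) errors and gains: the circular mean of
#' the positional error and the mean gain over the last 10 percent of the
#' trajectory, final values, and extremes.
#'
#' @param traj A trajectory data frame (must contain `t`; uses
#'   `theta_tilde`, `k0` or `k_star` columns when present).
#' @param tail_frac Trailing fraction used for steady-state estimates.
#' @return A named list of summary statistics.
#' @export
summarize_trajectory <- function(traj, tail_frac = 0.1) {
  if (nrow(traj) == 0) stop("summarize_trajectory: empty trajectory")
  tail_idx <- traj$t >= (1 - tail_frac) * max(traj$t)
  out <- list(duration = max(traj$t), n_records = nrow(traj))
  if (!is.null(traj$theta_tilde)) {
    out$theta_tilde_final <- traj$theta_tilde[nrow(traj)]
    out$theta_tilde_steady <- circular_mean(traj$theta_tilde[tail_idx])
    out$abs_theta_tilde_max <- max(abs(traj$theta_tilde))
  }
  if (!is.null(traj$k0)) {
    out$k0_final <- traj$k0[nrow(traj)]
    out$k0_steady <- mean(traj$k0[tail_idx])
    if (!is.null(traj$k_star)) {
      out$k_tilde_final <- traj$k_star[nrow(traj)] - out$k0_final
      out$abs_k_tilde_final <- abs(out$k_tilde_final)
    }
  }
  gains <- attr(traj, "gains")
  if (!is.null(gains)) {
    out$gain_initial <- gains$gain[1L]
    out$gain_final <- gains$gain[nrow(gains)]
  }
  out
}

#' Read and write trajectories as CSV
#'
#' Plain one-row-per-sample CSV with a header; columns are the trajectory
#' fields (times in seconds, angles in radians, rates in Hz). Written
#' files are deterministic for identical inputs.
#'
#' @param traj A trajectory data frame.
#' @param path File path.
#' @return `write_trajectory` returns `path` invisibly;
#'   `read_trajectory` returns the trajectory data frame.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  out <- utils::read.csv(path)
  class(out) <- c("trajectory", "data.frame")
  out
}

#' Write full rate snapshots as long-format CSV
#'
#' Hierarchical rate arrays are stored as plain text: one row per
#' (time, population, neuron) with the firing rate, so snapshots can be
#' reassembled with a single reshape.
#'
#' @param times Vector of snapshot times (seconds).
#' @param rates Named list of rate matrices (one row per snapshot time,
#'   one column per neuron), e.g. `list(central = ..., cw = ...)`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_rate_snapshots <- function(times, rates, path) {
  stopifnot(is.list(rates), length(names(rates)) == length(rates))
  rows <- lapply(names(rates), function(pop) {
    m <- rates[[pop]]
    stopifnot(nrow(m) == length(times))
    data.frame(t = rep(times, each = ncol(m)),
               population = pop,
               neuron = rep(seq_len(ncol(m)), times = length(times)),
               rate = as.vector(t(m)))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
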