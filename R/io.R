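#' Declarative run configuration
#'
#' A flat key-value document covering the whole simulation and experiment
#' surface, with defaults equal to the model's standard constants. Unknown
#' keys are rejected. The effective configuration is echoed into every
#' output directory so a run can be reproduced from its outputs alone.
#'
#' @param ... Overrides of the defaults; see `run_config_defaults()` for
#'   the full key set.
#' @return A `run_config` list.
#' @examples
#' cfg <- run_config(condition = "flocking", sessions = 2, seed = 11)
#' @export
run_config <- function(...) {
  cfg <- run_config_defaults()
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @export
run_config_defaults <- function() {
  list(
    condition = "loose_coupling",
    sessions = 60L,
    ticks = 13500L,
    seed = 1L,
    L = 200,
    n_agents = 10L,
    d_v = 22.5,
    s = 15,
    rep_exp = 4,
    att_exp = 3,
    cutoff_factor = 1.5,
    speed = 1,
    target_units = 500,
    consumption_rate = 1,
    controller = "none",
    controller_slot = 1L,
    transient_exclusion = 14L
  )
}

#' Read / write a YAML run configuration
#'
#' `read_run_config()` parses a YAML file into a validated [run_config()]
#' (unknown keys are rejected); `write_run_config()` echoes a configuration
#' back to YAML. The two round-trip: a written configuration parses to an
#' identical object.
#'
#' @param path File path.
#' @param cfg A `run_config`.
#' @return `read_run_config()`: a `run_config`; `write_run_config()`: the
#'   path, invisibly.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  do.call(run_config, raw)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Build sim_params / experiment_plan from a configuration
#'
#' @param cfg A [run_config()].
#' @return `config_to_params()`: a [sim_params()]; `config_to_plan()`: an
#'   [experiment_plan()] for `cfg$sessions` sessions of `cfg$condition`.
#' @export
config_to_params <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  sim_params(
    condition = cfg$condition, L = cfg$L, n_agents = cfg$n_agents,
    session_ticks = cfg$ticks, target_units = cfg$target_units,
    consumption_rate = cfg$consumption_rate,
    rule = rule_params(d_v = cfg$d_v, s = cfg$s, rep_exp = cfg$rep_exp,
                       att_exp = cfg$att_exp,
                       cutoff_factor = cfg$cutoff_factor,
                       speed = cfg$speed),
    controller_slot = if (identical(cfg$controller, "none")) NA else
      cfg$controller_slot,
    seed = cfg$seed)
}

#' @rdname config_to_params
#' @export
config_to_plan <- function(cfg) {
  experiment_plan(conditions = cfg$condition,
                  sessions_per_condition = cfg$sessions,
                  base_seed = cfg$seed,
                  params = config_to_params(cfg),
                  controller = cfg$controller,
                  controller_slot = cfg$controller_slot)
}

#' Write the per-trial table of a session
#'
#' CSV with one row per trial: `trial_index, search_time,
#' consumption_time, trial_time, first_detector_id, complete`. Times are
#' in ticks.
#'
#' @param record A `forage_session`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_trial_table <- function(record, path) {
  tr <- record$trials
  out <- data.frame(trial_index = tr$trial,
                    search_time = tr$search_time,
                    consumption_time = tr$consumption_time,
                    trial_time = tr$trial_time,
                    first_detector_id = tr$first_detector,
                    complete = tr$complete)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write the per-tick trajectory log of a session
#'
#' CSV with one row per (tick, agent): `tick, agent_id, x, y, heading_deg,
#' flagged, consuming, trial_index`.
#'
#' @inheritParams write_trial_table
#' @export
write_trajectories <- function(record, path) {
  if (is.null(record$log)) {
    stop("session was run without `record = TRUE`", call. = FALSE)
  }
  lg <- record$log
  n <- record$params$n_agents
  T <- length(lg$tick)
  agent <- rep(seq_len(n), each = T)
  bit <- 2L^(rep(seq_len(n), each = T) - 1L)
  out <- data.frame(
    tick = rep(lg$tick, n),
    agent_id = agent,
    x = as.vector(lg$x),
    y = as.vector(lg$y),
    heading_deg = as.vector(lg$heading),
    flagged = (rep(lg$flagged, n) %/% bit) %% 2L == 1L,
    consuming = (rep(lg$consuming, n) %/% bit) %% 2L == 1L,
    trial_index = rep(lg$trial, n))
  out <- out[order(out$tick, out$agent_id), ]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Command-line entry point
#'
#' Thin CLI over [run_experiment()]: runs one movement condition for a
#' number of sessions and writes `summary.csv` (one row per session),
#' `aggregate.csv`, per-session `trials_<seed>.csv`, the effective
#' `config.yaml`, and optionally per-session trajectory logs. Flags
#' override values from `--config`.
#'
#' Invoke from a shell via the bundled wrapper:
#' \preformatted{Rscript $(Rscript -e 'cat(system.file("cli/forage-simulate.R",
#'   package = "swarmforage"))') --condition loose_coupling --sessions 1 \
#'   --seed 7 --out out/}
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status, invisibly: 0 on success, non-zero on usage errors.
#' @export
cli_simulate <- function(args = commandArgs(trailingOnly = TRUE)) {
  parser <- optparse::OptionParser(
    prog = "forage-simulate",
    description = "Run collective-foraging simulation sessions.",
    option_list = list(
      optparse::make_option("--condition", type = "character",
        default = NULL,
        help = "random | flocking | distancing | loose_coupling"),
      optparse::make_option("--sessions", type = "integer", default = NULL,
        help = "number of sessions [default from config: 60]"),
      optparse::make_option("--ticks", type = "integer", default = NULL,
        help = "ticks per session [default 13500]"),
      optparse::make_option("--seed", type = "integer", default = NULL,
        help = "base seed [default 1]"),
      optparse::make_option("--controller", type = "character",
        default = NULL, help = "none | ballistic | sweep [default none]"),
      optparse::make_option("--config", type = "character", default = NULL,
        help = "YAML configuration file (flags override it)"),
      optparse::make_option("--out", type = "character",
        default = "forage_out", help = "output directory [default %default]"),
      optparse::make_option("--log-trajectories", action = "store_true",
        default = FALSE, dest = "log_trajectories",
        help = "also write per-tick trajectory CSVs"),
      optparse::make_option("--no-metrics", action = "store_true",
        default = FALSE, dest = "no_metrics",
        help = "skip entropy / area-search-rate metrics (faster)")
    ))
  status <- tryCatch({
    opt <- optparse::parse_args(parser, args = args)
    cfg <- if (!is.null(opt$config)) read_run_config(opt$config) else
      run_config()
    for (key in c("condition", "sessions", "ticks", "seed", "controller")) {
      if (!is.null(opt[[key]])) cfg[[key]] <- opt[[key]]
    }
    cfg <- do.call(run_config, unclass(cfg))  # re-validate
    plan <- config_to_plan(cfg)
    dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)
    write_run_config(cfg, file.path(opt$out, "config.yaml"))

    metrics <- if (opt$no_metrics) "times" else
      c("times", "entropy", "area")
    controller <- if (identical(cfg$controller, "none")) NULL else
      builtin_policy(cfg$controller)
    need_log <- opt$log_trajectories || length(metrics) > 1
    rows <- vector("list", cfg$sessions)
    for (si in seq_len(cfg$sessions)) {
      p <- config_to_params(cfg)
      p$condition <- movement_condition(cfg$condition)
      p$seed <- session_seed(cfg$seed, 1L, si)
      rec <- run_session(p, controller = controller, record = need_log)
      write_trial_table(rec, file.path(opt$out,
                                       sprintf("trials_%d.csv", p$seed)))
      if (opt$log_trajectories) {
        write_trajectories(rec, file.path(
          opt$out, sprintf("trajectories_%d.csv", p$seed)))
      }
      row <- session_summary(rec, metrics = metrics,
                             transient = cfg$transient_exclusion)
      row$session <- si
      rows[[si]] <- row
      message(sprintf("[%s session %d/%d seed %d] %d targets",
                      cfg$condition, si, cfg$sessions, p$seed,
                      row$targets_found))
    }
    sessions <- do.call(rbind, rows)
    utils::write.csv(sessions, file.path(opt$out, "summary.csv"),
                     row.names = FALSE)
    utils::write.csv(condition_aggregate(sessions),
                     file.path(opt$out, "aggregate.csv"), row.names = FALSE)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
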