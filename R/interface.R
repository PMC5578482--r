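## Command-line entry points and run configuration: a thin shell over the
## package functions tying the stages into one reproducible pipeline.

#' Read and validate a run configuration
#'
#' YAML with keys: `parameters` (path to a parameter file, or `default`),
#' `mode` (`continuous-mutation` | `first-insult`), `span_years`,
#' `schedule` (list of `{start, end, level}` segments, optional),
#' `out_dir`, `seed` (optional), `rtol`, `atol` (optional scalars).
#' Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A validated list of class `mpn_run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  known <- c("parameters", "mode", "span_years", "schedule", "out_dir",
             "seed", "rtol", "atol")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- list(
    parameters = if (is.null(raw$parameters)) "default" else raw$parameters,
    mode = if (is.null(raw$mode)) "continuous-mutation" else raw$mode,
    span_years = if (is.null(raw$span_years)) 60 else raw$span_years,
    schedule = raw$schedule,
    out_dir = if (is.null(raw$out_dir)) "." else raw$out_dir,
    seed = raw$seed,
    rtol = if (is.null(raw$rtol)) .default_rtol else raw$rtol,
    atol = if (is.null(raw$atol)) .default_atol else raw$atol
  )
  if (!cfg$mode %in% c("continuous-mutation", "first-insult"))
    stop("mode must be continuous-mutation or first-insult")
  if (!is.numeric(cfg$span_years) || cfg$span_years <= 0)
    stop("span_years must be positive")
  class(cfg) <- "mpn_run_config"
  cfg
}

## internal: materialise config pieces
.cfg_params <- function(cfg) {
  if (identical(cfg$parameters, "default")) default_parameters()
  else read_parameters(cfg$parameters)
}
.cfg_schedule <- function(cfg, params) {
  if (is.null(cfg$schedule))
    return(stimulus_schedule(base_level = params$I_base))
  segs <- cfg$schedule
  stimulus_schedule(vapply(segs, `[[`, numeric(1), "start"),
                    vapply(segs, `[[`, numeric(1), "end"),
                    vapply(segs, `[[`, numeric(1), "level"),
                    base_level = params$I_base)
}

## internal: writers (full double precision in machine tables; 4 significant
## digits in human summaries; times in years)
.write_trajectory <- function(traj, path) {
  utils::write.csv(format(as.data.frame(traj), digits = 17, trim = TRUE,
                          scientific = NA),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
.write_summary <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Command-line interface
#'
#' Subcommands: `simulate` (trajectory table + crossing-time summary),
#' `steady` (steady states of all branches), `calibrate` (steady + timeline
#' calibration from a starting parameter file), `scenarios` (canonical
#' inflammatory-load suite), `validate-biomarkers` (linear maps + panel
#' report for a biomarker table), `synth` (synthetic trajectory and
#' biomarker table). Most take `--config <yaml>`; see the package vignette.
#' Designed to be called from the thin wrapper script in
#' `system.file("cli", "mpninflam", package = "mpninflam")`.
#'
#' @param args character vector of command-line arguments
#'   (e.g. `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit status, invisibly: 0 success, 1 runtime failure,
#'   2 usage error.
#' @export
mpn_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: mpninflam <subcommand> [--config cfg.yaml] [--table table.tsv]",
    "subcommands: simulate | steady | calibrate | scenarios |",
    "             validate-biomarkers | synth", sep = "\n")
  if (!length(args) || args[1] %in% c("-h", "--help")) {
    message(usage); return(invisible(2L))
  }
  sub <- args[1]
  opts <- .parse_cli_opts(args[-1])
  if (!sub %in% c("simulate", "steady", "calibrate", "scenarios",
                  "validate-biomarkers", "synth")) {
    message("unknown subcommand: ", sub, "\n", usage)
    return(invisible(2L))
  }
  status <- tryCatch({
    cfg <- if (!is.null(opts$config)) read_run_config(opts$config)
           else structure(list(parameters = "default",
                               mode = "continuous-mutation",
                               span_years = 60, schedule = NULL,
                               out_dir = ".", seed = NULL,
                               rtol = .default_rtol, atol = .default_atol),
                          class = "mpn_run_config")
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    params <- .cfg_params(cfg)
    ## resolved config is written beside the outputs for provenance
    .write_summary(c(unclass(cfg),
                     list(parameter_values = unclass(params)[.param_fields])),
                   file.path(cfg$out_dir, "resolved_config.json"))
    switch(sub,
      "simulate" = .cli_simulate(cfg, params),
      "steady" = .cli_steady(cfg, params),
      "calibrate" = .cli_calibrate(cfg, params),
      "scenarios" = .cli_scenarios(cfg, params),
      "validate-biomarkers" = .cli_validate(cfg, params, opts$table),
      "synth" = .cli_synth(cfg, params))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

.parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    if (args[i] %in% c("--config", "--table")) {
      if (i == length(args)) stop("missing value for ", args[i])
      opts[[sub("^--", "", args[i])]] <- args[i + 1L]
      i <- i + 2L
    } else stop("unknown option: ", args[i])
  }
  opts
}

.cli_simulate <- function(cfg, params) {
  sched <- .cfg_schedule(cfg, params)
  scen <- run_scenario(params, sched, mode = cfg$mode,
                       span_years = cfg$span_years)
  .write_trajectory(scen$trajectory, file.path(cfg$out_dir, "trajectory.csv"))
  .write_summary(list(mode = cfg$mode,
                      crossings_years = as.list(signif(scen$crossings, 4))),
                 file.path(cfg$out_dir, "simulate_summary.json"))
}

.cli_steady <- function(cfg, params) {
  branches <- c("healthy", "full-MPN", "trivial")
  out <- lapply(branches, function(b) {
    ss <- solve_steady_state(params, b)
    if (is.null(ss$state)) list(kind = ss$kind)
    else list(kind = ss$kind, stability = ss$stability,
              leading_eigenvalue = signif(ss$leading_eigenvalue, 4),
              state = as.list(signif(ss$state, 4)))
  })
  names(out) <- branches
  .write_summary(out, file.path(cfg$out_dir, "steady_states.json"))
}

.cli_calibrate <- function(cfg, params) {
  st <- calibrate_steady(params)
  tl <- suppressWarnings(calibrate_timeline(st))
  write_parameters(tl, file.path(cfg$out_dir, "calibrated_parameters.yaml"))
  .write_summary(list(achieved_years = signif(attr(tl, "achieved_years"), 4),
                      steady_residuals = signif(attr(st, "residuals"), 4)),
                 file.path(cfg$out_dir, "calibrate_summary.json"))
}

.cli_scenarios <- function(cfg, params) {
  suite <- scenario_suite(params, mode = cfg$mode,
                          span_years = cfg$span_years)
  utils::write.csv(suite$table, file.path(cfg$out_dir, "scenario_table.csv"),
                   row.names = FALSE)
  .write_summary(lapply(seq_len(nrow(suite$table)), function(i)
    as.list(suite$table[i, ])),
    file.path(cfg$out_dir, "scenarios_summary.json"))
}

.cli_validate <- function(cfg, params, table_path) {
  if (is.null(table_path))
    table_path <- system.file("extdata", "biomarker_medians_synthetic.tsv",
                              package = "mpninflam")
  tab <- read_biomarker_table(table_path)
  scen <- run_scenario(params, stimulus_schedule(base_level = params$I_base),
                       mode = cfg$mode, span_years = cfg$span_years)
  anchors <- anchor_levels(scen$trajectory)
  maps <- fit_linear_map(tab, anchors)
  val <- validate_panel(maps, tab)
  utils::write.csv(val$report, file.path(cfg$out_dir, "biomarker_report.csv"),
                   row.names = FALSE)
  .write_summary(list(flagged = val$flagged,
                      anchors = lapply(anchors[c("s", "DI")],
                                       function(v) as.list(signif(v, 4)))),
                 file.path(cfg$out_dir, "validate_summary.json"))
}

.cli_synth <- function(cfg, params) {
  seed <- if (is.null(cfg$seed)) 1L else cfg$seed
  spec <- synthetic_spec(params, sigma = 0.05, seed = seed, mode = cfg$mode)
  traj <- make_trajectory(spec)
  .write_trajectory(traj, file.path(cfg$out_dir, "synthetic_trajectory.csv"))
  anchors <- anchor_levels(attr(traj, "truth"))
  tab <- make_biomarker_table(spec, anchors)
  utils::write.table(as.data.frame(tab),
                     file.path(cfg$out_dir, "synthetic_biomarkers.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  .write_summary(list(seed = seed, sigma = spec$sigma),
                 file.path(cfg$out_dir, "synth_summary.json"))
}
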