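# Parameter/config file handling, artifact writers, pipeline subcommands.

#' Read a parameter file
#'
#' YAML with a `model:` section (flat dimensionless parameter mapping), or a
#' `dimensional:` section (converted through the characteristic-scale map),
#' and an optional `thresholds:` section (`th_T`, `th_S`).
#'
#' @param path Path to the YAML file.
#' @return List with `params` (`mirseize_params`) and `thresholds`
#'   (`mirseize_thresholds` or `NULL`).
#' @export
read_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  y <- yaml::read_yaml(path)
  params <- if (!is.null(y$model)) {
    do.call(model_parameters, lapply(y$model, as.numeric))
  } else if (!is.null(y$dimensional)) {
    nondimensionalize(do.call(dimensional_parameters,
                              lapply(y$dimensional, as.numeric)))
  } else stop("parameter file needs a 'model' or 'dimensional' section: ", path)
  thresholds <- if (!is.null(y$thresholds))
    phenotype_thresholds(th_T = y$thresholds$th_T, th_S = y$thresholds$th_S)
  list(params = params, thresholds = thresholds)
}

#' Write a parameter file
#'
#' @param params A `mirseize_params`.
#' @param path Output YAML path.
#' @param thresholds Optional `mirseize_thresholds` to store alongside.
#' @export
write_parameters <- function(params, path, thresholds = NULL) {
  stopifnot(inherits(params, "mirseize_params"))
  y <- list(model = lapply(unclass(params), as.numeric))
  if (!is.null(thresholds))
    y$thresholds <- list(th_T = thresholds$th_T, th_S = thresholds$th_S)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Path to the calibrated parameter fixture shipped with the package
#' @return File path.
#' @export
calibrated_parameter_file <- function()
  system.file("extdata", "params_calibrated.yaml", package = "mirseize",
              mustWork = TRUE)

#' Write a trajectory as CSV
#'
#' Columns `t,A1,A2,A3,R1,R2,R3,T,S,phenotype` (phenotype empty unless the
#' trajectory was classified).
#'
#' @param traj A `mirseize_trajectory`.
#' @param path Output CSV path.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.config_defaults <- function() {
  list(
    protocol = list(kind = "control", dose = 0, n_injections = 1,
                    window = c(-24, 0)),
    integrator = list(rtol = 1e-8, atol = 1e-10, grid_dt = 0.1),
    t_end = 24,
    seed = 1,
    outdir = "."
  )
}

.known_config_keys <- function()
  c("params_file", "thresholds", "protocol", "integrator", "t_end", "seed",
    "outdir", "scan", "sensitivity", "fit", "synth")

#' Load and validate a run configuration
#'
#' YAML keys: `params_file` (required; a parameter YAML), optional
#' `thresholds` (`th_T`, `th_S`; defaults to the values in the parameter
#' file), `protocol` (`kind`, `dose`, `n_injections`, `window`),
#' `integrator` (`rtol`, `atol`, `grid_dt`), `t_end`, `seed`, `outdir`, and
#' per-subcommand blocks `scan` (`kind`, `ladder`), `sensitivity` (`arm`,
#' `output`, `N`, `M`, `NR`), `synth` (`noise_sd`, `replicates`), `fit`
#' (`obs_file`). Unknown keys are rejected by name; numeric fields are
#' validated by the downstream constructors at load time.
#'
#' @param path Path to the YAML config.
#' @return A validated list of class `mirseize_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  unknown <- setdiff(names(y), .known_config_keys())
  if (length(unknown))
    stop("unknown config key(s) in ", path, ": ", paste(unknown, collapse = ", "))
  if (is.null(y$params_file)) stop("config key 'params_file' is required")
  pf <- y$params_file
  if (!file.exists(pf))
    pf <- file.path(dirname(path), y$params_file)
  if (!file.exists(pf)) stop("config 'params_file' not found: ", y$params_file)
  def <- .config_defaults()
  cfg <- utils::modifyList(def, y[setdiff(names(y), "params_file")])
  cfg$params_file <- normalizePath(pf)
  loaded <- read_parameters(cfg$params_file)
  cfg$params <- loaded$params
  cfg$thresholds <- if (!is.null(y$thresholds))
    phenotype_thresholds(th_T = y$thresholds$th_T, th_S = y$thresholds$th_S)
  else if (!is.null(loaded$thresholds)) loaded$thresholds
  else phenotype_thresholds()
  pr <- cfg$protocol
  cfg$protocol_obj <- tryCatch(
    dosing_protocol(pr$kind, dose = pr$dose,
                    n_injections = if (is.null(pr$n_injections)) 1 else pr$n_injections,
                    window = if (is.null(pr$window)) c(-24, 0) else unlist(pr$window)),
    error = function(e) stop("invalid config field 'protocol': ",
                             conditionMessage(e)))
  if (!is.numeric(cfg$seed) || cfg$seed != as.integer(cfg$seed))
    stop("config field 'seed' must be an integer")
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "mirseize_config"
  cfg
}

#' Dump a configuration back to YAML
#'
#' Inverse of [load_config()] up to default filling: `dump_config` followed
#' by `load_config` is idempotent.
#'
#' @param config A `mirseize_config`.
#' @param path Output path.
#' @export
dump_config <- function(config, path) {
  keep <- intersect(.known_config_keys(), names(config))
  y <- config[keep]
  yaml::write_yaml(y, path)
  invisible(path)
}

.write_manifest <- function(outdir, subcommand, config, elapsed, artifacts) {
  manifest <- list(
    subcommand = subcommand,
    package_version = as.character(utils::packageVersion("mirseize")),
    seed = config$seed,
    config_md5 = if (!is.null(config$params_file) && file.exists(config$params_file))
      unname(tools::md5sum(config$params_file)) else NA_character_,
    wall_time_s = round(elapsed, 3),
    artifacts = artifacts
  )
  jsonlite::write_json(manifest, file.path(outdir, paste0(subcommand, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Run one pipeline stage
#'
#' Executes a subcommand against a loaded configuration and writes its
#' artifacts (CSV/JSON/YAML) plus a manifest into `config$outdir`:
#' `simulate` (two trajectory CSVs, control and antagomir arms), `scan`
#' (dose-ladder CSV `dose,sustained,first_switch_time`), `phaseplane`
#' (nullcline point CSV), `sensitivity` (index CSV
#' `parameter,S1,S1_lo,S1_hi,ST,ST_lo,ST_hi`), `synth` (observation CSV),
#' `fit` (fit-report JSON), `calibrate` (calibrated parameter YAML).
#' Deterministic subcommands are byte-reproducible under a fixed config and
#' seed.
#'
#' @param name Subcommand name.
#' @param config A `mirseize_config` from [load_config()].
#' @return Invisibly, the character vector of artifact paths.
#' @export
run_subcommand <- function(name = c("simulate", "scan", "phaseplane",
                                    "sensitivity", "fit", "calibrate", "synth"),
                           config) {
  name <- match.arg(name)
  stopifnot(inherits(config, "mirseize_config"))
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  params <- config$params
  thr <- config$thresholds
  grid <- seq(config$protocol_obj$window_start, config$t_end,
              by = config$integrator$grid_dt)
  artifacts <- character(0)

  if (name == "simulate") {
    arms <- list(control = dosing_protocol("control"),
                 antagomir = config$protocol_obj)
    if (config$protocol_obj$kind == "control")
      arms$antagomir <- dosing_protocol("bolus", dose = 1.0)
    for (arm in names(arms)) {
      traj <- simulate_protocol(params, arms[[arm]], t_end = config$t_end,
                                grid = grid, rtol = config$integrator$rtol,
                                atol = config$integrator$atol)
      traj <- classify_trajectory(traj, thr, c(0, config$t_end))
      f <- file.path(outdir, paste0("trajectory_", arm, ".csv"))
      write_trajectory(traj, f)
      artifacts <- c(artifacts, f)
    }
  } else if (name == "scan") {
    sc <- config$scan
    kind <- if (is.null(sc$kind)) "bolus" else sc$kind
    ladder <- if (is.null(sc$ladder)) seq(0.1, 1.5, by = 0.1) else unlist(sc$ladder)
    rows <- lapply(ladder, function(d) {
      proto <- if (d == 0) dosing_protocol("control") else
        dosing_protocol(kind, dose = d)
      traj <- simulate_protocol(params, proto, t_end = config$t_end, grid = grid)
      cl <- classify_trajectory(traj, thr, c(0, config$t_end))
      data.frame(dose = d, sustained = cl$summary$sustained_anti_seizure,
                 first_switch_time = cl$summary$first_switch_time)
    })
    f <- file.path(outdir, paste0("scan_", kind, ".csv"))
    utils::write.csv(do.call(rbind, rows), f, row.names = FALSE, quote = FALSE)
    artifacts <- f
  } else if (name == "phaseplane") {
    for (arm in c("control", "antagomir")) {
      A_const <- if (arm == "control") c(0, 0, 0) else c(1, 1, 1)
      for (ri in c("R1", "R2", "R3")) for (vv in c("T", "S")) {
        nc <- nullclines_2d(params, pair = c(ri, vv), A_const = A_const)
        f <- file.path(outdir, sprintf("nullclines_%s_%s_%s.csv", arm, ri, vv))
        both <- rbind(cbind(curve = paste0(vv, "-nullcline"), nc$var2_nullcline),
                      cbind(curve = paste0(ri, "-nullcline"), nc$var1_nullcline))
        utils::write.csv(both, f, row.names = FALSE, quote = FALSE)
        artifacts <- c(artifacts, f)
      }
    }
  } else if (name == "sensitivity") {
    se <- config$sensitivity
    spec <- efast_spec(
      N = if (is.null(se$N)) 1000 else se$N,
      M = if (is.null(se$M)) 4 else se$M,
      NR = if (is.null(se$NR)) 5 else se$NR,
      seed = config$seed,
      outputs = if (is.null(se$output)) c("R1", "R2", "R3", "T", "S") else se$output,
      arm = if (is.null(se$arm)) "control" else se$arm
    )
    res <- run_efast(spec, params_base = params)
    for (sp in names(res)) {
      f <- file.path(outdir, sprintf("sensitivity_%s_%s.csv", spec$arm, sp))
      utils::write.csv(res[[sp]][, c("parameter", "S1", "S1_lo", "S1_hi",
                                     "ST", "ST_lo", "ST_hi")],
                       f, row.names = FALSE, quote = FALSE)
      artifacts <- c(artifacts, f)
    }
  } else if (name == "synth") {
    sy <- config$synth
    obs <- generate_observations(
      params,
      noise_sd = if (is.null(sy$noise_sd)) 0.1 else sy$noise_sd,
      n_replicates = if (is.null(sy$replicates)) 4 else sy$replicates,
      seed = config$seed)
    f <- file.path(outdir, "observations.csv")
    utils::write.csv(as.data.frame(obs), f, row.names = FALSE, quote = FALSE)
    artifacts <- f
  } else if (name == "fit") {
    ft <- config$fit
    if (is.null(ft$obs_file)) stop("config block 'fit' needs 'obs_file'")
    obs <- utils::read.csv(ft$obs_file)
    res <- fit_parameters(obs, base_params = params, seed = config$seed,
                          n_starts = if (is.null(ft$n_starts)) 8 else ft$n_starts)
    f <- file.path(outdir, "fit_report.json")
    jsonlite::write_json(
      list(estimates = as.list(res$estimates), rss = res$rss,
           converged = res$converged, free = res$free),
      f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    artifacts <- f
  } else if (name == "calibrate") {
    res <- calibrate(base = params, seed = config$seed)
    f <- file.path(outdir, "params_calibrated_out.yaml")
    write_parameters(res$params, f, thresholds = res$thresholds)
    artifacts <- f
  }

  .write_manifest(outdir, name, config, proc.time()[["elapsed"]] - t0, artifacts)
  invisible(artifacts)
}
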