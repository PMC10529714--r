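#' Default run configuration ("hamburgerryg" scenario)
#'
#' A plain list mirroring the packaged industrial scenario: an 85 mm x
#' 540 mm cylindrical loin at a uniform 280.65 K, direct thermophysical
#' properties (1064.5 kg/m^3, 3535.5 J/(kg K), 0.47 W/(m K)), the
#' seven-stage schedule of [default_schedule()], a 45 x 90 grid and the
#' default integrator control.
#'
#' @return A named list (a "run configuration").
#' @export
default_config <- function() {
  list(
    geometry = list(diameter_m = 0.085, length_m = 0.54),
    properties = list(direct = list(rho = 1064.5, cp = 3535.5, k = 0.47)),
    initial_temperature_K = 280.65,
    schedule = list(default = "hamburgerryg"),
    grid = list(nr = 45, nz = 90),
    control = list(dt_init_s = 1, dt_max_s = 30, n_startup = 2,
                   sample_dt_s = 60),
    seed = 1L)
}

.config_keys <- list(
  geometry = c("diameter_m", "length_m", "radius_m", "half_length_m"),
  properties = c("direct", "composition", "g"),
  schedule = c("default", "stages", "t_d", "t_smoke", "overrides"),
  grid = c("nr", "nz"),
  control = c("dt_init_s", "dt_max_s", "n_startup", "sample_dt_s"),
  top = c("geometry", "properties", "initial_temperature_K",
          "initial_temperature_C", "schedule", "grid", "control", "seed"))

# temperatures may be given in C with an explicit _C suffix; stored as K
.temp_key <- function(lst, base) {
  kK <- paste0(base, "_K"); kC <- paste0(base, "_C")
  if (!is.null(lst[[kC]])) lst[[kC]] + 273.15 else lst[[kK]]
}

#' Load and validate a run configuration
#'
#' Reads a JSON configuration, validates it against the schema (unknown
#' keys are rejected with their key path) and merges it over
#' [default_config()]. A file containing only `{"schedule": {"default":
#' "hamburgerryg"}}` (or an empty object) yields the packaged scenario.
#' Temperatures may be supplied in Kelvin (`*_K` keys) or Celsius (`*_C`).
#'
#' @param path Path to a JSON file.
#' @return A validated run configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(user) == 0) user <- list()
  bad <- setdiff(names(user), .config_keys$top)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (blk in c("geometry", "properties", "grid", "control")) {
    extra <- setdiff(names(user[[blk]]), .config_keys[[blk]])
    if (length(extra))
      stop(sprintf("unknown key(s) under '%s': %s", blk,
                   paste(extra, collapse = ", ")), call. = FALSE)
  }
  if (!is.null(user$initial_temperature_C)) {
    user$initial_temperature_K <- user$initial_temperature_C + 273.15
    user$initial_temperature_C <- NULL
  }
  cfg <- utils::modifyList(default_config(), user)
  build_inputs(cfg)  # full validation as a side effect
  cfg
}

#' Materialize model inputs from a run configuration
#'
#' @param cfg A run configuration list (see [default_config()]).
#' @return List with `geometry`, `props`, `schedule`, `T0`, `grid`,
#'   `control`, `seed`.
#' @export
build_inputs <- function(cfg) {
  g <- cfg$geometry
  geometry <- if (!is.null(g$radius_m))
    cyl_geometry(g$radius_m, g$half_length_m)
  else geometry_from_product(g$diameter_m, g$length_m)

  pr <- cfg$properties
  props <- if (!is.null(pr$direct)) {
    thermo_props(pr$direct$rho, pr$direct$cp, pr$direct$k)
  } else if (!is.null(pr$composition)) {
    comp <- do.call(composition, as.list(pr$composition))
    props_from_composition(comp, g = pr$g %||% 0.5)
  } else stop("properties: need either 'direct' or 'composition'",
              call. = FALSE)

  sc <- cfg$schedule
  schedule <- if (!is.null(sc$stages)) {
    st <- sc$stages
    if (is.data.frame(st)) st <- split(st, seq_len(nrow(st)))
    process_schedule(lapply(st, function(s) {
      Tp <- .temp_key(s, "T_process") %||% s$T_process_K
      process_stage(s$name, s$duration_s, Tp, s$h_W_m2K)
    }))
  } else if (identical(sc$default, "hamburgerryg")) {
    args <- list()
    if (!is.null(sc$t_d)) args$t_d <- sc$t_d
    if (!is.null(sc$t_smoke)) args$t_smoke <- sc$t_smoke
    if (!is.null(sc$overrides)) args <- c(args, sc$overrides)
    do.call(default_schedule, args)
  } else stop("schedule: need 'stages' or default: \"hamburgerryg\"",
              call. = FALSE)

  ct <- cfg$control %||% list()
  control <- solver_control(
    dt_init = ct$dt_init_s %||% 1, dt_max = ct$dt_max_s %||% 30,
    n_startup = ct$n_startup %||% 2, sample_dt = ct$sample_dt_s %||% 60)
  list(geometry = geometry, props = props, schedule = schedule,
       T0 = cfg$initial_temperature_K %||% 280.65,
       grid = solver_grid(cfg$grid$nr %||% 45, cfg$grid$nz %||% 90),
       control = control, seed = cfg$seed %||% 1L)
}

#' Run-to-run reproducibility manifest
#'
#' Writes `manifest.json` into `out_dir`, capturing the configuration (and
#' its MD5 hash), the seed and the package version.
#'
#' @param out_dir Output directory.
#' @param cfg Run configuration list.
#' @param seed Seed used for the run.
#' @param extra Optional named list appended to the manifest.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(out_dir, cfg, seed = cfg$seed %||% 1L,
                           extra = list()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(out_dir, "config_used.json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  man <- c(list(config_file = basename(cfg_path),
                config_md5 = unname(tools::md5sum(cfg_path)),
                seed = seed,
                package_version =
                  as.character(utils::packageVersion("loinheat"))),
           extra)
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(man, mp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(mp)
}

#' Validation report against a set of loggers
#'
#' Compares one simulation's centre-probe prediction against each logger
#' series: a per-probe table of R^2 and RMSE plus an `average` row (metrics
#' of the prediction against the mean of all measured series), the residual
#' series, and the simulation's Tavv/Tmin/Tmax summary. When `out_dir` is
#' given, writes `metrics.csv` (`probe_id,R2,RMSE_K`), `residuals.csv`
#' (`probe_id,time_s,residual_K`) and `summary.csv`.
#'
#' @param result A `"simulation_result"` with a centre probe at (0, 0).
#' @param loggers A named list of [logger_dataset()]s, or a bundle
#'   directory for [read_fixture_bundle()].
#' @param out_dir Optional output directory.
#' @return List with `metrics` (data.frame), `residuals` (data.frame) and
#'   `summary` (data.frame), invisibly when writing.
#' @export
report <- function(result, loggers, out_dir = NULL) {
  if (is.character(loggers)) loggers <- read_fixture_bundle(loggers)
  if (length(loggers) == 0) stop("no logger datasets given", call. = FALSE)
  pred <- probe(result, 0, 0)
  metrics <- NULL; residuals <- NULL
  meas_mat <- NULL
  for (ds in loggers) {
    if (length(ds$time_s) != nrow(pred) ||
        any(abs(ds$time_s - pred$time_s) > 1e-6))
      stop(sprintf("probe %s is not on the simulation's sample grid",
                   ds$probe_id), call. = FALSE)
    m <- compute_metrics(pred$temperature_K, ds$temperature_K)
    metrics <- rbind(metrics, data.frame(probe_id = ds$probe_id,
                                         R2 = m$R2, RMSE_K = m$RMSE))
    residuals <- rbind(residuals, data.frame(
      probe_id = ds$probe_id, time_s = ds$time_s,
      residual_K = m$residuals$residual_K))
    meas_mat <- cbind(meas_mat, ds$temperature_K)
  }
  mavg <- compute_metrics(pred$temperature_K, rowMeans(meas_mat))
  metrics <- rbind(metrics, data.frame(probe_id = "average",
                                       R2 = mavg$R2, RMSE_K = mavg$RMSE))
  summ <- summarize(result)
  out <- list(metrics = metrics, residuals = residuals, summary = summ)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(residuals, file.path(out_dir, "residuals.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(summ, file.path(out_dir, "summary.csv"),
                     row.names = FALSE, quote = FALSE)
    return(invisible(out))
  }
  out
}
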