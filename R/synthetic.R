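#' Default industrial probe layout
#'
#' Sixteen centre-of-product loggers T1-T16 spread over 4 pallets, each
#' pallet instrumented at four of the ten box layers (3, 5, 7 and 10,
#' counted from the bottom).
#'
#' @return data.frame with columns `probe`, `pallet`, `layer`.
#' @export
probe_layout <- function() {
  df <- data.frame(
    probe = c("T12", "T10", "T11", "T2",
              "T3",  "T5",  "T16", "T15",
              "T7",  "T6",  "T14", "T8",
              "T13", "T4",  "T1",  "T9"),
    pallet = rep(1:4, each = 4),
    layer = rep(c(10L, 7L, 5L, 3L), times = 4))
  validate_probe_layout(df)
  df
}

validate_probe_layout <- function(layout) {
  if (!all(c("probe", "pallet", "layer") %in% names(layout)))
    stop("layout needs columns probe, pallet, layer", call. = FALSE)
  if (anyDuplicated(layout$probe))
    stop("duplicate probe ids in layout", call. = FALSE)
  tab <- table(layout$pallet)
  if (nrow(layout) == 16 &&
      (length(tab) != 4 || any(tab != 4) ||
       !all(vapply(split(layout$layer, layout$pallet),
                   function(l) setequal(l, c(3, 5, 7, 10)), logical(1)))))
    stop("16-probe layout must place 4 probes per pallet covering layers ",
         "3, 5, 7, 10", call. = FALSE)
  invisible(layout)
}

#' Positional perturbation and noise model for synthetic loggers
#'
#' Emulates the positional structure seen in the industrial data:
#' the cooling water warms as it flows down the pallet, so the water-stage
#' process temperature is offset by `+delta_Tw_K` at layer 3 (bottom) and
#' `-delta_Tw_K` at layer 10 (top), linearly interpolated in layer index in
#' between; each pallet sees a uniform effective-temperature offset during
#' the drying-smoking stages (airflow differences between pallet
#' positions); and the logger adds iid Gaussian measurement noise.
#'
#' @param delta_Tw_K Half-range of the water-temperature variation (K);
#'   default 5 K (the 25 +/- 5 degrees C scenario).
#' @param pallet_offsets_K Drying/smoking process-temperature offset per
#'   pallet (K), length 4. Default `c(2, -2, 1, -1)`: pallets run
#'   alternately above and below the nominal chamber temperature.
#' @param sigma_K Standard deviation of the measurement noise (K);
#'   default 0.5 K, a SmartButton-class logger resolution.
#' @param seed Integer seed; all randomness in the generator derives
#'   from it.
#' @export
perturbation_model <- function(delta_Tw_K = 5,
                               pallet_offsets_K = c(2, -2, 1, -1),
                               sigma_K = 0.5, seed = 1L) {
  stopifnot(is.finite(delta_Tw_K), sigma_K >= 0,
            length(pallet_offsets_K) >= 1)
  if (abs(delta_Tw_K) > 5 + 1e-9)
    warning("delta_Tw_K outside the +/-5 K default range")
  structure(list(delta_Tw_K = delta_Tw_K,
                 pallet_offsets_K = pallet_offsets_K,
                 sigma_K = sigma_K, seed = as.integer(seed)),
            class = "perturbation_model")
}

# layer 3 (bottom) -> +delta, layer 10 (top) -> -delta, linear in between
layer_Tw_offset <- function(layer, delta) delta * (1 - 2 * (layer - 3) / 7)

#' Generate synthetic logger datasets
#'
#' Runs the forward model once per distinct (layer, pallet) condition with
#' the layer's water-temperature offset and the pallet's drying/smoking
#' offset applied to the schedule, samples the probe position at the output
#' cadence, and adds Gaussian measurement noise. Ground truth (true
#' coefficients and offsets) is attached to each dataset's `meta` so
#' recovery studies can close the loop.
#'
#' @param layout Probe layout data.frame, see [probe_layout()].
#' @param base_config Run configuration, see [default_config()].
#' @param perturbation A [perturbation_model()].
#' @return Named list of [logger_dataset()]s (one per probe).
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$grid <- list(nr = 9, nz = 12)  # desk-scale demo
#' lg <- generate_loggers(probe_layout()[1:2, ], cfg,
#'                        perturbation_model(sigma_K = 0.2, seed = 7))
generate_loggers <- function(layout = probe_layout(),
                             base_config = default_config(),
                             perturbation = perturbation_model()) {
  validate_probe_layout(layout)
  inp <- build_inputs(base_config)
  sch <- inp$schedule
  pert <- perturbation
  conds <- unique(layout[, c("pallet", "layer")])
  sims <- list()
  for (i in seq_len(nrow(conds))) {
    pal <- conds$pallet[i]; lay <- conds$layer[i]
    s2 <- sch
    dTw <- layer_Tw_offset(lay, pert$delta_Tw_K)
    if ("water_cooling" %in% s2$stages$name)
      s2 <- set_stage_Tp(s2, "water_cooling",
                         s2$stages$T_process_K[
                           match("water_cooling", s2$stages$name)] + dTw)
    dPal <- pert$pallet_offsets_K[(pal - 1) %%
                                    length(pert$pallet_offsets_K) + 1]
    for (nm in intersect(c("drying", "smoking"), s2$stages$name))
      s2 <- set_stage_Tp(s2, nm,
                         s2$stages$T_process_K[match(nm, s2$stages$name)] +
                           dPal)
    res <- simulate(inp$geometry, inp$props, s2, T0 = inp$T0,
                    grid = inp$grid, control = inp$control,
                    probe_points = cbind(r = 0, z = 0))
    sims[[paste(pal, lay)]] <- list(t = res$times, T = res$probes[, 1],
                                    dTw = dTw, dPal = dPal)
  }
  set.seed(pert$seed)
  out <- list()
  for (i in seq_len(nrow(layout))) {
    pal <- layout$pallet[i]; lay <- layout$layer[i]
    s <- sims[[paste(pal, lay)]]
    noisy <- s$T + stats::rnorm(length(s$T), 0, pert$sigma_K)
    truth <- list(
      h_w = if ("water_cooling" %in% sch$stages$name)
        sch$stages$h_W_m2K[match("water_cooling", sch$stages$name)]
      else NA,
      h_air = if ("air_cooling" %in% sch$stages$name)
        sch$stages$h_W_m2K[match("air_cooling", sch$stages$name)]
      else NA,
      Tw_offset_K = s$dTw, pallet_offset_K = s$dPal,
      sigma_K = pert$sigma_K, seed = pert$seed)
    out[[layout$probe[i]]] <- logger_dataset(
      probe_id = layout$probe[i], time_s = s$t, temperature_K = noisy,
      pallet = pal, layer = lay, meta = truth)
  }
  out
}

#' Write / read a synthetic logger bundle
#'
#' Writes one CSV per probe (dialect of [read_logger()]), a `metadata.csv`
#' with labels and ground truth, and `config.json` with the generating
#' configuration and perturbation model. Reading the bundle back
#' round-trips every timestamp and value.
#'
#' @param datasets Named list from [generate_loggers()].
#' @param out_dir Output directory (created if needed).
#' @param base_config,perturbation The generating configuration and
#'   perturbation model, stored for provenance.
#' @return Character vector of the files written (the manifest).
#' @export
write_fixture_bundle <- function(datasets, out_dir,
                                 base_config = NULL, perturbation = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  meta <- NULL
  for (ds in datasets) {
    csv <- file.path(out_dir, paste0(ds$probe_id, ".csv"))
    .write_series_csv(ds$time_s, ds$temperature_K, csv)
    files <- c(files, csv)
    meta <- rbind(meta, data.frame(
      probe = ds$probe_id, pallet = ds$pallet, layer = ds$layer,
      position_r = ds$position[["r"]], position_z = ds$position[["z"]],
      h_w = ds$meta$h_w %||% NA, h_air = ds$meta$h_air %||% NA,
      Tw_offset_K = ds$meta$Tw_offset_K %||% NA,
      pallet_offset_K = ds$meta$pallet_offset_K %||% NA,
      sigma_K = ds$meta$sigma_K %||% NA, seed = ds$meta$seed %||% NA))
  }
  mf <- file.path(out_dir, "metadata.csv")
  utils::write.csv(meta, mf, row.names = FALSE, quote = FALSE)
  cf <- file.path(out_dir, "config.json")
  jsonlite::write_json(list(config = base_config,
                            perturbation = unclass(perturbation)),
                       cf, auto_unbox = TRUE, digits = NA, null = "null")
  c(files, mf, cf)
}

#' @rdname write_fixture_bundle
#' @param dir Bundle directory.
#' @return (read_fixture_bundle) named list of [logger_dataset()]s.
#' @export
read_fixture_bundle <- function(dir) {
  meta <- utils::read.csv(file.path(dir, "metadata.csv"))
  out <- list()
  for (i in seq_len(nrow(meta))) {
    df <- utils::read.csv(file.path(dir, paste0(meta$probe[i], ".csv")))
    out[[meta$probe[i]]] <- logger_dataset(
      probe_id = meta$probe[i], time_s = df$time_s,
      temperature_K = df$temperature_K,
      pallet = meta$pallet[i], layer = meta$layer[i],
      position = c(meta$position_r[i], meta$position_z[i]),
      meta = list(h_w = meta$h_w[i], h_air = meta$h_air[i],
                  Tw_offset_K = meta$Tw_offset_K[i],
                  pallet_offset_K = meta$pallet_offset_K[i],
                  sigma_K = meta$sigma_K[i], seed = meta$seed[i]))
  }
  out
}
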