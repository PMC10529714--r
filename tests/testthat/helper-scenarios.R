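# Shared desk-scale fixtures. All synthetic inputs are generated in code.

default_geom <- function() cyl_geometry(0.0425, 0.27)
default_props <- function() thermo_props(1064.5, 3535.5, 0.47)

# small grid + long steps: fast, still physically sensible
tiny_cfg <- function() {
  cfg <- default_config()
  cfg$grid <- list(nr = 9, nz = 12)
  cfg$control <- list(dt_init_s = 1, dt_max_s = 240, n_startup = 2,
                      sample_dt_s = 60)
  cfg
}

# calibration-scale config: coarse enough for repeated forward solves,
# fine enough that the cooling-stage dynamics are resolved
cal_cfg <- function() {
  cfg <- default_config()
  cfg$grid <- list(nr = 13, nz = 20)
  cfg$control <- list(dt_init_s = 1, dt_max_s = 240, n_startup = 2,
                      sample_dt_s = 60)
  cfg
}

one_stage_schedule <- function(duration = 1800, Tp = 351.15, h = 2000,
                               name = "heat") {
  process_schedule(list(process_stage(name, duration, Tp, h)))
}

t11_layout <- function() {
  lay <- probe_layout()
  lay[lay$probe == "T11", ]
}

# noise-free, offset-free generator settings (pure forward model + sampling)
quiet_perturbation <- function(seed = 1L)
  perturbation_model(delta_Tw_K = 0, pallet_offsets_K = 0, sigma_K = 0,
                     seed = seed)
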