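test_that("default probe layout matches the industrial experiment", {
  lay <- probe_layout()
  expect_equal(nrow(lay), 16)
  expect_equal(sort(unique(lay$pallet)), 1:4)
  expect_true(all(table(lay$pallet) == 4))
  for (p in 1:4)
    expect_setequal(lay$layer[lay$pallet == p], c(3, 5, 7, 10))
  # calibration probe: T11 on pallet 1, layer 5
  expect_equal(lay[lay$probe == "T11", c("pallet", "layer")],
               data.frame(pallet = 1L, layer = 5L, row.names = 3L))
  bad <- lay; bad$layer[1] <- 4L
  expect_error(generate_loggers(bad, tiny_cfg()), "layers")
})

test_that("layer offsets interpolate linearly between bottom (+d) and top (-d)", {
  expect_equal(loinheat:::layer_Tw_offset(3, 5), 5)
  expect_equal(loinheat:::layer_Tw_offset(10, 5), -5)
  expect_equal(loinheat:::layer_Tw_offset(6.5, 5), 0)
  l <- 3:10
  off <- loinheat:::layer_Tw_offset(l, 5)
  expect_true(all(diff(off) < 0))
  expect_equal(diff(off), rep(diff(off)[1], 7))
})

test_that("zero noise and zero offsets reproduce the deterministic base run", {
  cfg <- tiny_cfg()
  lay <- probe_layout()[c(3, 8), ]  # two probes, different pallets/layers
  ds <- generate_loggers(lay, cfg, quiet_perturbation())
  inp <- build_inputs(cfg)
  base <- simulate(inp$geometry, inp$props, inp$schedule, T0 = inp$T0,
                   grid = inp$grid, control = inp$control)
  for (d in ds)
    expect_equal(d$temperature_K, base$probes[, 1], tolerance = 1e-12)
})

test_that("generation is deterministic in the seed", {
  cfg <- tiny_cfg()
  lay <- probe_layout()[1:2, ]
  pm <- perturbation_model(delta_Tw_K = 2, pallet_offsets_K = c(1, -1),
                           sigma_K = 0.4, seed = 7)
  d1 <- generate_loggers(lay, cfg, pm)
  d2 <- generate_loggers(lay, cfg, pm)
  expect_identical(d1, d2)
  pm2 <- perturbation_model(delta_Tw_K = 2, pallet_offsets_K = c(1, -1),
                            sigma_K = 0.4, seed = 8)
  d3 <- generate_loggers(lay, cfg, pm2)
  expect_false(identical(d1[[1]]$temperature_K, d3[[1]]$temperature_K))
})

test_that("top layer cools faster than bottom layer during water-cooling", {
  cfg <- tiny_cfg()
  lay <- probe_layout()
  lay <- lay[lay$pallet == 1 & lay$layer %in% c(3, 10), ]
  ds <- generate_loggers(lay, cfg,
                         perturbation_model(delta_Tw_K = 5,
                                            pallet_offsets_K = 0,
                                            sigma_K = 0, seed = 1))
  top <- ds[[which(vapply(ds, function(d) d$layer == 10, logical(1)))]]
  bottom <- ds[[which(vapply(ds, function(d) d$layer == 3, logical(1)))]]
  # 600 s into water-cooling (starts 21720 s) and until its end
  sel <- top$time_s >= 21720 + 600 & top$time_s <= 28920
  expect_true(all(top$temperature_K[sel] < bottom$temperature_K[sel]))
  expect_equal(top$meta$Tw_offset_K, -5)
  expect_equal(bottom$meta$Tw_offset_K, 5)
})

test_that("measurement noise has the stated magnitude over the full series", {
  cfg <- tiny_cfg()
  lay <- probe_layout()[3, ]
  quiet <- generate_loggers(lay, cfg, quiet_perturbation())[[1]]
  noisy <- generate_loggers(lay, cfg,
                            perturbation_model(0, 0, sigma_K = 0.5,
                                               seed = 5))[[1]]
  expect_equal(length(noisy$temperature_K), 1403)
  rmse <- sqrt(mean((noisy$temperature_K - quiet$temperature_K)^2))
  expect_lt(abs(rmse - 0.5) / 0.5, 0.10)   # law of large numbers at n = 1403
})

test_that("fixture bundle writes a complete manifest and round-trips", {
  cfg <- tiny_cfg()
  lay <- probe_layout()[c(1, 6, 12), ]
  pm <- perturbation_model(delta_Tw_K = 3, sigma_K = 0.3, seed = 9)
  ds <- generate_loggers(lay, cfg, pm)
  tmp <- withr::local_tempdir()
  manifest <- write_fixture_bundle(ds, file.path(tmp, "b1"), cfg, pm)
  expect_length(manifest, nrow(lay) + 2)   # n data files + metadata + config
  expect_true(all(file.exists(manifest)))
  back <- read_fixture_bundle(file.path(tmp, "b1"))
  for (nm in names(ds)) {
    expect_identical(back[[nm]]$time_s, ds[[nm]]$time_s)
    expect_identical(back[[nm]]$temperature_K, ds[[nm]]$temperature_K)
    expect_equal(back[[nm]]$meta$Tw_offset_K, ds[[nm]]$meta$Tw_offset_K)
  }
  # regeneration with the same seed reproduces identical files byte-wise
  write_fixture_bundle(generate_loggers(lay, cfg, pm), file.path(tmp, "b2"),
                       cfg, pm)
  for (f in list.files(file.path(tmp, "b1")))
    expect_identical(readLines(file.path(tmp, "b1", f)),
                     readLines(file.path(tmp, "b2", f)))
})

test_that("mean of a noisy bundle approaches the unperturbed centre series", {
  cfg <- tiny_cfg()
  lay <- probe_layout()
  ds <- generate_loggers(lay, cfg,
                         perturbation_model(0, 0, sigma_K = 0.5, seed = 2))
  inp <- build_inputs(cfg)
  base <- simulate(inp$geometry, inp$props, inp$schedule, T0 = inp$T0,
                   grid = inp$grid, control = inp$control)$probes[, 1]
  avg <- rowMeans(vapply(ds, function(d) d$temperature_K,
                         numeric(length(base))))
  sd_mean <- 0.5 / sqrt(16)
  # pointwise RMS of the 16-probe mean matches the noise model, and no
  # sample strays beyond 5 standard errors
  expect_lt(abs(sqrt(mean((avg - base)^2)) - sd_mean) / sd_mean, 0.25)
  expect_lt(max(abs(avg - base)), 5 * sd_mean)
})

test_that("recovery closes on a perturbed probe when its offsets are known", {
  cfg <- cal_cfg()
  ds <- generate_loggers(t11_layout(), cfg,
                         perturbation_model(delta_Tw_K = 5,
                                            pallet_offsets_K = c(2, -2, 1, -1),
                                            sigma_K = 0.3, seed = 4))$T11
  # fit against a base configuration matching the probe's true environment
  cfg_probe <- cfg
  inp <- build_inputs(cfg)
  sch <- inp$schedule
  sch <- set_stage_Tp(sch, "water_cooling",
                      298.15 + ds$meta$Tw_offset_K)
  sch <- set_stage_Tp(sch, "drying", 333.15 + ds$meta$pallet_offset_K)
  sch <- set_stage_Tp(sch, "smoking", 318.15 + ds$meta$pallet_offset_K)
  cfg_probe$schedule <- list(stages = sch$stages)
  f <- fit_coefficients(ds, cfg_probe)
  expect_lt(abs(f$par[["h_w"]] - ds$meta$h_w) / ds$meta$h_w, 0.05)
  expect_lt(abs(f$par[["h_air"]] - ds$meta$h_air) / ds$meta$h_air, 0.05)
})
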