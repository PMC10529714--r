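test_that("equilibrium is a fixed point of the integrator", {
  g <- default_geom(); p <- default_props()
  sch <- one_stage_schedule(1800, Tp = 280.65, h = 500)
  res <- simulate(g, p, sch, T0 = 280.65, grid = solver_grid(9, 12))
  expect_lt(max(abs(res$probes - 280.65)), 1e-10)
  s <- summarize(res)
  expect_lt(max(abs(s$Tmax - 280.65)), 1e-10)
  expect_lt(max(abs(s$Tmin - 280.65)), 1e-10)
})

test_that("centre series matches the analytic finite-cylinder oracle", {
  g <- default_geom(); p <- default_props()
  sch <- one_stage_schedule(1800, Tp = 351.15, h = 2000)
  res <- simulate(g, p, sch, T0 = 280.65, grid = solver_grid(23, 46))
  ctr <- probe(res, 0, 0)
  sel <- ctr$time_s >= 300
  exact <- analytic_finite_cylinder(g, p, 2000, 351.15, 280.65,
                                    ctr$time_s[sel])
  expect_lt(max(abs(ctr$temperature_K[sel] - exact)), 0.2)
  # cooling problem, moderate h, off-centre point
  sch2 <- one_stage_schedule(3600, Tp = 276.15, h = 80)
  res2 <- simulate(g, p, sch2, T0 = 350, grid = solver_grid(23, 46),
                   probe_points = cbind(r = 0.02, z = 0.1))
  pr <- probe(res2, 0.02, 0.1)
  sel2 <- pr$time_s >= 300
  exact2 <- analytic_finite_cylinder(g, p, 80, 276.15, 350,
                                     pr$time_s[sel2], r = 0.02, z = 0.1)
  expect_lt(max(abs(pr$temperature_K[sel2] - exact2)), 0.2)
})

test_that("probe interpolation is exact at nodes and bilinear between them", {
  g <- cyl_geometry(0.04, 0.1)
  p <- default_props()
  grid <- solver_grid(5, 5)          # dr = 0.01, dz = 0.025
  # initial field linear in r: T = 300 + 500 r  (exact under bilinear interp)
  r_nodes <- seq(0, 0.04, length.out = 5)
  T0 <- matrix(rep(300 + 500 * r_nodes, 5), 5, 5)
  sch <- one_stage_schedule(60, Tp = 320, h = 1e-4)
  res <- simulate(g, p, sch, T0 = T0, grid = grid,
                  probe_points = rbind(c(0.02, 0.05), c(0.015, 0.05)),
                  store_fields = TRUE)
  # t = 0 row reflects the initial field
  expect_equal(probe(res, 0.02, 0.05)$temperature_K[1], 300 + 500 * 0.02)
  # midway between nodes r = 0.01 and r = 0.02: arithmetic mean
  expect_equal(probe(res, 0.015, 0.05)$temperature_K[1],
               mean(c(300 + 500 * 0.01, 300 + 500 * 0.02)))
  # store_fields route agrees with precomputed probes
  pr_any <- probe(res, 0.0317, 0.033)
  expect_equal(nrow(pr_any), length(res$times))
  expect_error(probe(res, 0.05, 0), "outside")
})

test_that("probe without stored fields requires a precomputed point", {
  g <- default_geom(); p <- default_props()
  res <- simulate(g, p, one_stage_schedule(300), T0 = 280.65,
                  grid = solver_grid(9, 12))
  expect_error(probe(res, 0.01, 0.01), "store_fields")
  expect_equal(nrow(probe(res, 0, 0)), floor(300 / 60) + 1)
})

test_that("maximum principle and heating monotonicity hold on a two-stage run", {
  g <- default_geom(); p <- default_props()
  sch <- process_schedule(list(
    process_stage("heat", 3600, 351.15, 2000),
    process_stage("cool", 3600, 276.15, 80)))
  res <- simulate(g, p, sch, T0 = 280.65, grid = solver_grid(9, 12))
  s <- summarize(res)
  expect_gte(min(s$Tmin), 276.15 - 1e-6)
  expect_lte(max(s$Tmax), 351.15 + 1e-6)
  # centre temperature non-decreasing while Tp exceeds the field maximum
  ctr <- probe(res, 0, 0)
  heat <- ctr$time_s <= 3600
  expect_true(all(diff(ctr$temperature_K[heat]) >= -1e-9))
})

test_that("per-stage energy balance closes", {
  g <- default_geom(); p <- default_props()
  sch <- process_schedule(list(
    process_stage("heat", 1800, 351.15, 2000),
    process_stage("hold", 600, 298.15, 8),
    process_stage("cool", 1800, 276.15, 80)))
  res <- simulate(g, p, sch, T0 = 280.65, grid = solver_grid(9, 12))
  expect_true(all(res$energy$rel_err < 0.005))
})

test_that("snapshots land exactly on stage boundaries and requested times", {
  g <- default_geom(); p <- default_props()
  sch <- process_schedule(list(
    process_stage("heat", 900, 351.15, 2000),
    process_stage("cool", 900, 276.15, 80)))
  res <- simulate(g, p, sch, T0 = 280.65, grid = solver_grid(9, 12),
                  snapshot_times = c(450, 1200))
  expect_setequal(names(res$snapshots), c("0", "450", "900", "1200", "1800"))
  # snapshot at a stage boundary equals the final field of that stage
  expect_equal(res$snapshots[["1800"]], res$final_field)
  # interior snapshot consistent with the centre probe series
  ctr <- probe(res, 0, 0)
  expect_equal(res$snapshots[["1200"]][1, 1],
               ctr$temperature_K[ctr$time_s == 1200], tolerance = 1e-6)
  expect_error(simulate(g, p, sch, grid = solver_grid(9, 12),
                        snapshot_times = 5000), "outside")
})

test_that("solution is axially flat at the mid-plane in the long-cylinder limit", {
  g <- cyl_geometry(0.0425, 2)      # end face far away
  p <- default_props()
  res <- simulate(g, p, one_stage_schedule(1800), T0 = 280.65,
                  grid = solver_grid(15, 40))
  f <- res$final_field
  # mid-plane neighbourhood sees no axial gradient
  expect_lt(max(abs(f[, 1] - f[, 2])), 1e-6)
  # and the radial profile matches the infinite-cylinder series (slab ~ 1)
  ctr <- probe(res, 0, 0)
  exact <- analytic_finite_cylinder(g, p, 2000, 351.15, 280.65,
                                    ctr$time_s[ctr$time_s >= 300])
  expect_lt(max(abs(ctr$temperature_K[ctr$time_s >= 300] - exact)), 0.35)
})

test_that("invalid simulate inputs are rejected", {
  g <- default_geom(); p <- default_props()
  sch <- one_stage_schedule(300)
  expect_error(simulate(g, p, sch, T0 = -5, grid = solver_grid(9, 12)),
               "T0")
  expect_error(simulate(g, p, sch, T0 = matrix(280, 3, 3),
                        grid = solver_grid(9, 12)), "nr x nz")
  expect_error(simulate(g, p, sch, grid = solver_grid(9, 12),
                        probe_points = cbind(1, 0)), "outside")
  expect_error(solver_grid(3, 10), "nr")
  expect_error(cyl_geometry(-1, 2), "> 0")
})
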