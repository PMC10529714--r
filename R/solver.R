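#' Cylindrical product geometry
#'
#' The computational domain is the axisymmetric quarter-section of the full
#' cylinder: `r` in `[0, radius]`, `z` in `[0, half_length]` with `z`
#' measured from the mid-plane. Symmetry (zero flux) applies at the axis and
#' mid-plane; the convective boundary applies at the lateral surface
#' `r = radius` and the end face `z = half_length`.
#'
#' @param radius Product radius R (m).
#' @param half_length Half of the product length (m).
#' @return List of class `"cyl_geometry"`.
#' @export
#' @examples
#' cyl_geometry(0.0425, 0.27)          # the default 85 mm x 540 mm loin
#' geometry_from_product(0.085, 0.54)  # equivalent, from full dimensions
cyl_geometry <- function(radius, half_length) {
  if (!is.finite(radius) || radius <= 0 ||
      !is.finite(half_length) || half_length <= 0)
    stop("radius and half_length must be > 0", call. = FALSE)
  structure(list(radius = radius, half_length = half_length),
            class = "cyl_geometry")
}

#' @rdname cyl_geometry
#' @param diameter,length Full product dimensions (m).
#' @export
geometry_from_product <- function(diameter, length) {
  cyl_geometry(diameter / 2, length / 2)
}

#' Solver grid
#'
#' Vertex-centred uniform grid: `nr` radial nodes from the axis to the
#' surface and `nz` axial nodes from the mid-plane to the end face.
#'
#' @param nr,nz Node counts per axis (>= 4).
#' @export
solver_grid <- function(nr = 45, nz = 90) {
  if (nr < 4 || nz < 4) stop("nr and nz must be >= 4", call. = FALSE)
  structure(list(nr = as.integer(nr), nz = as.integer(nz)),
            class = "solver_grid")
}

#' Time-integration control
#'
#' Each stage restarts the integrator: `n_startup` backward-Euler steps of
#' length `dt_init` damp the boundary-condition jump (Rannacher start-up),
#' after which Crank-Nicolson steps grow geometrically up to `dt_max`.
#' Probe and summary series are reported on a fixed `sample_dt` grid
#' (linear interpolation between accepted steps; stage boundaries are hit
#' exactly).
#'
#' @param dt_init Start-up step (s).
#' @param dt_max Maximum step (s).
#' @param n_startup Number of backward-Euler start-up steps per stage.
#' @param sample_dt Output cadence (s); 60 s matches the logger cadence.
#' @export
solver_control <- function(dt_init = 1, dt_max = 30, n_startup = 2,
                           sample_dt = 60) {
  stopifnot(dt_init > 0, dt_max >= dt_init, n_startup >= 0, sample_dt > 0)
  structure(list(dt_init = dt_init, dt_max = dt_max,
                 n_startup = as.integer(n_startup), sample_dt = sample_dt),
            class = "solver_control")
}

# Conservative finite-volume mesh on the (r, z) rectangle with cylindrical
# metric. Control volumes surround each node (half cells at boundaries);
# radial cell "volumes" are exact integrals of r dr, so the axis needs no
# 1/r evaluation. Returns the assembled conduction operator (symmetric,
# Robin terms excluded) plus boundary node indices and areas.
fv_mesh <- function(geometry, grid, props) {
  R <- geometry$radius; Lh <- geometry$half_length
  nr <- grid$nr; nz <- grid$nz
  dr <- R / (nr - 1); dz <- Lh / (nz - 1)
  r <- (seq_len(nr) - 1) * dr
  z <- (seq_len(nz) - 1) * dz
  wr <- r * dr                      # interior: int r dr over [r-dr/2, r+dr/2]
  wr[1] <- dr^2 / 8                 # axis half cell: int_0^{dr/2} r dr
  wr[nr] <- dr / 2 * (R - dr / 4)   # surface half cell
  wz <- rep(dz, nz); wz[c(1, nz)] <- dz / 2
  n <- nr * nz
  idx <- function(i, j) i + (j - 1L) * nr
  km <- props$k
  ii <- vector("list", nr + nz); jj <- ii; xx <- ii; p <- 0L
  for (i in seq_len(nr - 1)) {           # radial faces at r_{i+1/2}
    G <- km * ((i - 0.5) * dr) * wz / dr
    a <- idx(i, seq_len(nz)); b <- idx(i + 1L, seq_len(nz))
    p <- p + 1L
    ii[[p]] <- c(a, b, a, b); jj[[p]] <- c(b, a, a, b)
    xx[[p]] <- c(G, G, -G, -G)
  }
  for (j in seq_len(nz - 1)) {           # axial faces at z_{j+1/2}
    G <- km * wr / dz
    a <- idx(seq_len(nr), j); b <- idx(seq_len(nr), j + 1L)
    p <- p + 1L
    ii[[p]] <- c(a, b, a, b); jj[[p]] <- c(b, a, a, b)
    xx[[p]] <- c(G, G, -G, -G)
  }
  A_cond <- Matrix::sparseMatrix(i = unlist(ii[seq_len(p)]),
                                 j = unlist(jj[seq_len(p)]),
                                 x = unlist(xx[seq_len(p)]),
                                 dims = c(n, n))
  # convective boundary: lateral surface (i = nr) and end face (j = nz);
  # the corner node carries both face areas
  b_idx <- c(idx(nr, seq_len(nz)), idx(seq_len(nr), nz))
  b_area <- c(R * wz, wr)
  agg <- rowsum(b_area, b_idx)
  list(geometry = geometry, grid = grid, props = props,
       nr = nr, nz = nz, dr = dr, dz = dz, r = r, z = z,
       wr = wr, wz = wz,
       Mv = as.vector(outer(wr, wz)) * props$rho * props$cp,
       A_cond = A_cond,
       b_idx = as.integer(rownames(agg)), b_area = as.vector(agg))
}

# Bilinear interpolation weights at (r, z): indices into the field vector
# and weights summing to 1.
bilinear_weights <- function(mesh, r, z) {
  R <- mesh$geometry$radius; Lh <- mesh$geometry$half_length
  if (r < -1e-12 || r > R + 1e-12 || z < -1e-12 || z > Lh + 1e-12)
    stop(sprintf("probe point (r = %g, z = %g) outside the domain", r, z),
         call. = FALSE)
  r <- min(max(r, 0), R); z <- min(max(z, 0), Lh)
  i <- min(1L + floor(r / mesh$dr), mesh$nr - 1L)
  j <- min(1L + floor(z / mesh$dz), mesh$nz - 1L)
  fr <- r / mesh$dr - (i - 1L); fz <- z / mesh$dz - (j - 1L)
  idx <- function(i, j) i + (j - 1L) * mesh$nr
  list(idx = c(idx(i, j), idx(i + 1L, j), idx(i, j + 1L),
               idx(i + 1L, j + 1L)),
       w = c((1 - fr) * (1 - fz), fr * (1 - fz), (1 - fr) * fz, fr * fz))
}

# Step times for one stage: geometric ramp after the BE start-up, capped at
# dt_max, with forced interior times (snapshots) merged in. Returns the
# vector of step end times (relative to stage start, excluding 0).
stage_step_times <- function(duration, control, forced = numeric(0)) {
  ts <- numeric(0); t <- 0; k <- 0L
  while (t < duration - 1e-9) {
    dt <- min(control$dt_init * 2^max(0L, k - control$n_startup),
              control$dt_max, duration - t)
    t <- t + dt; k <- k + 1L
    ts <- c(ts, t)
  }
  forced <- forced[forced > 1e-9 & forced < duration - 1e-9]
  sort(unique(c(ts, forced, duration)))
}

# Advance one stage. Returns final field, per-step record, energy tallies.
# `forced` times (relative to stage start) become exact step endpoints and
# the field at each is captured in `captures`.
run_stage <- function(mesh, T_field, h, Tp, duration, control,
                      probe_w, forced = numeric(0), record_fields = FALSE) {
  n <- length(mesh$Mv)
  A <- mesh$A_cond -
    Matrix::sparseMatrix(i = mesh$b_idx, j = mesh$b_idx,
                         x = h * mesh$b_area, dims = c(n, n))
  bb <- numeric(n); bb[mesh$b_idx] <- h * mesh$b_area * Tp
  Msp <- Matrix::Diagonal(x = mesh$Mv)
  flux <- function(Tv) sum(h * mesh$b_area * (Tp - Tv[mesh$b_idx]))
  ts <- stage_step_times(duration, control, forced)
  nstep <- length(ts)
  rec_t <- numeric(nstep + 1); rec_t[1] <- 0
  np <- length(probe_w)
  rec_probe <- matrix(NA_real_, nstep + 1, np)
  rec_sum <- matrix(NA_real_, nstep + 1, 7)  # Tavv Tmin Tmax rmin zmin rmax zmax
  fields <- if (record_fields) vector("list", nstep + 1) else NULL
  record <- function(s, Tv) {
    for (q in seq_len(np))
      rec_probe[s, q] <<- sum(probe_w[[q]]$w * Tv[probe_w[[q]]$idx])
    imin <- which.min(Tv); imax <- which.max(Tv)
    loc <- function(i) c(mesh$r[(i - 1L) %% mesh$nr + 1L],
                         mesh$z[(i - 1L) %/% mesh$nr + 1L])
    rec_sum[s, ] <<- c(sum(mesh$Mv * Tv) / sum(mesh$Mv), Tv[imin], Tv[imax],
                       loc(imin), loc(imax))
    if (record_fields) fields[[s]] <<- Tv
  }
  record(1L, T_field)
  captures <- list()
  U0 <- sum(mesh$Mv * T_field)
  flux_int <- 0
  fact <- new.env(parent = emptyenv())
  t_prev <- 0
  for (s in seq_len(nstep)) {
    dt <- ts[s] - t_prev
    th <- if (s <= control$n_startup) 1 else 0.5
    key <- sprintf("%.10e_%.2f", dt, th)
    ch <- get0(key, envir = fact)
    if (is.null(ch)) {
      ch <- Matrix::Cholesky(Matrix::forceSymmetric(Msp - dt * th * A),
                             LDL = FALSE)
      assign(key, ch, envir = fact)
    }
    rhs <- mesh$Mv * T_field + dt * (1 - th) * as.vector(A %*% T_field) +
      dt * bb
    T_new <- as.vector(Matrix::solve(ch, rhs, system = "A"))
    if (any(!is.finite(T_new)))
      stop(sprintf(
        "solver produced non-finite values at stage time %.1f s (h = %g)",
        ts[s], h), call. = FALSE)
    flux_int <- flux_int + dt * (th * flux(T_new) + (1 - th) * flux(T_field))
    T_field <- T_new
    t_prev <- ts[s]
    rec_t[s + 1] <- ts[s]
    record(s + 1L, T_field)
    if (length(forced) && any(abs(forced - ts[s]) < 1e-9))
      captures[[format(ts[s], trim = TRUE)]] <- T_field
  }
  list(T_field = T_field, t = rec_t, probe = rec_probe, summ = rec_sum,
       fields = fields, captures = captures,
       dU = sum(mesh$Mv * T_field) - U0, flux_int = flux_int)
}

#' Simulate the multistage process
#'
#' Solves the transient axisymmetric conduction equation
#' `rho cp dT/dt = div(k grad T)` on the quarter-section of the cylinder,
#' with the schedule's convective boundary condition
#' `-n . (k grad T) = h(t) (Tp(t) - Ts)` on the lateral surface and end
#' face, and zero flux on the axis and mid-plane. Conservative second-order
#' finite volumes in space; implicit stepping restarted at every stage
#' boundary so the discontinuities in `h` and `Tp` are resolved exactly
#' (see [solver_control()]).
#'
#' @param geometry A [cyl_geometry()].
#' @param props A [thermo_props()].
#' @param schedule A [process_schedule()].
#' @param T0 Initial temperature: a single value (uniform field, K) or a
#'   full `nr x nz` matrix (used when restarting from a cached state).
#' @param grid A [solver_grid()].
#' @param control A [solver_control()].
#' @param probe_points Matrix or data.frame with columns `r`, `z`: points
#'   whose temperature series are sampled at the output cadence. Default:
#'   the product centre (0, 0).
#' @param snapshot_times Times (s, relative to schedule start) at which the
#'   full field is stored; stage boundaries (including 0 and the end) are
#'   always included and hit exactly.
#' @param t_start Time label of the schedule start (s); nonzero when
#'   simulating a schedule tail from [split_schedule()].
#' @param store_fields If `TRUE`, additionally store the full field at every
#'   output sample time (memory-heavy; intended for small grids, enables
#'   [probe()] at arbitrary points after the fact).
#' @return Object of class `"simulation_result"`: `times` (output grid, s),
#'   `probes` (matrix, one column per probe point), `summary` (data.frame
#'   `time_s`, `Tavv`, `Tmin`, `Tmax`, argmin/argmax coordinates), `snapshots`
#'   (named list of `nr x nz` matrices keyed by time), `energy` (per-stage
#'   internal-energy change vs time-integrated boundary flux, J per radian
#'   times 2*pi), and the inputs.
#' @export
#' @examples
#' g <- cyl_geometry(0.0425, 0.27)
#' p <- thermo_props(1064.5, 3535.5, 0.47)
#' res <- simulate(g, p, default_schedule(), T0 = 280.65,
#'                 grid = solver_grid(15, 20))
#' tail(summarize(res))
simulate <- function(geometry, props, schedule, T0 = 280.65,
                     grid = solver_grid(), control = solver_control(),
                     probe_points = cbind(r = 0, z = 0),
                     snapshot_times = NULL, t_start = 0,
                     store_fields = FALSE) {
  stopifnot(inherits(geometry, "cyl_geometry"),
            inherits(props, "thermo_props"),
            inherits(schedule, "process_schedule"))
  mesh <- fv_mesh(geometry, grid, props)
  n <- mesh$nr * mesh$nz
  if (is.matrix(T0)) {
    if (!all(dim(T0) == c(mesh$nr, mesh$nz)))
      stop("initial field must be an nr x nz matrix", call. = FALSE)
    T_field <- as.vector(T0)
  } else {
    if (!is.finite(T0) || T0 <= 0)
      stop("T0 must be a positive temperature in K", call. = FALSE)
    T_field <- rep(T0, n)
  }
  probe_points <- as.matrix(probe_points)
  probe_w <- lapply(seq_len(nrow(probe_points)), function(q)
    bilinear_weights(mesh, probe_points[q, 1], probe_points[q, 2]))

  total <- total_duration(schedule)
  snap_req <- sort(unique(c(schedule$boundaries, snapshot_times - t_start)))
  if (any(snap_req < -1e-9 | snap_req > total + 1e-9))
    stop("snapshot_times outside the schedule window", call. = FALSE)

  all_t <- list(); all_probe <- list(); all_sum <- list()
  all_fields <- list()
  snapshots <- list(); energy <- NULL
  t0 <- 0
  snap_key <- function(t) format(t + t_start, trim = TRUE)
  snapshots[[snap_key(0)]] <- matrix(T_field, mesh$nr, mesh$nz)
  for (s in seq_len(nrow(schedule$stages))) {
    st <- schedule$stages[s, ]
    forced <- snap_req[snap_req > t0 & snap_req < t0 + st$duration_s] - t0
    out <- run_stage(mesh, T_field, st$h_W_m2K, st$T_process_K,
                     st$duration_s, control, probe_w, forced,
                     record_fields = store_fields)
    T_field <- out$T_field
    keep <- if (s == 1) seq_along(out$t) else -1L  # drop duplicated t0 row
    all_t[[s]] <- out$t[keep] + t0
    all_probe[[s]] <- out$probe[keep, , drop = FALSE]
    all_sum[[s]] <- out$summ[keep, , drop = FALSE]
    if (store_fields) all_fields[[s]] <- out$fields[keep]
    for (nm in names(out$captures))
      snapshots[[snap_key(t0 + as.numeric(nm))]] <-
        matrix(out$captures[[nm]], mesh$nr, mesh$nz)
    t0 <- t0 + st$duration_s
    snapshots[[snap_key(t0)]] <- matrix(T_field, mesh$nr, mesh$nz)
    energy <- rbind(energy, data.frame(
      stage = st$name, dU = out$dU, flux_int = out$flux_int,
      rel_err = abs(out$flux_int - out$dU) /
        max(abs(out$dU), abs(out$flux_int), 1e-12)))
  }
  step_t <- unlist(all_t)
  step_probe <- do.call(rbind, all_probe)
  step_sum <- do.call(rbind, all_sum)

  times <- seq(0, total, by = control$sample_dt)
  if (abs(times[length(times)] - total) > 1e-9) times <- c(times, total)
  interp <- function(y) stats::approx(step_t, y, times, ties = "ordered")$y
  probes <- apply(step_probe, 2, interp)
  if (is.null(dim(probes))) probes <- matrix(probes, ncol = 1)
  nearest <- findInterval(times, step_t, all.inside = TRUE)
  nearest <- ifelse(step_t[nearest + 1] - times < times - step_t[nearest],
                    nearest + 1, nearest)
  summary_df <- data.frame(
    time_s = times + t_start,
    Tavv = interp(step_sum[, 1]), Tmin = interp(step_sum[, 2]),
    Tmax = interp(step_sum[, 3]),
    argmin_r = step_sum[nearest, 4], argmin_z = step_sum[nearest, 5],
    argmax_r = step_sum[nearest, 6], argmax_z = step_sum[nearest, 7])

  fields_60 <- NULL
  if (store_fields) {
    step_fields <- unlist(all_fields, recursive = FALSE)
    fields_60 <- lapply(seq_along(times), function(i) {
      j <- findInterval(times[i], step_t, all.inside = TRUE)
      if (abs(step_t[j] - times[i]) < 1e-9) f <- step_fields[[j]]
      else {
        w <- (times[i] - step_t[j]) / (step_t[j + 1] - step_t[j])
        f <- (1 - w) * step_fields[[j]] + w * step_fields[[j + 1]]
      }
      matrix(f, mesh$nr, mesh$nz)
    })
  }
  structure(list(
    geometry = geometry, props = props, schedule = schedule,
    grid = grid, control = control, mesh = mesh, t_start = t_start,
    probe_points = probe_points,
    times = times + t_start, probes = probes, summary = summary_df,
    snapshots = snapshots, fields = fields_60, energy = energy,
    final_field = matrix(T_field, mesh$nr, mesh$nz)),
    class = "simulation_result")
}

#' Temperature series at a point
#'
#' Returns the temperature series at `(r, z)` on the output cadence,
#' bilinearly interpolated on the grid. The point must either match one of
#' the `probe_points` requested in [simulate()] (tolerance 1e-9 m) or the
#' result must have been run with `store_fields = TRUE`.
#'
#' @param result A `"simulation_result"`.
#' @param r,z Point coordinates (m), `z` from the mid-plane.
#' @return data.frame with `time_s` and `temperature_K`.
#' @export
probe <- function(result, r = 0, z = 0) {
  pp <- result$probe_points
  hit <- which(abs(pp[, 1] - r) < 1e-9 & abs(pp[, 2] - z) < 1e-9)
  if (length(hit) >= 1) {
    return(data.frame(time_s = result$times,
                      temperature_K = result$probes[, hit[1]]))
  }
  if (is.null(result$fields))
    stop("point was not among simulate()'s probe_points and fields were ",
         "not stored; rerun simulate() with this probe point or with ",
         "store_fields = TRUE", call. = FALSE)
  w <- bilinear_weights(result$mesh, r, z)
  v <- vapply(result$fields, function(f) sum(w$w * as.vector(f)[w$idx]),
              numeric(1))
  data.frame(time_s = result$times, temperature_K = v)
}

#' @export
#' @method print simulation_result
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    "simulation_result: %d stages, t = [%g, %g] s, grid %d x %d, %d samples\n",
    nrow(x$schedule$stages), min(x$times), max(x$times),
    x$grid$nr, x$grid$nz, length(x$times)))
  cat(sprintf("  final field: min %.2f K, max %.2f K\n",
              min(x$final_field), max(x$final_field)))
  invisible(x)
}
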