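#' Summary of a single temperature field
#'
#' Volume-average, minimum (cold spot) and maximum (hot spot) temperature of
#' one field snapshot, with extremum locations. The volume average uses the
#' same cylindrical finite-volume cell weights as the solver, so it is
#' consistent with the energy-balance accounting. Ties in the extrema are
#' broken toward the smallest radial index, then the smallest axial index.
#'
#' @param field `nr x nz` temperature matrix (K).
#' @param geometry A [cyl_geometry()].
#' @param grid A [solver_grid()] matching the field dimensions.
#' @return List with `Tavv`, `Tmin`, `Tmax` (K), `argmin`, `argmax`
#'   (named `c(r, z)` in m).
#' @export
field_summary <- function(field, geometry, grid) {
  if (!all(dim(field) == c(grid$nr, grid$nz)))
    stop("field dimensions do not match the grid", call. = FALSE)
  mesh <- fv_mesh(geometry, grid, thermo_props(1, 1, 1))  # weights only
  w <- outer(mesh$wr, mesh$wz)
  imin <- which.min(field); imax <- which.max(field)
  loc <- function(i) c(r = mesh$r[(i - 1L) %% grid$nr + 1L],
                       z = mesh$z[(i - 1L) %/% grid$nr + 1L])
  list(Tavv = sum(w * field) / sum(w),
       Tmin = field[imin], Tmax = field[imax],
       argmin = loc(imin), argmax = loc(imax))
}

#' Summary series of a simulation
#'
#' The volume-average (`Tavv`), minimum (`Tmin`, cold spot) and maximum
#' (`Tmax`, hot spot) temperature of the product at the output cadence,
#' with the extremum locations, as tracked during the run.
#'
#' @param result A `"simulation_result"`.
#' @return data.frame with columns `time_s`, `Tavv`, `Tmin`, `Tmax`,
#'   `argmin_r`, `argmin_z`, `argmax_r`, `argmax_z`.
#' @export
summarize <- function(result) {
  if (!inherits(result, "simulation_result"))
    stop("summarize() expects a simulation_result", call. = FALSE)
  if (is.null(result$summary) || nrow(result$summary) == 0)
    stop("empty simulation result", call. = FALSE)
  result$summary
}

#' Validation metrics between predicted and measured series
#'
#' Root-mean-square error and the coefficient of determination
#' `R^2 = 1 - SS_res / SS_tot`, with `SS_tot` taken about the measured mean.
#' Both series must be aligned on the same time grid.
#'
#' @param predicted,measured Numeric vectors, or data.frames with columns
#'   `time_s` and `temperature_K` (timestamps are then checked to agree).
#' @return List of class `"validation_metrics"`: `R2`, `RMSE` (K) and
#'   `residuals` (data.frame `time_s`, `residual_K`; `time_s` is the sample
#'   index when plain vectors are supplied). `R2` is `NA` (with a warning)
#'   when the measured series is constant.
#' @export
#' @examples
#' compute_metrics(c(1, 2, 3) + 0.1, c(1, 2, 3))
compute_metrics <- function(predicted, measured) {
  tgrid <- NULL
  if (is.data.frame(predicted)) {
    tgrid <- predicted$time_s; predicted <- predicted$temperature_K
  }
  if (is.data.frame(measured)) {
    if (!is.null(tgrid) &&
        (length(tgrid) != length(measured$time_s) ||
         any(abs(tgrid - measured$time_s) > 1e-6)))
      stop("predicted and measured timestamps are not aligned",
           call. = FALSE)
    tgrid <- measured$time_s; measured <- measured$temperature_K
  }
  if (length(predicted) != length(measured))
    stop(sprintf("length mismatch: predicted %d vs measured %d",
                 length(predicted), length(measured)), call. = FALSE)
  if (is.null(tgrid)) tgrid <- seq_along(measured)
  res <- predicted - measured
  rmse <- sqrt(mean(res^2))
  ss_tot <- sum((measured - mean(measured))^2)
  if (ss_tot <= 0) {
    warning("measured series is constant; R^2 undefined")
    r2 <- NA_real_
  } else r2 <- 1 - sum(res^2) / ss_tot
  structure(list(R2 = r2, RMSE = rmse,
                 residuals = data.frame(time_s = tgrid, residual_K = res)),
            class = "validation_metrics")
}

#' @export
#' @method print validation_metrics
print.validation_metrics <- function(x, ...) {
  cat(sprintf("validation_metrics: R2 = %.4f, RMSE = %.3f K (n = %d)\n",
              x$R2, x$RMSE, nrow(x$residuals)))
  invisible(x)
}
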