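#' A centre-probe temperature logger dataset
#'
#' @param probe_id Logger label, e.g. `"T11"`.
#' @param time_s Sample times (s), strictly increasing at a fixed cadence.
#' @param temperature_K Measured temperatures (K), within the plausible
#'   range \[250, 400\] K.
#' @param pallet,layer Position labels of the product on the pallet.
#' @param position Probe location `c(r, z)` in the product (m, `z` from the
#'   mid-plane); loggers sit at the product centre.
#' @param meta Optional list of generating metadata (ground truth for
#'   synthetic data).
#' @return List of class `"logger_dataset"`.
#' @export
logger_dataset <- function(probe_id, time_s, temperature_K,
                           pallet = NA_integer_, layer = NA_integer_,
                           position = c(r = 0, z = 0), meta = list()) {
  if (length(time_s) != length(temperature_K) || length(time_s) < 2)
    stop("time_s and temperature_K must be equal-length (>= 2)",
         call. = FALSE)
  dt <- diff(time_s)
  if (any(dt <= 0) || any(abs(dt - dt[1]) > 1e-6))
    stop("timestamps must be strictly increasing at a fixed cadence",
         call. = FALSE)
  if (any(temperature_K < 250 | temperature_K > 400))
    stop("temperatures outside the plausible range [250, 400] K",
         call. = FALSE)
  structure(list(probe_id = probe_id, pallet = pallet, layer = layer,
                 position = c(r = unname(position[1]),
                              z = unname(position[2])),
                 cadence_s = dt[1],
                 time_s = as.numeric(time_s),
                 temperature_K = as.numeric(temperature_K),
                 meta = meta),
            class = "logger_dataset")
}

#' Read / write a logger CSV
#'
#' The on-disk dialect is a CSV with header `time_s,temperature_K`, plus an
#' optional JSON sidecar `<id>_meta.json` naming the probe position and
#' labels.
#'
#' @param path CSV path.
#' @param meta_path Optional sidecar path; defaults to
#'   `<path without .csv>_meta.json` when that file exists.
#' @return A [logger_dataset()].
#' @export
read_logger <- function(path, meta_path = NULL) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "temperature_K") %in% names(df)))
    stop("logger CSV must have columns time_s,temperature_K", call. = FALSE)
  if (is.null(meta_path)) {
    cand <- sub("\\.csv$", "_meta.json", path)
    if (file.exists(cand)) meta_path <- cand
  }
  m <- if (!is.null(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  logger_dataset(
    probe_id = m$probe_id %||% sub("\\.csv$", "", basename(path)),
    time_s = df$time_s, temperature_K = df$temperature_K,
    pallet = m$pallet %||% NA_integer_, layer = m$layer %||% NA_integer_,
    position = c(m$position_r %||% 0, m$position_z %||% 0),
    meta = m$meta %||% list())
}

#' @rdname read_logger
#' @param data A [logger_dataset()].
#' @param dir Output directory.
#' @return (write_logger) the paths written, invisibly.
#' @export
write_logger <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, paste0(data$probe_id, ".csv"))
  .write_series_csv(data$time_s, data$temperature_K, csv)
  mj <- file.path(dir, paste0(data$probe_id, "_meta.json"))
  jsonlite::write_json(list(probe_id = data$probe_id, pallet = data$pallet,
                            layer = data$layer,
                            position_r = data$position[["r"]],
                            position_z = data$position[["z"]],
                            meta = data$meta),
                       mj, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(csv, mj))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# full-precision series CSV so write -> read round-trips bit-exactly
.write_series_csv <- function(time_s, temperature_K, path) {
  lines <- c("time_s,temperature_K",
             paste(sprintf("%.17g", time_s),
                   sprintf("%.17g", temperature_K), sep = ","))
  writeLines(lines, path)
}

# stages influenced by each fittable heat-transfer coefficient
.param_stages <- list(
  h_d = c("drying", "smoking"), h_smoke = "smoking",
  h_amb = c("transfer1", "transfer2"), h_st = "steam_cooking",
  h_w = "water_cooling", h_air = "air_cooling")

# Shared forward machinery for objective() and fit_coefficients().
# Residuals are evaluated from the start of the earliest stage any free
# parameter influences; the solution up to that point does not depend on
# theta and is computed once and cached.
.forward_model <- function(data, base_config, free_params) {
  inp <- build_inputs(base_config)
  sch <- inp$schedule
  stages <- unique(unlist(.param_stages[free_params]))
  if (any(!free_params %in% names(.param_stages)))
    stop("unknown free parameter(s): ",
         paste(setdiff(free_params, names(.param_stages)), collapse = ", "),
         call. = FALSE)
  present <- intersect(stages, sch$stages$name)
  if (length(present) == 0)
    stop("schedule has none of the stages influenced by ",
         paste(free_params, collapse = ", "), call. = FALSE)
  t_split <- min(vapply(present, function(s) stage_window(sch, s)[1],
                        numeric(1)))
  sel <- data$time_s >= t_split - 1e-9
  if (!any(sel))
    stop(sprintf(
      "logger data (up to t = %g s) do not cover the stages influenced by %s (from t = %g s)",
      max(data$time_s), paste(free_params, collapse = ", "), t_split),
      call. = FALSE)
  meas_t <- data$time_s[sel]
  meas_T <- data$temperature_K[sel]
  pos <- rbind(data$position)
  if (t_split > 0) {
    sp <- split_schedule(sch, t_split)
    head_res <- simulate(inp$geometry, inp$props, sp$head, T0 = inp$T0,
                         grid = inp$grid, control = inp$control,
                         probe_points = pos)
    T_init <- head_res$final_field
    tail_sch <- sp$tail
  } else {
    T_init <- inp$T0
    tail_sch <- sch
  }
  # the tail only needs to reach the last measured sample
  t_end_rel <- max(meas_t) - t_split
  if (t_end_rel < total_duration(tail_sch) - 1e-9 && t_end_rel > 0) {
    ts0 <- attr(tail_sch, "t_start")
    tail_sch <- split_schedule(tail_sch, t_end_rel)$head
    attr(tail_sch, "t_start") <- ts0
  }
  predict_series <- function(theta) {
    s2 <- tail_sch
    for (p in names(theta)) {
      nm <- intersect(.param_stages[[p]], s2$stages$name)
      if (length(nm)) s2 <- set_stage_h(s2, nm, theta[[p]])
    }
    res <- simulate(inp$geometry, inp$props, s2, T0 = T_init,
                    grid = inp$grid, control = inp$control,
                    probe_points = pos, t_start = t_split)
    stats::approx(res$times, res$probes[, 1], meas_t, rule = 2,
                  ties = "ordered")$y
  }
  list(predict_series = predict_series, meas_t = meas_t, meas_T = meas_T,
       t_split = t_split)
}

#' Sum-of-squared-residuals objective
#'
#' One forward simulation with the candidate coefficients substituted into
#' the schedule, compared to the measured series on the logger's sample
#' grid, restricted to the stages the free parameters influence (and all
#' later stages).
#'
#' @param theta Named numeric vector of candidate coefficients
#'   (subset of `h_d`, `h_smoke`, `h_amb`, `h_st`, `h_w`, `h_air`).
#' @param data A [logger_dataset()].
#' @param base_config A run configuration list, see [default_config()].
#' @param cache Optional precomputed model from a previous call (internal).
#' @return Sum of squared residuals (K^2).
#' @export
objective <- function(theta, data, base_config = default_config(),
                      cache = NULL) {
  fm <- cache %||% .forward_model(data, base_config, names(theta))
  sum((fm$predict_series(theta) - fm$meas_T)^2)
}

# Bounded Levenberg-Marquardt on the residual vector; small and
# deterministic. Jacobian by forward differences. Steps are clipped to the
# bounds; damping grows until a step reduces the SSR.
.lm_fit <- function(rfun, theta0, lower, upper, max_iter = 40,
                    trace_env = NULL) {
  th <- pmin(pmax(theta0, lower), upper)
  r <- rfun(th); ssr <- sum(r^2)
  lambda <- 1e-3; n_iter <- 0L; converged <- FALSE
  for (it in seq_len(max_iter)) {
    n_iter <- it
    J <- matrix(0, length(r), length(th))
    for (p in seq_along(th)) {
      hstep <- max(1e-3 * abs(th[p]), 1e-6)
      thp <- th; thp[p] <- min(th[p] + hstep, upper[p])
      if (thp[p] - th[p] < hstep / 2) thp[p] <- th[p] - hstep  # at upper bound
      J[, p] <- (rfun(thp) - r) / (thp[p] - th[p])
    }
    g <- crossprod(J, r); H <- crossprod(J)
    improved <- FALSE
    for (inner in 1:10) {
      delta <- tryCatch(
        as.vector(solve(H + lambda * diag(diag(H) + 1e-12,
                                          length(th)), -g)),
        error = function(e) rep(0, length(th)))
      th_new <- pmin(pmax(th + delta, lower), upper)
      r_new <- rfun(th_new); ssr_new <- sum(r_new^2)
      if (!is.null(trace_env))
        trace_env$trace <- rbind(trace_env$trace,
                                 c(unname(th_new), ssr_new))
      if (ssr_new < ssr) {
        step_rel <- max(abs(th_new - th) / pmax(abs(th), 1e-8))
        dssr_rel <- (ssr - ssr_new) / max(ssr, 1e-300)
        th <- th_new; r <- r_new; ssr <- ssr_new
        lambda <- max(lambda / 3, 1e-12)
        improved <- TRUE
        if (step_rel < 1e-6 || dssr_rel < 1e-10) converged <- TRUE
        break
      }
      lambda <- lambda * 10
    }
    if (!improved) { converged <- TRUE; break }  # no descent direction left
    if (converged) break
  }
  list(par = th, ssr = ssr, iterations = n_iter, converged = converged)
}

#' Estimate heat-transfer coefficients from a logger series
#'
#' Least-squares fit of the selected coefficients against a centre-probe
#' temperature series: the objective is the sum of squared differences
#' between the simulated and measured series on the logger's sample grid,
#' restricted to the earliest stage any free parameter influences and all
#' later stages. The forward solution before that point is computed once
#' and cached. The fit itself is deterministic given the data.
#'
#' After the fit, each parameter is screened for identifiability: the
#' parameter is perturbed to 0.5x and 1.5x its estimate and the maximum
#' absolute change of the predicted series is compared against
#' `sens_tol_K`. A parameter whose +/-50 percent perturbation moves the
#' prediction by less than this threshold (e.g. `h_st` in the large-Biot
#' steam stage) is flagged non-identifiable.
#'
#' @param data A [logger_dataset()].
#' @param base_config Run configuration list, see [default_config()].
#' @param free_params Non-empty character vector of coefficients to fit,
#'   subset of `h_d`, `h_smoke`, `h_amb`, `h_st`, `h_w`, `h_air`.
#' @param bounds Named list of `c(lower, upper)` per parameter. Defaults:
#'   `h_w` in \[1, 500\], `h_air` in \[0.5, 100\], others \[0.5, 5000\].
#' @param initial_guess Named numeric vector; defaults to half the
#'   schedule's current value for each parameter.
#' @param sens_tol_K Identifiability threshold (K), default 1.
#' @return List of class `"fit_result"`: `par` (named estimates,
#'   W/(m^2 K)), `objective` (SSR, K^2), `rmse` (K), `iterations`,
#'   `convergence` (logical), `trace` (data.frame of every objective
#'   evaluation; the accepted subsequence is non-increasing), `bounds`,
#'   `identifiable` (named logical), `window` (residual time window, s),
#'   `n_obs`.
#' @export
fit_coefficients <- function(data, base_config = default_config(),
                             free_params = c("h_w", "h_air"),
                             bounds = NULL, initial_guess = NULL,
                             sens_tol_K = 1) {
  if (length(free_params) == 0)
    stop("free_params must be non-empty", call. = FALSE)
  bad <- setdiff(free_params, names(.param_stages))
  if (length(bad))
    stop("unknown free parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!inherits(data, "logger_dataset"))
    stop("data must be a logger_dataset", call. = FALSE)
  default_bounds <- list(h_w = c(1, 500), h_air = c(0.5, 100))
  lower <- upper <- numeric(length(free_params))
  names(lower) <- names(upper) <- free_params
  for (p in free_params) {
    b <- bounds[[p]] %||% default_bounds[[p]] %||% c(0.5, 5000)
    lower[p] <- b[1]; upper[p] <- b[2]
  }
  sch <- build_inputs(base_config)$schedule
  th0 <- vapply(free_params, function(p) {
    g <- initial_guess[[p]]
    if (!is.null(g)) return(as.numeric(g))
    nm <- intersect(.param_stages[[p]], sch$stages$name)
    sch$stages$h_W_m2K[match(nm[1], sch$stages$name)] / 2
  }, numeric(1))

  fm <- .forward_model(data, base_config, free_params)
  tr <- new.env(parent = emptyenv()); tr$trace <- NULL
  rfun <- function(th) {
    names(th) <- free_params
    fm$predict_series(as.list(th)) - fm$meas_T
  }
  r0 <- rfun(th0)
  tr$trace <- rbind(tr$trace, c(unname(th0), sum(r0^2)))
  fit <- .lm_fit(rfun, th0, lower, upper, trace_env = tr)
  est <- stats::setNames(fit$par, free_params)

  base_pred <- fm$predict_series(as.list(est))
  identifiable <- vapply(free_params, function(p) {
    lo <- est; hi <- est
    lo[p] <- max(0.5 * est[p], lower[p])
    hi[p] <- min(1.5 * est[p], upper[p])
    d <- max(abs(fm$predict_series(as.list(hi)) -
                   fm$predict_series(as.list(lo))))
    d > sens_tol_K
  }, logical(1))

  trace_df <- as.data.frame(tr$trace)
  names(trace_df) <- c(free_params, "ssr")
  structure(list(par = est, objective = fit$ssr,
                 rmse = sqrt(fit$ssr / length(fm$meas_T)),
                 iterations = fit$iterations, convergence = fit$converged,
                 trace = trace_df,
                 bounds = list(lower = lower, upper = upper),
                 identifiable = identifiable,
                 window = range(fm$meas_t), n_obs = length(fm$meas_T)),
            class = "fit_result")
}

#' @export
#' @method print fit_result
print.fit_result <- function(x, ...) {
  cat("fit_result:",
      paste(sprintf("%s = %.3f", names(x$par), x$par), collapse = ", "),
      "W/(m^2 K)\n")
  cat(sprintf("  SSR = %.4g K^2, RMSE = %.3f K over %d samples in [%g, %g] s\n",
              x$objective, x$rmse, x$n_obs, x$window[1], x$window[2]))
  cat("  converged:", x$convergence, "| identifiable:",
      paste(sprintf("%s=%s", names(x$identifiable), x$identifiable),
            collapse = " "), "\n")
  invisible(x)
}
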