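#' A single process stage
#'
#' @param name Stage name (free text; the default industrial scenario uses
#'   `drying`, `smoking`, `transfer1`, `steam_cooking`, `water_cooling`,
#'   `transfer2`, `air_cooling`).
#' @param duration_s Stage duration (s), non-negative.
#' @param T_process_K Process medium temperature during the stage (K).
#' @param h_W_m2K Convective heat-transfer coefficient (W/(m^2 K)).
#' @return A one-row data.frame.
#' @export
process_stage <- function(name, duration_s, T_process_K, h_W_m2K) {
  if (!is.character(name) || length(name) != 1 || !nzchar(name))
    stop("stage name must be a non-empty string", call. = FALSE)
  if (!is.finite(duration_s) || duration_s < 0)
    stop(sprintf("stage '%s': duration must be >= 0 s", name), call. = FALSE)
  if (!is.finite(h_W_m2K) || h_W_m2K <= 0)
    stop(sprintf("stage '%s': h must be > 0", name), call. = FALSE)
  if (!is.finite(T_process_K) || T_process_K <= 0)
    stop(sprintf("stage '%s': process temperature must be > 0 K", name),
         call. = FALSE)
  data.frame(name = name, duration_s = as.numeric(duration_s),
             T_process_K = as.numeric(T_process_K),
             h_W_m2K = as.numeric(h_W_m2K), stringsAsFactors = FALSE)
}

#' An ordered multistage process schedule
#'
#' Stacks stages into piecewise-constant functions of time, `h(t)` and
#' `Tp(t)`. Zero-duration stages are elided. Stage windows are half-open
#' `[start, end)`; the final instant of the schedule is included. Boundary
#' times are exact cumulative sums of the stated durations.
#'
#' @param stages A list of [process_stage()] rows (or a data.frame with the
#'   same columns).
#' @return An object of class `"process_schedule"` with elements `stages`
#'   (data.frame) and `boundaries` (numeric, length nstages + 1, starting
#'   at 0).
#' @export
#' @examples
#' sch <- process_schedule(list(
#'   process_stage("heat", 600, 351.15, 2000),
#'   process_stage("cool", 1200, 276.15, 12)))
#' h_at(sch, c(0, 599, 600, 1800))
process_schedule <- function(stages) {
  if (is.data.frame(stages)) stages <- list(stages)
  df <- do.call(rbind, lapply(stages, function(s) {
    process_stage(s$name, s$duration_s, s$T_process_K, s$h_W_m2K)
  }))
  df <- df[df$duration_s > 0, , drop = FALSE]
  if (nrow(df) == 0)
    stop("schedule needs at least one stage of positive duration",
         call. = FALSE)
  rownames(df) <- NULL
  structure(list(stages = df,
                 boundaries = c(0, cumsum(df$duration_s))),
            class = "process_schedule")
}

#' Default "Hamburgerryg" schedule
#'
#' The seven-stage industrial scenario: drying and smoking (sharing one
#' chamber and one heat-transfer coefficient), transfer to the cooking
#' chamber, steam-cooking, water-cooling, transfer to the cooling room, and
#' air-cooling. The combined drying-smoking time `t_ds` is fixed by the
#' process recipe; only its split between drying and smoking is an
#' assumption (equal split by default) and `t_d + t_smoke == t_ds` is
#' enforced.
#'
#' @param t_d,t_smoke Drying and smoking durations (s).
#' @param t_ds Total drying-smoking duration (s); consistency-checked
#'   against `t_d + t_smoke`.
#' @param t_trans1,t_st,t_w,t_trans2,t_air Remaining stage durations (s).
#' @param T_d,T_smoke,T_amb,T_st,T_w,T_air Process temperatures (K).
#' @param h_d,h_smoke,h_amb,h_st,h_w,h_air Heat-transfer coefficients
#'   (W/(m^2 K)); smoking shares the drying coefficient by default.
#' @return A [process_schedule()] with total duration 84120 s under the
#'   defaults.
#' @export
#' @examples
#' sch <- default_schedule()
#' sch$boundaries  # 0 6300 12600 13800 21720 28920 30120 84120
default_schedule <- function(t_d = 6300, t_smoke = 6300, t_ds = 12600,
                             t_trans1 = 1200, t_st = 7920, t_w = 7200,
                             t_trans2 = 1200, t_air = 54000,
                             T_d = 333.15, T_smoke = 318.15,
                             T_amb = 298.15, T_st = 351.15,
                             T_w = 298.15, T_air = 276.15,
                             h_d = 20, h_smoke = h_d, h_amb = 8,
                             h_st = 2000, h_w = 80, h_air = 12) {
  if (abs(t_d + t_smoke - t_ds) > 1e-9)
    stop(sprintf("t_d + t_smoke = %g must equal t_ds = %g", t_d + t_smoke,
                 t_ds), call. = FALSE)
  process_schedule(list(
    list(name = "drying", duration_s = t_d, T_process_K = T_d,
         h_W_m2K = h_d),
    list(name = "smoking", duration_s = t_smoke, T_process_K = T_smoke,
         h_W_m2K = h_smoke),
    list(name = "transfer1", duration_s = t_trans1, T_process_K = T_amb,
         h_W_m2K = h_amb),
    list(name = "steam_cooking", duration_s = t_st, T_process_K = T_st,
         h_W_m2K = h_st),
    list(name = "water_cooling", duration_s = t_w, T_process_K = T_w,
         h_W_m2K = h_w),
    list(name = "transfer2", duration_s = t_trans2, T_process_K = T_amb,
         h_W_m2K = h_amb),
    list(name = "air_cooling", duration_s = t_air, T_process_K = T_air,
         h_W_m2K = h_air)))
}

.stage_index_at <- function(schedule, t) {
  b <- schedule$boundaries
  total <- b[length(b)]
  if (any(!is.finite(t)) || any(t < 0) || any(t > total))
    stop(sprintf("time outside schedule domain [0, %g]", total),
         call. = FALSE)
  # [start, end) windows, final boundary closed
  i <- findInterval(t, b, rightmost.closed = TRUE)
  pmin(i, nrow(schedule$stages))
}

#' Heat-transfer coefficient at a time
#'
#' @param schedule A [process_schedule()].
#' @param t Time(s) in seconds, within `[0, total duration]`.
#' @return h (W/(m^2 K)), vectorized over `t`.
#' @export
h_at <- function(schedule, t) {
  schedule$stages$h_W_m2K[.stage_index_at(schedule, t)]
}

#' Process temperature at a time
#'
#' @inheritParams h_at
#' @return Tp (K), vectorized over `t`.
#' @export
Tp_at <- function(schedule, t) {
  schedule$stages$T_process_K[.stage_index_at(schedule, t)]
}

#' Total schedule duration (s)
#' @inheritParams h_at
#' @export
total_duration <- function(schedule) {
  b <- schedule$boundaries
  b[length(b)]
}

#' Time window of a named stage
#'
#' @inheritParams h_at
#' @param name Stage name.
#' @return `c(start, end)` in seconds.
#' @export
stage_window <- function(schedule, name) {
  i <- match(name, schedule$stages$name)
  if (is.na(i)) stop("no stage named '", name, "'", call. = FALSE)
  c(schedule$boundaries[i], schedule$boundaries[i + 1])
}

#' Replace the heat-transfer coefficient of a named stage
#'
#' @inheritParams stage_window
#' @param h New coefficient (W/(m^2 K)).
#' @export
set_stage_h <- function(schedule, name, h) {
  i <- match(name, schedule$stages$name)
  if (any(is.na(i))) stop("no stage named '", name[is.na(i)][1], "'",
                          call. = FALSE)
  schedule$stages$h_W_m2K[i] <- h
  schedule
}

#' Replace the process temperature of a named stage
#'
#' @inheritParams stage_window
#' @param T_K New process temperature (K).
#' @export
set_stage_Tp <- function(schedule, name, T_K) {
  i <- match(name, schedule$stages$name)
  if (any(is.na(i))) stop("no stage named '", name[is.na(i)][1], "'",
                          call. = FALSE)
  schedule$stages$T_process_K[i] <- T_K
  schedule
}

#' Split a schedule at a time point
#'
#' Used by the calibration module to cache the forward solution up to the
#' first stage a free parameter influences.
#'
#' @inheritParams h_at
#' @param t Split time (s), strictly inside the schedule.
#' @return List with `head` and `tail` schedules; the tail's stages carry an
#'   attribute `t_start = t`.
#' @export
split_schedule <- function(schedule, t) {
  total <- total_duration(schedule)
  if (t <= 0 || t >= total)
    stop("split time must lie strictly inside (0, total duration)",
         call. = FALSE)
  df <- schedule$stages
  b <- schedule$boundaries
  i <- findInterval(t, b, rightmost.closed = TRUE)
  head_df <- df[seq_len(i), , drop = FALSE]
  head_df$duration_s[i] <- t - b[i]
  tail_df <- df[i:nrow(df), , drop = FALSE]
  tail_df$duration_s[1] <- b[i + 1] - t
  head_df <- head_df[head_df$duration_s > 0, , drop = FALSE]
  tail_df <- tail_df[tail_df$duration_s > 0, , drop = FALSE]
  head <- process_schedule(split(head_df, seq_len(nrow(head_df))))
  tail <- process_schedule(split(tail_df, seq_len(nrow(tail_df))))
  attr(tail, "t_start") <- t
  list(head = head, tail = tail)
}

#' @export
#' @method print process_schedule
print.process_schedule <- function(x, ...) {
  cat("process_schedule:", nrow(x$stages), "stages, total",
      total_duration(x), "s\n")
  df <- x$stages
  df$start_s <- x$boundaries[-length(x$boundaries)]
  print(df, row.names = FALSE)
  invisible(x)
}
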