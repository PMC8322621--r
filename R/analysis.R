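# Turning-response analysis chain: merge the key-value event log with the
# FicTrac stream on the shared experiment clock, label every camera frame
# with its trial/condition/epoch, convert heading to smoothed yaw velocity,
# average per fly and then across flies, fold counterclockwise responses
# onto clockwise ones, and summarize as mean +/- SEM tuning curves and
# bar-following profiles. Closed-loop trials are always excluded from tuning
# computations.

#' Annotate FicTrac frames with trial, condition and epoch
#'
#' Reconstructs the trial timeline from the server events of the key-value
#' log (`trial-start`, `motion-start`, `motion-stop`, `trial-end`) and labels
#' every camera frame by the trial containing its timestamp. Epochs are
#' half-open: a frame exactly at motion onset belongs to the motion epoch,
#' `[on, off)`. Frames outside any trial get epoch `"none"`.
#'
#' @param event_log Event-log tibble (from [run_experiment()] or
#'   [read_event_log()]).
#' @param frames FicTrac frame tibble on the same experiment clock.
#' @param format A [fictrac_format()].
#' @return The frames with added columns `t_s`, `trial_index`,
#'   `condition_id`, `epoch`.
#' @export
merge_logs <- function(event_log, frames, format = fictrac_format()) {
  sv <- event_log[event_log$source == "server" &
                  event_log$key %in% c("trial-start", "motion-start",
                                       "motion-stop", "trial-end"), ]
  sv <- sv[order(sv$t_us), ]
  starts <- sv[sv$key == "trial-start", ]
  ons    <- sv[sv$key == "motion-start", ]
  offs   <- sv[sv$key == "motion-stop", ]
  ends   <- sv[sv$key == "trial-end", ]
  if (!(nrow(starts) > 0 && nrow(starts) == nrow(ons) &&
        nrow(starts) == nrow(offs) && nrow(starts) == nrow(ends)))
    stop("merge_logs(): event log does not contain a complete trial structure")
  trial_tbl <- tibble::tibble(
    trial_index = seq_len(nrow(starts)),
    condition_id = starts$value,
    t_start_s = starts$t_us / 1e6, t_on_s = ons$t_us / 1e6,
    t_off_s = offs$t_us / 1e6, t_end_s = ends$t_us / 1e6
  )
  t_s <- frames[[format$timestamp]] / 1000
  if (max(t_s) <= min(trial_tbl$t_start_s) || min(t_s) >= max(trial_tbl$t_end_s))
    stop("merge_logs(): event log and treadmill data do not overlap in time")
  idx <- findInterval(t_s, trial_tbl$t_start_s)
  in_trial <- idx >= 1 & t_s < trial_tbl$t_end_s[pmax(idx, 1)]
  trial_index <- ifelse(in_trial, idx, NA_integer_)
  epoch <- rep("none", length(t_s))
  ti <- pmax(idx, 1)
  epoch[in_trial & t_s <  trial_tbl$t_on_s[ti]] <- "pre"
  epoch[in_trial & t_s >= trial_tbl$t_on_s[ti] & t_s < trial_tbl$t_off_s[ti]] <- "motion"
  epoch[in_trial & t_s >= trial_tbl$t_off_s[ti]] <- "post"
  out <- frames
  out$t_s <- t_s
  out$trial_index <- trial_index
  out$condition_id <- ifelse(in_trial, trial_tbl$condition_id[ti], NA_character_)
  out$epoch <- epoch
  attr(out, "trial_table") <- trial_tbl
  attr(out, "fictrac_format") <- format
  out
}

#' Centered sliding-window average
#'
#' Moving average over an odd window of camera frames (default 5). At the
#' series edges the window truncates to the available samples, so the output
#' has the same length as the input and a constant series is unchanged.
#'
#' @param x Numeric vector.
#' @param window Odd window length in samples, >= 1.
#' @return Numeric vector, same length as `x`.
#' @examples
#' smooth_sliding(c(0, 0, 5, 0, 0))  # 5/3, 5/4, 1, 5/4, 5/3
#' @export
smooth_sliding <- function(x, window = 5) {
  if (window < 1 || window %% 2 == 0)
    stop("smooth_sliding(): window must be odd and >= 1")
  n <- length(x)
  if (window == 1 || n == 0) return(x)
  k <- (window - 1) / 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - k, 1)
  hi <- pmin(seq_len(n) + k, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Per-trial turning time series of one experiment
#'
#' Converts a run's FicTrac stream to yaw velocity, smooths it with the
#' sliding window, and returns one row per camera frame inside a trial,
#' aligned to motion onset. Walking speed is included for completeness.
#'
#' @param run An `experiment_run` from [run_experiment()], or a list with
#'   elements `event_log`, `fictrac`, and `trials`.
#' @param window Sliding-window length in camera frames (odd).
#' @param sphere A [sphere_spec()] for the walking-speed conversion.
#' @return Tibble: `trial_index`, `condition_id`, `stim_kind`, `direction`,
#'   `omega`, `lambda`, `tf`, `epoch`, `t_s`, `t_rel_s` (relative to motion
#'   onset), `rel_frame`, `yaw_deg_s`, `walk_mm_s`.
#' @export
trial_time_series <- function(run, window = 5, sphere = sphere_spec()) {
  stopifnot(!is.null(run$fictrac))
  fmt <- attr(run$fictrac, "fictrac_format")
  if (is.null(fmt)) fmt <- fictrac_format()
  merged <- merge_logs(run$event_log, run$fictrac, fmt)
  yaw <- yaw_velocity(run$fictrac, fmt)
  walk <- translational_speed(run$fictrac, sphere, fmt)
  keep <- !is.na(yaw)
  yaw_s <- smooth_sliding(yaw[keep], window)
  walk_s <- smooth_sliding(walk[keep], window)
  trial_tbl <- attr(merged, "trial_table")
  df <- tibble::tibble(
    t_s = merged$t_s[keep],
    trial_index = merged$trial_index[keep],
    condition_id = merged$condition_id[keep],
    epoch = merged$epoch[keep],
    yaw_deg_s = yaw_s,
    walk_mm_s = walk_s
  )
  df <- df[!is.na(df$trial_index), ]
  df$t_rel_s <- df$t_s - trial_tbl$t_on_s[df$trial_index]
  dt <- stats::median(run$fictrac[[fmt$delta_timestamp]])
  df$rel_frame <- as.integer(floor(df$t_rel_s / dt + 1e-9))
  meta <- run$trials[!duplicated(run$trials$condition_id),
                     c("condition_id", "stim_kind", "direction", "omega",
                       "lambda", "tf")]
  dplyr::left_join(df, meta, by = "condition_id")
}

#' Two-stage trial averaging: within fly, then across flies
#'
#' Stage 1 averages a fly's trials of each condition on the common
#' motion-locked frame grid; stage 2 averages the per-fly traces across
#' flies with equal weight per fly (a fly contributing more trials does not
#' count more).
#'
#' @param tts Row-bound [trial_time_series()] tables with a `fly_id` column.
#' @param value Column to average (default `yaw_deg_s`).
#' @return Tibble: `condition_id`, `rel_frame`, `t_rel_s`, `mean`, `sem`,
#'   `n_flies`.
#' @export
per_fly_then_population <- function(tts, value = "yaw_deg_s") {
  stopifnot("fly_id" %in% names(tts))
  per_fly <- tts |>
    dplyr::group_by(.data$fly_id, .data$condition_id, .data$rel_frame) |>
    dplyr::summarise(v = mean(.data[[value]]),
                     t_rel_s = mean(.data$t_rel_s), .groups = "drop")
  per_fly |>
    dplyr::group_by(.data$condition_id, .data$rel_frame) |>
    dplyr::summarise(
      t_rel_s = mean(.data$t_rel_s),
      mean = mean(.data$v),
      sem = stats::sd(.data$v) / sqrt(dplyr::n()),
      n_flies = dplyr::n(), .groups = "drop")
}

#' Fold counterclockwise responses onto clockwise ones
#'
#' Combined response `(cw + (-1) * ccw) / 2`: responses to counterclockwise
#' motion are scaled by -1 and averaged with the clockwise responses, which
#' cancels any direction-independent turning bias exactly.
#'
#' @param cw,ccw Numeric response traces on a common time grid.
#' @param t_cw,t_ccw Optional time grids; if both given they must match.
#' @return Combined numeric trace.
#' @export
combine_directions <- function(cw, ccw, t_cw = NULL, t_ccw = NULL) {
  if (length(cw) != length(ccw))
    stop("combine_directions(): traces must share a common grid")
  if (!is.null(t_cw) || !is.null(t_ccw)) {
    if (is.null(t_cw) || is.null(t_ccw) || length(t_cw) != length(t_ccw) ||
        any(abs(t_cw - t_ccw) > 1e-9))
      stop("combine_directions(): time grids do not match")
  }
  (cw - ccw) / 2
}

base_condition <- function(condition_id) sub("_(cw|ccw)$", "", condition_id)

# per-fly combined (direction-folded) mean turning during the motion epoch
per_fly_combined_means <- function(tts) {
  stopifnot("fly_id" %in% names(tts))
  open_loop <- tts[tts$stim_kind %in% c("grating", "bar"), ]
  per_trial <- open_loop[open_loop$epoch == "motion", ] |>
    dplyr::group_by(.data$fly_id, .data$condition_id, .data$direction,
                    .data$omega, .data$lambda, .data$tf, .data$stim_kind,
                    .data$trial_index) |>
    dplyr::summarise(yaw = mean(.data$yaw_deg_s), .groups = "drop")
  per_cond <- per_trial |>
    dplyr::group_by(.data$fly_id, .data$condition_id, .data$direction,
                    .data$omega, .data$lambda, .data$tf, .data$stim_kind) |>
    dplyr::summarise(yaw = mean(.data$yaw), .groups = "drop")
  per_cond$base_id <- base_condition(per_cond$condition_id)
  wide <- per_cond |>
    dplyr::group_by(.data$fly_id, .data$base_id, .data$stim_kind) |>
    dplyr::summarise(
      combined = combine_directions(.data$yaw[.data$direction == "cw"],
                                    .data$yaw[.data$direction == "ccw"]),
      omega = abs(.data$omega[1]), lambda = .data$lambda[1], tf = .data$tf[1],
      .groups = "drop")
  wide
}

#' Tuning curve: mean +/- SEM turning velocity per condition
#'
#' The full summary chain: per fly, the smoothed yaw velocity is averaged
#' over the motion epoch of every open-loop trial, trials of a condition are
#' averaged, and the two motion directions are folded together
#' ([combine_directions()]); across flies the combined per-fly means give
#' the curve's mean and SEM (`sd / sqrt(n_flies)`). Closed-loop trials are
#' excluded. The tuning parameter `x` is the temporal frequency for
#' lambda = 90 deg gratings of a temporal protocol, the spatial period for a
#' spatial protocol, or the bar speed for a bar protocol.
#'
#' @param tts Row-bound [trial_time_series()] tables with `fly_id`.
#' @param x One of `"tf"`, `"lambda"`, `"omega"`; what to put on the x axis.
#' @return A tibble of class `tuning_curve`: `x`, `base_id`, `mean`, `sem`,
#'   `n_flies`. With a single fly the SEM is `NA` (flagged by a warning).
#' @export
tuning_curve <- function(tts, x = c("tf", "lambda", "omega")) {
  x <- match.arg(x)
  wide <- per_fly_combined_means(tts)
  out <- wide |>
    dplyr::group_by(.data$base_id) |>
    dplyr::summarise(
      x = .data[[x]][1],
      mean = mean(.data$combined),
      sem = stats::sd(.data$combined) / sqrt(dplyr::n()),
      n_flies = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$x)
  if (any(out$n_flies < 2)) {
    warning("tuning_curve(): fewer than 2 flies; SEM undefined")
    out$sem[out$n_flies < 2] <- NA_real_
  }
  out <- out[, c("x", "base_id", "mean", "sem", "n_flies")]
  class(out) <- c("tuning_curve", class(out))
  out
}

#' Bar-following profile with the expected bar position
#'
#' Population-mean combined turning trace for each bar speed, time-locked to
#' sweep onset, with the deterministic bar-center trajectory attached for
#' plotting (the "expected position of the bar" overlay).
#'
#' @param tts Row-bound [trial_time_series()] tables with `fly_id`
#'   (bar-protocol trials).
#' @param sweep_span,bar_width Bar geometry used for the overlay, degrees.
#' @return Tibble: `speed` (deg/s), `t_rel_s`, `mean`, `sem`, `n_flies`,
#'   `bar_azimuth` (deg, CW convention).
#' @export
bar_profile <- function(tts, sweep_span = 175.5, bar_width = 45) {
  bars <- tts[tts$stim_kind == "bar", ]
  if (!nrow(bars)) stop("bar_profile(): no bar trials present")
  bars$speed <- abs(bars$omega)
  # fold direction at the trace level: negate CCW yaw, keep CW time base
  bars$yaw_folded <- ifelse(bars$direction == "cw", bars$yaw_deg_s,
                            -bars$yaw_deg_s)
  per_fly <- bars |>
    dplyr::group_by(.data$fly_id, .data$speed, .data$rel_frame) |>
    dplyr::summarise(v = mean(.data$yaw_folded),
                     t_rel_s = mean(.data$t_rel_s), .groups = "drop")
  pop <- per_fly |>
    dplyr::group_by(.data$speed, .data$rel_frame) |>
    dplyr::summarise(
      t_rel_s = mean(.data$t_rel_s),
      mean = mean(.data$v),
      sem = stats::sd(.data$v) / sqrt(dplyr::n()),
      n_flies = dplyr::n(), .groups = "drop")
  pop$bar_azimuth <- vapply(seq_len(nrow(pop)), function(i) {
    spec <- bar_sweep_spec(pop$speed[i], bar_width = bar_width,
                           sweep_span = sweep_span)
    bar_center_azimuth(spec, pop$t_rel_s[i])
  }, numeric(1))
  pop[order(pop$speed, pop$rel_frame), ]
}

#' Plot a tuning curve
#'
#' @param x A `tuning_curve`.
#' @param xlab Axis label.
#' @param ... Unused.
#' @return A ggplot object (mean +/- SEM on a log-spaced x axis).
#' @export
plot.tuning_curve <- function(x, xlab = "condition", ...) {
  ggplot2::ggplot(x, ggplot2::aes(x = .data$x, y = .data$mean)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           width = 0) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10(xlab) +
    ggplot2::labs(y = "turning velocity (deg/s)") +
    ggplot2::theme_minimal()
}

#' Run and analyze a multi-fly synthetic experiment
#'
#' Convenience wrapper for the full simulate-log-analyze pipeline: schedules
#' the protocol once, renders the per-condition drive table once, simulates
#' `n_flies` independent flies (fly seeds derived from `seed`), and returns
#' the per-frame time series, the tuning curve, and the per-fly runs.
#'
#' @param p A [protocol()].
#' @param n_flies Number of synthetic flies.
#' @param fly Template [fly_model()]; each fly gets its own derived seed.
#' @param geom A [display_geometry()].
#' @param transport A [transport_model()].
#' @param seed Master integer seed (trial order and fly seeds derive from it).
#' @param window Sliding-window length in camera frames.
#' @param x Tuning-curve x axis, as in [tuning_curve()].
#' @return List with `tts` (all flies' time series), `curve`
#'   (a `tuning_curve`), `trials`, and `runs`.
#' @export
run_tuning_experiment <- function(p, n_flies = 30, fly = fly_model(),
                                  geom = display_geometry(),
                                  transport = transport_model(), seed = 1L,
                                  window = 5,
                                  x = c("tf", "lambda", "omega")) {
  x <- match.arg(x)
  trials <- randomize_blocks(p, seed = seed)
  drives <- condition_drives(trials, geom)
  run0 <- run_experiment(trials, geom, transport, fly = NULL)
  runs <- vector("list", n_flies)
  tts_list <- vector("list", n_flies)
  for (i in seq_len(n_flies)) {
    f <- fly
    f$seed <- as.integer((seed * 1000L + i) %% .Machine$integer.max)
    run <- run0
    run$fictrac <- simulate_fly(f, trials, geom, drives = drives)
    runs[[i]] <- run
    tt <- trial_time_series(run, window = window)
    tt$fly_id <- i
    tts_list[[i]] <- tt
  }
  tts <- dplyr::bind_rows(tts_list)
  list(tts = tts, curve = tuning_curve(tts, x = x), trials = trials,
       runs = runs)
}
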