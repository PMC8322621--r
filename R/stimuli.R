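# Stimulus definitions and the three experimental protocols: square-wave
# gratings for temporal-frequency and spatial-period tuning, single bright-bar
# sweeps for object following, plus closed-loop scaffolding. Sign convention:
# azimuth 0 deg straight ahead, positive to the fly's right; positive angular
# velocity = clockwise (CW) = pattern moving toward positive azimuth.

#' Square-wave grating stimulus
#'
#' A periodic pattern of alternating bright and dark vertical bars on the
#' virtual cylinder, each bar spanning half a spatial period.
#'
#' @param spatial_period Spatial period lambda in degrees (one bright + one
#'   dark bar); must be > 0.
#' @param angular_velocity Signed angular velocity omega in deg/s; positive is
#'   clockwise (toward the fly's right).
#' @param bright_luminance,dark_luminance Luminances in `[0, 1]`.
#' @param phase0 Initial pattern phase in degrees; with the default 0 a bright
#'   bar starts at azimuth 0.
#' @return An object of class `grating_spec` (also `stimulus_spec`).
#' @examples
#' g <- grating_spec(spatial_period = 90, angular_velocity = 675)
#' temporal_frequency(g)  # 7.5 Hz
#' @export
grating_spec <- function(spatial_period, angular_velocity,
                         bright_luminance = 1, dark_luminance = 0,
                         phase0 = 0) {
  if (!isTRUE(spatial_period > 0)) stop("grating_spec(): spatial_period must be > 0")
  stopifnot(
    bright_luminance >= 0, bright_luminance <= 1,
    dark_luminance >= 0, dark_luminance <= 1
  )
  structure(
    list(spatial_period = spatial_period, angular_velocity = angular_velocity,
         bright_luminance = bright_luminance, dark_luminance = dark_luminance,
         phase0 = phase0),
    class = c("grating_spec", "stimulus_spec")
  )
}

#' Single bright-bar sweep stimulus
#'
#' One bright vertical bar crosses the display exactly once over a dark
#' background. The default sweep span of 175.5 deg is the visible azimuth
#' span of the default panel (about 130.5 deg) plus the bar width (45 deg),
#' so the bar starts fully off one edge and ends fully off the other.
#'
#' @param angular_speed Signed sweep velocity in deg/s; positive is clockwise.
#' @param bar_width Bar width in degrees of azimuth.
#' @param bar_luminance,background_luminance Luminances in `[0, 1]`; the
#'   background (and the pre/post screen) is dark by default.
#' @param sweep_span Total angular travel of the bar center, degrees.
#' @return An object of class `bar_sweep_spec` (also `stimulus_spec`).
#' @export
bar_sweep_spec <- function(angular_speed, bar_width = 45,
                           bar_luminance = 1, background_luminance = 0,
                           sweep_span = 175.5) {
  stopifnot(
    bar_width > 0, sweep_span >= bar_width,
    bar_luminance >= 0, bar_luminance <= 1,
    background_luminance >= 0, background_luminance <= 1
  )
  structure(
    list(angular_speed = angular_speed, bar_width = bar_width,
         bar_luminance = bar_luminance,
         background_luminance = background_luminance,
         sweep_span = sweep_span),
    class = c("bar_sweep_spec", "stimulus_spec")
  )
}

#' Closed-loop stimulus condition
#'
#' A grating whose orientation is coupled to the fly's turning:
#' each delivered update shifts the pattern by `coupling_gain` times the
#' fly's heading change. With gain -1 the pattern is stabilized on the
#' retina. These trials are scheduling/engine scaffolding; they are excluded
#' from tuning analyses.
#'
#' @param base Grating shown during the trial (a [grating_spec()]).
#' @param duration_ms Closed-loop epoch length; 3000 ms in behavioral use,
#'   30000 ms in the technical-verification mode.
#' @param coupling_gain Dimensionless coupling from fly heading change to
#'   pattern orientation change.
#' @return An object of class `closed_loop_spec` (also `stimulus_spec`).
#' @export
closed_loop_spec <- function(base = grating_spec(90, 0), duration_ms = 3000,
                             coupling_gain = -1) {
  stopifnot(inherits(base, "grating_spec"), duration_ms > 0)
  structure(
    list(base = base, duration_ms = duration_ms, coupling_gain = coupling_gain),
    class = c("closed_loop_spec", "stimulus_spec")
  )
}

#' Temporal frequency of a grating
#'
#' Angular speed divided by spatial period, `|omega| / lambda`, in Hz.
#'
#' @param g A [grating_spec()].
#' @return Temporal frequency in Hz.
#' @export
temporal_frequency <- function(g) {
  stopifnot(inherits(g, "grating_spec"))
  abs(g$angular_velocity) / g$spatial_period
}

#' Duration of a bar sweep
#'
#' `sweep_span / |angular_speed|`, in seconds.
#'
#' @param spec A [bar_sweep_spec()].
#' @return Duration in seconds.
#' @export
sweep_duration <- function(spec) {
  stopifnot(inherits(spec, "bar_sweep_spec"))
  if (spec$angular_speed == 0)
    stop("sweep_duration(): angular_speed must be nonzero")
  spec$sweep_span / abs(spec$angular_speed)
}

#' Bar center azimuth during a sweep
#'
#' The bar center starts at `-sign(omega) * sweep_span / 2` and travels with
#' velocity `omega`, crossing azimuth 0 at mid-sweep.
#'
#' @param spec A [bar_sweep_spec()].
#' @param t Time since motion onset, s (vectorized; clamped to the sweep).
#' @return Azimuth of the bar center, degrees.
#' @export
bar_center_azimuth <- function(spec, t) {
  stopifnot(inherits(spec, "bar_sweep_spec"))
  dur <- sweep_duration(spec)
  t <- pmin(pmax(t, 0), dur)
  -sign(spec$angular_speed) * spec$sweep_span / 2 + spec$angular_speed * t
}

#' Stimulus luminance at an azimuth and time
#'
#' Samples the ideal (continuous) stimulus: for a grating, a square wave in
#' `azimuth - omega * t - phase0`, bright over the first half of each spatial
#' period; for a bar sweep, `bar_luminance` inside the bar's current extent
#' and the background elsewhere. `t` is time since motion onset; callers
#' freeze `t` at 0 / the trial end during pre/post epochs (which for a bar
#' leaves the visible screen at uniform background, since the bar starts and
#' ends fully off-screen).
#'
#' @param spec A [grating_spec()] or [bar_sweep_spec()].
#' @param azimuth Azimuth(s), degrees.
#' @param t Time since motion onset, seconds (scalar).
#' @return Luminance value(s) in `[0, 1]`.
#' @export
luminance_at <- function(spec, azimuth, t = 0) UseMethod("luminance_at")

#' @export
luminance_at.grating_spec <- function(spec, azimuth, t = 0) {
  phase <- (azimuth - spec$angular_velocity * t - spec$phase0) %% spec$spatial_period
  ifelse(phase < spec$spatial_period / 2, spec$bright_luminance, spec$dark_luminance)
}

#' @export
luminance_at.bar_sweep_spec <- function(spec, azimuth, t = 0) {
  center <- bar_center_azimuth(spec, t)
  inside <- abs(azimuth - center) <= spec$bar_width / 2
  ifelse(inside, spec$bar_luminance, spec$background_luminance)
}

#' @export
luminance_at.closed_loop_spec <- function(spec, azimuth, t = 0) {
  luminance_at(spec$base, azimuth, t)
}

#' One trial: pre / motion / post epochs around a stimulus
#'
#' @param stimulus A stimulus spec. For bar sweeps the motion epoch is the
#'   sweep duration; for closed-loop specs it is `duration_ms`.
#' @param pre_ms,post_ms Stationary epochs bracketing the motion, ms.
#' @param motion_ms Motion epoch, ms; defaults to 3000 for gratings and to
#'   the stimulus-determined duration otherwise.
#' @param condition_id Label identifying the condition.
#' @return An object of class `trial_spec`.
#' @export
trial_spec <- function(stimulus, condition_id, pre_ms = 500, motion_ms = NULL,
                       post_ms = 500) {
  stopifnot(inherits(stimulus, "stimulus_spec"), pre_ms >= 0, post_ms >= 0)
  if (is.null(motion_ms)) {
    motion_ms <-
      if (inherits(stimulus, "bar_sweep_spec")) sweep_duration(stimulus) * 1000
      else if (inherits(stimulus, "closed_loop_spec")) stimulus$duration_ms
      else 3000
  }
  stopifnot(motion_ms >= 0)
  if (inherits(stimulus, "bar_sweep_spec")) {
    stopifnot(abs(motion_ms - sweep_duration(stimulus) * 1000) < 1e-6)
  }
  structure(
    list(stimulus = stimulus, condition_id = as.character(condition_id),
         pre_ms = pre_ms, motion_ms = motion_ms, post_ms = post_ms),
    class = "trial_spec"
  )
}

trial_duration_ms <- function(trial) trial$pre_ms + trial$motion_ms + trial$post_ms

#' Experimental protocol: a condition set presented in randomized blocks
#'
#' @param conditions List of [trial_spec()] objects, one per condition.
#' @param n_blocks Number of blocks; each block presents every condition
#'   exactly once in random order.
#' @param startup_delay_ms Delay before the first trial, ms.
#' @param rng_seed Integer seed for block randomization.
#' @param kind Optional label (`"temporal"`, `"spatial"`, `"bar"`, ...).
#' @return An object of class `protocol`.
#' @export
protocol <- function(conditions, n_blocks = 6, startup_delay_ms = 10000,
                     rng_seed = 1L, kind = "custom") {
  stopifnot(length(conditions) > 0, n_blocks >= 1, startup_delay_ms >= 0)
  stopifnot(all(vapply(conditions, inherits, logical(1), "trial_spec")))
  ids <- vapply(conditions, `[[`, character(1), "condition_id")
  if (anyDuplicated(ids)) stop("protocol(): condition_id values must be unique")
  structure(
    list(conditions = conditions, n_blocks = as.integer(n_blocks),
         startup_delay_ms = startup_delay_ms, rng_seed = as.integer(rng_seed),
         kind = kind),
    class = "protocol"
  )
}

#' @export
print.protocol <- function(x, ...) {
  cat(sprintf("<protocol:%s> %d conditions x %d blocks, startup delay %g s\n",
              x$kind, length(x$conditions), x$n_blocks, x$startup_delay_ms / 1000))
  invisible(x)
}

# Speed sets of the three protocols (deg/s).
.temporal_speeds <- c(22.5, 90, 180, 360, 675, 1350, 2700)
.spatial_periods <- c(5, 10, 20, 30, 60, 90, 120)
.bar_speeds      <- c(22.5, 90, 180, 360, 675, 1350)

#' Build one of the three standard protocols
#'
#' * `"temporal"`: temporal-frequency tuning — lambda = 90 deg gratings at
#'   omega = 22.5, 90, 180, 360, 675, 1350, 2700 deg/s in both directions
#'   (14 conditions; temporal frequencies 0.25 ... 30 Hz, the 30 Hz condition
#'   being the flicker control at half the display refresh rate).
#' * `"spatial"`: spatial-period tuning — lambda = 5, 10, 20, 30, 60, 90,
#'   120 deg, all at a temporal frequency of 7.5 Hz, both directions
#'   (14 conditions; angular speeds 37.5 ... 900 deg/s).
#' * `"bar"`: object following — a single bright 45 deg bar sweeping once at
#'   omega = 22.5, 90, 180, 360, 675, 1350 deg/s in each direction
#'   (12 conditions; trial durations 0.13 ... 7.8 s).
#'
#' Grating trials run 500 ms pre / 3 s motion / 500 ms post; bar trials use
#' the sweep duration as the motion epoch with a dark screen pre/post.
#'
#' @param kind One of `"temporal"`, `"spatial"`, `"bar"`.
#' @param n_blocks,startup_delay_ms,rng_seed Passed to [protocol()].
#' @param sweep_span Bar travel in degrees (bar protocol only).
#' @return A [protocol()].
#' @examples
#' p <- build_protocol("temporal")
#' length(p$conditions)  # 14
#' @export
build_protocol <- function(kind = c("temporal", "spatial", "bar"),
                           n_blocks = 6, startup_delay_ms = 10000,
                           rng_seed = 1L, sweep_span = 175.5) {
  kind <- match.arg(kind)
  conds <- switch(kind,
    temporal = {
      grid <- expand.grid(speed = .temporal_speeds, dir = c(1, -1))
      lapply(seq_len(nrow(grid)), function(i) {
        g <- grating_spec(90, grid$dir[i] * grid$speed[i])
        trial_spec(g, condition_id = sprintf(
          "tf%g_%s", temporal_frequency(g), if (grid$dir[i] > 0) "cw" else "ccw"))
      })
    },
    spatial = {
      grid <- expand.grid(lambda = .spatial_periods, dir = c(1, -1))
      lapply(seq_len(nrow(grid)), function(i) {
        g <- grating_spec(grid$lambda[i], grid$dir[i] * 7.5 * grid$lambda[i])
        trial_spec(g, condition_id = sprintf(
          "sp%g_%s", grid$lambda[i], if (grid$dir[i] > 0) "cw" else "ccw"))
      })
    },
    bar = {
      grid <- expand.grid(speed = .bar_speeds, dir = c(1, -1))
      lapply(seq_len(nrow(grid)), function(i) {
        b <- bar_sweep_spec(grid$dir[i] * grid$speed[i], sweep_span = sweep_span)
        trial_spec(b, condition_id = sprintf(
          "bar%g_%s", grid$speed[i], if (grid$dir[i] > 0) "cw" else "ccw"))
      })
    }
  )
  protocol(conds, n_blocks = n_blocks, startup_delay_ms = startup_delay_ms,
           rng_seed = rng_seed, kind = kind)
}

trial_info <- function(tr) {
  s <- tr$stimulus
  if (inherits(s, "grating_spec")) {
    tibble::tibble(
      condition_id = tr$condition_id, stim_kind = "grating",
      direction = ifelse(s$angular_velocity >= 0, "cw", "ccw"),
      omega = s$angular_velocity, lambda = s$spatial_period,
      tf = temporal_frequency(s)
    )
  } else if (inherits(s, "bar_sweep_spec")) {
    tibble::tibble(
      condition_id = tr$condition_id, stim_kind = "bar",
      direction = ifelse(s$angular_speed >= 0, "cw", "ccw"),
      omega = s$angular_speed, lambda = NA_real_, tf = NA_real_
    )
  } else {
    tibble::tibble(
      condition_id = tr$condition_id, stim_kind = "closed_loop",
      direction = NA_character_, omega = NA_real_, lambda = NA_real_,
      tf = NA_real_
    )
  }
}

condition_table <- function(p) {
  dplyr::bind_rows(lapply(p$conditions, trial_info))
}

#' Randomize a protocol into an ordered, scheduled trial list
#'
#' Concatenates `n_blocks` independent uniform permutations of the condition
#' list (every condition appears exactly once per block) and computes planned
#' start/epoch times from the startup delay and trial durations. Optionally a
#' closed-loop trial is interleaved after each block. Deterministic for a
#' fixed seed; the global RNG state is left untouched.
#'
#' @param p A [protocol()].
#' @param seed Integer seed; defaults to the protocol's `rng_seed`.
#' @param closed_loop Optional [closed_loop_spec()] appended after each block.
#' @return A tibble with one row per scheduled trial: `trial_index`, `block`,
#'   `condition_id`, stimulus descriptors, epoch times in ms
#'   (`t_start_ms`, `t_motion_on_ms`, `t_motion_off_ms`, `t_end_ms`) and a
#'   `trial` list-column of [trial_spec()] objects.
#' @examples
#' trials <- randomize_blocks(build_protocol("temporal"))
#' nrow(trials)  # 84
#' @export
randomize_blocks <- function(p, seed = p$rng_seed, closed_loop = NULL) {
  stopifnot(inherits(p, "protocol"))
  if (length(p$conditions) == 0) stop("randomize_blocks(): empty condition list")
  n_cond <- length(p$conditions)
  cl_trial <- if (!is.null(closed_loop)) {
    stopifnot(inherits(closed_loop, "closed_loop_spec"))
    trial_spec(closed_loop, condition_id = "closed_loop")
  }
  order_all <- withr::with_seed(seed, {
    unlist(lapply(seq_len(p$n_blocks), function(b) sample.int(n_cond)), use.names = FALSE)
  })
  trials <- list(); blocks <- integer(0)
  idx <- 1
  for (b in seq_len(p$n_blocks)) {
    ord <- order_all[((b - 1) * n_cond + 1):(b * n_cond)]
    for (j in ord) {
      trials[[idx]] <- p$conditions[[j]]; blocks[idx] <- b; idx <- idx + 1
    }
    if (!is.null(cl_trial)) {
      trials[[idx]] <- cl_trial; blocks[idx] <- b; idx <- idx + 1
    }
  }
  info <- dplyr::bind_rows(lapply(trials, function(tr) {
    ct <- trial_info(tr)
    ct$pre_ms <- tr$pre_ms; ct$motion_ms <- tr$motion_ms; ct$post_ms <- tr$post_ms
    ct
  }))
  dur <- vapply(trials, trial_duration_ms, numeric(1))
  t_start <- p$startup_delay_ms + cumsum(c(0, dur[-length(dur)]))
  tibble::tibble(
    trial_index = seq_along(trials),
    block = blocks,
    info,
    t_start_ms = t_start,
    t_motion_on_ms = t_start + info$pre_ms,
    t_motion_off_ms = t_start + info$pre_ms + info$motion_ms,
    t_end_ms = t_start + dur,
    trial = trials
  )
}
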