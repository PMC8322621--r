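# A synthetic walking fly with a temporal-frequency-tuned optomotor response.
# The simulator consumes the *rendered* stimulus (through the net-motion
# index of each condition's space-time diagram), not the nominal angular
# velocity, so a grating at half the display refresh rate — pure flicker —
# correctly drives no net turning.

#' Synthetic fly model
#'
#' Parameters of the simulated walking fly. The turning drive follows a
#' log-Gaussian tuning over temporal frequency (the minimal unimodal shape
#' consistent with an optomotor optimum); the analysis pipeline never assumes
#' this form. Defaults: optimum at 4 Hz with peak turning 50 deg/s, a 50 ms
#' response latency, heavy per-frame motor noise, forward walking around
#' 10 mm/s, and a 180 Hz camera.
#'
#' @param peak_gain Turning velocity at the tuning optimum, deg/s.
#' @param optimal_tf Temporal-frequency optimum, Hz.
#' @param tuning_log_width Log-Gaussian tuning width (dimensionless).
#' @param response_latency_ms Stimulus-to-turning latency, ms.
#' @param motor_noise_sd Per-camera-frame yaw noise SD, deg/s.
#' @param forward_speed_mean,forward_speed_sd Forward walking speed, mm/s.
#' @param camera_rate Treadmill camera rate, Hz.
#' @param seed Integer seed for the fly's noise.
#' @param bar_midline_gating If `TRUE`, bar-sweep turning is driven only
#'   after the bar crosses the visual midline (progressive motion); off by
#'   default.
#' @return An object of class `fly_model`.
#' @export
fly_model <- function(peak_gain = 50, optimal_tf = 4, tuning_log_width = 1.2,
                      response_latency_ms = 50, motor_noise_sd = 100,
                      forward_speed_mean = 10, forward_speed_sd = 3,
                      camera_rate = 180, seed = 1L,
                      bar_midline_gating = FALSE) {
  stopifnot(peak_gain >= 0, optimal_tf > 0, tuning_log_width > 0,
            response_latency_ms >= 0, motor_noise_sd >= 0,
            forward_speed_mean >= 0, forward_speed_sd >= 0, camera_rate > 0)
  structure(
    list(peak_gain = peak_gain, optimal_tf = optimal_tf,
         tuning_log_width = tuning_log_width,
         response_latency_ms = response_latency_ms,
         motor_noise_sd = motor_noise_sd,
         forward_speed_mean = forward_speed_mean,
         forward_speed_sd = forward_speed_sd,
         camera_rate = camera_rate, seed = as.integer(seed),
         bar_midline_gating = isTRUE(bar_midline_gating)),
    class = "fly_model"
  )
}

#' Optomotor turning gain at a temporal frequency
#'
#' Log-Gaussian tuning:
#' `peak_gain * exp(-(ln(tf / optimal_tf))^2 / (2 * width^2))`, with gain 0
#' at `tf = 0` (the limit of the log-Gaussian).
#'
#' @param fly A [fly_model()].
#' @param tf Temporal frequency, Hz (vectorized, >= 0).
#' @return Turning drive in deg/s.
#' @export
optomotor_gain <- function(fly, tf) {
  stopifnot(all(tf >= 0))
  out <- numeric(length(tf))
  pos <- tf > 0
  out[pos] <- fly$peak_gain *
    exp(-(log(tf[pos] / fly$optimal_tf))^2 / (2 * fly$tuning_log_width^2))
  out
}

#' Rendered-motion drive of each condition
#'
#' For every unique condition in a scheduled trial list, renders a short
#' space-time diagram of the motion epoch and computes its signed
#' [net_motion_index()]. The sign is the direction a motion-sensitive
#' observer of the *display* would report and the gate is 0 when the
#' rendered pattern carries no net motion (the aliased half-refresh-rate
#' condition), so the synthetic fly responds to what is actually shown.
#'
#' @param trials Scheduled trial tibble from [randomize_blocks()].
#' @param geom A [display_geometry()].
#' @param gate_threshold Minimum `|net_motion_index|` counted as real motion.
#' @return Tibble: `condition_id`, `net_motion`, `drive_sign`, `gate`.
#' @export
condition_drives <- function(trials, geom = display_geometry(),
                             gate_threshold = 0.2) {
  first <- !duplicated(trials$condition_id)
  rows <- lapply(which(first), function(i) {
    tr <- trials$trial[[i]]
    if (inherits(tr$stimulus, "bar_sweep_spec")) {
      # a single sweep always carries net motion in its sweep direction;
      # rendering adds nothing, so the drive is taken from the kinematics
      return(tibble::tibble(condition_id = tr$condition_id,
                            net_motion = sign(tr$stimulus$angular_speed),
                            drive_sign = sign(tr$stimulus$angular_speed),
                            gate = 1))
    }
    if (!inherits(tr$stimulus, "grating_spec")) {
      return(tibble::tibble(condition_id = tr$condition_id, net_motion = 0,
                            drive_sign = 0, gate = 0))
    }
    probe <- trial_spec(tr$stimulus, tr$condition_id, pre_ms = 0,
                        motion_ms = min(tr$motion_ms, 1000), post_ms = 0)
    nmi <- net_motion_index(space_time(probe, geom))
    tibble::tibble(
      condition_id = tr$condition_id, net_motion = nmi,
      drive_sign = ifelse(abs(nmi) > gate_threshold, sign(nmi), 0),
      gate = as.numeric(abs(nmi) > gate_threshold)
    )
  })
  dplyr::bind_rows(rows)
}

# effective TF used for the bar drive: the sweep treated as one cycle of a
# 90 deg-period pattern
bar_effective_tf <- function(omega) abs(omega) / 90

#' Simulate a walking fly through a scheduled experiment
#'
#' Generates FicTrac-format camera frames at the fly's camera rate across
#' the whole experiment. During each motion epoch (shifted by the response
#' latency) the heading increments at the condition's drive velocity —
#' `drive_sign * optomotor_gain(tf)` for gratings, gated by the rendered net
#' motion; for bar sweeps the drive uses an effective temporal frequency of
#' `|omega| / 90 deg` and is optionally gated to the post-midline half of the
#' sweep — plus Gaussian motor noise on every frame. Outside motion epochs
#' only the noise remains. Forward displacement is drawn around the mean
#' walking speed and encoded as sphere rotation per camera frame.
#'
#' @param fly A [fly_model()].
#' @param trials Scheduled trial tibble from [randomize_blocks()].
#' @param geom A [display_geometry()].
#' @param drives Optional precomputed [condition_drives()] table (rendering
#'   the conditions once and reusing the table across flies is much faster).
#' @param sphere A [sphere_spec()].
#' @param format A [fictrac_format()].
#' @return A FicTrac frame tibble (25 columns) that passes
#'   [validate_fictrac()], with the format attached as an attribute.
#' @export
simulate_fly <- function(fly, trials, geom = display_geometry(),
                         drives = NULL, sphere = sphere_spec(),
                         format = fictrac_format()) {
  stopifnot(inherits(fly, "fly_model"), nrow(trials) > 0)
  if (is.null(drives)) drives <- condition_drives(trials, geom)
  dt <- 1 / fly$camera_rate
  total_s <- max(trials$t_end_ms) / 1000
  n <- ceiling(total_s * fly$camera_rate)
  t_frame <- seq_len(n) * dt                      # frame timestamps, s
  # drive evaluated at the mid-point of each inter-frame interval, delayed
  t_eval <- t_frame - dt / 2 - fly$response_latency_ms / 1000

  drive <- numeric(n)
  dr <- drives[match(trials$condition_id, drives$condition_id), ]
  vis_half <- unname(visible_field(geom)["azimuth"]) / 2
  for (i in seq_len(nrow(trials))) {
    on_s <- trials$t_motion_on_ms[i] / 1000
    off_s <- trials$t_motion_off_ms[i] / 1000
    idx <- t_eval >= on_s & t_eval < off_s
    if (!any(idx)) next
    kind <- trials$stim_kind[i]
    if (kind == "grating") {
      drive[idx] <- dr$drive_sign[i] * optomotor_gain(fly, trials$tf[i]) *
        dr$gate[i]
    } else if (kind == "bar") {
      spec <- trials$trial[[i]]$stimulus
      g <- dr$gate[i] * dr$drive_sign[i] *
        optomotor_gain(fly, bar_effective_tf(trials$omega[i]))
      if (fly$bar_midline_gating) {
        center <- bar_center_azimuth(spec, t_eval[idx] - on_s)
        # progressive (front-to-back) half: bar past the midline
        past <- sign(spec$angular_speed) * center > 0
        drive[idx] <- g * as.numeric(past)
      } else {
        on_screen <- abs(bar_center_azimuth(spec, t_eval[idx] - on_s)) <=
          vis_half + spec$bar_width / 2
        drive[idx] <- g * as.numeric(on_screen)
      }
    }
    # closed-loop trials: base pattern stationary, no open-loop drive
  }

  sim <- withr::with_seed(fly$seed, {
    noise <- if (fly$motor_noise_sd > 0)
      stats::rnorm(n, 0, fly$motor_noise_sd) else numeric(n)
    fwd <- pmax(0, stats::rnorm(n, fly$forward_speed_mean, fly$forward_speed_sd))
    list(noise = noise, fwd = fwd)
  })

  dheading_rad <- (drive + sim$noise) * dt * pi / 180
  heading <- (cumsum(dheading_rad)) %% (2 * pi)
  speed_rad_per_frame <- sim$fwd * dt / (sphere$diameter / 2)

  m <- matrix(0, nrow = n, ncol = format$n_cols)
  m[, format$frame] <- seq_len(n)
  m[, format$heading] <- heading
  m[, format$speed] <- speed_rad_per_frame
  m[, format$timestamp] <- t_frame * 1000       # ms
  m[, format$delta_timestamp] <- dt             # s
  frames <- tibble::as_tibble(m, .name_repair = ~ paste0("v", seq_len(format$n_cols)))
  attr(frames, "fictrac_format") <- format
  validate_fictrac(frames, format)
  frames
}
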