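# Event-based trial execution on a simulated clock with an injectable
# transport. The "server" emits parameter updates at trial boundaries (and
# orientation updates during closed-loop trials); the "client" renders one
# frame per display refresh, always showing the latest *delivered*
# parameters — if an update has not arrived by the frame deadline the
# previous content is rendered again and the frame is logged as delayed.
# Server and client share one simulated clock (integer microseconds since
# experiment start; exported as ms).

US_PER_MS <- 1000

#' Simulated message transport between server and display client
#'
#' One-way latencies are drawn per message: either a fixed value
#' (`jitter = "none"`) or exponentially distributed with the given mean
#' (`jitter = "exponential"`). Delivery is in-order. `spike_every`/`spike_ms`
#' inject a deterministic extra delay into every k-th per-frame content
#' request — the hook used to construct exact frame-drop scenarios.
#'
#' @param latency_mean_ms Mean one-way latency, ms (>= 0).
#' @param jitter `"none"` (constant latency) or `"exponential"`.
#' @param seed Integer seed for latency draws.
#' @param spike_every Optional integer k: every k-th frame request is delayed.
#' @param spike_ms Extra round-trip delay injected on spiked requests, ms.
#' @return An object of class `transport_model`.
#' @export
transport_model <- function(latency_mean_ms = 0, jitter = c("none", "exponential"),
                            seed = 1L, spike_every = NULL, spike_ms = 0) {
  jitter <- match.arg(jitter)
  stopifnot(latency_mean_ms >= 0, spike_ms >= 0)
  if (!is.null(spike_every)) stopifnot(spike_every >= 1)
  structure(
    list(latency_mean_ms = latency_mean_ms, jitter = jitter,
         seed = as.integer(seed), spike_every = spike_every,
         spike_ms = spike_ms),
    class = "transport_model"
  )
}

# n one-way latency draws (ms) on an isolated RNG stream
draw_one_way <- function(transport, n, stream = 0L) {
  if (n == 0) return(numeric(0))
  if (transport$jitter == "none" || transport$latency_mean_ms == 0) {
    rep(transport$latency_mean_ms, n)
  } else {
    withr::with_seed(transport$seed + stream,
                     stats::rexp(n, rate = 1 / transport$latency_mean_ms))
  }
}

spike_extra_ms <- function(transport, idx) {
  if (is.null(transport$spike_every)) return(numeric(length(idx)))
  ifelse(idx %% transport$spike_every == 0, transport$spike_ms, 0)
}

#' Closed-loop stimulus update rule
#'
#' The server shifts the stimulus orientation by the fly's heading change
#' scaled by the coupling gain: `orientation + gain * fly_delta_heading`.
#' With gain -1 a fly turn of +10 deg moves the stimulus by -10 deg,
#' stabilizing the pattern on the retina.
#'
#' @param orientation Current stimulus orientation, deg.
#' @param fly_delta_heading Fly heading change since the last update, deg.
#' @param gain Dimensionless coupling gain.
#' @return Updated orientation, deg.
#' @export
closed_loop_update <- function(orientation, fly_delta_heading, gain) {
  orientation + gain * fly_delta_heading
}

#' Simulate the coupled fly-stimulus closed loop
#'
#' Discrete-time dynamics of one closed-loop trial at display-frame
#' resolution: each step the stimulus moves at its base angular velocity
#' plus the coupling applied to the fly's last (delivered) turn, the retinal
#' slip equals that stimulus velocity (the fly's body is fixed), and the fly
#' turns in proportion to the slip, optionally with an integral term. With a
#' purely proportional fly the slip converges geometrically to
#' `omega_base / (1 - gain * fly_gain)` whenever `|gain * fly_gain| < 1`
#' (so for gain -1 the residual slip shrinks as the fly's proportional gain
#' grows); with any integral action the slip converges to zero.
#'
#' @param gain Coupling gain of the stimulus (see [closed_loop_update()]).
#' @param fly_gain Proportional gain of the fly (yaw per unit slip).
#' @param n_steps Number of display frames.
#' @param omega_base Intrinsic stimulus angular velocity, deg/s.
#' @param fly_integral Integral gain of the fly (1/s); 0 for proportional.
#' @param delay_steps Whole-frame transport delay of the coupling.
#' @param refresh_rate Display refresh rate, Hz.
#' @return Tibble with `step`, `t_s`, `slip_deg_s`, `yaw_deg_s`,
#'   `orientation_deg`.
#' @export
simulate_closed_loop <- function(gain, fly_gain, n_steps, omega_base = 0,
                                 fly_integral = 0, delay_steps = 0,
                                 refresh_rate = 60) {
  stopifnot(n_steps >= 1, delay_steps >= 0)
  dt <- 1 / refresh_rate
  slip <- yaw <- ori <- numeric(n_steps)
  acc <- 0
  yaw_hist <- numeric(n_steps + delay_steps)
  o <- 0
  for (k in seq_len(n_steps)) {
    yaw_applied <- if (k - 1 - delay_steps >= 1) yaw_hist[k - 1 - delay_steps] else 0
    v_stim <- omega_base + gain * yaw_applied
    o <- o + v_stim * dt
    slip[k] <- v_stim
    acc <- acc + slip[k] * dt
    yaw_hist[k] <- fly_gain * slip[k] + fly_integral * acc
    yaw[k] <- yaw_hist[k]
    ori[k] <- o
  }
  tibble::tibble(step = seq_len(n_steps), t_s = (seq_len(n_steps) - 1) * dt,
                 slip_deg_s = slip, yaw_deg_s = yaw, orientation_deg = ori)
}

# ---- event log ------------------------------------------------------------

new_event_log <- function(t_us = numeric(0), source = character(0),
                          key = character(0), value = character(0)) {
  tibble::tibble(t_us = round(t_us), source = source, key = key, value = value)
}

#' Write / read a key-value event log
#'
#' Long-format CSV with columns `t_ms` (millisecond timestamps at
#' microsecond resolution), `source` (`server`/`client`), `key`, `value`.
#' Reading a written log reproduces the original object exactly.
#'
#' @param log Event-log tibble (`t_us`, `source`, `key`, `value`).
#' @param path File path.
#' @return `path` invisibly (write); the event-log tibble (read).
#' @export
write_event_log <- function(log, path) {
  df <- data.frame(t_ms = sprintf("%.3f", log$t_us / US_PER_MS),
                   source = log$source, key = log$key, value = log$value)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  df <- utils::read.csv(path, colClasses = c(t_ms = "character",
                                             source = "character",
                                             key = "character",
                                             value = "character"))
  new_event_log(t_us = as.numeric(df$t_ms) * US_PER_MS, source = df$source,
                key = df$key, value = df$value)
}

# server messages for a scheduled trial table: one version per message
schedule_messages <- function(trials) {
  per_trial <- lapply(seq_len(nrow(trials)), function(i) {
    tr <- trials[i, ]
    tibble::tibble(
      send_us = c(tr$t_start_ms, tr$t_start_ms, tr$t_motion_on_ms,
                  tr$t_motion_off_ms, tr$t_end_ms) * US_PER_MS,
      key = c("trial-start", "stim-kind", "motion-start", "motion-stop",
              "trial-end"),
      value = c(tr$condition_id, tr$stim_kind,
                format(ifelse(is.na(tr$omega), 0, tr$omega), digits = 10),
                "0", tr$condition_id),
      trial_index = tr$trial_index
    )
  })
  msg <- dplyr::bind_rows(per_trial)
  msg$send_us <- round(msg$send_us)
  msg$version <- seq_len(nrow(msg))
  msg
}

#' Run a simulated experiment
#'
#' Executes a scheduled trial list on the simulated clock: server parameter
#' updates travel through the transport and are applied by the client at
#' frame deadlines; every display frame is accounted for (on-time or delayed
#' by whole frame intervals); all state changes are logged as time-stamped
#' key-value events; and, when a fly model is supplied, its walking is
#' simulated concurrently and returned as FicTrac frames. During closed-loop
#' trials with a fly, the fly's per-frame heading changes are fed back
#' through [closed_loop_update()] and emitted as orientation events.
#'
#' Identical inputs (trials, transport, fly seeds) give bit-identical
#' outputs.
#'
#' @param trials Scheduled trial tibble from [randomize_blocks()].
#' @param geom A [display_geometry()].
#' @param transport A [transport_model()].
#' @param fly Optional [fly_model()].
#' @param coupling_gain Gain used for closed-loop trials when a fly is
#'   present.
#' @return An object of class `experiment_run`: list with `event_log`,
#'   `frame_records` (tibble: `frame_index`, `scheduled_ms`, `rendered_ms`,
#'   `params_version_shown`, `on_time`, `delay_frames`), `fictrac` (or
#'   `NULL`), and the input `trials`.
#' @export
run_experiment <- function(trials, geom = display_geometry(),
                           transport = transport_model(), fly = NULL,
                           coupling_gain = -1) {
  stopifnot(nrow(trials) > 0)
  interval_us <- 1e6 / geom$refresh_rate
  total_us <- max(trials$t_end_ms) * US_PER_MS
  n_frames <- ceiling(total_us / 1e6 * geom$refresh_rate)

  # fly first: closed-loop orientation messages derive from its turning
  fictrac <- NULL
  cl_msgs <- NULL
  if (!is.null(fly)) {
    fictrac <- simulate_fly(fly, trials, geom)
    cl_rows <- which(trials$stim_kind == "closed_loop")
    if (length(cl_rows)) {
      fmt <- attr(fictrac, "fictrac_format")
      t_fly_us <- fictrac[[fmt$timestamp]] * US_PER_MS
      heading_deg <- signal::unwrap(fictrac[[fmt$heading]]) * 180 / pi
      cl_list <- lapply(cl_rows, function(i) {
        on_us <- trials$t_motion_on_ms[i] * US_PER_MS
        off_us <- trials$t_motion_off_ms[i] * US_PER_MS
        ticks <- seq(on_us, off_us, by = interval_us)
        h <- stats::approx(t_fly_us, heading_deg, xout = ticks, rule = 2)$y
        ori <- closed_loop_update(0, h - h[1], coupling_gain)
        tibble::tibble(send_us = round(ticks), key = "orientation",
                       value = sprintf("%.6f", ori),
                       trial_index = trials$trial_index[i])
      })
      cl_msgs <- dplyr::bind_rows(cl_list)
    }
  }

  msg <- schedule_messages(trials)
  if (!is.null(cl_msgs)) {
    msg <- dplyr::bind_rows(msg[, c("send_us", "key", "value", "trial_index")],
                            cl_msgs)
    msg <- msg[order(msg$send_us), ]
    msg$version <- seq_len(nrow(msg))
  }
  lat_msg_us <- draw_one_way(transport, nrow(msg), stream = 1L) * US_PER_MS
  msg$delivery_us <- cummax(round(msg$send_us + lat_msg_us))  # in-order

  # per-frame content requests: issued one interval before display
  scheduled_us <- round((seq_len(n_frames) - 1) * interval_us)
  rt_us <- (draw_one_way(transport, n_frames, stream = 2L) +
            draw_one_way(transport, n_frames, stream = 3L) +
            spike_extra_ms(transport, seq_len(n_frames))) * US_PER_MS
  arrival_us <- scheduled_us - interval_us + rt_us
  delay_frames <- pmax(0, ceiling((arrival_us - scheduled_us) / interval_us - 1e-9))
  rendered_us <- scheduled_us + delay_frames * interval_us
  version_shown <- findInterval(scheduled_us, sort(msg$delivery_us))

  frame_records <- tibble::tibble(
    frame_index = seq_len(n_frames),
    scheduled_ms = scheduled_us / US_PER_MS,
    rendered_ms = rendered_us / US_PER_MS,
    params_version_shown = version_shown,
    on_time = delay_frames == 0,
    delay_frames = as.integer(delay_frames)
  )

  log <- dplyr::bind_rows(
    new_event_log(t_us = msg$send_us, source = "server", key = msg$key,
                  value = msg$value),
    new_event_log(t_us = msg$delivery_us, source = "client",
                  key = paste0("applied-", msg$key), value = msg$value)
  )
  log <- log[order(log$t_us, log$source), ]

  structure(
    list(event_log = log, frame_records = frame_records, fictrac = fictrac,
         trials = trials, geom = geom, transport = transport),
    class = "experiment_run"
  )
}

#' @export
print.experiment_run <- function(x, ...) {
  fs <- frame_statistics(x$frame_records)
  cat(sprintf("<experiment_run> %d trials, %d frames (%.2f%% on time), %s\n",
              nrow(x$trials), nrow(x$frame_records), 100 * fs$on_time_fraction,
              if (is.null(x$fictrac)) "no fly" else
                sprintf("%d fly frames", nrow(x$fictrac))))
  invisible(x)
}

#' Frame accounting: on-time fraction and delay histogram
#'
#' @param records Frame-record tibble from [run_experiment()].
#' @return List with `on_time_fraction` and `delay_histogram`, the counts of
#'   delayed frames binned by whole frame intervals (`"1"`, `"2"`, `">=3"`).
#' @export
frame_statistics <- function(records) {
  if (is.null(records) || nrow(records) == 0)
    stop("frame_statistics(): no frame records")
  d <- records$delay_frames[records$delay_frames >= 1]
  bins <- c("1" = sum(d == 1), "2" = sum(d == 2), ">=3" = sum(d >= 3))
  list(on_time_fraction = mean(records$on_time),
       delay_histogram = bins[bins > 0])
}

#' Round-trip latency measurement through the transport
#'
#' Simulates `n` server-to-client-and-back round trips (two one-way latency
#' draws each, plus any injected spikes) and reports, for each k = 1..4, the
#' fraction that completed within k display frame intervals.
#'
#' @param transport A [transport_model()].
#' @param n Number of round trips.
#' @param seed Seed for the latency draws; defaults to the transport's seed.
#' @param refresh_rate Display refresh rate, Hz (frame interval 1000/rate ms).
#' @return List with `latency_ms` (the `n` round-trip times) and
#'   `fraction_within` (named vector over k = 1..4 frame intervals).
#' @export
roundtrip_latency_trial <- function(transport, n, seed = transport$seed,
                                    refresh_rate = 60) {
  stopifnot(n >= 1)
  tm <- transport
  tm$seed <- as.integer(seed)
  rt <- draw_one_way(tm, n, stream = 11L) + draw_one_way(tm, n, stream = 12L) +
    spike_extra_ms(tm, seq_len(n))
  interval_ms <- 1000 / refresh_rate
  ks <- 1:4
  frac <- vapply(ks, function(k) mean(rt <= k * interval_ms + 1e-12), numeric(1))
  names(frac) <- paste0("within_", ks, "_frames")
  list(latency_ms = rt, fraction_within = frac)
}
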