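# Headless rasterization of stimuli through the display geometry. A frame is
# sampled at pixel-column centers (square-wave LCD content, no anti-aliasing
# by default); frames are zero-order-hold between refreshes, so a grating at
# half the refresh rate alternates with its half-period shift every frame and
# carries no net motion.

#' Render one horizontal scanline of the display
#'
#' Each pixel column at physical offset `x` from screen center shows the
#' stimulus luminance at azimuth `atan(x / d)` — the view-angle-corrected
#' projection of the virtual cylinder. With `supersample > 1` each column is
#' the mean of that many evenly spaced sub-pixel samples, approximating the
#' spatial averaging of a physical sensor or a finite-aperture eye.
#'
#' @param stimulus A stimulus spec ([grating_spec()] / [bar_sweep_spec()]).
#' @param geom A [display_geometry()].
#' @param t Time since motion onset, s.
#' @param supersample Integer >= 1; sub-pixel samples per column.
#' @return Numeric vector of length `px_width` with luminances in `[0, 1]`.
#' @export
render_scanline <- function(stimulus, geom = display_geometry(), t = 0,
                            supersample = 1L) {
  supersample <- as.integer(supersample)
  stopifnot(supersample >= 1)
  if (supersample == 1L) {
    az <- screen_x_to_azimuth(pixel_centers_x(geom), geom)
    return(luminance_at(stimulus, az, t))
  }
  pitch <- geom$physical_width / geom$px_width
  offs <- ((seq_len(supersample) - 0.5) / supersample - 0.5) * pitch
  acc <- numeric(geom$px_width)
  for (o in offs) {
    az <- screen_x_to_azimuth(pixel_centers_x(geom) + o, geom)
    acc <- acc + luminance_at(stimulus, az, t)
  }
  acc / supersample
}

#' Space-time diagram of a trial
#'
#' Renders every display frame of a trial (pre, motion, and post epochs) as
#' one row of a luminance matrix: a space-time representation in which a
#' pattern drifting clockwise (toward positive azimuth) traces edges that,
#' with the spatial axis plotted right-to-left and time downward, run down
#' and to the left. Motion time is frozen at its initial/final value during
#' the pre/post epochs (zero-order hold at trial boundaries).
#'
#' @param trial A [trial_spec()].
#' @param geom A [display_geometry()].
#' @param supersample Passed to [render_scanline()].
#' @return An object of class `space_time_diagram`: list with `matrix`
#'   (frames x pixel columns), `frame_times` (s, frame onset since trial
#'   start), `column_azimuths` (deg) and `motion_window` (s).
#' @export
space_time <- function(trial, geom = display_geometry(), supersample = 1L) {
  stopifnot(inherits(trial, "trial_spec"))
  total_s <- trial_duration_ms(trial) / 1000
  n_frames <- ceiling(total_s * geom$refresh_rate)
  stopifnot(n_frames >= 1)
  frame_times <- (seq_len(n_frames) - 1) / geom$refresh_rate
  pre_s <- trial$pre_ms / 1000
  motion_s <- trial$motion_ms / 1000
  t_motion <- pmin(pmax(frame_times - pre_s, 0), motion_s)
  mat <- t(vapply(
    t_motion,
    function(tm) render_scanline(trial$stimulus, geom, tm, supersample),
    numeric(geom$px_width)
  ))
  structure(
    list(
      matrix = mat,
      frame_times = frame_times,
      column_azimuths = screen_x_to_azimuth(pixel_centers_x(geom), geom),
      motion_window = c(pre_s, pre_s + motion_s)
    ),
    class = "space_time_diagram"
  )
}

#' @export
print.space_time_diagram <- function(x, ...) {
  cat(sprintf("<space_time_diagram> %d frames x %d columns, %.2f s\n",
              nrow(x$matrix), ncol(x$matrix),
              utils::tail(x$frame_times, 1) + diff(x$frame_times[1:2])))
  invisible(x)
}

#' Simulated photodiode trace over a display patch
#'
#' Mean luminance per frame over a rectangular pixel patch, emulating a
#' photodiode taped to the display. The default patch is a ~5 mm square
#' adjacent to the right display edge at mid-height.
#'
#' @param trial A [trial_spec()].
#' @param geom A [display_geometry()].
#' @param patch Integer vector `c(col_lo, col_hi, row_lo, row_hi)` (1-based,
#'   inclusive pixel bounds). Rows are accepted for interface completeness;
#'   stimuli are uniform in elevation so only columns affect the trace.
#' @param supersample Passed to [render_scanline()].
#' @return A tibble with `t_s` (frame onset) and `luminance`.
#' @export
photodiode_trace <- function(trial, geom = display_geometry(),
                             patch = default_photodiode_patch(geom),
                             supersample = 1L) {
  patch <- as.integer(patch)
  stopifnot(length(patch) == 4)
  if (patch[1] < 1 || patch[2] > geom$px_width || patch[3] < 1 ||
      patch[4] > geom$px_height || patch[2] < patch[1] || patch[4] < patch[3])
    stop("photodiode_trace(): patch must be a pixel rectangle inside the panel")
  st <- space_time(trial, geom, supersample)
  lum <- rowMeans(st$matrix[, patch[1]:patch[2], drop = FALSE])
  tibble::tibble(t_s = st$frame_times, luminance = lum)
}

#' @rdname photodiode_trace
#' @export
default_photodiode_patch <- function(geom = display_geometry()) {
  px_per_mm <- geom$px_width / geom$physical_width
  w <- max(1L, as.integer(round(5 * px_per_mm)))
  row_mid <- as.integer(round(geom$px_height / 2))
  c(geom$px_width - w + 1L, geom$px_width,
    max(1L, row_mid - w %/% 2L), min(geom$px_height, row_mid + w %/% 2L))
}

#' Dominant frequency of a luminance trace
#'
#' Argmax of the periodogram excluding DC. A (near-)constant trace has no
#' dominant frequency and returns `NA` with a warning.
#'
#' @param series Numeric vector (e.g. the `luminance` column of
#'   [photodiode_trace()]).
#' @param fs Sampling rate in Hz (the display refresh rate for per-frame
#'   traces).
#' @return Frequency in Hz, or `NA_real_` for a constant trace.
#' @export
dominant_frequency <- function(series, fs) {
  stopifnot(is.numeric(series), length(series) >= 4, fs > 0)
  x <- series - mean(series)
  if (stats::sd(series) < 1e-12) {
    warning("dominant_frequency(): constant trace, no dominant frequency")
    return(NA_real_)
  }
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  half <- 2:(floor(n / 2) + 1)                  # positive frequencies, no DC
  freqs <- (half - 1) * fs / n
  freqs[which.max(p[half])]
}

#' Net directional motion of a space-time diagram
#'
#' A signed, normalized motion-energy index computed from the 2-D Fourier
#' spectrum of the (mean-subtracted) space-time matrix: energy in the
#' spectral quadrants consistent with motion toward positive azimuth
#' (clockwise) minus energy in the opposite quadrants, divided by their sum.
#' Positive values indicate net clockwise motion; a counterphase flicker —
#' e.g. a grating stepped by half its period every frame, as happens at a
#' temporal frequency of half the display refresh rate — scores 0, as does a
#' static pattern.
#'
#' The index is computed on an azimuth-resampled copy of the diagram
#' (uniform angular sampling), so perspective distortion of the flat panel
#' does not leak into the direction estimate.
#'
#' @param diagram A `space_time_diagram` from [space_time()].
#' @param n_az Number of uniform azimuth samples used internally.
#' @return Signed scalar in `[-1, 1]`.
#' @export
net_motion_index <- function(diagram, n_az = 256L) {
  stopifnot(inherits(diagram, "space_time_diagram"), nrow(diagram$matrix) >= 2)
  az <- diagram$column_azimuths
  az_grid <- seq(min(az), max(az), length.out = n_az)
  m <- diagram$matrix
  # nearest-column lookup: columns are monotone in azimuth
  idx <- findInterval(az_grid, az, all.inside = TRUE)
  nudge <- az_grid - az[idx] > az[pmin(idx + 1, length(az))] - az_grid
  idx <- pmin(idx + nudge, length(az))
  m <- m[, idx, drop = FALSE]
  m <- m - mean(m)
  if (sum(m^2) < 1e-12) return(0)
  s <- Mod(stats::fft(m))^2
  nt <- nrow(s); nx <- ncol(s)
  ft <- ifelse(seq_len(nt) - 1 > nt / 2, seq_len(nt) - 1 - nt, seq_len(nt) - 1)
  fx <- ifelse(seq_len(nx) - 1 > nx / 2, seq_len(nx) - 1 - nx, seq_len(nx) - 1)
  sgn <- outer(sign(ft), sign(fx))
  # rigid drift toward +azimuth concentrates energy where ft and fx have
  # opposite signs (f_t + v f_x = 0 with v > 0)
  e_cw  <- sum(s[sgn == -1])
  e_ccw <- sum(s[sgn == +1])
  if (e_cw + e_ccw == 0) return(0)
  (e_cw - e_ccw) / (e_cw + e_ccw)
}

#' Plot a space-time diagram
#'
#' Renders the diagram with the spatial axis right-to-left and time downward,
#' the orientation in which clockwise pattern motion appears as streaks
#' running down and to the left.
#'
#' @param x A `space_time_diagram`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot.space_time_diagram <- function(x, ...) {
  df <- expand.grid(frame = seq_len(nrow(x$matrix)),
                    col = seq_len(ncol(x$matrix)))
  df$luminance <- as.vector(x$matrix)
  df$t_s <- x$frame_times[df$frame]
  df$azimuth <- x$column_azimuths[df$col]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$azimuth, y = .data$t_s,
                                   fill = .data$luminance)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::scale_x_reverse("azimuth (deg)") +
    ggplot2::scale_y_reverse("time (s)") +
    ggplot2::theme_minimal()
}
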