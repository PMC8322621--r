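# Shared fixtures: small geometries and deterministic flies so that unit
# tests render/simulate in milliseconds.

small_geom <- function(px = 128L) {
  display_geometry(physical_width = 151.8, physical_height = 83.4,
                   px_width = px, px_height = 75L)
}

# a noise-free, latency-free fly: its yaw equals the drive exactly
noise_free_fly <- function(..., camera_rate = 180) {
  fly_model(motor_noise_sd = 0, forward_speed_sd = 0, response_latency_ms = 0,
            camera_rate = camera_rate, ...)
}

# one-condition-per-direction mini protocol around a single grating speed
mini_protocol <- function(omega = 360, lambda = 90, n_blocks = 1,
                          startup_delay_ms = 1000) {
  cw <- trial_spec(grating_spec(lambda, omega), "g_cw")
  ccw <- trial_spec(grating_spec(lambda, -omega), "g_ccw")
  protocol(list(cw, ccw), n_blocks = n_blocks,
           startup_delay_ms = startup_delay_ms)
}

# brute-force ray-cast oracle: shoot a ray from the viewer through each pixel
# center onto a cylinder of the given diameter centered on the viewer, and
# look the luminance up at the angular position of the intersection point
ray_cast_scanline <- function(stimulus, geom, t = 0, diameter = 305) {
  vapply(pixel_centers_x(geom), function(px_x) {
    # ray direction (x right, z toward the screen), unnormalized
    dir <- c(px_x, geom$viewer_distance)
    # intersection with circle of radius R centered at the origin:
    # s * |dir| = R  ->  point = dir * R / |dir|
    r <- diameter / 2
    pt <- dir * r / sqrt(sum(dir^2))
    az <- atan2(pt[1], pt[2]) * 180 / pi
    luminance_at(stimulus, az, t)
  }, numeric(1))
}

# shift a recording's heading by a constant angular-velocity bias (deg/s)
inject_heading_bias <- function(frames, bias_deg_s,
                                format = fictrac_format()) {
  t_s <- frames[[format$timestamp]] / 1000
  h <- signal::unwrap(frames[[format$heading]])
  frames[[format$heading]] <- (h + bias_deg_s * pi / 180 * t_s) %% (2 * pi)
  frames
}

# mirror a recording left-right: negate all headings
negate_headings <- function(frames, format = fictrac_format()) {
  frames[[format$heading]] <- (2 * pi - frames[[format$heading]]) %% (2 * pi)
  frames
}
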