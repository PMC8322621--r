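# one small noise-free experiment reused across analysis tests
analysis_fixture <- function(n_flies = 2, omega = 360, noise = 0, seed = 1,
                             peak_gain = 50) {
  p <- mini_protocol(omega = omega, n_blocks = 2, startup_delay_ms = 1000)
  trials <- randomize_blocks(p, seed = seed)
  geom <- small_geom()
  drives <- condition_drives(trials, geom)
  run0 <- run_experiment(trials, geom, transport_model())
  tts <- dplyr::bind_rows(lapply(seq_len(n_flies), function(i) {
    fly <- fly_model(peak_gain = peak_gain, motor_noise_sd = noise,
                     forward_speed_sd = 0, response_latency_ms = 0,
                     seed = 100 + i)
    run <- run0
    run$fictrac <- simulate_fly(fly, trials, geom, drives = drives)
    tt <- trial_time_series(run)
    tt$fly_id <- i
    tt
  }))
  list(tts = tts, trials = trials, run0 = run0, geom = geom, drives = drives)
}

test_that("sliding-window smoothing truncates at the edges and preserves structure", {
  expect_equal(smooth_sliding(c(0, 0, 5, 0, 0), 5),
               c(5 / 3, 5 / 4, 1, 5 / 4, 5 / 3))
  expect_equal(smooth_sliding(rep(3.2, 40), 5), rep(3.2, 40))
  x <- stats::rnorm(30)
  expect_equal(smooth_sliding(x, 1), x)
  expect_error(smooth_sliding(x, 4), "odd")
  expect_error(smooth_sliding(x, 0), "odd")
  # interior of a cleanly divisible series preserves the global mean
  y <- rep(c(1, 2, 3, 4, 5), 8)
  sm <- smooth_sliding(y, 5)
  expect_equal(mean(sm[3:38]), mean(y[3:38]))
})

test_that("merging logs labels every frame with trial, condition and epoch", {
  fx <- analysis_fixture(n_flies = 1)
  run <- fx$run0
  run$fictrac <- simulate_fly(fly_model(seed = 1), fx$trials, fx$geom,
                              drives = fx$drives)
  merged <- merge_logs(run$event_log, run$fictrac)
  expect_true(all(c("trial_index", "condition_id", "epoch") %in% names(merged)))
  expect_setequal(stats::na.omit(unique(merged$trial_index)),
                  fx$trials$trial_index)
  # epochs carve each trial into pre / motion / post
  tr1 <- merged[which(merged$trial_index == 1), ]
  expect_setequal(unique(tr1$epoch), c("pre", "motion", "post"))
  # half-open boundary: a frame exactly at motion onset belongs to motion
  fmt <- fictrac_format()
  run2 <- run
  on_ms <- fx$trials$t_motion_on_ms[1]
  i <- which.min(abs(run2$fictrac[[fmt$timestamp]] - on_ms))
  run2$fictrac[[fmt$timestamp]][i] <- on_ms
  merged2 <- merge_logs(run2$event_log, run2$fictrac)
  expect_equal(merged2$epoch[i], "motion")
  # disjoint clocks are rejected
  far <- run$fictrac
  far[[fmt$timestamp]] <- far[[fmt$timestamp]] + 1e9
  expect_error(merge_logs(run$event_log, far), "overlap")
})

test_that("an 84-trial experiment yields 84 labeled trials end to end", {
  p <- build_protocol("temporal", rng_seed = 3)
  trials <- randomize_blocks(p)
  run <- run_experiment(trials, small_geom(), transport_model())
  run$fictrac <- simulate_fly(noise_free_fly(camera_rate = 60, seed = 1),
                              trials, small_geom())
  merged <- merge_logs(run$event_log, run$fictrac)
  expect_equal(dplyr::n_distinct(stats::na.omit(merged$trial_index)), 84)
})

test_that("direction folding cancels bias and averages antisymmetric traces", {
  expect_equal(combine_directions(rep(50, 5), rep(-50, 5)), rep(50, 5))
  expect_equal(combine_directions(rep(7, 5), rep(7, 5)), rep(0, 5))
  expect_error(combine_directions(1:5, 1:4), "common grid")
  expect_error(combine_directions(1:5, 1:5, t_cw = 1:5, t_ccw = 2:6),
               "grids")
})

test_that("two-stage averaging weights flies, not trials, equally", {
  grid <- tidyr::expand_grid(rel_frame = 0:9, trial = 1:6)
  flyA <- tibble::tibble(fly_id = 1, condition_id = "c",
                         rel_frame = grid$rel_frame,
                         t_rel_s = grid$rel_frame / 180,
                         yaw_deg_s = 10)
  flyB <- tibble::tibble(fly_id = 2, condition_id = "c",
                         rel_frame = rep(0:9, 3),
                         t_rel_s = rep(0:9, 3) / 180,
                         yaw_deg_s = -10)
  pop <- per_fly_then_population(dplyr::bind_rows(flyA, flyB))
  # 6 trials of +10 and 3 trials of -10, yet the population mean is 0
  expect_equal(pop$mean, rep(0, 10))
  expect_equal(unique(pop$n_flies), 2)
})

test_that("noise-free flies give the injected gain with zero SEM", {
  fx <- analysis_fixture(n_flies = 2, omega = 360, noise = 0)
  curve <- tuning_curve(fx$tts, x = "tf")
  expect_equal(nrow(curve), 1)
  expect_equal(curve$x, 4)
  drive <- optomotor_gain(fly_model(), 4)
  expect_equal(curve$mean, drive, tolerance = 0.02)
  expect_equal(curve$sem, 0, tolerance = 1e-9)
  expect_equal(curve$n_flies, 2)
})

test_that("a constant turning bias cancels exactly in the combined curve", {
  fx <- analysis_fixture(n_flies = 2, noise = 40, seed = 6)
  curve0 <- tuning_curve(fx$tts, x = "tf")
  biased <- dplyr::bind_rows(lapply(1:2, function(i) {
    fly <- fly_model(peak_gain = 50, motor_noise_sd = 40, forward_speed_sd = 0,
                     response_latency_ms = 0, seed = 100 + i)
    run <- fx$run0
    run$fictrac <- inject_heading_bias(
      simulate_fly(fly, fx$trials, fx$geom, drives = fx$drives), 25)
    tt <- trial_time_series(run)
    tt$fly_id <- i
    tt
  }))
  curve_b <- tuning_curve(biased, x = "tf")
  expect_equal(curve_b$mean, curve0$mean, tolerance = 1e-6)
})

test_that("negating every heading negates the tuning curve exactly", {
  fx <- analysis_fixture(n_flies = 2, noise = 40, seed = 8)
  flipped <- dplyr::bind_rows(lapply(1:2, function(i) {
    fly <- fly_model(peak_gain = 50, motor_noise_sd = 40, forward_speed_sd = 0,
                     response_latency_ms = 0, seed = 100 + i)
    run <- fx$run0
    run$fictrac <- negate_headings(
      simulate_fly(fly, fx$trials, fx$geom, drives = fx$drives))
    tt <- trial_time_series(run)
    tt$fly_id <- i
    tt
  }))
  c0 <- tuning_curve(fx$tts, x = "tf")
  c1 <- tuning_curve(flipped, x = "tf")
  expect_equal(c1$mean, -c0$mean, tolerance = 1e-9)
})

test_that("closed-loop trials are excluded from tuning computations", {
  p <- mini_protocol(n_blocks = 2, startup_delay_ms = 500)
  trials <- randomize_blocks(p, seed = 4, closed_loop = closed_loop_spec())
  expect_equal(sum(trials$stim_kind == "closed_loop"), 2)
  geom <- small_geom()
  run <- run_experiment(trials, geom, transport_model())
  run$fictrac <- simulate_fly(noise_free_fly(seed = 2), trials, geom)
  tt <- trial_time_series(run)
  tt$fly_id <- 1
  expect_warning(curve <- tuning_curve(tt, x = "tf"), "fewer than 2")
  expect_false(any(grepl("closed_loop", curve$base_id)))
  # the closed-loop trials were present in the merged stream, just excluded
  expect_equal(dplyr::n_distinct(tt$trial_index[tt$stim_kind == "closed_loop"]), 2)
  expect_true(is.na(curve$sem))
})

test_that("bar profiles track the bar and mirror across directions", {
  speeds <- c(90, 360)
  conds <- unlist(lapply(speeds, function(s) list(
    trial_spec(bar_sweep_spec(s), sprintf("bar%g_cw", s)),
    trial_spec(bar_sweep_spec(-s), sprintf("bar%g_ccw", s)))), recursive = FALSE)
  p <- protocol(conds, n_blocks = 2, startup_delay_ms = 500)
  trials <- randomize_blocks(p, seed = 2)
  geom <- small_geom()
  run0 <- run_experiment(trials, geom, transport_model())
  tts <- dplyr::bind_rows(lapply(1:2, function(i) {
    run <- run0
    run$fictrac <- simulate_fly(noise_free_fly(seed = 30 + i), trials, geom)
    tt <- trial_time_series(run); tt$fly_id <- i; tt
  }))
  prof <- bar_profile(tts)
  # overlay kinematics: the bar crosses the midline at (span/2)/speed
  p90 <- prof[prof$speed == 90, ]
  cross <- p90$t_rel_s[which.min(abs(p90$bar_azimuth))]
  expect_equal(cross, (175.5 / 2) / 90, tolerance = 0.05)
  # a symmetric synthetic fly turns with the bar in both directions
  expect_true(mean(p90$mean[p90$t_rel_s > 0.3 & p90$t_rel_s < 1.5]) > 0)
  # zero-gain fly: flat profile at zero
  tts0 <- dplyr::bind_rows(lapply(1:2, function(i) {
    run <- run0
    run$fictrac <- simulate_fly(
      fly_model(peak_gain = 0, motor_noise_sd = 0, forward_speed_sd = 0,
                seed = i), trials, geom)
    tt <- trial_time_series(run); tt$fly_id <- i; tt
  }))
  prof0 <- bar_profile(tts0)
  expect_true(all(abs(prof0$mean) < 1e-9))
})

test_that("run_tuning_experiment wires the whole pipeline deterministically", {
  p <- mini_protocol(omega = 360, n_blocks = 1, startup_delay_ms = 500)
  r1 <- run_tuning_experiment(p, n_flies = 2, seed = 11,
                              fly = fly_model(motor_noise_sd = 20))
  r2 <- run_tuning_experiment(p, n_flies = 2, seed = 11,
                              fly = fly_model(motor_noise_sd = 20))
  expect_equal(r1$curve, r2$curve)
  expect_equal(unique(r1$curve$n_flies), 2)
})
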