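test_that("a zero-latency transport renders every frame on time", {
  trials <- randomize_blocks(mini_protocol(), seed = 3)
  run <- run_experiment(trials, small_geom(), transport_model())
  stats <- frame_statistics(run$frame_records)
  expect_equal(stats$on_time_fraction, 1)
  expect_length(stats$delay_histogram, 0)
  # conservation: one record per display frame of the experiment
  total_s <- max(trials$t_end_ms) / 1000
  expect_equal(nrow(run$frame_records), ceiling(total_s * 60))
  expect_true(all(run$frame_records$rendered_ms >= run$frame_records$scheduled_ms))
  expect_true(all(diff(run$frame_records$frame_index) == 1))
})

test_that("injected delays are counted exactly: the constructed 99.9% scenario", {
  trials <- randomize_blocks(mini_protocol(omega = 360, startup_delay_ms = 0),
                             seed = 1)
  # every 100th content request misses its frame deadline by one frame
  tm <- transport_model(spike_every = 100, spike_ms = 30)
  run <- run_experiment(trials, small_geom(), tm)
  stats <- frame_statistics(run$frame_records)
  n <- nrow(run$frame_records)
  expect_equal(stats$on_time_fraction, 1 - floor(n / 100) / n)
  expect_equal(unname(stats$delay_histogram["1"]), floor(n / 100))
  # a two-frame spike lands in bin 2, not bin 1
  tm2 <- transport_model(spike_every = 100, spike_ms = 45)
  stats2 <- frame_statistics(run_experiment(trials, small_geom(), tm2)$frame_records)
  expect_equal(unname(stats2$delay_histogram["2"]), floor(n / 100))
  expect_true(is.na(stats2$delay_histogram["1"]) ||
              !"1" %in% names(stats2$delay_histogram))
  # no frame is double counted
  fr <- run$frame_records
  expect_equal(sum(fr$on_time) + sum(fr$delay_frames >= 1), n)
})

test_that("frame statistics reject empty input", {
  expect_error(frame_statistics(NULL))
  expect_error(frame_statistics(tibble::tibble()))
})

test_that("round-trip latency fractions follow the transport", {
  # fixed one-way 5 ms: round trip 10 ms, inside one ~17 ms frame interval
  rt5 <- roundtrip_latency_trial(transport_model(5), n = 100)
  expect_equal(unname(rt5$fraction_within["within_1_frames"]), 1)
  expect_equal(unique(rt5$latency_ms), 10)
  # fixed one-way 10 ms: round trip 20 ms, misses 1 interval, inside 2
  rt10 <- roundtrip_latency_trial(transport_model(10), n = 100)
  expect_equal(unname(rt10$fraction_within["within_1_frames"]), 0)
  expect_equal(unname(rt10$fraction_within["within_2_frames"]), 1)
})

test_that("exponential-jitter round trips match the Gamma(2) CDF", {
  mean_ms <- 6
  n <- 20000
  rt <- roundtrip_latency_trial(transport_model(mean_ms, jitter = "exponential"),
                                n = n, seed = 17)
  # sum of two iid Exp(mean) one-ways ~ Gamma(shape 2, scale mean)
  for (k in 1:4) {
    p <- stats::pgamma(k * 1000 / 60, shape = 2, scale = mean_ms)
    se <- sqrt(p * (1 - p) / n)
    got <- unname(rt$fraction_within[paste0("within_", k, "_frames")])
    expect_lt(abs(got - p), 3 * se + 1e-12)
  }
})

test_that("runs are deterministic and the client never sees undelivered parameters", {
  trials <- randomize_blocks(mini_protocol(), seed = 2)
  tm <- transport_model(4, jitter = "exponential", seed = 9)
  r1 <- run_experiment(trials, small_geom(), tm)
  r2 <- run_experiment(trials, small_geom(), tm)
  expect_identical(r1$event_log, r2$event_log)
  expect_identical(r1$frame_records, r2$frame_records)
  # causality: the version shown was delivered at or before the frame deadline
  deliveries <- sort(r1$event_log$t_us[r1$event_log$source == "client"])
  fr <- r1$frame_records
  shown <- fr$params_version_shown
  ok <- shown == 0 | deliveries[pmax(shown, 1)] <= fr$scheduled_ms * 1000
  expect_true(all(ok))
  # versions only ever advance
  expect_true(all(diff(shown) >= 0))
})

test_that("the event log round-trips through its CSV serialization", {
  trials <- randomize_blocks(mini_protocol(), seed = 4)
  run <- run_experiment(trials, small_geom(),
                        transport_model(3, jitter = "exponential", seed = 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_event_log(run$event_log, path)
  back <- read_event_log(path)
  expect_equal(back, run$event_log)
  # entries are time-ordered within each source
  for (src in c("server", "client")) {
    expect_true(!is.unsorted(run$event_log$t_us[run$event_log$source == src]))
  }
})

test_that("closed-loop updates follow orientation' = orientation + gain * turn", {
  expect_equal(closed_loop_update(30, 10, 0), 30)
  expect_equal(closed_loop_update(0, 10, -1), -10)
  expect_equal(closed_loop_update(5, -4, 2), -3)
})

test_that("the coupled loop settles on its fixed point and integral action nulls the slip", {
  # proportional fly: slip -> omega / (1 - gain * fly_gain)
  sim <- simulate_closed_loop(gain = -1, fly_gain = 0.8, n_steps = 400,
                              omega_base = 90)
  expect_equal(utils::tail(sim$slip_deg_s, 1), 90 / (1 + 0.8), tolerance = 1e-6)
  # stronger proportional gain -> smaller residual slip
  sim2 <- simulate_closed_loop(gain = -1, fly_gain = 0.95, n_steps = 400,
                               omega_base = 90)
  expect_lt(abs(utils::tail(sim2$slip_deg_s, 1)),
            abs(utils::tail(sim$slip_deg_s, 1)))
  # integral action drives the retinal slip to zero
  simi <- simulate_closed_loop(gain = -1, fly_gain = 0.5, fly_integral = 5,
                               n_steps = 3000, omega_base = 90)
  expect_lt(abs(utils::tail(simi$slip_deg_s, 1)), 0.5)
  # gain 0 decouples the loop: the stimulus follows its open-loop trajectory
  sim0 <- simulate_closed_loop(gain = 0, fly_gain = 0.8, n_steps = 120,
                               omega_base = 90)
  expect_equal(sim0$orientation_deg, 90 * sim0$t_s + 90 / 60,
               tolerance = 1e-9)
  expect_equal(unique(sim0$slip_deg_s), 90)
})

test_that("a coupled fly in a closed-loop trial produces orientation events", {
  cw <- trial_spec(grating_spec(90, 360), "g_cw")
  p <- protocol(list(cw), n_blocks = 1, startup_delay_ms = 0)
  trials <- randomize_blocks(p, closed_loop = closed_loop_spec())
  fly <- noise_free_fly(seed = 3)
  run <- run_experiment(trials, small_geom(), transport_model(), fly = fly,
                        coupling_gain = -1)
  ori <- run$event_log[run$event_log$key == "orientation", ]
  expect_gt(nrow(ori), 0)
  # with coupling gain 0 the orientation never moves (identical to open loop)
  run0 <- run_experiment(trials, small_geom(), transport_model(), fly = fly,
                         coupling_gain = 0)
  ori0 <- run0$event_log[run0$event_log$key == "orientation", ]
  expect_true(all(abs(as.numeric(ori0$value)) < 1e-9))
})
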