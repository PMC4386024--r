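# Eye-trace analytics: vergence, the convergent-saccade detector and its
# brute-force oracle, kinematics, evoked classification, location statistics.

flat_trace <- function(n = 6000, fs = 60, base = 10) {
  structure(list(fs = fs, left = rep(base, n), right = rep(base, n)),
            class = "eye_trace")
}

test_that("vergence is the sum of nasal-positive channels", {
  tr <- flat_trace(100, base = 0)
  expect_equal(compute_vergence(tr), rep(0, 100))
  tr$left <- rep(20, 100); tr$right <- rep(25, 100)
  expect_equal(compute_vergence(tr), rep(45, 100))
  tr$right <- tr$right[-1]
  expect_error(compute_vergence(tr), "length")
})

test_that("detector finds synchronous binocular ramps and rejects asynchrony", {
  expect_equal(nrow(detect_convergent_saccades(flat_trace())), 0L)

  # synchronous pair -> one event
  tr <- flat_trace(3000)
  tr$left <- plant_ramp(tr$left, 20, 10)
  tr$right <- plant_ramp(tr$right, 20, 10)
  ev <- detect_convergent_saccades(tr)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$dvergence, 20, tolerance = 0.01)

  # 200 ms onset gap exceeds the 150 ms pairing rule -> no event
  tr2 <- flat_trace(3000)
  tr2$left <- plant_ramp(tr2$left, 20, 10)
  tr2$right <- plant_ramp(tr2$right, 20.2, 10)
  expect_equal(nrow(detect_convergent_saccades(tr2)), 0L)

  # monocular ramp -> no event
  tr3 <- flat_trace(3000)
  tr3$left <- plant_ramp(tr3$left, 20, 10)
  expect_equal(nrow(detect_convergent_saccades(tr3)), 0L)

  expect_error(detect_convergent_saccades(flat_trace(2)), "shorter")
})

test_that("100 planted convergences in noise are all found without false positives", {
  set.seed(99)
  n <- 100 * 6 * 60 + 600
  tr <- flat_trace(n)
  onsets <- 6 * seq_len(100)
  noise_sd <- 0.5
  for (t0 in onsets) {
    tr$left <- plant_ramp(tr$left, t0, 9)
    tr$right <- plant_ramp(tr$right, t0, 9)
  }
  # smoothed fixational noise comparable to the generator's
  k <- rep(1 / 15, 15)
  tr$left <- tr$left + as.numeric(stats::filter(rnorm(n, 0, noise_sd), k,
                                                circular = TRUE))
  tr$right <- tr$right + as.numeric(stats::filter(rnorm(n, 0, noise_sd), k,
                                                  circular = TRUE))
  ev <- detect_convergent_saccades(tr)
  expect_equal(nrow(ev), 100L)
  expect_true(all(abs(sort(ev$t_onset) - onsets) < 0.2))
})

test_that("detector equals the brute-force pair-scan oracle", {
  for (seed in 1:4) {
    set.seed(seed)
    tr <- flat_trace(10000)
    n_ev <- sample(2:5, 1)
    onsets <- sort(runif(n_ev, 5, 150))
    onsets <- onsets[c(TRUE, diff(onsets) > 5)]
    for (t0 in onsets) {
      amp <- runif(1, 3, 12)
      asyn <- runif(1, 0, 0.2)   # sometimes beyond the pairing rule
      tr$left <- plant_ramp(tr$left, t0, amp)
      tr$right <- plant_ramp(tr$right, t0 + asyn, amp)
    }
    k <- rep(1 / 15, 15)
    tr$left <- tr$left + as.numeric(stats::filter(rnorm(10000, 0, 0.3), k,
                                                  circular = TRUE))
    tr$right <- tr$right + as.numeric(stats::filter(rnorm(10000, 0, 0.3), k,
                                                    circular = TRUE))
    got <- detect_convergent_saccades(tr)
    oracle <- brute_force_detect(tr)
    expect_equal(round(got$t_onset * 60) + 1, oracle)
  }
})

test_that("kinematics recover step sizes and ramp velocities", {
  tr <- flat_trace(2000)
  i0 <- 600
  tr$left[i0:2000] <- tr$left[i0:2000] + 10
  tr$right[i0:2000] <- tr$right[i0:2000] + 10
  ev <- saccade_kinematics(list(t_onset = (i0 - 1) / 60), tr)
  expect_equal(ev$d_left, 10, tolerance = 1e-6)
  expect_equal(ev$d_right, 10, tolerance = 1e-6)
  expect_equal(ev$dvergence, 20, tolerance = 1e-6)

  # 100 deg/s ramp for 100 ms
  tr2 <- flat_trace(2000)
  tr2$left <- plant_ramp(tr2$left, 10, 10)   # 10 deg over 0.1 s
  tr2$right <- plant_ramp(tr2$right, 10, 10)
  ev2 <- saccade_kinematics(list(t_onset = 10), tr2)
  expect_equal(ev2$peak_vel_left, 100, tolerance = 0.12)

  expect_error(saccade_kinematics(list(t_onset = 0.01), flat_trace(100)),
               "bounds")
})

test_that("contralateral eyes rotate more for lateralised stimuli", {
  sched <- generate_schedule(1, 200, seed = 31)
  eyes <- generate_eye_traces(sched, behavior_params(spont_rate_hr = 0),
                              seed = 32)
  ev <- classify_evoked(detect_convergent_saccades(eyes), sched)
  ev <- ev[ev$evoked & !is.na(ev$azimuth_at_event), ]
  expect_gte(nrow(ev), 30)
  contra <- ifelse(ev$azimuth_at_event >= 0, ev$d_left, ev$d_right)
  ipsi <- ifelse(ev$azimuth_at_event >= 0, ev$d_right, ev$d_left)
  tt <- t.test(contra, ipsi, paired = TRUE, alternative = "greater")
  expect_lt(tt$p.value, 0.01)
})

test_that("events are classified evoked only inside spot presentation", {
  sched <- generate_schedule(1, 3, seed = 33)
  ev <- data.frame(t_onset = c(sched$epoch_onset[1] + 1,        # pre-stimulus
                               sched$spot_onset[2] + 0.5),      # during spot
                   pre_left = 0, post_left = 0, pre_right = 0, post_right = 0,
                   d_left = 5, d_right = 5, peak_vel_left = 100,
                   peak_vel_right = 100, dvergence = 10,
                   evoked = NA, epoch_index = NA_integer_,
                   stimulus_id = NA_integer_, azimuth_at_event = NA_real_)
  out <- classify_evoked(ev, sched)
  expect_false(out$evoked[1])
  expect_true(out$evoked[2])
  expect_equal(out$stimulus_id[2], sched$stimulus_id[2])

  # midpoint of the traverse maps to azimuth 0
  epo <- sched[!sched$is_flash, ][1, ]
  ev$t_onset[2] <- epo$spot_onset + (epo$spot_offset - epo$spot_onset) / 2
  out2 <- classify_evoked(ev, sched)
  expect_equal(out2$azimuth_at_event[2], 0)
})

test_that("location statistics behave under symmetric and offset generators", {
  mk_ev <- function(az, sid) {
    data.frame(t_onset = seq_along(az), evoked = TRUE,
               epoch_index = seq_along(az), stimulus_id = sid,
               azimuth_at_event = az)
  }
  set.seed(5)
  az <- rnorm(200, 0, 20)
  sid <- sample(c(3, 11), 200, replace = TRUE)  # both directions
  st <- response_location_stats(mk_ev(az, sid))
  expect_lt(abs(st$median_azimuth), 5)
  expect_gt(st$p_signed_rank, 0.05)
  expect_gt(st$p_direction_ks, 0.01)

  # the generator's offset distribution is recovered
  sched <- generate_schedule(1, 150, seed = 41)
  eyes <- generate_eye_traces(sched, behavior_params(spont_rate_hr = 0,
                                                     azimuth_sd = 15),
                              seed = 42)
  ev <- classify_evoked(detect_convergent_saccades(eyes), sched)
  st2 <- response_location_stats(ev)
  true_med <- median(eyes$events$azimuth, na.rm = TRUE)
  expect_lt(abs(st2$median_azimuth - true_med), 3)
  expect_lt(abs(st2$median_azimuth - (-5.6)), 8)
  expect_error(
    response_location_stats(data.frame(evoked = logical(0),
                                       azimuth_at_event = numeric(0),
                                       stimulus_id = integer(0))),
    "no evoked")
})

test_that("response-rate tables count per-stimulus responses", {
  sched <- generate_schedule(1, 4, seed = 51)
  empty <- data.frame(epoch_index = integer(0))
  tab0 <- response_rate_table(empty, sched)
  expect_true(all(tab0$rate == 0))
  expect_true(all(tab0$n_trials == 4))
  all_ev <- data.frame(epoch_index = sched$epoch_index[sched$stimulus_id < 16])
  tab1 <- response_rate_table(all_ev, sched)
  expect_true(all(tab1$rate == 1))
})

test_that("angular geometry matches the near-field prey example", {
  g <- angular_geometry(0.135, 0.5, 0.5)
  expect_equal(round(g$angular_size_deg), 15)
  expect_equal(g$angular_speed_dps, (0.5 / 0.5) * 180 / pi, tolerance = 1e-12)
  # scale invariance and small-size limit
  expect_equal(angular_geometry(1, 0.5)$angular_size_deg,
               angular_geometry(2, 1)$angular_size_deg)
  expect_lt(angular_geometry(1e-6, 0.5)$angular_size_deg, 1e-3)
  expect_error(angular_geometry(0.1, 0), "positive")
})
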