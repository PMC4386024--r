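# Synthetic-experiment generator: schedules, trajectories, eye traces,
# populations, fluorescence.

test_that("schedules have exact stimulus counts, spacing, and background steps", {
  sched <- generate_schedule(1, 5, seed = 0)
  expect_equal(nrow(sched), 90L)
  expect_true(all(table(sched$stimulus_id) == 5L))
  expect_true(all(sched$epoch_onset %% 32 == 0))

  sched8 <- generate_schedule(1, 8, seed = 0)
  expect_equal(nrow(sched8), 144L)
  expect_equal(max(sched8$epoch_onset) + 32, 4608)

  dark <- sched[!sched$is_flash & sched$polarity == 1, ]
  expect_equal(dark$bg_step_on, dark$spot_onset - 2)
  expect_equal(dark$bg_step_off, dark$spot_offset + 2)
  bright <- sched[!sched$is_flash & sched$polarity == 0, ]
  expect_true(all(is.na(bright$bg_step_on)))

  expect_error(generate_schedule(1, 0), "positive")
})

test_that("spot trajectories are linear with the documented sign convention", {
  sched <- generate_schedule(1, 5, seed = 1)
  # L->R fast spot at traverse midpoint is directly ahead
  lr_fast <- sched[which(sched$direction == 1 & sched$speed == 1)[1], ]
  mid <- lr_fast$spot_onset + (200 / 30) / 2
  expect_equal(spot_azimuth(lr_fast, mid), 0)
  # R->L slow spot 2 s after onset: +100 - 30 = +70
  rl_slow <- sched[which(sched$direction == 0 & sched$speed == 0)[1], ]
  expect_equal(spot_azimuth(rl_slow, rl_slow$spot_onset + 2), 70)
  # absent outside the traverse and for flashes
  expect_true(is.na(spot_azimuth(rl_slow, rl_slow$spot_onset - 1)))
  flash <- sched[sched$is_flash, ][1, ]
  expect_true(is.na(spot_azimuth(flash, flash$spot_onset + 1)))
})

test_that("seeded generation is deterministic end to end", {
  a <- synth_experiment(reps = 3, seed = 7, geometry = list(n_rois = 60L))
  b <- synth_experiment(reps = 3, seed = 7, geometry = list(n_rois = 60L))
  expect_identical(a$schedule, b$schedule)
  expect_identical(a$eyes$left, b$eyes$left)
  expect_identical(a$eyes$events, b$eyes$events)
  expect_identical(a$population$rois, b$population$rois)
  expect_identical(a$dff$mat, b$dff$mat)
})

test_that("eye-trace generator respects response probabilities and rates", {
  sched <- generate_schedule(1, 3, seed = 2)
  # all-zero response probability and zero spontaneous rate: no events
  p0 <- behavior_params(coef = c(intercept = -1e6, size = 0, polarity = 0,
                                 speed_size_polarity = 0),
                        spont_rate_hr = 0)
  eyes0 <- generate_eye_traces(sched, p0, seed = 1)
  expect_equal(nrow(eyes0$events), 0L)

  # evoked counts match the logistic model (pooled binomial check)
  sched_big <- generate_schedule(1, 200, seed = 3)
  eyes <- generate_eye_traces(sched_big,
                              behavior_params(spont_rate_hr = 0), seed = 4)
  p <- preytect:::epoch_response_prob(sched_big, behavior_params()$coef)
  expected <- sum(p)
  sdev <- sqrt(sum(p * (1 - p)))
  expect_lt(abs(sum(eyes$events$evoked) - expected), 3 * sdev)
  # each evoked event maps to exactly one epoch
  ev <- eyes$events[eyes$events$evoked, ]
  expect_true(all(!duplicated(ev$epoch_index)))
  expect_lte(nrow(ev), nrow(sched_big))
})

test_that("populations are placed consistently with the region map", {
  pop <- generate_population(list(n_rois = 400L), seed = 5)
  loc <- locate_region(pop$rois$x_um, pop$rois$y_um, pop$map)
  expect_identical(loc$region, pop$rois$region)
  # map rectangles are pairwise disjoint
  m <- pop$map
  for (i in seq_len(nrow(m) - 1)) for (j in (i + 1):nrow(m)) {
    overlap <- m$x0[i] < m$x1[j] && m$x1[i] > m$x0[j] &&
      m$y0[i] < m$y1[j] && m$y1[i] > m$y0[j]
    expect_false(overlap)
  }
  # assembly cells lie in one hemisphere per assembly, in the SPV
  asm_cells <- pop$rois[!is.na(pop$rois$assembly_id), ]
  expect_true(all(asm_cells$region == "OTc-SPV"))
  hemi_per_asm <- tapply(asm_cells$hemisphere, asm_cells$assembly_id,
                         function(h) length(unique(h)))
  expect_true(all(hemi_per_asm == 1L))
  # degenerate mixture
  pop0 <- generate_population(list(n_rois = 50L),
                              mixture_weights = c(nonresponsive = 1),
                              seed = 1)
  expect_true(all(pop0$rois$archetype == "nonresponsive"))
  expect_equal(nrow(pop0$assemblies), 0L)
  expect_error(generate_population(mixture_weights = c(nonresponsive = 0.5)),
               "sum to 1")
})

test_that("noiseless fluorescence matches the planted forward model", {
  sched <- generate_schedule(1, 2, seed = 6)
  # plenty of NLMS and assembly cells, and a responsive behaviour model so
  # that evoked events (assembly hosts) are guaranteed
  pop <- generate_population(
    list(n_rois = 120L),
    mixture_weights = c(nonresponsive = 0.3, nlms = 0.5, assembly = 0.2),
    seed = 6)
  eager <- behavior_params(coef = c(intercept = 0, size = 0, polarity = 0,
                                    speed_size_polarity = 0),
                           spont_rate_hr = 0)
  eyes <- generate_eye_traces(sched, eager, seed = 6)
  dff <- generate_fluorescence(pop, sched, eyes$events, list(sd = 0),
                               seed = 6)
  expect_equal(nrow(dff$mat), nrow(sched) * 57L)

  silent <- which(pop$rois$archetype == "nonresponsive")
  expect_true(all(dff$mat[, silent] == 0))

  # nDS-nSp cell: equal peak response to the four large&dark stimuli only
  j <- which(pop$rois$subtype == "nDS-nSp")[1]
  expect_false(is.na(j))
  pk <- vapply(0:15, function(sid) {
    rows <- which(sched$stimulus_id == sid)
    max(vapply(rows, function(r) {
      max(dff$mat[(sched$epoch_index[r] - 1) * 57 + 1:57, j])
    }, numeric(1)))
  }, numeric(1))
  ld <- c(3, 7, 11, 15) + 1
  expect_true(all(pk[ld] > 0))
  expect_equal(max(pk[ld]) - min(pk[ld]), 0, tolerance = 1e-12)
  expect_true(all(pk[-ld] == 0))

  # planted assembly burst starts exactly lead_frames before the saccade frame
  ae <- dff$assembly_events
  expect_gt(nrow(ae), 0)
  aid <- ae$assembly_id[1]
  members <- pop$rois$roi_id[!is.na(pop$rois$assembly_id) &
                               pop$rois$assembly_id == aid]
  lead <- pop$assemblies$lead_frames[pop$assemblies$assembly_id == aid]
  g0 <- (ae$epoch_index[1] - 1) * 57
  burst_start <- ae$saccade_frame[1] - lead
  pure <- dff$mat[g0 + 1:57, members[1]]
  # subtract the visual component measured in a non-burst epoch of the same
  # stimulus to isolate the burst
  other <- setdiff(which(sched$stimulus_id ==
                           sched$stimulus_id[ae$epoch_index[1]]),
                   ae$epoch_index[1])[1]
  vis <- dff$mat[(sched$epoch_index[other] - 1) * 57 + 1:57, members[1]]
  burst <- pure - vis
  expect_equal(min(which(burst > 1e-9)), burst_start)
})

test_that("rendered movies reproduce the frame grid and planted motion", {
  sched <- generate_schedule(1, 1, seed = 8)[1:4, ]
  sched$epoch_index <- 1:4
  pop <- generate_population(list(n_rois = 30L), seed = 8)
  eyes <- generate_eye_traces(sched, seed = 8)
  dff <- generate_fluorescence(pop, sched, eyes$events, list(sd = 0), seed = 8)
  mov <- render_movie(pop, dff, frame_px = c(64L, 64L))
  expect_equal(dim(mov)[1], 4L * 57L)

  # zero traces, zero shifts: constant stack
  zero <- dff; zero$mat[] <- 0
  mz <- render_movie(pop, zero, frame_px = c(64L, 64L))
  expect_true(all(apply(mz, 1, function(f) identical(f, mz[1, , ]))))

  # TIFF round trip preserves page count
  tf <- tempfile(fileext = ".tif")
  render_movie(pop, zero, frame_px = c(32L, 32L), file = tf)
  expect_equal(length(tiff::readTIFF(tf, all = TRUE)), 4L * 57L)
  unlink(tf)
})
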