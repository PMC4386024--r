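# Convergence-triggered modulation windows, assembly detection, lead times,
# correlations, permutation FDR, and oculomotor statistics.

# A dedicated experiment with many planted assemblies at a fixed 3-frame
# lead and a responsive behaviour model so that every assembly finds a host
# event.
asm_exp <- function() {
  if (is.null(.fixtures$asm_exp)) {
    .fixtures$asm_exp <- synth_experiment(
      n_planes = 1, reps = 8, seed = 55,
      geometry = list(n_rois = 260L, assembly_lead = 3L),
      weights = c(nonresponsive = 0.45, ms = 0.05, assembly = 0.5),
      behavior = behavior_params(
        coef = c(intercept = -2, size = 0, polarity = 0,
                 speed_size_polarity = 0),
        spont_rate_hr = 0),
      noise = list(sd = 0.1))
  }
  .fixtures$asm_exp
}

asm_events <- function() {
  if (is.null(.fixtures$asm_events)) {
    exp <- asm_exp()
    .fixtures$asm_events <-
      classify_evoked(detect_convergent_saccades(exp$eyes), exp$schedule)
  }
  .fixtures$asm_events
}

test_that("window arithmetic is exact on the frame grid", {
  expect_equal(preytect:::conv_window_frames(10, "pre"), 7:9)
  expect_equal(preytect:::conv_window_frames(10, "peri"), 8:12)
  # 3 frames at 1.8 Hz ~ 1.65 s; 5 frames ~ 2.78 s
  expect_equal(round(3 / 1.8, 2), 1.67)
  expect_lt(abs(5 / 1.8 - 2.75), 0.05)
})

test_that("planted assembly cells are modulated pre-conv; nulls are calibrated", {
  exp <- asm_exp()
  ev <- asm_events()
  ae <- exp$dff$assembly_events
  expect_gt(nrow(ae), 3)
  # find the detected event row matching the first hosted assembly
  r <- which(abs(ev$t_onset - ae$t_onset[1]) < 0.5)[1]
  expect_false(is.na(r))
  mod <- conv_modulation(exp$dff, exp$schedule, ev, r, "pre")
  rois <- exp$population$rois
  members <- rois$roi_id[!is.na(rois$assembly_id) &
                           rois$assembly_id == ae$assembly_id[1]]
  hit <- mod$p[members] < 0.05 & mod$snr[members] > 3
  expect_gt(mean(hit), 0.8)
  # null cells show approximately uniform p-values
  null_cells <- rois$roi_id[rois$archetype == "nonresponsive"]
  expect_lt(mean(mod$p[null_cells] < 0.05), 0.15)
  # the joint p/SNR gate passes almost no null cells
  expect_lte(mean(mod$p[null_cells] < 0.05 & mod$snr[null_cells] > 3), 0.02)
})

test_that("a post-saccadic burst is peri-conv but not pre-conv modulated", {
  sched <- generate_schedule(1, 5, seed = 56)
  # one synthetic cell bursting one frame after the saccade frame
  sid <- sched$stimulus_id[!sched$is_flash][1]
  rows <- which(sched$stimulus_id == sid)
  resp_epoch <- sched$epoch_index[rows[1]]
  s <- 20L
  mat <- matrix(rnorm(nrow(sched) * 57, 0, 0.05), ncol = 1)
  g0 <- (resp_epoch - 1) * 57
  mat[g0 + s + 1:3, 1] <- c(3, 2, 1.4)   # burst one frame post-saccade + decay
  traces <- structure(list(mat = mat, fs = 1.8, frames_per_epoch = 57,
                           n_epochs = nrow(sched)), class = "dff_traces")
  ev <- data.frame(t_onset = sched$epoch_onset[rows[1]] + (s - 0.5) / 1.8,
                   evoked = TRUE, epoch_index = resp_epoch,
                   stimulus_id = sid)
  pre <- conv_modulation(traces, sched, ev, 1, "pre")
  peri <- conv_modulation(traces, sched, ev, 1, "peri")
  expect_true(peri$p[1] < 0.05 && peri$snr[1] > 3)
  expect_false(pre$p[1] < 0.05 && pre$snr[1] > 3)

  # spontaneous variant: a burst in the window is modulated, a burst 10
  # frames earlier is not
  evs <- data.frame(t_onset = sched$epoch_onset[rows[2]] + (s - 0.5) / 1.8,
                    evoked = FALSE, epoch_index = NA_integer_,
                    stimulus_id = NA_integer_)
  mat2 <- matrix(rnorm(nrow(sched) * 57, 0, 0.05), ncol = 1)
  g2 <- (sched$epoch_index[rows[2]] - 1) * 57
  mat2[g2 + (s - 3):(s - 1), 1] <- 3
  tr2 <- structure(list(mat = mat2, fs = 1.8, frames_per_epoch = 57,
                        n_epochs = nrow(sched)), class = "dff_traces")
  m2 <- spontaneous_modulation(tr2, sched, evs, 1, "pre")
  expect_true(m2$p[1] < 0.05 && m2$snr[1] > 3)
  mat3 <- matrix(rnorm(nrow(sched) * 57, 0, 0.05), ncol = 1)
  mat3[g2 + (s - 13):(s - 11), 1] <- 3
  tr3 <- structure(list(mat = mat3, fs = 1.8, frames_per_epoch = 57,
                        n_epochs = nrow(sched)), class = "dff_traces")
  m3 <- spontaneous_modulation(tr3, sched, evs, 1, "pre")
  expect_false(m3$p[1] < 0.05 && m3$snr[1] > 3)
})

test_that("assembly geometry gates are exact at their boundaries", {
  mkmod <- function(n, spread, hemi = "L") {
    set.seed(57)
    th <- seq(0, 2 * pi, length.out = n + 1)[-1]
    rr <- spread * sqrt(runif(n))
    data.frame(roi = seq_len(n), p = 1e-6, snr = 10,
               x = -100 + rr * cos(th), y = 150 + rr * sin(th))
  }
  roi_tab <- function(m) data.frame(roi_id = m$roi, x_um = m$x, y_um = m$y,
                                    hemisphere = "L", region = "OTc-SPV")
  # five cells can never satisfy the six-cell minimum
  m5 <- mkmod(5, 10)
  expect_length(detect_assembly(m5[, 1:3], roi_tab(m5)), 0L)
  # six tightly packed cells are accepted (boundary n = min_cells)
  m6 <- mkmod(6, 10)
  a6 <- detect_assembly(m6[, 1:3], roi_tab(m6))
  expect_length(a6, 1L)
  expect_equal(a6[[1]]$n, 6L)
  expect_lte(a6[[1]]$density, 533)
  # eight cells in a 30 um disk pass the density gate
  m8 <- mkmod(8, 30)
  a8 <- detect_assembly(m8[, 1:3], roi_tab(m8))
  expect_length(a8, 1L)
  expect_lte(a8[[1]]$area_um2, 8 * 533)
  # eight cells spread over 400 um fail it
  mspread <- mkmod(8, 400)
  mspread$y <- 150 + (mspread$y - 150) * 0.25   # keep inside the map range
  expect_length(detect_assembly(mspread[, 1:3], roi_tab(mspread)), 0L)
  # collinear centroids do not crash (minimum-axis floor)
  mc <- mkmod(7, 10)
  mc$y <- 150
  expect_no_error(detect_assembly(mc[, 1:3], roi_tab(mc)))
})

test_that("planted assemblies are recovered with hemisphere and members", {
  exp <- asm_exp()
  ev <- asm_events()
  rois <- exp$population$rois
  pre <- find_assemblies(exp$dff, exp$schedule, ev, rois, "pre")
  ae <- exp$dff$assembly_events
  truth <- exp$population$assemblies
  hosted <- truth[truth$assembly_id %in% ae$assembly_id, ]
  # match each hosted planted assembly to a detection at the same event;
  # assemblies whose host saccade itself went undetected are out of scope
  recovered <- 0
  n_eligible <- 0
  for (i in seq_len(nrow(hosted))) {
    t_on <- ae$t_onset[ae$assembly_id == hosted$assembly_id[i]]
    r <- which(abs(ev$t_onset - t_on) < 0.5)[1]
    if (is.na(r)) next
    n_eligible <- n_eligible + 1
    det <- Filter(function(a) a$event_row == r &&
                    a$hemisphere == hosted$hemisphere[i], pre)
    if (!length(det)) next
    members_true <- rois$roi_id[!is.na(rois$assembly_id) &
                                  rois$assembly_id == hosted$assembly_id[i]]
    recall <- max(vapply(det, function(a) {
      mean(members_true %in% a$members)
    }, numeric(1)))
    if (recall >= 0.8) recovered <- recovered + 1
  }
  expect_gte(n_eligible, 8)
  expect_gte(recovered / n_eligible, 0.9)

  # matched pure-noise dataset yields no assemblies
  noise_exp <- synth_experiment(
    n_planes = 1, reps = 5, seed = 58,
    geometry = list(n_rois = 260L),
    weights = c(nonresponsive = 1),
    noise = list(sd = 0.1))
  npre <- find_assemblies(noise_exp$dff, noise_exp$schedule, ev,
                          noise_exp$population$rois, "pre")
  expect_length(npre, 0L)
})

test_that("lead times are exact on noiseless planted bursts", {
  sched <- generate_schedule(1, 2, seed = 59)
  nf <- nrow(sched) * 57
  s <- 20L
  epoch <- 3L
  g0 <- (epoch - 1) * 57
  mk_traces <- function(burst_frames) {
    mat <- matrix(0, nf, 8)
    for (j in 1:8) mat[g0 + burst_frames, j] <- 1
    structure(list(mat = mat, fs = 1.8, frames_per_epoch = 57,
                   n_epochs = nrow(sched)), class = "dff_traces")
  }
  ev <- data.frame(t_onset = sched$epoch_onset[epoch] + (s - 0.5) / 1.8,
                   epoch_index = epoch)
  asm <- list(members = 1:8, hemisphere = "L")
  lt3 <- assembly_lead_time(asm, mk_traces((s - 3):(s + 1)), ev[1, ], sched)
  expect_equal(lt3$lead_frames, 3L)
  expect_equal(lt3$lead_s, 3 / 1.8)
  lt0 <- assembly_lead_time(asm, mk_traces(s:(s + 2)), ev[1, ], sched)
  expect_equal(lt0$lead_frames, 0L)
  # threshold never crossed before the saccade
  ltn <- assembly_lead_time(asm, mk_traces((s + 5):(s + 7)), ev[1, ], sched)
  expect_null(ltn)
})

test_that("intra-assembly correlations summarise member coherence", {
  sched <- generate_schedule(1, 1, seed = 60)
  nf <- nrow(sched) * 57
  base <- sin(seq(0, 6 * pi, length.out = 57))
  asm <- list(members = 1:10)
  # identical members
  mat <- matrix(rep(c(base, rep(0, nf - 57)), 10), nf, 10)
  tr <- structure(list(mat = mat, fs = 1.8, frames_per_epoch = 57,
                       n_epochs = nrow(sched)), class = "dff_traces")
  ic <- intra_assembly_correlation(asm, tr, 1L)
  expect_equal(ic$r_avg, 1)
  # independent noise members
  set.seed(61)
  tr$mat <- matrix(rnorm(nf * 10), nf, 10)
  ic0 <- intra_assembly_correlation(asm, tr, 1L)
  expect_lt(abs(ic0$r_avg), 0.3)
  # common burst with noise at one fifth of the burst amplitude
  burst <- c(rep(0, 15), rep(1, 6), rep(0, 36))
  tr$mat <- matrix(rep(c(burst, rep(0, nf - 57)), 10), nf, 10) +
    matrix(rnorm(nf * 10, 0, 0.2), nf, 10)
  ic2 <- intra_assembly_correlation(asm, tr, 1L)
  expect_gt(ic2$r_avg, 0.8)
  # constant members are excluded rather than propagating NAs
  tr$mat[, 3] <- 5
  ic3 <- intra_assembly_correlation(asm, tr, 1L)
  expect_true(is.na(ic3$per_cell[3]))
  expect_false(is.na(ic3$r_avg))
})

test_that("circular-permutation FDR is low for planted and ~1 for null data", {
  exp <- asm_exp()
  ev <- asm_events()
  fdr <- fdr_circular_permutation(exp$dff, exp$schedule, ev,
                                  exp$population$rois, "pre", n_perm = 3,
                                  seed = 62)
  expect_gt(fdr$original_count, 0)
  expect_lt(fdr$fdr, 0.25)

  # with gates relaxed to pass noise, original and shuffled counts match and
  # the estimate sits near 1
  noise_exp <- synth_experiment(
    n_planes = 1, reps = 5, seed = 63,
    geometry = list(n_rois = 120L),
    weights = c(nonresponsive = 1),
    noise = list(sd = 0.1))
  fdr0 <- fdr_circular_permutation(noise_exp$dff, noise_exp$schedule, ev,
                                   noise_exp$population$rois, "pre",
                                   n_perm = 3, seed = 64,
                                   alpha = 0.9, snr_min = -10, min_cells = 2L,
                                   max_density = 1e9)
  expect_gt(fdr0$original_count, 0)
  expect_gt(fdr0$fdr, 0.5)
  expect_lt(fdr0$fdr, 2)
})

test_that("laterality and AP-location statistics recover planted structure", {
  set.seed(65)
  n <- 40
  hemi <- rep(c("L", "R"), n / 2)
  d_ipsi <- rnorm(n, 12, 1.5)
  d_contra <- d_ipsi - 3 + rnorm(n, 0, 0.5)
  events <- data.frame(
    post_left = ifelse(hemi == "L", d_ipsi, d_contra) + 10,
    post_right = ifelse(hemi == "L", d_contra, d_ipsi) + 10,
    d_left = ifelse(hemi == "L", d_ipsi, d_contra),
    d_right = ifelse(hemi == "L", d_contra, d_ipsi),
    peak_vel_left = ifelse(hemi == "L", d_ipsi, d_contra) * 10,
    peak_vel_right = ifelse(hemi == "L", d_contra, d_ipsi) * 10)
  assemblies <- lapply(seq_len(n), function(i) {
    list(hemisphere = hemi[i], event_row = i, center = c(0, 100),
         members = 1:6)
  })
  tab <- laterality_oculomotor_stats(assemblies, events)
  expect_true(all(tab$mean_ipsi > tab$mean_contra))
  expect_true(all(tab$p_paired < 0.01))
  # symmetric generator: typically no laterality signal (fixed seed)
  ev_sym <- events
  ev_sym$d_left <- rnorm(n, 10, 1); ev_sym$d_right <- rnorm(n, 10, 1)
  ev_sym$post_left <- rnorm(n, 20, 1); ev_sym$post_right <- rnorm(n, 20, 1)
  ev_sym$peak_vel_left <- rnorm(n, 100, 5)
  ev_sym$peak_vel_right <- rnorm(n, 100, 5)
  tab_sym <- laterality_oculomotor_stats(assemblies, ev_sym)
  expect_true(all(tab_sym$p_paired > 0.05))
  expect_error(laterality_oculomotor_stats(assemblies[1], events), ">= 2")

  # AP-location trend: planted positive right-eye / negative left-eye slope
  ap <- runif(n, 20, 200)
  ev_ap <- events
  ev_ap$d_right <- 5 + 0.03 * ap + rnorm(n, 0, 0.3)
  ev_ap$d_left <- 12 - 0.03 * ap + rnorm(n, 0, 0.3)
  asm_ap <- lapply(seq_len(n), function(i) {
    list(hemisphere = hemi[i], event_row = i, center = c(0, 65 + ap[i]),
         members = 1:6)
  })
  tr <- ap_location_trend(asm_ap, ev_ap)
  expect_true(all(tr$slope[tr$eye == "right"] > 0))
  expect_true(all(tr$slope[tr$eye == "left"] < 0))
  # slope invariance under landmark translation
  tr2 <- ap_location_trend(asm_ap, ev_ap, landmark = c(x = 0, y = 165))
  expect_equal(tr$slope, tr2$slope, tolerance = 1e-10)
  # location-independent generator: slopes near zero
  tr0 <- ap_location_trend(asm_ap, events)
  expect_true(all(abs(tr0$slope) < 0.02))
})

test_that("pre/peri overlap fractions follow the planted window structure", {
  a <- function(ev, members, hemi = "L") {
    list(event_row = ev, members = members, hemisphere = hemi)
  }
  pre <- list(a(1, 1:8), a(2, 11:18))
  peri_same <- list(a(1, 1:8), a(2, 11:18))
  ov <- overlap_stats(pre, peri_same)
  expect_equal(ov$event_overlap, 1)
  expect_equal(ov$cell_overlap, 1)
  peri_disjoint <- list(a(1, 21:28), a(3, 31:38))
  ov2 <- overlap_stats(pre, peri_disjoint)
  expect_equal(ov2$event_overlap, 0.5)
  expect_equal(ov2$cell_overlap, 0)

  # planted bursts spanning both windows: detected pre members reappear in
  # the peri assemblies of the same events
  exp <- asm_exp()
  ev <- asm_events()
  rois <- exp$population$rois
  pre_d <- find_assemblies(exp$dff, exp$schedule, ev, rois, "pre")
  peri_d <- find_assemblies(exp$dff, exp$schedule, ev, rois, "peri")
  ov3 <- overlap_stats(pre_d, peri_d)
  expect_gt(ov3$cell_overlap, 0.5)
  expect_gt(ov3$event_overlap, 0.5)
})
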