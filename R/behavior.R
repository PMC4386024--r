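# Eye-trace analytics: vergence, convergent-saccade detection, kinematics,
# evoked/spontaneous classification, and response-location statistics.

#' Binocular vergence time series
#'
#' Vergence is the sum of the two nasal-positive eye angles.
#'
#' @param trace An `eye_trace` (list with `left`, `right`, `fs`) or any list
#'   with those elements.
#' @return Numeric vector of vergence angles (deg).
#' @export
compute_vergence <- function(trace) {
  if (length(trace$left) != length(trace$right)) {
    stopf("left/right channels differ in length")
  }
  trace$left + trace$right
}

#' Default convergent-saccade detector parameters
#'
#' The assay's defining criterion is binocular: nasal rotations of both eyes
#' with onsets within 150 ms of one another. The velocity and displacement
#' gates below only reject fixation noise; they are deliberately permissive
#' (20 deg/s, 1 deg/eye) so that the detector stays sensitive across the full
#' empirical range of vergence changes (mean 19 deg, SD 9.3 deg implies that
#' a strict per-eye gate would censor the lower quartile of real events and
#' bias amplitude statistics upward).
#'
#' @param ... Named overrides.
#' @return Named list: `smooth_s`, `vel_thresh_dps`, `min_disp_deg`,
#'   `max_asynchrony_s`, `refractory_s`.
#' @export
saccade_params <- function(...) {
  p <- list(smooth_s = 0.05, vel_thresh_dps = 20, min_disp_deg = 1,
            max_asynchrony_s = 0.15, refractory_s = 1)
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) stopf("unknown detector parameter(s): %s",
                         paste(bad, collapse = ", "))
  p[names(over)] <- over
  p
}

# Onset samples of maximal runs where smoothed nasal velocity >= threshold.
velocity_onsets <- function(x, fs, smooth_s, thresh) {
  v <- c(0, diff(running_mean(x, smooth_s * fs))) * fs
  above <- v >= thresh
  onsets <- which(above & !c(FALSE, above[-length(above)]))
  list(onsets = onsets, velocity = v)
}

#' Detect convergent saccades in a binocular eye trace
#'
#' Finds events where both eyes show a nasal rotation exceeding the velocity
#' and displacement gates, with onsets within `max_asynchrony_s` of one
#' another. The event onset is the earlier eye's threshold crossing;
#' kinematics are populated via [saccade_kinematics()].
#'
#' @param trace An `eye_trace`.
#' @param params Detector parameters from [saccade_params()].
#' @return Data frame of class `saccade_events`, one row per event: `t_onset`
#'   (s), per-eye pre/post positions, displacement and peak nasal velocity,
#'   `dvergence`, plus `evoked`, `epoch_index`, `stimulus_id`,
#'   `azimuth_at_event` placeholders filled by [classify_evoked()].
#' @export
detect_convergent_saccades <- function(trace, params = saccade_params()) {
  fs <- trace$fs
  n <- length(trace$left)
  if (n < params$smooth_s * fs + 2) stopf("trace shorter than smoothing window")
  L <- velocity_onsets(trace$left, fs, params$smooth_s, params$vel_thresh_dps)
  R <- velocity_onsets(trace$right, fs, params$smooth_s, params$vel_thresh_dps)
  tol <- round(params$max_asynchrony_s * fs)
  cand <- integer(0)
  if (length(L$onsets) && length(R$onsets)) {
    for (i in L$onsets) {
      js <- R$onsets[abs(R$onsets - i) <= tol]
      if (length(js)) cand <- c(cand, min(i, min(js)))
    }
  }
  cand <- sort(unique(cand))
  # refractory: keep the first onset of each burst
  if (length(cand) > 1L) {
    keep <- c(TRUE, diff(cand) > params$refractory_s * fs)
    cand <- cand[keep]
  }
  vel <- list(left = L$velocity, right = R$velocity)
  rows <- lapply(cand, function(i) {
    ev <- tryCatch(saccade_kinematics(list(t_onset = (i - 1) / fs), trace,
                                      velocities = vel),
                   error = function(e) NULL)
    if (is.null(ev)) return(NULL)
    # displacement gate: both eyes must rotate nasally by >= min_disp_deg
    if (is.na(ev$d_left) || is.na(ev$d_right)) return(NULL)
    if (ev$d_left < params$min_disp_deg || ev$d_right < params$min_disp_deg) {
      return(NULL)
    }
    ev
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else empty_events()
  out$evoked <- rep(NA, nrow(out))
  out$epoch_index <- rep(NA_integer_, nrow(out))
  out$stimulus_id <- rep(NA_integer_, nrow(out))
  out$azimuth_at_event <- rep(NA_real_, nrow(out))
  class(out) <- c("saccade_events", "data.frame")
  out
}

empty_events <- function() {
  data.frame(t_onset = numeric(0), pre_left = numeric(0),
             post_left = numeric(0), pre_right = numeric(0),
             post_right = numeric(0), d_left = numeric(0),
             d_right = numeric(0), peak_vel_left = numeric(0),
             peak_vel_right = numeric(0), dvergence = numeric(0))
}

#' Saccade kinematics from pre/post window means
#'
#' Pre- and post-saccadic positions are window means (default 200 ms windows;
#' the post window starts 250 ms after onset so that the slower eye's ramp,
#' up to 150 ms asynchrony plus ~100 ms duration, has completed). Peak nasal
#' velocity is the maximum smoothed derivative within 400 ms of onset.
#'
#' @param event List or one-row data frame with `t_onset` (s).
#' @param trace An `eye_trace`.
#' @param windows List: `window_s` (0.2), `pre_gap_s` (0.05), `post_gap_s`
#'   (0.25), `vel_win_s` (0.4), `smooth_s` (0.05).
#' @param velocities Optional list with precomputed smoothed nasal velocity
#'   vectors `left`, `right` (deg/s), to avoid re-smoothing long traces.
#' @return One-row data frame with per-eye pre/post positions, displacements,
#'   peak velocities, and `dvergence`.
#' @export
saccade_kinematics <- function(event, trace, windows = list(),
                               velocities = NULL) {
  w <- utils::modifyList(list(window_s = 0.2, pre_gap_s = 0.05,
                              post_gap_s = 0.25, vel_win_s = 0.4,
                              smooth_s = 0.05), windows)
  fs <- trace$fs
  n <- length(trace$left)
  i0 <- round(event$t_onset * fs) + 1
  pre_idx <- seq(round(i0 - (w$pre_gap_s + w$window_s) * fs),
                 round(i0 - w$pre_gap_s * fs))
  post_idx <- seq(round(i0 + w$post_gap_s * fs),
                  round(i0 + (w$post_gap_s + w$window_s) * fs))
  if (min(pre_idx) < 1 || max(post_idx) > n) {
    stopf("kinematics window exceeds trace bounds")
  }
  vel_idx <- seq(max(1, i0 - 2), min(n, round(i0 + w$vel_win_s * fs)))
  if (is.null(velocities)) {
    vL <- c(0, diff(running_mean(trace$left, w$smooth_s * fs))) * fs
    vR <- c(0, diff(running_mean(trace$right, w$smooth_s * fs))) * fs
  } else {
    vL <- velocities$left; vR <- velocities$right
  }
  pre_l <- mean(trace$left[pre_idx]); post_l <- mean(trace$left[post_idx])
  pre_r <- mean(trace$right[pre_idx]); post_r <- mean(trace$right[post_idx])
  data.frame(
    t_onset = event$t_onset,
    pre_left = pre_l, post_left = post_l,
    pre_right = pre_r, post_right = post_r,
    d_left = post_l - pre_l, d_right = post_r - pre_r,
    peak_vel_left = max(vL[vel_idx]), peak_vel_right = max(vR[vel_idx]),
    dvergence = (post_l + post_r) - (pre_l + pre_r)
  )
}

#' Label detected saccades as evoked or spontaneous
#'
#' An event is evoked when its onset falls inside the spot- (or flash-)
#' presentation interval of its epoch; evoked events get the epoch index,
#' stimulus id, and the spot azimuth at onset.
#'
#' @param events A `saccade_events` data frame.
#' @param schedule A [generate_schedule()] schedule.
#' @return `events` with `evoked`, `epoch_index`, `stimulus_id`, and
#'   `azimuth_at_event` filled in.
#' @export
classify_evoked <- function(events, schedule) {
  if (!nrow(events)) return(events)
  for (r in seq_len(nrow(events))) {
    t0 <- events$t_onset[r]
    k <- which(schedule$epoch_onset <= t0 & t0 < schedule$epoch_onset + EPOCH_S)
    evoked <- FALSE
    if (length(k) == 1L && !schedule$is_flash[k] &&
        t0 >= schedule$spot_onset[k] && t0 <= schedule$spot_offset[k]) {
      evoked <- TRUE
      events$epoch_index[r] <- schedule$epoch_index[k]
      events$stimulus_id[r] <- schedule$stimulus_id[k]
      events$azimuth_at_event[r] <- spot_azimuth(schedule[k, ], t0)
    }
    events$evoked[r] <- evoked
  }
  events
}

#' Spatial statistics of hunting-response locations
#'
#' Summarises spot azimuths at evoked convergent saccades: the median
#' azimuth with a Wilcoxon signed-rank test against 0 deg, and
#' Kolmogorov-Smirnov comparisons of the azimuth distributions for
#' left-right versus right-left spots and (after mirroring all azimuths to a
#' common left-right motion convention) slow versus fast spots.
#'
#' @param events Classified `saccade_events` (see [classify_evoked()]).
#' @return List: `n`, `median_azimuth`, `p_signed_rank`, `p_direction_ks`,
#'   `p_speed_ks`.
#' @export
response_location_stats <- function(events) {
  ev <- events[!is.na(events$evoked) & events$evoked &
                 !is.na(events$azimuth_at_event), , drop = FALSE]
  if (!nrow(ev)) stopf("no evoked events")
  az <- ev$azimuth_at_event
  direction <- ev$stimulus_id %/% 8L
  speed <- (ev$stimulus_id %/% 4L) %% 2L
  p_sr <- tryCatch(stats::wilcox.test(az, mu = 0, exact = FALSE)$p.value,
                   error = function(e) NA_real_)
  p_dir <- if (length(unique(direction)) == 2L) {
    suppressWarnings(stats::ks.test(az[direction == 1], az[direction == 0])$p.value)
  } else NA_real_
  # mirror so all azimuths are expressed as if the spot moved left-to-right
  az_lr <- ifelse(direction == 1, az, -az)
  p_sp <- if (length(unique(speed)) == 2L) {
    suppressWarnings(stats::ks.test(az_lr[speed == 1], az_lr[speed == 0])$p.value)
  } else NA_real_
  list(n = nrow(ev), median_azimuth = stats::median(az), p_signed_rank = p_sr,
       p_direction_ks = p_dir, p_speed_ks = p_sp)
}

#' Per-stimulus hunting response rates
#'
#' Response rate R(s) = fraction of epochs of moving-spot stimulus s that
#' contain an evoked convergent saccade.
#'
#' @param events Classified `saccade_events`.
#' @param schedule Schedule data frame.
#' @return Data frame with one row per moving-spot stimulus: `stimulus_id`,
#'   feature bits, `n_trials`, `n_responses`, `rate`.
#' @export
response_rate_table <- function(events, schedule) {
  if (!nrow(schedule)) stopf("empty schedule")
  st <- stimulus_table()[1:16, ]
  resp_epochs <- unique(events$epoch_index[!is.na(events$epoch_index)])
  n_tr <- n_re <- integer(16)
  for (i in 1:16) {
    sid <- st$stimulus_id[i]
    epochs <- schedule$epoch_index[schedule$stimulus_id == sid]
    n_tr[i] <- length(epochs)
    n_re[i] <- sum(epochs %in% resp_epochs)
  }
  data.frame(stimulus_id = st$stimulus_id, direction = st$direction,
             speed = st$speed, size = st$size, polarity = st$polarity,
             n_trials = n_tr, n_responses = n_re,
             rate = ifelse(n_tr > 0, n_re / n_tr, NA_real_))
}

#' Angular geometry of a nearby object
#'
#' Converts physical object size, distance, and tangential speed into the
#' angular size and speed it subtends at the eye: size from the exact
#' subtended angle 2*atan(size / (2*distance)), speed from the small-angle
#' rate speed/distance (rad/s) expressed in deg/s. A 135 um object 0.5 mm
#' away moving at 0.5 mm/s subtends ~15 deg moving at ~57 deg/s.
#'
#' @param object_size_mm Object diameter (mm).
#' @param distance_mm Viewing distance (mm); must be positive.
#' @param speed_mm_s Tangential speed (mm/s); optional.
#' @return List: `angular_size_deg`, `angular_speed_dps` (`NA` if speed is
#'   missing).
#' @export
angular_geometry <- function(object_size_mm, distance_mm, speed_mm_s = NA) {
  if (any(distance_mm <= 0)) stopf("distance must be positive")
  if (any(object_size_mm < 0)) stopf("object size must be non-negative")
  size_deg <- 2 * atan(object_size_mm / (2 * distance_mm)) * 180 / pi
  speed_dps <- (speed_mm_s / distance_mm) * 180 / pi
  list(angular_size_deg = size_deg, angular_speed_dps = speed_dps)
}
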