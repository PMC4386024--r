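# Stimulus panel, binary feature coding, and pseudo-random schedules.
#
# The virtual hunting assay presents 18 stimuli: 16 moving spots spanning a
# 2x2x2x2 factorial of binary features, plus two whole-field flashes. Each
# feature is coded as a bit:
#   direction: left-to-right = 1, right-to-left = 0
#   speed:     fast (30 deg/s) = 1, slow (15 deg/s) = 0
#   size:      large (13.2 deg) = 1, small (3.5 deg) = 0
#   polarity:  dark = 1, bright = 0
# The canonical stimulus order is id = 8*direction + 4*speed + 2*size +
# polarity for spots (0-15), then 16 = dim flash, 17 = bright flash.
# Spots appear 100 deg lateral and sweep 200 deg across the frontal field at
# constant speed (negative azimuth = left). Dark-spot epochs carry a
# background-luminance step from 2 s before spot onset to 2 s after offset.

SPOT_ONSET_S <- 4    # spot/flash onset within the epoch
FLASH_DUR_S <- 3

#' The 18-stimulus panel with binary feature codes
#'
#' Returns one row per stimulus in canonical order: the 16 moving spots
#' (factorial of direction/speed/size/polarity bits) followed by the dim
#' (id 16) and bright (id 17) whole-field flashes.
#'
#' @return A data frame with columns `stimulus_id`, `direction`, `speed`,
#'   `size`, `polarity` (bits, `NA` for flashes), `spot_speed_dps`,
#'   `spot_diam_deg`, `is_flash`, and `weber_contrast`.
#' @export
#' @examples
#' stimulus_table()
stimulus_table <- function() {
  id <- 0:15
  direction <- id %/% 8L
  speed <- (id %/% 4L) %% 2L
  size <- (id %/% 2L) %% 2L
  polarity <- id %% 2L
  spots <- data.frame(
    stimulus_id = id,
    direction = direction, speed = speed, size = size, polarity = polarity,
    spot_speed_dps = ifelse(speed == 1L, 30, 15),
    spot_diam_deg = ifelse(size == 1L, 13.2, 3.5),
    is_flash = FALSE,
    weber_contrast = ifelse(polarity == 1L, -0.97, 370)
  )
  flashes <- data.frame(
    stimulus_id = 16:17,
    direction = NA_integer_, speed = NA_integer_, size = NA_integer_,
    polarity = NA_integer_,
    spot_speed_dps = NA_real_, spot_diam_deg = NA_real_,
    is_flash = TRUE,
    weber_contrast = NA_real_
  )
  rbind(spots, flashes)
}

#' Generate a pseudo-random stimulus schedule
#'
#' Builds the trial structure of a synthetic imaging session: per focal plane,
#' `reps` repetitions of each of the 18 stimuli in a seeded pseudo-random
#' order, one stimulus per 32 s epoch. Dark-spot epochs carry the
#' background-luminance step interval (2 s before spot onset to 2 s after
#' offset).
#'
#' @param n_planes Number of focal planes (sessions are concatenated in time).
#' @param reps Repetitions of each stimulus per plane (the assay used 5-8).
#' @param seed Integer seed; fully determines the permutation.
#' @return A data frame of epochs with columns `plane`, `epoch_index`
#'   (1-based, global), `stimulus_id`, the four feature bits, `epoch_onset`
#'   (s), `spot_onset`, `spot_offset` (absolute s, flash interval for
#'   flashes), `bg_step_on`, `bg_step_off` (dark-spot epochs, else `NA`),
#'   `start_azimuth`, `spot_speed_dps`, `spot_diam_deg`, `is_flash`.
#' @export
#' @examples
#' sched <- generate_schedule(1, 5, seed = 1)
#' table(sched$stimulus_id)
generate_schedule <- function(n_planes = 1L, reps = 5L, seed = NULL) {
  if (length(reps) != 1L || is.na(reps) || reps < 1) {
    stopf("`reps` must be a positive integer")
  }
  if (n_planes < 1) stopf("`n_planes` must be a positive integer")
  stim <- stimulus_table()
  ids <- with_seed(seed, {
    unlist(lapply(seq_len(n_planes), function(p) {
      sample(rep(stim$stimulus_id, reps))
    }))
  })
  n <- length(ids)
  k <- match(ids, stim$stimulus_id)
  onset <- (seq_len(n) - 1) * EPOCH_S
  traverse <- 200 / stim$spot_speed_dps[k]
  spot_on <- onset + SPOT_ONSET_S
  spot_off <- ifelse(stim$is_flash[k], spot_on + FLASH_DUR_S, spot_on + traverse)
  dark <- !is.na(stim$polarity[k]) & stim$polarity[k] == 1L
  sched <- data.frame(
    plane = rep(seq_len(n_planes), each = N_STIM * reps),
    epoch_index = seq_len(n),
    stimulus_id = ids,
    direction = stim$direction[k], speed = stim$speed[k],
    size = stim$size[k], polarity = stim$polarity[k],
    epoch_onset = onset,
    spot_onset = spot_on,
    spot_offset = spot_off,
    bg_step_on = ifelse(dark, spot_on - 2, NA_real_),
    bg_step_off = ifelse(dark, spot_off + 2, NA_real_),
    start_azimuth = ifelse(stim$is_flash[k], NA_real_,
                           ifelse(stim$direction[k] == 1L, -100, 100)),
    spot_speed_dps = stim$spot_speed_dps[k],
    spot_diam_deg = stim$spot_diam_deg[k],
    is_flash = stim$is_flash[k]
  )
  class(sched) <- c("hunt_schedule", "data.frame")
  sched
}

#' Spot azimuth at a given time
#'
#' Linear spot trajectory within an epoch: the spot appears at +/-100 deg,
#' sweeps 200 deg toward the opposite side at its constant speed, and is
#' absent otherwise. Negative azimuth is left of the midline.
#'
#' @param epoch A single row of a schedule (see [generate_schedule()]).
#' @param t Time in seconds (same clock as the schedule); vectorised.
#' @return Azimuth in degrees, or `NA` outside the traverse interval and for
#'   flash epochs.
#' @export
spot_azimuth <- function(epoch, t) {
  if (nrow(epoch) != 1L) stopf("`epoch` must be a single schedule row")
  if (isTRUE(epoch$is_flash)) return(rep(NA_real_, length(t)))
  dirsign <- if (epoch$direction == 1L) 1 else -1
  az <- epoch$start_azimuth + dirsign * epoch$spot_speed_dps *
    (t - epoch$spot_onset)
  az[t < epoch$spot_onset | t > epoch$spot_offset] <- NA_real_
  az
}

# Inverse of spot_azimuth: time at which the spot is at azimuth `az`.
spot_time_at_azimuth <- function(epoch, az) {
  dirsign <- if (epoch$direction == 1L) 1 else -1
  epoch$spot_onset + dirsign * (az - epoch$start_azimuth) / epoch$spot_speed_dps
}
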