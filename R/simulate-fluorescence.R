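# Forward model from planted tuning to dF/F traces at the imaging frame rate.
#
# Each ROI's archetype defines a sparse train of latent activity impulses
# (e.g. an impulse when the moving spot crosses the cell's receptive-field
# azimuth, at a luminance transition, or a premotor burst starting
# `lead_frames` before a convergent saccade). The train is convolved with a
# difference-of-exponentials calcium-indicator kernel and sampled on the
# 1.8 Hz frame grid (57 frames per 32 s epoch), then Gaussian noise is added.

#' Calcium indicator impulse kernel on the imaging frame grid
#'
#' Difference-of-exponentials kernel (defaults: rise 0.1 s, decay 1.5 s,
#' generic fast-indicator values) evaluated at frame centres and normalised
#' to unit peak. Because the rise time is much shorter than the 0.56 s frame
#' interval, the discrete kernel peaks at the impulse frame.
#'
#' @param rise,decay Time constants in seconds.
#' @param fs Sampling rate (Hz).
#' @return Numeric vector of kernel taps (unit peak).
#' @export
calcium_kernel <- function(rise = 0.1, decay = 1.5, fs = IMG_HZ) {
  nk <- ceiling(5 * decay * fs) + 1L
  t <- (seq_len(nk) - 0.5) / fs
  h <- exp(-t / decay) - exp(-t / rise)
  h[h < 0] <- 0
  h / max(h)
}

# frame index (1-based, within epoch) of an absolute time
frame_of <- function(t, epoch_onset) {
  pmin(FRAMES_PER_EPOCH, pmax(1L, floor((t - epoch_onset) * IMG_HZ) + 1L))
}

# Latent impulse train (global frame index, amplitude) for one ROI.
roi_impulses <- function(roi, schedule, events, asm_events) {
  fr <- integer(0); am <- numeric(0)
  push <- function(epoch_row, within_frame, a) {
    fr <<- c(fr, (epoch_row$epoch_index - 1L) * FRAMES_PER_EPOCH + within_frame)
    am <<- c(am, a)
  }
  arch <- roi$archetype
  if (arch == "nonresponsive") return(data.frame(frame = fr, amp = am))

  if (arch %in% c("ms", "nlms", "assembly")) {
    w <- archetype_spot_weights(roi$subtype)
    for (i in seq_len(nrow(schedule))) {
      epo <- schedule[i, ]
      if (epo$is_flash || is.na(epo$stimulus_id) || epo$stimulus_id > 15) next
      wi <- w[epo$stimulus_id + 1L]
      if (wi <= 0) next
      tc <- spot_time_at_azimuth(epo, roi$rf_azimuth)
      if (tc >= epo$spot_onset && tc <= epo$spot_offset) {
        push(epo, frame_of(tc, epo$epoch_onset), roi$amplitude * wi)
      }
    }
  } else if (arch %in% c("lum_on", "lum_dim", "lum_inh")) {
    for (i in seq_len(nrow(schedule))) {
      epo <- schedule[i, ]
      if (epo$is_flash) {
        bright <- epo$stimulus_id == 17L
        if (arch == "lum_on" && bright) {
          push(epo, frame_of(epo$spot_onset, epo$epoch_onset), roi$amplitude)
        } else if (arch == "lum_on" && !bright) {
          push(epo, frame_of(epo$spot_onset, epo$epoch_onset), 0.4 * roi$amplitude)
        } else if (arch == "lum_dim") {
          push(epo, frame_of(epo$spot_offset, epo$epoch_onset), roi$amplitude)
        } else if (arch == "lum_inh") {
          f0 <- frame_of(epo$spot_onset, epo$epoch_onset)
          f1 <- frame_of(epo$spot_offset, epo$epoch_onset)
          for (f in f0:f1) push(epo, f, -0.15 * roi$amplitude)
        }
      } else if (!is.na(epo$bg_step_on)) {      # dark-spot background step
        if (arch == "lum_on") {
          push(epo, frame_of(epo$bg_step_on, epo$epoch_onset), 0.6 * roi$amplitude)
        } else if (arch == "lum_dim") {
          push(epo, frame_of(epo$bg_step_off, epo$epoch_onset), 0.6 * roi$amplitude)
        }
      }
    }
  }
  # premotor burst for assembly members, only in their assigned response trial
  if (arch == "assembly" && !is.na(roi$assembly_id) && nrow(asm_events)) {
    k <- which(asm_events$assembly_id == roi$assembly_id)
    if (length(k) == 1L && !is.na(asm_events$saccade_frame[k])) {
      s <- asm_events$saccade_frame[k]
      g0 <- (asm_events$epoch_index[k] - 1L) * FRAMES_PER_EPOCH
      for (f in max(1L, s - roi$lead_frames):s) {
        fr <- c(fr, g0 + f); am <- c(am, roi$amplitude)
      }
    }
  }
  data.frame(frame = fr, amp = am)
}

#' Generate dF/F fluorescence traces for a planted population
#'
#' @param population A [generate_population()] result.
#' @param schedule A [generate_schedule()] result.
#' @param events Ground-truth saccade events (the `events` element of a
#'   [generate_eye_traces()] trace); evoked events are matched, in order, to
#'   planted assemblies, whose member cells burst starting `lead_frames`
#'   before the saccade frame of their assigned event.
#' @param noise_params List: `sd` (additive Gaussian noise SD on dF/F,
#'   default 0.1), `kernel_rise`, `kernel_decay` (s).
#' @param seed Integer seed.
#' @return Object of class `dff_traces`: list with `mat` (frames x ROI dF/F
#'   matrix), `fs`, `frames_per_epoch`, `n_epochs`, and `assembly_events`
#'   (data frame mapping each planted assembly to its assigned event:
#'   `assembly_id`, `event_row`, `epoch_index`, `saccade_frame`, `t_onset`).
#' @export
generate_fluorescence <- function(population, schedule, events = NULL,
                                  noise_params = list(), seed = NULL) {
  np <- utils::modifyList(
    list(sd = 0.1, kernel_rise = 0.1, kernel_decay = 1.5), noise_params)
  if (np$sd < 0) stopf("noise SD must be non-negative")
  rois <- population$rois
  n_epochs <- nrow(schedule)
  nf <- n_epochs * FRAMES_PER_EPOCH
  kern <- calcium_kernel(np$kernel_rise, np$kernel_decay)

  # assign planted assemblies to evoked events, in order
  asm <- population$assemblies
  asm_events <- data.frame(assembly_id = integer(0), event_row = integer(0),
                           epoch_index = integer(0), saccade_frame = integer(0),
                           t_onset = numeric(0))
  if (!is.null(events) && nrow(asm)) {
    evoked <- which(events$evoked)
    npair <- min(nrow(asm), length(evoked))
    if (npair > 0) {
      rows <- evoked[seq_len(npair)]
      epo_i <- events$epoch_index[rows]
      s <- frame_of(events$t_onset[rows], schedule$epoch_onset[epo_i])
      asm_events <- data.frame(assembly_id = asm$assembly_id[seq_len(npair)],
                               event_row = rows, epoch_index = epo_i,
                               saccade_frame = as.integer(s),
                               t_onset = events$t_onset[rows])
    }
  }

  mat <- matrix(0, nrow = nf, ncol = nrow(rois))
  for (j in seq_len(nrow(rois))) {
    imp <- roi_impulses(rois[j, ], schedule, events, asm_events)
    if (nrow(imp)) {
      x <- numeric(nf)
      ok <- imp$frame >= 1L & imp$frame <= nf
      x[imp$frame[ok]] <- x[imp$frame[ok]] + imp$amp[ok]
      y <- numeric(nf)
      for (k in seq_along(kern)) {
        idx <- seq_len(nf - k + 1L)
        y[idx + k - 1L] <- y[idx + k - 1L] + kern[k] * x[idx]
      }
      mat[, j] <- y
    }
  }
  if (np$sd > 0) {
    mat <- mat + with_seed(seed, matrix(stats::rnorm(length(mat), 0, np$sd),
                                        nrow = nf))
  }
  colnames(mat) <- rois$roi_id
  structure(list(mat = mat, fs = IMG_HZ, frames_per_epoch = FRAMES_PER_EPOCH,
                 n_epochs = n_epochs, assembly_events = asm_events,
                 kernel = kern),
            class = "dff_traces")
}

#' @export
print.dff_traces <- function(x, ...) {
  cat(sprintf("<dff_traces> %d frames (%d epochs x %d) x %d ROIs at %.1f Hz\n",
              nrow(x$mat), x$n_epochs, x$frames_per_epoch, ncol(x$mat), x$fs))
  invisible(x)
}

# frames (global indices) belonging to one epoch
epoch_frames <- function(epoch_index, frames = VRV_FRAMES) {
  (epoch_index - 1L) * FRAMES_PER_EPOCH + seq_len(frames)
}
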