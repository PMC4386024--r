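# Synthetic binocular eye traces with planted convergent saccades.
#
# Angles are nasal-positive for each eye, so the vergence angle is the sum of
# the two channels. Hunting responses are Bernoulli per spot epoch with
# probability given by the behavioural logistic model (defaults are the
# printed feature-compound model), occur while the spot is near the midline,
# and increase vergence by ~19 deg. Spontaneous convergences are placed by a
# Poisson process outside stimulus-presentation windows.

#' Default behavioural simulation parameters
#'
#' Parameters of the eye-trace generator. The logistic coefficients default to
#' the published feature-compound model (intercept -6.51, size 1.33, polarity
#' 1.87, speed x size x polarity 0.90); the vergence-change distribution
#' defaults to mean 19.03 deg with SD 9.3 deg (SEM 0.49 x sqrt(361)),
#' truncated at zero since a convergent saccade increases vergence by
#' definition.
#'
#' @param ... Named overrides of the defaults.
#' @return A named list of parameters:
#' \describe{
#'   \item{coef}{named logistic coefficients `intercept`, `size`, `polarity`,
#'     `speed_size_polarity` on the feature bits.}
#'   \item{dvergence_mean, dvergence_sd}{vergence-change distribution (deg).}
#'   \item{dvergence_min}{lower truncation of the vergence change (deg).}
#'   \item{contra_bias_deg}{extra nasal rotation of the eye contralateral to
#'     the spot (deg, split as +/- bias/2 between the eyes).}
#'   \item{spont_rate_hr}{spontaneous convergence rate (events/hour).}
#'   \item{azimuth_mean, azimuth_sd}{truncated-normal distribution of spot
#'     azimuth at evoked saccades (deg; median ~ -5.6).}
#'   \item{saccade_dur_s}{nasal ramp duration (s).}
#'   \item{max_asynchrony_s}{SD/ceiling of the binocular onset asynchrony.}
#'   \item{hold_s, return_s}{post-saccadic hold and divergence-return times.}
#'   \item{rest_deg}{resting nasal angle of each eye.}
#'   \item{noise_sd}{fixation noise SD (deg) before slow smoothing.}
#' }
#' @export
behavior_params <- function(...) {
  p <- list(
    coef = c(intercept = -6.51, size = 1.33, polarity = 1.87,
             speed_size_polarity = 0.90),
    dvergence_mean = 19.03,
    dvergence_sd = 9.3,
    dvergence_min = 0,
    contra_bias_deg = 3,
    spont_rate_hr = 1.89,
    azimuth_mean = -5.6,
    azimuth_sd = 30,
    saccade_dur_s = 0.1,
    max_asynchrony_s = 0.12,
    hold_s = 2,
    return_s = 1.5,
    rest_deg = 12.5,
    noise_sd = 0.2
  )
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) stopf("unknown behavior parameter(s): %s",
                         paste(bad, collapse = ", "))
  p[names(over)] <- over
  p
}

# Response probability of one scheduled epoch under the logistic model.
epoch_response_prob <- function(sched, coef) {
  eta <- coef[["intercept"]] +
    coef[["size"]] * sched$size +
    coef[["polarity"]] * sched$polarity +
    coef[["speed_size_polarity"]] * sched$speed * sched$size * sched$polarity
  p <- stats::plogis(eta)
  p[is.na(sched$size)] <- 0  # flashes do not evoke hunting responses
  p
}

#' Generate binocular eye traces with planted convergent saccades
#'
#' Simulates 60 Hz nasal-positive eye-position traces for a stimulus schedule.
#' At most one evoked convergence is drawn per spot epoch (Bernoulli with the
#' logistic feature-compound probability), timed so the spot is near the
#' azimuth drawn for that event; spontaneous convergences are Poisson-placed
#' outside stimulus windows. Each saccade is a linear nasal ramp in both eyes
#' with a small binocular onset asynchrony, a post-saccadic hold, and a slow
#' divergent return.
#'
#' @param schedule Schedule from [generate_schedule()], or `NULL` for a
#'   stimulus-free recording (then `duration_s` is required).
#' @param params Parameter list from [behavior_params()].
#' @param seed Integer seed.
#' @param duration_s Total trace duration in seconds (default: schedule end).
#' @return An object of class `eye_trace`: list with `fs` (60), `left`,
#'   `right` (deg, nasal-positive) and attribute-free `events` data frame of
#'   planted ground-truth saccades (`t_onset`, `evoked`, `epoch_index`,
#'   `stimulus_id`, `azimuth`, `dvergence_true`, `d_left_true`,
#'   `d_right_true`, `lead_eye`).
#' @export
generate_eye_traces <- function(schedule, params = behavior_params(),
                                seed = NULL, duration_s = NULL) {
  need <- c("coef", "dvergence_mean", "dvergence_sd", "spont_rate_hr")
  miss <- setdiff(need, names(params))
  if (length(miss)) stopf("behavior params missing: %s",
                          paste(miss, collapse = ", "))
  if (is.null(duration_s)) {
    if (is.null(schedule) || nrow(schedule) == 0L) {
      stopf("`duration_s` is required without a schedule")
    }
    duration_s <- max(schedule$epoch_onset) + EPOCH_S
  }
  n <- round(duration_s * EYE_HZ)
  with_seed(seed, {
    ev <- list()
    if (!is.null(schedule) && nrow(schedule)) {
      p <- epoch_response_prob(schedule, params$coef)
      hit <- stats::runif(nrow(schedule)) < p
      for (i in which(hit)) {
        epo <- schedule[i, ]
        az <- rtruncnorm(1, params$azimuth_mean, params$azimuth_sd, -95, 95)
        t0 <- spot_time_at_azimuth(epo, az)
        ev[[length(ev) + 1L]] <- data.frame(
          t_onset = t0, evoked = TRUE, epoch_index = epo$epoch_index,
          stimulus_id = epo$stimulus_id, azimuth = az
        )
      }
    }
    # spontaneous events outside stimulus-presentation windows
    n_spont <- stats::rpois(1, params$spont_rate_hr * duration_s / 3600)
    if (n_spont > 0) {
      cand <- stats::runif(4 * n_spont + 20, 1, duration_s - 5)
      if (!is.null(schedule) && nrow(schedule)) {
        in_stim <- vapply(cand, function(tt) {
          k <- which(schedule$epoch_onset <= tt &
                       tt < schedule$epoch_onset + EPOCH_S)
          length(k) == 1L && tt >= schedule$spot_onset[k] - 1 &&
            tt <= schedule$spot_offset[k] + 1
        }, logical(1))
        cand <- cand[!in_stim]
      }
      cand <- sort(cand)[seq_len(min(n_spont, length(cand)))]
      for (t0 in cand) {
        ev[[length(ev) + 1L]] <- data.frame(
          t_onset = t0, evoked = FALSE, epoch_index = NA_integer_,
          stimulus_id = NA_integer_, azimuth = NA_real_
        )
      }
    }
    events <- if (length(ev)) do.call(rbind, ev) else data.frame(
      t_onset = numeric(0), evoked = logical(0), epoch_index = integer(0),
      stimulus_id = integer(0), azimuth = numeric(0)
    )
    events <- events[order(events$t_onset), , drop = FALSE]
    # enforce a minimum separation so waveforms never overlap
    if (nrow(events) > 1L) {
      keep <- c(TRUE, diff(events$t_onset) > 5)
      events <- events[keep, , drop = FALSE]
    }
    rownames(events) <- NULL

    ne <- nrow(events)
    events$dvergence_true <- if (ne) {
      rtruncnorm(ne, params$dvergence_mean, params$dvergence_sd,
                 lower = params$dvergence_min)
    } else numeric(0)
    # the eye contralateral to the spot gets the larger rotation;
    # spontaneous saccades are symmetric
    bias <- rep(0, ne)
    if (ne) {
      spot_left <- !is.na(events$azimuth) & events$azimuth < 0
      spot_right <- !is.na(events$azimuth) & events$azimuth >= 0
      # bias > 0 favours the left eye
      bias[spot_right] <- params$contra_bias_deg
      bias[spot_left] <- -params$contra_bias_deg
    }
    events$d_left_true <- events$dvergence_true / 2 + bias / 2
    events$d_right_true <- events$dvergence_true / 2 - bias / 2
    events$lead_eye <- if (ne) sample(c("L", "R"), ne, replace = TRUE)
      else character(0)

    left <- numeric(n)
    right <- numeric(n)
    tgrid_add <- function(chan, t0, amp) {
      # linear ramp of `saccade_dur_s`, hold, then linear return
      i0 <- floor(t0 * EYE_HZ) + 1L
      nr <- max(1L, round(params$saccade_dur_s * EYE_HZ))
      nh <- round(params$hold_s * EYE_HZ)
      nb <- max(1L, round(params$return_s * EYE_HZ))
      prof <- c(seq(0, amp, length.out = nr + 1L)[-1L],
                rep(amp, nh),
                seq(amp, 0, length.out = nb + 1L)[-1L])
      idx <- i0 + seq_along(prof) - 1L
      ok <- idx >= 1L & idx <= n
      chan[idx[ok]] <- chan[idx[ok]] + prof[ok]
      chan
    }
    if (ne) {
      asyn <- abs(stats::rnorm(ne, 0, params$max_asynchrony_s / 3))
      asyn <- pmin(asyn, params$max_asynchrony_s)
      for (j in seq_len(ne)) {
        tl <- events$t_onset[j] + if (events$lead_eye[j] == "L") 0 else asyn[j]
        tr <- events$t_onset[j] + if (events$lead_eye[j] == "R") 0 else asyn[j]
        left <- tgrid_add(left, tl, events$d_left_true[j])
        right <- tgrid_add(right, tr, events$d_right_true[j])
      }
    }
    if (params$noise_sd > 0) {
      # slow fixational jitter: white noise low-passed over ~0.25 s
      k <- 15L
      left <- left + running_mean(stats::rnorm(n, 0, params$noise_sd), k)
      right <- right + running_mean(stats::rnorm(n, 0, params$noise_sd), k)
    }
    trace <- structure(
      list(fs = EYE_HZ, left = left + params$rest_deg,
           right = right + params$rest_deg, events = events),
      class = "eye_trace")
    trace
  })
}

#' Plant an exact number of convergent saccades on a stimulus-free trace
#'
#' Places `n` spontaneous-type convergent saccades at regular spacing, with
#' vergence increments drawn from the configured (truncated-normal)
#' distribution and symmetric per-eye split. Used for calibration
#' experiments where the event count must be exact.
#'
#' @param n Number of saccades.
#' @param spacing_s Event spacing in seconds (default 10).
#' @param params [behavior_params()] list.
#' @param seed Integer seed.
#' @return An `eye_trace` with `events` ground truth.
#' @export
simulate_saccade_train <- function(n, spacing_s = 10,
                                   params = behavior_params(), seed = NULL) {
  duration_s <- (n + 1) * spacing_s
  nt <- round(duration_s * EYE_HZ)
  with_seed(seed, {
    events <- data.frame(
      t_onset = spacing_s * seq_len(n), evoked = FALSE,
      epoch_index = NA_integer_, stimulus_id = NA_integer_,
      azimuth = NA_real_,
      dvergence_true = rtruncnorm(n, params$dvergence_mean,
                                  params$dvergence_sd,
                                  lower = params$dvergence_min))
    events$d_left_true <- events$d_right_true <- events$dvergence_true / 2
    events$lead_eye <- sample(c("L", "R"), n, replace = TRUE)
    left <- numeric(nt); right <- numeric(nt)
    nr <- max(1L, round(params$saccade_dur_s * EYE_HZ))
    nh <- round(params$hold_s * EYE_HZ)
    nb <- max(1L, round(params$return_s * EYE_HZ))
    asyn <- pmin(abs(stats::rnorm(n, 0, params$max_asynchrony_s / 3)),
                 params$max_asynchrony_s)
    for (j in seq_len(n)) {
      amp <- events$d_left_true[j]
      prof <- c(seq(0, amp, length.out = nr + 1L)[-1L], rep(amp, nh),
                seq(amp, 0, length.out = nb + 1L)[-1L])
      for (eye in c("L", "R")) {
        t0 <- events$t_onset[j] + if (events$lead_eye[j] == eye) 0 else asyn[j]
        idx <- floor(t0 * EYE_HZ) + seq_along(prof)
        ok <- idx <= nt
        if (eye == "L") left[idx[ok]] <- left[idx[ok]] + prof[ok]
        else right[idx[ok]] <- right[idx[ok]] + prof[ok]
      }
    }
    if (params$noise_sd > 0) {
      left <- left + running_mean(stats::rnorm(nt, 0, params$noise_sd), 15L)
      right <- right + running_mean(stats::rnorm(nt, 0, params$noise_sd), 15L)
    }
    structure(list(fs = EYE_HZ, left = left + params$rest_deg,
                   right = right + params$rest_deg, events = events),
              class = "eye_trace")
  })
}

#' @export
print.eye_trace <- function(x, ...) {
  cat(sprintf("<eye_trace> %.1f s at %d Hz, %d planted saccade(s)\n",
              length(x$left) / x$fs, x$fs, nrow(x$events)))
  invisible(x)
}
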