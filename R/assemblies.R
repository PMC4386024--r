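# Convergence-triggered detection of premotor tectal assemblies.
#
# For each convergent saccade, cells are tested for response modulation in
# two windows on the 1.8 Hz frame grid: "pre-conv" = 3 frames (1.65 s)
# immediately before the saccade frame, "peri-conv" = 5 frames (2.75 s)
# centred on it. Evoked events are compared against non-response trials of
# the same stimulus; spontaneous events against the remainder of their
# epoch. Modulated SPV cells (p < 0.05 and SNR > 3) are grouped per
# hemisphere by an ellipse fit with density and size gates (>= 6 cells at
# <= 533 um^2/cell).

PRE_CONV_FRAMES <- 3L    # 3 / 1.8 Hz ~ 1.65 s
PERI_CONV_FRAMES <- 5L   # 5 / 1.8 Hz ~ 2.78 s, reported as 2.75 s

# saccade frame (within-epoch) of an event row
event_saccade_frame <- function(event, schedule) {
  e <- event$epoch_index
  frame_of(event$t_onset, schedule$epoch_onset[schedule$epoch_index == e])
}

conv_window_frames <- function(s, window = c("pre", "peri")) {
  window <- match.arg(window)
  w <- if (window == "pre") (s - PRE_CONV_FRAMES):(s - 1L) else
    (s - 2L):(s + 2L)
  w[w >= 1L & w <= FRAMES_PER_EPOCH]
}

# Two-sample pooled-variance t-test p-values, vectorised over ROIs (columns
# of two value blocks). The pooled form keeps power when only part of the
# short response window is elevated, and is calibrated under the null since
# both blocks share the noise variance.
pooled_t_p <- function(xa, xb) {
  na <- nrow(xa); nb <- nrow(xb)
  ma <- colMeans(xa); mb <- colMeans(xb)
  va <- apply(xa, 2, stats::var); vb <- apply(xb, 2, stats::var)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  t <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
  p <- 2 * stats::pt(-abs(t), na + nb - 2)
  p[!is.finite(p)] <- 1
  p
}

#' Convergence-triggered response modulation (evoked events)
#'
#' Compares dF/F of every ROI during the pre-conv (3 frames ending at the
#' frame before the saccade frame) or peri-conv (5 frames centred on the
#' saccade frame) window of a response trial against the same epoch-relative
#' frames pooled across non-response trials of the same stimulus (two-sample
#' t-test on frame values), plus SNR = (max windowed dF/F - non-response
#' mean) / non-response SD.
#'
#' @param traces A `dff_traces`.
#' @param schedule Schedule data frame.
#' @param events Classified `saccade_events` (all events, used to exclude
#'   response trials from the comparison set).
#' @param event_row Row index into `events` of the evoked event to analyse.
#' @param window `"pre"` or `"peri"`.
#' @return Data frame `roi`, `p`, `snr`, `window`; or `NULL` (with a
#'   warning) when the window is truncated by the epoch edge.
#' @export
conv_modulation <- function(traces, schedule, events, event_row,
                            window = c("pre", "peri")) {
  window <- match.arg(window)
  ev <- events[event_row, ]
  if (!isTRUE(ev$evoked)) stopf("event %d is not evoked", event_row)
  s <- event_saccade_frame(ev, schedule)
  win <- conv_window_frames(s, window)
  full <- if (window == "pre") PRE_CONV_FRAMES else PERI_CONV_FRAMES
  if (length(win) < full) {
    warning("window truncated by epoch edge; event skipped")
    return(NULL)
  }
  sid <- ev$stimulus_id
  resp_epochs <- events$epoch_index[!is.na(events$epoch_index)]
  comp <- schedule$epoch_index[schedule$stimulus_id == sid &
                                 !(schedule$epoch_index %in% resp_epochs)]
  if (length(comp) < 3L) stopf("need >= 3 non-response trials of stimulus %d",
                               sid)
  mat <- traces$mat
  g0 <- (ev$epoch_index - 1L) * FRAMES_PER_EPOCH
  xa <- mat[g0 + win, , drop = FALSE]
  xb <- do.call(rbind, lapply(comp, function(e) {
    mat[(e - 1L) * FRAMES_PER_EPOCH + win, , drop = FALSE]
  }))
  snr_den <- apply(xb, 2, stats::sd)
  snr <- (apply(xa, 2, max) - colMeans(xb)) / ifelse(snr_den > 0, snr_den, Inf)
  data.frame(roi = seq_len(ncol(mat)), p = pooled_t_p(xa, xb), snr = snr,
             window = window)
}

#' Response modulation at a spontaneous convergence
#'
#' Compares dF/F within the pre- or peri-conv window against the remainder
#' of the same 32 s epoch (two-sample t-test), with SNR against the remainder
#' statistics.
#'
#' @inheritParams conv_modulation
#' @export
spontaneous_modulation <- function(traces, schedule, events, event_row,
                                   window = c("pre", "peri")) {
  window <- match.arg(window)
  ev <- events[event_row, ]
  t0 <- ev$t_onset
  e <- which(schedule$epoch_onset <= t0 & t0 < schedule$epoch_onset + EPOCH_S)
  if (length(e) != 1L) {
    warning("event outside any epoch; skipped")
    return(NULL)
  }
  s <- frame_of(t0, schedule$epoch_onset[e])
  win <- conv_window_frames(s, window)
  full <- if (window == "pre") PRE_CONV_FRAMES else PERI_CONV_FRAMES
  if (length(win) < full) {
    warning("window truncated by epoch edge; event skipped")
    return(NULL)
  }
  mat <- traces$mat
  g0 <- (schedule$epoch_index[e] - 1L) * FRAMES_PER_EPOCH
  rest <- setdiff(seq_len(FRAMES_PER_EPOCH), win)
  xa <- mat[g0 + win, , drop = FALSE]
  xb <- mat[g0 + rest, , drop = FALSE]
  snr_den <- apply(xb, 2, stats::sd)
  snr <- (apply(xa, 2, max) - colMeans(xb)) / ifelse(snr_den > 0, snr_den, Inf)
  data.frame(roi = seq_len(ncol(mat)), p = pooled_t_p(xa, xb), snr = snr,
             window = window)
}

# 2-SD covariance ellipse of a point set; area and geometry.
cov_ellipse <- function(pts, floor_um = 1) {
  mu <- colMeans(pts)
  S <- stats::cov(pts)
  eg <- eigen(S, symmetric = TRUE)
  lam <- pmax(eg$values, floor_um^2)   # minimum-axis floor for collinear sets
  semi <- 2 * sqrt(lam)                # 2-SD semi-axes
  list(center = mu, semi_axes = semi,
       angle = atan2(eg$vectors[2, 1], eg$vectors[1, 1]),
       area = pi * semi[1] * semi[2], S = S, lam = lam, vec = eg$vectors)
}

#' Detect a spatial assembly among modulated SPV cells
#'
#' Per hemisphere, fits a 2-SD covariance ellipse to the centroids of
#' response-modulated SPV cells; while the density (ellipse area per cell)
#' exceeds `max_density`, the cell farthest from the ellipse centre in
#' Mahalanobis distance is dropped and the ellipse refit. A hemisphere
#' yields an assembly when at least `min_cells` cells remain at density
#' `<= max_density` (boundary values accepted).
#'
#' @param modulation Data frame `roi`, `p`, `snr` (one event, one window).
#' @param roi_table ROI table (`roi_id`, `x_um`, `y_um`, `hemisphere`,
#'   `region`).
#' @param alpha,snr_min Modulation gates (p < alpha and SNR > snr_min).
#' @param min_cells Minimum assembly size (default 6).
#' @param max_density Maximal ellipse area per cell (default 533 um^2/cell).
#' @return List of assemblies (possibly empty), each a list with
#'   `hemisphere`, `members` (roi ids), `center`, `semi_axes`, `angle`,
#'   `area_um2`, `density`, `n`.
#' @export
detect_assembly <- function(modulation, roi_table, alpha = 0.05, snr_min = 3,
                            min_cells = 6L, max_density = 533) {
  mod <- merge(modulation, roi_table, by.x = "roi", by.y = "roi_id")
  mod <- mod[mod$region == "OTc-SPV" & mod$p < alpha & mod$snr > snr_min, ]
  out <- list()
  for (hemi in c("L", "R")) {
    sub <- mod[mod$hemisphere == hemi, ]
    if (nrow(sub) < min_cells) next
    pts <- as.matrix(sub[, c("x_um", "y_um")])
    ids <- sub$roi
    repeat {
      if (nrow(pts) < min_cells) { pts <- NULL; break }
      el <- cov_ellipse(pts)
      if (el$area / nrow(pts) <= max_density) break
      # drop the farthest cell (Mahalanobis) and refit
      Sinv <- el$vec %*% diag(1 / el$lam, 2) %*% t(el$vec)
      d <- stats::mahalanobis(pts, el$center, Sinv, inverted = TRUE)
      k <- which.max(d)
      pts <- pts[-k, , drop = FALSE]
      ids <- ids[-k]
    }
    if (is.null(pts)) next
    el <- cov_ellipse(pts)
    out[[length(out) + 1L]] <- list(
      hemisphere = hemi, members = ids, center = el$center,
      semi_axes = el$semi_axes, angle = el$angle, area_um2 = el$area,
      density = el$area / nrow(pts), n = nrow(pts))
  }
  out
}

#' Detect assemblies for every convergence event
#'
#' Runs the appropriate modulation analysis (evoked: response vs
#' non-response trials; spontaneous: window vs epoch remainder) and the
#' spatial assembly detector for every event, in one window type.
#'
#' @inheritParams conv_modulation
#' @inheritParams detect_assembly
#' @param min_comparison Minimum non-response trials for evoked events.
#' @return List of assemblies, each additionally tagged with `event_row` and
#'   `window`.
#' @export
find_assemblies <- function(traces, schedule, events, roi_table,
                            window = c("pre", "peri"), alpha = 0.05,
                            snr_min = 3, min_cells = 6L, max_density = 533,
                            min_comparison = 3L) {
  window <- match.arg(window)
  out <- list()
  for (r in seq_len(nrow(events))) {
    mod <- withCallingHandlers(
      tryCatch({
        if (isTRUE(events$evoked[r])) {
          conv_modulation(traces, schedule, events, r, window)
        } else {
          spontaneous_modulation(traces, schedule, events, r, window)
        }
      }, error = function(e) NULL),
      warning = function(w) invokeRestart("muffleWarning"))
    if (is.null(mod)) next
    asm <- detect_assembly(mod, roi_table, alpha, snr_min, min_cells,
                           max_density)
    for (a in asm) {
      a$event_row <- r
      a$window <- window
      out[[length(out) + 1L]] <- a
    }
  }
  out
}

#' Assembly lead time relative to the convergent saccade
#'
#' The population trace is the mean of the members' max-normalised dF/F time
#' courses over the event's epoch; the threshold is the pre-stimulus
#' baseline mean + 2 SD (first 3 epoch frames). The lead is the saccade
#' frame minus the onset of the suprathreshold run active at (or nearest
#' before) the saccade frame.
#'
#' @param assembly An assembly from [detect_assembly()]/[find_assemblies()].
#' @param traces A `dff_traces`.
#' @param event One-row event (with `epoch_index`, `t_onset`).
#' @param schedule Schedule data frame.
#' @return List `lead_frames`, `lead_s`, or `NULL` when the threshold is
#'   never crossed before the saccade.
#' @export
assembly_lead_time <- function(assembly, traces, event, schedule) {
  e <- event$epoch_index
  if (is.na(e)) {
    t0 <- event$t_onset
    e <- schedule$epoch_index[schedule$epoch_onset <= t0 &
                                t0 < schedule$epoch_onset + EPOCH_S][1]
  }
  s <- frame_of(event$t_onset, schedule$epoch_onset[schedule$epoch_index == e])
  sub <- traces$mat[(e - 1L) * FRAMES_PER_EPOCH + seq_len(FRAMES_PER_EPOCH),
                    assembly$members, drop = FALSE]
  mx <- apply(sub, 2, max)
  ok <- mx > 0
  if (!any(ok)) return(NULL)
  pop <- rowMeans(sweep(sub[, ok, drop = FALSE], 2, mx[ok], "/"))
  thr <- mean(pop[1:3]) + 2 * stats::sd(pop[1:3])
  above <- pop > thr
  onsets <- which(above & !c(FALSE, above[-length(above)]))
  onsets <- onsets[onsets <= s]
  if (!length(onsets)) return(NULL)
  lead <- s - max(onsets)
  list(lead_frames = lead, lead_s = lead / IMG_HZ)
}

#' Intra-assembly activity correlation
#'
#' Leave-one-out correlation of each member's epoch trace with the mean of
#' the remaining members; summarised as the median with interquartile range.
#'
#' @inheritParams assembly_lead_time
#' @param epoch_index Epoch over which to correlate (default: the event
#'   epoch is supplied by the caller).
#' @return List `r_avg` (median), `iqr` (length 2), `per_cell` (named r per
#'   member; constant traces are `NA` and excluded from the summary).
#' @export
intra_assembly_correlation <- function(assembly, traces, epoch_index) {
  if (length(assembly$members) < 2) stopf("need >= 2 members")
  sub <- traces$mat[(epoch_index - 1L) * FRAMES_PER_EPOCH +
                      seq_len(FRAMES_PER_EPOCH), assembly$members,
                    drop = FALSE]
  r <- vapply(seq_len(ncol(sub)), function(j) {
    x <- sub[, j]
    m <- rowMeans(sub[, -j, drop = FALSE])
    if (stats::sd(x) == 0 || stats::sd(m) == 0) return(NA_real_)
    stats::cor(x, m)
  }, numeric(1))
  names(r) <- assembly$members
  ok <- !is.na(r)
  list(r_avg = stats::median(r[ok]),
       iqr = unname(stats::quantile(r[ok], c(0.25, 0.75))),
       per_cell = r)
}

#' Circular-permutation false-discovery estimate for assembly detection
#'
#' Circularly shifts every ROI's full fluorescence time series by a common
#' seeded offset of at least two epochs (preserving inter-cell correlations
#' while destroying event alignment), re-runs modulation and assembly
#' detection with identical criteria, and estimates FDR as the mean shuffled
#' assembly count divided by the original count. Per-ROI independent shifts
#' are available as an option.
#'
#' @inheritParams find_assemblies
#' @param n_perm Number of permutations (default 5).
#' @param seed Integer seed.
#' @param per_roi Use independent per-ROI shifts instead of a common one.
#' @return List `fdr`, `original_count`, `shuffled_counts`; `fdr` is `NA`
#'   when no original assemblies exist.
#' @export
fdr_circular_permutation <- function(traces, schedule, events, roi_table,
                                     window = c("pre", "peri"), n_perm = 5L,
                                     seed = NULL, per_roi = FALSE, ...) {
  window <- match.arg(window)
  if (n_perm < 1) stopf("n_perm must be >= 1")
  orig <- length(find_assemblies(traces, schedule, events, roi_table, window,
                                 ...))
  nf <- nrow(traces$mat)
  lo <- 2L * FRAMES_PER_EPOCH
  counts <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    shifted <- traces
    if (per_roi) {
      for (j in seq_len(ncol(traces$mat))) {
        k <- sample(lo:(nf - lo), 1)
        shifted$mat[, j] <- c(traces$mat[(nf - k + 1L):nf, j],
                              traces$mat[seq_len(nf - k), j])
      }
    } else {
      k <- sample(lo:(nf - lo), 1)
      shifted$mat <- rbind(traces$mat[(nf - k + 1L):nf, , drop = FALSE],
                           traces$mat[seq_len(nf - k), , drop = FALSE])
    }
    length(find_assemblies(shifted, schedule, events, roi_table, window, ...))
  }, numeric(1)))
  list(fdr = if (orig > 0) mean(counts) / orig else NA_real_,
       original_count = orig, shuffled_counts = counts)
}

#' Ipsilateral versus contralateral oculomotor statistics
#'
#' For each assembly, takes the saccade kinematics of its event and compares
#' the eye ipsilateral to the assembly hemisphere against the contralateral
#' eye (paired t-tests) for post-saccadic position, change in position, and
#' peak nasal velocity.
#'
#' @param assemblies List of assemblies (with `event_row`, `hemisphere`).
#' @param events Detected `saccade_events` with kinematics.
#' @return Data frame, one row per parameter: `parameter`, `mean_ipsi`,
#'   `mean_contra`, `p_paired`, `n`.
#' @export
laterality_oculomotor_stats <- function(assemblies, events) {
  if (length(assemblies) < 2) stopf("need >= 2 assemblies")
  pick <- function(a, lcol, rcol) {
    ev <- events[a$event_row, ]
    if (a$hemisphere == "L") c(ev[[lcol]], ev[[rcol]]) else
      c(ev[[rcol]], ev[[lcol]])
  }
  params <- list(post_position = c("post_left", "post_right"),
                 delta_position = c("d_left", "d_right"),
                 peak_velocity = c("peak_vel_left", "peak_vel_right"))
  rows <- lapply(names(params), function(pn) {
    cols <- params[[pn]]
    m <- t(vapply(assemblies, pick, numeric(2), lcol = cols[1],
                  rcol = cols[2]))
    ok <- stats::complete.cases(m)
    m <- m[ok, , drop = FALSE]
    if (nrow(m) < 2) return(NULL)
    p <- stats::t.test(m[, 1], m[, 2], paired = TRUE)$p.value
    data.frame(parameter = pn, mean_ipsi = mean(m[, 1]),
               mean_contra = mean(m[, 2]), p_paired = p, n = nrow(m))
  })
  do.call(rbind, rows)
}

#' Oculomotor parameters versus anterior-posterior assembly location
#'
#' Ordinary least-squares fits of an eye parameter against the assembly's
#' anterior-posterior distance from the posterior-commissure landmark,
#' separately per tectum and eye. Under a tectal motor map the right-eye
#' slope should be positive and the left-eye slope negative.
#'
#' @param assemblies List of assemblies.
#' @param events Detected `saccade_events` with kinematics.
#' @param landmark Posterior-commissure coordinate `c(x, y)` in um.
#' @param parameter Kinematic column prefix: `"d"` (change in position) or
#'   `"post"` (post-saccadic position).
#' @return Data frame `tectum`, `eye`, `slope`, `ci_lo`, `ci_hi`, `n` (rows
#'   with fewer than 3 assemblies have `NA` fits).
#' @export
ap_location_trend <- function(assemblies, events, landmark = c(x = 0, y = 65),
                              parameter = c("d", "post")) {
  parameter <- match.arg(parameter)
  cols <- if (parameter == "d") c("d_left", "d_right") else
    c("post_left", "post_right")
  rows <- list()
  for (hemi in c("L", "R")) {
    sub <- Filter(function(a) a$hemisphere == hemi, assemblies)
    ap <- vapply(sub, function(a) a$center[2] - landmark[["y"]], numeric(1))
    for (eye in c("left", "right")) {
      yv <- vapply(sub, function(a) {
        events[[cols[if (eye == "left") 1 else 2]]][a$event_row]
      }, numeric(1))
      if (length(ap) >= 3 && stats::sd(ap) > 0) {
        fit <- stats::lm(yv ~ ap)
        ci <- stats::confint(fit)["ap", ]
        rows[[length(rows) + 1L]] <- data.frame(
          tectum = hemi, eye = eye, slope = stats::coef(fit)[["ap"]],
          ci_lo = ci[1], ci_hi = ci[2], n = length(ap))
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          tectum = hemi, eye = eye, slope = NA_real_, ci_lo = NA_real_,
          ci_hi = NA_real_, n = length(ap))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Overlap between pre-conv and peri-conv assemblies
#'
#' @param pre,peri Lists of assemblies keyed by `event_row`.
#' @return List: `event_overlap` (fraction of pre-conv events that also have
#'   a peri-conv assembly) and `cell_overlap` (fraction of pre-conv member
#'   cells appearing in the same event's peri-conv assembly).
#' @export
overlap_stats <- function(pre, peri) {
  if (!length(pre)) return(list(event_overlap = NA_real_,
                                cell_overlap = NA_real_))
  peri_by_event <- split(peri, vapply(peri, `[[`, numeric(1), "event_row"))
  ev_hit <- 0; cells_tot <- 0; cells_hit <- 0
  for (a in pre) {
    match <- peri_by_event[[as.character(a$event_row)]]
    if (!is.null(match)) {
      ev_hit <- ev_hit + 1
      peri_members <- unique(unlist(lapply(match, `[[`, "members")))
      cells_hit <- cells_hit + sum(a$members %in% peri_members)
    }
    cells_tot <- cells_tot + length(a$members)
  }
  list(event_overlap = ev_hit / length(pre),
       cell_overlap = if (cells_tot > 0) cells_hit / cells_tot else NA_real_)
}
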