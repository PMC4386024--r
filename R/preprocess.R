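# Imaging front end: rigid registration, ROI segmentation, dF/F, and
# visual-responsiveness classification.

shift_matrix <- function(m, dy, dx, fill = stats::median(m)) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(fill, H, W)
  ys <- seq_len(H) - dy; xs <- seq_len(W) - dx
  oky <- ys >= 1 & ys <= H; okx <- xs >= 1 & xs <= W
  out[oky, okx] <- m[ys[oky], xs[okx]]
  out
}

#' Rigid registration of an imaging stack
#'
#' Estimates a per-frame rigid translation maximizing the FFT
#' cross-correlation with a template (default: the stack mean), with
#' parabolic sub-pixel refinement, and returns the shift-corrected stack.
#' Shifts beyond `max_shift_px` are clipped and the frame flagged; constant
#' frames get zero shift with a warning.
#'
#' @param stack 3-D array (frame, row, col).
#' @param template Optional template matrix; default is the frame mean.
#' @param max_shift_px Maximum allowed |shift| per axis (px).
#' @return List: `shifts` (data frame `frame`, `dy`, `dx`, `dy_sub`,
#'   `dx_sub`, `clipped`), `corrected` (array like `stack`), `template`.
#' @export
register_frames <- function(stack, template = NULL, max_shift_px = 20) {
  if (length(dim(stack)) != 3L) stopf("`stack` must be a 3-D array")
  nf <- dim(stack)[1]; H <- dim(stack)[2]; W <- dim(stack)[3]
  if (is.null(template)) template <- apply(stack, c(2, 3), mean)
  Tf <- stats::fft(template - mean(template))
  sub_peak <- function(cc, k) {
    # parabolic interpolation around index k along one axis of a vector
    if (k <= 1 || k >= length(cc)) return(0)
    d <- (cc[k - 1] - cc[k + 1]) / (2 * (cc[k - 1] - 2 * cc[k] + cc[k + 1]))
    if (!is.finite(d)) 0 else d
  }
  shifts <- data.frame(frame = seq_len(nf), dy = 0L, dx = 0L,
                       dy_sub = 0, dx_sub = 0, clipped = FALSE)
  corrected <- stack
  warned <- FALSE
  for (f in seq_len(nf)) {
    fr <- stack[f, , ]
    if (stats::sd(fr) == 0) { warned <- TRUE; next }
    cc <- Re(stats::fft(stats::fft(fr - mean(fr)) * Conj(Tf), inverse = TRUE))
    # wrap circular lags to signed shifts
    k <- which.max(cc)
    ky <- (k - 1) %% H + 1; kx <- (k - 1) %/% H + 1
    dy <- ky - 1; dx <- kx - 1
    if (dy > H / 2) dy <- dy - H
    if (dx > W / 2) dx <- dx - W
    clip <- abs(dy) > max_shift_px || abs(dx) > max_shift_px
    dy <- max(-max_shift_px, min(max_shift_px, dy))
    dx <- max(-max_shift_px, min(max_shift_px, dx))
    dys <- sub_peak(cc[((ky + c(-2, -1, 0) ) %% H) + 1], 2)
    dxs <- sub_peak(cc[(((kx + c(-2, -1, 0)) %% W) * H) + ky], 2)
    shifts$dy[f] <- dy; shifts$dx[f] <- dx
    shifts$dy_sub[f] <- dy + dys; shifts$dx_sub[f] <- dx + dxs
    shifts$clipped[f] <- clip
    if (dy != 0 || dx != 0) corrected[f, , ] <- shift_matrix(fr, -dy, -dx)
  }
  if (warned) warning("constant frame(s); zero shift assumed")
  list(shifts = shifts, corrected = corrected, template = template)
}

#' Segment somatic ROIs from a registered stack
#'
#' Seeds are local maxima of a temporal-activity x local-correlation score
#' map (per-pixel temporal SD times the rectified correlation of each pixel's
#' time course with its 4-neighbour mean); regions are grown around seeds to
#' soma-scale area bounds, and oversized regions are split in two and
#' flagged. This is a deliberately simple segmentation, adequate for the
#' synthetic movies it is tested on rather than for real tissue.
#'
#' @param stack Registered 3-D array (frame, row, col).
#' @param pixel_um Pixel pitch (um/px).
#' @param area_um2 Soma area bounds in um^2 (default 20-200).
#' @param grow_frac Region-growing threshold as a fraction of the seed score.
#' @return Data frame with `roi_id`, `cy_px`, `cx_px`, `x_um`, `y_um`,
#'   `area_um2`, `split_flag`; attribute `masks` holds per-ROI pixel index
#'   matrices (row, col).
#' @export
segment_rois <- function(stack, pixel_um = 1, area_um2 = c(20, 200),
                         grow_frac = 0.25) {
  nf <- dim(stack)[1]; H <- dim(stack)[2]; W <- dim(stack)[3]
  X <- matrix(stack, nrow = nf)              # frames x pixels, column-major
  mu <- colMeans(X)
  sdv <- sqrt(pmax(0, colMeans(X^2) - mu^2))
  # neighbour-mean time course per pixel (4-connectivity)
  A <- array(aperm(stack, c(2, 3, 1)), dim = c(H, W, nf))
  nb <- array(0, dim = c(H, W, nf)); cnt <- matrix(0, H, W)
  addsh <- function(dy, dx) {
    ys <- max(1, 1 + dy):min(H, H + dy); xs <- max(1, 1 + dx):min(W, W + dx)
    nb[ys, xs, ] <<- nb[ys, xs, ] + A[ys - dy, xs - dx, , drop = FALSE]
    cnt[ys, xs] <<- cnt[ys, xs] + 1
  }
  addsh(1, 0); addsh(-1, 0); addsh(0, 1); addsh(0, -1)
  nb <- nb / array(cnt, dim = c(H, W, nf))
  Nmat <- matrix(aperm(nb, c(3, 1, 2)), nrow = nf)
  nmu <- colMeans(Nmat)
  nsd <- sqrt(pmax(0, colMeans(Nmat^2) - nmu^2))
  cov_ <- colMeans(X * Nmat) - mu * nmu
  corr <- ifelse(sdv > 0 & nsd > 0, cov_ / (sdv * nsd), 0)
  score <- matrix(sdv * pmax(corr, 0), H, W)

  thr <- max(stats::median(score) + 5 * stats::mad(score),
             0.25 * max(score))
  if (!is.finite(thr) || thr <= 0) thr <- max(score) + 1
  is_max <- score >= thr
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    sh <- shift_matrix(score, dy, dx, fill = -Inf)
    is_max <- is_max & score >= sh
  }
  seeds <- which(is_max, arr.ind = TRUE)
  if (!nrow(seeds)) {
    out <- data.frame(roi_id = integer(0), cy_px = numeric(0),
                      cx_px = numeric(0), x_um = numeric(0), y_um = numeric(0),
                      area_um2 = numeric(0), split_flag = logical(0))
    attr(out, "masks") <- list()
    return(out)
  }
  seeds <- seeds[order(-score[seeds]), , drop = FALSE]
  max_px <- ceiling(area_um2[2] / pixel_um^2)
  min_px <- max(1, floor(area_um2[1] / pixel_um^2))
  rmax <- ceiling(sqrt(4 * max_px / pi))
  claimed <- matrix(FALSE, H, W)
  rois <- list(); masks <- list()
  for (s in seq_len(nrow(seeds))) {
    sy <- seeds[s, 1]; sx <- seeds[s, 2]
    if (claimed[sy, sx]) next
    lvl <- grow_frac * score[sy, sx]
    # breadth-first growth over unclaimed pixels above the level
    front <- matrix(c(sy, sx), ncol = 2)
    member <- matrix(c(sy, sx), ncol = 2)
    seen <- matrix(FALSE, H, W); seen[sy, sx] <- TRUE
    while (nrow(front) && nrow(member) < 2 * max_px) {
      nxt <- NULL
      for (i in seq_len(nrow(front))) {
        for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
          y <- front[i, 1] + d[1]; x <- front[i, 2] + d[2]
          if (y < 1 || y > H || x < 1 || x > W) next
          if (seen[y, x] || claimed[y, x]) next
          if (score[y, x] < lvl) next
          if ((y - sy)^2 + (x - sx)^2 > rmax^2) next
          seen[y, x] <- TRUE
          nxt <- rbind(nxt, c(y, x))
        }
      }
      if (!is.null(nxt)) member <- rbind(member, nxt)
      front <- if (is.null(nxt)) matrix(numeric(0), ncol = 2) else nxt
    }
    if (nrow(member) < min_px) next
    split_flag <- FALSE
    pieces <- list(member)
    if (nrow(member) > max_px) {
      # oversized: split by 2-means on pixel coordinates
      km <- stats::kmeans(member, 2, nstart = 3)
      pieces <- split.data.frame(as.data.frame(member), km$cluster)
      pieces <- lapply(pieces, as.matrix)
      split_flag <- TRUE
    }
    for (pc in pieces) {
      if (nrow(pc) < min_px) next
      claimed[pc] <- TRUE
      rois[[length(rois) + 1L]] <- data.frame(
        cy_px = mean(pc[, 1]), cx_px = mean(pc[, 2]),
        area_um2 = nrow(pc) * pixel_um^2, split_flag = split_flag)
      masks[[length(masks) + 1L]] <- pc
    }
  }
  out <- if (length(rois)) do.call(rbind, rois) else
    data.frame(cy_px = numeric(0), cx_px = numeric(0),
               area_um2 = numeric(0), split_flag = logical(0))
  out$roi_id <- seq_len(nrow(out))
  out$x_um <- (out$cx_px - 1) * pixel_um
  out$y_um <- (out$cy_px - 1) * pixel_um
  out <- out[, c("roi_id", "cy_px", "cx_px", "x_um", "y_um", "area_um2",
                 "split_flag")]
  attr(out, "masks") <- masks
  out
}

#' Fractional fluorescence change (dF/F)
#'
#' Computes dF/F = (F - F0)/F0 per ROI. The default baseline F0 is the mean
#' of the first `n_baseline` frames of each epoch (all stimuli start at
#' least 2 s into the epoch, so these frames are pre-stimulus); a rolling
#' lower-percentile baseline is available as an alternative.
#'
#' @param raw Numeric matrix (frames x ROI) or vector of raw fluorescence.
#' @param frames_per_epoch Frames per epoch (default 57).
#' @param n_baseline Baseline frames at the start of each epoch.
#' @param method `"epoch_start"` or `"rolling"` (percentile over a running
#'   window).
#' @param percentile,window_frames Rolling-baseline parameters.
#' @return Matrix of dF/F values; attribute `invalid_rois` flags columns
#'   whose baseline was non-positive (their values are `NA`).
#' @export
compute_dff <- function(raw, frames_per_epoch = FRAMES_PER_EPOCH,
                        n_baseline = 3L, method = c("epoch_start", "rolling"),
                        percentile = 0.2, window_frames = 171L) {
  method <- match.arg(method)
  raw <- as.matrix(raw)
  nf <- nrow(raw)
  out <- raw
  invalid <- logical(ncol(raw))
  if (method == "epoch_start") {
    if (nf %% frames_per_epoch != 0) {
      stopf("trace length %d is not a multiple of %d frames/epoch", nf,
            frames_per_epoch)
    }
    n_ep <- nf %/% frames_per_epoch
    for (e in seq_len(n_ep)) {
      idx <- (e - 1L) * frames_per_epoch + seq_len(frames_per_epoch)
      f0 <- colMeans(raw[idx[seq_len(n_baseline)], , drop = FALSE])
      bad <- f0 <= 0
      invalid <- invalid | bad
      f0[bad] <- NA_real_
      out[idx, ] <- sweep(sweep(raw[idx, , drop = FALSE], 2, f0), 2, f0, "/")
    }
  } else {
    half <- window_frames %/% 2L
    for (j in seq_len(ncol(raw))) {
      f0 <- vapply(seq_len(nf), function(i) {
        stats::quantile(raw[max(1, i - half):min(nf, i + half), j],
                        percentile, names = FALSE)
      }, numeric(1))
      if (any(f0 <= 0)) { invalid[j] <- TRUE; out[, j] <- NA_real_ }
      else out[, j] <- (raw[, j] - f0) / f0
    }
  }
  attr(out, "invalid_rois") <- which(invalid)
  out
}

# window frames (within epoch) covering the stimulus presentation + decay
stimulus_window_frames <- function(sched_row, pad_s = 2) {
  f0 <- floor((sched_row$spot_onset - sched_row$epoch_onset) * IMG_HZ) + 1L
  f1 <- frame_of(sched_row$spot_offset + pad_s, sched_row$epoch_onset)
  f0:f1
}

#' Classify an ROI (or all ROIs) as visually responsive
#'
#' For each of the 18 stimuli, compares per-trial peak dF/F in the stimulus
#' window against per-trial pre-stimulus baseline means (paired t-test) and
#' computes a signal-to-noise ratio, SNR = (max rep-averaged window signal -
#' baseline mean) / baseline SD. An ROI is visually responsive when any
#' stimulus passes `p < alpha` and `SNR > snr_min`. No multiple-testing
#' correction is applied across the 18 stimuli (the classification asks for
#' modulation by at least one stimulus); the resulting per-ROI false-positive
#' rate is bounded by `alpha * 18` and quantified in the package tests.
#'
#' @param traces A `dff_traces` or a frames x ROI dF/F matrix.
#' @param schedule Schedule data frame.
#' @param alpha Significance level per stimulus.
#' @param snr_min SNR gate.
#' @param n_baseline Pre-stimulus baseline frames per epoch.
#' @return List: `responsive` (logical per ROI), `stats` (data frame
#'   `roi`, `stimulus_id`, `p`, `snr`).
#' @export
classify_visually_responsive <- function(traces, schedule, alpha = 0.05,
                                         snr_min = 3, n_baseline = 3L) {
  mat <- if (inherits(traces, "dff_traces")) traces$mat else as.matrix(traces)
  n_roi <- ncol(mat)
  stats_rows <- vector("list", N_STIM)
  for (sid in 0:(N_STIM - 1L)) {
    rows <- which(schedule$stimulus_id == sid)
    if (length(rows) < 3L) stopf("need >= 3 repetitions of stimulus %d", sid)
    win <- stimulus_window_frames(schedule[rows[1], ])
    base_idx <- seq_len(n_baseline)
    peaks <- matrix(NA_real_, length(rows), n_roi)
    bases <- matrix(NA_real_, length(rows), n_roi)
    winsum <- matrix(0, length(win), n_roi)
    for (i in seq_along(rows)) {
      g0 <- (schedule$epoch_index[rows[i]] - 1L) * FRAMES_PER_EPOCH
      wmat <- mat[g0 + win, , drop = FALSE]
      peaks[i, ] <- apply(wmat, 2, max)
      bases[i, ] <- colMeans(mat[g0 + base_idx, , drop = FALSE])
      winsum <- winsum + wmat
    }
    winmean <- winsum / length(rows)
    base_all <- do.call(rbind, lapply(rows, function(r) {
      mat[(schedule$epoch_index[r] - 1L) * FRAMES_PER_EPOCH + base_idx, ,
          drop = FALSE]
    }))
    bmu <- colMeans(base_all)
    bsd <- apply(base_all, 2, stats::sd)
    snr <- (apply(winmean, 2, max) - bmu) / ifelse(bsd > 0, bsd, Inf)
    d <- peaks - bases
    dm <- colMeans(d)
    dsd <- apply(d, 2, stats::sd)
    tstat <- dm / (dsd / sqrt(nrow(d)))
    p <- 2 * stats::pt(-abs(tstat), df = nrow(d) - 1)
    p[!is.finite(p)] <- 1
    stats_rows[[sid + 1L]] <- data.frame(roi = seq_len(n_roi),
                                         stimulus_id = sid, p = p, snr = snr)
  }
  st <- do.call(rbind, stats_rows)
  hit <- st$p < alpha & st$snr > snr_min
  responsive <- vapply(seq_len(n_roi), function(j) any(hit[st$roi == j]),
                       logical(1))
  list(responsive = responsive, stats = st)
}
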