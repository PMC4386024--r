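# Non-linear mixed selectivity: binary conjunction regressors, regressor
# assignment, and equal-complexity linear vs non-linear model comparison.
#
# All six regressors are selective for large, dark spots; variants add speed
# and/or direction selectivity:
#   nDS-nSp (4 ones), nDS-Sp (2), R2L-nSp (2), R2L-Sp (1), L2R-nSp (2),
#   L2R-Sp (1), over the 16 moving-spot stimuli in canonical order.

#' The six binary conjunction regressors
#'
#' @return 6 x 16 matrix (rows named by regressor key, columns in canonical
#'   stimulus order).
#' @export
build_regressors <- function() {
  out <- t(vapply(NLMS_TYPES, archetype_spot_weights, numeric(16)))
  rownames(out) <- NLMS_TYPES
  out
}

#' Peak average response to each moving-spot stimulus
#'
#' Per stimulus, the maximum over the spot-presentation frames of the
#' rep-averaged dF/F (not rectified).
#'
#' @param traces A `dff_traces` or frames x ROI matrix.
#' @param schedule Schedule data frame.
#' @param roi ROI column index.
#' @return Numeric vector of length 16.
#' @export
peak_response_vector <- function(traces, schedule, roi) {
  mat <- if (inherits(traces, "dff_traces")) traces$mat else as.matrix(traces)
  out <- numeric(16)
  for (sid in 0:15) {
    rows <- which(schedule$stimulus_id == sid)
    if (!length(rows)) stopf("stimulus %d missing from schedule", sid)
    win <- stimulus_window_frames(schedule[rows[1], ])
    acc <- 0
    for (r in rows) {
      acc <- acc + mat[(schedule$epoch_index[r] - 1L) * FRAMES_PER_EPOCH + win,
                       roi]
    }
    out[sid + 1L] <- max(acc / length(rows))
  }
  out
}

#' Assign an ROI to its best-matching regressor
#'
#' Pearson correlation of the 16-element peak-response vector with each
#' regressor; the ROI is assigned to the arg-max regressor when that
#' correlation is at least `r_min`, else unassigned. Ties are broken by the
#' fixed regressor order nDS-nSp, nDS-Sp, R2L-nSp, R2L-Sp, L2R-nSp, L2R-Sp.
#'
#' @param vec Length-16 peak-response vector.
#' @param regressors Matrix from [build_regressors()].
#' @param r_min Assignment threshold (default 0.75).
#' @return List `key`, `r`, or `NULL` when no regressor reaches `r_min` or
#'   the vector has zero variance.
#' @export
assign_regressor <- function(vec, regressors = build_regressors(),
                             r_min = 0.75) {
  if (length(vec) != 16L || anyNA(vec) || any(!is.finite(vec))) {
    stopf("`vec` must be a finite vector of length 16")
  }
  if (stats::sd(vec) == 0) return(NULL)
  r <- as.numeric(stats::cor(vec, t(regressors)))
  k <- which.max(r)  # which.max takes the first maximum: fixed key order
  if (r[k] < r_min) return(NULL)
  list(key = rownames(regressors)[k], r = r[k])
}

#' Compare linear and non-linear mixed-selectivity models for one ROI
#'
#' Fits, by least squares, two 5-parameter models of per-trial peak responses
#' y on the binary feature bits d (direction), s (speed), z (size),
#' p (polarity):
#'   linear:     y ~ 1 + d + s + z + p
#'   non-linear: y ~ 1 + z:p + s:z:p + d:z:p + d:s:z:p
#' The interaction set captures conjunction tuning to large, dark spots with
#' optional speed and/or direction selectivity at the same parameter count as
#' the linear model. Both are scored by cross-validated R^2 on held-out
#' repetition halves, averaged over `n_splits` seeded halvings, and compared
#' through SI_nlin = (cvR2_nlin - cvR2_lin) / (|cvR2_nlin| + |cvR2_lin|).
#'
#' @param y Per-trial peak responses (one element per trial).
#' @param codes Data frame of feature bits, one row per trial (same order).
#' @param n_splits Number of random rep halvings (default 20).
#' @param seed Integer seed.
#' @return Object of class `nlms_glm`: list with `coef_lin`, `coef_nlin`,
#'   `cv_r2_lin`, `cv_r2_nlin`, `si_nlin`, `n_trials`.
#' @export
fit_models <- function(y, codes, n_splits = 20, seed = NULL) {
  stopifnot(length(y) == nrow(codes))
  code16 <- codes$direction * 8 + codes$speed * 4 + codes$size * 2 +
    codes$polarity
  if (any(table(factor(code16, levels = 0:15)) < 2)) {
    stopf("need >= 2 repetitions per stimulus to cross-validate")
  }
  lin_terms <- FEATURE_BITS
  nlin_terms <- c("size:polarity", "speed:size:polarity",
                  "direction:size:polarity", "direction:speed:size:polarity")
  design <- function(d, terms) cbind(1, as.matrix(term_columns(d, terms)))
  Xl <- design(codes, lin_terms); Xn <- design(codes, nlin_terms)
  fit_ls <- function(X, idx) stats::lm.fit(X[idx, , drop = FALSE], y[idx])$coefficients
  r2_test <- function(X, beta, idx) {
    pred <- as.numeric(X[idx, , drop = FALSE] %*% ifelse(is.na(beta), 0, beta))
    1 - sum((y[idx] - pred)^2) / sum((y[idx] - mean(y[idx]))^2)
  }
  cv <- with_seed(seed, {
    res <- matrix(NA_real_, n_splits, 2)
    for (s in seq_len(n_splits)) {
      train <- logical(length(y))
      for (cd in unique(code16)) {
        k <- which(code16 == cd)
        train[sample(k, ceiling(length(k) / 2))] <- TRUE
      }
      res[s, 1] <- r2_test(Xl, fit_ls(Xl, train), !train)
      res[s, 2] <- r2_test(Xn, fit_ls(Xn, train), !train)
    }
    colMeans(res)
  })
  beta_l <- fit_ls(Xl, rep(TRUE, length(y)))
  beta_n <- fit_ls(Xn, rep(TRUE, length(y)))
  names(beta_l) <- c("(Intercept)", lin_terms)
  names(beta_n) <- c("(Intercept)", nlin_terms)
  denom <- abs(cv[2]) + abs(cv[1])
  si <- if (denom == 0) 0 else (cv[2] - cv[1]) / denom
  structure(list(coef_lin = beta_l, coef_nlin = beta_n,
                 cv_r2_lin = cv[1], cv_r2_nlin = cv[2], si_nlin = si,
                 n_trials = length(y)),
            class = "nlms_glm")
}

#' @export
print.nlms_glm <- function(x, ...) {
  cat(sprintf("<nlms_glm> cvR2 nlin %.3f vs lin %.3f (SI_nlin %.3f), %d trials\n",
              x$cv_r2_nlin, x$cv_r2_lin, x$si_nlin, x$n_trials))
  invisible(x)
}

#' @export
coef.nlms_glm <- function(object, ...) {
  list(linear = object$coef_lin, nonlinear = object$coef_nlin)
}

#' Population summary of the non-linear model advantage
#'
#' @param results List of `nlms_glm` objects.
#' @return List: `fraction_nlin_better` (share of ROIs with cvR2_nlin >
#'   cvR2_lin) and `p_signed_rank` (Wilcoxon signed-rank test of the paired
#'   cvR2 values).
#' @export
nlms_population_summary <- function(results) {
  if (length(results) < 2) stopf("need >= 2 model results")
  a <- vapply(results, function(r) r$cv_r2_nlin, numeric(1))
  b <- vapply(results, function(r) r$cv_r2_lin, numeric(1))
  p <- stats::wilcox.test(a, b, paired = TRUE, exact = FALSE)$p.value
  list(fraction_nlin_better = mean(a > b), p_signed_rank = p)
}

#' Estimate the spatial receptive field of an ROI
#'
#' For each moving-spot stimulus with a substantial rep-averaged response
#' (peak >= `resp_frac` of the best stimulus), one RF sample is taken as the
#' spot azimuth one frame (`lag_frames`) before the response peak, corrected
#' for eye position by subtracting the mean screen-coordinate gaze deviation
#' of the contralateral (viewing) eye during the epoch. The RF centre is the
#' circular mean of the samples, the dispersion their circular SD.
#'
#' Screen-gaze convention: for the left eye a nasal rotation points the gaze
#' rightward (+), for the right eye leftward (-); the viewing eye of a
#' left-hemisphere tectal cell is the right eye and vice versa.
#'
#' @param traces A `dff_traces` or frames x ROI matrix.
#' @param schedule Schedule data frame.
#' @param roi ROI column index.
#' @param eye_trace An `eye_trace` aligned to the schedule, or `NULL` for no
#'   eye-position correction.
#' @param hemisphere `"L"` or `"R"`: the cell's tectal hemisphere.
#' @param lag_frames Indicator lag between spot position and response peak.
#' @param resp_frac Responsiveness threshold relative to the best stimulus.
#' @param min_peak Minimum rep-averaged peak dF/F for the ROI to count as
#'   responsive at all.
#' @return List `center_deg`, `dispersion_deg`, `n_stimuli`, or `NULL` when
#'   no stimulus is responsive.
#' @export
estimate_rf <- function(traces, schedule, roi, eye_trace = NULL,
                        hemisphere = "L", lag_frames = 1L, resp_frac = 0.5,
                        min_peak = 0.1) {
  mat <- if (inherits(traces, "dff_traces")) traces$mat else as.matrix(traces)
  pk <- spot_peak_means(mat, schedule, roi)
  if (max(pk) < min_peak) return(NULL)
  resp <- which(pk >= resp_frac * max(pk) & pk > 0) - 1L
  rest <- if (!is.null(eye_trace)) {
    stats::median(c(eye_trace$left, eye_trace$right))
  } else 0
  samples <- numeric(0)
  for (sid in resp) {
    rows <- which(schedule$stimulus_id == sid)
    win <- stimulus_window_frames(schedule[rows[1], ])
    acc <- 0
    for (r in rows) {
      acc <- acc + mat[(schedule$epoch_index[r] - 1L) * FRAMES_PER_EPOCH + win,
                       roi]
    }
    fpk <- win[which.max(acc)]
    epo <- schedule[rows[1], ]
    for (r in rows) {
      epo_r <- schedule[r, ]
      t_pk <- epo_r$epoch_onset + (fpk - 1 + 0.5) / IMG_HZ
      az <- spot_azimuth(epo_r, t_pk - lag_frames / IMG_HZ)
      if (is.na(az)) next
      gaze <- 0
      if (!is.null(eye_trace)) {
        idx <- pmin(length(eye_trace$left),
                    pmax(1, round((epo_r$epoch_onset + c(0, EPOCH_S)) *
                                    eye_trace$fs)))
        idx <- idx[1]:idx[2]
        if (hemisphere == "L") {
          gaze <- -(mean(eye_trace$right[idx]) - rest)   # right eye views
        } else {
          gaze <- +(mean(eye_trace$left[idx]) - rest)    # left eye views
        }
      }
      samples <- c(samples, az - gaze)
    }
  }
  if (!length(samples)) return(NULL)
  list(center_deg = circ_mean_deg(samples),
       dispersion_deg = circ_sd_deg(samples),
       n_stimuli = length(resp))
}
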