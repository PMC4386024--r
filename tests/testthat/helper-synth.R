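# Shared fixtures (built in code, memoised per test run) and independent
# oracles used across test files.

.fixtures <- new.env(parent = emptyenv())

# A moderate complete experiment reused by several files.
small_exp <- function() {
  if (is.null(.fixtures$exp)) {
    .fixtures$exp <- synth_experiment(
      n_planes = 1, reps = 5, seed = 1,
      geometry = list(n_rois = 300L, n_fish = 8L),
      noise = list(sd = 0.1))
  }
  .fixtures$exp
}

small_events <- function() {
  if (is.null(.fixtures$events)) {
    exp <- small_exp()
    ev <- detect_convergent_saccades(exp$eyes)
    .fixtures$events <- classify_evoked(ev, exp$schedule)
  }
  .fixtures$events
}

# Adjusted Rand index by pair counting (independent of any clustering code).
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- si * sj / n2
  (sij - expected) / ((si + sj) / 2 - expected)
}

# Brute-force convergent-saccade detector: scans all onset pairs satisfying
# the velocity, asynchrony, refractory, and displacement rules.
brute_force_detect <- function(trace, params = saccade_params()) {
  fs <- trace$fs
  sm <- function(x) {
    k <- max(1L, as.integer(params$smooth_s * fs))
    if (k %% 2L == 0L) k <- k + 1L
    if (k == 1L) return(x)
    stats::filter(x, rep(1 / k, k), sides = 2)
  }
  onsets_of <- function(x) {
    v <- c(0, diff(as.numeric(sm(x)))) * fs
    v[is.na(v)] <- 0
    above <- v >= params$vel_thresh_dps
    which(above & !c(FALSE, above[-length(above)]))
  }
  ol <- onsets_of(trace$left); orr <- onsets_of(trace$right)
  tol <- round(params$max_asynchrony_s * fs)
  cand <- integer(0)
  for (i in ol) for (j in orr) {
    if (abs(i - j) <= tol) cand <- c(cand, min(i, j))
  }
  cand <- sort(unique(cand))
  kept <- integer(0)
  for (i in cand) {
    if (length(kept) && i - kept[length(kept)] <= params$refractory_s * fs) next
    kept <- c(kept, i)
  }
  # displacement gate via the same window definition as the package
  ok <- vapply(kept, function(i) {
    ev <- tryCatch(saccade_kinematics(list(t_onset = (i - 1) / fs), trace),
                   error = function(e) NULL)
    !is.null(ev) && ev$d_left >= params$min_disp_deg &&
      ev$d_right >= params$min_disp_deg
  }, logical(1))
  kept[ok]
}

# Plant a linear nasal ramp (100 ms) of amplitude `amp` in channel `x`.
plant_ramp <- function(x, t_onset, amp, fs = 60, dur = 0.1, hold = 2) {
  i0 <- floor(t_onset * fs) + 1
  prof <- c(seq(0, amp, length.out = round(dur * fs) + 1)[-1],
            rep(amp, round(hold * fs)))
  idx <- i0 + seq_along(prof) - 1
  ok <- idx <= length(x)
  x[idx[ok]] <- x[idx[ok]] + prof[ok]
  x
}
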