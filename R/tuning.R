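# Visual response vectors, correlation-threshold clustering, selectivity
# indices, and anatomical distributions.

#' Build visual response vectors
#'
#' For each ROI, averages dF/F across the repeated presentations of each of
#' the 18 stimuli (first 38 epoch frames) and concatenates the averages in
#' canonical stimulus order, giving 18 x 38 = 684 time points per cell.
#'
#' @param traces A `dff_traces` or frames x ROI matrix.
#' @param schedule Schedule data frame.
#' @param normalize Divide each VRV by its SD (the clustering substrate).
#' @return Matrix (ROI x 684); attribute `stimulus_block` maps columns to
#'   stimulus ids.
#' @export
build_vrv <- function(traces, schedule, normalize = FALSE) {
  mat <- if (inherits(traces, "dff_traces")) traces$mat else as.matrix(traces)
  n_roi <- ncol(mat)
  vrv <- matrix(NA_real_, n_roi, N_STIM * VRV_FRAMES)
  for (sid in 0:(N_STIM - 1L)) {
    rows <- which(schedule$stimulus_id == sid)
    if (!length(rows)) stopf("stimulus %d missing from schedule", sid)
    acc <- matrix(0, VRV_FRAMES, n_roi)
    for (r in rows) {
      acc <- acc + mat[epoch_frames(schedule$epoch_index[r]), , drop = FALSE]
    }
    cols <- sid * VRV_FRAMES + seq_len(VRV_FRAMES)
    vrv[, cols] <- t(acc / length(rows))
  }
  if (normalize) {
    s <- apply(vrv, 1, stats::sd)
    vrv <- vrv / ifelse(s > 0, s, Inf)
  }
  attr(vrv, "stimulus_block") <- rep(0:(N_STIM - 1L), each = VRV_FRAMES)
  vrv
}

#' Correlation-threshold clustering of visual response vectors
#'
#' Greedy seeded centroid clustering: the seed is the cell with the most
#' neighbours at correlation >= `r_min`; membership is grown and shrunk by
#' correlation to the cluster centroid (mean of member VRVs) until a fixed
#' point; members are removed from the pool and the procedure repeats.
#' Clusters are retained only if they contain at least `min_cells` cells
#' drawn from at least `min_fish` distinct fish. Every retained member
#' satisfies r(member, centroid) >= `r_min` by construction.
#'
#' @param vrv ROI x 684 matrix of (typically SD-normalised) VRVs of visually
#'   responsive cells.
#' @param fish_id Fish label per ROI (for the `min_fish` gate).
#' @param r_min Minimum correlation to the centroid (default 0.75).
#' @param min_fish Minimum number of distinct fish per cluster (default 6).
#' @param min_cells Minimum cluster size.
#' @param max_iter Fixed-point iteration cap per cluster.
#' @return Object of class `vrv_clusters`: list with `membership` (integer
#'   per ROI, `NA` = unclustered), `clusters` (list of `roi_idx`, `centroid`,
#'   `centroid_sd`, `n_fish`, `r_to_centroid`), `r_min`, `min_fish`.
#' @export
cluster_vrvs <- function(vrv, fish_id, r_min = 0.75, min_fish = 6,
                         min_cells = 2, max_iter = 50) {
  n <- nrow(vrv)
  if (n < 2) stopf("need at least 2 cells")
  membership <- rep(NA_integer_, n)
  pool <- which(apply(vrv, 1, stats::sd) > 0)
  clusters <- list()
  R <- suppressWarnings(stats::cor(t(vrv)))
  R[!is.finite(R)] <- 0
  while (length(pool) >= max(2, min_cells)) {
    nb <- rowSums(R[pool, pool, drop = FALSE] >= r_min) - 1
    if (max(nb) + 1 < max(2, min_cells)) break
    seed <- pool[which.max(nb)]
    members <- pool[R[seed, pool] >= r_min]
    for (it in seq_len(max_iter)) {
      centroid <- colMeans(vrv[members, , drop = FALSE])
      r <- suppressWarnings(as.numeric(stats::cor(centroid, t(vrv[pool, ,
                                                       drop = FALSE]))))
      new_members <- pool[!is.na(r) & r >= r_min]
      if (length(new_members) < 2) break
      if (identical(sort(new_members), sort(members))) break
      members <- new_members
    }
    if (length(members) < 2) { pool <- setdiff(pool, seed); next }
    centroid <- colMeans(vrv[members, , drop = FALSE])
    r_mem <- as.numeric(stats::cor(centroid, t(vrv[members, , drop = FALSE])))
    keep <- r_mem >= r_min
    members <- members[keep]; r_mem <- r_mem[keep]
    pool <- setdiff(pool, if (length(members)) members else seed)
    if (length(members) >= min_cells &&
        length(unique(fish_id[members])) >= min_fish) {
      clusters[[length(clusters) + 1L]] <- list(
        roi_idx = members, centroid = centroid,
        centroid_sd = apply(vrv[members, , drop = FALSE], 2, stats::sd),
        n_fish = length(unique(fish_id[members])),
        r_to_centroid = r_mem)
      membership[members] <- length(clusters)
    }
  }
  structure(list(membership = membership, clusters = clusters, r_min = r_min,
                 min_fish = min_fish),
            class = "vrv_clusters")
}

#' @export
print.vrv_clusters <- function(x, ...) {
  cat(sprintf("<vrv_clusters> %d cluster(s) at r >= %.2f, >= %d fish\n",
              length(x$clusters), x$r_min, x$min_fish))
  for (i in seq_along(x$clusters)) {
    cl <- x$clusters[[i]]
    cat(sprintf("  %2d: %3d cells from %d fish\n", i, length(cl$roi_idx),
                cl$n_fish))
  }
  invisible(x)
}

# Mean peak response to each of the 16 moving-spot stimuli, rectified at 0.
spot_peak_means <- function(trace_mat, schedule, roi) {
  out <- numeric(16)
  for (sid in 0:15) {
    rows <- which(schedule$stimulus_id == sid)
    win <- stimulus_window_frames(schedule[rows[1], ])
    acc <- 0
    for (r in rows) {
      acc <- acc + trace_mat[(schedule$epoch_index[r] - 1L) * FRAMES_PER_EPOCH +
                               win, roi]
    }
    out[sid + 1L] <- max(acc / length(rows))
  }
  pmax(out, 0)
}

#' Feature selectivity index
#'
#' SI = (R_pref - R_flip) / (R_pref + R_flip), where R_pref is the largest
#' rep-averaged peak dF/F across the 16 moving-spot stimuli (negative
#' responses rectified to 0) and R_flip is the response to the stimulus
#' identical except with the queried feature bit inverted. The sign is
#' oriented so that positive values indicate preference for bit value 1
#' (left-to-right / fast / large / dark).
#'
#' @param traces A `dff_traces` or frames x ROI matrix.
#' @param schedule Schedule data frame.
#' @param roi ROI column index.
#' @param feature One of `"direction"`, `"speed"`, `"size"`, `"polarity"`,
#'   or `"all"` for all four.
#' @return Named numeric (length 1 or 4) in [-1, 1]; `NA` when both responses
#'   are zero.
#' @export
selectivity_index <- function(traces, schedule, roi,
                              feature = c("all", "direction", "speed", "size",
                                          "polarity")) {
  feature <- match.arg(feature)
  mat <- if (inherits(traces, "dff_traces")) traces$mat else as.matrix(traces)
  pk <- spot_peak_means(mat, schedule, roi)
  feats <- if (feature == "all") FEATURE_BITS else feature
  bitpos <- c(direction = 8L, speed = 4L, size = 2L, polarity = 1L)
  s_pref <- which.max(pk) - 1L
  out <- vapply(feats, function(f) {
    s_flip <- bitwXor(s_pref, bitpos[[f]])
    r_pref <- pk[s_pref + 1L]; r_flip <- pk[s_flip + 1L]
    if (r_pref <= 0 && r_flip <= 0) return(NA_real_)
    si <- (r_pref - r_flip) / (r_pref + r_flip)
    # orient: positive = preference for bit value 1
    if (bitwAnd(s_pref, bitpos[[f]]) == 0L) si <- -si
    si
  }, numeric(1))
  names(out) <- feats
  out
}

#' Anatomical distribution of a cluster
#'
#' Contingency counts of cluster members over region x hemisphere.
#'
#' @param cluster One element of a [cluster_vrvs()] result (or an integer
#'   vector of ROI indices).
#' @param roi_table ROI table with `region` and `hemisphere` columns (row
#'   order matching the VRV matrix).
#' @return Data frame `region`, `hemisphere`, `count`, `fraction`.
#' @export
anatomical_distribution <- function(cluster, roi_table) {
  idx <- if (is.list(cluster)) cluster$roi_idx else cluster
  reg <- roi_table$region[idx]; hemi <- roi_table$hemisphere[idx]
  if (anyNA(reg) || anyNA(hemi)) stopf("unlabeled cluster member(s)")
  tab <- as.data.frame(table(region = reg, hemisphere = hemi),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0, ]
  names(tab)[3] <- "count"
  tab$fraction <- tab$count / sum(tab$count)
  rownames(tab) <- NULL
  tab
}
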