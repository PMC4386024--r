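# File codecs: plain-text, lossless round trips for every table and trace.
#
# Dialects: schedules/events/ROI tables as CSV; eye traces as CSV
# (t, left_deg, right_deg); dF/F matrices as CSV with a frame column and one
# column per ROI; ground truth and reports as JSON; configs as YAML.

#' @rdname codecs
#' @export
write_schedule <- function(schedule, path) {
  utils::write.csv(as.data.frame(schedule), path, row.names = FALSE)
  invisible(path)
}

#' @rdname codecs
#' @export
read_schedule <- function(path) {
  sched <- utils::read.csv(path)
  class(sched) <- c("hunt_schedule", "data.frame")
  sched
}

#' @rdname codecs
#' @export
write_eye_trace <- function(trace, path) {
  n <- length(trace$left)
  utils::write.csv(data.frame(t = (seq_len(n) - 1) / trace$fs,
                              left_deg = trace$left,
                              right_deg = trace$right),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname codecs
#' @export
read_eye_trace <- function(path, fs = EYE_HZ) {
  d <- utils::read.csv(path)
  need <- c("t", "left_deg", "right_deg")
  if (!all(need %in% names(d))) {
    stopf("malformed eye-trace file (need columns %s)",
          paste(need, collapse = ", "))
  }
  structure(list(fs = fs, left = d$left_deg, right = d$right_deg,
                 events = NULL), class = "eye_trace")
}

#' @rdname codecs
#' @export
write_events <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}

#' @rdname codecs
#' @export
read_events <- function(path) {
  ev <- utils::read.csv(path)
  class(ev) <- c("saccade_events", "data.frame")
  ev
}

#' @rdname codecs
#' @export
write_rois <- function(rois, path) {
  utils::write.csv(rois, path, row.names = FALSE)
  invisible(path)
}

#' @rdname codecs
#' @export
read_rois <- function(path) utils::read.csv(path)

#' Read/write codecs for the pipeline's tabular formats
#'
#' Plain-CSV (tables, eye traces, dF/F matrices) and JSON (ground truth)
#' codecs with lossless numeric round trips.
#'
#' @param schedule,trace,events,rois,traces,x Objects to write.
#' @param path File path.
#' @param fs Sampling rate when reading an eye trace.
#' @name codecs
#' @export
write_trace_matrix <- function(traces, path) {
  mat <- if (inherits(traces, "dff_traces")) traces$mat else as.matrix(traces)
  df <- data.frame(frame = seq_len(nrow(mat)), mat, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname codecs
#' @export
read_trace_matrix <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  if (!"frame" %in% names(d)) stopf("malformed trace store: no `frame` column")
  mat <- as.matrix(d[, setdiff(names(d), "frame"), drop = FALSE])
  if (nrow(mat) %% FRAMES_PER_EPOCH == 0) {
    structure(list(mat = mat, fs = IMG_HZ,
                   frames_per_epoch = FRAMES_PER_EPOCH,
                   n_epochs = nrow(mat) %/% FRAMES_PER_EPOCH,
                   assembly_events = NULL),
              class = "dff_traces")
  } else mat
}

#' @rdname codecs
#' @export
write_ground_truth <- function(x, path) {
  jsonlite::write_json(x, path, dataframe = "columns", digits = NA,
                       na = "null", auto_unbox = TRUE)
  invisible(path)
}
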