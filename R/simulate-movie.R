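# Rendering of synthetic imaging movies (frame-scanned fluorescence stacks).

#' Render a synthetic imaging movie from ROI traces
#'
#' Draws each ROI as a disk whose brightness follows F0 * (1 + dF/F) on a
#' constant background, with optional per-frame rigid shifts emulating the
#' small motion artifacts of frame-scanned imaging. Optionally written as a
#' multi-page TIFF.
#'
#' @param population A [generate_population()] result.
#' @param traces A [generate_fluorescence()] result (or any frames x ROI
#'   matrix matching the population).
#' @param motion_params List: `shifts` (data frame `frame`, `dx`, `dy` in px)
#'   or `NULL` for no motion; `shift_sd_px` plus `shift_frames` to draw
#'   random integer shifts at the given frames.
#' @param frame_px Frame size in pixels `c(height, width)`.
#' @param pixel_um Pixel pitch (um/px); default scales the anatomical field
#'   to the frame.
#' @param roi_radius_um ROI disk radius in micrometres.
#' @param f0,background Baseline ROI and background intensities (arbitrary
#'   counts).
#' @param file Optional path; the stack is written as a multi-page TIFF.
#' @param seed Seed for random shifts.
#' @return A 3-D array (frame, row, col) of intensities, invisibly when
#'   written to file. Attribute `shifts` holds the applied per-frame shifts.
#' @export
render_movie <- function(population, traces, motion_params = list(),
                         frame_px = c(128L, 128L), pixel_um = NULL,
                         roi_radius_um = 3, f0 = 100, background = 20,
                         file = NULL, seed = NULL) {
  mat <- if (inherits(traces, "dff_traces")) traces$mat else traces
  rois <- population$rois
  if (ncol(mat) != nrow(rois)) stopf("traces do not match population")
  H <- frame_px[1]; W <- frame_px[2]
  x0 <- min(population$map$x0); x1 <- max(population$map$x1)
  y0 <- min(population$map$y0); y1 <- max(population$map$y1)
  if (is.null(pixel_um)) pixel_um <- max((x1 - x0) / W, (y1 - y0) / H)
  cx <- round((rois$x_um - x0) / pixel_um) + 1L
  cy <- round((rois$y_um - y0) / pixel_um) + 1L
  r_px <- max(1L, round(roi_radius_um / pixel_um))
  if (any(cx < 1 - r_px | cx > W + r_px | cy < 1 - r_px | cy > H + r_px)) {
    stopf("ROI masks fall outside the frame; reduce pixel_um or enlarge frame")
  }
  # disk offsets
  off <- expand.grid(dx = -r_px:r_px, dy = -r_px:r_px)
  off <- off[off$dx^2 + off$dy^2 <= r_px^2, ]

  nf <- nrow(mat)
  shifts <- motion_params$shifts
  if (is.null(shifts) && !is.null(motion_params$shift_frames)) {
    sdpx <- motion_params$shift_sd_px %||% 2
    shifts <- with_seed(seed, data.frame(
      frame = motion_params$shift_frames,
      dx = round(stats::rnorm(length(motion_params$shift_frames), 0, sdpx)),
      dy = round(stats::rnorm(length(motion_params$shift_frames), 0, sdpx))))
  }
  dxv <- integer(nf); dyv <- integer(nf)
  if (!is.null(shifts) && nrow(shifts)) {
    dxv[shifts$frame] <- as.integer(shifts$dx)
    dyv[shifts$frame] <- as.integer(shifts$dy)
  }
  stack <- array(background, dim = c(nf, H, W))
  for (f in seq_len(nf)) {
    img <- matrix(background, H, W)
    for (j in seq_len(nrow(rois))) {
      val <- f0 * (1 + mat[f, j])
      px <- cx[j] + off$dx + dxv[f]
      py <- cy[j] + off$dy + dyv[f]
      ok <- px >= 1 & px <= W & py >= 1 & py <= H
      img[cbind(py[ok], px[ok])] <- val
    }
    stack[f, , ] <- img
  }
  attr(stack, "shifts") <- data.frame(frame = seq_len(nf), dx = dxv, dy = dyv)
  attr(stack, "pixel_um") <- pixel_um
  attr(stack, "origin_um") <- c(x = x0, y = y0)
  if (!is.null(file)) {
    pages <- lapply(seq_len(nf), function(f) {
      m <- stack[f, , ]
      m <- m / max(m, 1)
      m
    })
    tiff::writeTIFF(pages, file, bits.per.sample = 16)
    return(invisible(stack))
  }
  stack
}
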