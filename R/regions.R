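# Anatomical region map for the synthetic experiment.
#
# A schematic dorsal view of the larval zebrafish midbrain in physical
# micrometres: midline at x = 0 (left hemisphere x < 0), anterior at y = 0.
# Regions are axis-aligned rectangles (non-overlapping): left/right tectal
# stratum periventriculare (SPV), left/right tectal neuropil lateral to the
# SPV, left/right habenula anteriorly, and the torus longitudinalis (TL) at
# the midline. The posterior-commissure landmark anchors anterior-posterior
# distance measurements.

#' Build the synthetic anatomical region map
#'
#' @param field_um Half-width of the mapped field in micrometres.
#' @return A data frame of class `region_map` with one rectangle per row
#'   (`region`, `hemisphere`, `x0`, `x1`, `y0`, `y1`, in um) and attribute
#'   `landmark`, the posterior-commissure coordinate `c(x, y)`.
#' @export
region_map <- function(field_um = 400) {
  rects <- data.frame(
    region = c("Hb", "Hb", "TL", "OTc-SPV", "OTc-SPV", "OTc-Np", "OTc-Np"),
    hemisphere = c("L", "R", "none", "L", "R", "L", "R"),
    x0 = c(-60, 10, -30, -150, 40, -195, 155),
    x1 = c(-10, 60, 30, -40, 150, -155, 195),
    y0 = c(0, 0, 70, 70, 70, 80, 80),
    y1 = c(60, 60, 120, 260, 260, 250, 250)
  )
  structure(rects, class = c("region_map", "data.frame"),
            landmark = c(x = 0, y = 65))
}

#' Resolve centroids to anatomical regions
#'
#' @param x,y Centroid coordinates in micrometres (vectorised).
#' @param map A [region_map()].
#' @return A data frame with `region` (`"other"` when outside every
#'   rectangle) and `hemisphere` (`"L"`/`"R"`/`"none"`).
#' @export
locate_region <- function(x, y, map = region_map()) {
  region <- rep("other", length(x))
  hemi <- ifelse(x < 0, "L", ifelse(x > 0, "R", "none"))
  for (i in seq_len(nrow(map))) {
    inside <- x >= map$x0[i] & x <= map$x1[i] & y >= map$y0[i] & y <= map$y1[i]
    region[inside] <- map$region[i]
    hemi[inside] <- map$hemisphere[i]
  }
  data.frame(region = region, hemisphere = hemi)
}

# Uniform draw inside a named region (one hemisphere).
sample_in_region <- function(n, map, region, hemisphere = NULL,
                             margin = 0) {
  k <- if (is.null(hemisphere)) which(map$region == region) else
    which(map$region == region & map$hemisphere == hemisphere)
  if (!length(k)) stopf("region '%s' (%s) not present in map", region,
                        hemisphere %||% "any")
  k <- k[1L]
  data.frame(
    x = stats::runif(n, map$x0[k] + margin, map$x1[k] - margin),
    y = stats::runif(n, map$y0[k] + margin, map$y1[k] - margin)
  )
}
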