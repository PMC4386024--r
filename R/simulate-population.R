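# Planted cell populations with known tuning archetypes.
#
# Archetypes emulate the response classes seen in the tectum and adjacent
# regions: whole-field luminance cells (ON, dimming, inhibited), mixed-
# selectivity spot-tuned cells (including a mirror-symmetric direction-
# selective pair), the six non-linear mixed-selectivity (NLMS) conjunction
# types, premotor assembly cells, and non-responsive cells. Every ROI carries
# its ground-truth tuning so downstream stages have recovery tests.

NLMS_TYPES <- c("nDS-nSp", "nDS-Sp", "R2L-nSp", "R2L-Sp", "L2R-nSp", "L2R-Sp")

#' Default archetype mixture weights
#' @return Named numeric vector summing to 1.
#' @export
default_mixture_weights <- function() {
  c(nonresponsive = 0.50, lum_on = 0.06, lum_dim = 0.04, lum_inh = 0.03,
    ms = 0.15, nlms = 0.12, assembly = 0.10)
}

# Spot-stimulus weight vector (length 16, canonical order) for a subtype.
archetype_spot_weights <- function(subtype) {
  st <- stimulus_table()[1:16, ]
  w <- numeric(16)
  if (subtype %in% NLMS_TYPES) {
    sel <- st$size == 1 & st$polarity == 1
    if (grepl("-Sp$", subtype)) sel <- sel & st$speed == 1
    if (grepl("^R2L", subtype)) sel <- sel & st$direction == 0
    if (grepl("^L2R", subtype)) sel <- sel & st$direction == 1
    w[sel] <- 1
  } else if (subtype == "ms_largedark") {
    w[st$size == 1 & st$polarity == 1] <- 1
  } else if (subtype == "ms_smallbright") {
    w[st$size == 0 & st$polarity == 0] <- 1
  } else if (subtype == "ms_dirL") {        # left-tectum member of the mirror pair
    w[st$direction == 1 & st$size == 1 & st$polarity == 0] <- 1
  } else if (subtype == "ms_dirR") {        # right-tectum mirror partner
    w[st$direction == 0 & st$size == 1 & st$polarity == 0] <- 1
  } else if (subtype == "assembly") {
    w[st$size == 1 & st$polarity == 1] <- 0.4  # weak visual drive
  }
  w
}

#' Generate a planted ROI population with ground truth
#'
#' Places ROIs in the synthetic anatomical map with archetype-appropriate
#' locations (luminance-ON cells enriched in the torus longitudinalis,
#' mixed-selectivity/NLMS cells in the tectal SPV with hemisphere-appropriate
#' receptive fields, assembly cells as compact unilateral SPV groups) and
#' labels every ROI with its true tuning parameters.
#'
#' @param geometry_params List: `map` (a [region_map()]), `n_rois`, `n_fish`,
#'   `n_planes`, `assembly_radius_um` (default 30), `assembly_size` (range,
#'   default 8:15), `assembly_lead` (lead frames, or a range to sample;
#'   default 2:4).
#' @param mixture_weights Named archetype weights summing to 1
#'   (see [default_mixture_weights()]).
#' @param seed Integer seed.
#' @return Object of class `synth_population`: list with `rois` (data frame:
#'   `roi_id`, `fish_id`, `plane_z`, `x_um`, `y_um`, `hemisphere`, `region`,
#'   `archetype`, `subtype`, `rf_azimuth`, `amplitude`, `assembly_id`,
#'   `lead_frames`), `assemblies` (one row per planted assembly), `map`,
#'   `weights`, `seed`.
#' @export
generate_population <- function(geometry_params = list(),
                                mixture_weights = default_mixture_weights(),
                                seed = NULL) {
  gp <- utils::modifyList(
    list(map = region_map(), n_rois = 600L, n_fish = 8L, n_planes = 1L,
         assembly_radius_um = 30, assembly_size = 8:15, assembly_lead = 2:4),
    geometry_params)
  if (abs(sum(mixture_weights) - 1) > 1e-8) {
    stopf("mixture weights must sum to 1")
  }
  map <- gp$map
  n <- gp$n_rois
  with_seed(seed, {
    counts <- stats::setNames(round(mixture_weights * n), names(mixture_weights))
    counts[1] <- counts[1] + n - sum(counts)  # absorb rounding in first class

    rois <- list()
    add <- function(df) rois[[length(rois) + 1L]] <<- df
    blank <- function(m, archetype, subtype = NA_character_) {
      data.frame(archetype = rep(archetype, m), subtype = subtype,
                 x_um = NA_real_, y_um = NA_real_,
                 rf_azimuth = NA_real_, amplitude = NA_real_,
                 assembly_id = NA_integer_, lead_frames = NA_integer_)
    }
    rf_for_hemi <- function(hemi) {
      # left tectum views the right visual hemifield and vice versa
      ifelse(hemi == "L", stats::runif(length(hemi), 10, 80),
             stats::runif(length(hemi), -80, -10))
    }

    asm_tab <- data.frame(assembly_id = integer(0), hemisphere = character(0),
                          n_cells = integer(0), lead_frames = integer(0),
                          x_um = numeric(0), y_um = numeric(0))

    for (a in names(counts)) {
      m <- counts[[a]]
      if (m <= 0) next
      if (a == "nonresponsive") {
        d <- blank(m, a)
        d$x_um <- stats::runif(m, min(map$x0), max(map$x1))
        d$y_um <- stats::runif(m, min(map$y0), max(map$y1))
        add(d)
      } else if (a %in% c("lum_on", "lum_dim", "lum_inh")) {
        d <- blank(m, a, a)
        # ON cells enriched at the TL (41%); the rest split Hb / tectum
        probs <- if (a == "lum_on") c(TL = 0.41, Hb = 0.30, `OTc-SPV` = 0.29)
          else c(TL = 0.2, Hb = 0.4, `OTc-SPV` = 0.4)
        reg <- sample(names(probs), m, replace = TRUE, prob = probs)
        for (i in seq_len(m)) {
          hemi <- if (reg[i] == "TL") NULL else sample(c("L", "R"), 1)
          xy <- sample_in_region(1, map, reg[i], hemi)
          d$x_um[i] <- xy$x; d$y_um[i] <- xy$y
        }
        d$amplitude <- stats::runif(m, 0.8, 1.2)
        add(d)
      } else if (a == "ms") {
        sub <- sample(c("ms_largedark", "ms_smallbright", "ms_dir"), m,
                      replace = TRUE, prob = c(0.4, 0.3, 0.3))
        hemi <- sample(c("L", "R"), m, replace = TRUE)
        sub[sub == "ms_dir"] <- ifelse(hemi[sub == "ms_dir"] == "L",
                                       "ms_dirL", "ms_dirR")
        d <- blank(m, a, sub)
        for (i in seq_len(m)) {
          xy <- sample_in_region(1, map, "OTc-SPV", hemi[i])
          d$x_um[i] <- xy$x; d$y_um[i] <- xy$y
        }
        # mixed-selectivity archetypes occupy narrow retinotopic bands
        # (mirrored across hemispheres) so that members share response
        # timing, as coherent functional clusters do
        ctr <- c(ms_largedark = 45, ms_smallbright = 25, ms_dirL = 60,
                 ms_dirR = 60)[sub]
        rf <- ctr + stats::rnorm(m, 0, 6)
        d$rf_azimuth <- ifelse(hemi == "L", rf, -rf)
        d$amplitude <- stats::runif(m, 0.8, 1.2)
        add(d)
      } else if (a == "nlms") {
        sub <- sample(NLMS_TYPES, m, replace = TRUE)
        # direction-selective types view the hemifield their motion enters
        hemi <- sample(c("L", "R"), m, replace = TRUE)
        d <- blank(m, a, sub)
        for (i in seq_len(m)) {
          xy <- sample_in_region(1, map, "OTc-SPV", hemi[i])
          d$x_um[i] <- xy$x; d$y_um[i] <- xy$y
        }
        d$rf_azimuth <- rf_for_hemi(hemi)
        d$amplitude <- stats::runif(m, 0.8, 1.2)
        add(d)
      } else if (a == "assembly") {
        left <- m
        aid <- nrow(asm_tab)
        while (left >= min(gp$assembly_size)) {
          sz <- min(left, sample(gp$assembly_size, 1))
          if (sz < min(gp$assembly_size)) break
          aid <- aid + 1L
          hemi <- if (aid %% 2L == 1L) "L" else "R"
          ctr <- sample_in_region(1, map, "OTc-SPV", hemi,
                                  margin = gp$assembly_radius_um + 5)
          th <- stats::runif(sz, 0, 2 * pi)
          rr <- gp$assembly_radius_um * sqrt(stats::runif(sz))
          d <- blank(sz, a, "assembly")
          d$x_um <- ctr$x + rr * cos(th)
          d$y_um <- ctr$y + rr * sin(th)
          d$rf_azimuth <- rf_for_hemi(rep(hemi, sz))
          d$amplitude <- stats::runif(sz, 1.2, 1.8)
          d$assembly_id <- aid
          lead <- if (length(gp$assembly_lead) == 1L) gp$assembly_lead else
            sample(gp$assembly_lead, 1)
          d$lead_frames <- lead
          asm_tab <- rbind(asm_tab, data.frame(
            assembly_id = aid, hemisphere = hemi, n_cells = sz,
            lead_frames = lead, x_um = ctr$x, y_um = ctr$y))
          add(d)
          left <- left - sz
        }
        if (left > 0) {  # remainder too small for an assembly
          d <- blank(left, "nonresponsive")
          d$x_um <- stats::runif(left, min(map$x0), max(map$x1))
          d$y_um <- stats::runif(left, min(map$y0), max(map$y1))
          add(d)
        }
      } else {
        stopf("unknown archetype '%s'", a)
      }
    }
    rois <- do.call(rbind, rois)
    rois$roi_id <- seq_len(nrow(rois))
    rois$fish_id <- sample.int(gp$n_fish, nrow(rois), replace = TRUE)
    rois$plane_z <- 4 * (sample.int(gp$n_planes, nrow(rois), replace = TRUE) - 1L)
    loc <- locate_region(rois$x_um, rois$y_um, map)
    rois$region <- loc$region
    rois$hemisphere <- loc$hemisphere
    rois <- rois[, c("roi_id", "fish_id", "plane_z", "x_um", "y_um",
                     "hemisphere", "region", "archetype", "subtype",
                     "rf_azimuth", "amplitude", "assembly_id", "lead_frames")]
    structure(list(rois = rois, assemblies = asm_tab, map = map,
                   weights = mixture_weights, seed = seed),
              class = "synth_population")
  })
}

#' @export
print.synth_population <- function(x, ...) {
  cat(sprintf("<synth_population> %d ROIs, %d planted assemblies\n",
              nrow(x$rois), nrow(x$assemblies)))
  print(table(x$rois$archetype))
  invisible(x)
}
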