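# End-to-end pipeline driver.

#' Default pipeline configuration
#'
#' All analysis thresholds default to the published parameters: assignment
#' and clustering correlation threshold 0.75, modulation gates p < 0.05 and
#' SNR > 3, assembly gates >= 6 cells at <= 533 um^2/cell, pre/peri windows
#' of 3/5 frames, imaging at 1.8 Hz, eye tracking at 60 Hz.
#'
#' @param ... Named overrides (nested lists are merged).
#' @return Nested configuration list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    simulate = list(n_planes = 1L, reps = 5L,
                    geometry = list(n_rois = 400L, n_fish = 8L),
                    noise = list(sd = 0.1)),
    cluster = list(r_min = 0.75, min_fish = 6L, min_cells = 5L),
    nlms = list(r_min = 0.75, n_splits = 10L),
    assemblies = list(alpha = 0.05, snr_min = 3, min_cells = 6L,
                      max_density = 533, n_perm = 3L),
    out = NULL
  )
  utils::modifyList(cfg, list(...))
}

#' Run the full analysis pipeline on a synthetic experiment
#'
#' Executes simulate -> behavior -> tuning -> NLMS -> assemblies and returns
#' a report bundle with every result table plus the parameter manifest. With
#' a fixed seed the report is reproducible; when `config$out` is set the
#' tables are also written (CSV/JSON) to that directory.
#'
#' @param config A [pipeline_config()], or a path to a YAML file with the
#'   same structure.
#' @return List of class `preytect_report`: `config`, `experiment`,
#'   `events`, `location_stats`, `rate_table`, `model`, `clusters`,
#'   `nlms_assignments`, `assemblies_pre`, `assemblies_peri`, `overlap`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- utils::modifyList(pipeline_config(),
                                                        yaml::read_yaml(config))
  for (field in c("seed", "simulate")) {
    if (is.null(config[[field]])) stopf("config is missing `%s`", field)
  }
  sim <- config$simulate
  exp <- synth_experiment(n_planes = sim$n_planes, reps = sim$reps,
                          seed = config$seed,
                          geometry = sim$geometry %||% list(),
                          noise = sim$noise %||% list())

  events <- detect_convergent_saccades(exp$eyes)
  events <- classify_evoked(events, exp$schedule)
  rate_tab <- response_rate_table(events, exp$schedule)
  loc <- if (any(events$evoked)) response_location_stats(events) else NULL
  # fit the behavioural model only when there are enough responses for a
  # stable maximum-likelihood fit
  model <- if (sum(rate_tab$n_responses) >= 20) {
    tryCatch(fit_logistic_model(rate_tab), error = function(e) NULL)
  } else NULL

  vres <- classify_visually_responsive(exp$dff, exp$schedule)
  vrv <- build_vrv(exp$dff, exp$schedule, normalize = TRUE)
  keep <- which(vres$responsive)
  cl <- config$cluster
  clusters <- if (length(keep) >= 2) {
    cv <- cluster_vrvs(vrv[keep, , drop = FALSE],
                       exp$population$rois$fish_id[keep],
                       r_min = cl$r_min, min_fish = cl$min_fish,
                       min_cells = cl$min_cells)
    cv$roi_rows <- keep
    cv
  } else NULL

  regs <- build_regressors()
  assigns <- lapply(seq_len(ncol(exp$dff$mat)), function(j) {
    v <- peak_response_vector(exp$dff, exp$schedule, j)
    a <- assign_regressor(v, regs, config$nlms$r_min)
    if (is.null(a)) NULL else data.frame(roi = j, key = a$key, r = a$r)
  })
  assigns <- do.call(rbind, assigns[!vapply(assigns, is.null, logical(1))])

  ac <- config$assemblies
  pre <- find_assemblies(exp$dff, exp$schedule, events, exp$population$rois,
                         "pre", alpha = ac$alpha, snr_min = ac$snr_min,
                         min_cells = ac$min_cells,
                         max_density = ac$max_density)
  peri <- find_assemblies(exp$dff, exp$schedule, events, exp$population$rois,
                          "peri", alpha = ac$alpha, snr_min = ac$snr_min,
                          min_cells = ac$min_cells,
                          max_density = ac$max_density)
  report <- structure(list(
    config = config, experiment = exp, events = events,
    location_stats = loc, rate_table = rate_tab, model = model,
    responsive = vres$responsive, clusters = clusters,
    nlms_assignments = assigns, assemblies_pre = pre, assemblies_peri = peri,
    overlap = overlap_stats(pre, peri)), class = "preytect_report")

  if (!is.null(config$out)) {
    dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
    write_schedule(exp$schedule, file.path(config$out, "schedule.csv"))
    write_events(events, file.path(config$out, "events.csv"))
    write_rois(exp$population$rois, file.path(config$out, "rois.csv"))
    write_trace_matrix(exp$dff, file.path(config$out, "dff.csv"))
    utils::write.csv(rate_tab, file.path(config$out, "rate_table.csv"),
                     row.names = FALSE)
    manifest <- config
    manifest$out <- NULL
    jsonlite::write_json(
      list(parameters = manifest,
           n_events = nrow(events),
           n_responsive = sum(vres$responsive),
           n_clusters = length(clusters$clusters %||% list()),
           n_assemblies_pre = length(pre),
           n_assemblies_peri = length(peri)),
      file.path(config$out, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.preytect_report <- function(x, ...) {
  cat("preytect pipeline report\n")
  cat(sprintf("  events: %d detected (%d evoked)\n", nrow(x$events),
              sum(x$events$evoked, na.rm = TRUE)))
  cat(sprintf("  visually responsive ROIs: %d / %d\n", sum(x$responsive),
              length(x$responsive)))
  cat(sprintf("  clusters: %d\n", length(x$clusters$clusters %||% list())))
  cat(sprintf("  NLMS assignments: %d\n",
              if (is.null(x$nlms_assignments)) 0L else
                nrow(x$nlms_assignments)))
  cat(sprintf("  assemblies: %d pre-conv, %d peri-conv\n",
              length(x$assemblies_pre), length(x$assemblies_peri)))
  invisible(x)
}
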