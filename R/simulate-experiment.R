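# One-call generator for a complete synthetic experiment.

#' Simulate a complete tethered-imaging experiment
#'
#' Convenience driver that generates a stimulus schedule, binocular eye
#' traces with planted convergent saccades, a planted ROI population, and
#' dF/F traces, all from one seed. The returned bundle is the ground-truth
#' substrate for every downstream analysis stage.
#'
#' @param n_planes,reps Schedule size (see [generate_schedule()]).
#' @param seed Integer master seed (sub-stage seeds are derived from it).
#' @param behavior Parameters for [generate_eye_traces()].
#' @param geometry,weights Parameters for [generate_population()].
#' @param noise Parameters for [generate_fluorescence()].
#' @return Object of class `synth_experiment`: list with `schedule`, `eyes`
#'   (an `eye_trace`), `population`, `dff` (a `dff_traces`), and `seed`.
#' @export
synth_experiment <- function(n_planes = 1L, reps = 5L, seed = 1L,
                             behavior = behavior_params(),
                             geometry = list(), weights = default_mixture_weights(),
                             noise = list()) {
  seed <- as.integer(seed)
  sched <- generate_schedule(n_planes, reps, seed = seed)
  eyes <- generate_eye_traces(sched, behavior, seed = seed + 1L)
  pop <- generate_population(geometry, weights, seed = seed + 2L)
  dff <- generate_fluorescence(pop, sched, eyes$events, noise, seed = seed + 3L)
  structure(list(schedule = sched, eyes = eyes, population = pop, dff = dff,
                 seed = seed),
            class = "synth_experiment")
}

#' @export
print.synth_experiment <- function(x, ...) {
  cat(sprintf(paste0("<synth_experiment> %d epochs, %d ROIs, ",
                     "%d planted saccades (%d evoked), seed %d\n"),
              nrow(x$schedule), nrow(x$population$rois),
              nrow(x$eyes$events), sum(x$eyes$events$evoked), x$seed))
  invisible(x)
}
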