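# Per-movie transport statistics from segmented tracks: flux, velocity, run
# length, pause duration, directionality, stationary fraction, density.

DIRECTIONS <- c("anterograde", "retrograde")

#' Per-direction transport flux
#'
#' Flux = sum of directed-run displacements, divided by axon length and movie
#' duration: `sum(d_i) / (l * t)` with `d_i` the individual run lengths (um),
#' `l` the imaged axon length (um) and `t` the duration in minutes. Units:
#' um traveled per um of axon per minute.
#'
#' @param runs data.frame of directed runs (needs `direction`,
#'   `displacement_um`).
#' @param axon_length_um imaged axon length `l`, um (> 0).
#' @param duration_min movie duration `t`, minutes (> 0).
#' @return named numeric: flux for `anterograde` and `retrograde` (zero when
#'   a direction has no runs).
#' @export
flux <- function(runs, axon_length_um, duration_min) {
  check_positive(axon_length_um, "axon_length_um")
  check_positive(duration_min, "duration_min")
  vapply(DIRECTIONS, function(d) {
    sum(runs$displacement_um[runs$direction == d]) /
      (axon_length_um * duration_min)
  }, numeric(1))
}

#' Per-direction run speed and run length statistics
#'
#' Run speed is displacement over time in motion (same-position frames
#' excluded). Directions with no runs are reported as `NA` (a mean of an
#' empty set is undefined), not zero.
#'
#' @param runs data.frame of directed runs.
#' @return data.frame with one row per direction: `n`, `mean_speed`,
#'   `sd_speed`, `mean_run_length`, `sd_run_length`, `mean_duration`.
#' @export
velocity_stats <- function(runs) {
  out <- lapply(DIRECTIONS, function(d) {
    r <- runs[runs$direction == d, , drop = FALSE]
    if (nrow(r) == 0)
      return(data.frame(direction = d, n = 0L, mean_speed = NA_real_,
                        sd_speed = NA_real_, mean_run_length = NA_real_,
                        sd_run_length = NA_real_, mean_duration = NA_real_))
    data.frame(direction = d, n = nrow(r),
               mean_speed = mean(r$mean_speed_um_s),
               sd_speed = stats::sd(r$mean_speed_um_s),
               mean_run_length = mean(r$displacement_um),
               sd_run_length = stats::sd(r$displacement_um),
               mean_duration = mean(r$duration_s))
  })
  do.call(rbind, out)
}

#' Cargo density along the axon
#'
#' All movement events (directed runs) plus stationary objects, divided by the
#' physical length of the kymograph.
#'
#' @param n_runs number of directed runs.
#' @param n_stationary number of stationary objects.
#' @param length_um kymograph physical length, um (> 0).
#' @return objects per um.
#' @export
density_per_um <- function(n_runs, n_stationary, length_um) {
  check_positive(length_um, "length_um")
  (n_runs + n_stationary) / length_um
}

#' Percentage of stationary particles
#'
#' @param classifications character vector of `"stationary"` / `"motile"`
#'   (NA = unclassified, excluded).
#' @return percentage in [0, 100].
#' @export
percent_stationary <- function(classifications) {
  cl <- classifications[!is.na(classifications)]
  if (length(cl) == 0) stop("no classified tracks", call. = FALSE)
  100 * sum(cl == "stationary") / length(cl)
}

#' Assemble the per-movie transport summary
#'
#' @param tracks list of track data.frames (`frame`, `position_um`).
#' @param runs pooled directed-run data.frame (from [segment_track()]).
#' @param pauses pooled pause data.frame.
#' @param axon_length imaged axon length, um.
#' @param duration_s movie duration, seconds.
#' @param frame_interval seconds per frame.
#' @param rules a [run_rule_config()] (stationary classification).
#' @return object of class `transport_summary`: a one-row data.frame with
#'   per-direction flux, mean velocity, mean run length, mean pause duration,
#'   event counts, plus percent stationary, density (objects/um),
#'   directionality (fraction of directed runs that are anterograde), axon
#'   length and duration.
#' @export
summarize_transport <- function(tracks, runs, pauses, axon_length, duration_s,
                                frame_interval, rules = run_rule_config()) {
  check_positive(axon_length, "axon_length")
  check_positive(duration_s, "duration_s")
  duration_min <- duration_s / 60
  fl <- flux(runs, axon_length, duration_min)
  vs <- velocity_stats(runs)
  cls <- vapply(tracks, classify_stationary, character(1), rules = rules,
                movie_duration_s = duration_s, frame_interval = frame_interval,
                quiet = TRUE)
  if (anyNA(cls))
    message(sum(is.na(cls)), " of ", length(cls),
            " tracks span less than half the movie; excluded from ",
            "stationary classification")
  n_stat <- sum(cls == "stationary", na.rm = TRUE)
  pct_stat <- if (all(is.na(cls))) NA_real_ else percent_stationary(cls)
  n_runs <- nrow(runs)
  # pause duration is a property of actively transported cargo: count only
  # pauses on tracks that produced at least one directed run, so stationary
  # particles (one movie-long stall) do not swamp the statistic
  if (nrow(pauses) && "track_id" %in% names(pauses) && "track_id" %in% names(runs))
    pauses <- pauses[pauses$track_id %in% runs$track_id, , drop = FALSE]
  ant <- vs[vs$direction == "anterograde", ]
  ret <- vs[vs$direction == "retrograde", ]
  out <- data.frame(
    flux_antero = fl[["anterograde"]], flux_retro = fl[["retrograde"]],
    velocity_antero = ant$mean_speed, velocity_retro = ret$mean_speed,
    run_length_antero = ant$mean_run_length, run_length_retro = ret$mean_run_length,
    pause_duration = if (nrow(pauses)) mean(pauses$duration_s) else NA_real_,
    n_events_antero = ant$n, n_events_retro = ret$n,
    directionality = if (n_runs > 0) ant$n / n_runs else NA_real_,
    percent_stationary = pct_stat,
    density = density_per_um(n_runs, n_stat, axon_length),
    n_stationary = n_stat,
    n_tracks = length(tracks),
    axon_length_um = axon_length,
    duration_min = duration_min
  )
  class(out) <- c("transport_summary", class(out))
  out
}

#' Aggregate per-movie summaries across movies
#'
#' Movies (axons) are the experimental unit; parameters are averaged across
#' movies and reported as mean +/- SEM.
#'
#' @param summaries list of `transport_summary` rows, or a data.frame of
#'   stacked summaries.
#' @return data.frame with one row per parameter: `parameter`, `mean`, `sem`,
#'   `n` (movies with a defined value).
#' @export
aggregate_summaries <- function(summaries) {
  df <- if (is.data.frame(summaries)) summaries else
    do.call(rbind, lapply(summaries, as.data.frame))
  params <- c("flux_antero", "flux_retro", "velocity_antero", "velocity_retro",
              "run_length_antero", "run_length_retro", "pause_duration",
              "directionality", "percent_stationary", "density")
  out <- lapply(params, function(p) {
    v <- df[[p]]
    v <- v[!is.na(v)]
    data.frame(parameter = p, mean = mean(v), sem = se_mean(v), n = length(v))
  })
  do.call(rbind, out)
}

#' Brute-force flux oracle
#'
#' Accumulates per-frame displacement over the frames belonging to each
#' directed run and divides by `l * t`. Reference route used to validate the
#' closed-form [flux()] on synthetic movies; not meant for routine analysis.
#'
#' @param tracks list of track data.frames.
#' @param runs pooled directed-run data.frame with a `track_id` column.
#' @param axon_length_um,duration_min normalization as in [flux()].
#' @return named numeric flux per direction.
#' @export
flux_brute_force <- function(tracks, runs, axon_length_um, duration_min) {
  acc <- c(anterograde = 0, retrograde = 0)
  for (i in seq_len(nrow(runs))) {
    tr <- tracks[[runs$track_id[i]]]
    sel <- tr$frame >= runs$start_frame[i] & tr$frame <= runs$end_frame[i]
    x <- tr$position_um[sel]
    step_sum <- 0
    for (k in seq_len(length(x) - 1L)) step_sum <- step_sum + (x[k + 1L] - x[k])
    acc[[runs$direction[i]]] <- acc[[runs$direction[i]]] + abs(step_sum)
  }
  acc / (axon_length_um * duration_min)
}
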