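# Stochastic simulator of bidirectional cargo transport along an axon,
# two-channel puncta fields, and field-intensity images. Every generator
# returns the ground truth used to render the image, so each analysis stage
# downstream can be validated against known answers.

ACQUISITION_REGIMES <- list(
  lamp1     = list(frame_interval = 0.75, duration_s = 120),
  lysobrite = list(frame_interval = 1.00, duration_s = 90),
  mito      = list(frame_interval = 2.00, duration_s = 180)
)

#' Configuration for the axonal transport simulator
#'
#' Defaults describe a typical lysosome-transport recording: a straight axon
#' segment imaged at 630x (0.160508 um/pixel) at one of three acquisition
#' regimes, with bidirectional two-state (run/pause) cargo motion, a
#' stationary sub-population undergoing confined diffusion, and rendering as
#' diffraction-limited Gaussian spots over Poisson background noise.
#'
#' @param axon_length axon segment length imaged, um.
#' @param pixel_size um per pixel (default: the 630x calibration,
#'   0.160508 um/pixel).
#' @param frame_interval seconds between frames. The three bundled regimes
#'   (see `regime`) are 0.75 s x 120 s, 1 s x 90 s and 2 s x 180 s.
#' @param n_frames number of frames.
#' @param regime optional name (`"lamp1"`, `"lysobrite"`, `"mito"`) setting
#'   `frame_interval` and `n_frames` to one of the three acquisition regimes;
#'   explicit arguments override it.
#' @param n_particles particles present at any time (density is kept constant
#'   by respawning absorbed particles at the opposite axon end).
#' @param stationary_fraction fraction of particles that are stationary
#'   (planted exactly as `round(stationary_fraction * n_particles)`).
#' @param run_speed_anterograde,run_speed_retrograde mean run speed, um/s
#'   (per-run speeds are truncated-normal with `run_speed_sd`).
#' @param run_speed_sd SD of per-run speed, um/s.
#' @param run_length_mean mean of the exponential run length, um.
#' @param pause_rate hazard (1/s) of a run being interrupted by a pause.
#' @param pause_duration_mean mean of the exponential pause duration, s.
#' @param reversal_prob probability that a run ending by run-length exhaustion
#'   reverses direction instead of pausing.
#' @param diffusion_coeff diffusion coefficient D (um^2/s) for stationary and
#'   paused particles; default 0.01 um^2/s.
#' @param psf_sigma Gaussian point-spread sigma, pixels.
#' @param snr peak spot amplitude over background noise SD; `Inf` renders
#'   noise-free images.
#' @param background mean background level, counts.
#' @param img_height rendered image height, pixels (axon runs horizontally
#'   through the middle row).
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return a list of class `transport_sim_config`.
#' @export
transport_sim_config <- function(axon_length = 80,
                                 pixel_size = 0.160508,
                                 frame_interval = NULL,
                                 n_frames = NULL,
                                 regime = "lamp1",
                                 n_particles = 12,
                                 stationary_fraction = 0.5,
                                 run_speed_anterograde = 1.0,
                                 run_speed_retrograde = 1.2,
                                 run_speed_sd = 0.2,
                                 run_length_mean = 8,
                                 pause_rate = 0.02,
                                 pause_duration_mean = 3,
                                 reversal_prob = 0.3,
                                 diffusion_coeff = 0.01,
                                 psf_sigma = 1.3,
                                 snr = 10,
                                 background = 20,
                                 img_height = 15,
                                 seed = NULL) {
  if (!is.null(regime)) {
    reg <- ACQUISITION_REGIMES[[match.arg(regime, names(ACQUISITION_REGIMES))]]
    if (is.null(frame_interval)) frame_interval <- reg$frame_interval
    if (is.null(n_frames)) n_frames <- round(reg$duration_s / frame_interval)
  }
  check_positive(axon_length, "axon_length")
  check_positive(pixel_size, "pixel_size")
  check_positive(frame_interval, "frame_interval")
  n_frames <- check_count(n_frames, "n_frames", min = 2L)
  n_particles <- check_count(n_particles, "n_particles", min = 0L)
  check_prob(stationary_fraction, "stationary_fraction")
  check_positive(run_speed_anterograde, "run_speed_anterograde")
  check_positive(run_speed_retrograde, "run_speed_retrograde")
  check_nonneg(run_speed_sd, "run_speed_sd")
  check_positive(run_length_mean, "run_length_mean")
  check_nonneg(pause_rate, "pause_rate")
  check_positive(pause_duration_mean, "pause_duration_mean")
  check_prob(reversal_prob, "reversal_prob")
  check_nonneg(diffusion_coeff, "diffusion_coeff")
  check_positive(psf_sigma, "psf_sigma")
  check_positive(snr, "snr")
  check_positive(background, "background")
  img_height <- check_count(img_height, "img_height", min = 3L)
  structure(list(
    axon_length = axon_length, pixel_size = pixel_size,
    frame_interval = frame_interval, n_frames = n_frames,
    n_particles = n_particles, stationary_fraction = stationary_fraction,
    run_speed_anterograde = run_speed_anterograde,
    run_speed_retrograde = run_speed_retrograde,
    run_speed_sd = run_speed_sd, run_length_mean = run_length_mean,
    pause_rate = pause_rate, pause_duration_mean = pause_duration_mean,
    reversal_prob = reversal_prob, diffusion_coeff = diffusion_coeff,
    psf_sigma = psf_sigma, snr = snr, background = background,
    img_height = img_height, seed = seed
  ), class = "transport_sim_config")
}

# One motile particle's frame-sampled trajectory, starting at frame `frame0`
# and position `x0`. Returns a data.frame(frame, position_um, state) that ends
# either at the final frame or at the step where the particle leaves [0, L]
# (absorption). Direction convention: +1 = anterograde (away from soma,
# increasing position).
simulate_motile_particle <- function(cfg, frame0, x0, dir0 = NULL) {
  dt <- cfg$frame_interval
  L <- cfg$axon_length
  n <- cfg$n_frames
  p_pause_step <- 1 - exp(-cfg$pause_rate * dt)

  new_run <- function(dir) {
    speed_mean <- if (dir > 0) cfg$run_speed_anterograde else cfg$run_speed_retrograde
    list(dir = dir,
         v = rtnorm(1, speed_mean, cfg$run_speed_sd, lower = 1e-3),
         remaining = stats::rexp(1, 1 / cfg$run_length_mean))
  }
  dir <- if (is.null(dir0)) sample(c(-1, 1), 1) else dir0
  run <- new_run(dir)
  pause_left <- 0L

  n_steps <- n - frame0
  pos <- numeric(n_steps + 1L); state <- character(n_steps + 1L)
  pos[1L] <- x0
  state[1L] <- if (run$dir > 0) "run_antero" else "run_retro"
  x <- x0
  absorbed_at <- 0L
  for (k in seq_len(n_steps)) {
    if (pause_left > 0L) {
      # paused: confined diffusion only
      x <- x + stats::rnorm(1, 0, sqrt(2 * cfg$diffusion_coeff * dt))
      x <- reflect_interval(x, L)
      pause_left <- pause_left - 1L
      if (pause_left == 0L) {
        run <- new_run(run$dir)  # resume same direction after a pause
      }
      pos[k + 1L] <- x; state[k + 1L] <- "pause"
      next
    }
    step <- run$dir * run$v * dt
    if (run$remaining < run$v * dt) {
      # run exhausted this frame: end the run at this frame boundary
      x_new <- x + run$dir * run$remaining
      ended_by_length <- TRUE
    } else {
      x_new <- x + step
      run$remaining <- run$remaining - run$v * dt
      ended_by_length <- FALSE
    }
    if (x_new < 0 || x_new > L) { absorbed_at <- k; break }
    x <- x_new
    pos[k + 1L] <- x
    state[k + 1L] <- if (run$dir > 0) "run_antero" else "run_retro"
    if (ended_by_length) {
      if (stats::runif(1) < cfg$reversal_prob) {
        run <- new_run(-run$dir)
      } else {
        pause_left <- max(1L, ceiling(stats::rexp(1, 1 / cfg$pause_duration_mean) / dt))
      }
    } else if (stats::runif(1) < p_pause_step) {
      pause_left <- max(1L, ceiling(stats::rexp(1, 1 / cfg$pause_duration_mean) / dt))
    }
  }
  keep <- if (absorbed_at > 0L) seq_len(absorbed_at) else seq_len(n_steps + 1L)
  data.frame(frame = frame0 - 1L + keep, position_um = pos[keep],
             state = state[keep], stringsAsFactors = FALSE)
}

reflect_interval <- function(x, L) {
  # reflecting boundaries for diffusing particles
  while (x < 0 || x > L) {
    if (x < 0) x <- -x
    if (x > L) x <- 2 * L - x
  }
  x
}

#' Simulate an axonal transport movie with ground truth
#'
#' Generates bidirectional two-state (run/pause) cargo motion along a straight
#' horizontal axon, plus a stationary diffusing sub-population, and renders
#' each frame as Gaussian spots over Poisson background noise. Motile
#' particles reaching an axon end are absorbed and a fresh particle is spawned
#' at the opposite end (as a new particle id), keeping density constant.
#'
#' @param config a [transport_sim_config()].
#' @param render if `FALSE`, skip image rendering and return only the ground
#'   truth (much faster; used for large statistical batteries).
#' @return a list of class `transport_sim` with elements `stack` (a
#'   `movie_stack`, or `NULL` when `render = FALSE`), `truth` (a data.frame
#'   with columns `particle_id`, `frame`, `position_um`, `state`, `motile`),
#'   and `config`.
#' @export
simulate_transport <- function(config, render = TRUE) {
  stopifnot(inherits(config, "transport_sim_config"))
  cfg <- config
  with_seed(cfg$seed, {
    n_stat <- round(cfg$stationary_fraction * cfg$n_particles)
    n_mot <- cfg$n_particles - n_stat
    dt <- cfg$frame_interval
    trajs <- list()
    next_id <- 1L

    # stationary particles: pure 1-D Brownian jitter with reflection
    if (n_stat > 0L) {
      x0 <- stats::runif(n_stat, 0, cfg$axon_length)
      sd_step <- sqrt(2 * cfg$diffusion_coeff * dt)
      for (i in seq_len(n_stat)) {
        steps <- stats::rnorm(cfg$n_frames - 1L, 0, sd_step)
        pos <- cumsum(c(x0[i], steps))
        pos <- vapply(pos, reflect_interval, numeric(1), L = cfg$axon_length)
        trajs[[next_id]] <- data.frame(
          particle_id = next_id, frame = seq_len(cfg$n_frames),
          position_um = pos, state = "stationary", motile = FALSE,
          stringsAsFactors = FALSE)
        next_id <- next_id + 1L
      }
    }

    # motile particles: respawn chains keep n_mot active at all times
    for (i in seq_len(n_mot)) {
      frame0 <- 1L
      x0 <- stats::runif(1, 0, cfg$axon_length)
      dir0 <- NULL
      while (frame0 <= cfg$n_frames) {
        tr <- simulate_motile_particle(cfg, frame0, x0, dir0)
        tr$particle_id <- next_id
        tr$motile <- TRUE
        trajs[[next_id]] <- tr[, c("particle_id", "frame", "position_um",
                                   "state", "motile")]
        next_id <- next_id + 1L
        last <- tr$frame[nrow(tr)]
        if (last >= cfg$n_frames) break
        # absorbed: respawn at the opposite end, heading inward
        frame0 <- last + 1L
        exited_high <- tr$position_um[nrow(tr)] > cfg$axon_length / 2
        x0 <- if (exited_high) 0 else cfg$axon_length
        dir0 <- if (exited_high) 1 else -1
      }
    }

    truth <- do.call(rbind, trajs)
    rownames(truth) <- NULL
    stack <- if (render) render_stack(truth, cfg) else NULL
    structure(list(stack = stack, truth = truth, config = cfg),
              class = "transport_sim")
  })
}

# Render ground-truth trajectories as Gaussian spots over Poisson background.
render_stack <- function(truth, cfg) {
  nx <- ceiling(cfg$axon_length / cfg$pixel_size)
  ny <- cfg$img_height
  y0 <- (ny + 1) / 2
  # snr = Inf means "no shot noise": render at a fixed bright amplitude
  amp <- (if (is.finite(cfg$snr)) cfg$snr else 20) * sqrt(cfg$background)
  halfw <- ceiling(4 * cfg$psf_sigma)
  dat <- array(0, dim = c(ny, nx, cfg$n_frames))
  rows <- seq_len(ny)
  gy <- exp(-(rows - y0)^2 / (2 * cfg$psf_sigma^2))
  by_frame <- split(truth$position_um, truth$frame)
  for (f in seq_len(cfg$n_frames)) {
    img <- matrix(cfg$background, ny, nx)
    for (x_um in by_frame[[as.character(f)]]) {
      xc <- x_um / cfg$pixel_size + 1  # column coordinate, 1-based
      c0 <- max(1L, floor(xc - halfw)); c1 <- min(nx, ceiling(xc + halfw))
      if (c0 > c1) next
      cols <- c0:c1
      gx <- exp(-(cols - xc)^2 / (2 * cfg$psf_sigma^2))
      img[, cols] <- img[, cols] + amp * (gy %o% gx)
    }
    if (is.finite(cfg$snr))
      img <- matrix(stats::rpois(length(img), img), ny, nx)
    dat[, , f] <- img
  }
  movie_stack(dat, pixel_size = cfg$pixel_size,
              frame_interval = cfg$frame_interval)
}

#' Ground-truth transport summary for a simulated movie
#'
#' Segments each ground-truth trajectory with the reference (brute-force)
#' segmenter and assembles the per-movie transport summary. This is the
#' "known answer" against which the image-based pipeline is validated.
#'
#' @param sim result of [simulate_transport()].
#' @param rules a [run_rule_config()].
#' @param brute_force use the exhaustive stall-window enumerator instead of
#'   the (equivalent, much faster) linear scan.
#' @return a `transport_summary` (see [summarize_transport()]).
#' @export
ground_truth_summary <- function(sim, rules = run_rule_config(),
                                 brute_force = FALSE) {
  stopifnot(inherits(sim, "transport_sim"))
  cfg <- sim$config
  tracks <- split(sim$truth[, c("frame", "position_um")], sim$truth$particle_id)
  seg <- segment_tracks(tracks, rules, cfg$frame_interval,
                        brute_force = brute_force)
  movie_s <- cfg$n_frames * cfg$frame_interval
  summarize_transport(tracks, seg$runs, seg$pauses,
                      axon_length = cfg$axon_length,
                      duration_s = movie_s,
                      frame_interval = cfg$frame_interval,
                      rules = rules)
}

#' Simulate a two-channel puncta field with planted colocalization
#'
#' Lays out `n_cells` square cell ROIs on a grid, places `n_lamp1_per_cell`
#' channel-1 (LAMP1) spots per cell with guaranteed spacing, and plants
#' channel-2 (marker) spots so that exactly `round(coloc_fraction * n)` per
#' cell fall within `max_offset` of a channel-1 spot; the remaining channel-2
#' spots are placed at least `3 * max_offset` from every channel-1 spot.
#'
#' @param n_cells number of cell ROIs.
#' @param n_lamp1_per_cell channel-1 spots per cell.
#' @param coloc_fraction planted fraction of colocalized channel-1 spots.
#' @param max_offset maximum center distance (pixels) for a planted pair.
#' @param cell_size cell ROI side, pixels.
#' @param psf_sigma spot Gaussian sigma, pixels.
#' @param snr peak amplitude over background noise SD; `Inf` = noise-free.
#' @param background mean background, counts.
#' @param seed integer seed or `NULL`.
#' @param max_tries placement attempts before declaring overcrowding.
#' @return list with `ch1`, `ch2` (matrices), `rois` (list of polygon
#'   data.frames), and `truth` (data.frame of planted spots with
#'   `cell`, `channel`, `x`, `y`, `colocalized`).
#' @export
simulate_puncta_field <- function(n_cells = 4, n_lamp1_per_cell = 10,
                                  coloc_fraction = 0.4, max_offset = 2,
                                  cell_size = 96, psf_sigma = 1.5,
                                  snr = 10, background = 20,
                                  seed = NULL, max_tries = 2000) {
  check_prob(coloc_fraction, "coloc_fraction")
  check_positive(max_offset, "max_offset")
  n_cells <- check_count(n_cells, "n_cells", 1L)
  n_per <- check_count(n_lamp1_per_cell, "n_lamp1_per_cell", 0L)

  ncol_cells <- ceiling(sqrt(n_cells))
  nrow_cells <- ceiling(n_cells / ncol_cells)
  width <- ncol_cells * cell_size
  height <- nrow_cells * cell_size
  margin <- max(6 * max_offset, 4 * psf_sigma, 6)
  min_spacing <- max(8 * max_offset, 6 * psf_sigma)

  with_seed(seed, {
    spots <- list()
    rois <- list()
    for (ci in seq_len(n_cells)) {
      gx <- (ci - 1L) %% ncol_cells
      gy <- (ci - 1L) %/% ncol_cells
      x_lo <- gx * cell_size; y_lo <- gy * cell_size
      rois[[ci]] <- data.frame(
        x = c(x_lo + 1, x_lo + cell_size - 1, x_lo + cell_size - 1, x_lo + 1),
        y = c(y_lo + 1, y_lo + 1, y_lo + cell_size - 1, y_lo + cell_size - 1))
      # channel-1 spots with minimum spacing, inside the ROI with a margin
      pts <- matrix(numeric(0), ncol = 2)
      tries <- 0L
      while (nrow(pts) < n_per) {
        cand <- c(stats::runif(1, x_lo + margin, x_lo + cell_size - margin),
                  stats::runif(1, y_lo + margin, y_lo + cell_size - margin))
        ok <- nrow(pts) == 0 ||
          min(sqrt((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2)) >= min_spacing
        if (ok) pts <- rbind(pts, cand)
        tries <- tries + 1L
        if (tries > max_tries)
          stop("overcrowded puncta field: cannot satisfy spot spacing",
               call. = FALSE)
      }
      n_coloc <- round(coloc_fraction * n_per)
      coloc_idx <- if (n_per > 0) seq_len(n_per) <= n_coloc else logical(0)
      # channel-2: colocalized partners within max_offset
      ch2 <- matrix(numeric(0), ncol = 2)
      for (i in seq_len(n_per)) {
        if (coloc_idx[i]) {
          theta <- stats::runif(1, 0, 2 * pi)
          r <- stats::runif(1, 0, 0.8 * max_offset)
          ch2 <- rbind(ch2, pts[i, ] + r * c(cos(theta), sin(theta)))
        }
      }
      # non-colocalized channel-2 spots: >= 3 * max_offset from every ch1 spot
      n_far <- n_per - sum(coloc_idx)
      tries <- 0L
      while (nrow(ch2) < n_per) {
        cand <- c(stats::runif(1, x_lo + margin, x_lo + cell_size - margin),
                  stats::runif(1, y_lo + margin, y_lo + cell_size - margin))
        d1 <- sqrt((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2)
        d2 <- if (nrow(ch2)) sqrt((ch2[, 1] - cand[1])^2 + (ch2[, 2] - cand[2])^2) else Inf
        if (min(d1) >= 3 * max_offset && min(d2) >= min_spacing / 2)
          ch2 <- rbind(ch2, cand)
        tries <- tries + 1L
        if (tries > max_tries)
          stop("overcrowded puncta field: cannot place background spots",
               call. = FALSE)
      }
      if (n_per > 0) {
        spots[[length(spots) + 1L]] <- data.frame(
          cell = ci, channel = 1L, x = pts[, 1], y = pts[, 2],
          colocalized = coloc_idx)
        spots[[length(spots) + 1L]] <- data.frame(
          cell = ci, channel = 2L, x = ch2[, 1], y = ch2[, 2],
          colocalized = c(rep(TRUE, sum(coloc_idx)), rep(FALSE, n_far)))
      }
    }
    truth <- if (length(spots)) do.call(rbind, spots) else
      data.frame(cell = integer(), channel = integer(), x = numeric(),
                 y = numeric(), colocalized = logical())
    rownames(truth) <- NULL

    render_channel <- function(ch) {
      img <- matrix(background, height, width)
      amp <- (if (is.finite(snr)) snr else 20) * sqrt(background)
      sub <- truth[truth$channel == ch, , drop = FALSE]
      for (i in seq_len(nrow(sub))) {
        img <- add_gaussian_spot(img, sub$x[i], sub$y[i], amp, psf_sigma)
      }
      if (is.finite(snr)) img <- matrix(stats::rpois(length(img), img),
                                        height, width)
      img
    }
    list(ch1 = render_channel(1L), ch2 = render_channel(2L),
         rois = rois, truth = truth)
  })
}

# add an isotropic Gaussian spot at (x, y) [pixel coords, 1-based columns/rows]
add_gaussian_spot <- function(img, x, y, amp, sigma) {
  halfw <- ceiling(4 * sigma)
  c0 <- max(1L, floor(x - halfw)); c1 <- min(ncol(img), ceiling(x + halfw))
  r0 <- max(1L, floor(y - halfw)); r1 <- min(nrow(img), ceiling(y + halfw))
  if (c0 > c1 || r0 > r1) return(img)
  cols <- c0:c1; rows <- r0:r1
  g <- exp(-(rows - y)^2 / (2 * sigma^2)) %o% exp(-(cols - x)^2 / (2 * sigma^2))
  img[rows, cols] <- img[rows, cols] + amp * g
  img
}

#' Simulate a field-of-view intensity image with planted objects
#'
#' Plants `n_objects` constant-intensity square objects on a constant
#' background, for validating threshold-based field statistics against an
#' exact pixelwise oracle.
#'
#' @param background_level constant background intensity (> 0).
#' @param n_objects number of square objects to plant.
#' @param object_intensity object pixel intensity; must exceed
#'   `3 * background_level` for the objects to count as planted-positive.
#' @param object_size object side length, pixels.
#' @param dim image dimensions `c(rows, cols)`.
#' @param noise_sd optional Gaussian noise SD (default 0: exact oracle holds).
#' @param seed integer seed or `NULL`.
#' @return list with `image`, `mask` (ground-truth object mask), `area`
#'   (planted above-threshold pixel count) and `integrated` (planted summed
#'   intensity over the mask).
#' @export
simulate_intensity_field <- function(background_level = 100, n_objects = 5,
                                     object_intensity = 1000, object_size = 10,
                                     dim = c(256, 256), noise_sd = 0,
                                     seed = NULL) {
  check_positive(background_level, "background_level")
  n_objects <- check_count(n_objects, "n_objects", 0L)
  check_positive(object_intensity, "object_intensity")
  if (n_objects > 0 && object_intensity <= 3 * background_level)
    stop("object_intensity must exceed 3x background_level", call. = FALSE)
  object_size <- check_count(object_size, "object_size", 1L)
  with_seed(seed, {
    img <- matrix(background_level, dim[1], dim[2])
    mask <- matrix(FALSE, dim[1], dim[2])
    placed <- 0L; tries <- 0L
    while (placed < n_objects) {
      r0 <- sample.int(dim[1] - object_size + 1L, 1)
      c0 <- sample.int(dim[2] - object_size + 1L, 1)
      rr <- r0:(r0 + object_size - 1L); cc <- c0:(c0 + object_size - 1L)
      if (!any(mask[rr, cc])) {
        img[rr, cc] <- object_intensity
        mask[rr, cc] <- TRUE
        placed <- placed + 1L
      }
      tries <- tries + 1L
      if (tries > 100 * max(n_objects, 1L))
        stop("cannot place objects without overlap", call. = FALSE)
    }
    if (noise_sd > 0)
      img <- img + matrix(stats::rnorm(length(img), 0, noise_sd),
                          dim[1], dim[2])
    list(image = img, mask = mask, area = sum(mask),
         integrated = sum(img[mask]))
  })
}
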