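# Track extraction from kymographs and segmentation of tracks into directed
# runs, pauses, and motile/stationary classifications.
#
# Rule set (all thresholds configurable in run_rule_config):
#   * a run TERMINATES when the particle stays at the same position (per-frame
#     movement <= same_position_tol) for at least pause_min_frames consecutive
#     frames, or when it reverses direction;
#   * a candidate run is DIRECTED if its displacement >= run_threshold (5 um),
#     a cutoff chosen to dominate the diffusion bound sqrt(2 D t) = 1 um at
#     D = 0.01 um^2/s, t = 50 s;
#   * a particle is STATIONARY if its whole-movie excursion is < 5 um.

#' Segmentation rule configuration
#'
#' @param run_threshold minimum displacement (um) for a directed run
#'   (default 5).
#' @param diffusion_coeff diffusion coefficient D, um^2/s (default 0.01).
#' @param diffusion_horizon time horizon t for the diffusion bound, s
#'   (default 50).
#' @param pause_min_frames consecutive same-position frames that terminate a
#'   run (default 4).
#' @param same_position_tol per-frame movement (um) counted as "same
#'   position"; default 2 pixels at the 630x calibration (0.321016 um),
#'   i.e. within localization jitter.
#' @param stationary_threshold whole-movie excursion (um) below which a
#'   particle is stationary (default 5).
#' @return list of class `run_rule_config`.
#' @export
run_rule_config <- function(run_threshold = 5,
                            diffusion_coeff = 0.01,
                            diffusion_horizon = 50,
                            pause_min_frames = 4,
                            same_position_tol = 2 * PIXEL_SIZE_630X,
                            stationary_threshold = 5) {
  check_positive(run_threshold, "run_threshold")
  check_nonneg(diffusion_coeff, "diffusion_coeff")
  check_nonneg(diffusion_horizon, "diffusion_horizon")
  pause_min_frames <- check_count(pause_min_frames, "pause_min_frames", 2L)
  check_nonneg(same_position_tol, "same_position_tol")
  check_positive(stationary_threshold, "stationary_threshold")
  bound <- diffusion_bound(diffusion_coeff, diffusion_horizon)
  if (run_threshold < bound)
    stop(sprintf(paste("run_threshold (%.3g um) must dominate the diffusion",
                       "bound sqrt(2 D t) = %.3g um"),
                 run_threshold, bound), call. = FALSE)
  structure(list(run_threshold = run_threshold,
                 diffusion_coeff = diffusion_coeff,
                 diffusion_horizon = diffusion_horizon,
                 pause_min_frames = pause_min_frames,
                 same_position_tol = same_position_tol,
                 stationary_threshold = stationary_threshold),
            class = "run_rule_config")
}

#' Root-mean-squared displacement bound for 1-D diffusion
#'
#' `sqrt(2 * D * t)`: the expected RMS excursion of a freely diffusing
#' particle, used to justify the directed-run distance cutoff (at the default
#' D = 0.01 um^2/s and t = 50 s the bound is 1 um, well below the 5 um run
#' threshold).
#'
#' @param D diffusion coefficient, um^2/s (>= 0).
#' @param t time horizon, s (>= 0).
#' @return RMS displacement in um.
#' @export
diffusion_bound <- function(D, t) {
  if (any(D < 0) || any(t < 0))
    stop("D and t must be non-negative", call. = FALSE)
  sqrt(2 * D * t)
}

#' Extract particle tracks from a kymograph
#'
#' Per-row local-maxima detection on matched-filtered rows above a robust
#' intensity threshold, followed by frame-to-frame linking against a
#' constant-velocity motion prediction (greedy, ascending prediction error,
#' with a per-frame reach bound). Tracks losing their peak to a merge coast on
#' their own extrapolation; long-stationary tracks claim their peak with
#' priority; severed fragments are re-joined when each extrapolates onto the
#' other's endpoint. Dense crossings can still swap identities - a documented
#' limitation of any local linker - so accuracy claims are validated on the
#' simulator's ground truth.
#'
#' @param kymo a `kymograph`.
#' @param intensity_k detection threshold in robust SDs (MAD) above the row
#'   median, applied after matched filtering.
#' @param max_speed maximum credible particle speed (um/s); sets the linking
#'   radius to `max_speed * frame_interval`.
#' @param max_gap frames a track may go undetected before being closed.
#' @param min_frames minimum track length in frames.
#' @param min_separation minimum distance between detections in one frame,
#'   pixels (peaks closer than this are merged to the brighter one).
#' @param smooth_sigma Gaussian matched-filter sigma, pixels (should match
#'   the point-spread sigma; 0 disables smoothing).
#' @return list of tracks; each is a data.frame with `frame` and
#'   `position_um`.
#' @export
extract_tracks <- function(kymo, intensity_k = 5, max_speed = 2.5,
                           max_gap = 3, min_frames = 10, min_separation = 3,
                           smooth_sigma = 1.3) {
  stopifnot(inherits(kymo, "kymograph"))
  k <- kymo$data
  if (length(k) == 0) return(list())
  dt <- kymo$frame_interval
  px <- kymo$pixel_size
  max_jump_px <- max_speed * dt / px * (max_gap + 1)

  kernel <- if (smooth_sigma > 0) {
    half <- ceiling(3 * smooth_sigma)
    kk <- exp(-(-half:half)^2 / (2 * smooth_sigma^2))
    kk / sum(kk)
  } else NULL

  detect_row <- function(v) {
    if (!is.null(kernel)) {
      # matched filter: convolve with the PSF profile (reflected edges)
      half <- (length(kernel) - 1L) %/% 2L
      vp <- c(rev(v[seq_len(half)]), v, rev(v[length(v) - seq_len(half) + 1L]))
      v <- as.numeric(stats::filter(vp, kernel, sides = 2))[(half + 1L):(half + length(v))]
    }
    thr <- stats::median(v) + intensity_k * stats::mad(v)
    n <- length(v)
    if (n < 3) return(integer(0))
    peaks <- which(v > thr & v >= c(-Inf, v[-n]) & v >= c(v[-1], -Inf))
    if (length(peaks) > 1) {
      # merge peaks closer than min_separation, keeping the brighter one
      keep <- rep(TRUE, length(peaks))
      ord <- order(v[peaks], decreasing = TRUE)
      for (i in ord) {
        if (!keep[i]) next
        too_close <- abs(peaks - peaks[i]) < min_separation & seq_along(peaks) != i
        keep[too_close & v[peaks] <= v[peaks[i]]] <- FALSE
      }
      peaks <- peaks[keep]
    }
    peaks
  }

  # constant-velocity prediction of a track's position `gap` frames ahead,
  # from its last few points; resolves most identity conflicts at crossings.
  # Tracks below 0.3 um/s - stationary/paused jitter, well under any real
  # run speed - are predicted in place so they never drift while coasting;
  # anything faster keeps its velocity, which is what disambiguates crossings.
  slow_px <- 0.3 * dt / px
  predict_col <- function(tr, gap) {
    n <- length(tr$cols)
    k3 <- min(5L, n - 1L)
    vel <- if (k3 >= 1L)
      (tr$cols[n] - tr$cols[n - k3]) / (tr$frames[n] - tr$frames[n - k3])
    else 0
    if (abs(vel) < slow_px) vel <- 0
    tr$cols[n] + vel * gap
  }

  active <- list()   # each: list(frames=..., cols=..., last_frame)
  done <- list()
  for (f in seq_len(nrow(k))) {
    det <- detect_row(k[f, ])
    # close stale tracks
    if (length(active)) {
      stale <- vapply(active, function(tr) f - tr$last_frame > max_gap + 1L,
                      logical(1))
      done <- c(done, active[stale])
      active <- active[!stale]
    }
    used_det <- logical(length(det))
    if (length(det) && length(active)) {
      gaps <- vapply(active, function(tr) f - tr$last_frame, numeric(1))
      preds <- vapply(seq_along(active), function(i)
        predict_col(active[[i]], gaps[i]), numeric(1))
      lasts <- vapply(active, function(tr) tr$cols[length(tr$cols)], numeric(1))
      # cost = distance to the motion prediction; admissible if the implied
      # speed from the last seen position is credible. Slow (paused or
      # stationary) tracks additionally get a tight cap: their genuine next
      # step is at most a pause-to-run resume, so anything farther is a noise
      # peak or another particle. Fast tracks keep the full reach so direction
      # reversals (prediction overshoot ~ 2 v dt) are not severed.
      cost <- abs(outer(preds, det, "-"))
      reach <- abs(outer(lasts, det, "-"))
      vels <- vapply(seq_along(active), function(i) {
        tr <- active[[i]]; n <- length(tr$cols); k3 <- min(5L, n - 1L)
        if (k3 < 1L) return(0)
        abs(tr$cols[n] - tr$cols[n - k3]) / (tr$frames[n] - tr$frames[n - k3])
      }, numeric(1))
      slow <- vels < slow_px
      cap <- ifelse(slow, 6 * gaps + 2, max_speed * dt / px * gaps + 2)
      admissible <- reach <= max_speed * dt / px * gaps + 2 & cost <= cap
      used_tr <- logical(length(active))
      # anchored tracks - long-stationary within a tight envelope - claim
      # their own peak first and never anything farther: a particle that has
      # not moved for 20 frames does not jump, so this immunizes stationary
      # tracks against capture by (and theft from) passing cargo
      anchored <- vapply(seq_along(active), function(i) {
        tr <- active[[i]]; n <- length(tr$cols)
        if (!slow[i] || n < 20L) return(FALSE)
        w <- tr$cols[(n - 19L):n]
        # envelope adapts to the track's own localization scatter, so
        # anchoring works both on clean and on noisy data
        diff(range(w)) < 3 + 4 * stats::median(abs(diff(w)))
      }, logical(1))
      for (i in order(gaps)[anchored[order(gaps)]]) {
        dists <- abs(det - lasts[i])
        j <- which.min(replace(dists, used_det, Inf))
        if (length(j) && !used_det[j] && dists[j] <= 3) {
          used_tr[i] <- TRUE; used_det[j] <- TRUE
          active[[i]]$frames <- c(active[[i]]$frames, f)
          active[[i]]$cols <- c(active[[i]]$cols, det[j])
          active[[i]]$real <- c(active[[i]]$real, TRUE)
          active[[i]]$last_frame <- f
          active[[i]]$coasts <- 0L
        }
      }
      pairs <- which(admissible, arr.ind = TRUE)
      if (nrow(pairs)) {
        ord <- order(cost[pairs])
        for (idx in ord) {
          i <- pairs[idx, 1]; j <- pairs[idx, 2]
          if (used_tr[i] || used_det[j]) next
          used_tr[i] <- TRUE; used_det[j] <- TRUE
          active[[i]]$frames <- c(active[[i]]$frames, f)
          active[[i]]$cols <- c(active[[i]]$cols, det[j])
          active[[i]]$real <- c(active[[i]]$real, TRUE)
          active[[i]]$last_frame <- f
          active[[i]]$coasts <- 0L
        }
      }
      # merged spots: when an unmatched track's miss is explained by a nearby
      # already-claimed detection (two particles, one merged peak), the track
      # coasts along its own motion prediction instead of breaking, so
      # crossings sever neither track nor hijack the stationary one
      # fast tracks may only coast briefly (their extrapolation is the risky
      # kind); a slow track coasting holds its position, which stays truthful
      # for however long two stationary neighbors remain merged into one peak
      for (i in which(!used_tr)) {
        j <- which.min(cost[i, ])
        coasts <- if (is.null(active[[i]]$coasts)) 0L else active[[i]]$coasts
        if (length(j) && used_det[j] &&
            cost[i, j] <= min_separation + 1 &&
            (slow[i] || coasts < max_gap + 2L)) {
          active[[i]]$frames <- c(active[[i]]$frames, f)
          active[[i]]$cols <- c(active[[i]]$cols, preds[i])
          active[[i]]$real <- c(active[[i]]$real, FALSE)
          active[[i]]$last_frame <- f
          active[[i]]$coasts <- coasts + 1L
          used_tr[i] <- TRUE
        }
      }
      # leftover detections reclaim coasting tracks (a merged peak splitting
      # apart again must continue the coasting track, not spawn a duplicate)
      if (any(!used_det)) {
        for (j in which(!used_det)) {
          cand <- which(vapply(active, function(tr) {
            tr$last_frame == f && !is.null(tr$coasts) && tr$coasts > 0L
          }, logical(1)))
          if (!length(cand)) next
          dists <- vapply(cand, function(i)
            abs(active[[i]]$cols[length(active[[i]]$cols)] - det[j]),
            numeric(1))
          i <- cand[which.min(dists)]
          if (min(dists) <= min_separation + 1) {
            nl <- length(active[[i]]$cols)
            active[[i]]$cols[nl] <- det[j]
            active[[i]]$real[nl] <- TRUE
            active[[i]]$coasts <- 0L
            used_det[j] <- TRUE
          }
        }
      }
      # a detection right next to an updated track is a secondary peak of the
      # same particle: absorb it rather than spawning a duplicate track
      if (any(!used_det)) {
        cur <- vapply(active, function(tr)
          if (tr$last_frame == f) tr$cols[length(tr$cols)] else NA_real_,
          numeric(1))
        for (j in which(!used_det)) {
          if (any(abs(cur - det[j]) <= min_separation, na.rm = TRUE))
            used_det[j] <- TRUE
        }
      }
      det <- det[!used_det]
    }
    for (d in det) {
      active[[length(active) + 1L]] <- list(frames = f, cols = d,
                                            real = TRUE,
                                            last_frame = f, last_col = d)
    }
  }
  done <- c(done, active)

  # trailing coasted (predicted) positions were never confirmed by a
  # detection: trim them so fabricated extrapolation neither distorts a
  # track's excursion nor blocks the healing pass below
  done <- lapply(done, function(tr) {
    keep <- max(which(tr$real))
    list(frames = tr$frames[seq_len(keep)], cols = tr$cols[seq_len(keep)],
         last_frame = tr$frames[keep])
  })

  # healing pass: rejoin fragments severed at crossings. Two fragments are
  # the same particle when each extrapolates onto the other's endpoint.
  vel_at <- function(tr, head) {
    n <- length(tr$cols)
    k3 <- min(5L, n - 1L)
    if (k3 < 1L) return(0)
    if (head) (tr$cols[1L + k3] - tr$cols[1L]) / (tr$frames[1L + k3] - tr$frames[1L])
    else (tr$cols[n] - tr$cols[n - k3]) / (tr$frames[n] - tr$frames[n - k3])
  }
  join_tol <- min_separation + 1
  join_gap <- max(8L, max_gap + 3L)
  repeat {
    joined <- FALSE
    if (length(done) >= 2L) {
      starts <- vapply(done, function(tr) tr$frames[1], numeric(1))
      ends <- vapply(done, function(tr) tr$frames[length(tr$frames)], numeric(1))
      for (i in seq_along(done)) {
        gap_to <- starts - ends[i]
        cand <- which(gap_to > 0 & gap_to <= join_gap)
        for (j in cand) {
          g <- gap_to[j]
          a <- done[[i]]; b <- done[[j]]
          fwd <- a$cols[length(a$cols)] + vel_at(a, head = FALSE) * g
          bwd <- b$cols[1] - vel_at(b, head = TRUE) * g
          if (abs(fwd - b$cols[1]) <= join_tol &&
              abs(bwd - a$cols[length(a$cols)]) <= join_tol) {
            done[[i]] <- list(frames = c(a$frames, b$frames),
                              cols = c(a$cols, b$cols),
                              last_frame = b$frames[length(b$frames)])
            done[[j]] <- NULL
            joined <- TRUE
            break
          }
        }
        if (joined) break
      }
    }
    if (!joined) break
  }

  done <- Filter(function(tr) length(tr$frames) >= min_frames, done)
  lapply(done, function(tr) {
    # fill bridged detection gaps by linear interpolation so downstream
    # segmentation sees contiguous frames (gap steps otherwise masquerade as
    # single-frame jumps, inflating apparent speed)
    frames <- seq(tr$frames[1], tr$frames[length(tr$frames)])
    cols <- stats::approx(tr$frames, tr$cols, xout = frames)$y
    # kymograph columns are centered at half-pixel arc positions
    data.frame(frame = frames, position_um = (cols - 0.5) * px)
  })
}

# --- segmentation ----------------------------------------------------------

# Identify maximal stall windows by linear scan: runs of >= (pause_min - 1)
# consecutive steps with |step| <= tol. Returns matrix[, c(start, end)] of
# FRAME indices (inclusive).
find_stalls_scan <- function(x, tol, pause_min) {
  d <- diff(x)
  small <- abs(d) <= tol
  r <- rle(small)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- r$values & r$lengths >= (pause_min - 1L)
  cbind(start = starts[sel], end = ends[sel] + 1L)  # step i spans frames i..i+1
}

# Independent stall finder used by the brute-force oracle: enumerates every
# window [i, j], keeps those whose internal steps are all within tolerance and
# whose length >= pause_min, then reduces to maximal windows.
find_stalls_exhaustive <- function(x, tol, pause_min) {
  n <- length(x)
  wins <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (j - i + 1L < pause_min) next
      steps <- abs(diff(x[i:j]))
      if (all(steps <= tol)) wins[[length(wins) + 1L]] <- c(i, j)
    }
  }
  if (!length(wins)) return(cbind(start = integer(0), end = integer(0)))
  m <- do.call(rbind, wins)
  maximal <- vapply(seq_len(nrow(m)), function(k) {
    !any(m[, 1] <= m[k, 1] & m[, 2] >= m[k, 2] &
           (m[, 1] < m[k, 1] | m[, 2] > m[k, 2]))
  }, logical(1))
  m <- m[maximal, , drop = FALSE]
  m <- unique(m)
  colnames(m) <- c("start", "end")
  m[order(m[, 1]), , drop = FALSE]
}

# Split a frame segment [s, e] into maximal unidirectional candidate runs.
# Steps with |step| <= tol carry no direction and attach to the ongoing run.
# A sign flip closes the run at the extremal position within the ambiguous
# window between the last step of one direction and the first step of the
# other; that frame is shared by both runs. The extremum convention makes
# segmentation invariant to time reversal (up to direction relabeling).
split_reversals <- function(x, s, e, tol) {
  if (e <= s) return(list())
  steps <- s:(e - 1L)
  d <- x[steps + 1L] - x[steps]
  big <- abs(d) > tol
  sgn <- sign(d)
  idx <- steps[big]
  sg <- sgn[big]
  if (!length(idx)) return(list(c(s, e)))
  # group consecutive same-sign big steps
  grp <- cumsum(c(1L, sg[-1] != sg[-length(sg)]))
  runs <- list()
  run_start <- s
  n_grp <- max(grp)
  for (g in seq_len(n_grp)) {
    if (g < n_grp) {
      e1 <- max(idx[grp == g]) + 1L    # last frame of this group's last step
      s2 <- min(idx[grp == g + 1L])    # first frame of next group's first step
      window <- e1:s2
      b <- if (sg[grp == g][1] > 0) window[which.max(x[window])]
           else window[which.min(x[window])]
      runs[[length(runs) + 1L]] <- c(run_start, b)
      run_start <- b
    } else {
      runs[[length(runs) + 1L]] <- c(run_start, e)
    }
  }
  runs
}

segment_from_stalls <- function(track, stalls, rules, frame_interval) {
  x <- track$position_um
  frames <- track$frame
  n <- length(x)
  tol <- rules$same_position_tol
  dt <- frame_interval

  pauses <- if (nrow(stalls)) data.frame(
    start_frame = frames[stalls[, "start"]],
    end_frame = frames[stalls[, "end"]],
    duration_s = (stalls[, "end"] - stalls[, "start"]) * dt
  ) else data.frame(start_frame = integer(0), end_frame = integer(0),
                    duration_s = numeric(0))

  # complementary segments, extended inclusively to stall boundary frames
  bounds <- rbind(c(NA, 0L), stalls, c(n + 1L, NA))
  runs <- list()
  for (b in seq_len(nrow(bounds) - 1L)) {
    s <- bounds[b, 2] + 1L       # first frame after previous stall
    e <- bounds[b + 1L, 1] - 1L  # last frame before next stall
    # include the boundary frames themselves (the positions where motion
    # stopped/restarted) so displacement is measured stop-to-stop
    s_in <- max(1L, s - 1L)
    e_in <- min(n, e + 1L)
    if (e_in - s_in < 1L) next
    for (r in split_reversals(x, s_in, e_in, tol)) {
      rs <- r[1]; re <- r[2]
      disp <- abs(x[re] - x[rs])
      if (disp < rules$run_threshold) next
      moving_steps <- sum(abs(diff(x[rs:re])) > tol)
      dur <- moving_steps * dt
      if (dur <= 0) next
      runs[[length(runs) + 1L]] <- data.frame(
        direction = if (x[re] > x[rs]) "anterograde" else "retrograde",
        start_frame = frames[rs], end_frame = frames[re],
        displacement_um = disp, duration_s = dur,
        mean_speed_um_s = disp / dur)
    }
  }
  runs <- if (length(runs)) do.call(rbind, runs) else
    data.frame(direction = character(0), start_frame = integer(0),
               end_frame = integer(0), displacement_um = numeric(0),
               duration_s = numeric(0), mean_speed_um_s = numeric(0))
  rownames(runs) <- NULL
  list(runs = runs, pauses = pauses)
}

#' Segment a track into directed runs and pauses
#'
#' A run terminates where the particle remains at the same position (per-frame
#' movement within `same_position_tol`) for at least `pause_min_frames`
#' consecutive frames, or where it reverses direction. Maximal unidirectional
#' stretches between termination events whose displacement reaches
#' `run_threshold` (default 5 um) are emitted as directed runs; run duration
#' excludes internal same-position frames, so mean speed reflects time in
#' motion.
#'
#' @param track data.frame with columns `frame` (strictly increasing) and
#'   `position_um`.
#' @param rules a [run_rule_config()].
#' @param frame_interval seconds per frame.
#' @param brute_force use the exhaustive stall-window enumerator (reference
#'   implementation, O(n^2); identical output, used for validation).
#' @return list with `runs` (data.frame: `direction`, `start_frame`,
#'   `end_frame`, `displacement_um`, `duration_s`, `mean_speed_um_s`) and
#'   `pauses` (data.frame: `start_frame`, `end_frame`, `duration_s`).
#' @export
segment_track <- function(track, rules = run_rule_config(), frame_interval,
                          brute_force = FALSE) {
  stopifnot(is.data.frame(track), nrow(track) >= 2L,
            all(diff(track$frame) > 0))
  check_positive(frame_interval, "frame_interval")
  gaps <- diff(track$frame)
  if (any(gaps > rules$pause_min_frames)) {
    warning("track has frame gaps larger than pause_min_frames; splitting",
            call. = FALSE)
    cuts <- cumsum(c(0, gaps > rules$pause_min_frames))
    parts <- split(track, cuts)
    segs <- lapply(parts[vapply(parts, nrow, 1L) >= 2L], segment_track,
                   rules = rules, frame_interval = frame_interval,
                   brute_force = brute_force)
    return(list(runs = do.call(rbind, c(lapply(segs, `[[`, "runs"),
                                        make.row.names = FALSE)),
                pauses = do.call(rbind, c(lapply(segs, `[[`, "pauses"),
                                          make.row.names = FALSE))))
  }
  finder <- if (brute_force) find_stalls_exhaustive else find_stalls_scan
  stalls <- finder(track$position_um, rules$same_position_tol,
                   rules$pause_min_frames)
  segment_from_stalls(track, stalls, rules, frame_interval)
}

#' Segment a list of tracks
#'
#' Applies [segment_track()] to each track and pools the results, adding a
#' `track_id` column (index into `tracks`).
#'
#' @inheritParams segment_track
#' @param tracks list of track data.frames.
#' @return list with pooled `runs` and `pauses` data.frames.
#' @export
segment_tracks <- function(tracks, rules, frame_interval, brute_force = FALSE) {
  runs <- list(); pauses <- list()
  for (i in seq_along(tracks)) {
    if (nrow(tracks[[i]]) < 2L) next
    seg <- segment_track(tracks[[i]], rules, frame_interval,
                         brute_force = brute_force)
    if (nrow(seg$runs)) { seg$runs$track_id <- i; runs[[length(runs) + 1L]] <- seg$runs }
    if (nrow(seg$pauses)) { seg$pauses$track_id <- i; pauses[[length(pauses) + 1L]] <- seg$pauses }
  }
  empty_runs <- data.frame(direction = character(0), start_frame = integer(0),
                           end_frame = integer(0), displacement_um = numeric(0),
                           duration_s = numeric(0), mean_speed_um_s = numeric(0),
                           track_id = integer(0))
  empty_pauses <- data.frame(start_frame = integer(0), end_frame = integer(0),
                             duration_s = numeric(0), track_id = integer(0))
  list(runs = if (length(runs)) do.call(rbind, runs) else empty_runs,
       pauses = if (length(pauses)) do.call(rbind, pauses) else empty_pauses)
}

#' Classify a track as motile or stationary
#'
#' A particle is stationary if its maximum positional excursion over the whole
#' movie is below `stationary_threshold` (default: moved < 5 um over the
#' recording).
#'
#' @param track data.frame with `frame`, `position_um`.
#' @param rules a [run_rule_config()].
#' @param movie_duration_s full movie duration in seconds.
#' @param frame_interval seconds per frame.
#' @param quiet suppress the per-track exclusion message.
#' @return `"stationary"`, `"motile"`, or `NA_character_` (unclassified) if
#'   the track spans less than half the movie.
#' @export
classify_stationary <- function(track, rules = run_rule_config(),
                                movie_duration_s, frame_interval,
                                quiet = FALSE) {
  span <- (max(track$frame) - min(track$frame)) * frame_interval
  if (span < movie_duration_s / 2) {
    if (!quiet)
      message("track spans less than half the movie; excluded from ",
              "stationary classification")
    return(NA_character_)
  }
  excursion <- max(track$position_um) - min(track$position_um)
  if (excursion < rules$stationary_threshold) "stationary" else "motile"
}

#' Direction of a run relative to the soma
#'
#' On an orientation-normalized kymograph (increasing position = away from
#' soma), net movement toward larger positions is anterograde, toward the soma
#' retrograde. Provided for un-normalized coordinates via `soma_end`.
#'
#' @param start_position,end_position run endpoints, um.
#' @param soma_end `"start"` if the soma is at position 0 (normalized
#'   convention), `"end"` if at the far end (mirrored coordinates).
#' @return `"anterograde"` or `"retrograde"`.
#' @export
assign_direction <- function(start_position, end_position,
                             soma_end = c("start", "end")) {
  soma_end <- match.arg(soma_end)
  delta <- end_position - start_position
  if (delta == 0) stop("zero net displacement has no direction", call. = FALSE)
  away <- if (soma_end == "start") delta > 0 else delta < 0
  if (away) "anterograde" else "retrograde"
}
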