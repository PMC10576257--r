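# Shared fixture builders. All synthetic inputs are generated in code at test
# time; nothing is read from disk.

# straight-axon path down the middle row of a simulated stack
sim_path <- function(sim, soma_end = "start") {
  nx <- dim(sim$stack$data)[2]
  y <- (sim$config$img_height + 1) / 2
  axon_path(c(1, nx), c(y, y), soma_end = soma_end)
}

# track data.frame from a position vector at consecutive frames
make_track <- function(positions, frames = seq_along(positions)) {
  data.frame(frame = frames, position_um = positions)
}

# random two-state walk for the segmentation battery: mixes runs, stalls and
# sub-tolerance jitter, all scaled in um
random_track <- function(n_frames, dt = 1, tol = 0.3) {
  x <- numeric(n_frames)
  state <- sample(c("run", "stall"), 1)
  dir <- sample(c(-1, 1), 1)
  for (k in 2:n_frames) {
    if (runif(1) < 0.2) state <- if (state == "run") "stall" else "run"
    if (runif(1) < 0.1) dir <- -dir
    step <- if (state == "run") dir * runif(1, 0.4, 1.5)
            else runif(1, -0.8, 0.8) * tol
    x[k] <- x[k - 1] + step
  }
  make_track(x)
}

# minimal movie rendering for kymograph tests: one or more particles given as
# data.frames(frame, position_um), drawn on a straight horizontal axon
render_test_stack <- function(particles, n_frames, nx = 200, ny = 11,
                              pixel_size = 0.160508, frame_interval = 1,
                              amp = 100, bg = 10, psf_sigma = 1.3,
                              noisy = FALSE) {
  dat <- array(bg, dim = c(ny, nx, n_frames))
  y0 <- (ny + 1) / 2
  for (p in particles) {
    for (r in seq_len(nrow(p))) {
      f <- p$frame[r]
      xc <- p$position_um[r] / pixel_size + 1
      if (xc < -5 || xc > nx + 5) stop("particle outside test image")
      cols <- max(1, floor(xc - 5)):min(nx, ceiling(xc + 5))
      g <- exp(-(seq_len(ny) - y0)^2 / (2 * psf_sigma^2)) %o%
        exp(-(cols - xc)^2 / (2 * psf_sigma^2))
      dat[, cols, f] <- dat[, cols, f] + amp * g
    }
  }
  if (noisy) dat[] <- rpois(length(dat), dat)
  movie_stack(dat, pixel_size = pixel_size, frame_interval = frame_interval)
}
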