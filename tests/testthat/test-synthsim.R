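test_that("config validation rejects bad values", {
  expect_error(transport_sim_config(axon_length = -1), "axon_length")
  expect_error(transport_sim_config(stationary_fraction = 1.5), "probability")
  expect_error(transport_sim_config(run_length_mean = 0), "run_length_mean")
  expect_error(transport_sim_config(n_frames = 1), "n_frames")
})

test_that("the three acquisition regimes set frame interval and duration", {
  c1 <- transport_sim_config(regime = "lamp1")
  expect_equal(c1$frame_interval, 0.75)
  expect_equal(c1$n_frames * c1$frame_interval, 120)
  c2 <- transport_sim_config(regime = "lysobrite")
  expect_equal(c2$frame_interval, 1)
  expect_equal(c2$n_frames * c2$frame_interval, 90)
  c3 <- transport_sim_config(regime = "mito")
  expect_equal(c3$frame_interval, 2)
  expect_equal(c3$n_frames * c3$frame_interval, 180)
})

test_that("identical seeds give bit-identical stacks and ground truth", {
  cfg <- transport_sim_config(seed = 11, n_frames = 30, n_particles = 6)
  a <- simulate_transport(cfg)
  b <- simulate_transport(cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(a$stack$data, b$stack$data)
  c <- simulate_transport(transport_sim_config(seed = 12, n_frames = 30,
                                               n_particles = 6))
  expect_false(identical(a$truth, c$truth))
})

test_that("a single stationary particle with no diffusion never moves", {
  cfg <- transport_sim_config(seed = 1, n_particles = 1,
                              stationary_fraction = 1, diffusion_coeff = 0,
                              n_frames = 40)
  sim <- simulate_transport(cfg, render = FALSE)
  expect_equal(length(unique(sim$truth$position_um)), 1L)
  expect_true(all(sim$truth$state == "stationary"))
  expect_equal(nrow(sim$truth), 40L)
})

test_that("uniform motion covers speed x time exactly", {
  # one motile particle, constant 1 um/s, 1 s frames, no pauses or reversals
  cfg <- transport_sim_config(seed = 3, n_particles = 1,
                              stationary_fraction = 0, run_speed_sd = 0,
                              run_speed_anterograde = 1, run_speed_retrograde = 1,
                              run_length_mean = 1e6, pause_rate = 0,
                              reversal_prob = 0, diffusion_coeff = 0,
                              frame_interval = 1, n_frames = 51, regime = NULL,
                              axon_length = 500)
  sim <- simulate_transport(cfg, render = FALSE)
  tr <- sim$truth[sim$truth$particle_id == 1, ]
  expect_gte(nrow(tr), 51)  # survived the full movie with this seed
  expect_equal(abs(tr$position_um[51] - tr$position_um[1]), 50)
  expect_equal(unique(round(abs(diff(tr$position_um)), 12)), 1)
})

test_that("trajectories stay inside the axon and frames are complete", {
  for (seed in 1:3) {
    cfg <- transport_sim_config(seed = seed, n_frames = 60)
    sim <- simulate_transport(cfg, render = FALSE)
    expect_true(all(sim$truth$position_um >= 0 &
                      sim$truth$position_um <= cfg$axon_length))
    by_frame <- table(sim$truth$frame)
    # constant density: every frame has n_particles active particles
    expect_true(all(by_frame == cfg$n_particles))
    for (tr in split(sim$truth, sim$truth$particle_id))
      expect_true(all(diff(tr$frame) == 1L))
  }
})

test_that("stationary-particle RMS displacement follows sqrt(2 D t)", {
  cfg <- transport_sim_config(seed = 42, n_particles = 1500,
                              stationary_fraction = 1, frame_interval = 1,
                              n_frames = 51, regime = NULL)
  sim <- simulate_transport(cfg, render = FALSE)
  x <- matrix(sim$truth$position_um, nrow = 51)
  disp50 <- x[51, ] - x[1, ]
  expect_equal(sqrt(mean(disp50^2)), diffusion_bound(0.01, 50),
               tolerance = 0.05)
  # MSD grows linearly with slope 2D
  lags <- c(10, 20, 30, 40, 50)
  msd <- vapply(lags, function(l) mean((x[1 + l, ] - x[1, ])^2), numeric(1))
  fit <- stats::lm(msd ~ lags)
  expect_equal(unname(stats::coef(fit)[2]), 2 * 0.01, tolerance = 0.1)
})

test_that("rendered spot centroid is within half a pixel at snr >= 5", {
  cfg <- transport_sim_config(seed = 5, n_particles = 1,
                              stationary_fraction = 1, diffusion_coeff = 0,
                              n_frames = 20, snr = 5)
  sim <- simulate_transport(cfg)
  true_col <- sim$truth$position_um[1] / cfg$pixel_size + 1
  errs <- lapply(seq_len(20), function(f) {
    img <- sim$stack$data[, , f]
    p <- detect_puncta(img, detection_config(min_size = 3,
                                             intensity_threshold = 3.5))
    if (nrow(p) == 0) return(NULL)       # shot noise can drop a frame
    abs(p$x[which.max(p$integrated_intensity)] - true_col)
  })
  errs <- unlist(errs)
  expect_gte(length(errs), 10)           # detected in at least half the frames
  expect_lt(mean(errs), 0.5)
})

test_that("puncta fields plant exactly the requested colocalized pairs", {
  # trivial fractions
  f0 <- simulate_puncta_field(n_cells = 2, n_lamp1_per_cell = 10,
                              coloc_fraction = 0, seed = 1)
  expect_equal(sum(f0$truth$colocalized[f0$truth$channel == 2]), 0)
  f1 <- simulate_puncta_field(n_cells = 2, n_lamp1_per_cell = 10,
                              coloc_fraction = 1, seed = 2)
  expect_equal(sum(f1$truth$colocalized[f1$truth$channel == 2]), 20)

  # 0.4 x 20 = 8 pairs per cell, recoverable by an exhaustive distance check
  f <- simulate_puncta_field(n_cells = 1, n_lamp1_per_cell = 20,
                             coloc_fraction = 0.4, max_offset = 2,
                             cell_size = 220, seed = 3)
  ch1 <- f$truth[f$truth$channel == 1, ]
  ch2 <- f$truth[f$truth$channel == 2, ]
  d <- sqrt(outer(ch1$x, ch2$x, "-")^2 + outer(ch1$y, ch2$y, "-")^2)
  expect_equal(sum(d <= 2), 8)           # planted pairs, one per row/col
  expect_true(all(apply(d <= 2, 1, sum) <= 1))
  # non-colocalized marker spots are at least 3x max_offset from any lamp1
  far <- ch2[!ch2$colocalized, ]
  dfar <- sqrt(outer(ch1$x, far$x, "-")^2 + outer(ch1$y, far$y, "-")^2)
  expect_true(all(apply(dfar, 2, min) >= 3 * 2))
})

test_that("overcrowded puncta fields raise a generation error", {
  expect_error(
    simulate_puncta_field(n_cells = 1, n_lamp1_per_cell = 500, cell_size = 40,
                          seed = 1, max_tries = 200),
    "overcrowded")
})

test_that("intensity fields match their planted ground truth", {
  f0 <- simulate_intensity_field(n_objects = 0, seed = 1)
  expect_equal(f0$area, 0)
  f1 <- simulate_intensity_field(background_level = 100, n_objects = 1,
                                 object_intensity = 1000, object_size = 10,
                                 seed = 2)
  expect_equal(f1$area, 100)
  expect_equal(f1$integrated, 1000 * 100)
  expect_error(simulate_intensity_field(object_intensity = 250,
                                        background_level = 100),
               "3x background")
})
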