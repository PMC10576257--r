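rules_test <- run_rule_config(same_position_tol = 0.3)

test_that("diffusion bound follows sqrt(2 D t)", {
  expect_equal(diffusion_bound(0.01, 50), 1)
  expect_equal(diffusion_bound(0, 123), 0)
  expect_equal(diffusion_bound(0.04, 50), 2 * diffusion_bound(0.01, 50))
  expect_error(diffusion_bound(-0.01, 1), "non-negative")
  expect_error(diffusion_bound(0.01, -1), "non-negative")
})

test_that("rule config enforces the diffusion-bound dominance invariant", {
  r <- run_rule_config()
  expect_equal(r$run_threshold, 5)
  expect_equal(r$diffusion_coeff, 0.01)
  expect_equal(r$diffusion_horizon, 50)
  expect_equal(r$pause_min_frames, 4L)
  expect_gte(r$run_threshold, diffusion_bound(r$diffusion_coeff,
                                              r$diffusion_horizon))
  expect_error(run_rule_config(run_threshold = 0.5), "dominate")
})

test_that("a noiseless line yields exactly one faithful track", {
  p <- make_track(3 + 0.7 * (0:29))
  stack <- render_test_stack(list(p), n_frames = 30)
  kymo <- build_kymograph(stack, axon_path(c(1, 200), c(6, 6)))
  tracks <- extract_tracks(kymo)
  expect_length(tracks, 1)
  expect_equal(tracks[[1]]$frame, 1:30)
  expect_true(all(abs(tracks[[1]]$position_um - p$position_um) <=
                    0.5 * 0.160508 + 1e-9))
})

test_that("two separated parallel lines give two tracks with no swaps", {
  p1 <- make_track(3 + 0.5 * (0:29))
  p2 <- make_track(20 + 0.5 * (0:29))
  stack <- render_test_stack(list(p1, p2), n_frames = 30, nx = 250)
  kymo <- build_kymograph(stack, axon_path(c(1, 250), c(6, 6)))
  tracks <- extract_tracks(kymo)
  expect_length(tracks, 2)
  starts <- vapply(tracks, function(t) t$position_um[1], numeric(1))
  tracks <- tracks[order(starts)]
  expect_true(all(abs(tracks[[1]]$position_um - p1$position_um) < 0.3))
  expect_true(all(abs(tracks[[2]]$position_um - p2$position_um) < 0.3))
})

test_that("an empty kymograph yields no tracks", {
  kymo <- structure(list(data = matrix(numeric(0), 0, 0),
                         pixel_size = 0.160508, frame_interval = 1),
                    class = "kymograph")
  expect_identical(extract_tracks(kymo), list())
})

test_that("tracks recover >= 95% of ground-truth points for separated cargo", {
  cfg <- transport_sim_config(seed = 21, n_particles = 6, n_frames = 80,
                              snr = 10)
  sim <- simulate_transport(cfg)
  kymo <- build_kymograph(sim$stack, sim_path(sim))
  tracks <- extract_tracks(kymo, min_frames = 5)
  got <- do.call(rbind, tracks)
  truth <- sim$truth
  hit <- vapply(seq_len(nrow(truth)), function(i) {
    sel <- got$frame == truth$frame[i]
    any(abs(got$position_um[sel] - truth$position_um[i]) < 0.5)
  }, logical(1))
  expect_gte(mean(hit), 0.95)
})

test_that("segmentation reproduces the worked examples", {
  # monotone 10 um, no stall: one run
  s <- segment_track(make_track(seq(0, 10, by = 1)), rules_test, 1)
  expect_equal(nrow(s$runs), 1L)
  expect_equal(s$runs$displacement_um, 10)
  expect_equal(s$runs$direction, "anterograde")
  expect_equal(nrow(s$pauses), 0L)

  # 6 um anterograde, 5-frame stall, 7 um retrograde
  tr <- make_track(c(seq(0, 6, by = 1), rep(6, 4),
                     seq(6 - 1.4, -1, by = -1.4)))
  s <- segment_track(tr, rules_test, 1)
  expect_equal(s$runs$direction, c("anterograde", "retrograde"))
  expect_equal(s$runs$displacement_um, c(6, 7))
  expect_equal(nrow(s$pauses), 1L)
  expect_equal(s$pauses$duration_s, 4)
})

test_that("the 5 um run threshold is exact at the printed boundary", {
  for (case in list(list(d = 4.99, n = 0L), list(d = 5.00, n = 1L))) {
    tr <- make_track(seq(0, case$d, length.out = 11))
    expect_equal(nrow(segment_track(tr, rules_test, 1)$runs), case$n,
                 info = paste("displacement", case$d))
  }
})

test_that("scan segmentation equals the exhaustive stall enumerator", {
  set.seed(202)
  for (i in 1:150) {
    tr <- random_track(sample(5:30, 1))
    fast <- segment_track(tr, rules_test, 1)
    slow <- segment_track(tr, rules_test, 1, brute_force = TRUE)
    oracle <- oracle_segment(tr$position_um, tr$frame, rules_test, 1)
    expect_equal(fast$runs, slow$runs, ignore_attr = TRUE)
    expect_equal(fast$runs, oracle$runs, ignore_attr = TRUE)
    expect_equal(fast$pauses, oracle$pauses, ignore_attr = TRUE)
  }
})

test_that("every emitted directed run clears the threshold (property)", {
  set.seed(303)
  for (i in 1:50) {
    tr <- random_track(sample(10:40, 1))
    runs <- segment_track(tr, rules_test, 1)$runs
    if (nrow(runs)) {
      expect_true(all(runs$displacement_um >= rules_test$run_threshold))
      expect_true(all(runs$duration_s > 0))
      expect_equal(runs$mean_speed_um_s,
                   runs$displacement_um / runs$duration_s)
    }
  }
})

test_that("segmentation is invariant to time reversal up to relabeling", {
  set.seed(404)
  for (i in 1:80) {
    tr <- random_track(sample(6:30, 1))
    fwd <- segment_track(tr, rules_test, 1)$runs
    rev_tr <- make_track(rev(tr$position_um))
    bwd <- segment_track(rev_tr, rules_test, 1)$runs
    expect_equal(nrow(fwd), nrow(bwd))
    expect_equal(sort(fwd$displacement_um), sort(bwd$displacement_um))
    expect_equal(sort(fwd$duration_s), sort(bwd$duration_s))
    if (nrow(fwd))
      expect_equal(unname(sort(table(fwd$direction))),
                   unname(sort(table(bwd$direction))))
  }
})

test_that("large frame gaps split a track with a warning", {
  tr <- data.frame(frame = c(1:10, 20:29),
                   position_um = c(seq(0, 9), seq(9, 0)))
  expect_warning(s <- segment_track(tr, rules_test, 1), "gaps")
  expect_equal(nrow(s$runs), 2L)
  expect_setequal(s$runs$direction, c("anterograde", "retrograde"))
})

test_that("stationary classification boundary is exact at 5 um", {
  dur <- 90; dt <- 1
  base <- rep(0, 91)
  for (case in list(list(exc = 4.99, cl = "stationary"),
                    list(exc = 5.00, cl = "motile"))) {
    x <- base; x[50] <- case$exc
    tr <- make_track(x, frames = 1:91)
    expect_equal(classify_stationary(tr, rules_test, dur, dt), case$cl,
                 info = paste("excursion", case$exc))
  }
  expect_equal(classify_stationary(make_track(rep(3, 91), 1:91),
                                   rules_test, dur, dt), "stationary")
})

test_that("tracks spanning less than half the movie are unclassified", {
  tr <- make_track(rep(1, 30), frames = 1:30)
  expect_message(
    cl <- classify_stationary(tr, rules_test, movie_duration_s = 90,
                              frame_interval = 1),
    "less than half")
  expect_identical(cl, NA_character_)
})

test_that("planted stationary fraction is recovered exactly from clean tracks", {
  # a long axon relative to the horizon keeps this seed free of absorptions,
  # so every planted particle yields exactly one classifiable track
  cfg <- transport_sim_config(seed = 32, n_particles = 20,
                              stationary_fraction = 0.5, diffusion_coeff = 0,
                              n_frames = 50, frame_interval = 1, regime = NULL,
                              axon_length = 500)
  sim <- simulate_transport(cfg, render = FALSE)
  expect_equal(length(unique(sim$truth$particle_id)), 20L)
  tracks <- split(sim$truth[, c("frame", "position_um")], sim$truth$particle_id)
  cls <- vapply(tracks, classify_stationary, character(1), rules = rules_test,
                movie_duration_s = 50, frame_interval = 1, quiet = TRUE)
  expect_equal(percent_stationary(cls), 50)
})

test_that("direction assignment respects the soma-side convention", {
  expect_equal(assign_direction(0, 5), "anterograde")
  expect_equal(assign_direction(5, 0), "retrograde")
  # mirrored coordinates flip the call
  expect_equal(assign_direction(0, 5, soma_end = "end"), "retrograde")
  expect_error(assign_direction(2, 2), "zero net displacement")
})

test_that("simulated run directions agree with ground-truth labels", {
  cfg <- transport_sim_config(seed = 8, n_particles = 4,
                              stationary_fraction = 0, diffusion_coeff = 0,
                              n_frames = 60)
  sim <- simulate_transport(cfg, render = FALSE)
  for (tr in split(sim$truth, sim$truth$particle_id)) {
    runs <- segment_track(tr[, c("frame", "position_um")], rules_test,
                          cfg$frame_interval)$runs
    for (r in seq_len(nrow(runs))) {
      states <- tr$state[tr$frame > runs$start_frame[r] &
                           tr$frame <= runs$end_frame[r]]
      states <- states[startsWith(states, "run_")]
      dominant <- names(which.max(table(states)))
      expected <- if (dominant == "run_antero") "anterograde" else "retrograde"
      expect_equal(runs$direction[r], expected)
    }
  }
})
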