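mk_runs <- function(direction, displacement, duration = displacement) {
  data.frame(direction = direction,
             start_frame = rep(1, length(direction)),
             end_frame = rep(2, length(direction)),
             displacement_um = displacement, duration_s = duration,
             mean_speed_um_s = displacement / duration,
             track_id = seq_along(direction))
}

test_that("flux follows sum(d_i) / (l t) and its homogeneity", {
  runs <- mk_runs(c("anterograde", "anterograde"), c(10, 20))
  f <- flux(runs, axon_length_um = 50, duration_min = 2)
  expect_equal(unname(f["anterograde"]), 30 / (50 * 2))
  expect_equal(unname(f["retrograde"]), 0)

  none <- flux(mk_runs(character(0), numeric(0)), 50, 2)
  expect_equal(unname(none), c(0, 0))

  runs2 <- runs; runs2$displacement_um <- 2 * runs$displacement_um
  expect_equal(flux(runs2, 50, 2), 2 * f)
  expect_equal(flux(runs, 100, 2), f / 2)
  expect_equal(flux(runs, 50, 4), f / 2)
  expect_error(flux(runs, 0, 2), "axon_length")
  expect_error(flux(runs, 50, -1), "duration")
})

test_that("velocity stats report per-direction means and missing directions", {
  runs <- mk_runs(c("anterograde"), 10, duration = 10)
  vs <- velocity_stats(runs)
  expect_equal(vs$mean_speed[vs$direction == "anterograde"], 1)
  expect_true(is.na(vs$mean_speed[vs$direction == "retrograde"]))
  expect_equal(vs$n, c(1L, 0L))
})

test_that("run duration excludes sub-tolerance stall frames (oracle check)", {
  rules <- run_rule_config(same_position_tol = 0.3)
  # 1 um/s run with an internal 3-frame stall (below pause_min_frames)
  x <- c(seq(0, 5, by = 1), rep(5, 2), seq(6, 10, by = 1))
  tr <- make_track(x)
  runs <- segment_track(tr, rules, 1)$runs
  expect_equal(nrow(runs), 1L)
  # frame-by-frame oracle: moving steps are those exceeding tolerance
  moving <- sum(abs(diff(x)) > rules$same_position_tol)
  expect_equal(runs$duration_s, moving * 1)
  expect_equal(runs$mean_speed_um_s, 10 / moving)
})

test_that("planted speed is recovered within 2% from noiseless trajectories", {
  speeds <- c(anterograde = 1.2, retrograde = 1.2)
  got <- c(0, 0); n <- c(0, 0)
  for (seed in 1:6) {
    cfg <- transport_sim_config(seed = seed, n_particles = 10,
                                stationary_fraction = 0, diffusion_coeff = 0,
                                run_speed_anterograde = 1.2,
                                run_speed_retrograde = 1.2, run_speed_sd = 0)
    sim <- simulate_transport(cfg, render = FALSE)
    seg <- segment_tracks(split(sim$truth[, c("frame", "position_um")],
                                sim$truth$particle_id),
                          run_rule_config(), cfg$frame_interval)
    vs <- velocity_stats(seg$runs)
    got <- got + ifelse(is.na(vs$mean_speed), 0, vs$mean_speed * vs$n)
    n <- n + vs$n
  }
  expect_equal(got[1] / n[1], 1.2, tolerance = 0.02)
  expect_equal(got[2] / n[2], 1.2, tolerance = 0.02)
})

test_that("density counts runs plus stationary objects per um", {
  expect_equal(density_per_um(3, 2, 50), 0.1)
  expect_equal(density_per_um(0, 0, 50), 0)
  expect_error(density_per_um(1, 1, 0), "length_um")
  # ratio invariance: half the kymograph with half the content
  expect_equal(density_per_um(6, 4, 100), density_per_um(3, 2, 50))
})

test_that("percent stationary handles the printed examples", {
  expect_equal(percent_stationary(rep("stationary", 5)), 100)
  expect_equal(percent_stationary(c(rep("stationary", 2), rep("motile", 6))),
               25)
  expect_equal(percent_stationary(c("stationary", "motile", NA)), 50)
  expect_error(percent_stationary(c(NA_character_)), "no classified")
})

test_that("summaries assemble consistently and ignore track order", {
  cfg <- transport_sim_config(seed = 44, n_frames = 90, frame_interval = 1,
                              regime = NULL)
  sim <- simulate_transport(cfg, render = FALSE)
  tracks <- split(sim$truth[, c("frame", "position_um")], sim$truth$particle_id)
  rules <- run_rule_config()
  seg <- segment_tracks(tracks, rules, 1)
  s1 <- suppressMessages(
    summarize_transport(tracks, seg$runs, seg$pauses, cfg$axon_length, 90, 1,
                        rules))
  expect_s3_class(s1, "transport_summary")
  expect_equal(s1$n_events_antero + s1$n_events_retro, nrow(seg$runs))
  expect_gte(s1$directionality, 0); expect_lte(s1$directionality, 1)
  expect_gte(s1$percent_stationary, 0); expect_lte(s1$percent_stationary, 100)
  expect_gte(s1$flux_antero, 0); expect_gte(s1$density, 0)

  # permuting tracks leaves every statistic unchanged
  perm <- rev(seq_along(tracks))
  seg2 <- segment_tracks(tracks[perm], rules, 1)
  s2 <- suppressMessages(
    summarize_transport(tracks[perm], seg2$runs, seg2$pauses, cfg$axon_length,
                        90, 1, rules))
  expect_equal(as.data.frame(s1)[setdiff(names(s1), "n_tracks")],
               as.data.frame(s2)[setdiff(names(s2), "n_tracks")])
})

test_that("a single-run movie reports that run's values", {
  tr <- make_track(seq(0, 10, by = 1))
  rules <- run_rule_config()
  seg <- segment_tracks(list(tr), rules, 1)
  s <- suppressMessages(
    summarize_transport(list(tr), seg$runs, seg$pauses, axon_length = 50,
                        duration_s = 10, frame_interval = 1, rules = rules))
  expect_equal(s$velocity_antero, 1)
  expect_equal(s$run_length_antero, 10)
  expect_equal(s$flux_antero, 10 / (50 * (10 / 60)))
  expect_equal(s$n_events_antero, 1L)
  expect_equal(s$directionality, 1)
})

test_that("formula flux equals per-frame brute-force accumulation", {
  for (seed in 1:5) {
    cfg <- transport_sim_config(seed = seed)
    sim <- simulate_transport(cfg, render = FALSE)
    tracks <- split(sim$truth[, c("frame", "position_um")],
                    sim$truth$particle_id)
    seg <- segment_tracks(tracks, run_rule_config(), cfg$frame_interval)
    dur_min <- cfg$n_frames * cfg$frame_interval / 60
    f1 <- flux(seg$runs, cfg$axon_length, dur_min)
    f2 <- flux_brute_force(tracks, seg$runs, cfg$axon_length, dur_min)
    expect_equal(f1, f2, tolerance = 1e-9)
  }
})

test_that("aggregation across movies reports mean and SEM per parameter", {
  rows <- lapply(1:4, function(i) {
    cfg <- transport_sim_config(seed = 50 + i)
    sim <- simulate_transport(cfg, render = FALSE)
    suppressMessages(ground_truth_summary(sim))
  })
  agg <- aggregate_summaries(do.call(rbind, rows))
  expect_true(all(c("parameter", "mean", "sem", "n") %in% names(agg)))
  v <- vapply(rows, function(r) r$velocity_antero, numeric(1))
  expect_equal(agg$mean[agg$parameter == "velocity_antero"], mean(v))
  expect_equal(agg$sem[agg$parameter == "velocity_antero"],
               stats::sd(v) / 2)
})
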