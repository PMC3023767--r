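test_that("noiseless planted events have exact depth and pre-rupture slope", {
  cfg <- curve_sim_config(n_curves = 5, noise_sd = 0, specific_fraction = 1,
                          specific_force = c(80, 0),
                          specific_stiffness = c(0.6, 0),
                          events_per_curve_lambda = 1, seed = 21)
  sim <- simulate_force_curves(cfg)
  for (i in seq_len(nrow(sim$truth))) {
    cv <- sim$curves[[match(sim$truth$curve_id[i],
                            vapply(sim$curves, `[[`, "", "curve_id"))]]
    idx <- sim$truth$index[i]
    expect_equal(cv$force[idx], -80, tolerance = 1e-12)
    expect_equal(min(cv$force), -80, tolerance = 1e-12)
    # slope over the linear part of the ramp, displacement spacing 1 nm
    seg <- (idx - 20):idx
    expect_equal(unname(diff(cv$force[seg])), rep(-0.6, 20),
                 tolerance = 1e-12)
  }
  expect_equal(sim$truth$f_prime_pN_per_s,
               sim$truth$k_eff_pN_per_nm * cfg$velocity)
})

test_that("generators are pure functions of their configuration", {
  cfg <- curve_sim_config(n_curves = 4, seed = 9)
  s1 <- simulate_force_curves(cfg)
  s2 <- simulate_force_curves(cfg)
  expect_identical(s1$truth, s2$truth)
  expect_identical(lapply(s1$curves, `[[`, "force"),
                   lapply(s2$curves, `[[`, "force"))

  tcfg <- track_sim_config(n_cells = 4, n_frames = 30, seed = 9)
  expect_identical(simulate_prw_tracks(tcfg), simulate_prw_tracks(tcfg))

  kcfg <- kymo_sim_config(n_frames = 50, events = data.frame(
    start_frame = 10, slope = 2, ramp_frames = 5, plateau_frames = 2),
    noise_sd = 0.2, seed = 9)
  expect_identical(simulate_kymograph(kcfg), simulate_kymograph(kcfg))

  fcfg <- frame_sim_config(y_offset_schedule = c(4, 4.1),
                           rigid_jitter_sd = 0.01, seed = 9)
  expect_identical(simulate_headpiece_frames(fcfg),
                   simulate_headpiece_frames(fcfg))
})

test_that("planted specific fraction matches the binomial expectation", {
  ev <- simulate_rupture_events(n_cells = 10, events_per_cell = 1000,
                                specific_fraction = 0.3, seed = 5)
  n <- nrow(ev)
  p_hat <- mean(ev$class == "specific")
  expect_lt(abs(p_hat - 0.3), 3 * sqrt(0.3 * 0.7 / n))
})

test_that("simulated track ensemble follows the closed-form PRW MSD", {
  cfg <- track_sim_config(n_cells = 500, S_true = 1, P_true = 20, dt = 5,
                          n_frames = 96, seed = 31)
  tracks <- simulate_prw_tracks(cfg)
  for (n_int in 1:10) {
    per_track <- vapply(tracks, function(trk) {
      m <- msd_nonoverlapping(trk)
      m$msd_um2[m$interval == n_int]
    }, numeric(1))
    model <- prw_msd(n_int * 5, 1, 20)
    sem_hat <- sd(per_track) / sqrt(length(per_track))
    expect_lt(abs(mean(per_track) - model), 3 * sem_hat)
  }
})

test_that("PRW generator reproduces the diffusive and ballistic limits", {
  # P << dt: MSD linear in t (diffusive at all observable lags)
  cfg <- track_sim_config(n_cells = 300, S_true = 2, P_true = 0.05, dt = 5,
                          n_frames = 20, seed = 41)
  tracks <- simulate_prw_tracks(cfg)
  msd_mean <- rowMeans(vapply(tracks, function(trk) {
    msd_nonoverlapping(trk)$msd_um2[1:6]
  }, numeric(6)))
  ratio <- msd_mean / (1:6)
  expect_lt(max(abs(ratio / ratio[1] - 1)), 0.15)

  # dt << P: short-time MSD ~ S^2 t^2 (ballistic)
  cfg2 <- track_sim_config(n_cells = 300, S_true = 1, P_true = 500, dt = 1,
                           n_frames = 8, seed = 42)
  tracks2 <- simulate_prw_tracks(cfg2)
  m1 <- mean(vapply(tracks2, function(trk) {
    msd_nonoverlapping(trk)$msd_um2[1]
  }, numeric(1)))
  expect_equal(m1, 1, tolerance = 0.1)
})

test_that("simulated shapes report their exact polygon area and perimeter", {
  rect <- simulate_shapes("rectangle", list(width = 2, height = 4))
  expect_equal(rect$area, 8)
  expect_equal(rect$perimeter, 12)

  ngon <- simulate_shapes("circle_ngon", list(r = 1, n = 1024))
  expect_equal(ngon$area, pi, tolerance = 1e-4)

  star <- simulate_shapes("star", list(n_arms = 7, r_outer = 3,
                                       r_inner = 1.2))
  oracle <- oracle_shoelace(star$vertices)
  expect_equal(star$area, oracle$area)
  expect_equal(star$perimeter, oracle$perimeter)
  expect_error(simulate_shapes("star", list(n_arms = 5, r_outer = 1,
                                            r_inner = 2)),
               class = "acidhesion_bad_arg")
})

test_that("kymograph construction matches the planted schedule", {
  cfg <- kymo_sim_config(n_frames = 40, events = data.frame(
    start_frame = 5, slope = 2, ramp_frames = 10, plateau_frames = 0),
    noise_sd = 0, seed = 1)
  sim <- simulate_kymograph(cfg)
  expect_equal(max(sim$trace$position_px), 20)
  expect_equal(sim$truth$height_px, 20)

  flat <- simulate_kymograph(kymo_sim_config(n_frames = 30, noise_sd = 0))
  expect_equal(flat$trace$position_px, rep(0, 30))
  expect_equal(nrow(flat$truth), 0)

  sched <- random_kymo_events(n_events = 50, seed = 3)
  expect_equal(sched$events$slope * sched$events$ramp_frames,
               simulate_kymograph(kymo_sim_config(
                 n_frames = sched$n_frames, events = sched$events,
                 noise_sd = 0.3, seed = 4))$truth$height_px)
  # overlapping footprints are rejected
  expect_error(kymo_sim_config(n_frames = 100, events = data.frame(
    start_frame = c(5, 10), slope = 2, ramp_frames = 10,
    plateau_frames = 0)), class = "acidhesion_bad_arg")
})

test_that("frame simulator places group separations exactly as scheduled", {
  cfg <- frame_sim_config(y_offset_schedule = c(4.0, 4.2, 4.5),
                          rigid_jitter_sd = 0, seed = 1)
  sim <- simulate_headpiece_frames(cfg)
  expect_equal(sim$true_d, c(4.0, 4.2, 4.5))
  d <- opening_distance(sim$frame_sets[[1]])
  expect_equal(d, c(4.0, 4.2, 4.5), tolerance = 1e-10)

  # rigid whole-frame translation leaves the separation unchanged
  fs <- sim$frame_sets[[1]]
  shifted <- fs
  shifted$coords <- sweep(fs$coords, 3, c(7, -3, 2), `+`)
  expect_equal(opening_distance(shifted), d, tolerance = 1e-10)
})

test_that("group-level jitter propagates into d as sqrt(2) * jitter SD", {
  cfg <- frame_sim_config(y_offset_schedule = rep(4.2, 2000),
                          rigid_jitter_sd = 0.01, seed = 17)
  d <- opening_distance(simulate_headpiece_frames(cfg)$frame_sets[[1]])
  expect_equal(mean(d), 4.2, tolerance = 0.001)   # unbiased
  expect_equal(sd(d), sqrt(2) * 0.01, tolerance = 0.1)
})

test_that("invalid generator parameters are rejected", {
  expect_error(curve_sim_config(noise_sd = -1), class = "acidhesion_bad_arg")
  expect_error(curve_sim_config(specific_fraction = 1.5),
               class = "acidhesion_bad_arg")
  expect_error(curve_sim_config(specific_force = c(80, -1)),
               class = "acidhesion_bad_arg")
  expect_error(track_sim_config(n_frames = 2), class = "acidhesion_bad_arg")
  expect_error(track_sim_config(P_true = 0), class = "acidhesion_bad_arg")
  expect_error(frame_sim_config(y_offset_schedule = numeric(0)),
               class = "acidhesion_bad_arg")
})
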