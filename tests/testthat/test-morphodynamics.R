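test_that("circularity matches closed forms and the shoelace oracle", {
  circ <- simulate_shapes("circle_ngon", list(r = 10, n = 1024))
  expect_equal(shape_metrics(circ$vertices)$circularity_raw, 1,
               tolerance = 1e-4)
  sq <- simulate_shapes("rectangle", list(width = 2, height = 2))
  expect_equal(shape_metrics(sq$vertices)$circularity_raw, pi / 4,
               tolerance = 1e-12)
  star <- simulate_shapes("star", list(n_arms = 5, r_outer = 2,
                                       r_inner = 0.8))
  o <- oracle_shoelace(star$vertices)
  expect_equal(shape_metrics(star$vertices)$circularity_raw,
               4 * pi * o$area / o$perimeter^2)
})

test_that("circularity is scale invariant and self-intersection rejected", {
  star <- simulate_shapes("star", list(n_arms = 6, r_outer = 3,
                                       r_inner = 1))
  c1 <- shape_metrics(star$vertices)$circularity_raw
  c2 <- shape_metrics(star$vertices * 7.3)$circularity_raw
  expect_equal(c1, c2)
  bowtie <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  expect_error(shape_metrics(bowtie), class = "acidhesion_bad_shape")
})

test_that("mask metrics count pixels and boundary edges", {
  m <- matrix(0L, 10, 10)
  m[3:6, 3:7] <- 1L   # 4 x 5 rectangle of pixels
  out <- shape_metrics(m, pixel_size = 1)
  expect_equal(out$area_um2, 20)
  expect_equal(out$perim_um, 18)
  two <- m
  two[9, 9] <- 1L
  expect_error(shape_metrics(two), class = "acidhesion_bad_shape")
})

test_that("area oscillation recovers planted peak timing", {
  times <- seq(0, 240, by = 5)
  tri <- function(t) {
    ph <- t %% 60
    1000 + 100 * ifelse(ph <= 30, ph / 30, (60 - ph) / 30)
  }
  areas <- tri(times)
  out <- area_oscillation(times, areas, switch_times = c(60, 120, 180),
                          window = 60)
  expect_equal(out$time_to_peak_min, rep(30, 3))
  expect_true(all(out$amplitude_ratio > 1.05))

  const <- area_oscillation(times, rep(500, length(times)),
                            switch_times = 60, window = 60)
  expect_equal(const$amplitude_ratio, 1)
  expect_true(is.na(const$time_to_peak_min))

  expect_warning(
    area_oscillation(times, areas, switch_times = 200, window = 60),
    "truncated")
})

test_that("edge extraction recovers a known edge and flags empty frames", {
  set.seed(5)
  edge <- round(20 + 10 * sin(seq(0, 3, length.out = 80)))
  kymo <- sapply(edge, function(e) c(rep(1, e), rep(0, 40 - e)))
  tr <- extract_edge_trace(kymo, threshold = 0.5)
  expect_equal(tr$position_px, edge)
  # otsu thresholding on a noisy version stays within 1 px RMS
  noisy <- kymo + matrix(rnorm(length(kymo), 0, 0.1), nrow(kymo))
  tr2 <- extract_edge_trace(noisy, threshold = "otsu")
  expect_lt(sqrt(mean((tr2$position_px - edge)^2)), 1)
  # uniform image has no edge
  expect_error(extract_edge_trace(matrix(1, 10, 10)),
               class = "acidhesion_no_edge")
  # a frame with no suprathreshold pixel is interpolated and flagged
  gap <- kymo
  gap[, 40] <- 0
  tr3 <- extract_edge_trace(gap, threshold = 0.5)
  expect_true(tr3$interpolated[40])
  expect_false(any(tr3$interpolated[-40]))
})

test_that("protrusion quantification reproduces the worked example", {
  cfg <- kymo_sim_config(n_frames = 60, frame_interval = 5,
                         pixel_size = 0.1,
                         events = data.frame(start_frame = 15, slope = 2,
                                             ramp_frames = 10,
                                             plateau_frames = 5),
                         noise_sd = 0, seed = 1)
  d <- detect_protrusions(simulate_kymograph(cfg)$trace)
  expect_equal(nrow(d), 1L)
  expect_equal(d$height_px, 20)
  expect_equal(d$velocity_px_frame, 2)
  expect_equal(d$velocity_um_min, 2.4)
  expect_equal(d$lifetime_s, 75)
})

test_that("events below the 4-pixel height rule are neglected", {
  cfg <- kymo_sim_config(n_frames = 40, events = data.frame(
    start_frame = 10, slope = 1, ramp_frames = 3, plateau_frames = 0),
    noise_sd = 0, seed = 1)
  expect_equal(nrow(detect_protrusions(simulate_kymograph(cfg)$trace)), 0L)
  # exactly 4 px is retained ("less than 4 pixels were neglected")
  cfg4 <- kymo_sim_config(n_frames = 40, events = data.frame(
    start_frame = 10, slope = 1, ramp_frames = 4, plateau_frames = 0),
    noise_sd = 0, seed = 1)
  expect_equal(nrow(detect_protrusions(simulate_kymograph(cfg4)$trace)), 1L)
})

test_that("protrusion detection is offset invariant and height monotone", {
  sched <- random_kymo_events(n_events = 10, seed = 13)
  sim <- simulate_kymograph(kymo_sim_config(
    n_frames = sched$n_frames, events = sched$events, noise_sd = 0.3,
    seed = 14))
  base <- detect_protrusions(sim$trace)
  shifted <- sim$trace
  shifted$position_px <- shifted$position_px + 57
  expect_equal(detect_protrusions(shifted), base)
  n_by_h <- vapply(c(0, 2, 4, 8, 16), function(h) {
    nrow(detect_protrusions(sim$trace, min_height = h))
  }, integer(1))
  expect_true(all(diff(n_by_h) <= 0))
})

test_that("protrusion summaries separate planted fast/slow conditions", {
  fast <- tibble::tibble(condition = "pH7.4",
                         velocity_um_min = c(1, 3), lifetime_s = c(30, 40))
  out <- summarize_protrusions(fast)$by_event
  expect_equal(out$velocity_mean, 2)
  expect_equal(out$velocity_sem, 1)

  set.seed(9)
  ev <- tibble::tibble(
    condition = rep(c("pH7.4", "pH6.5"), each = 60),
    cell_id = rep(rep(c("a", "b", "c"), each = 20), 2),
    velocity_um_min = c(rnorm(60, 3, 0.3), rnorm(60, 1.5, 0.3)),
    lifetime_s = c(rnorm(60, 40, 5), rnorm(60, 80, 5))
  )
  s <- summarize_protrusions(ev)
  be <- s$by_event
  expect_gt(be$velocity_mean[be$condition == "pH7.4"],
            be$velocity_mean[be$condition == "pH6.5"])
  expect_lt(be$lifetime_mean[be$condition == "pH7.4"],
            be$lifetime_mean[be$condition == "pH6.5"])
  expect_false(is.null(s$by_cell))
  expect_equal(nrow(s$by_cell), 2L)
})
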