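test_that("non-overlapping MSD is exact on straight-line and static tracks", {
  L <- 2
  trk <- track(x = L * (0:19), y = rep(0, 20), dt = 5)
  m <- msd_nonoverlapping(trk)
  expect_equal(m$msd_um2, (m$interval * L)^2)
  expect_equal(m$n_segments, 19L %/% m$interval)
  expect_equal(cell_speed(m), L / 5)

  still <- track(x = rep(1, 10), y = rep(-2, 10), dt = 5)
  expect_true(all(msd_nonoverlapping(still)$msd_um2 == 0))
  expect_equal(cell_speed(msd_nonoverlapping(still)), 0)
})

test_that("non-overlapping MSD equals the exhaustive disjoint-segment oracle", {
  set.seed(77)
  for (i in 1:25) {
    nf <- sample(5:20, 1)
    trk <- track(x = cumsum(rnorm(nf)), y = cumsum(rnorm(nf)), dt = 5)
    m <- msd_nonoverlapping(trk)
    o <- oracle_msd(trk$x, trk$y, 5)
    expect_equal(m$msd_um2, o$msd_um2)
    expect_equal(m$n_segments, o$n_segments)
  }
})

test_that("MSD is invariant to translation/rotation, speed scales linearly", {
  set.seed(78)
  nf <- 24
  x <- cumsum(rnorm(nf)); y <- cumsum(rnorm(nf))
  base <- msd_nonoverlapping(track(x, y, dt = 5))
  shifted <- msd_nonoverlapping(track(x + 13, y - 6, dt = 5))
  th <- 0.7
  rot <- msd_nonoverlapping(track(cos(th) * x - sin(th) * y,
                                  sin(th) * x + cos(th) * y, dt = 5))
  expect_equal(shifted$msd_um2, base$msd_um2)
  expect_equal(rot$msd_um2, base$msd_um2)
  scaled <- msd_nonoverlapping(track(3 * x, 3 * y, dt = 5))
  expect_equal(cell_speed(scaled), 3 * cell_speed(base))
})

test_that("PRW model evaluates exactly and is stable in both limits", {
  expect_equal(prw_msd(1, 1, 1), 2 * exp(-1))
  # deep ballistic regime: the naive formula loses ~6 digits to cancellation
  # at t/P = 1e-5; the series branch must track the exact value (4-term
  # series, truncation error ~ 2e-17 relative) and hence S^2 t^2 to O(x/3)
  x <- 1e-5
  exact <- 1.3^2 * 1e-10 * (1 - x / 3 + x^2 / 12 - x^3 / 60)
  expect_equal(prw_msd(1e-5, 1.3, 1), exact, tolerance = 1e-12)
  expect_equal(prw_msd(1e-5, 1.3, 1) / (1.3^2 * 1e-10), 1,
               tolerance = 1e-5)
  expect_equal(prw_msd(1e-3, 2, 1) / (2^2 * 1e-6), 1, tolerance = 1e-3)
  # diffusive limit: the asymptotic gap from 2 S^2 P t at t = 1000 P is
  # exactly P/t = 1e-3; the margin above it covers floating rounding only
  expect_equal(prw_msd(100, 1, 1) / (2 * 100), 1, tolerance = 0.02)
  expect_lte(abs(prw_msd(1000, 1, 1) / (2 * 1000) - 1), 1.000001e-3)
  expect_equal(prw_msd(1000, 1, 1), 2 * (1000 - 1), tolerance = 1e-12)
  expect_error(prw_msd(1, 1, 0), class = "acidhesion_bad_arg")
})

test_that("fitting exact model data is an identity map", {
  trk <- simulate_prw_tracks(track_sim_config(n_cells = 1, n_frames = 40,
                                              seed = 1))[[1]]
  m <- msd_nonoverlapping(trk)
  m$msd_um2 <- prw_msd(m$t_min, 0.8, 15)
  fit <- fit_prw(m)
  expect_true(fit$converged)
  expect_equal(fit$S, 0.8, tolerance = 1e-6)
  expect_equal(fit$P, 15, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("pure linear MSD drives the fit to the diffusive regime", {
  trk <- simulate_prw_tracks(track_sim_config(n_cells = 1, n_frames = 60,
                                              seed = 2))[[1]]
  m <- msd_nonoverlapping(trk)
  D <- 3
  m$msd_um2 <- 2 * D * m$t_min
  fit <- fit_prw(m)
  expect_true(fit$converged)
  expect_gt(fit$r_squared, 0.999)
  expect_lt(fit$P, attr(m, "dt"))          # persistence below resolution
  expect_equal(fit$S^2 * fit$P, D, tolerance = 0.05)
})

test_that("R^2 filter is strict and monotone in its threshold", {
  cells <- tibble::tibble(
    cell_id = letters[1:3], condition = "pH7.4",
    speed_um_min = c(1, 2, 3), r_squared = c(0.4, 0.6, 0.9),
    converged = TRUE
  )
  out <- filter_and_average(cells, min_cells = 2)
  expect_equal(out$n_retained, 2L)
  expect_equal(out$speed_mean, 2.5)
  expect_false(out$underpowered)
  # boundary: R^2 exactly at the threshold is retained ("< 0.5 not included")
  cells$r_squared <- c(0.5, 0.6, 0.9)
  expect_equal(filter_and_average(cells, min_cells = 2)$n_retained, 3L)
  # monotonicity
  retained <- vapply(c(0, 0.3, 0.55, 0.7, 0.9), function(r2) {
    filter_and_average(cells, r2_min = r2, min_cells = 1)$n_retained
  }, integer(1))
  expect_true(all(diff(retained) <= 0))
  expect_error(filter_and_average(cells, r2_min = 0.99),
               class = "acidhesion_bad_arg")
})

test_that("speed-vs-ligand finds the peak and flags a leftward shift", {
  tab <- tibble::tibble(
    condition = rep(c("pH7.4", "pH6.5"), each = 3),
    ligand_ug_per_ml = rep(c(0.1, 1, 10), 2),
    speed_mean = c(2, 5, 3,   5, 3, 2)
  )
  out <- speed_vs_ligand(tab)
  expect_equal(
    out$argmax$ligand_ug_per_ml[out$argmax$condition == "pH7.4"], 1)
  expect_equal(
    out$argmax$ligand_ug_per_ml[out$argmax$condition == "pH6.5"], 0.1)
  expect_true(out$leftward_shift)

  # identical profiles: no shift
  tab2 <- tab
  tab2$speed_mean <- rep(c(2, 5, 3), 2)
  expect_false(speed_vs_ligand(tab2)$leftward_shift)

  # ties are all reported
  tab3 <- tibble::tibble(condition = "pH7.4",
                         ligand_ug_per_ml = c(0.1, 1, 10),
                         speed_mean = c(5, 5, 3))
  expect_equal(speed_vs_ligand(tab3)$argmax$ligand_ug_per_ml, c(0.1, 1))
})

test_that("excluded tracks are dropped from analysis", {
  tracks <- simulate_prw_tracks(track_sim_config(n_cells = 3, n_frames = 40,
                                                 seed = 3))
  tracks[[2]]$excluded <- TRUE
  cells <- analyze_tracks(tracks)
  expect_equal(nrow(cells), 2L)
})
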