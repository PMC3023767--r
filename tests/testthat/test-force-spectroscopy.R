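test_that("detector recovers a noiseless planted event exactly", {
  cv <- make_noiseless_curve(f_r = 80, k_eff = 0.6, min_index = 800)
  idx <- detect_ruptures(cv)
  expect_equal(idx, 800L)
  expect_equal(rupture_force(cv, idx), 80, tolerance = 1e-12)
  lr <- effective_loading_rate(cv, idx)
  expect_equal(lr$k_eff, 0.6, tolerance = 1e-9)
  expect_equal(lr$f_prime, 3000, tolerance = 1e-6)
})

test_that("flat noise-only traces yield (almost) no detections", {
  set.seed(101)
  n_events <- vapply(1:100, function(i) {
    cv <- force_curve(0:1999, rnorm(2000, 0, 5), 5000, 25)
    length(detect_ruptures(cv))
  }, integer(1))
  expect_gte(mean(n_events == 0), 0.99)
})

test_that("detector recall and localization hold under noise", {
  cfg <- curve_sim_config(n_curves = 250, noise_sd = 5,
                          specific_fraction = 1,
                          specific_force = c(80, 15),
                          specific_stiffness = c(0.6, 0.1),
                          events_per_curve_lambda = 1.5, seed = 11)
  sim <- simulate_force_curves(cfg)
  tr <- sim$truth
  ev <- analyze_curves(sim$curves)
  offsets <- vapply(seq_len(nrow(tr)), function(i) {
    d <- ev$index[ev$curve_id == tr$curve_id[i]]
    if (!length(d)) return(NA_real_)
    min(abs(d - tr$index[i]))
  }, numeric(1))
  expect_gte(mean(!is.na(offsets) & offsets <= 2), 0.95)
  expect_lte(median(offsets, na.rm = TRUE), 2)
})

test_that("rupture force follows its definition on constructed traces", {
  # post-rupture baseline 0, minimum -80
  cv <- make_noiseless_curve(f_r = 80, k_eff = 0.6, min_index = 500)
  expect_equal(rupture_force(cv, 500L), 80)
  # constant trace: F_R = 0 at any index
  flat <- force_curve(0:199, rep(-3, 200), 5000, 25)
  expect_equal(rupture_force(flat, 100L), 0)
  # too little room after the jump
  expect_warning(out <- rupture_force(cv, 500L, next_index = 504L))
  expect_true(is.na(out))
  # noisy estimate stays within the propagated error bound
  set.seed(7)
  errs <- vapply(1:50, function(i) {
    cvn <- make_noiseless_curve(f_r = 120, k_eff = 0.8, min_index = 700)
    cvn$force <- cvn$force + rnorm(2000, 0, 5)
    rupture_force(cvn, detect_ruptures(cvn)[1], m_post = 50) - 120
  }, numeric(1))
  expect_lt(abs(mean(errs)), 3 * (5 / sqrt(50) + 5))
})

test_that("effective loading rate is slope times velocity", {
  disp <- 0:199
  ramp <- force_curve(disp, -0.4 * disp, velocity = 5000,
                      spring_constant = 25)
  lr <- effective_loading_rate(ramp, 200L)
  expect_equal(lr$k_eff, 0.4, tolerance = 1e-12)
  expect_equal(lr$f_prime, 2000, tolerance = 1e-9)

  flat <- force_curve(disp, rep(0, 200), 5000, 25)
  lr0 <- effective_loading_rate(flat, 200L)
  expect_equal(lr0$k_eff, 0)
  expect_equal(lr0$f_prime, 0)

  # noisy slope within 3x the closed-form least-squares SE
  set.seed(8)
  m_pre <- 30
  se <- 5 / sqrt((m_pre^3 - m_pre) / 12)
  errs <- vapply(1:200, function(i) {
    y <- -0.8 * disp + rnorm(200, 0, 5)
    cvn <- force_curve(disp, y, 5000, 25)
    effective_loading_rate(cvn, 200L, m_pre = m_pre)$k_eff - 0.8
  }, numeric(1))
  expect_lt(abs(mean(errs)), 3 * se / sqrt(200))
  expect_lt(sd(errs), 2 * se)
  # insufficient pre-samples flags the event
  expect_warning(bad <- effective_loading_rate(ramp, 10L, m_pre = 30))
  expect_true(is.na(bad$k_eff))
})

test_that("specificity gate assigns quadrants with strict inequalities", {
  out <- classify_specific(c(60, 50, 60, 40), c(2500, 2500, 1500, 1500))
  expect_equal(as.character(out$quadrant), c("II", "I", "IV", "III"))
  expect_equal(out$specific, c(TRUE, FALSE, FALSE, FALSE))
  expect_error(classify_specific(NA_real_, 100), class = "acidhesion_bad_arg")
})

test_that("raising either gate threshold never increases the specific count", {
  ev <- simulate_rupture_events(n_cells = 2, events_per_cell = 500, seed = 3)
  base <- sum(classify_specific(ev$f_r_pN, ev$f_prime_pN_per_s)$specific)
  for (fr in c(50, 60, 80, 120)) {
    for (fp in c(2000, 2500, 4000)) {
      n <- sum(classify_specific(ev$f_r_pN, ev$f_prime_pN_per_s,
                                 gate_thresholds(fr, fp))$specific)
      expect_lte(n, base)
    }
  }
})

test_that("binding frequency is the specific fraction per cell", {
  ev <- tibble::tibble(
    cell_id = rep(c("a", "b"), each = 200),
    condition = "pH7.4",
    specific = c(rep(c(TRUE, FALSE), c(30, 170)),
                 rep(FALSE, 200))
  )
  fb <- binding_frequency(ev)
  expect_equal(fb$f_b[fb$cell_id == "a"], 0.15)
  expect_equal(fb$f_b[fb$cell_id == "b"], 0)
  expect_equal(fb$n_events_total, c(200L, 200L))
  expect_error(binding_frequency(ev[0, ]), class = "acidhesion_bad_arg")

  # binomial consistency on simulated events
  sim <- simulate_rupture_events(n_cells = 1, events_per_cell = 200,
                                 specific_fraction = 0.17, seed = 12)
  cls <- classify_specific(sim$f_r_pN, sim$f_prime_pN_per_s)
  sim$specific <- cls$specific
  fb2 <- binding_frequency(sim)
  expect_lt(abs(fb2$f_b - 0.17), 3 * sqrt(0.17 * 0.83 / 200))
})

test_that("relative binding frequency normalizes to the reference mean", {
  s <- tibble::tibble(condition = c("pH7.4", "pH7.4", "pH6.0"),
                      cell_id = c("a", "b", "c"),
                      f_b = c(0.1, 0.2, 0.3))
  out <- relative_binding_frequency(s, "pH7.4")
  expect_equal(out$f_b_rel[out$cell_id == "c"], 2.0)
  expect_equal(mean(out$f_b_rel[out$condition == "pH7.4"]), 1)
  expect_error(relative_binding_frequency(
    tibble::tibble(condition = "pH7.4", cell_id = "a", f_b = 0), "pH7.4"),
    class = "acidhesion_bad_arg")
})

test_that("condition summaries use the cell as the unit of replication", {
  s <- tibble::tibble(condition = rep("pH7.4", 2), cell_id = c("a", "b"),
                      f_b = c(0.1, 0.3))
  out <- summarize_binding(s)$cells
  expect_equal(out$f_b_mean, 0.2)
  expect_equal(out$f_b_sem, 0.1)
  s3 <- tibble::tibble(condition = "x", cell_id = letters[1:3],
                       f_b = rep(1, 3), f_b_rel = rep(1, 3))
  out3 <- summarize_binding(s3)$cells
  expect_equal(out3$f_b_rel_mean, 1)
  expect_equal(out3$f_b_rel_sem, 0)
})

test_that("pooled f_b equals the event-weighted per-cell average at equal n", {
  ev <- simulate_rupture_events(n_cells = 5, events_per_cell = 200, seed = 6)
  cls <- classify_specific(ev$f_r_pN, ev$f_prime_pN_per_s)
  ev$specific <- cls$specific
  fb <- binding_frequency(ev)
  expect_equal(mean(fb$f_b), mean(ev$specific))
})
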