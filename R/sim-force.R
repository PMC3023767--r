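#' Configuration for the force-curve simulator
#'
#' Bundles the instrument constants and planted-event populations used by
#' [simulate_force_curves()]. Defaults mirror the experimental protocol the
#' pipeline was designed around: retraction at 5 um/s (5000 nm/s), cantilever
#' spring constant ~25 pN/nm, and two event populations — "specific"
#' receptor-ligand ruptures (high force, high pre-rupture stiffness) and
#' "nonspecific" adhesions (low force, low stiffness). The default specific
#' fraction of 0.168 reproduces the quadrant-II occupancy measured on
#' RGD-functionalized cantilevers before receptor blocking.
#'
#' @param n_curves number of retraction curves to simulate.
#' @param velocity cantilever retraction velocity, nm/s.
#' @param spring_constant cantilever spring constant, pN/nm.
#' @param noise_sd baseline Gaussian force noise SD, pN (>= 0).
#' @param specific_fraction probability that a planted event is specific.
#' @param specific_force,specific_stiffness `c(mean, sd)` of the planted
#'   rupture force (pN) and pre-rupture stiffness (pN/nm) for specific events.
#' @param nonspecific_force,nonspecific_stiffness analogues for nonspecific
#'   events.
#' @param events_per_curve_lambda Poisson mean of the number of planted events
#'   per curve.
#' @param samples_per_curve samples per retraction trace (1 nm spacing).
#' @param n_cells curves are assigned round-robin to this many cell ids.
#' @param condition condition label stamped on every curve.
#' @param seed integer seed; fixes the output exactly.
#' @return an object of class `curve_sim_config`.
#' @export
curve_sim_config <- function(n_curves = 10,
                             velocity = 5000,
                             spring_constant = 25,
                             noise_sd = 5,
                             specific_fraction = 0.168,
                             specific_force = c(90, 15),
                             specific_stiffness = c(0.8, 0.1),
                             nonspecific_force = c(30, 10),
                             nonspecific_stiffness = c(0.2, 0.05),
                             events_per_curve_lambda = 1,
                             samples_per_curve = 2000,
                             n_cells = 1,
                             condition = "pH7.4",
                             seed = 1) {
  check_scalar_pos(n_curves, "n_curves")
  check_scalar_pos(velocity, "velocity")
  check_scalar_pos(spring_constant, "spring_constant")
  check_scalar_pos(noise_sd, "noise_sd", strict = FALSE)
  check_finite(specific_fraction, "specific_fraction")
  if (specific_fraction < 0 || specific_fraction > 1) {
    abort2("`specific_fraction` must lie in [0, 1]", "acidhesion_bad_arg")
  }
  for (nm in c("specific_force", "specific_stiffness",
               "nonspecific_force", "nonspecific_stiffness")) {
    v <- get(nm)
    check_finite(v, nm)
    if (length(v) != 2L || v[1] <= 0 || v[2] < 0) {
      abort2(sprintf("`%s` must be c(mean > 0, sd >= 0)", nm),
             "acidhesion_bad_arg")
    }
  }
  check_scalar_pos(events_per_curve_lambda, "events_per_curve_lambda",
                   strict = FALSE)
  check_scalar_pos(samples_per_curve, "samples_per_curve")
  if (samples_per_curve < 256) {
    abort2("`samples_per_curve` must be >= 256", "acidhesion_bad_arg")
  }
  structure(
    list(n_curves = as.integer(n_curves), velocity = velocity,
         spring_constant = spring_constant, noise_sd = noise_sd,
         specific_fraction = specific_fraction,
         specific_force = specific_force,
         specific_stiffness = specific_stiffness,
         nonspecific_force = nonspecific_force,
         nonspecific_stiffness = nonspecific_stiffness,
         events_per_curve_lambda = events_per_curve_lambda,
         samples_per_curve = as.integer(samples_per_curve),
         n_cells = as.integer(n_cells), condition = condition,
         seed = as.integer(seed)),
    class = "curve_sim_config"
  )
}

# draw (f_r, k_eff, class) for one planted event
draw_event_params <- function(cfg) {
  specific <- stats::runif(1) < cfg$specific_fraction
  if (specific) {
    fmu <- cfg$specific_force; kmu <- cfg$specific_stiffness
  } else {
    fmu <- cfg$nonspecific_force; kmu <- cfg$nonspecific_stiffness
  }
  # truncate at small positive values: negative force/stiffness is unphysical
  f_r <- max(5, stats::rnorm(1, fmu[1], fmu[2]))
  k_eff <- max(0.02, stats::rnorm(1, kmu[1], kmu[2]))
  list(f_r = f_r, k_eff = k_eff,
       class = if (specific) "specific" else "nonspecific")
}

#' Simulate AFM retraction curves with planted rupture events
#'
#' Each curve is a Gaussian baseline (adhesion negative, baseline ~0 pN) on a
#' 1 nm displacement grid, plus, for every planted event, a linear loading
#' ramp of slope `-k_eff` that reaches exactly `-F_R` at the rupture sample
#' and then returns instantaneously to baseline. Planted minima are separated
#' by at least three pre-rupture fit windows so the ground truth stays
#' unambiguous.
#'
#' @param config a [curve_sim_config()].
#' @return a list with elements
#'   \describe{
#'     \item{curves}{list of [force_curve()] objects,}
#'     \item{truth}{tibble of planted events: `curve_id`, `cell_id`,
#'       `condition`, `index` (sample of the force minimum),
#'       `f_r_pN`, `k_eff_pN_per_nm`, `f_prime_pN_per_s`, `class`,}
#'     \item{config}{the configuration used.}
#'   }
#' @export
#' @examples
#' sim <- simulate_force_curves(curve_sim_config(n_curves = 2, seed = 7))
#' sim$truth
simulate_force_curves <- function(config) {
  stopifnot(inherits(config, "curve_sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$samples_per_curve
  disp <- as.numeric(0:(n - 1L))           # nm, 1 nm spacing
  guard_pre <- 90L   # >= 3 x default pre-rupture fit window (30 samples)
  guard_post <- 60L  # room for the post-rupture baseline window

  curves <- vector("list", cfg$n_curves)
  truth <- vector("list", cfg$n_curves)
  for (ci in seq_len(cfg$n_curves)) {
    k_events <- stats::rpois(1, cfg$events_per_curve_lambda)
    params <- lapply(seq_len(k_events), function(i) draw_event_params(cfg))
    ramp_len <- vapply(params, function(p) {
      as.integer(ceiling(p$f_r / p$k_eff))
    }, integer(1))

    # sequential placement left to right with guard gaps; drop events that no
    # longer fit (rare at the default density)
    force <- stats::rnorm(n, 0, cfg$noise_sd)
    idx <- integer(0); kept <- integer(0)
    cursor <- guard_pre + 1L
    for (ei in seq_len(k_events)) {
      lo <- cursor + ramp_len[ei]
      hi <- n - guard_post
      if (lo > hi) next
      pos <- lo + as.integer(floor(stats::runif(1) * (hi - lo + 1L)))
      idx <- c(idx, pos); kept <- c(kept, ei)
      cursor <- pos + guard_pre + guard_post
    }
    for (j in seq_along(kept)) {
      p <- params[[kept[j]]]
      pos <- idx[j]
      d_start <- disp[pos] - p$f_r / p$k_eff
      jr <- max(1L, pos - ramp_len[kept[j]]):pos
      depth <- pmax(0, p$k_eff * (disp[jr] - d_start))
      force[jr] <- force[jr] - depth
    }
    cell <- sprintf("cell%02d", ((ci - 1L) %% cfg$n_cells) + 1L)
    cid <- sprintf("curve%04d", ci)
    curves[[ci]] <- force_curve(
      displacement = disp, force = force, velocity = cfg$velocity,
      spring_constant = cfg$spring_constant, cell_id = cell,
      condition = cfg$condition, curve_id = cid
    )
    truth[[ci]] <- if (length(kept)) {
      tibble(
        curve_id = cid, cell_id = cell, condition = cfg$condition,
        index = idx,
        f_r_pN = vapply(params[kept], `[[`, numeric(1), "f_r"),
        k_eff_pN_per_nm = vapply(params[kept], `[[`, numeric(1), "k_eff"),
        class = vapply(params[kept], `[[`, character(1), "class")
      )
    } else NULL
  }
  truth <- dplyr::bind_rows(truth)
  if (nrow(truth)) {
    truth$f_prime_pN_per_s <- truth$k_eff_pN_per_nm * cfg$velocity
  }
  list(curves = curves, truth = truth, config = cfg)
}

#' Simulate rupture-event tables directly
#'
#' Draws per-event `(F_R, k_eff)` pairs from the same two populations as
#' [simulate_force_curves()] without constructing force traces. This is the
#' generator for studying the specificity gate and the binding-frequency
#' statistics at the event level, where curve reconstruction and detector
#' recall are not the quantity of interest.
#'
#' @param n_cells number of cells.
#' @param events_per_cell events observed on each cell.
#' @param specific_fraction probability an event is specific.
#' @param velocity cantilever velocity (nm/s) used for `F' = k_eff * v`.
#' @param specific_force,specific_stiffness,nonspecific_force,nonspecific_stiffness
#'   population parameters `c(mean, sd)` as in [curve_sim_config()].
#' @param condition condition label.
#' @param seed integer seed.
#' @return tibble with `cell_id`, `condition`, `f_r_pN`, `k_eff_pN_per_nm`,
#'   `f_prime_pN_per_s`, `class`.
#' @export
simulate_rupture_events <- function(n_cells = 5,
                                    events_per_cell = 200,
                                    specific_fraction = 0.168,
                                    velocity = 5000,
                                    specific_force = c(90, 15),
                                    specific_stiffness = c(0.8, 0.1),
                                    nonspecific_force = c(30, 10),
                                    nonspecific_stiffness = c(0.2, 0.05),
                                    condition = "pH7.4",
                                    seed = 1) {
  cfg <- curve_sim_config(
    n_curves = 1, velocity = velocity,
    specific_fraction = specific_fraction,
    specific_force = specific_force,
    specific_stiffness = specific_stiffness,
    nonspecific_force = nonspecific_force,
    nonspecific_stiffness = nonspecific_stiffness,
    seed = seed
  )
  set.seed(cfg$seed)
  n_tot <- n_cells * events_per_cell
  ev <- lapply(seq_len(n_tot), function(i) draw_event_params(cfg))
  tibble(
    cell_id = rep(sprintf("cell%02d", seq_len(n_cells)),
                  each = events_per_cell),
    condition = condition,
    f_r_pN = vapply(ev, `[[`, numeric(1), "f_r"),
    k_eff_pN_per_nm = vapply(ev, `[[`, numeric(1), "k_eff"),
    f_prime_pN_per_s = vapply(ev, `[[`, numeric(1), "k_eff") * velocity,
    class = vapply(ev, `[[`, character(1), "class")
  )
}
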