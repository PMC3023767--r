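#' Force-displacement retraction curve
#'
#' Container for one AFM retraction record. Forces follow the convention that
#' adhesion is negative and the free-cantilever baseline is ~0 pN; the
#' displacement axis is monotone increasing during retraction.
#'
#' @param displacement displacement samples, nm (monotone non-decreasing).
#' @param force force samples, pN (same length as `displacement`).
#' @param velocity cantilever retraction velocity, nm/s.
#' @param spring_constant cantilever spring constant, pN/nm.
#' @param cell_id,condition,curve_id metadata labels.
#' @return an object of class `force_curve`.
#' @export
force_curve <- function(displacement, force, velocity, spring_constant,
                        cell_id = "cell01", condition = "pH7.4",
                        curve_id = "curve0001") {
  check_finite(displacement, "displacement")
  check_finite(force, "force")
  if (length(displacement) != length(force) || length(force) < 16L) {
    abort2("displacement and force must have equal length >= 16",
           "acidhesion_bad_curve")
  }
  if (is.unsorted(displacement)) {
    abort2("displacement must be monotone non-decreasing during retraction",
           "acidhesion_bad_curve")
  }
  check_scalar_pos(velocity, "velocity")
  check_scalar_pos(spring_constant, "spring_constant")
  structure(
    list(displacement = as.numeric(displacement), force = as.numeric(force),
         velocity = velocity, spring_constant = spring_constant,
         cell_id = cell_id, condition = condition, curve_id = curve_id),
    class = "force_curve"
  )
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf(
    "<force_curve %s> %d samples, %.0f-%.0f nm, v = %g nm/s, k = %g pN/nm (%s, %s)\n",
    x$curve_id, length(x$force), min(x$displacement), max(x$displacement),
    x$velocity, x$spring_constant, x$cell_id, x$condition))
  invisible(x)
}

# robust baseline-noise SD from the final fraction of the trace. Estimated
# from first differences (MAD / sqrt(2)): a loading ramp shifts differences
# by only its per-sample slope and a rupture jump is a single outlier, so an
# event sitting in the tail does not inflate the estimate the way a
# value-based MAD would.
baseline_noise_sd <- function(force, tail_fraction = 0.2) {
  n <- length(force)
  tail_seg <- force[max(1L, floor(n * (1 - tail_fraction))):n]
  stats::mad(diff(tail_seg)) / sqrt(2)
}

#' Detect rupture events on a retraction curve
#'
#' Unbinding events appear as upward jumps in the retraction force trace.
#' The trace is smoothed with a centred moving average of width `w`; any
#' position where the smoothed force rises by at least `theta` within at most
#' 3 samples marks a candidate jump. Adjacent candidates are clustered
#' (refractory gap); the jump is then localized on the *raw* trace at the
#' largest single-sample rise in the cluster window (the rupture step is the
#' sharpest feature of the trace, so this pins the sample far more precisely
#' than a raw-force argmin, which wanders along the shallow loading ramp
#' under noise), and the event index is the raw-force minimum in the three
#' samples up to and including the step. On noiseless curves the planted
#' minimum is recovered exactly.
#'
#' @param curve a [force_curve()].
#' @param w odd smoothing window, samples.
#' @param theta jump threshold in pN, or `"auto"` for
#'   `max(20, 4 * robust noise SD)` with the noise SD estimated from the
#'   final fifth of the trace.
#' @param refractory minimum sample gap merged into a single event.
#' @return integer vector of event indices (force minima), sorted; empty when
#'   no event is found.
#' @export
detect_ruptures <- function(curve, w = 5L, theta = "auto", refractory = 3L) {
  stopifnot(inherits(curve, "force_curve"))
  f <- curve$force
  n <- length(f)
  if (n < 64L) abort2("trace too short for event detection",
                      "acidhesion_bad_curve")
  w <- as.integer(w)
  if (w < 1L || w %% 2L == 0L) abort2("`w` must be odd and >= 1",
                                      "acidhesion_bad_arg")
  if (identical(theta, "auto")) {
    theta <- max(20, 4 * baseline_noise_sd(f))
  }
  check_scalar_pos(theta, "theta")

  s <- moving_average(f, w)
  # largest forward rise within <= 3 samples
  rise <- rep(-Inf, n)
  for (lag in 1:3) {
    idx <- seq_len(n - lag)
    rise[idx] <- pmax(rise[idx], s[idx + lag] - s[idx])
  }
  cand <- which(rise >= theta)
  if (!length(cand)) return(integer(0))

  # cluster candidates separated by more than (refractory + w) samples
  gap <- diff(cand)
  starts <- cand[c(TRUE, gap > (refractory + w))]

  events <- vapply(starts, function(i0) {
    win <- max(1L, i0 - w):min(n - 1L, i0 + w + 3L)
    steps <- f[win + 1L] - f[win]
    j <- win[which.max(steps)]          # sample just before the sharpest rise
    pre <- max(1L, j - 2L):j
    pre[which.min(f[pre])]
  }, integer(1))
  events <- sort(unique(events))
  # enforce the refractory separation on the refined indices too
  if (length(events) > 1L) {
    keep <- c(TRUE, diff(events) > refractory)
    events <- events[keep]
  }
  events
}

#' Rupture force of a detected event
#'
#' `F_R` is the difference between the average force following rupture and
#' the force at the minimum: the mean force over `m_post` samples after the
#' jump minus `force[index]`. The post-rupture window starts `jump_skip` samples after
#' the minimum (the jump completes within <= 3 samples) and is truncated at
#' the next event or the end of the trace.
#'
#' @param curve a [force_curve()].
#' @param index sample index of the event minimum.
#' @param m_post post-rupture baseline window, samples.
#' @param next_index index of the following event (optional; `NA` if none).
#' @param jump_skip samples skipped after the minimum before the baseline
#'   window starts.
#' @return rupture force in pN, or `NA` (with a warning) when fewer than 3
#'   post-rupture samples are available.
#' @export
rupture_force <- function(curve, index, m_post = 50L, next_index = NA,
                          jump_skip = 3L) {
  stopifnot(inherits(curve, "force_curve"))
  f <- curve$force
  n <- length(f)
  if (index < 1L || index > n) abort2("event index out of range",
                                      "acidhesion_bad_arg")
  lo <- index + jump_skip
  hi <- min(n, index + jump_skip + m_post - 1L)
  if (!is.na(next_index)) hi <- min(hi, next_index - refit_guard())
  if (hi - lo + 1L < 3L) {
    warning("fewer than 3 post-rupture samples; event unquantifiable")
    return(NA_real_)
  }
  mean(f[lo:hi]) - f[index]
}

# minimum sample gap kept clear of a neighbouring event
refit_guard <- function() 3L

#' Pre-rupture stiffness and effective loading rate
#'
#' `k_eff` is the magnitude of the least-squares slope of force against
#' displacement over the `m_pre` samples ending at the event minimum
#' (inclusive); the effective loading rate is `F' = k_eff * v` with `v` the
#' cantilever retraction velocity.
#'
#' @param curve a [force_curve()].
#' @param index sample index of the event minimum.
#' @param m_pre pre-rupture fit window, samples.
#' @param prev_index index of the preceding event (optional), used to refuse
#'   windows that overlap it.
#' @return list with `k_eff` (pN/nm), `f_prime` (pN/s) and `k_eff_se`
#'   (closed-form slope standard error, pN/nm); all `NA` when the window is
#'   unavailable.
#' @export
effective_loading_rate <- function(curve, index, m_pre = 30L,
                                   prev_index = NA) {
  stopifnot(inherits(curve, "force_curve"))
  lo <- index - m_pre + 1L
  if (lo < 1L || (!is.na(prev_index) && lo <= prev_index + refit_guard())) {
    warning("insufficient pre-rupture samples; event unquantifiable")
    return(list(k_eff = NA_real_, f_prime = NA_real_, k_eff_se = NA_real_))
  }
  x <- curve$displacement[lo:index]
  y <- curve$force[lo:index]
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  slope <- sum(xc * y) / sxx
  res <- y - mean(y) - slope * xc
  se <- if (length(x) > 2L) sqrt(sum(res^2) / (length(x) - 2L) / sxx) else NA_real_
  list(k_eff = abs(slope), f_prime = abs(slope) * curve$velocity,
       k_eff_se = se)
}

#' Specificity gate thresholds
#'
#' Events with `F_R > f_r_min` and `F' > f_prime_min` (strict inequalities)
#' are taken to be specific receptor-ligand ruptures; defaults are 50 pN and
#' 2000 pN/s.
#'
#' @param f_r_min rupture-force threshold, pN.
#' @param f_prime_min loading-rate threshold, pN/s.
#' @return an object of class `gate_thresholds`.
#' @export
gate_thresholds <- function(f_r_min = 50, f_prime_min = 2000) {
  check_scalar_pos(f_r_min, "f_r_min")
  check_scalar_pos(f_prime_min, "f_prime_min")
  structure(list(f_r_min = f_r_min, f_prime_min = f_prime_min),
            class = "gate_thresholds")
}

#' Classify events into force/loading-rate quadrants
#'
#' Quadrant II (`F_R > f_r_min` and `F' > f_prime_min`, both strict) holds the
#' specific events. Quadrant I: `F_R <= f_r_min`, `F' > f_prime_min`;
#' quadrant III: both at or below threshold; quadrant IV: `F_R > f_r_min`,
#' `F' <= f_prime_min`.
#'
#' @param f_r rupture forces, pN.
#' @param f_prime effective loading rates, pN/s.
#' @param gate a [gate_thresholds()].
#' @return tibble with `f_r_pN`, `f_prime_pN_per_s`, `quadrant`
#'   (factor I-IV) and `specific` (logical).
#' @export
#' @examples
#' classify_specific(c(60, 50, 60), c(2500, 2500, 1500))
classify_specific <- function(f_r, f_prime, gate = gate_thresholds()) {
  stopifnot(inherits(gate, "gate_thresholds"))
  check_finite(f_r, "f_r")
  check_finite(f_prime, "f_prime")
  if (length(f_r) != length(f_prime)) {
    abort2("f_r and f_prime must have equal length", "acidhesion_bad_arg")
  }
  high_f <- f_r > gate$f_r_min
  high_r <- f_prime > gate$f_prime_min
  quadrant <- factor(
    ifelse(high_f & high_r, "II",
           ifelse(!high_f & high_r, "I",
                  ifelse(high_f & !high_r, "IV", "III"))),
    levels = c("I", "II", "III", "IV")
  )
  tibble(f_r_pN = f_r, f_prime_pN_per_s = f_prime,
         quadrant = quadrant, specific = high_f & high_r)
}

#' Detect and quantify every rupture event on a set of curves
#'
#' Runs [detect_ruptures()], [rupture_force()], [effective_loading_rate()] and
#' [classify_specific()] over a list of curves and assembles the event table.
#'
#' @param curves list of [force_curve()] objects.
#' @param gate a [gate_thresholds()].
#' @param w,theta,refractory detector parameters, see [detect_ruptures()].
#' @param m_pre,m_post estimation windows, samples.
#' @return tibble with one row per quantifiable event: curve/cell/condition
#'   ids, `index`, `f_r_pN`, `k_eff_pN_per_nm`, `f_prime_pN_per_s`,
#'   `quadrant`, `specific`.
#' @export
analyze_curves <- function(curves, gate = gate_thresholds(),
                           w = 5L, theta = "auto", refractory = 3L,
                           m_pre = 30L, m_post = 50L) {
  rows <- lapply(curves, function(cv) {
    idx <- detect_ruptures(cv, w = w, theta = theta, refractory = refractory)
    if (!length(idx)) return(NULL)
    nxt <- c(idx[-1], NA)
    prv <- c(NA, idx[-length(idx)])
    ev <- lapply(seq_along(idx), function(j) {
      fr <- suppressWarnings(
        rupture_force(cv, idx[j], m_post = m_post, next_index = nxt[j]))
      lr <- suppressWarnings(
        effective_loading_rate(cv, idx[j], m_pre = m_pre,
                               prev_index = prv[j]))
      tibble(curve_id = cv$curve_id, cell_id = cv$cell_id,
             condition = cv$condition, index = idx[j], f_r_pN = fr,
             k_eff_pN_per_nm = lr$k_eff, f_prime_pN_per_s = lr$f_prime)
    })
    dplyr::bind_rows(ev)
  })
  events <- dplyr::bind_rows(rows)
  if (!nrow(events)) return(events)
  events <- events[is.finite(events$f_r_pN) &
                     is.finite(events$f_prime_pN_per_s), , drop = FALSE]
  cls <- classify_specific(events$f_r_pN, events$f_prime_pN_per_s, gate)
  events$quadrant <- cls$quadrant
  events$specific <- cls$specific
  events
}

#' Per-cell specific binding frequency
#'
#' `f_b` is the number of specific unbinding events on a cell divided by the
#' total number of events observed on that cell. Cells with zero events are
#' excluded with a warning (the frequency is undefined for them).
#'
#' @param events tibble with columns `cell_id`, `condition` and `specific`
#'   (logical), e.g. from [analyze_curves()].
#' @return tibble with `cell_id`, `condition`, `n_events_total`,
#'   `n_events_specific`, `f_b`.
#' @export
binding_frequency <- function(events) {
  if (!nrow(events)) abort2("no events supplied", "acidhesion_bad_arg")
  stopifnot(all(c("cell_id", "specific") %in% names(events)))
  if (!"condition" %in% names(events)) events$condition <- "unlabelled"
  out <- dplyr::summarise(
    dplyr::group_by(events, .data$condition, .data$cell_id),
    n_events_total = dplyr::n(),
    n_events_specific = sum(.data$specific),
    f_b = sum(.data$specific) / dplyr::n(),
    .groups = "drop"
  )
  out
}

#' Relative specific binding frequency
#'
#' Normalizes each cell's `f_b` to the mean `f_b` over cells of the reference
#' condition, so the reference-condition mean of `f_b_rel` is exactly 1.
#'
#' @param summaries per-cell tibble from [binding_frequency()].
#' @param reference reference condition label (e.g. `"pH7.4"`).
#' @return `summaries` with an added `f_b_rel` column.
#' @export
relative_binding_frequency <- function(summaries, reference = "pH7.4") {
  stopifnot(all(c("condition", "f_b") %in% names(summaries)))
  ref <- summaries$f_b[summaries$condition == reference]
  if (!length(ref)) abort2("reference condition has no cells",
                           "acidhesion_bad_arg")
  m <- mean(ref)
  if (m == 0) abort2("reference-condition mean f_b is zero",
                     "acidhesion_bad_arg")
  summaries$f_b_rel <- summaries$f_b / m
  summaries
}

#' Condition-level binding summary
#'
#' Means and SEMs of `f_b` (and `f_b_rel` when present) with the cell as the
#' unit of replication, plus quadrant occupancy fractions over all events
#' pooled within each condition.
#'
#' @param summaries per-cell tibble from [binding_frequency()] /
#'   [relative_binding_frequency()].
#' @param events event tibble with `condition` and `quadrant` columns
#'   (optional; quadrant fractions omitted when `NULL`).
#' @return list with tibbles `cells` (per-condition mean/SEM/n; SEM is `NA`
#'   for single-cell conditions) and `quadrants` (pooled occupancy fractions),
#'   the latter `NULL` when `events` is not given.
#' @export
summarize_binding <- function(summaries, events = NULL) {
  cells <- dplyr::summarise(
    dplyr::group_by(summaries, .data$condition),
    n_cells = dplyr::n(),
    f_b_mean = mean(.data$f_b),
    f_b_sem = if (dplyr::n() >= 2) stats::sd(.data$f_b) / sqrt(dplyr::n())
              else NA_real_,
    f_b_rel_mean = if ("f_b_rel" %in% names(summaries))
      mean(.data$f_b_rel) else NA_real_,
    f_b_rel_sem = if ("f_b_rel" %in% names(summaries) && dplyr::n() >= 2)
      stats::sd(.data$f_b_rel) / sqrt(dplyr::n()) else NA_real_,
    .groups = "drop"
  )
  quads <- NULL
  if (!is.null(events) && nrow(events)) {
    quads <- dplyr::summarise(
      dplyr::group_by(events, .data$condition, .data$quadrant,
                      .drop = FALSE),
      n = dplyr::n(), .groups = "drop_last"
    )
    quads <- dplyr::mutate(quads, fraction = .data$n / sum(.data$n))
    quads <- dplyr::ungroup(quads)
  }
  list(cells = cells, quadrants = quads)
}
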