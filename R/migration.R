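#' Cell-centroid track
#'
#' @param x,y centroid coordinates, um, one value per frame (>= 3 frames,
#'   equally spaced in time).
#' @param dt frame interval, min.
#' @param cell_id,condition metadata labels.
#' @param ligand_ug_per_ml ligand (e.g. fibronectin) coating concentration,
#'   ug/ml; optional.
#' @param excluded logical flag marking cells excluded from analysis (cells
#'   that divided or touched another cell); exclusion is an input flag, not
#'   detected here.
#' @return an object of class `track`.
#' @export
track <- function(x, y, dt, cell_id = "cell001", condition = "pH7.4",
                  ligand_ug_per_ml = NA_real_, excluded = FALSE) {
  check_finite(x, "x"); check_finite(y, "y")
  if (length(x) != length(y) || length(x) < 3L) {
    abort2("track needs x and y of equal length >= 3", "acidhesion_bad_track")
  }
  check_scalar_pos(dt, "dt")
  structure(
    list(x = as.numeric(x), y = as.numeric(y), dt = dt, cell_id = cell_id,
         condition = condition, ligand_ug_per_ml = ligand_ug_per_ml,
         excluded = isTRUE(excluded)),
    class = "track"
  )
}

#' @export
print.track <- function(x, ...) {
  cat(sprintf("<track %s> %d frames, dt = %g min (%s)%s\n",
              x$cell_id, length(x$x), x$dt, x$condition,
              if (x$excluded) " [excluded]" else ""))
  invisible(x)
}

#' Mean squared displacement by the method of non-overlapping intervals
#'
#' For interval length `n` frames the trajectory is partitioned from the first
#' frame into consecutive disjoint segments of `n` frames; the MSD at
#' `t_n = n * dt` is the mean over segments of the squared end-to-start
#' displacement. Frames beyond the last full segment are dropped, so each
#' displacement enters at most one segment per interval: segments are
#' statistically independent under the model, unlike overlapping-window
#' estimators. `n_segments(t_n) = floor((frames - 1) / n)`.
#'
#' @param trk a [track()].
#' @return an `msd_curve`: tibble with `interval` (frames), `t_min`,
#'   `msd_um2`, `n_segments`, plus a `dt` attribute.
#' @export
msd_nonoverlapping <- function(trk) {
  stopifnot(inherits(trk, "track"))
  nf <- length(trk$x)
  ndisp <- nf - 1L
  rows <- lapply(seq_len(ndisp), function(n) {
    nseg <- ndisp %/% n
    starts <- (seq_len(nseg) - 1L) * n + 1L
    ends <- starts + n
    d2 <- (trk$x[ends] - trk$x[starts])^2 + (trk$y[ends] - trk$y[starts])^2
    tibble(interval = n, t_min = n * trk$dt, msd_um2 = mean(d2),
           n_segments = nseg)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "dt") <- trk$dt
  class(out) <- c("msd_curve", class(out))
  out
}

#' Cell speed from the shortest MSD interval
#'
#' The root mean squared displacement at the shortest interval divided by the
#' interval time: `S = sqrt(msd(dt)) / dt`.
#'
#' @param msd an `msd_curve` from [msd_nonoverlapping()].
#' @return speed, um/min.
#' @export
cell_speed <- function(msd) {
  stopifnot(inherits(msd, "msd_curve"))
  first <- msd[msd$interval == 1L, ]
  if (!nrow(first)) abort2("MSD is missing the first interval",
                           "acidhesion_bad_arg")
  sqrt(first$msd_um2) / attr(msd, "dt")
}

#' Persistent-random-walk MSD model
#'
#' Evaluates `2 S^2 P [t - P (1 - e^(-t/P))]`. For `t/P < 1e-4` a series
#' branch `S^2 t^2 (1 - x/3 + x^2/12)` (x = t/P) avoids catastrophic
#' cancellation; the model tends to `S^2 t^2` (ballistic) for `t << P` and to
#' `2 S^2 P t` (diffusive) for `t >> P`.
#'
#' @param t interval time(s), min (>= 0).
#' @param S root-mean-square speed, um/min (>= 0).
#' @param P persistence time, min (> 0).
#' @return model MSD, um^2 (vectorized over `t`).
#' @export
#' @examples
#' prw_msd(1, S = 1, P = 1)  # 2/e
prw_msd <- function(t, S, P) {
  if (any(P <= 0)) abort2("`P` must be > 0", "acidhesion_bad_arg")
  if (any(t < 0) || any(S < 0)) abort2("`t` and `S` must be >= 0",
                                       "acidhesion_bad_arg")
  x <- t / P
  out <- 2 * S^2 * P * (t - P * (1 - exp(-x)))
  small <- x < 1e-4
  if (any(small)) {
    xs <- x[small]
    out[small] <- (S^2 * t[small]^2) * (1 - xs / 3 + xs^2 / 12)
  }
  out
}

#' Fit the persistent-random-walk model to an MSD curve
#'
#' Nonlinear least squares of [prw_msd()] against the measured MSD. Only
#' intervals with at least `min_segments` disjoint segments are usable
#' (single-segment long-interval estimates are degenerate), and by default
#' only the first `max_interval_fraction` of the usable intervals enter the
#' fit — the few-segment tail of the MSD curve has such high variance that it
#' would otherwise dominate the unweighted residual. Start values:
#' `S0` from [cell_speed()], `P0` the median fitted interval time; bounds
#' `S > 0`, `P` in `(dt/100, 100 * t_max)`. `R^2 = 1 - SS_res/SS_tot` is
#' computed on the fitted points, unweighted.
#'
#' @param msd an `msd_curve`.
#' @param max_interval_fraction fraction of intervals used (default 0.5).
#' @param min_segments minimum disjoint segments per fitted interval.
#' @param init optional `c(S, P)` start values.
#' @return a `prw_fit` list: `S`, `P`, `r_squared`, `converged`, `n_points`,
#'   and the fitted points tibble.
#' @export
fit_prw <- function(msd, max_interval_fraction = 0.5, min_segments = 2L,
                    init = NULL) {
  stopifnot(inherits(msd, "msd_curve"))
  dt <- attr(msd, "dt")
  usable <- msd[msd$n_segments >= min_segments, ]
  n_max <- max(usable$interval)
  pts <- usable[usable$interval <=
                  max(4L, floor(n_max * max_interval_fraction)), ]
  if (nrow(pts) < 4L) abort2("need at least 4 usable MSD intervals",
                             "acidhesion_bad_arg")
  t_max <- max(pts$t_min)
  if (is.null(init)) {
    s0 <- max(cell_speed(msd), 1e-6)
    p0 <- stats::median(pts$t_min)
  } else {
    s0 <- init[1]; p0 <- init[2]
  }
  fit <- try(minpack.lm::nlsLM(
    msd_um2 ~ prw_msd(t_min, S, P),
    data = pts,
    start = list(S = s0, P = p0),
    lower = c(S = 1e-9, P = dt / 100),
    upper = c(S = Inf, P = 100 * t_max),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  ), silent = TRUE)
  if (inherits(fit, "try-error")) {
    out <- list(S = NA_real_, P = NA_real_, r_squared = -Inf,
                converged = FALSE, n_points = nrow(pts), points = pts)
  } else {
    cf <- stats::coef(fit)
    ss_res <- sum(stats::resid(fit)^2)
    ss_tot <- sum((pts$msd_um2 - mean(pts$msd_um2))^2)
    r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
    out <- list(S = unname(cf["S"]), P = unname(cf["P"]), r_squared = r2,
                converged = TRUE, n_points = nrow(pts), points = pts)
  }
  class(out) <- "prw_fit"
  out
}

#' @export
print.prw_fit <- function(x, ...) {
  cat(sprintf("<prw_fit> S = %.4g um/min, P = %.4g min, R^2 = %.4f (%s)\n",
              x$S, x$P, x$r_squared,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Analyze a set of tracks
#'
#' Runs the full per-cell chain: non-overlapping-interval MSD, speed, PRW fit.
#' Tracks flagged `excluded` (divided / touched another cell) are dropped.
#'
#' @param tracks list of [track()] objects.
#' @param ... passed to [fit_prw()].
#' @return tibble with one row per analyzed cell: `cell_id`, `condition`,
#'   `ligand_ug_per_ml`, `speed_um_min`, `S`, `P`, `r_squared`, `converged`.
#' @export
analyze_tracks <- function(tracks, ...) {
  rows <- lapply(tracks, function(trk) {
    if (trk$excluded) return(NULL)
    msd <- msd_nonoverlapping(trk)
    fit <- fit_prw(msd, ...)
    tibble(cell_id = trk$cell_id, condition = trk$condition,
           ligand_ug_per_ml = trk$ligand_ug_per_ml,
           speed_um_min = cell_speed(msd),
           S = fit$S, P = fit$P, r_squared = fit$r_squared,
           converged = fit$converged)
  })
  dplyr::bind_rows(rows)
}

#' Filter fits by goodness of fit and average speeds per condition
#'
#' Cells with `R^2 < r2_min` (strict) are not included. Reports the mean
#' speed +/- SEM over surviving cells and flags conditions with fewer than
#' `min_cells` survivors.
#'
#' @param cells per-cell tibble from [analyze_tracks()] (needs
#'   `speed_um_min`, `r_squared`, `condition`; `ligand_ug_per_ml` is carried
#'   through when present).
#' @param r2_min goodness-of-fit threshold (default 0.5).
#' @param min_cells minimum survivors per condition before a warning flag is
#'   raised (default 40).
#' @return tibble per condition (and ligand concentration when present):
#'   `n_cells`, `n_retained`, `speed_mean`, `speed_sem`, `underpowered`.
#' @export
filter_and_average <- function(cells, r2_min = 0.5, min_cells = 40L) {
  stopifnot(all(c("speed_um_min", "r_squared", "condition") %in% names(cells)))
  keep <- cells$r_squared >= r2_min   # drop strictly-below-threshold cells
  if (!any(keep)) abort2("no cells survive the R^2 filter",
                         "acidhesion_bad_arg")
  grp_vars <- intersect(c("condition", "ligand_ug_per_ml"), names(cells))
  grouped <- dplyr::group_by(cells,
                             dplyr::across(dplyr::all_of(grp_vars)))
  out <- dplyr::summarise(
    grouped,
    n_cells = dplyr::n(),
    n_retained = sum(.data$r_squared >= r2_min),
    speed_mean = mean(.data$speed_um_min[.data$r_squared >= r2_min]),
    speed_sem = if (sum(.data$r_squared >= r2_min) >= 2)
      stats::sd(.data$speed_um_min[.data$r_squared >= r2_min]) /
        sqrt(sum(.data$r_squared >= r2_min)) else NA_real_,
    .groups = "drop"
  )
  out$underpowered <- out$n_retained < min_cells
  out
}

#' Speed as a function of ligand coating concentration
#'
#' Tabulates mean speed against ligand concentration within each condition,
#' finds the concentration of maximum mean speed per condition (all tied
#' concentrations reported), and flags a leftward shift when the acidic
#' condition peaks at a lower concentration than the neutral one — the
#' signature of increased adhesiveness requiring less ligand for optimal
#' traction.
#'
#' @param summaries tibble with `condition`, `ligand_ug_per_ml`, `speed_mean`
#'   (e.g. from [filter_and_average()]); other columns carried through.
#' @param acidic,neutral condition labels compared for the shift flag.
#' @return list with `table` (input, ordered), `argmax` (per condition, all
#'   tied maxima) and `leftward_shift` (logical; `NA` when either label is
#'   absent).
#' @export
speed_vs_ligand <- function(summaries, acidic = "pH6.5", neutral = "pH7.4") {
  stopifnot(all(c("condition", "ligand_ug_per_ml", "speed_mean")
                %in% names(summaries)))
  conds <- split(summaries, summaries$condition)
  if (any(vapply(conds, nrow, integer(1)) < 2)) {
    abort2("need >= 2 ligand concentrations per condition",
           "acidhesion_bad_arg")
  }
  argmax <- dplyr::bind_rows(lapply(conds, function(df) {
    mx <- max(df$speed_mean)
    tibble(condition = df$condition[1],
           ligand_ug_per_ml = df$ligand_ug_per_ml[df$speed_mean == mx],
           speed_mean = mx)
  }))
  shift <- NA
  if (acidic %in% argmax$condition && neutral %in% argmax$condition) {
    a <- min(argmax$ligand_ug_per_ml[argmax$condition == acidic])
    n <- min(argmax$ligand_ug_per_ml[argmax$condition == neutral])
    shift <- a < n
  }
  list(
    table = dplyr::arrange(summaries, .data$condition,
                           .data$ligand_ug_per_ml),
    argmax = argmax,
    leftward_shift = shift
  )
}
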