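#' Membrane edge-position trace from a kymograph
#'
#' @param position_px edge position per frame, px.
#' @param pixel_size spatial calibration, um/px.
#' @param frame_interval s between frames.
#' @param interpolated logical per frame, marking positions filled in from
#'   neighbours (see [extract_edge_trace()]).
#' @param cell_id,condition metadata labels.
#' @return an object of class `edge_trace`.
#' @export
edge_trace <- function(position_px, pixel_size, frame_interval,
                       interpolated = NULL,
                       cell_id = "cell01", condition = "pH7.4") {
  check_finite(position_px, "position_px")
  check_scalar_pos(pixel_size, "pixel_size")
  check_scalar_pos(frame_interval, "frame_interval")
  if (is.null(interpolated)) interpolated <- rep(FALSE, length(position_px))
  structure(
    list(position_px = as.numeric(position_px), pixel_size = pixel_size,
         frame_interval = frame_interval,
         interpolated = as.logical(interpolated),
         cell_id = cell_id, condition = condition),
    class = "edge_trace"
  )
}

#' @export
print.edge_trace <- function(x, ...) {
  cat(sprintf("<edge_trace %s> %d frames @ %g s, %g um/px (%s)\n",
              x$cell_id, length(x$position_px), x$frame_interval,
              x$pixel_size, x$condition))
  invisible(x)
}

#' Cell-shape metrics: area, perimeter, circularity
#'
#' Circularity is `4 * pi * A / P^2`: 1 for a circle, approaching 0 for
#' elongated or dendritic shapes. Input is either a simple closed polygon
#' (shoelace area, edge-sum perimeter) or a single-component binary mask
#' (pixel-count area, exposed-pixel-edge perimeter; note the staircase
#' perimeter biases circularity low for smooth diagonal boundaries — the
#' polygon route is preferred when outlines are available). The reported
#' `circularity` is clipped at 1; the raw value is kept in
#' `circularity_raw`.
#'
#' @param outline two-column matrix of polygon vertices (first vertex not
#'   repeated), or a binary matrix mask (values 0/1).
#' @param pixel_size um per pixel for mask input (area/perimeter scale).
#' @param cell_id,condition metadata labels.
#' @return one-row tibble: `cell_id`, `condition`, `area_um2`, `perim_um`,
#'   `circularity_raw`, `circularity`.
#' @export
#' @examples
#' sq <- simulate_shapes("rectangle", list(width = 2, height = 2))
#' shape_metrics(sq$vertices)   # circularity pi/4
shape_metrics <- function(outline, pixel_size = 1,
                          cell_id = "cell01", condition = "pH7.4") {
  is_mask <- is.matrix(outline) && all(outline %in% c(0, 1)) &&
    nrow(outline) > 2 && ncol(outline) > 2 && any(outline == 1) &&
    !is.null(dim(outline)) && all(outline == round(outline))
  if (is_mask && ncol(outline) != 2) {
    lab <- EBImage::bwlabel(outline)
    if (max(lab) != 1L) {
      abort2("mask must contain exactly one connected component",
             "acidhesion_bad_shape")
    }
    area <- sum(outline) * pixel_size^2
    perim <- mask_boundary_length(outline) * pixel_size
  } else {
    v <- as.matrix(outline)
    if (ncol(v) != 2 || nrow(v) < 3) {
      abort2("polygon needs a two-column vertex matrix with >= 3 rows",
             "acidhesion_bad_shape")
    }
    if (polygon_self_intersects(v)) {
      abort2("polygon is self-intersecting", "acidhesion_bad_shape")
    }
    area <- abs(polygon_area_signed(v))
    perim <- polygon_perimeter(v)
  }
  if (area <= 0 || perim <= 0) {
    abort2("degenerate outline: zero area or perimeter",
           "acidhesion_bad_shape")
  }
  c_raw <- 4 * pi * area / perim^2
  tibble(cell_id = cell_id, condition = condition, area_um2 = area,
         perim_um = perim, circularity_raw = c_raw,
         circularity = pmin(1, c_raw))
}

# boundary length of a binary mask = number of pixel edges exposed to
# background or to the image border
mask_boundary_length <- function(m) {
  pad <- matrix(0, nrow(m) + 2, ncol(m) + 2)
  pad[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
  core <- pad[2:(nrow(m) + 1), 2:(ncol(m) + 1)]
  up    <- pad[1:nrow(m), 2:(ncol(m) + 1)]
  down  <- pad[3:(nrow(m) + 2), 2:(ncol(m) + 1)]
  left  <- pad[2:(nrow(m) + 1), 1:ncol(m)]
  right <- pad[2:(nrow(m) + 1), 3:(ncol(m) + 2)]
  sum(core == 1 & up == 0) + sum(core == 1 & down == 0) +
    sum(core == 1 & left == 0) + sum(core == 1 & right == 0)
}

#' Area response to media pH switches
#'
#' For each media-change timestamp, finds the projected-area peak within a
#' window after the switch on a 3-point-smoothed series, and reports the time
#' to peak and the peak / pre-switch amplitude ratio. A window extending past
#' the end of the series is truncated with a warning; when the area never
#' rises above its pre-switch value the time to peak is undefined (`NA`).
#'
#' @param times sample times, min (strictly increasing).
#' @param areas projected areas, um^2 (> 0).
#' @param switch_times media-change timestamps, min.
#' @param window post-switch search window, min (default 60).
#' @return tibble: `switch_time`, `time_to_peak_min`, `amplitude_ratio`,
#'   `truncated`.
#' @export
area_oscillation <- function(times, areas, switch_times, window = 60) {
  check_finite(times, "times"); check_finite(areas, "areas")
  if (length(times) != length(areas)) {
    abort2("times and areas must have equal length", "acidhesion_bad_arg")
  }
  if (any(diff(times) <= 0)) abort2("times must be strictly increasing",
                                    "acidhesion_bad_arg")
  if (any(areas <= 0)) abort2("areas must be > 0", "acidhesion_bad_arg")
  if (!length(switch_times)) abort2("need >= 1 switch time",
                                    "acidhesion_bad_arg")
  smooth <- moving_average(areas, 3L)
  rows <- lapply(switch_times, function(ts) {
    win <- which(times > ts & times <= ts + window)
    truncated <- (ts + window) > max(times)
    if (truncated) {
      warning(sprintf("window after switch at %g min truncated at series end",
                      ts))
    }
    if (length(win) < 3L) {
      abort2("need >= 3 samples in each post-switch window",
             "acidhesion_bad_arg")
    }
    pre_idx <- max(which(times <= ts))
    pre <- smooth[pre_idx]
    pk <- win[which.max(smooth[win])]
    ratio <- smooth[pk] / pre
    t_peak <- if (max(smooth[win]) > pre + 1e-12) times[pk] - ts else NA_real_
    tibble(switch_time = ts, time_to_peak_min = t_peak,
           amplitude_ratio = ratio, truncated = truncated)
  })
  dplyr::bind_rows(rows)
}

#' Extract the membrane edge trace from a kymograph image
#'
#' The kymograph is a space-time intensity array with one spatial column per
#' frame (rows = position along the measurement line, columns = frames). The
#' edge at each frame is the outermost (largest row index) position whose
#' intensity exceeds the threshold. Frames with no suprathreshold pixel are
#' linearly interpolated from neighbouring frames and flagged.
#'
#' @param kymo numeric matrix, rows = spatial positions, columns = frames.
#' @param threshold `"otsu"` (Otsu's method on the normalized intensity
#'   histogram) or a fixed numeric intensity threshold.
#' @param pixel_size,frame_interval calibration passed to [edge_trace()].
#' @return an [edge_trace()] with the `interpolated` flag set on filled-in
#'   frames.
#' @export
extract_edge_trace <- function(kymo, threshold = "otsu",
                               pixel_size = 0.1, frame_interval = 5) {
  if (!is.matrix(kymo) || !is.numeric(kymo)) {
    abort2("kymograph must be a numeric matrix", "acidhesion_bad_arg")
  }
  rng <- range(kymo)
  if (identical(threshold, "otsu")) {
    if (diff(rng) == 0) {
      abort2("uniform kymograph: no edge in any frame", "acidhesion_no_edge")
    }
    norm <- (kymo - rng[1]) / diff(rng)
    threshold <- rng[1] + EBImage::otsu(norm) * diff(rng)
  }
  check_finite(threshold, "threshold")
  pos <- apply(kymo, 2, function(col) {
    hit <- which(col > threshold)
    if (length(hit)) max(hit) else NA_real_
  })
  interp <- is.na(pos)
  if (all(interp)) {
    abort2("no suprathreshold pixel in any frame", "acidhesion_no_edge")
  }
  if (any(interp)) {
    pos <- stats::approx(which(!interp), pos[!interp], xout = seq_along(pos),
                         rule = 2)$y
  }
  edge_trace(position_px = pos, pixel_size = pixel_size,
             frame_interval = frame_interval, interpolated = interp)
}

#' Detect membrane protrusion events on an edge trace
#'
#' Protrusions are rising runs from a local minimum to the following peak or
#' plateau onset. Steps are classified on a 3-point-smoothed trace: rising
#' when the smoothed increment exceeds `plateau_tol` px/frame, falling below
#' `-plateau_tol`, plateau otherwise; plateau onset takes precedence over a
#' later peak. Start and peak frames are refined on the *raw* trace (the
#' event height is measured raw, matching the manual line-drawing
#' convention), with ties broken towards the ramp. Events with height below
#' `min_height` px are discarded. Velocity is `height / ramp duration`
#' (reported in px/frame and um/min); lifetime is ramp plus plateau duration
#' in seconds.
#'
#' @param trace an [edge_trace()].
#' @param min_height minimum retained event height, px (default 4).
#' @param plateau_tol plateau slope tolerance, px/frame (default 0.5).
#' @return tibble of events: `start_frame`, `peak_frame`, `plateau_frames`,
#'   `height_px`, `velocity_px_frame`, `velocity_um_min`, `lifetime_s`.
#' @export
detect_protrusions <- function(trace, min_height = 4, plateau_tol = 0.5) {
  stopifnot(inherits(trace, "edge_trace"))
  x <- trace$position_px
  n <- length(x)
  if (n < 4L) abort2("edge trace too short", "acidhesion_bad_arg")
  s <- moving_average(x, 3L)
  ds <- diff(s)
  state <- ifelse(ds > plateau_tol, 1L, ifelse(ds < -plateau_tol, -1L, 0L))
  noise_est <- stats::mad(x - s) / sqrt(2 / 3)   # MA3 residual -> noise SD
  level_tol <- max(plateau_tol, 2.5 * noise_est)

  events <- list()
  t <- 1L
  while (t <= n - 1L) {
    if (state[t] != 1L) { t <- t + 1L; next }
    # ramp: maximal run of rising steps
    t2 <- t
    while (t2 + 1L <= n - 1L && state[t2 + 1L] == 1L) t2 <- t2 + 1L
    # plateau: run of flat steps after the ramp
    p2 <- t2
    while (p2 + 1L <= n - 1L && state[p2 + 1L] == 0L) p2 <- p2 + 1L
    start_cl <- t            # classified start frame
    rampend_cl <- t2 + 1L    # classified peak frame

    # refine boundaries on the raw trace by level: the start is the last
    # frame still at the pre-event minimum level, the peak the first frame
    # reaching the peak level (argmin/argmax would chase noise extremes and
    # bias the ramp duration)
    ws <- start_cl:min(n, start_cl + 2L)
    start_r <- ws[max(which(x[ws] <= min(x[ws]) + level_tol))]
    wp <- max(1L, rampend_cl - 2L):min(n, rampend_cl + 1L)
    peak_r <- wp[min(which(x[wp] >= max(x[wp]) - level_tol))]

    height <- x[peak_r] - x[start_r]
    ramp_frames <- peak_r - start_r
    # plateau end: last frame near the raw plateau level before descent
    plat_frames <- 0L
    if (p2 > t2) {
      wq <- (peak_r + 1L):min(n, p2 + 2L)
      near <- wq[abs(x[wq] - x[peak_r]) <= level_tol]
      if (length(near)) plat_frames <- max(near) - peak_r
    }
    if (height >= min_height && ramp_frames >= 1L) {
      events[[length(events) + 1L]] <- tibble(
        start_frame = start_r, peak_frame = peak_r,
        plateau_frames = plat_frames, height_px = height,
        velocity_px_frame = height / ramp_frames,
        velocity_um_min = height / ramp_frames * trace$pixel_size /
          trace$frame_interval * 60,
        lifetime_s = (ramp_frames + plat_frames) * trace$frame_interval
      )
    }
    t <- max(p2, t2) + 1L
  }
  if (!length(events)) {
    return(tibble(start_frame = integer(0), peak_frame = integer(0),
                  plateau_frames = integer(0), height_px = numeric(0),
                  velocity_px_frame = numeric(0),
                  velocity_um_min = numeric(0), lifetime_s = numeric(0)))
  }
  dplyr::bind_rows(events)
}

#' Summarize protrusion events per condition
#'
#' Means and SEMs of protrusion velocity and lifetime, treating individual
#' events as replicates; when a `cell_id` column is present a per-cell-first
#' summary (cells as replicates of their event means) is also returned.
#'
#' @param events tibble with `condition`, `velocity_um_min`, `lifetime_s`
#'   (and optionally `cell_id`).
#' @return list with tibbles `by_event` and `by_cell` (the latter `NULL`
#'   without `cell_id`).
#' @export
summarize_protrusions <- function(events) {
  if (!nrow(events)) abort2("no protrusion events", "acidhesion_bad_arg")
  if (!"condition" %in% names(events)) events$condition <- "unlabelled"
  by_cond <- function(df) {
    dplyr::summarise(
      dplyr::group_by(df, .data$condition),
      n = dplyr::n(),
      velocity_mean = mean(.data$velocity_um_min),
      velocity_sem = if (dplyr::n() >= 2)
        stats::sd(.data$velocity_um_min) / sqrt(dplyr::n()) else NA_real_,
      lifetime_mean = mean(.data$lifetime_s),
      lifetime_sem = if (dplyr::n() >= 2)
        stats::sd(.data$lifetime_s) / sqrt(dplyr::n()) else NA_real_,
      .groups = "drop"
    )
  }
  by_event <- by_cond(events)
  by_cell <- NULL
  if ("cell_id" %in% names(events)) {
    cell_means <- dplyr::summarise(
      dplyr::group_by(events, .data$condition, .data$cell_id),
      velocity_um_min = mean(.data$velocity_um_min),
      lifetime_s = mean(.data$lifetime_s), .groups = "drop"
    )
    by_cell <- by_cond(cell_means)
  }
  list(by_event = by_event, by_cell = by_cell)
}
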