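#' Configuration for the kymograph edge-trace simulator
#'
#' Events are protrusion episodes on the membrane-edge position trace: a
#' linear rise of `slope` px/frame for `ramp_frames`, an optional flat plateau
#' of `plateau_frames`, then a linear retraction back to baseline over the
#' same number of frames as the rise (the trace must return to baseline so
#' successive protrusions start from a local minimum). Event footprints,
#' including the retraction, must not overlap.
#'
#' @param n_frames number of frames.
#' @param frame_interval seconds between frames (default 5).
#' @param pixel_size um per pixel.
#' @param events data frame (or tibble) with columns `start_frame`, `slope`
#'   (px/frame, > 0), `ramp_frames` (>= 1), `plateau_frames` (>= 0).
#' @param noise_sd Gaussian positional noise SD, px.
#' @param seed integer seed.
#' @return an object of class `kymo_sim_config`.
#' @export
kymo_sim_config <- function(n_frames = 300, frame_interval = 5,
                            pixel_size = 0.1, events = NULL,
                            noise_sd = 0, seed = 1) {
  check_scalar_pos(n_frames, "n_frames")
  check_scalar_pos(frame_interval, "frame_interval")
  check_scalar_pos(pixel_size, "pixel_size")
  check_scalar_pos(noise_sd, "noise_sd", strict = FALSE)
  if (is.null(events)) {
    events <- tibble(start_frame = integer(0), slope = numeric(0),
                     ramp_frames = integer(0), plateau_frames = integer(0))
  }
  events <- as_tibble(events)
  req <- c("start_frame", "slope", "ramp_frames", "plateau_frames")
  if (!all(req %in% names(events))) {
    abort2(paste("events needs columns:", paste(req, collapse = ", ")),
           "acidhesion_bad_arg")
  }
  if (nrow(events)) {
    check_finite(events$slope, "slope")
    if (any(events$slope <= 0)) abort2("event slopes must be > 0",
                                       "acidhesion_bad_arg")
    if (any(events$ramp_frames < 1)) abort2("ramp_frames must be >= 1",
                                            "acidhesion_bad_arg")
    if (any(events$plateau_frames < 0)) abort2("plateau_frames must be >= 0",
                                               "acidhesion_bad_arg")
    ord <- order(events$start_frame)
    events <- events[ord, ]
    ends <- events$start_frame + 2L * events$ramp_frames +
      events$plateau_frames
    if (any(ends > n_frames)) {
      abort2("an event footprint extends past the last frame",
             "acidhesion_bad_arg")
    }
    if (nrow(events) > 1L &&
        any(events$start_frame[-1] < utils::head(ends, -1))) {
      abort2("event footprints overlap", "acidhesion_bad_arg")
    }
  }
  structure(
    list(n_frames = as.integer(n_frames), frame_interval = frame_interval,
         pixel_size = pixel_size, events = events, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "kymo_sim_config"
  )
}

#' Simulate a kymograph edge-position trace with planted protrusions
#'
#' @param config a [kymo_sim_config()].
#' @return list with `trace` (an [edge_trace()]) and `truth` (tibble of
#'   planted events: `start_frame`, `peak_frame`, `slope`, `ramp_frames`,
#'   `plateau_frames`, `height_px`, `velocity_um_min`, `lifetime_s`).
#' @export
simulate_kymograph <- function(config) {
  stopifnot(inherits(config, "kymo_sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  pos <- numeric(cfg$n_frames)   # baseline 0 px
  ev <- cfg$events
  for (i in seq_len(nrow(ev))) {
    s <- ev$start_frame[i]; a <- ev$slope[i]
    nr <- ev$ramp_frames[i]; np <- ev$plateau_frames[i]
    h <- a * nr
    ramp_up <- s + seq_len(nr)
    pos[ramp_up] <- a * seq_len(nr)
    if (np > 0) pos[s + nr + seq_len(np)] <- h
    ramp_dn <- s + nr + np + seq_len(nr)
    pos[ramp_dn] <- h - a * seq_len(nr)
  }
  if (cfg$noise_sd > 0) {
    pos <- pos + stats::rnorm(cfg$n_frames, 0, cfg$noise_sd)
  }
  trace <- edge_trace(position_px = pos, pixel_size = cfg$pixel_size,
                      frame_interval = cfg$frame_interval)
  truth <- if (nrow(ev)) {
    h <- ev$slope * ev$ramp_frames
    tibble(
      start_frame = ev$start_frame,
      peak_frame = ev$start_frame + ev$ramp_frames,
      slope = ev$slope, ramp_frames = ev$ramp_frames,
      plateau_frames = ev$plateau_frames, height_px = h,
      velocity_um_min = ev$slope * cfg$pixel_size /
        cfg$frame_interval * 60,
      lifetime_s = (ev$ramp_frames + ev$plateau_frames) * cfg$frame_interval
    )
  } else tibble()
  list(trace = trace, truth = truth)
}

#' Draw a random non-overlapping protrusion-event schedule
#'
#' Convenience generator for simulation studies: events are laid out left to
#' right with a gap of at least `min_gap` frames between footprints.
#'
#' @param n_events number of events.
#' @param slope_range,ramp_range,plateau_range uniform sampling ranges for
#'   slope (px/frame), ramp length and plateau length (frames).
#' @param min_gap minimum baseline gap between event footprints, frames.
#' @param seed integer seed.
#' @return list with `events` tibble and the total `n_frames` required.
#' @export
random_kymo_events <- function(n_events = 20,
                               slope_range = c(1.5, 3),
                               ramp_range = c(8L, 15L),
                               plateau_range = c(0L, 6L),
                               min_gap = 6L, seed = 1) {
  set.seed(seed)
  slope <- stats::runif(n_events, slope_range[1], slope_range[2])
  ramp <- sample(ramp_range[1]:ramp_range[2], n_events, replace = TRUE)
  plat <- sample(plateau_range[1]:plateau_range[2], n_events, replace = TRUE)
  start <- integer(n_events)
  cursor <- min_gap
  for (i in seq_len(n_events)) {
    start[i] <- cursor
    cursor <- cursor + 2L * ramp[i] + plat[i] + min_gap
  }
  list(events = tibble(start_frame = start, slope = slope,
                       ramp_frames = ramp, plateau_frames = plat),
       n_frames = cursor + min_gap)
}
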