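# End-to-end runner: each stage simulates its own inputs (seeded from the
# master seed) and runs the corresponding analysis chain, writing plain-text
# outputs plus a provenance record into the run directory.

stage_registry <- function() {
  list(
    afm = list(
      params = c("n_curves", "n_cells", "noise_sd", "specific_fraction",
                 "events_per_curve_lambda", "condition"),
      run = stage_afm
    ),
    migration = list(
      params = c("n_cells", "S_true", "P_true", "dt", "n_frames",
                 "condition", "r2_min", "min_cells"),
      run = stage_migration
    ),
    shapes = list(params = character(0), run = stage_shapes),
    kymo = list(
      params = c("n_events", "noise_sd", "pixel_size", "frame_interval",
                 "min_height"),
      run = stage_kymo
    ),
    trajectory = list(
      params = c("n_replicates", "n_frames", "modes", "mode_sd",
                 "bin_width"),
      run = stage_trajectory
    )
  )
}

stage_afm <- function(params, seed, dir) {
  cfg <- curve_sim_config(
    n_curves = params$n_curves %||% 50,
    n_cells = params$n_cells %||% 5,
    noise_sd = params$noise_sd %||% 5,
    specific_fraction = params$specific_fraction %||% 0.168,
    events_per_curve_lambda = params$events_per_curve_lambda %||% 1,
    condition = params$condition %||% "pH7.4",
    seed = seed
  )
  sim <- simulate_force_curves(cfg)
  write_curves(sim$curves, file.path(dir, "curves.csv"),
               file.path(dir, "curves_meta.csv"))
  write_events(sim$truth, file.path(dir, "planted_events.csv"))
  events <- analyze_curves(sim$curves)
  write_events(events, file.path(dir, "events.csv"))
  cells <- binding_frequency(events)
  write_events(cells, file.path(dir, "cell_binding.csv"))
  summ <- summarize_binding(cells, events)
  jsonlite::write_json(summ, file.path(dir, "binding_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  c("curves.csv", "curves_meta.csv", "planted_events.csv", "events.csv",
    "cell_binding.csv", "binding_summary.json")
}

stage_migration <- function(params, seed, dir) {
  cfg <- track_sim_config(
    n_cells = params$n_cells %||% 50,
    S_true = params$S_true %||% 1,
    P_true = params$P_true %||% 20,
    dt = params$dt %||% 5,
    n_frames = params$n_frames %||% 96,
    condition = params$condition %||% "pH7.4",
    seed = seed
  )
  tracks <- simulate_prw_tracks(cfg)
  write_tracks(tracks, file.path(dir, "tracks.csv"))
  cells <- analyze_tracks(tracks)
  write_fits(cells, file.path(dir, "cell_fits.csv"))
  summ <- filter_and_average(cells, r2_min = params$r2_min %||% 0.5,
                             min_cells = params$min_cells %||% 40L)
  jsonlite::write_json(summ, file.path(dir, "migration_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  c("tracks.csv", "cell_fits.csv", "migration_summary.json")
}

stage_shapes <- function(params, seed, dir) {
  shapes <- list(
    circle = simulate_shapes("circle_ngon", list(r = 10, n = 256)),
    rectangle = simulate_shapes("rectangle", list(width = 20, height = 40)),
    star = simulate_shapes("star",
                           list(n_arms = 5, r_outer = 15, r_inner = 6))
  )
  out <- dplyr::bind_rows(lapply(names(shapes), function(nm) {
    shape_metrics(shapes[[nm]]$vertices, cell_id = nm)
  }))
  write_events(out, file.path(dir, "shape_metrics.csv"))
  "shape_metrics.csv"
}

stage_kymo <- function(params, seed, dir) {
  sched <- random_kymo_events(n_events = params$n_events %||% 20,
                              seed = seed)
  cfg <- kymo_sim_config(
    n_frames = sched$n_frames,
    frame_interval = params$frame_interval %||% 5,
    pixel_size = params$pixel_size %||% 0.1,
    events = sched$events,
    noise_sd = params$noise_sd %||% 0.3,
    seed = seed
  )
  sim <- simulate_kymograph(cfg)
  detected <- detect_protrusions(sim$trace,
                                 min_height = params$min_height %||% 4)
  write_events(sim$truth, file.path(dir, "planted_protrusions.csv"))
  write_events(detected, file.path(dir, "protrusions.csv"))
  detected$condition <- "synthetic"
  summ <- summarize_protrusions(detected)
  jsonlite::write_json(summ$by_event, file.path(dir, "kymo_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  c("planted_protrusions.csv", "protrusions.csv", "kymo_summary.json")
}

stage_trajectory <- function(params, seed, dir) {
  n_rep <- params$n_replicates %||% 4
  nf <- params$n_frames %||% 400
  modes <- params$modes %||% c(4.1, 4.55)
  mode_sd <- params$mode_sd %||% 0.05
  set.seed(seed)
  sched <- sample(modes, nf, replace = TRUE) + stats::rnorm(nf, 0, mode_sd)
  cfg <- frame_sim_config(y_offset_schedule = sched,
                          rigid_jitter_sd = 0.01,
                          n_replicates = n_rep, seed = seed + 1L)
  sim <- simulate_headpiece_frames(cfg)
  series <- lapply(sim$frame_sets, opening_distance,
                   sel_a = "A:250-438", sel_b = "B:55-106+356-434")
  per_frame <- dplyr::bind_rows(lapply(seq_along(series), function(r) {
    tibble(replicate_id = sim$frame_sets[[r]]$replicate_id,
           frame = seq_along(series[[r]]), d_nm = series[[r]])
  }))
  write_events(per_frame, file.path(dir, "opening_distance.csv"))
  h <- replicate_histogram(series, bin_width = params$bin_width %||% 0.05)
  hist_df <- tibble(bin_lo_nm = utils::head(h$edges, -1),
                    bin_hi_nm = h$edges[-1], mean_freq = h$mean,
                    sem = h$sem)
  write_events(hist_df, file.path(dir, "opening_histogram.csv"))
  c("opening_distance.csv", "opening_histogram.csv")
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  unname(tools::md5sum(tmp))
}

#' Run the full synthetic-data pipeline from a configuration
#'
#' Executes each configured stage (simulate inputs, analyze, write outputs)
#' in a run directory named by the configuration hash, and writes a
#' provenance record (`provenance.json`: config echo, hash, per-stage seeds
#' and status, package version, output listing). Every source of randomness
#' derives from the master seed, so the same configuration produces
#' byte-identical outputs. If a stage fails, outputs of completed stages are
#' left intact, the failure is marked in the provenance record, and an error
#' is raised.
#'
#' @param config path to a YAML/JSON config (see [read_run_config()]) or an
#'   equivalent list. Keys: `seed`, `out_dir`, `stages` (named list of
#'   per-stage parameter lists).
#' @param out_dir output directory root; overrides the config's `out_dir`.
#' @return invisibly, the run directory path.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) read_run_config(config)
         else validate_run_config(config)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  if (is.null(cfg$out_dir)) abort2("config needs an out_dir",
                                   "acidhesion_bad_config")
  hash <- config_hash(cfg[c("seed", "stages")])
  run_dir <- file.path(cfg$out_dir, paste0("run-", substr(hash, 1, 12)))
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  registry <- stage_registry()
  stage_names <- names(cfg$stages)
  status <- list()
  failed <- NULL
  for (i in seq_along(stage_names)) {
    st <- stage_names[i]
    stage_seed <- cfg$seed + 1000L * i   # independent, reproducible streams
    stage_dir <- file.path(run_dir, st)
    dir.create(stage_dir, showWarnings = FALSE)
    params <- cfg$stages[[st]]
    if (is.null(params) || identical(params, "")) params <- list()
    res <- tryCatch(
      list(ok = TRUE,
           outputs = registry[[st]]$run(params, stage_seed, stage_dir)),
      error = function(e) list(ok = FALSE, message = conditionMessage(e))
    )
    status[[st]] <- c(list(seed = stage_seed), res)
    if (!res$ok) { failed <- st; break }
  }
  prov <- list(
    package = "acidhesion",
    version = as.character(utils::packageVersion("acidhesion")),
    config = cfg[c("seed", "stages")],
    config_hash = hash,
    stages = status
  )
  jsonlite::write_json(prov, file.path(run_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(failed)) {
    abort2(sprintf("stage '%s' failed: %s", failed,
                   status[[failed]]$message),
           "acidhesion_stage_error")
  }
  invisible(run_dir)
}
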