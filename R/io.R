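# Readers and writers for the pipeline's plain-text formats. Units are
# encoded in column names (_nm, _pN, _um, _min, ...) and no implicit
# conversion is ever applied; a schema violation is reported with the
# offending column names.

require_columns <- function(df, cols, file) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort2(sprintf("%s: missing required column(s): %s",
                   file, paste(missing, collapse = ", ")),
           "acidhesion_schema_error")
  }
  invisible(df)
}

#' Write force curves as tidy CSV
#'
#' Long format, one sample per row (`curve_id`, `cell_id`, `condition`,
#' `displacement_nm`, `force_pN`) plus a per-curve metadata CSV
#' (`curve_id`, `velocity_nm_per_s`, `spring_constant_pN_per_nm`).
#'
#' @param curves list of [force_curve()] objects.
#' @param curves_path,meta_path output CSV paths.
#' @return invisibly, the two paths.
#' @export
write_curves <- function(curves, curves_path, meta_path) {
  long <- dplyr::bind_rows(lapply(curves, function(cv) {
    tibble(curve_id = cv$curve_id, cell_id = cv$cell_id,
           condition = cv$condition, displacement_nm = cv$displacement,
           force_pN = cv$force)
  }))
  meta <- dplyr::bind_rows(lapply(curves, function(cv) {
    tibble(curve_id = cv$curve_id, velocity_nm_per_s = cv$velocity,
           spring_constant_pN_per_nm = cv$spring_constant)
  }))
  utils::write.csv(long, curves_path, row.names = FALSE)
  utils::write.csv(meta, meta_path, row.names = FALSE)
  invisible(c(curves_path, meta_path))
}

#' Read force curves from tidy CSV
#'
#' @param curves_path,meta_path CSV paths as written by [write_curves()].
#' @return list of [force_curve()] objects.
#' @export
read_curves <- function(curves_path, meta_path) {
  long <- utils::read.csv(curves_path)
  require_columns(long, c("curve_id", "cell_id", "condition",
                          "displacement_nm", "force_pN"), curves_path)
  meta <- utils::read.csv(meta_path)
  require_columns(meta, c("curve_id", "velocity_nm_per_s",
                          "spring_constant_pN_per_nm"), meta_path)
  ids <- unique(long$curve_id)
  lapply(ids, function(id) {
    seg <- long[long$curve_id == id, ]
    mrow <- meta[meta$curve_id == id, ]
    if (nrow(mrow) != 1L) {
      abort2(sprintf("%s: curve %s needs exactly one metadata row",
                     meta_path, id), "acidhesion_schema_error")
    }
    force_curve(displacement = seg$displacement_nm, force = seg$force_pN,
                velocity = mrow$velocity_nm_per_s,
                spring_constant = mrow$spring_constant_pN_per_nm,
                cell_id = seg$cell_id[1], condition = seg$condition[1],
                curve_id = id)
  })
}

#' Write an event or fit table as CSV
#' @param x tibble/data frame.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_events <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
write_fits <- write_events

#' Write cell tracks as tidy CSV
#'
#' Columns: `cell_id`, `condition`, `ligand_ug_per_ml`, `frame`, `x_um`,
#' `y_um`. The frame interval is not stored per row; supply it to
#' [read_tracks()].
#'
#' @param tracks list of [track()] objects.
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
write_tracks <- function(tracks, path) {
  long <- dplyr::bind_rows(lapply(tracks, function(trk) {
    tibble(cell_id = trk$cell_id, condition = trk$condition,
           ligand_ug_per_ml = trk$ligand_ug_per_ml,
           frame = seq_along(trk$x), x_um = trk$x, y_um = trk$y)
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Read cell tracks from tidy CSV
#'
#' @param path CSV path as written by [write_tracks()].
#' @param dt frame interval, min.
#' @return list of [track()] objects.
#' @export
read_tracks <- function(path, dt) {
  long <- utils::read.csv(path)
  require_columns(long, c("cell_id", "condition", "frame", "x_um", "y_um"),
                  path)
  if (!"ligand_ug_per_ml" %in% names(long)) {
    long$ligand_ug_per_ml <- NA_real_
  }
  parts <- split(long, long$cell_id)
  out <- lapply(parts, function(seg) {
    seg <- seg[order(seg$frame), ]
    track(x = seg$x_um, y = seg$y_um, dt = dt, cell_id = seg$cell_id[1],
          condition = seg$condition[1],
          ligand_ug_per_ml = seg$ligand_ug_per_ml[1])
  })
  unname(out)
}

#' Write coordinate frames as a multi-model PDB
#'
#' One MODEL/ENDMDL block per frame; coordinates are converted from nm to
#' Angstrom on output.
#'
#' @param fs a [frame_set()].
#' @param path output PDB path.
#' @return invisibly, the path.
#' @export
write_frames_pdb <- function(fs, path) {
  stopifnot(inherits(fs, "frame_set"))
  a <- fs$atoms
  con <- file(path, "w")
  on.exit(close(con))
  nf <- dim(fs$coords)[1]
  for (f in seq_len(nf)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- fs$coords[f, , , drop = FALSE][1, , , drop = TRUE] * 10  # nm -> A
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    lines <- sprintf(
      "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      a$eleno, a$elety, "GLY", a$chain, a$resno,
      xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, a$elesy)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read coordinate frames from a multi-model PDB
#'
#' Parses MODEL/ENDMDL blocks (via bio3d), converts Angstrom to nm, and
#' assigns standard atomic masses from the element symbol. All frames must
#' share the atom count and ordering.
#'
#' @param path PDB path.
#' @param frame_spacing_ps frame spacing, ps.
#' @param replicate_id replicate label.
#' @return a [frame_set()].
#' @export
read_frames_pdb <- function(path, frame_spacing_ps = 5,
                            replicate_id = "rep01") {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  elesy <- toupper(trimws(at$elesy))
  elesy[!nzchar(elesy)] <- substr(trimws(at$elety[!nzchar(elesy)]), 1, 1)
  masses <- atomic_masses()[elesy]
  if (any(is.na(masses))) {
    abort2(sprintf("unknown element symbol(s): %s",
                   paste(unique(elesy[is.na(masses)]), collapse = ", ")),
           "acidhesion_bad_frames")
  }
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_at <- nrow(at)
  if (ncol(xyz) != 3L * n_at) {
    abort2("inconsistent atom counts across PDB models",
           "acidhesion_bad_frames")
  }
  nf <- nrow(xyz)
  coords <- array(NA_real_, c(nf, n_at, 3))
  for (f in seq_len(nf)) {
    m <- matrix(xyz[f, ], ncol = 3, byrow = TRUE) / 10  # A -> nm
    coords[f, , ] <- m
  }
  frame_set(
    atoms = tibble(eleno = at$eleno, elety = trimws(at$elety),
                   elesy = elesy, resno = at$resno,
                   chain = as.character(at$chain), mass = unname(masses)),
    coords = coords, frame_spacing_ps = frame_spacing_ps,
    replicate_id = replicate_id
  )
}

#' Write coordinate frames as multi-frame XYZ with a sidecar group map
#'
#' Plain XYZ (atom count, comment, `element x y z` in nm per frame) plus a
#' JSON sidecar carrying the chain, residue and mass annotation that XYZ
#' cannot hold.
#'
#' @param fs a [frame_set()].
#' @param path output XYZ path.
#' @param sidecar_path output JSON path (default: `path` with `.json`).
#' @return invisibly, the two paths.
#' @export
write_frames_xyz <- function(fs, path,
                             sidecar_path = paste0(path, ".json")) {
  stopifnot(inherits(fs, "frame_set"))
  a <- fs$atoms
  con <- file(path, "w")
  on.exit(close(con))
  nf <- dim(fs$coords)[1]
  for (f in seq_len(nf)) {
    writeLines(as.character(nrow(a)), con)
    writeLines(sprintf("frame %d", f), con)
    xyz <- fs$coords[f, , , drop = FALSE][1, , , drop = TRUE]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    writeLines(sprintf("%-2s %12.6f %12.6f %12.6f",
                       a$elesy, xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  jsonlite::write_json(
    list(chain = a$chain, resno = a$resno, mass = a$mass,
         elety = a$elety, frame_spacing_ps = fs$frame_spacing_ps,
         replicate_id = fs$replicate_id),
    sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(c(path, sidecar_path))
}

#' Read coordinate frames from multi-frame XYZ + sidecar JSON
#'
#' @param path XYZ path.
#' @param sidecar_path JSON sidecar path.
#' @return a [frame_set()].
#' @export
read_frames_xyz <- function(path, sidecar_path = paste0(path, ".json")) {
  side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  lines <- readLines(path)
  n_at <- as.integer(lines[1])
  block <- n_at + 2L
  nf <- length(lines) %/% block
  coords <- array(NA_real_, c(nf, n_at, 3))
  elesy <- character(n_at)
  for (f in seq_len(nf)) {
    off <- (f - 1L) * block
    if (as.integer(lines[off + 1L]) != n_at) {
      abort2("inconsistent atom counts across XYZ frames",
             "acidhesion_bad_frames")
    }
    body <- lines[(off + 3L):(off + 2L + n_at)]
    parts <- strsplit(trimws(body), "\\s+")
    if (f == 1L) elesy <- vapply(parts, `[[`, character(1), 1)
    coords[f, , ] <- t(vapply(parts, function(p) {
      as.numeric(p[2:4])
    }, numeric(3)))
  }
  frame_set(
    atoms = tibble(eleno = seq_len(n_at),
                   elety = side$elety %||% rep("CA", n_at),
                   elesy = elesy, resno = as.integer(side$resno),
                   chain = as.character(side$chain),
                   mass = as.numeric(side$mass)),
    coords = coords,
    frame_spacing_ps = side$frame_spacing_ps %||% 5,
    replicate_id = side$replicate_id %||% "rep01"
  )
}

#' Read a pipeline run configuration
#'
#' YAML or JSON by file extension. Top level keys: `seed`, `out_dir`,
#' `stages`. Unknown keys at either level are rejected so typos do not pass
#' silently.
#'
#' @param path config path.
#' @return validated config list.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    abort2("config must be .yaml/.yml or .json", "acidhesion_bad_config"))
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  allowed_top <- c("seed", "out_dir", "stages")
  unknown <- setdiff(names(cfg), allowed_top)
  if (length(unknown)) {
    abort2(paste("unknown config key(s):", paste(unknown, collapse = ", ")),
           "acidhesion_bad_config")
  }
  if (is.null(cfg$stages) || !length(cfg$stages)) {
    abort2("config must list at least one stage", "acidhesion_bad_config")
  }
  bad <- setdiff(names(cfg$stages), names(stage_registry()))
  if (length(bad)) {
    abort2(paste("unknown stage(s):", paste(bad, collapse = ", ")),
           "acidhesion_bad_config")
  }
  for (st in names(cfg$stages)) {
    params <- cfg$stages[[st]]
    if (is.null(params)) params <- list()
    extra <- setdiff(names(params), stage_registry()[[st]]$params)
    if (length(extra)) {
      abort2(sprintf("stage '%s': unknown parameter(s): %s", st,
                     paste(extra, collapse = ", ")),
             "acidhesion_bad_config")
    }
  }
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg
}
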