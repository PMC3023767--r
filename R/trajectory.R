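#' Annotated coordinate frames
#'
#' Ordered coordinate snapshots sharing one atom annotation table, as read
#' from a multi-model PDB or an XYZ file with a sidecar group map. All
#' coordinates are in nm; the coordinate axes are taken as given in the input
#' file (the y-axis of the headpiece-opening metric is the y-axis of the
#' simulation box — no reorientation is attempted).
#'
#' @param atoms tibble with columns `eleno`, `elety`, `elesy`, `resno`,
#'   `chain`, `mass`.
#' @param coords numeric array `[n_frames, n_atoms, 3]`, nm.
#' @param frame_spacing_ps time between frames, ps.
#' @param replicate_id replicate label.
#' @return an object of class `frame_set`.
#' @export
frame_set <- function(atoms, coords, frame_spacing_ps = 5,
                      replicate_id = "rep01") {
  atoms <- as_tibble(atoms)
  req <- c("eleno", "resno", "chain", "mass")
  if (!all(req %in% names(atoms))) {
    abort2(paste("atoms needs columns:", paste(req, collapse = ", ")),
           "acidhesion_bad_frames")
  }
  if (length(dim(coords)) != 3L || dim(coords)[2] != nrow(atoms) ||
      dim(coords)[3] != 3L) {
    abort2("coords must be an [n_frames, n_atoms, 3] array matching atoms",
           "acidhesion_bad_frames")
  }
  if (any(!is.finite(coords))) abort2("coordinates must be finite",
                                      "acidhesion_bad_frames")
  check_scalar_pos(frame_spacing_ps, "frame_spacing_ps")
  structure(
    list(atoms = atoms, coords = coords,
         frame_spacing_ps = frame_spacing_ps, replicate_id = replicate_id),
    class = "frame_set"
  )
}

#' @export
print.frame_set <- function(x, ...) {
  cat(sprintf("<frame_set %s> %d frames x %d atoms @ %g ps\n",
              x$replicate_id, dim(x$coords)[1], dim(x$coords)[2],
              x$frame_spacing_ps))
  invisible(x)
}

#' Parse a chain:residue-range selection
#'
#' Mini-syntax: comma-separated chain components, each
#' `CHAIN:range[+range...]` with ranges `a-b` or single residue numbers,
#' e.g. `"A:250-438,B:55-106+356-434"`.
#'
#' @param sel selection string.
#' @return list of components, each `list(chain, resno)`.
#' @export
parse_selection <- function(sel) {
  if (!is.character(sel) || length(sel) != 1L || !nzchar(sel)) {
    abort2("selection must be a non-empty string", "acidhesion_bad_selection")
  }
  comps <- strsplit(sel, ",", fixed = TRUE)[[1]]
  lapply(comps, function(cc) {
    parts <- strsplit(cc, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2L) {
      abort2(sprintf("malformed selection component '%s'", cc),
             "acidhesion_bad_selection")
    }
    ranges <- strsplit(parts[2], "+", fixed = TRUE)[[1]]
    resno <- unlist(lapply(ranges, function(r) {
      ab <- suppressWarnings(as.integer(strsplit(r, "-", fixed = TRUE)[[1]]))
      if (any(is.na(ab)) || length(ab) > 2L) {
        abort2(sprintf("malformed residue range '%s'", r),
               "acidhesion_bad_selection")
      }
      if (length(ab) == 2L) ab[1]:ab[2] else ab
    }))
    list(chain = trimws(parts[1]), resno = resno)
  })
}

# resolve a selection string (or parsed selection) to atom row indices
resolve_selection <- function(fs, sel) {
  comps <- if (is.character(sel)) parse_selection(sel) else sel
  idx <- unlist(lapply(comps, function(cc) {
    hit <- which(fs$atoms$chain == cc$chain & fs$atoms$resno %in% cc$resno)
    if (!length(hit)) {
      abort2(sprintf(
        "selection '%s:%d-%d' matches no atoms (missing residues %s)",
        cc$chain, min(cc$resno), max(cc$resno),
        paste(range(cc$resno), collapse = "-")),
        "acidhesion_bad_selection")
    }
    hit
  }))
  sort(unique(idx))
}

#' Center of mass of an atom selection in one frame
#'
#' @param coords n x 3 coordinate matrix for the selected atoms, nm.
#' @param masses atomic masses, amu (ignored when `use_masses = FALSE`).
#' @param use_masses mass-weighted (default) or geometric mean.
#' @return length-3 numeric `(x, y, z)`.
#' @export
#' @examples
#' group_com(rbind(c(0, 0, 0), c(2, 0, 0)), c(1, 1))  # (1, 0, 0)
group_com <- function(coords, masses = NULL, use_masses = TRUE) {
  coords <- rbind(coords)
  if (!nrow(coords)) abort2("empty selection", "acidhesion_bad_selection")
  if (use_masses) {
    if (is.null(masses) || any(masses <= 0)) {
      abort2("mass-weighted COM needs positive masses",
             "acidhesion_bad_arg")
    }
    colSums(coords * masses) / sum(masses)
  } else {
    colMeans(coords)
  }
}

#' Headpiece opening distance
#'
#' The y-component of the distance between the centers of mass of a portion
#' of the beta-propeller domain (default residues A:250-438) and a portion of
#' the hybrid domain (default residues B:55-106 and B:356-434):
#' `d = |COM_A.y - COM_B.y|`, evaluated at every frame. The metric is
#' invariant under rigid translations and rotations about the y-axis, but by
#' construction not under general rotations.
#'
#' @param fs a [frame_set()].
#' @param sel_a,sel_b selection strings (see [parse_selection()]).
#' @param use_masses mass-weighted centers (default) or geometric.
#' @return numeric vector of `d` (nm), one value per frame.
#' @export
opening_distance <- function(fs, sel_a = "A:250-438",
                             sel_b = "B:55-106+356-434",
                             use_masses = TRUE) {
  stopifnot(inherits(fs, "frame_set"))
  ia <- resolve_selection(fs, sel_a)
  ib <- resolve_selection(fs, sel_b)
  ma <- fs$atoms$mass[ia]; mb <- fs$atoms$mass[ib]
  nf <- dim(fs$coords)[1]
  vapply(seq_len(nf), function(f) {
    ca <- group_com(fs$coords[f, ia, , drop = FALSE][1, , ], ma, use_masses)
    cb <- group_com(fs$coords[f, ib, , drop = FALSE][1, , ], mb, use_masses)
    abs(ca[2] - cb[2])
  }, numeric(1))
}

#' Residue-ion center-of-mass distance
#'
#' Full 3D Euclidean distance between the centers of mass of two selections
#' (e.g. an ADMIDAS-site ion and a coordinating aspartate), per frame, with
#' the per-replicate mean and SEM over frames.
#'
#' @param fs a [frame_set()].
#' @param sel_residue,sel_ion selection strings.
#' @param use_masses mass-weighted centers (default).
#' @return list with `distance_nm` (per frame), `mean`, `sem`,
#'   `replicate_id`.
#' @export
residue_ion_distance <- function(fs, sel_residue, sel_ion,
                                 use_masses = TRUE) {
  stopifnot(inherits(fs, "frame_set"))
  ir <- resolve_selection(fs, sel_residue)
  ii <- resolve_selection(fs, sel_ion)
  mr <- fs$atoms$mass[ir]; mi <- fs$atoms$mass[ii]
  nf <- dim(fs$coords)[1]
  d <- vapply(seq_len(nf), function(f) {
    cr <- group_com(fs$coords[f, ir, , drop = FALSE][1, , ], mr, use_masses)
    ci <- group_com(fs$coords[f, ii, , drop = FALSE][1, , ], mi, use_masses)
    sqrt(sum((cr - ci)^2))
  }, numeric(1))
  list(distance_nm = d, mean = mean(d),
       sem = if (nf >= 2) stats::sd(d) / sqrt(nf) else NA_real_,
       replicate_id = fs$replicate_id)
}

#' Replicate-averaged distance histogram
#'
#' Each replicate's distance series is binned on shared edges and normalized
#' to sum to 1 independently; the per-bin mean and SEM are then taken across
#' replicates, so replicates (not frames) are the unit of replication —
#' matching how independent simulation runs are averaged.
#'
#' @param series_list list of numeric distance series, one per replicate
#'   (at least two replicates).
#' @param bin_width bin width, nm (default 0.05 — fine enough to resolve
#'   peaks ~0.45 nm apart).
#' @param range optional `c(lo, hi)`; extended with a warning when values
#'   fall outside.
#' @return object of class `replicate_histogram`: list with `edges`, `mid`,
#'   `freq` (replicates x bins matrix), `mean`, `sem`.
#' @export
replicate_histogram <- function(series_list, bin_width = 0.05,
                                range = NULL) {
  if (length(series_list) < 2L) abort2("need >= 2 replicates",
                                       "acidhesion_bad_arg")
  check_scalar_pos(bin_width, "bin_width")
  vals <- unlist(series_list)
  check_finite(vals, "series values")
  if (is.null(range)) {
    range <- c(floor(min(vals) / bin_width) * bin_width,
               ceiling(max(vals) / bin_width) * bin_width)
  } else if (min(vals) < range[1] || max(vals) > range[2]) {
    warning("values outside the requested range; extending")
    range <- c(min(range[1], floor(min(vals) / bin_width) * bin_width),
               max(range[2], ceiling(max(vals) / bin_width) * bin_width))
  }
  edges <- seq(range[1], range[2] + bin_width / 2, by = bin_width)
  nb <- length(edges) - 1L
  freq <- t(vapply(series_list, function(x) {
    cts <- graphics::hist(x, breaks = edges, plot = FALSE,
                          include.lowest = TRUE, right = FALSE)$counts
    cts / sum(cts)
  }, numeric(nb)))
  m <- colMeans(freq)
  s <- apply(freq, 2, stats::sd) / sqrt(nrow(freq))
  structure(
    list(edges = edges, mid = (edges[-1] + edges[-length(edges)]) / 2,
         freq = freq, mean = m, sem = s),
    class = "replicate_histogram"
  )
}

#' @export
print.replicate_histogram <- function(x, ...) {
  cat(sprintf("<replicate_histogram> %d replicates x %d bins, [%g, %g] nm\n",
              nrow(x$freq), length(x$mean), min(x$edges), max(x$edges)))
  invisible(x)
}

#' Local maxima of a replicate-histogram mean frequency
#'
#' Peaks are bins strictly greater than both neighbours with mean frequency
#' above `min_fraction` of the global maximum (suppressing noise-level
#' bumps).
#'
#' @param hist a [replicate_histogram()].
#' @param min_fraction minimum peak height as a fraction of the tallest bin.
#' @return tibble with `mid` (peak positions, nm) and `frequency`.
#' @export
histogram_peaks <- function(hist, min_fraction = 0.3) {
  stopifnot(inherits(hist, "replicate_histogram"))
  m <- hist$mean
  n <- length(m)
  if (n < 3L) return(tibble(mid = numeric(0), frequency = numeric(0)))
  is_peak <- c(FALSE, m[2:(n - 1)] > m[1:(n - 2)] &
                 m[2:(n - 1)] > m[3:n], FALSE)
  is_peak <- is_peak & m >= min_fraction * max(m)
  tibble(mid = hist$mid[is_peak], frequency = m[is_peak])
}
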