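#' Build a labeled atom group for frame simulation
#'
#' One atom per residue, scattered in a compact blob, with element-appropriate
#' masses. Used to assemble the two domains whose center-of-mass separation
#' the trajectory metrics measure.
#'
#' @param chain chain identifier (single character).
#' @param resno integer vector of residue numbers (one atom each).
#' @param spread SD of the isotropic scatter around the group origin, nm.
#' @param seed integer seed (group geometry is deterministic given it).
#' @return list with `coords` (n x 3 matrix, nm, COM at the origin),
#'   `masses` (amu), `chain`, `resno`, `elety`, `elesy`.
#' @export
make_atom_group <- function(chain, resno, spread = 0.5, seed = 42) {
  if (!length(resno)) abort2("atom group must be non-empty",
                             "acidhesion_bad_arg")
  set.seed(seed)
  n <- length(resno)
  coords <- matrix(stats::rnorm(3 * n, 0, spread), n, 3)
  elesy <- sample(c("C", "N", "O", "S"), n, replace = TRUE,
                  prob = c(0.55, 0.2, 0.2, 0.05))
  masses <- atomic_masses()[elesy]
  # centre COM at the origin so group placement is exact
  com <- colSums(coords * masses) / sum(masses)
  coords <- sweep(coords, 2, com)
  list(coords = coords, masses = unname(masses), chain = chain,
       resno = as.integer(resno), elety = rep("CA", n), elesy = elesy)
}

atomic_masses <- function() {
  c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
    MG = 24.305, MN = 54.938, CA = 40.078)
}

#' Configuration for the coordinate-frame simulator
#'
#' Two labeled atom groups stand in for the beta-propeller and hybrid domains;
#' per frame their centers of mass are separated along y by a prescribed
#' schedule. An independent rigid translation of each *group* per frame
#' (`rigid_jitter_sd`) emulates thermal motion: whole-frame translations
#' would leave the separation exactly invariant, and per-atom jitter would
#' average away as 1/sqrt(n_atoms), so the group-level jitter is what
#' propagates into the measured distance (SD = sqrt(2) * rigid_jitter_sd).
#'
#' @param group_a,group_b atom groups from [make_atom_group()]; defaults are
#'   a chain-A group in residues 250-264 and a chain-B group in residues
#'   55-69 (inside the default propeller/hybrid selections of
#'   [opening_distance()]).
#' @param y_offset_schedule per-frame center-of-mass y-separation, nm; its
#'   length defines `frames_per_replicate`.
#' @param rigid_jitter_sd per-group rigid-translation SD, nm.
#' @param n_replicates number of replicate frame sets.
#' @param frame_spacing_ps time between recorded frames, ps (default 5).
#' @param seed integer seed.
#' @return an object of class `frame_sim_config`.
#' @export
frame_sim_config <- function(group_a = make_atom_group("A", 250:264, seed = 42),
                             group_b = make_atom_group("B", 55:69, seed = 43),
                             y_offset_schedule = rep(4.2, 100),
                             rigid_jitter_sd = 0,
                             n_replicates = 1,
                             frame_spacing_ps = 5,
                             seed = 1) {
  for (g in list(group_a, group_b)) {
    if (!length(g$resno)) abort2("both atom groups must be non-empty",
                                 "acidhesion_bad_arg")
  }
  check_finite(y_offset_schedule, "y_offset_schedule")
  if (!length(y_offset_schedule)) {
    abort2("y_offset_schedule must be non-empty", "acidhesion_bad_arg")
  }
  check_scalar_pos(rigid_jitter_sd, "rigid_jitter_sd", strict = FALSE)
  check_scalar_pos(n_replicates, "n_replicates")
  check_scalar_pos(frame_spacing_ps, "frame_spacing_ps")
  structure(
    list(group_a = group_a, group_b = group_b,
         y_offset_schedule = y_offset_schedule,
         rigid_jitter_sd = rigid_jitter_sd,
         n_replicates = as.integer(n_replicates),
         frame_spacing_ps = frame_spacing_ps, seed = as.integer(seed)),
    class = "frame_sim_config"
  )
}

#' Simulate annotated coordinate frames with a scheduled domain separation
#'
#' @param config a [frame_sim_config()].
#' @return list with `frame_sets` (list of [frame_set()] objects, one per
#'   replicate) and `true_d` (the scheduled |y|-separations, nm; identical
#'   across replicates).
#' @export
simulate_headpiece_frames <- function(config) {
  stopifnot(inherits(config, "frame_sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  ga <- cfg$group_a; gb <- cfg$group_b
  na <- nrow(ga$coords); nb <- nrow(gb$coords)
  nf <- length(cfg$y_offset_schedule)
  atoms <- tibble(
    eleno = seq_len(na + nb),
    elety = c(ga$elety, gb$elety),
    elesy = c(ga$elesy, gb$elesy),
    resno = c(ga$resno, gb$resno),
    chain = c(rep(ga$chain, na), rep(gb$chain, nb)),
    mass = c(ga$masses, gb$masses)
  )
  # fixed arbitrary x/z offsets between the groups
  base_b <- c(2.0, 0, -1.0)
  frame_sets <- lapply(seq_len(cfg$n_replicates), function(r) {
    coords <- array(NA_real_, c(nf, na + nb, 3))
    for (f in seq_len(nf)) {
      ja <- if (cfg$rigid_jitter_sd > 0)
        stats::rnorm(3, 0, cfg$rigid_jitter_sd) else c(0, 0, 0)
      jb <- if (cfg$rigid_jitter_sd > 0)
        stats::rnorm(3, 0, cfg$rigid_jitter_sd) else c(0, 0, 0)
      off_b <- base_b + c(0, cfg$y_offset_schedule[f], 0)
      coords[f, seq_len(na), ] <- sweep(ga$coords, 2, ja, `+`)
      coords[f, na + seq_len(nb), ] <- sweep(gb$coords, 2, off_b + jb, `+`)
    }
    frame_set(atoms = atoms, coords = coords,
              frame_spacing_ps = cfg$frame_spacing_ps,
              replicate_id = sprintf("rep%02d", r))
  })
  list(frame_sets = frame_sets, true_d = abs(cfg$y_offset_schedule))
}
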