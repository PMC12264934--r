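# Per-frame unbinding/translocation criteria and first-crossing residence
# times. Every criterion is a named per-frame series with a cutoff and a
# direction; the event is the first frame at or beyond the cutoff (closed
# boundary), with censoring at the last frame when never crossed.

#' Construct a criterion series
#'
#' @param values Per-frame numeric values.
#' @param name Criterion name.
#' @param units Units string ("A", "percent", ...).
#' @param cutoff Default cutoff in the declared units.
#' @param direction "exceed" (event when value >= cutoff) or "fall-below".
#' @param dt Frame interval (ps).
#' @return Object of class `criterion_series`.
#' @export
criterion_series <- function(values, name = "criterion", units = "A",
                             cutoff = NA_real_, direction = "exceed", dt = 1) {
  direction <- match.arg(direction, c("exceed", "fall-below"))
  structure(list(values = as.numeric(values), name = name, units = units,
                 cutoff = cutoff, direction = direction, dt = dt),
            class = "criterion_series")
}

#' @export
print.criterion_series <- function(x, ...) {
  cat(sprintf("criterion_series '%s': %d frames, cutoff %s %s (%s)\n",
              x$name, length(x$values),
              if (x$direction == "exceed") ">=" else "<=",
              format(x$cutoff), x$units))
  invisible(x)
}

#' First crossing of a criterion series
#'
#' Event at the first frame whose value reaches the cutoff (>= for the
#' "exceed" direction, <= for "fall-below"; closed boundary). A single frame
#' beyond the cutoff triggers the event; recrossings are ignored. Censored
#' at the last frame when never crossed.
#'
#' @param series A `criterion_series` or plain numeric vector.
#' @param cutoff Cutoff; defaults to the series' own.
#' @param dt Frame interval in ps (for plain vectors).
#' @return Object of class `event_time`: `time` (ps, frame-1 is time 0),
#'   `frame` (1-based index), `censored`.
#' @export
first_crossing <- function(series, cutoff = NULL, dt = NULL) {
  if (inherits(series, "criterion_series")) {
    values <- series$values
    if (is.null(cutoff)) cutoff <- series$cutoff
    if (is.null(dt)) dt <- series$dt
    dir <- series$direction
  } else {
    values <- as.numeric(series)
    if (is.null(dt)) dt <- 1
    dir <- "exceed"
  }
  if (length(values) == 0L) stop("empty series")
  if (anyNA(values)) stop("NaN/NA in criterion series")
  if (is.null(cutoff) || is.na(cutoff)) stop("no cutoff given")
  hit <- if (dir == "exceed") which(values >= cutoff) else which(values <= cutoff)
  if (length(hit)) {
    structure(list(time = (hit[1L] - 1L) * dt, frame = hit[1L],
                   censored = FALSE), class = "event_time")
  } else {
    n <- length(values)
    structure(list(time = (n - 1L) * dt, frame = n, censored = TRUE),
              class = "event_time")
  }
}

#' @export
print.event_time <- function(x, ...) {
  cat(sprintf("event_time: %s at %g ps (frame %d)\n",
              if (x$censored) "censored" else "event", x$time, x$frame))
  invisible(x)
}

#' Atom-pair distance series
#'
#' Distance between two atoms per frame, e.g. the ligand quaternary
#' nitrogen to the binding-site aspartate gamma-carbon; the 12 Angstrom
#' crossing of that pair marks translocation out of the bound basin.
#'
#' @param traj A `trajectory3d`.
#' @param atom_a,atom_b Atom indices (1-based).
#' @param cutoff Cutoff in Angstrom (default 12; the criterion sweep also
#'   uses 6 and 9).
#' @return A `criterion_series` in Angstrom.
#' @export
atom_pair_distance_series <- function(traj, atom_a, atom_b, cutoff = 12) {
  vals <- vapply(seq_len(n_frames(traj)), function(i) {
    x <- get_frame(traj, i)
    sqrt(sum((x[atom_a, ] - x[atom_b, ])^2))
  }, numeric(1))
  criterion_series(vals, name = "pair_distance", units = "A",
                   cutoff = cutoff, dt = traj$dt)
}

#' Ligand RMSD series criterion
#'
#' Ligand RMSD relative to the starting pose, by default after receptor
#' superposition (fit on receptor atoms), wrapped as a criterion.
#'
#' @param traj A `trajectory3d`.
#' @param ligand_sel Ligand selection; default from the topology flags.
#' @param fit_sel Receptor selection used for superposition; NULL disables
#'   the fit.
#' @param cutoff Cutoff in Angstrom (default 14; sweep uses 6, 10, 14).
#' @return A `criterion_series` in Angstrom.
#' @export
ligand_rmsd_series <- function(traj, ligand_sel = NULL, fit_sel = NULL,
                               cutoff = 14) {
  if (is.null(ligand_sel)) ligand_sel <- select_atoms(traj, ligand = TRUE)
  vals <- rmsd_series(traj, reference = 1L, fit_sel = fit_sel,
                      measure_sel = ligand_sel)
  criterion_series(vals, name = "ligand_rmsd", units = "A", cutoff = cutoff,
                   dt = traj$dt)
}

#' Ligand-to-binding-site centre-of-mass distance series
#'
#' @param traj A `trajectory3d`.
#' @param ligand_sel,site_sel Atom selections (site: e.g. the alpha-carbons
#'   of the pocket-floor residues).
#' @param cutoff Cutoff in Angstrom (default 10; sweep uses 5, 10, 15).
#' @param masses Optional per-atom masses for mass-weighted COMs.
#' @return A `criterion_series` in Angstrom.
#' @export
com_distance_series <- function(traj, ligand_sel, site_sel, cutoff = 10,
                                masses = NULL) {
  li <- sel_indices(ligand_sel); si <- sel_indices(site_sel)
  if (length(li) == 0L || length(si) == 0L) stop("empty selection")
  vals <- vapply(seq_len(n_frames(traj)), function(i) {
    x <- get_frame(traj, i)
    cl <- centre_of_mass(x, li, if (is.null(masses)) NULL else masses[li])
    cs <- centre_of_mass(x, si, if (is.null(masses)) NULL else masses[si])
    sqrt(sum((cl - cs)^2))
  }, numeric(1))
  criterion_series(vals, name = "com_distance", units = "A", cutoff = cutoff,
                   dt = traj$dt)
}

#' Fraction of ligand solvent-accessible surface area, per frame
#'
#' 100 x (ligand SASA within the complex) / (SASA of the ligand isolated,
#' same frame conformation). Solvent and ion atoms are excluded from the
#' occluding environment (they stand in for the solvent probe itself).
#'
#' @param traj A `trajectory3d`.
#' @param ligand_sel Ligand selection; default from the topology flags.
#' @param cutoff Cutoff in percent (default 10; sweep uses 10, 20, 30, 40).
#' @param probe_radius,n_sphere_points Passed to [shrake_rupley_sasa()].
#' @return A `criterion_series` in percent, values in \[0, 100\].
#' @export
sasa_fraction_series <- function(traj, ligand_sel = NULL, cutoff = 10,
                                 probe_radius = 1.4, n_sphere_points = 960L) {
  if (is.null(ligand_sel)) ligand_sel <- select_atoms(traj, ligand = TRUE)
  li <- sel_indices(ligand_sel)
  if (length(li) == 0L) stop("empty ligand selection")
  at <- traj$topology$atoms
  env <- which(!at$is_solvent & !at$is_ion)   # ligand + receptor heavy context
  vals <- vapply(seq_len(n_frames(traj)), function(i) {
    x <- get_frame(traj, i)
    in_complex <- shrake_rupley_sasa(x[env, , drop = FALSE], at$radius[env],
                                     probe_radius, n_sphere_points)
    iso <- shrake_rupley_sasa(x[li, , drop = FALSE], at$radius[li],
                              probe_radius, n_sphere_points)
    lig_in_env <- sum(in_complex$atom_area[match(li, env)])
    if (iso$total <= 0) return(0)
    100 * lig_in_env / iso$total
  }, numeric(1))
  criterion_series(vals, name = "sasa_fraction", units = "%", cutoff = cutoff,
                   dt = traj$dt)
}

#' Is the ligand surrounded only by solvent?
#'
#' TRUE iff no non-solvent, non-ion, non-ligand atom lies within `shell`
#' Angstrom of any ligand atom (closed boundary: an atom at exactly the
#' shell distance still counts as contact).
#'
#' @param structure A `structure3d`, or a `trajectory3d` with `frame`.
#' @param ligand_sel Ligand selection; default from flags.
#' @param shell Shell radius in Angstrom (default 6, about two solvation
#'   shells).
#' @param frame Frame index when `structure` is a trajectory.
#' @return Logical.
#' @export
solvation_shell_unbound <- function(structure, ligand_sel = NULL, shell = 6,
                                    frame = 1L) {
  if (inherits(structure, "trajectory3d")) {
    coords <- get_frame(structure, frame)
    at <- structure$topology$atoms
  } else {
    coords <- structure$coords
    at <- structure$atoms
  }
  if (is.null(ligand_sel)) {
    li <- which(at$is_ligand)
  } else li <- sel_indices(ligand_sel)
  if (length(li) == 0L) stop("empty ligand selection")
  other <- setdiff(which(!at$is_solvent & !at$is_ion), li)
  if (length(other) == 0L) return(TRUE)
  d2 <- outer(rowSums(coords[li, , drop = FALSE]^2),
              rowSums(coords[other, , drop = FALSE]^2), "+") -
    2 * coords[li, , drop = FALSE] %*% t(coords[other, , drop = FALSE])
  min(d2) > shell^2
}

#' Default criterion/cutoff configuration of the comparison experiment
#'
#' The full cutoff sweep: pair distance 6/9/12 A, ligand RMSD 6/10/14 A,
#' COM distance 5/10/15 A, SASA fraction 10/20/30/40 %.
#' @return Named list of numeric cutoff vectors.
#' @export
criteria_cutoffs_default <- function() {
  list(pair_distance = c(6, 9, 12), ligand_rmsd = c(6, 10, 14),
       com_distance = c(5, 10, 15), sasa_fraction = c(10, 20, 30, 40))
}

#' Evaluate every translocation criterion at every cutoff
#'
#' @param traj A `trajectory3d`.
#' @param config List with `pair` (two atom indices), `ligand_sel`,
#'   `site_sel`, optional `fit_sel`, and optional `cutoffs` overriding
#'   [criteria_cutoffs_default()]. Optional `tanimoto` cutoffs add the
#'   fingerprint criterion (needs typed atoms).
#' @return data.frame with one row per (criterion, cutoff): event time
#'   (ps), frame, censored.
#' @export
evaluate_all_criteria <- function(traj, config) {
  cuts <- config$cutoffs
  if (is.null(cuts)) cuts <- criteria_cutoffs_default()
  series <- list(
    pair_distance = atom_pair_distance_series(traj, config$pair[1L], config$pair[2L]),
    ligand_rmsd = ligand_rmsd_series(traj, config$ligand_sel, config$fit_sel),
    com_distance = com_distance_series(traj, config$ligand_sel, config$site_sel),
    sasa_fraction = sasa_fraction_series(traj, config$ligand_sel))
  if (!is.null(config$tanimoto)) {
    tan <- tanimoto_series(traj, config$ligand_sel)
    series$tanimoto <- tan
    cuts$tanimoto <- config$tanimoto
  }
  rows <- list()
  for (nm in names(series)) {
    for (ct in cuts[[nm]]) {
      ev <- first_crossing(series[[nm]], cutoff = ct)
      rows[[length(rows) + 1L]] <- data.frame(
        criterion = nm, cutoff = ct, time = ev$time, frame = ev$frame,
        censored = ev$censored)
    }
  }
  do.call(rbind, rows)
}
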