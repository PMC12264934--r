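# Structure / Trajectory / AtomSelection data model.
#
# A `structure3d` is a list with an `atoms` data.frame (one row per atom) and
# an N x 3 coordinate matrix in Angstrom. A `trajectory3d` adds an ordered
# stack of frames (N x 3 x F array) and a constant frame interval in ps.
# Atom indices are 1-based at the R surface (documented); frame times are
# (frame_index - 1) * frame_interval so frame 1 is time 0.

#' Default van der Waals radii by element (Angstrom)
#'
#' Used when a structure is built without explicit radii. Values are the
#' common fixed-radius table used for solvent-accessible-surface work.
#'
#' @return Named numeric vector of radii in Angstrom.
#' @export
vdw_radii_default <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)
}

#' Residue-name whitelists for solvent and ion detection
#'
#' @return List with character vectors `solvent` and `ion`.
#' @export
solvent_residues_default <- function() {
  list(solvent = c("WAT", "HOH", "TIP3", "SOL"),
       ion = c("NA", "CL", "K", "NA+", "CL-", "K+", "MG", "CA"))
}

#' Construct a molecular structure
#'
#' @param coords N x 3 numeric matrix of coordinates (Angstrom).
#' @param name Atom names (character, length N).
#' @param resid Residue ids (integer, non-decreasing within a chain).
#' @param resname Residue names.
#' @param chain Chain ids.
#' @param element Element symbols; guessed from the first letter of `name`
#'   when missing.
#' @param radius Per-atom van der Waals radii (Angstrom); defaulted by
#'   element from [vdw_radii_default()] (1.7 for unknown elements).
#' @param itype Optional per-atom interaction type tag used by the
#'   fingerprint module (one of "apolar", "donor", "acceptor", "cation",
#'   "anion", "aromatic", or NA).
#' @param is_ligand Logical per atom; defaults to FALSE.
#' @param solvent_cfg Whitelists from [solvent_residues_default()].
#' @return Object of class `structure3d`.
#' @export
structure3d <- function(coords, name = NULL, resid = NULL, resname = NULL,
                        chain = NULL, element = NULL, radius = NULL,
                        itype = NULL, is_ligand = NULL,
                        solvent_cfg = solvent_residues_default()) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must be an N x 3 matrix")
  n <- nrow(coords)
  if (is.null(name)) name <- rep("X", n)
  if (is.null(resid)) resid <- seq_len(n)
  if (is.null(resname)) resname <- rep("UNK", n)
  if (is.null(chain)) chain <- rep("A", n)
  if (is.null(element)) element <- toupper(substr(name, 1L, 1L))
  if (is.null(radius)) {
    tab <- vdw_radii_default()
    radius <- unname(tab[element])
    radius[is.na(radius)] <- 1.70
  }
  if (any(!is.finite(radius)) || any(radius <= 0)) {
    stop("vdW radii must be strictly positive")
  }
  if (is.null(itype)) itype <- rep(NA_character_, n)
  lens <- vapply(list(name, resid, resname, chain, element, radius, itype),
                 length, integer(1))
  if (any(lens != n)) stop("atom annotation length does not match atom count")
  resname <- toupper(resname)
  is_solvent <- resname %in% solvent_cfg$solvent
  is_ion <- resname %in% solvent_cfg$ion
  if (is.null(is_ligand)) is_ligand <- rep(FALSE, n)
  for (ch in unique(chain)) {
    r <- resid[chain == ch]
    if (is.unsorted(r)) stop("residue ids must be non-decreasing within a chain")
  }
  atoms <- data.frame(name = as.character(name), resid = as.integer(resid),
                      resname = resname, chain = as.character(chain),
                      element = as.character(element), radius = as.numeric(radius),
                      itype = as.character(itype),
                      is_solvent = is_solvent, is_ion = is_ion,
                      is_ligand = as.logical(is_ligand),
                      stringsAsFactors = FALSE)
  dimnames(coords) <- NULL
  structure(list(atoms = atoms, coords = coords), class = "structure3d")
}

#' @export
print.structure3d <- function(x, ...) {
  cat(sprintf("structure3d: %d atoms, %d residues, %d chain(s)\n",
              nrow(x$atoms), length(unique(paste(x$atoms$chain, x$atoms$resid))),
              length(unique(x$atoms$chain))))
  invisible(x)
}

#' Number of atoms in a structure or trajectory
#' @param x A `structure3d` or `trajectory3d`.
#' @return Integer atom count.
#' @export
n_atoms <- function(x) {
  if (inherits(x, "trajectory3d")) nrow(x$topology$atoms) else nrow(x$atoms)
}

#' Construct a trajectory
#'
#' @param topology A `structure3d` describing the atoms.
#' @param frames N x 3 x F array, or a list of N x 3 matrices (Angstrom).
#' @param dt Frame interval in ps (constant, positive).
#' @return Object of class `trajectory3d`.
#' @export
trajectory3d <- function(topology, frames, dt = 1) {
  stopifnot(inherits(topology, "structure3d"))
  if (is.list(frames)) {
    frames <- array(unlist(frames), dim = c(nrow(frames[[1L]]), 3L, length(frames)))
  }
  if (length(dim(frames)) == 2L) frames <- array(frames, dim = c(dim(frames), 1L))
  if (dim(frames)[1L] != nrow(topology$atoms)) {
    stop("frame atom count does not match topology")
  }
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
    stop("frame interval must be a positive scalar (ps)")
  }
  structure(list(topology = topology, frames = frames, dt = dt),
            class = "trajectory3d")
}

#' @export
print.trajectory3d <- function(x, ...) {
  cat(sprintf("trajectory3d: %d atoms x %d frames, dt = %g ps\n",
              dim(x$frames)[1L], dim(x$frames)[3L], x$dt))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `trajectory3d`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$frames)[3L]

#' Extract one frame of a trajectory as an N x 3 matrix
#' @param traj A `trajectory3d`.
#' @param i Frame index (1-based).
#' @return N x 3 coordinate matrix.
#' @export
get_frame <- function(traj, i) {
  if (i < 1L || i > n_frames(traj)) stop("frame index out of range")
  x <- traj$frames[, , i, drop = FALSE]
  dim(x) <- dim(x)[1:2]
  x
}

#' Frame times of a trajectory
#' @param traj A `trajectory3d`.
#' @return Numeric vector of times in ps; frame 1 is time 0.
#' @export
frame_times <- function(traj) (seq_len(n_frames(traj)) - 1) * traj$dt

#' Construct an atom selection
#'
#' @param indices Unique, in-range atom indices (1-based), order preserved.
#' @param weights Optional non-negative per-atom weights (not all zero).
#' @param n Optional atom count for range validation.
#' @return Object of class `atom_selection`.
#' @export
atom_selection <- function(indices, weights = NULL, n = NULL) {
  indices <- as.integer(indices)
  if (anyDuplicated(indices)) stop("selection indices must be unique")
  if (any(indices < 1L)) stop("selection indices must be >= 1")
  if (!is.null(n) && any(indices > n)) stop("selection index out of range")
  if (!is.null(weights)) {
    if (length(weights) != length(indices)) stop("weights length mismatch")
    if (any(weights < 0)) stop("weights must be non-negative")
    if (all(weights == 0)) stop("weights must not be all zero")
  }
  structure(list(indices = indices, weights = weights), class = "atom_selection")
}

#' Select atoms of a structure by predicate columns
#'
#' Convenience wrapper building an [atom_selection()] from the `atoms` table.
#'
#' @param x A `structure3d` or `trajectory3d`.
#' @param ligand,solvent,ion Logical filters on the corresponding flags;
#'   NULL leaves the flag unconstrained.
#' @param name,resid,chain Optional value filters.
#' @param element Optional element filter.
#' @return An `atom_selection`.
#' @export
select_atoms <- function(x, ligand = NULL, solvent = NULL, ion = NULL,
                         name = NULL, resid = NULL, chain = NULL,
                         element = NULL) {
  atoms <- if (inherits(x, "trajectory3d")) x$topology$atoms else x$atoms
  keep <- rep(TRUE, nrow(atoms))
  if (!is.null(ligand)) keep <- keep & (atoms$is_ligand == ligand)
  if (!is.null(solvent)) keep <- keep & (atoms$is_solvent == solvent)
  if (!is.null(ion)) keep <- keep & (atoms$is_ion == ion)
  if (!is.null(name)) keep <- keep & (atoms$name %in% name)
  if (!is.null(resid)) keep <- keep & (atoms$resid %in% resid)
  if (!is.null(chain)) keep <- keep & (atoms$chain %in% chain)
  if (!is.null(element)) keep <- keep & (atoms$element %in% element)
  atom_selection(which(keep), n = nrow(atoms))
}

#' Centre of mass of a coordinate subset
#'
#' Masses default to 1 per atom (geometric centre); supply per-atom masses
#' for a mass-weighted centre.
#'
#' @param coords N x 3 matrix.
#' @param sel An `atom_selection` or integer indices; NULL means all atoms.
#' @param masses Optional per-atom masses for the selected atoms.
#' @return Length-3 numeric vector.
#' @export
centre_of_mass <- function(coords, sel = NULL, masses = NULL) {
  idx <- if (is.null(sel)) seq_len(nrow(coords)) else sel_indices(sel)
  if (length(idx) == 0L) stop("empty selection")
  xyz <- coords[idx, , drop = FALSE]
  if (is.null(masses)) masses <- rep(1, length(idx))
  colSums(xyz * masses) / sum(masses)
}

sel_indices <- function(sel) {
  if (inherits(sel, "atom_selection")) sel$indices else as.integer(sel)
}
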