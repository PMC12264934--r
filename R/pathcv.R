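# Path collective variables in mean-square-deviation (MSD) space.
#
# A frameset holds P milestone configurations x_i over a fixed atom subset,
# per-atom align and displace weights, and the smoothness parameter lambda.
# S and Z follow the PATHMSD convention:
#   S = sum_i i * exp(-lambda d_i^2) / sum_i exp(-lambda d_i^2),  i = 1..P
#   Z = -lambda^-1 * log sum_i exp(-lambda d_i^2)
# with d_i^2 the displace-weighted MSD to milestone i after optimal
# superposition on the align weights. Both sums are evaluated through
# log-sum-exp so lambda * d^2 up to ~1e4 stays finite.

#' Construct a path frameset
#'
#' @param frames List of P coordinate matrices (n x d, Angstrom) over a
#'   fixed atom subset; d = 3 for molecular paths, lower for toy systems.
#' @param align Non-negative per-atom align weights (superposition); at
#'   least one positive entry. Ignored (no superposition) when the frameset
#'   has fewer than 3 atoms or `use_alignment = FALSE`.
#' @param displace Non-negative per-atom displace weights (MSD averaging);
#'   at least one positive entry.
#' @param lambda Smoothness parameter (1/Angstrom^2); computed by
#'   [lambda_rule()] when NULL and P >= 2.
#' @param use_alignment Logical; set FALSE for point-particle toy paths
#'   where rigid-body superposition is undefined.
#' @return Object of class `path_frameset`.
#' @export
path_frameset <- function(frames, align = NULL, displace = NULL,
                          lambda = NULL, use_alignment = NULL) {
  if (!is.list(frames) || length(frames) < 1L) stop("need at least one frame")
  frames <- lapply(frames, as.matrix)
  n <- nrow(frames[[1L]]); d <- ncol(frames[[1L]])
  if (any(vapply(frames, nrow, integer(1)) != n) ||
      any(vapply(frames, ncol, integer(1)) != d)) {
    stop("all frameset frames must share dimensions")
  }
  if (is.null(align)) align <- rep(1, n)
  if (is.null(displace)) displace <- rep(1, n)
  if (length(align) != n || length(displace) != n) stop("weight length mismatch")
  if (any(align < 0) || any(displace < 0)) stop("weights must be non-negative")
  if (all(align == 0)) stop("align weights must have a positive entry")
  if (all(displace == 0)) stop("displace weights must have a positive entry")
  if (is.null(use_alignment)) use_alignment <- (n >= 3L && d == 3L)
  fs <- structure(list(frames = frames, align = align, displace = displace,
                       lambda = lambda, P = length(frames),
                       use_alignment = use_alignment),
                  class = "path_frameset")
  if (fs$P >= 2L) {
    msd <- adjacent_msds(fs)
    if (any(msd <= 0)) stop("duplicate milestones: zero adjacent-frame MSD")
    if (is.null(lambda)) fs$lambda <- lambda_rule(fs)
  }
  fs
}

#' @export
print.path_frameset <- function(x, ...) {
  cat(sprintf("path_frameset: P = %d milestones, %d atoms, lambda = %s 1/A^2%s\n",
              x$P, nrow(x$frames[[1L]]),
              if (is.null(x$lambda)) "unset" else format(x$lambda, digits = 4),
              if (x$use_alignment) "" else " (no alignment)"))
  invisible(x)
}

#' Weighted mean-square deviation of a configuration from one milestone
#'
#' Superposes `x` onto the milestone using the align weights (when
#' alignment is active), then averages squared deviations with the
#' displace weights.
#'
#' @param x Coordinate matrix over the frameset atom subset.
#' @param frame_index Milestone index (1-based).
#' @param frameset A `path_frameset`.
#' @return MSD in Angstrom^2 (non-negative).
#' @export
msd_to_frame <- function(x, frame_index, frameset) {
  x <- as.matrix(x)
  ref <- frameset$frames[[frame_index]]
  if (!all(dim(x) == dim(ref))) stop("atom-count mismatch with frameset")
  if (frameset$use_alignment) {
    fit <- kabsch_superpose(x, ref, weights = frameset$align)
    x <- apply_transform(x, fit)
  }
  w <- frameset$displace / sum(frameset$displace)
  sum(w * rowSums((x - ref)^2))
}

#' Evaluate the path collective variables S and Z
#'
#' @param x Coordinate matrix over the frameset atom subset.
#' @param frameset A `path_frameset` with `lambda` set.
#' @return List with `S` (dimensionless, in \[1, P\]), `Z` (Angstrom^2, may
#'   be negative at small lambda) and the per-milestone `msd` vector.
#' @export
path_cvs <- function(x, frameset) {
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("non-finite coordinates")
  lambda <- frameset$lambda
  if (is.null(lambda) || lambda <= 0) stop("frameset lambda must be positive")
  d2 <- vapply(seq_len(frameset$P), function(i) msd_to_frame(x, i, frameset),
               numeric(1))
  # log-sum-exp: factor out the dominant term so lambda*d^2 ~ 1e4 is safe
  a <- -lambda * d2
  m <- max(a)
  w <- exp(a - m)
  sw <- sum(w)
  s <- sum(seq_len(frameset$P) * w) / sw
  z <- -(m + log(sw)) / lambda
  list(S = s, Z = z, msd = d2)
}

adjacent_msds <- function(frameset) {
  vapply(seq_len(frameset$P - 1L), function(i) {
    msd_to_frame(frameset$frames[[i + 1L]], i, frameset)
  }, numeric(1))
}

#' Smoothness parameter from the adjacent-milestone spacing
#'
#' The usual PATHMSD rule of thumb: lambda = 2.3 divided by the mean
#' adjacent-milestone MSD, so that exp(-lambda d^2) decays by ~an order of
#' magnitude per milestone.
#'
#' @param frameset A `path_frameset` with P >= 2.
#' @return lambda in 1/Angstrom^2.
#' @export
lambda_rule <- function(frameset) {
  if (frameset$P < 2L) stop("lambda rule needs at least 2 milestones")
  msd <- adjacent_msds(frameset)
  if (any(msd <= 0)) stop("duplicate milestones: zero adjacent-frame MSD")
  2.3 / mean(msd)
}

#' Select stable atoms for path alignment by an RMSF threshold
#'
#' Keeps candidate atoms whose RMSF over the trajectory is below the
#' threshold (default 0.6 Angstrom), preserving order. This mirrors the
#' practice of aligning on low-mobility C-alpha atoms.
#'
#' @param traj A `trajectory3d` with >= 2 frames.
#' @param threshold RMSF cutoff in Angstrom.
#' @param candidates An `atom_selection` of candidate atoms (default: atoms
#'   named "CA"; falls back to all non-solvent atoms when none).
#' @param fit_sel Optional selection to superpose frames before the RMSF.
#' @return An `atom_selection` of the retained atoms.
#' @export
select_align_atoms <- function(traj, threshold = 0.6, candidates = NULL,
                               fit_sel = NULL) {
  if (is.null(candidates)) {
    ca <- which(traj$topology$atoms$name == "CA")
    if (length(ca) == 0L) {
      ca <- which(!traj$topology$atoms$is_solvent & !traj$topology$atoms$is_ion &
                    !traj$topology$atoms$is_ligand)
    }
    candidates <- atom_selection(ca, n = n_atoms(traj))
  }
  vals <- rmsf(traj, sel = candidates, fit_sel = fit_sel)
  keep <- sel_indices(candidates)[vals < threshold]
  if (length(keep) == 0L) stop("no stable atoms below the RMSF threshold")
  atom_selection(keep, n = n_atoms(traj))
}

#' Build an equidistant milestone frameset from a guess trajectory
#'
#' Re-spaces the guess unbinding trajectory into P milestones with equal
#' adjacent-frame MSDs: frames are restricted to the union of the align and
#' displace selections, arc length is accumulated as the root-MSD between
#' consecutive guess frames, and milestones are linearly interpolated in
#' coordinate space at equal arc-length spacing. Optionally the guess is
#' first reduced by k-medoids clustering on pairwise displace-atom RMSD
#' (medoids ordered by progression) before re-spacing; the default bypasses
#' clustering, which is appropriate for monotone guess paths.
#'
#' @param guess A `trajectory3d` spanning bound to translocated states.
#' @param P Number of milestones (>= 2).
#' @param align_sel,displace_sel Atom selections (indices into the guess
#'   topology); weights taken from the selections (default 1).
#' @param cluster_first If TRUE, reduce the guess to P k-medoid
#'   representatives before re-spacing.
#' @param tol Maximum relative spread of adjacent MSDs accepted (warning
#'   beyond it).
#' @return A `path_frameset` over the union of the two selections.
#' @export
build_frameset <- function(guess, P, align_sel, displace_sel,
                           cluster_first = FALSE, tol = 0.15) {
  if (P < 2L) stop("need at least 2 milestones")
  if (n_frames(guess) < P) stop("guess trajectory shorter than P frames")
  ai <- sel_indices(align_sel); di <- sel_indices(displace_sel)
  idx <- sort(unique(c(ai, di)))
  aw <- dw <- rep(0, length(idx))
  aw[match(ai, idx)] <- if (is.null(align_sel$weights)) 1 else align_sel$weights
  dw[match(di, idx)] <- if (is.null(displace_sel$weights)) 1 else displace_sel$weights
  frames <- lapply(seq_len(n_frames(guess)), function(i) {
    get_frame(guess, i)[idx, , drop = FALSE]
  })
  if (cluster_first && length(frames) > P) {
    dmat <- pairwise_rmsd_matrix(frames, dw)
    med <- cluster::pam(as.dist(dmat), k = P, diss = TRUE)$id.med
    frames <- frames[sort(med)]
  }
  # cumulative arc length in root-MSD metric over the displace atoms
  probe <- path_frameset(frames, align = aw, displace = dw, lambda = 1,
                         use_alignment = length(idx) >= 3L && ncol(frames[[1L]]) == 3L)
  seg <- sqrt(adjacent_msds(probe))
  arc <- c(0, cumsum(seg))
  if (arc[length(arc)] <= 0) stop("guess trajectory does not progress")
  targets <- seq(0, arc[length(arc)], length.out = P)
  nodes <- lapply(targets, function(s) {
    j <- findInterval(s, arc, rightmost.closed = TRUE)
    j <- min(max(j, 1L), length(frames) - 1L)
    f <- if (seg[j] > 0) (s - arc[j]) / seg[j] else 0
    (1 - f) * frames[[j]] + f * frames[[j + 1L]]
  })
  fs <- path_frameset(nodes, align = aw, displace = dw,
                      use_alignment = probe$use_alignment)
  msd <- adjacent_msds(fs)
  spread <- (max(msd) - min(msd)) / mean(msd)
  if (spread > tol) {
    warning(sprintf("adjacent-milestone MSD spread %.1f%% exceeds %.1f%%",
                    100 * spread, 100 * tol))
  }
  fs
}

pairwise_rmsd_matrix <- function(frames, weights) {
  nf <- length(frames)
  w <- weights / sum(weights)
  m <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1L)) {
    for (j in (i + 1L):nf) {
      m[i, j] <- m[j, i] <- sqrt(sum(w * rowSums((frames[[i]] - frames[[j]])^2)))
    }
  }
  m
}

#' Read a PLUMED-dialect path PDB
#'
#' Multi-model PDB where the occupancy column holds the align weight and the
#' B-factor column the displace weight for each atom.
#'
#' @param file Path file.
#' @param lambda Optional lambda override; defaults to [lambda_rule()].
#' @return A `path_frameset`.
#' @export
read_path_pdb <- function(file, lambda = NULL) {
  pdb <- read_pdb_checked(file, multi = TRUE)
  n <- nrow(pdb$atom)
  nf <- nrow(pdb$xyz)
  if (ncol(pdb$xyz) != 3L * n) stop("inconsistent atom counts across models")
  frames <- lapply(seq_len(nf), function(i) matrix(pdb$xyz[i, ], ncol = 3L, byrow = TRUE))
  path_frameset(frames, align = pdb$atom$o, displace = pdb$atom$b,
                lambda = lambda)
}

#' Write a frameset as a PLUMED-dialect path PDB
#'
#' @param frameset A `path_frameset` (3-D coordinates).
#' @param file Output path.
#' @param topology Optional `structure3d` supplying atom names/residues;
#'   a generic carbon topology is synthesised when absent.
#' @return Invisibly, `file`.
#' @export
write_path_pdb <- function(frameset, file, topology = NULL) {
  if (ncol(frameset$frames[[1L]]) != 3L) stop("path PDB needs 3-D coordinates")
  n <- nrow(frameset$frames[[1L]])
  if (is.null(topology)) {
    topology <- structure3d(frameset$frames[[1L]],
                            name = rep("CA", n), element = rep("C", n))
  }
  write_pdb_frames(topology, frameset$frames, file,
                   o = frameset$align, b = frameset$displace)
  invisible(file)
}
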