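# Synthetic fixtures: a pseudo-atomic pocket/ligand system with a scripted
# translocation trajectory and machine-readable ground truth, scheduled
# criterion series, and exponential replica-time samplers. These make the
# analysis modules testable without any molecular download; they emulate
# the geometry of an unbinding event, not real protein chemistry.

#' Scripted pocket/ligand fixture with ground-truth crossing frames
#'
#' Builds a pseudo-receptor cage of typed single-atom "residues" (anion,
#' donors, acceptors, aromatics, apolars) around a five-atom rigid ligand,
#' a solvent cloud at the channel exit, and a trajectory translating the
#' ligand along the channel axis into the solvent. Ground truth is
#' recorded for every criterion: the pair-distance, ligand-RMSD and
#' COM-distance crossing frames follow from the constructed geometry in
#' closed form; the SASA-fraction and Tanimoto crossing frames are
#' recorded from the corresponding modules at construction time
#' (self-consistency anchors).
#'
#' @param seed Integer seed (solvent cloud jitter only; the ligand path is
#'   deterministic).
#' @param n_frames Trajectory length (default 60).
#' @param dz Ligand displacement per frame along +z (Angstrom, default
#'   0.6).
#' @param dt Frame interval in ps (default 100).
#' @return List with `trajectory` (a `trajectory3d` with typed atoms),
#'   `structure` (frame 1), selections (`ligand_sel`, `site_sel`, `pair`),
#'   and `truth`: the crossing frame (1-based) for each criterion at its
#'   default cutoff, plus per-frame series used to derive them.
#' @export
make_pocket_fixture <- function(seed = 1L, n_frames = 60L, dz = 0.6,
                                dt = 100) {
  set.seed(seed)
  # --- receptor cage: rings of 10 pseudo-residues around the channel axis
  ring_z <- seq(-2, 6, by = 1.6)
  ring_r <- 4.2
  n_ring <- 10L
  cage <- list(); types <- character(); resn <- character()
  for (zi in seq_along(ring_z)) {
    ang <- 2 * pi * (seq_len(n_ring) - 1L) / n_ring + (zi %% 2L) * pi / n_ring
    xyz <- cbind(ring_r * cos(ang), ring_r * sin(ang), ring_z[zi])
    cage[[zi]] <- xyz
    # type pattern per ring: mostly apolar with polar/aromatic accents
    tp <- rep("apolar", n_ring)
    tp[1L] <- "acceptor"; tp[4L] <- "donor"; tp[7L] <- "aromatic"
    types <- c(types, tp)
    resn <- c(resn, rep("RES", n_ring))
  }
  # bottom cap closing the pocket floor
  cap <- rbind(c(0, 0, -3.4),
               cbind(2.1 * cos(2 * pi * (0:5) / 6),
                     2.1 * sin(2 * pi * (0:5) / 6), -3.2))
  cage[[length(cage) + 1L]] <- cap
  types <- c(types, "anion", rep("apolar", 6L))  # the Asp-like anion at the floor
  resn <- c(resn, rep("RES", 7L))
  rec_xyz <- do.call(rbind, cage)
  n_rec <- nrow(rec_xyz)
  anion_idx <- n_rec - 6L                        # the cap-centre anion
  # --- ligand: rigid 5-atom probe, cation head near the anion
  lig_local <- rbind(c(0, 0, -1.6),   # cation (quaternary-amine surrogate)
                     c(0, 0, -0.2),   # apolar
                     c(0.9, 0, 1.0),  # aromatic
                     c(-0.9, 0.3, 1.0), # donor
                     c(0, -0.9, 2.0)) # acceptor
  lig_types <- c("cation", "apolar", "aromatic", "donor", "acceptor")
  n_lig <- nrow(lig_local)
  # --- solvent cloud at the channel exit
  exit_z <- dz * (n_frames - 1L)
  n_wat <- 48L
  wat <- cbind(runif(n_wat, -6, 6), runif(n_wat, -6, 6),
               exit_z + runif(n_wat, -4, 5))
  coords0 <- rbind(rec_xyz, lig_local, wat)
  topo <- structure3d(
    coords0,
    name = c(rep("P", n_rec), c("NQ", "C1", "AR", "ND", "OA"), rep("O", n_wat)),
    resid = c(seq_len(n_rec), rep(n_rec + 1L, n_lig),
              n_rec + 1L + seq_len(n_wat)),
    resname = c(resn, rep("LIG", n_lig), rep("WAT", n_wat)),
    element = c(rep("C", n_rec), c("N", "C", "C", "N", "O"), rep("O", n_wat)),
    itype = c(types, lig_types, rep(NA_character_, n_wat)),
    is_ligand = c(rep(FALSE, n_rec), rep(TRUE, n_lig), rep(FALSE, n_wat)))
  lig_rows <- n_rec + seq_len(n_lig)
  frames <- array(rep(coords0, n_frames), dim = c(nrow(coords0), 3L, n_frames))
  shift <- dz * (seq_len(n_frames) - 1L)
  for (i in seq_len(n_frames)) {
    frames[lig_rows, 3L, i] <- lig_local[, 3L] + shift[i]
  }
  traj <- trajectory3d(topo, frames, dt = dt)
  ligand_sel <- atom_selection(lig_rows, n = nrow(coords0))
  site_idx <- which(rec_xyz[, 3L] <= 0)[1:5]     # pocket-floor "C-alpha" site
  site_sel <- atom_selection(site_idx, n = nrow(coords0))
  pair <- c(lig_rows[1L], anion_idx)
  # --- ground truth
  # pair distance: both atoms fixed in x/y; closed form in the shift
  d_pair <- sqrt(colSums((t(frames[pair[1L], , ]) - rec_xyz[rep(anion_idx, n_frames), ])^2 * 1))
  d_pair <- vapply(seq_len(n_frames), function(i) {
    sqrt(sum((frames[pair[1L], , i] - frames[pair[2L], , i])^2))
  }, numeric(1))
  # rigid +z translation: ligand RMSD (no fit) equals the shift exactly
  rmsd_truth <- shift
  com0 <- colMeans(lig_local)
  site_com <- colMeans(rec_xyz[site_idx, , drop = FALSE])
  d_com <- sqrt(rowSums((cbind(com0[1L], com0[2L], com0[3L] + shift) -
                           matrix(site_com, n_frames, 3L, byrow = TRUE))^2))
  first_ge <- function(v, ct) { h <- which(v >= ct); if (length(h)) h[1L] else NA_integer_ }
  truth <- list(
    pair_distance = list(cutoff = 12, frame = first_ge(d_pair, 12),
                         series = d_pair),
    ligand_rmsd = list(cutoff = 14, frame = first_ge(rmsd_truth, 14),
                       series = rmsd_truth),
    com_distance = list(cutoff = 10, frame = first_ge(d_com, 10),
                        series = d_com))
  # module-derived anchors (recorded at construction)
  sasa <- sasa_fraction_series(traj, ligand_sel)
  truth$sasa_fraction <- list(cutoff = 10,
                              frame = first_crossing(sasa, cutoff = 10)$frame,
                              series = sasa$values)
  tani <- tanimoto_series(traj, ligand_sel)
  truth$tanimoto <- list(cutoff = 0.3,
                         frame = first_crossing(tani, cutoff = 0.3)$frame,
                         series = tani$values)
  list(trajectory = traj, structure = structure3d(coords0,
         name = topo$atoms$name, resid = topo$atoms$resid,
         resname = topo$atoms$resname, element = topo$atoms$element,
         itype = topo$atoms$itype, is_ligand = topo$atoms$is_ligand),
       ligand_sel = ligand_sel, site_sel = site_sel, pair = pair,
       truth = truth, seed = seed)
}

#' Criterion series from a sparse (frame, value) schedule
#'
#' Values are held constant between scheduled frames (step function); the
#' series starts at the first scheduled value.
#'
#' @param schedule data.frame or matrix with columns frame (1-based) and
#'   value.
#' @param n_frames Series length (default: last scheduled frame).
#' @param ... Passed to [criterion_series()] (name, cutoff, dt, ...).
#' @return A `criterion_series`.
#' @export
scheduled_series <- function(schedule, n_frames = NULL, ...) {
  schedule <- as.data.frame(schedule)
  names(schedule)[1:2] <- c("frame", "value")
  schedule <- schedule[order(schedule$frame), ]
  if (is.null(n_frames)) n_frames <- max(schedule$frame)
  vals <- rep(NA_real_, n_frames)
  vals[schedule$frame] <- schedule$value
  for (i in seq_len(n_frames)) {
    if (is.na(vals[i])) vals[i] <- if (i > 1L) vals[i - 1L] else schedule$value[1L]
  }
  criterion_series(vals, ...)
}

#' Exponential replica-time sampler
#'
#' Draws n replica times per system from exponential distributions with
#' the given true means; the generator behind the rank-recovery and
#' bootstrap experiments.
#'
#' @param true_means Named numeric vector of true mean times per system.
#' @param n Replicas per system.
#' @param seed Integer seed.
#' @return data.frame (system, replica, time, censored = FALSE).
#' @export
sample_replica_times <- function(true_means, n, seed = 1L) {
  set.seed(seed)
  if (is.null(names(true_means))) {
    names(true_means) <- paste0("sys", seq_along(true_means))
  }
  do.call(rbind, lapply(names(true_means), function(s) {
    data.frame(system = s, replica = seq_len(n),
               time = rexp(n, rate = 1 / true_means[[s]]), censored = FALSE)
  }))
}

#' Planted two-state fingerprint features for cluster-recovery tests
#'
#' Generates a replica visiting a bound-like contact pattern then an
#' unbound-like one, with feature noise: each frame drops each pattern
#' feature with probability `noise`. The planted labels and the true
#' transition direction are returned with the features.
#'
#' @param n_frames Frames per replica.
#' @param switch_at Frame of the planted transition.
#' @param noise Per-feature dropout probability.
#' @param replica Replica id.
#' @param seed Integer seed.
#' @return A `frame_features` object with attribute `planted` (integer
#'   labels).
#' @export
make_planted_two_state <- function(n_frames = 20L, switch_at = 11L,
                                   noise = 0.05, replica = 1L, seed = 1L) {
  set.seed(seed)
  state_a <- paste0(1:8, ":hydrophobic")
  state_b <- paste0(11:18, ":aromatic")
  contacts_a <- 21:26; contacts_b <- 31:36   # stable nonspecific shells
  planted <- ifelse(seq_len(n_frames) < switch_at, 1L, 2L)
  ifps <- lapply(seq_len(n_frames), function(i) {
    base <- if (planted[i] == 1L) state_a else state_b
    shell <- if (planted[i] == 1L) contacts_a else contacts_b
    keep <- runif(length(base)) > noise
    if (!any(keep)) keep[1L] <- TRUE
    new_ifp(base[keep], c(feature_resids(base[keep]), shell))
  })
  out <- data.frame(replica = replica, frame = seq_len(n_frames),
                    time = (seq_len(n_frames) - 1) * 100,
                    dcom = ifelse(planted == 1L, 0.5, 6) +
                      rnorm(n_frames, 0, 0.1),
                    rmsd = ifelse(planted == 1L, 0.5, 6))
  attr(out, "ifps") <- ifps
  attr(out, "planted") <- planted
  class(out) <- c("frame_features", class(out))
  out
}
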