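# Protein-ligand interaction fingerprints: per-frame sets of
# (residue, interaction-class) features plus a nonspecific contact set,
# compared by Tanimoto (Jaccard) distance. Atom typing comes from the
# per-atom `itype` tag ("apolar", "donor", "acceptor", "cation", "anion",
# "aromatic"); aromatic-typed atoms act as ring centroids.

#' Geometric fingerprint definitions (defaults)
#'
#' All cutoffs in Angstrom; the H-bond donor angle in degrees. The angular
#' condition applies only when the donor carries an explicit hydrogen
#' (within `h_bond_length`); with hydrogens absent the heavy-atom distance
#' alone decides.
#'
#' @param contact,hydrophobic,hbond,ionic,aromatic,cation_pi Distance
#'   cutoffs per interaction class.
#' @param hbond_angle Minimum donor angle (deg) at the hydrogen.
#' @param h_bond_length Maximum donor-hydrogen covalent distance.
#' @return Named list of geometric parameters.
#' @export
ifp_config <- function(contact = 4.5, hydrophobic = 4.0, hbond = 3.5,
                       ionic = 4.5, aromatic = 5.0, cation_pi = 5.0,
                       hbond_angle = 150, h_bond_length = 1.3) {
  list(contact = contact, hydrophobic = hydrophobic, hbond = hbond,
       ionic = ionic, aromatic = aromatic, cation_pi = cation_pi,
       hbond_angle = hbond_angle, h_bond_length = h_bond_length)
}

#' Construct an interaction fingerprint
#'
#' @param features Character vector "resid:class" (unique).
#' @param contacts Integer residue ids with any heavy-atom contact
#'   (superset of residues in `features`).
#' @return Object of class `ifp`.
#' @export
new_ifp <- function(features = character(), contacts = integer()) {
  features <- unique(as.character(features))
  contacts <- sort(unique(c(as.integer(contacts), feature_resids(features))))
  structure(list(features = features, contacts = contacts), class = "ifp")
}

feature_resids <- function(features) {
  if (!length(features)) return(integer())
  as.integer(sub(":.*$", "", features))
}

#' @export
print.ifp <- function(x, ...) {
  cat(sprintf("ifp: %d specific features over %d contact residue(s)\n",
              length(x$features), length(x$contacts)))
  if (length(x$features)) cat(" ", paste(sort(x$features), collapse = ", "), "\n")
  invisible(x)
}

#' Crude element-based atom typing
#'
#' Fills missing `itype` tags from elements: C/S -> apolar, N -> donor,
#' O -> acceptor; hydrogens and other elements stay untyped. Synthetic
#' pocket fixtures carry explicit tags and do not need this.
#'
#' @param structure A `structure3d`.
#' @return The structure with `itype` filled where possible.
#' @export
type_atoms_default <- function(structure) {
  at <- structure$atoms
  miss <- is.na(at$itype) & at$element != "H"
  at$itype[miss & at$element %in% c("C", "S")] <- "apolar"
  at$itype[miss & at$element == "N"] <- "donor"
  at$itype[miss & at$element == "O"] <- "acceptor"
  structure$atoms <- at
  structure
}

#' Compute the interaction fingerprint of one frame
#'
#' @param structure A `structure3d`, or a `trajectory3d` with `frame`.
#' @param ligand_sel Ligand selection (default from flags).
#' @param protein_sel Protein selection (default: non-solvent, non-ion,
#'   non-ligand atoms).
#' @param config Geometric definitions from [ifp_config()].
#' @param frame Frame index when a trajectory is given.
#' @return An `ifp`. Heavy atoms without an `itype` tag contribute to the
#'   nonspecific contact set only (one warning per call).
#' @export
compute_ifp <- function(structure, ligand_sel = NULL, protein_sel = NULL,
                        config = ifp_config(), frame = 1L) {
  if (inherits(structure, "trajectory3d")) {
    coords <- get_frame(structure, frame)
    at <- structure$topology$atoms
  } else {
    coords <- structure$coords
    at <- structure$atoms
  }
  li <- if (is.null(ligand_sel)) which(at$is_ligand) else sel_indices(ligand_sel)
  pi_ <- if (is.null(protein_sel)) {
    setdiff(which(!at$is_solvent & !at$is_ion & !at$is_ligand), li)
  } else sel_indices(protein_sel)
  if (length(li) == 0L) stop("empty ligand selection")
  if (length(pi_) == 0L) return(new_ifp())
  lh <- li[at$element[li] != "H"]
  ph <- pi_[at$element[pi_] != "H"]
  if (anyNA(at$itype[c(lh, ph)])) {
    warning("untyped heavy atoms skipped for specific features")
  }
  # heavy-atom pair distances ligand x protein
  dm <- sqrt(outer(rowSums(coords[lh, , drop = FALSE]^2),
                   rowSums(coords[ph, , drop = FALSE]^2), "+") -
               2 * coords[lh, , drop = FALSE] %*% t(coords[ph, , drop = FALSE]))
  dm[dm < 0] <- 0  # numerical guard
  contacts <- unique(at$resid[ph[colSums(dm <= config$contact) > 0]])
  feats <- character()
  add <- function(resids, class) {
    if (length(resids)) feats <<- c(feats, paste0(unique(resids), ":", class))
  }
  lt <- at$itype[lh]; pt <- at$itype[ph]
  pair_resids <- function(lmask, pmask, cutoff) {
    if (!any(lmask, na.rm = TRUE) || !any(pmask, na.rm = TRUE)) return(integer())
    lm <- which(!is.na(lmask) & lmask); pm <- which(!is.na(pmask) & pmask)
    sub <- dm[lm, pm, drop = FALSE]
    at$resid[ph[pm[colSums(sub <= cutoff) > 0]]]
  }
  add(pair_resids(lt == "apolar", pt == "apolar", config$hydrophobic),
      "hydrophobic")
  add(pair_resids(lt == "cation", pt == "anion", config$ionic), "ionic")
  add(pair_resids(lt == "anion", pt == "cation", config$ionic), "ionic")
  add(pair_resids(lt == "aromatic", pt == "aromatic", config$aromatic),
      "aromatic")
  add(c(pair_resids(lt == "cation", pt == "aromatic", config$cation_pi),
        pair_resids(lt == "aromatic", pt == "cation", config$cation_pi)),
      "cation_pi")
  # hydrogen bonds with optional donor-angle condition
  hb <- function(donor_idx, acceptor_idx, class) {
    if (!length(donor_idx) || !length(acceptor_idx)) return()
    for (d in donor_idx) {
      hd <- which(at$element == "H")
      if (length(hd)) {
        dh <- sqrt(rowSums(sweep(coords[hd, , drop = FALSE], 2L, coords[d, ])^2))
        hd <- hd[dh <= config$h_bond_length]
      }
      for (a in acceptor_idx) {
        dda <- sqrt(sum((coords[d, ] - coords[a, ])^2))
        if (dda > config$hbond) next
        ok <- if (length(hd)) {
          any(vapply(hd, function(h) {
            v1 <- coords[d, ] - coords[h, ]; v2 <- coords[a, ] - coords[h, ]
            ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                       sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
            ang >= config$hbond_angle
          }, logical(1)))
        } else TRUE
        if (ok) {
          res <- if (class == "hbond_donor") at$resid[a] else at$resid[d]
          add(res, class)
        }
      }
    }
  }
  hb(lh[!is.na(lt) & lt == "donor"], ph[!is.na(pt) & pt == "acceptor"],
     "hbond_donor")
  hb(ph[!is.na(pt) & pt == "donor"], lh[!is.na(lt) & lt == "acceptor"],
     "hbond_acceptor")
  new_ifp(feats, contacts)
}

#' Tanimoto distance between two fingerprints
#'
#' `1 - |a & b| / |a | b|` on the specific feature sets; the distance of
#' two empty fingerprints is 0.
#'
#' @param a,b `ifp` objects (or plain feature character vectors).
#' @return Distance in \[0, 1\].
#' @export
tanimoto_distance <- function(a, b) {
  fa <- if (inherits(a, "ifp")) a$features else unique(as.character(a))
  fb <- if (inherits(b, "ifp")) b$features else unique(as.character(b))
  un <- length(union(fa, fb))
  if (un == 0L) return(0)
  1 - length(intersect(fa, fb)) / un
}

#' Tanimoto-distance-to-initial-fingerprint series
#'
#' Computes the fingerprint of every frame and its Tanimoto distance to the
#' frame-1 reference fingerprint.
#'
#' @param traj A `trajectory3d` with typed atoms.
#' @param ligand_sel,protein_sel,config As in [compute_ifp()].
#' @param cutoff Criterion cutoff (default 0.3, the best-correlating
#'   threshold).
#' @return A `criterion_series` (dimensionless, "exceed" direction).
#' @export
tanimoto_series <- function(traj, ligand_sel = NULL, protein_sel = NULL,
                            config = ifp_config(), cutoff = 0.3) {
  ref <- compute_ifp(traj, ligand_sel, protein_sel, config, frame = 1L)
  if (length(ref$features) == 0L) stop("no initial contacts in the reference fingerprint")
  vals <- vapply(seq_len(n_frames(traj)), function(i) {
    tanimoto_distance(ref, compute_ifp(traj, ligand_sel, protein_sel, config,
                                       frame = i))
  }, numeric(1))
  criterion_series(vals, name = "tanimoto", units = "", cutoff = cutoff,
                   dt = traj$dt)
}

#' Fingerprint-based residence time
#'
#' First frame at which the Tanimoto distance to the initial fingerprint
#' reaches the cutoff; censored when it never does.
#'
#' @param traj A `trajectory3d` with typed atoms.
#' @param cutoff Tanimoto cutoff (default 0.3).
#' @param ... Passed to [tanimoto_series()].
#' @return An `event_time`.
#' @export
ifp_residence_time <- function(traj, cutoff = 0.3, ...) {
  first_crossing(tanimoto_series(traj, ...), cutoff = cutoff)
}
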