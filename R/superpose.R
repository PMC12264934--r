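# Superposition and fluctuation primitives. The weighted Kabsch fit is
# written here because the path-variable alignment contract needs per-atom
# weights; reflections are rejected so chirality is preserved.

#' Weighted Kabsch superposition
#'
#' Finds the proper rotation and translation minimising the weighted RMSD of
#' `mobile` onto `reference`.
#'
#' @param mobile,reference N x 3 coordinate matrices, N >= 3.
#' @param weights Optional non-negative weights (not all zero).
#' @return List with `rotation` (3 x 3, det +1), `translation` (length 3),
#'   and `rmsd` (Angstrom). Applying `coords %*% R + t` (rows) maps mobile
#'   onto reference.
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference)) stop("point counts differ")
  if (nrow(mobile) < 3L) stop("underdetermined: need at least 3 points")
  n <- nrow(mobile)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n) stop("weights length mismatch")
  if (any(weights < 0)) stop("weights must be non-negative")
  w <- weights / sum(weights)
  if (!all(is.finite(w))) stop("weights must not be all zero")
  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  a <- sweep(mobile, 2L, cm)
  b <- sweep(reference, 2L, cr)
  h <- t(a * w) %*% b
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rot <- t(rot)                     # row-vector convention: x %*% rot
  fitted <- a %*% rot
  rmsd <- sqrt(sum(w * rowSums((fitted - b)^2)))
  list(rotation = rot, translation = cr - cm %*% rot, rmsd = rmsd)
}

#' Apply a superposition transform to coordinates
#' @param coords N x 3 matrix.
#' @param fit Result of [kabsch_superpose()].
#' @return Transformed N x 3 matrix.
#' @export
apply_transform <- function(coords, fit) {
  sweep(coords %*% fit$rotation, 2L, -as.numeric(fit$translation))
}

#' Per-frame RMSD series relative to a reference frame
#'
#' Each frame is superposed on the reference using `fit_sel`, then the RMSD
#' is measured over `measure_sel` (ligand RMSD after receptor fit, for
#' example). With `fit_sel = NULL` no superposition is applied.
#'
#' @param traj A `trajectory3d`.
#' @param reference Reference frame index (default 1) or an N x 3 matrix.
#' @param fit_sel Selection used for superposition (NULL = no fit).
#' @param measure_sel Selection over which the deviation is measured
#'   (NULL = all atoms).
#' @return Numeric vector, one RMSD (Angstrom) per frame.
#' @export
rmsd_series <- function(traj, reference = 1L, fit_sel = NULL,
                        measure_sel = NULL) {
  ref <- if (is.matrix(reference)) reference else get_frame(traj, reference)
  midx <- if (is.null(measure_sel)) seq_len(n_atoms(traj)) else sel_indices(measure_sel)
  if (length(midx) == 0L) stop("empty measure selection")
  fidx <- if (is.null(fit_sel)) NULL else sel_indices(fit_sel)
  if (!is.null(fidx) && length(fidx) == 0L) stop("empty fit selection")
  fw <- if (!is.null(fit_sel) && inherits(fit_sel, "atom_selection")) fit_sel$weights else NULL
  vapply(seq_len(n_frames(traj)), function(i) {
    x <- get_frame(traj, i)
    if (!is.null(fidx)) {
      fit <- kabsch_superpose(x[fidx, , drop = FALSE], ref[fidx, , drop = FALSE],
                              weights = fw)
      x <- apply_transform(x, fit)
    }
    sqrt(mean(rowSums((x[midx, , drop = FALSE] - ref[midx, , drop = FALSE])^2)))
  }, numeric(1))
}

#' Per-atom root-mean-square fluctuation
#'
#' RMSF about the time-mean position. Frames are assumed pre-superposed
#' unless `fit_sel` is given, in which case every frame is first fitted onto
#' frame 1 over that selection.
#'
#' @param traj A `trajectory3d` with at least 2 frames.
#' @param sel Selection of atoms to report (NULL = all).
#' @param fit_sel Optional selection used to superpose frames first.
#' @return Numeric vector of per-atom RMSF (Angstrom) for `sel`.
#' @export
rmsf <- function(traj, sel = NULL, fit_sel = NULL) {
  nf <- n_frames(traj)
  if (nf < 2L) stop("RMSF needs at least 2 frames")
  idx <- if (is.null(sel)) seq_len(n_atoms(traj)) else sel_indices(sel)
  if (length(idx) == 0L) stop("empty selection")
  frames <- lapply(seq_len(nf), function(i) get_frame(traj, i))
  if (!is.null(fit_sel)) {
    fidx <- sel_indices(fit_sel)
    ref <- frames[[1L]]
    frames <- lapply(frames, function(x) {
      fit <- kabsch_superpose(x[fidx, , drop = FALSE], ref[fidx, , drop = FALSE])
      apply_transform(x, fit)
    })
  }
  stack <- array(unlist(frames), dim = c(n_atoms(traj), 3L, nf))
  mean_pos <- apply(stack[idx, , , drop = FALSE], c(1L, 2L), mean)
  dev2 <- vapply(seq_len(nf), function(i) {
    rowSums((stack[idx, , i, drop = TRUE] - mean_pos)^2)
  }, numeric(length(idx)))
  if (is.null(dim(dev2))) dev2 <- matrix(dev2, nrow = length(idx))
  sqrt(rowMeans(dev2))
}
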