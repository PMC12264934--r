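# Shrake-Rupley solvent-accessible surface area. Test points are placed on
# a deterministic golden-section spiral over each atom's solvent-expanded
# sphere (radius + probe); a point is accessible when outside every
# neighbour's expanded sphere. Written here because no installed R package
# computes SASA without an external binary.

# unit sphere points, golden-section spiral (deterministic)
sphere_points <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' @param x A `structure3d`, or an N x 3 coordinate matrix (then `radii`
#'   must be given).
#' @param radii Per-atom vdW radii (Angstrom); taken from the structure
#'   when `x` is a `structure3d`.
#' @param probe_radius Solvent probe radius (Angstrom, default 1.4).
#' @param n_sphere_points Test points per atom (default 960).
#' @return List with `atom_area` (Angstrom^2 per atom) and `total`.
#' @export
shrake_rupley_sasa <- function(x, radii = NULL, probe_radius = 1.4,
                               n_sphere_points = 960L) {
  if (inherits(x, "structure3d")) {
    radii <- x$atoms$radius
    x <- x$coords
  }
  x <- as.matrix(x)
  n <- nrow(x)
  if (is.null(radii)) stop("missing radii")
  if (length(radii) != n || any(!is.finite(radii)) || any(radii <= 0)) {
    stop("missing or invalid radii")
  }
  pts <- sphere_points(n_sphere_points)
  r_ext <- radii + probe_radius
  # neighbour lists from the pairwise distance matrix (fixtures are small)
  d2 <- as.matrix(dist(x))^2
  area <- numeric(n)
  for (i in seq_len(n)) {
    cutoff2 <- (r_ext[i] + r_ext)^2
    nb <- which(d2[i, ] < cutoff2 & seq_len(n) != i)
    surf <- sweep(pts * r_ext[i], 2L, x[i, ], "+")
    if (length(nb)) {
      acc <- rep(TRUE, n_sphere_points)
      for (j in nb) {
        if (!any(acc)) break
        dj <- sweep(surf[acc, , drop = FALSE], 2L, x[j, ])
        acc[acc] <- rowSums(dj^2) > r_ext[j]^2
      }
      frac <- sum(acc) / n_sphere_points
    } else frac <- 1
    area[i] <- frac * 4 * pi * r_ext[i]^2
  }
  list(atom_area = area, total = sum(area))
}
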