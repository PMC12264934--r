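# Analytic toy "receptor" systems: a harmonic channel along the first axis
# with Gaussian barriers on the axis profile and soft confining walls at the
# channel ends. Because the transverse restraint and the end walls are zero
# on the axis where the Gaussians peak, the saddle height over the bound
# basin equals the Gaussian amplitude exactly, by construction.

#' Boltzmann constant in kcal/(mol K)
#' @export
KB_KCAL <- 0.0019872041

# kcal/mol -> amu A^2/ps^2
ENERGY_TO_MD <- 418.4

#' Construct an analytic toy unbinding system
#'
#' The potential (kcal/mol) over x in R^dim is
#' `U(x) = sum_j A_j exp(-(x1 - c_j)^2 / (2 w_j^2)) + (k_perp/2) sum_{d>1} x_d^2
#'  + k_end (x1 - x_min)^2 [x1 < x_min] + k_end (x1 - x_max)^2 [x1 > x_max]`.
#' The bound basin is the channel segment before the first barrier, the
#' vestibule the segment beyond it.
#'
#' @param barrier_kbt Barrier height in units of kBT (single Gaussian
#'   amplitude A = barrier_kbt * kB * T at the saddle).
#' @param dim Dimensionality (default 2: channel axis + one transverse).
#' @param channel_length Channel length x_max - x_min in Angstrom.
#' @param barrier_pos Barrier centre on the axis (Angstrom).
#' @param barrier_width Gaussian width w (Angstrom).
#' @param k_perp Transverse harmonic constant (kcal/mol/A^2).
#' @param k_end End-wall constant (kcal/mol/A^2).
#' @param temperature Kelvin.
#' @param friction Langevin friction (1/ps).
#' @param mass Particle mass (amu).
#' @return Object of class `toy_system` with labelled basins and the exact
#'   barrier height `delta_e_kbt`.
#' @export
toy_system <- function(barrier_kbt, dim = 2L, channel_length = 30,
                       barrier_pos = 15, barrier_width = 2,
                       k_perp = 2, k_end = 10,
                       temperature = 303, friction = 0.05, mass = 12) {
  stopifnot(barrier_kbt > 0, dim >= 1L, barrier_pos > 0,
            barrier_pos < channel_length)
  kbt <- KB_KCAL * temperature
  sys <- list(dim = as.integer(dim),
              gauss = data.frame(centre = barrier_pos,
                                 height = barrier_kbt * kbt,
                                 width = barrier_width),
              k_perp = k_perp, k_end = k_end,
              x_min = 0, x_max = channel_length,
              temperature = temperature, friction = friction, mass = mass,
              kbt = kbt, delta_e_kbt = barrier_kbt,
              basins = list(bound = c(0, barrier_pos),
                            vestibule = c(barrier_pos, channel_length)))
  class(sys) <- "toy_system"
  sys
}

#' @export
print.toy_system <- function(x, ...) {
  cat(sprintf("toy_system: %dD channel [%g, %g] A, barrier %.3g kBT at x = %g, T = %g K\n",
              x$dim, x$x_min, x$x_max, x$delta_e_kbt, x$gauss$centre[1L],
              x$temperature))
  invisible(x)
}

#' Potential energy and analytic gradient of a toy system
#'
#' @param system A `toy_system`.
#' @param x Position vector (length `system$dim`).
#' @return List with `energy` (kcal/mol) and `gradient` (kcal/mol/A).
#' @export
toy_potential <- function(system, x) {
  x <- as.numeric(x)
  stopifnot(length(x) == system$dim)
  u <- 0; g <- numeric(system$dim)
  for (j in seq_len(nrow(system$gauss))) {
    c0 <- system$gauss$centre[j]; a <- system$gauss$height[j]
    w <- system$gauss$width[j]
    e <- a * exp(-(x[1L] - c0)^2 / (2 * w^2))
    u <- u + e
    g[1L] <- g[1L] - e * (x[1L] - c0) / w^2
  }
  if (system$dim > 1L) {
    u <- u + 0.5 * system$k_perp * sum(x[-1L]^2)
    g[-1L] <- g[-1L] + system$k_perp * x[-1L]
  }
  if (x[1L] < system$x_min) {
    u <- u + system$k_end * (x[1L] - system$x_min)^2
    g[1L] <- g[1L] + 2 * system$k_end * (x[1L] - system$x_min)
  }
  if (x[1L] > system$x_max) {
    u <- u + system$k_end * (x[1L] - system$x_max)^2
    g[1L] <- g[1L] + 2 * system$k_end * (x[1L] - system$x_max)
  }
  list(energy = u, gradient = g)
}

#' Build a family of toy "mutants" differing only in barrier height
#'
#' All systems share the basin geometry; only the saddle height varies, so
#' mean escape times should rank exactly with the barrier heights.
#'
#' @param barriers Positive, distinct barrier heights in kBT.
#' @param ... Passed to [toy_system()].
#' @return Named list of `toy_system` objects ("dE3", "dE4", ...).
#' @export
make_mutant_family <- function(barriers = c(3, 4, 5, 6, 7), ...) {
  stopifnot(all(barriers > 0), !anyDuplicated(barriers))
  out <- lapply(barriers, toy_system, ...)
  names(out) <- paste0("dE", format(barriers, trim = TRUE))
  out
}

#' Default milestone frameset along a toy channel
#'
#' P point milestones on the channel axis between the bound minimum and the
#' channel end; Z then measures (approximately) the squared transverse
#' excursion. Alignment is disabled (single-particle path).
#'
#' @param system A `toy_system`.
#' @param P Number of milestones.
#' @param from,to Axis range; defaults to the full channel.
#' @return A `path_frameset`.
#' @export
toy_channel_frameset <- function(system, P = 20L, from = system$x_min,
                                 to = system$x_max) {
  pos <- seq(from, to, length.out = P)
  frames <- lapply(pos, function(p) {
    matrix(c(p, rep(0, system$dim - 1L)), nrow = 1L)
  })
  path_frameset(frames, use_alignment = FALSE)
}
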