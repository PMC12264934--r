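# Ratchet (adiabatic-bias) potential, walls, CV plumbing and the stochastic
# dynamics drivers. The bias is a one-sided harmonic on
# rho = (CV - CV0)^2 relative to its running minimum rho_m: the system pays
# nothing while progressing and is penalised when it recedes.

#' Ratchet bias bookkeeping
#'
#' @param cv0 Target CV value.
#' @param k Force constant (kcal/mol per CV^4 unit; e.g. kcal/mol/A^4 for a
#'   distance CV, kcal/mol for the dimensionless path progress S).
#' @return Object of class `ratchet_state` with running `rho` and `rho_m`
#'   (NA until the first update).
#' @export
ratchet_state <- function(cv0, k) {
  if (k < 0) stop("ratchet force constant must be non-negative")
  structure(list(cv0 = cv0, k = k, rho = NA_real_, rho_m = NA_real_),
            class = "ratchet_state")
}

#' One ratchet bias update
#'
#' Computes rho = (cv - cv0)^2, evaluates the bias against the previous
#' running minimum rho_m (bias energy `(k/2)(rho - rho_m)^2` only when
#' rho > rho_m), then updates rho_m. On the first call rho_m is initialised
#' to rho, so the bias is off at the start of a run.
#'
#' @param cv_value Current CV value (finite).
#' @param state A `ratchet_state`.
#' @return List with `energy` (kcal/mol), `force` (on the CV, = -dU/dCV)
#'   and the updated `state`.
#' @export
ratchet_update <- function(cv_value, state) {
  if (!is.finite(cv_value)) stop("non-finite CV value")
  rho <- (cv_value - state$cv0)^2
  rho_m <- if (is.na(state$rho_m)) rho else state$rho_m
  if (rho > rho_m) {
    energy <- 0.5 * state$k * (rho - rho_m)^2
    force <- -state$k * (rho - rho_m) * 2 * (cv_value - state$cv0)
  } else {
    energy <- 0
    force <- 0
  }
  state$rho <- rho
  state$rho_m <- min(rho_m, rho)
  list(energy = energy, force = force, state = state)
}

#' Harmonic wall specification
#'
#' @param z0 Threshold (Angstrom^2 for a Z wall).
#' @param k Force constant (> 0); PLUMED convention `U = k (z - z0)^2`
#'   beyond the threshold, without the 1/2 factor.
#' @param side "upper" or "lower".
#' @return Object of class `wall_spec`.
#' @export
wall_spec <- function(z0 = 10, k = 1000, side = "upper") {
  if (k <= 0) stop("wall force constant must be positive")
  side <- match.arg(side, c("upper", "lower"))
  structure(list(z0 = z0, k = k, side = side), class = "wall_spec")
}

#' Wall energy and restoring force
#'
#' @param z CV value (finite).
#' @param wall A `wall_spec`.
#' @return List with `energy` (kcal/mol) and `force` (= -dU/dz).
#' @export
wall_energy <- function(z, wall) {
  if (!is.finite(z)) stop("non-finite wall coordinate")
  viol <- if (wall$side == "upper") z - wall$z0 else wall$z0 - z
  if (viol > 0) {
    sgn <- if (wall$side == "upper") 1 else -1
    list(energy = wall$k * viol^2, force = -2 * wall$k * viol * sgn)
  } else {
    list(energy = 0, force = 0)
  }
}

#' Signed COM-distance projection collective variable
#'
#' Projection of the ligand-to-site centre-of-mass displacement on a unit
#' axis (e.g. the membrane normal).
#'
#' @param structure A `structure3d` or an N x 3 coordinate matrix.
#' @param ligand_sel,site_sel Atom selections.
#' @param axis Length-3 axis; normalised internally (error on zero).
#' @param masses Optional per-atom masses (length N).
#' @return Signed projection in Angstrom.
#' @export
distance_projection_cv <- function(structure, ligand_sel, site_sel,
                                   axis = c(0, 0, 1), masses = NULL) {
  coords <- if (inherits(structure, "structure3d")) structure$coords else as.matrix(structure)
  nrm <- sqrt(sum(axis^2))
  if (nrm == 0) stop("zero projection axis")
  axis <- axis / nrm
  li <- sel_indices(ligand_sel); si <- sel_indices(site_sel)
  if (length(li) == 0L || length(si) == 0L) stop("empty selection")
  ml <- if (is.null(masses)) NULL else masses[li]
  ms <- if (is.null(masses)) NULL else masses[si]
  com_l <- centre_of_mass(coords, li, ml)
  com_s <- centre_of_mass(coords, si, ms)
  sum((com_l - com_s) * axis)
}

#' One BAOAB Langevin step
#'
#' Reference R implementation of the integrator used by the compiled engine
#' (half kick, half drift, Ornstein-Uhlenbeck velocity update, half drift,
#' half kick). Uses R's RNG, so runs are reproducible with [set.seed()].
#'
#' @param x,v Position and velocity vectors (Angstrom, Angstrom/ps).
#' @param force_fn Function(x) returning the force in kcal/mol/Angstrom.
#' @param system A `toy_system` (supplies mass, friction, temperature).
#' @param dt Time step (ps, > 0).
#' @return List with updated `x` and `v`.
#' @export
langevin_step <- function(x, v, force_fn, system, dt) {
  if (dt <= 0) stop("dt must be positive")
  m <- system$mass
  f <- force_fn(x)
  if (any(!is.finite(f))) stop("non-finite force")
  v <- v + 0.5 * dt * f * ENERGY_TO_MD / m
  x <- x + 0.5 * dt * v
  c1 <- exp(-system$friction * dt)
  c2 <- sqrt((1 - c1^2) * system$kbt * ENERGY_TO_MD / m)
  v <- c1 * v + c2 * rnorm(length(v))
  x <- x + 0.5 * dt * v
  f <- force_fn(x)
  if (any(!is.finite(f))) stop("non-finite force")
  v <- v + 0.5 * dt * f * ENERGY_TO_MD / m
  list(x = x, v = v)
}

#' Run a ratchet-biased stochastic simulation on a toy system
#'
#' Integrates Langevin dynamics on the analytic toy potential with the
#' adiabatic-bias ratchet applied to the chosen collective variable, until
#' the stop criterion fires or `max_time` is reached (censored result).
#'
#' @param system A `toy_system`.
#' @param cv Either `list(type = "projection", axis = ...)` (axis in the
#'   system's dimension) or a `path_frameset` of point milestones.
#' @param ratchet A `ratchet_state` (use `k = 0` for an unbiased reference
#'   run; `NULL` disables the bias entirely, consuming the same random
#'   stream).
#' @param walls Optional `wall_spec` applied to Z (path CV only).
#' @param stop_criterion List `list(type, value)` with type "cv_ge"
#'   (CV >= value), "x_ge" (channel coordinate >= value) or "none".
#' @param max_time Simulation cap in ps.
#' @param seed Integer seed (applied via [set.seed()]).
#' @param x0 Starting position (default: bound-basin minimum).
#' @param dt Time step (ps).
#' @param record_stride Record every this many steps.
#' @return Object of class `simulation_result`: `time` (ps), `censored`,
#'   `series` data.frame (t, cv, z, bias, rho_m), recorded `coords`,
#'   `seed`, `n_steps`.
#' @export
run_abmd <- function(system, cv, ratchet, walls = NULL,
                     stop_criterion = list(type = "none", value = NA),
                     max_time = 1000, seed = 1, x0 = NULL, dt = 0.01,
                     record_stride = 10L) {
  stopifnot(inherits(system, "toy_system"))
  if (is.null(x0)) x0 <- c(system$x_min, rep(0, system$dim - 1L))
  if (inherits(cv, "path_frameset")) {
    nodes <- do.call(rbind, cv$frames)
    cv_type <- "path"
    lambda <- cv$lambda
    axis <- rep(0, system$dim)
  } else if (is.list(cv) && identical(cv$type, "projection")) {
    cv_type <- "proj"
    axis <- cv$axis / sqrt(sum(cv$axis^2))
    nodes <- matrix(0, 1L, system$dim)
    lambda <- 1
  } else stop("cv must be a path_frameset or list(type='projection', axis=)")
  bias_enabled <- !is.null(ratchet)
  if (is.null(ratchet)) ratchet <- ratchet_state(0, 0)
  wall_z0 <- if (is.null(walls)) Inf else walls$z0
  wall_k <- if (is.null(walls)) 0 else walls$k
  set.seed(seed)
  res <- .abmd_core(unclass(system), as.numeric(x0), dt, max_time,
                    system$mass, system$friction, system$kbt,
                    cv_type, as.numeric(axis), nodes, lambda,
                    ratchet$k, ratchet$cv0, bias_enabled,
                    wall_z0, wall_k,
                    stop_criterion$type, as.numeric(stop_criterion$value),
                    as.integer(record_stride))
  structure(list(time = res$time, censored = res$censored,
                 series = data.frame(t = res$t, cv = res$cv, z = res$z,
                                     bias = res$bias, rho_m = res$rho_m),
                 coords = res$coords, seed = seed, n_steps = res$n_steps,
                 max_time = max_time),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("simulation_result: %s at %g ps (%d recorded frames, seed %d)\n",
              if (x$censored) "censored" else "event", x$time,
              nrow(x$series), x$seed))
  invisible(x)
}

#' Run the path-variable ratchet protocol on a toy system
#'
#' Ratchet on the path progress S with target CV0 = P, harmonic upper wall
#' on Z, stop when S reaches `P - 0.5` (the end milestone) unless another
#' criterion is supplied.
#'
#' @param system A `toy_system`.
#' @param frameset A `path_frameset` over the system's coordinates (see
#'   [toy_channel_frameset()]).
#' @param k Ratchet force constant on S (kcal/mol; default 0.05).
#' @param z_wall Upper wall on Z (default threshold 10 Angstrom^2, force
#'   constant 1000).
#' @param stop_criterion As in [run_abmd()]; default `S >= P - 0.5`.
#' @param ... Passed to [run_abmd()] (max_time, seed, dt, ...).
#' @return A `simulation_result`.
#' @export
run_pcv_abmd <- function(system, frameset, k = 0.05,
                         z_wall = wall_spec(10, 1000), stop_criterion = NULL,
                         ...) {
  stopifnot(inherits(frameset, "path_frameset"))
  if (is.null(stop_criterion)) {
    stop_criterion <- list(type = "cv_ge", value = frameset$P - 0.5)
  }
  run_abmd(system, cv = frameset, ratchet = ratchet_state(frameset$P, k),
           walls = z_wall, stop_criterion = stop_criterion, ...)
}

#' First-passage times of a toy mutant family under the path-ratchet protocol
#'
#' Runs `n_replicas` seeded simulations per system and collects per-replica
#' event times, the desk-scale analogue of running biased unbinding replicas
#' per receptor mutant.
#'
#' @param family Named list of `toy_system`s (see [make_mutant_family()]).
#' @param n_replicas Replicas per system.
#' @param frameset_fn Function(system) returning the path frameset; default
#'   [toy_channel_frameset()].
#' @param k,z_wall,max_time,dt Protocol parameters (see [run_pcv_abmd()]).
#' @param seed Base seed; replica r of system s runs with
#'   `seed + 1000*(s-1) + r`.
#' @return data.frame (system, replica, time, censored, seed).
#' @export
simulate_family <- function(family, n_replicas = 20L,
                            frameset_fn = toy_channel_frameset,
                            k = 0.05, z_wall = wall_spec(10, 1000),
                            max_time = 2000, dt = 0.01, seed = 1) {
  out <- list()
  for (s in seq_along(family)) {
    sys <- family[[s]]
    fs <- frameset_fn(sys)
    for (r in seq_len(n_replicas)) {
      rseed <- seed + 1000L * (s - 1L) + r
      res <- run_pcv_abmd(sys, fs, k = k, z_wall = z_wall,
                          max_time = max_time, dt = dt, seed = rseed,
                          record_stride = 100L)
      out[[length(out) + 1L]] <- data.frame(
        system = names(family)[s], replica = r, time = res$time,
        censored = res$censored, seed = rseed)
    }
  }
  do.call(rbind, out)
}
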