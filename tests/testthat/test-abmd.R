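test_that("ratchet bias is inactive while progressing and follows the min recursion", {
  st <- ratchet_state(0, 1)
  # rho decreasing: bias stays off
  u <- ratchet_update(5, st)
  expect_equal(u$energy, 0)
  u2 <- ratchet_update(4, u$state)
  expect_equal(u2$energy, 0)
  expect_equal(u2$state$rho_m, 16)
  # direct substitution with the distance-protocol force constant
  st2 <- ratchet_state(0, 0.005)
  st2$rho_m <- 1
  u3 <- ratchet_update(sqrt(2), st2)   # rho = 2, rho_m = 1
  expect_equal(u3$energy, 0.5 * 0.005 * (2 - 1)^2)
  expect_equal(u3$energy, 0.0025)
  # hand-traced min recursion on CV sequence {10, 8, 9, 7}
  st3 <- ratchet_state(0, 1)
  trace_rho_m <- c(); energies <- c()
  for (v in c(10, 8, 9, 7)) {
    u <- ratchet_update(v, st3)
    st3 <- u$state
    trace_rho_m <- c(trace_rho_m, st3$rho_m)
    energies <- c(energies, u$energy)
  }
  expect_equal(trace_rho_m, c(100, 64, 64, 49))
  expect_equal(energies > 0, c(FALSE, FALSE, TRUE, FALSE))
  expect_error(ratchet_state(0, -1), "non-negative")
})

test_that("wall energy follows the PLUMED exponent-2 convention", {
  w <- wall_spec(10, 1000)
  expect_equal(wall_energy(10, w)$energy, 0)
  expect_equal(wall_energy(9, w)$energy, 0)
  expect_equal(wall_energy(11, w)$energy, 1000)
  expect_lt(wall_energy(11, w)$force, 0)
  lower <- wall_spec(2, 5, side = "lower")
  expect_equal(wall_energy(1, lower)$energy, 5)
  expect_gt(wall_energy(1, lower)$force, 0)
})

test_that("distance projection CV is the dot product with the axis", {
  x <- rbind(c(0, 0, 20), c(0, 0, 30))
  expect_equal(distance_projection_cv(x, 2L, 1L, c(0, 0, 1)), 10)
  # orthogonal displacement projects to zero
  x2 <- rbind(c(0, 0, 0), c(5, 3, 0))
  expect_equal(distance_projection_cv(x2, 2L, 1L, c(0, 0, 1)), 0)
  expect_error(distance_projection_cv(x, 2L, 1L, c(0, 0, 0)), "zero")
  # random geometry vs direct recomputation with mass weighting
  set.seed(13)
  coords <- random_points(6)
  m <- runif(6, 1, 16)
  ax <- c(1, 2, 2) / 3
  got <- distance_projection_cv(coords, 1:3, 4:6, ax, masses = m)
  coml <- colSums(coords[1:3, ] * m[1:3]) / sum(m[1:3])
  coms <- colSums(coords[4:6, ] * m[4:6]) / sum(m[4:6])
  expect_equal(got, sum((coml - coms) * ax), tolerance = 1e-12)
})

test_that("langevin step is deterministic, inert at T = 0 with no force", {
  sys <- toy_system(5, temperature = 0)
  out <- langevin_step(c(1, 2), c(0, 0), function(x) c(0, 0), sys, 0.01)
  expect_equal(out$x, c(1, 2))
  expect_equal(out$v, c(0, 0))
  sys2 <- toy_system(5)
  set.seed(1); a <- langevin_step(c(1, 0), c(0, 0), function(x) -x, sys2, 0.01)
  set.seed(1); b <- langevin_step(c(1, 0), c(0, 0), function(x) -x, sys2, 0.01)
  expect_identical(a, b)
  expect_error(langevin_step(c(1, 0), c(0, 0), function(x) c(NaN, 0), sys2,
                             0.01), "finite")
  expect_error(langevin_step(c(1, 0), c(0, 0), function(x) c(0, 0), sys2, 0),
               "positive")
})

test_that("unbiased sampling matches equipartition in the transverse well", {
  # transverse coordinate is harmonic with k_perp: var(y) = kBT / k_perp
  sys <- toy_system(5, k_perp = 2, friction = 1)
  res <- run_abmd(sys, cv = list(type = "projection", axis = c(1, 0)),
                  ratchet = NULL, max_time = 6000, seed = 99, x0 = c(15, 0),
                  record_stride = 5L)
  y <- res$coords[-seq_len(20000), 2L]  # discard equilibration
  expect_equal(var(y), sys$kbt / sys$k_perp, tolerance = 0.05)
})

test_that("toy potential gradient matches finite differences and barrier is exact", {
  set.seed(77)
  for (de in c(3, 7)) {
    sys <- toy_system(de)
    for (rep in 1:5) {
      x <- c(runif(1, 0, sys$x_max), runif(1, -2, 2))
      p <- toy_potential(sys, x)
      num <- vapply(1:2, function(d) {
        h <- 1e-6
        xp <- x; xm <- x
        xp[d] <- xp[d] + h; xm[d] <- xm[d] - h
        (toy_potential(sys, xp)$energy - toy_potential(sys, xm)$energy) / (2 * h)
      }, numeric(1))
      expect_equal(p$gradient, num, tolerance = 1e-5)
    }
    # saddle height over the bound basin equals the requested barrier
    saddle <- toy_potential(sys, c(sys$gauss$centre[1L], 0))$energy
    bound_min <- toy_potential(sys, c(0, 0))$energy
    expect_equal((saddle - bound_min) / sys$kbt, de, tolerance = 1e-6)
  }
})

test_that("zero ratchet constant reproduces the unbiased trajectory bitwise", {
  sys <- toy_system(4)
  cv <- list(type = "projection", axis = c(1, 0))
  a <- run_abmd(sys, cv, ratchet = ratchet_state(30, 0), max_time = 20,
                seed = 7, record_stride = 1L)
  b <- run_abmd(sys, cv, ratchet = NULL, max_time = 20, seed = 7,
                record_stride = 1L)
  expect_identical(a$coords, b$coords)
  expect_identical(a$series$cv, b$series$cv)
  expect_true(all(a$series$bias == 0))
  # same seed twice is bitwise reproducible
  c2 <- run_abmd(sys, cv, ratchet = ratchet_state(30, 0), max_time = 20,
                 seed = 7, record_stride = 1L)
  expect_identical(a$coords, c2$coords)
})

test_that("ratchet invariants hold along biased runs", {
  sys <- toy_system(6)
  fs <- toy_channel_frameset(sys)
  res <- run_pcv_abmd(sys, fs, max_time = 2000, seed = 3, record_stride = 1L)
  expect_true(all(diff(res$series$rho_m) <= 1e-12))
  expect_true(all(res$series$bias >= 0))
  # bias is zero whenever rho is at its running minimum
  rho <- (res$series$cv - fs$P)^2
  at_min <- abs(rho - res$series$rho_m) < 1e-9
  expect_true(all(res$series$bias[at_min & res$series$z <= 10] == 0))
})

test_that("stronger ratchet constants accelerate first passage", {
  sys <- toy_system(6)
  cv <- list(type = "projection", axis = c(1, 0))
  stop_c <- list(type = "x_ge", value = sys$x_max)
  # k grid spanning the weak-to-strong bias regime at this CV's rho scale
  # (rho ~ 1e3 A^2, so k ~ 1e-5..1e-3 kcal/mol/A^4 covers both limits)
  mean_fpt <- vapply(c(1e-5, 1e-4, 1e-3), function(k) {
    times <- vapply(1:20, function(r) {
      run_abmd(sys, cv, ratchet = ratchet_state(sys$x_max + 5, k),
               stop_criterion = stop_c, max_time = 10000, seed = 100 + r,
               record_stride = 1000L)$time
    }, numeric(1))
    mean(times)
  }, numeric(1))
  expect_true(all(diff(mean_fpt) < 0))
})

test_that("run_abmd censors when the stop criterion never fires", {
  sys <- toy_system(4)
  res <- run_abmd(sys, list(type = "projection", axis = c(1, 0)),
                  ratchet = NULL,
                  stop_criterion = list(type = "x_ge", value = 1e6),
                  max_time = 5, seed = 1)
  expect_true(res$censored)
  expect_equal(res$time, 5)
})

test_that("pcv run stops immediately when started at the end milestone", {
  sys <- toy_system(4)
  fs <- toy_channel_frameset(sys)
  res <- run_pcv_abmd(sys, fs, max_time = 100, seed = 2,
                      x0 = c(sys$x_max, 0))
  expect_false(res$censored)
  expect_equal(res$time, 0)
})

test_that("ratchet drives S to the end milestone and the wall confines Z", {
  sys <- toy_system(5)
  fs <- toy_channel_frameset(sys)
  for (seed in 1:5) {
    res <- run_pcv_abmd(sys, fs, max_time = 2000, seed = seed,
                        record_stride = 10L)
    expect_false(res$censored)
    expect_gte(max(res$series$cv), fs$P - 0.5)
    # k_w = 1000 allows only ~sqrt(kBT/k_w) thermal penetration beyond z0
    expect_lt(max(res$series$z), 10 + 0.5)
  }
})

test_that("unbiased integrator conserves energy at zero friction and temperature", {
  sys <- toy_system(5, temperature = 0, friction = 0)
  x <- c(10, 0.5); v <- c(2, 0)
  e0 <- toy_potential(sys, x)$energy +
    0.5 * sys$mass * sum(v^2) / 418.4
  for (i in 1:2000) {
    out <- langevin_step(x, v, function(p) -toy_potential(sys, p)$gradient,
                         sys, 0.005)
    x <- out$x; v <- out$v
  }
  e1 <- toy_potential(sys, x)$energy + 0.5 * sys$mass * sum(v^2) / 418.4
  expect_equal(e1, e0, tolerance = 0.02)
})

test_that("toy mutant family ranks by barrier height with perfect rank correlation", {
  fam <- make_mutant_family(c(3, 4, 5, 6, 7))
  expect_equal(vapply(fam, function(s) s$delta_e_kbt, numeric(1)),
               c(dE3 = 3, dE4 = 4, dE5 = 5, dE6 = 6, dE7 = 7))
  df <- simulate_family(fam, n_replicas = 20, max_time = 2000, seed = 11)
  means <- tapply(df$time, df$system, mean)[names(fam)]
  expect_true(all(diff(means) > 0))
  expect_equal(spearman(as.numeric(means), c(3, 4, 5, 6, 7)), 1.0)
  expect_equal(sum(df$censored), 0L)
})
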