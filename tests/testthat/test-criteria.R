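test_that("first_crossing uses a closed boundary and censors correctly", {
  s <- criterion_series(c(3, 5, 11, 13, 12), cutoff = 12, dt = 1)
  ev <- first_crossing(s)
  expect_equal(ev$frame, 4L)       # first value >= 12 (13 at frame 4)
  expect_false(ev$censored)
  # value exactly at the cutoff triggers (closed boundary)
  ev12 <- first_crossing(criterion_series(c(3, 12, 13), cutoff = 12))
  expect_equal(ev12$frame, 2L)
  # never exceeds -> censored at the last frame
  evc <- first_crossing(criterion_series(c(1, 2, 3), cutoff = 10, dt = 2))
  expect_true(evc$censored)
  expect_equal(evc$time, 4)
  # crossing at the first frame -> time 0
  ev0 <- first_crossing(criterion_series(c(15, 1), cutoff = 12))
  expect_equal(ev0$time, 0)
  expect_error(first_crossing(criterion_series(c(1, NA), cutoff = 1)), "NaN|NA")
  expect_error(first_crossing(numeric(), cutoff = 1), "empty")
  # fall-below direction
  fb <- criterion_series(c(5, 4, 2, 3), cutoff = 2, direction = "fall-below")
  expect_equal(first_crossing(fb)$frame, 3L)
})

test_that("first_crossing equals a linear-scan oracle on random series", {
  set.seed(101)
  for (rep in 1:20) {
    v <- cumsum(rnorm(30))
    ct <- quantile(v, runif(1))
    got <- first_crossing(criterion_series(v, cutoff = ct))
    hits <- which(v >= ct)
    if (length(hits)) {
      expect_equal(got$frame, hits[1L])
      expect_false(got$censored)
    } else expect_true(got$censored)
  }
})

test_that("event time is non-decreasing in cutoff for monotone series", {
  set.seed(31)
  v <- sort(runif(40, 0, 20))
  s <- criterion_series(v)
  cuts <- sort(runif(6, 0, 25))
  times <- vapply(cuts, function(ct) first_crossing(s, cutoff = ct)$time,
                  numeric(1))
  expect_true(all(diff(times) >= 0))
})

test_that("pair and COM distance series match direct geometry", {
  # static pair at 4 A
  topo <- structure3d(rbind(c(0, 0, 0), c(4, 0, 0)))
  tr <- trajectory3d(topo, lapply(1:3, function(i) topo$coords))
  expect_equal(atom_pair_distance_series(tr, 1L, 2L)$values, rep(4, 3))
  # linear separation gives a linear series
  frames <- lapply(0:3, function(i) rbind(c(0, 0, 0), c(4 + i, 0, 0)))
  tr2 <- trajectory3d(topo, frames)
  expect_equal(atom_pair_distance_series(tr2, 1L, 2L)$values, 4:7)
  # random frames vs direct norm oracle
  set.seed(8)
  rnd <- random_trajectory(5, 6)
  got <- atom_pair_distance_series(rnd, 2L, 5L)$values
  exp_ <- vapply(1:6, function(i) {
    x <- get_frame(rnd, i)
    sqrt(sum((x[2L, ] - x[5L, ])^2))
  }, numeric(1))
  expect_equal(got, exp_, tolerance = 1e-12)
  # COM distance: coincident COMs -> 0, pure translation -> magnitude
  topo4 <- structure3d(random_points(4))
  x0 <- topo4$coords
  x0[3:4, ] <- x0[1:2, ]          # ligand atoms coincide with site atoms
  tr3 <- trajectory3d(topo4, list(x0))
  expect_equal(com_distance_series(tr3, 3:4, 1:2)$values, 0)
  xz <- x0; xz[3:4, 3L] <- xz[3:4, 3L] + 7
  tr4 <- trajectory3d(topo4, list(x0, xz))
  expect_equal(com_distance_series(tr4, 3:4, 1:2)$values, c(0, 7))
  # mass-weighted oracle
  m <- c(12, 16, 14, 1)
  got_m <- com_distance_series(tr4, 3:4, 1:2, masses = m)$values[2L]
  cl <- colSums(xz[3:4, ] * m[3:4]) / sum(m[3:4])
  cs <- colSums(xz[1:2, ] * m[1:2]) / sum(m[1:2])
  expect_equal(got_m, sqrt(sum((cl - cs)^2)), tolerance = 1e-12)
})

test_that("shrake-rupley SASA matches analytic limits", {
  # isolated sphere: 4 pi (r + probe)^2
  one <- shrake_rupley_sasa(matrix(0, 1, 3), radii = 1.9)
  expect_equal(one$total, 4 * pi * 3.3^2, tolerance = 0.02 * 4 * pi * 3.3^2)
  # two atoms far apart: additivity
  two <- shrake_rupley_sasa(rbind(c(0, 0, 0), c(100, 0, 0)),
                            radii = c(1.9, 1.5))
  expect_equal(two$total, 4 * pi * (3.3^2 + 2.9^2), tolerance = 1)
  # atom enclosed in a tight cage has zero accessible area
  dirs <- sphere_pts_fixture(26)
  cage <- dirs * 2.0
  caged <- shrake_rupley_sasa(rbind(c(0, 0, 0), cage),
                              radii = c(1.5, rep(1.7, nrow(cage))))
  expect_equal(caged$atom_area[1L], 0)
  expect_error(shrake_rupley_sasa(matrix(0, 1, 3)), "radii")
})

test_that("SASA is invariant under rigid motion", {
  set.seed(12)
  x <- random_points(8, scale = 3)
  r <- runif(8, 1.2, 1.9)
  base <- shrake_rupley_sasa(x, r)$total
  moved <- x %*% t(random_rotation()) + matrix(rnorm(3), 8, 3, byrow = TRUE)
  expect_equal(shrake_rupley_sasa(moved, r)$total, base, tolerance = 0.5)
})

test_that("SASA fraction spans buried to fully exposed on the pocket fixture", {
  fx <- make_pocket_fixture(seed = 2, n_frames = 12, dz = 2)
  s <- sasa_fraction_series(fx$trajectory, fx$ligand_sel)
  expect_lt(s$values[1L], 10)                 # caged ligand
  expect_gt(s$values[length(s$values)], 90)   # ligand out in the solvent
  expect_true(all(s$values >= 0 & s$values <= 100))
  # two-pass independent oracle on one frame
  at <- fx$trajectory$topology$atoms
  li <- fx$ligand_sel$indices
  env <- which(!at$is_solvent & !at$is_ion)
  x <- get_frame(fx$trajectory, 5)
  cplx <- shrake_rupley_sasa(x[env, ], at$radius[env])
  iso <- shrake_rupley_sasa(x[li, ], at$radius[li])
  expect_equal(s$values[5L],
               100 * sum(cplx$atom_area[match(li, env)]) / iso$total,
               tolerance = 1e-9)
})

test_that("solvation shell detection honours the closed 6 A boundary", {
  # ligand atom at origin in a pure water environment
  wat <- cbind(runif(20, -3, 3), runif(20, -3, 3), runif(20, 4, 8))
  s <- structure3d(rbind(c(0, 0, 0), wat),
                   resname = c("LIG", rep("WAT", 20)),
                   resid = c(1, rep(2:21)), element = c("C", rep("O", 20)),
                   is_ligand = c(TRUE, rep(FALSE, 20)))
  expect_true(solvation_shell_unbound(s))
  # one protein atom at 5.9 A -> still bound
  s2 <- structure3d(rbind(c(0, 0, 0), c(5.9, 0, 0)),
                    resname = c("LIG", "ALA"), resid = 1:2,
                    element = c("C", "C"), is_ligand = c(TRUE, FALSE))
  expect_false(solvation_shell_unbound(s2))
  # exactly at 6.0 A -> closed boundary, still a contact
  s3 <- structure3d(rbind(c(0, 0, 0), c(6, 0, 0)),
                    resname = c("LIG", "ALA"), resid = 1:2,
                    element = c("C", "C"), is_ligand = c(TRUE, FALSE))
  expect_false(solvation_shell_unbound(s3))
  # at 6.01 A -> unbound
  s4 <- structure3d(rbind(c(0, 0, 0), c(6.01, 0, 0)),
                    resname = c("LIG", "ALA"), resid = 1:2,
                    element = c("C", "C"), is_ligand = c(TRUE, FALSE))
  expect_true(solvation_shell_unbound(s4))
})

test_that("evaluate_all_criteria reports the constructed crossing order", {
  fx <- make_pocket_fixture(seed = 1)
  tab <- evaluate_all_criteria(
    fx$trajectory,
    list(pair = fx$pair, ligand_sel = fx$ligand_sel, site_sel = fx$site_sel,
         tanimoto = 0.3))
  # ground-truth frames recorded by the generator are reproduced exactly
  for (nm in names(fx$truth)) {
    row <- tab[tab$criterion == nm & tab$cutoff == fx$truth[[nm]]$cutoff, ]
    expect_equal(row$frame, fx$truth[[nm]]$frame, label = nm)
    expect_false(row$censored)
  }
  # cutoff sweeps are monotone within each criterion
  for (nm in unique(tab$criterion)) {
    sub <- tab[tab$criterion == nm, ]
    expect_true(all(diff(sub$time[order(sub$cutoff)]) >= 0), label = nm)
  }
  # static trajectory: geometric criteria censored
  st <- fx$trajectory
  st$frames <- st$frames[, , c(1L, 1L), drop = FALSE]
  tab2 <- evaluate_all_criteria(
    st, list(pair = fx$pair, ligand_sel = fx$ligand_sel,
             site_sel = fx$site_sel))
  expect_true(all(tab2$censored))
})
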