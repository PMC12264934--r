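test_that("msd_to_frame is zero at milestones and rigid-motion invariant", {
  set.seed(3)
  fs <- random_frameset(P = 4, n_atoms = 6)
  for (i in 1:4) {
    expect_equal(msd_to_frame(fs$frames[[i]], i, fs), 0, tolerance = 1e-12)
    moved <- fs$frames[[i]] %*% t(random_rotation()) +
      matrix(rnorm(3), 6, 3, byrow = TRUE)
    expect_equal(msd_to_frame(moved, i, fs), 0, tolerance = 1e-10)
  }
  expect_error(msd_to_frame(random_points(5), 1, fs), "mismatch")
})

test_that("msd_to_frame applies displace weights as a weighted mean", {
  # 3 equal displace weights, one atom offset by 1 A -> MSD = 1/3
  base <- random_points(3)
  fs <- path_frameset(list(base, base + 5), use_alignment = FALSE)
  x <- base
  x[2L, 1L] <- x[2L, 1L] + 1
  expect_equal(msd_to_frame(x, 1, fs), 1 / 3, tolerance = 1e-12)
  # weight concentrated on the offset atom -> MSD = 1
  fs2 <- path_frameset(list(base, base + 5), displace = c(0, 1, 0),
                       use_alignment = FALSE)
  expect_equal(msd_to_frame(x, 1, fs2), 1, tolerance = 1e-12)
})

test_that("path_cvs matches hand-computed values on the 1D three-node path", {
  fs <- path_frameset(lapply(c(0, 1, 2), function(p) matrix(p, 1, 1)),
                      lambda = 1, use_alignment = FALSE)
  pc <- path_cvs(matrix(0.5, 1, 1), fs)
  # direct evaluation: d2 = (0.25, 0.25, 2.25), w = exp(-d2)
  w <- exp(-c(0.25, 0.25, 2.25))
  expect_equal(pc$S, sum(1:3 * w) / sum(w), tolerance = 1e-12)
  expect_equal(pc$Z, -log(sum(w)), tolerance = 1e-12)
  expect_equal(pc$S, 1.59507, tolerance = 1e-4)
  expect_equal(pc$Z, -0.50862, tolerance = 1e-4)
})

test_that("path_cvs handles degenerate and dominant-term limits", {
  # P = 1: single-term sums, S = 1 and Z = d1^2
  fs1 <- path_frameset(list(matrix(c(0, 0), 1, 2)), lambda = 0.7,
                       use_alignment = FALSE)
  pc <- path_cvs(matrix(c(3, 4), 1, 2), fs1)
  expect_equal(pc$S, 1)
  expect_equal(pc$Z, 25, tolerance = 1e-10)
  # large lambda at a node: S -> node index, Z -> 0
  fs <- path_frameset(lapply(0:4, function(p) matrix(p, 1, 1)),
                      lambda = 50, use_alignment = FALSE)
  for (i in 1:5) {
    pc <- path_cvs(matrix(i - 1, 1, 1), fs)
    expect_equal(pc$S, i, tolerance = 0.01)
    expect_lt(abs(pc$Z), 0.01)
  }
  expect_error(path_cvs(matrix(NaN, 1, 1), fs), "finite")
})

test_that("path_cvs is numerically stable at lambda*d^2 ~ 1e4", {
  fs <- path_frameset(lapply(c(0, 1), function(p) matrix(p, 1, 1)),
                      lambda = 100, use_alignment = FALSE)
  pc <- path_cvs(matrix(11, 1, 1), fs)   # lambda*d2 up to 1.21e4
  expect_true(is.finite(pc$S) && is.finite(pc$Z))
  expect_equal(pc$S, 2, tolerance = 1e-6)     # nearer node dominates
  expect_equal(pc$Z, 100, tolerance = 1e-6)   # Z -> min d2
})

test_that("path_cvs matches a direct-summation oracle on random framesets", {
  set.seed(17)
  for (rep in 1:20) {
    fs <- random_frameset(P = sample(2:10, 1), n_atoms = sample(4:30, 1))
    x <- fs$frames[[1L]] + matrix(rnorm(length(fs$frames[[1L]]), sd = 0.5),
                                  nrow(fs$frames[[1L]]))
    got <- path_cvs(x, fs)
    exp_ <- path_cv_oracle(x, fs)
    expect_equal(got$S, exp_$S, tolerance = 1e-10)
    expect_equal(got$Z, exp_$Z, tolerance = 1e-10)
  }
})

test_that("S along the frameset's own nodes is strictly increasing, S and Z rigid-motion invariant", {
  set.seed(19)
  fs <- random_frameset(P = 6, n_atoms = 8)
  s_at_nodes <- vapply(1:6, function(i) path_cvs(fs$frames[[i]], fs)$S,
                       numeric(1))
  expect_true(all(diff(s_at_nodes) > 0))
  x <- fs$frames[[3L]] + 0.2
  base <- path_cvs(x, fs)
  moved <- x %*% t(random_rotation()) + matrix(rnorm(3), nrow(x), 3,
                                               byrow = TRUE)
  got <- path_cvs(moved, fs)
  expect_equal(got$S, base$S, tolerance = 1e-8)
  expect_equal(got$Z, base$Z, tolerance = 1e-8)
})

test_that("lambda rule follows 2.3 over the mean adjacent MSD with scaling law", {
  # adjacent MSDs all 2.3 -> lambda = 1 (1D nodes sqrt(2.3) apart)
  d <- sqrt(2.3)
  fs <- path_frameset(lapply(0:3, function(i) matrix(i * d, 1, 1)),
                      use_alignment = FALSE)
  expect_equal(lambda_rule(fs), 1.0, tolerance = 1e-12)
  # adjacent MSDs {1, 3} -> lambda = 2.3 / 2
  fs2 <- path_frameset(list(matrix(0, 1, 1), matrix(1, 1, 1),
                            matrix(1 + sqrt(3), 1, 1)),
                       use_alignment = FALSE)
  expect_equal(lambda_rule(fs2), 1.15, tolerance = 1e-12)
  # doubling coordinates scales MSDs x4, lambda x1/4
  fs4 <- path_frameset(lapply(0:3, function(i) matrix(2 * i * d, 1, 1)),
                       use_alignment = FALSE)
  expect_equal(lambda_rule(fs4), 0.25, tolerance = 1e-12)
  expect_error(path_frameset(list(matrix(0, 1, 1), matrix(0, 1, 1)),
                             use_alignment = FALSE), "duplicate")
})

test_that("select_align_atoms filters candidates by RMSF threshold", {
  set.seed(23)
  base <- random_points(6)
  # atom 2 oscillates +-1 A, others rigid
  frames <- lapply(1:8, function(i) {
    x <- base
    x[2L, 1L] <- x[2L, 1L] + ifelse(i %% 2L == 0L, 1, -1)
    x
  })
  topo <- structure3d(base, name = rep("CA", 6))
  tr <- trajectory3d(topo, frames)
  sel <- select_align_atoms(tr, threshold = 0.6)
  expect_equal(sel$indices, c(1L, 3L, 4L, 5L, 6L))
  # rigid trajectory keeps all candidates
  rigid <- trajectory3d(topo, lapply(1:3, function(i) base))
  expect_equal(select_align_atoms(rigid, 0.6)$indices, 1:6)
  # threshold below every fluctuation errors
  expect_error(select_align_atoms(tr, threshold = 0), "no stable atoms")
  # agreement with an independent brute-force RMSF filter on mixed mobility
  base2 <- random_points(10)
  scale_atom <- seq(0.05, 1.2, length.out = 10)
  frames2 <- lapply(1:12, function(i) {
    base2 + matrix(rnorm(30), 10, 3) * scale_atom
  })
  jit <- trajectory3d(structure3d(base2, name = rep("CA", 10)), frames2)
  got <- select_align_atoms(jit, threshold = 0.8)$indices
  expect_equal(got, which(rmsf(jit) < 0.8))
})

test_that("build_frameset yields equidistant milestones", {
  # 1D straight line sampled over 200 frames -> nodes at 0..19
  topo <- structure3d(matrix(0, 1, 3), name = "CA")
  frames <- lapply(seq(0, 19, length.out = 200), function(p) {
    matrix(c(p, 0, 0), 1, 3)
  })
  tr <- trajectory3d(topo, frames)
  sel <- atom_selection(1L)
  fs <- build_frameset(tr, P = 20, align_sel = sel, displace_sel = sel)
  nodes_x <- vapply(fs$frames, function(f) f[1L, 1L], numeric(1))
  expect_equal(nodes_x, 0:19, tolerance = 1e-8)
  msd <- vapply(1:19, function(i) msd_to_frame(fs$frames[[i + 1L]], i, fs),
                numeric(1))
  expect_lt((max(msd) - min(msd)) / mean(msd), 1e-8)
  # already equidistant input is returned unchanged
  tr2 <- trajectory3d(topo, fs$frames |> lapply(function(f) f))
  fs2 <- build_frameset(tr2, P = 20, align_sel = sel, displace_sel = sel)
  expect_equal(vapply(fs2$frames, function(f) f[1L, 1L], numeric(1)), 0:19,
               tolerance = 1e-8)
  expect_error(build_frameset(tr2, P = 50, align_sel = sel,
                              displace_sel = sel), "shorter")
})

test_that("build_frameset re-spaces non-uniform paths to the arc-length oracle", {
  # quadratically sampled monotone 1D path: positions s^2 * 19
  topo <- structure3d(matrix(0, 1, 3), name = "CA")
  pos <- (seq(0, 1, length.out = 120))^2 * 19
  tr <- trajectory3d(topo, lapply(pos, function(p) matrix(c(p, 0, 0), 1, 3)))
  sel <- atom_selection(1L)
  fs <- build_frameset(tr, P = 10, align_sel = sel, displace_sel = sel)
  nodes_x <- vapply(fs$frames, function(f) f[1L, 1L], numeric(1))
  # arc length along a 1D line is the coordinate itself
  expect_equal(nodes_x, seq(0, 19, length.out = 10), tolerance = 0.05)
  msd <- vapply(1:9, function(i) msd_to_frame(fs$frames[[i + 1L]], i, fs),
                numeric(1))
  expect_lt((max(msd) - min(msd)) / mean(msd), 0.15)
})
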