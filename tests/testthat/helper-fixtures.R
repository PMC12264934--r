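# Shared fixtures built in code.

random_points <- function(n, d = 3L, scale = 5) {
  matrix(runif(n * d, -scale, scale), n, d)
}

rotation_z <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0,
           -sin(theta), cos(theta), 0,
           0, 0, 1), 3L, 3L)
}

random_rotation <- function() {
  # QR of a Gaussian matrix, determinant forced +1
  q <- qr.Q(qr(matrix(rnorm(9), 3L)))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

# small random trajectory around a base structure
random_trajectory <- function(n_atoms = 8L, n_frames = 10L, jitter = 0.3,
                              dt = 1) {
  base <- random_points(n_atoms)
  frames <- lapply(seq_len(n_frames), function(i) {
    base + matrix(rnorm(n_atoms * 3L, sd = jitter), n_atoms, 3L)
  })
  trajectory3d(structure3d(base), frames, dt = dt)
}

# brute-force best-fit RMSD over a quaternion grid (independent of Kabsch)
quaternion_grid_rmsd <- function(mobile, reference, n_coarse = 12L) {
  qs <- as.matrix(expand.grid(w = seq(-1, 1, length.out = n_coarse),
                              x = seq(-1, 1, length.out = n_coarse),
                              y = seq(-1, 1, length.out = n_coarse),
                              z = seq(-1, 1, length.out = n_coarse)))
  qs <- qs[rowSums(qs^2) > 1e-6, ]
  qs <- qs / sqrt(rowSums(qs^2))
  a <- sweep(mobile, 2L, colMeans(mobile))
  b <- sweep(reference, 2L, colMeans(reference))
  rmsd_q <- function(q) {
    w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
    r <- matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
                  2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
                  2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
                3L, 3L, byrow = TRUE)
    sqrt(mean(rowSums((a %*% t(r) - b)^2)))
  }
  vals <- apply(qs, 1L, rmsd_q)
  best <- qs[which.min(vals), ]
  # local refinement around the best grid quaternion
  fn <- function(p) rmsd_q(p / sqrt(sum(p^2)))
  opt <- optim(best, fn, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  opt$value
}

# independent direct-summation path CV oracle (no log-sum-exp)
path_cv_oracle <- function(x, frameset) {
  d2 <- vapply(seq_len(frameset$P), function(i) {
    msd_to_frame(x, i, frameset)
  }, numeric(1))
  w <- exp(-frameset$lambda * d2)
  list(S = sum(seq_len(frameset$P) * w) / sum(w),
       Z = -log(sum(w)) / frameset$lambda)
}

# random monotone frameset, kept inside the naive direct-summation oracle's
# validity domain (lambda * max MSD small enough that exp() cannot underflow;
# the log-sum-exp contract at large lambda*d^2 is tested separately)
random_frameset <- function(P = 5L, n_atoms = 10L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_atoms <- max(n_atoms, 4L)
  repeat {
    base <- random_points(n_atoms)
    step <- matrix(runif(n_atoms * 3L, 0.2, 0.6), n_atoms, 3L)
    frames <- lapply(seq_len(P), function(i) base + (i - 1L) * step)
    fs <- path_frameset(frames)
    d2max <- msd_to_frame(fs$frames[[P]], 1L, fs)
    if (fs$lambda * d2max < 600) return(fs)
  }
}

# n roughly uniform directions on the unit sphere (deterministic)
sphere_pts_fixture <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

random_ifp <- function(n_max = 8L) {
  classes <- c("hydrophobic", "aromatic", "hbond_donor", "hbond_acceptor",
               "ionic", "cation_pi")
  n <- sample.int(n_max, 1L)
  new_ifp(paste0(sample.int(20L, n), ":", sample(classes, n, replace = TRUE)))
}
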