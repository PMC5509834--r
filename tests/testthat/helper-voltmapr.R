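# Shared fixtures and independent oracles for the test suite.

rand_obs <- function(n, d = 2, seed = NULL, extent = 10) {
  voltmapr:::with_seed(seed, {
    obs_set(matrix(stats::runif(n * d, 0, extent), n, d), stats::rnorm(n))
  })
}

# Independent GP oracle: build the full joint (n + q) covariance and apply
# the Gaussian conditioning identity with explicit solve().
brute_gp_posterior <- function(spec, obs, Xq) {
  n <- n_obs(obs)
  Kqq <- kernel_eval(spec, Xq, Xq)
  if (n == 0) return(list(mean = rep(0, nrow(as.matrix(Xq))), cov = Kqq))
  Kxx <- kernel_eval(spec, obs$X, obs$X) + diag(spec$sigma2, n)
  Kqx <- kernel_eval(spec, Xq, obs$X)
  W <- solve(Kxx)
  list(mean = as.numeric(Kqx %*% W %*% obs$y),
       cov = Kqq - Kqx %*% W %*% t(Kqx))
}

# Independent scalar posterior entropy at one candidate (explicit inverse).
brute_entropy_at <- function(spec, obs, x) {
  v <- brute_gp_posterior(spec, obs, matrix(x, nrow = 1))$cov[1, 1]
  0.5 * log(max(v, .Machine$double.xmin)) + 0.5 * log(2 * pi * exp(1))
}

# Brute-force SSIM oracle: explicit loop over every valid 11x11 window.
brute_ssim <- function(est, truth, win = 11L, sigma = 1.5) {
  L <- diff(range(truth))
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  x <- seq_len(win) - (win + 1) / 2
  g1 <- exp(-x^2 / (2 * sigma^2)); g1 <- g1 / sum(g1)
  W <- outer(g1, g1)
  nr <- nrow(est); nc <- ncol(est)
  vals <- c()
  for (i in seq_len(nr - win + 1)) {
    for (j in seq_len(nc - win + 1)) {
      a <- est[i:(i + win - 1), j:(j + win - 1)]
      b <- truth[i:(i + win - 1), j:(j + win - 1)]
      mx <- sum(W * a); my <- sum(W * b)
      vx <- sum(W * a^2) - mx^2; vy <- sum(W * b^2) - my^2
      cxy <- sum(W * a * b) - mx * my
      vals <- c(vals, ((2 * mx * my + C1) * (2 * cxy + C2)) /
                        ((mx^2 + my^2 + C1) * (vx + vy + C2)))
    }
  }
  mean(vals)
}

# Independent 2D Epanechnikov sampler by rejection from the unit disc.
epan2_reject <- function(n) {
  out <- matrix(NA_real_, 0, 2)
  while (nrow(out) < n) {
    cand <- matrix(stats::runif(3 * n, -1, 1), ncol = 2)
    r2 <- rowSums(cand^2)
    acc <- cand[r2 <= 1 & stats::runif(nrow(cand)) <= (1 - r2), , drop = FALSE]
    out <- rbind(out, acc)
  }
  out[seq_len(n), , drop = FALSE]
}

# Tiny ASCII mesh fixture writers.
write_tetra_ply <- function(path) {
  writeLines(c(
    "ply", "format ascii 1.0",
    "element vertex 4",
    "property float x", "property float y", "property float z",
    "element face 4", "property list uchar int vertex_indices",
    "end_header",
    "0 0 0", "1 0 0", "0 1 0", "0 0 1",
    "3 0 1 2", "3 0 1 3", "3 0 2 3", "3 1 2 3"), path)
  path
}

write_cube_obj <- function(path) {
  v <- expand.grid(x = 0:1, y = 0:1, z = 0:1)
  quads <- rbind(c(1, 2, 4, 3), c(5, 6, 8, 7), c(1, 2, 6, 5),
                 c(3, 4, 8, 7), c(1, 3, 7, 5), c(2, 4, 8, 6))
  writeLines(c(sprintf("v %g %g %g", v$x, v$y, v$z),
               sprintf("f %d %d %d %d", quads[, 1], quads[, 2],
                       quads[, 3], quads[, 4])), path)
  path
}

write_tetra_vtk <- function(path) {
  writeLines(c(
    "# vtk DataFile Version 3.0", "tetra", "ASCII", "DATASET POLYDATA",
    "POINTS 4 float",
    "0 0 0", "1 0 0", "0 1 0", "0 0 1",
    "POLYGONS 4 16",
    "3 0 1 2", "3 0 1 3", "3 0 2 3", "3 1 2 3"), path)
  path
}

# Flat triangulated grid mesh in the z = 0 plane.
plane_mesh <- function(n = 10, extent = 1) {
  ax <- seq(0, extent, length.out = n)
  pts <- as.matrix(expand.grid(x = ax, y = ax))
  pts <- cbind(pts, 0)
  dimnames(pts) <- NULL
  faces <- matrix(0L, 0, 3)
  idx <- function(i, j) (j - 1L) * n + i
  for (j in seq_len(n - 1)) for (i in seq_len(n - 1)) {
    faces <- rbind(faces,
                   c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
                   c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1)))
  }
  voltmapr:::new_sample_domain(pts, "mesh", faces = faces)
}

# Matern via the general Bessel-function form (independent of the
# closed-form implementation).
matern_bessel <- function(r, l, sf2, nu) {
  ifelse(r == 0, sf2, {
    a <- sqrt(2 * nu) * r / l
    sf2 * 2^(1 - nu) / gamma(nu) * a^nu * besselK(a, nu)
  })
}

# Two-case demonstration CSV fixture for the CLI tests.
demo_csv_fixture <- function(path, n_cases = 2, n = 15, seed = 1) {
  voltmapr:::with_seed(seed, {
    rows <- do.call(rbind, lapply(seq_len(n_cases), function(i) {
      X <- cbind(runif(n, 0, 10), runif(n, 0, 10), runif(n, 0, 10))
      data.frame(case_id = paste0("c", i), x = X[, 1], y = X[, 2],
                 z = X[, 3], value = sin(X[, 1] / 2) + rnorm(n, 0, 0.05))
    }))
    write.csv(rows, path, row.names = FALSE)
  })
  path
}
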