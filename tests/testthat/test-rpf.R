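theta0 <- kernel_spec("matern", length_scale = 1, sf2 = 1, sigma2 = 0.01)

test_that("initial particle set is uniform and centred on the prior", {
  ps <- init_particles(theta0, m = 100, spread = 0.5, seed = 1)
  expect_equal(ps$weights, rep(0.01, 100))
  # degenerate support collapses on theta0
  ps0 <- init_particles(theta0, m = 10, spread = 1e-9, seed = 2)
  expect_equal(exp(ps0$theta[, 1]), rep(1, 10), tolerance = 1e-6)
  expect_equal(exp(ps0$theta[, 2]), rep(1, 10), tolerance = 1e-6)
  # Monte-Carlo mean of the log-particles equals log theta0 within 3 SE
  psb <- init_particles(theta0, m = 1e4, spread = 0.5, seed = 3)
  se <- log(1.5) / sqrt(3) / sqrt(1e4)
  expect_lt(abs(mean(psb$theta[, 1]) - 0), 3 * se)
  expect_lt(abs(mean(psb$theta[, 2]) - 0), 3 * se)
})

test_that("weight updates renormalize, keep symmetry, ignore particle order", {
  obs <- rand_obs(5, seed = 5)
  # two identical particles stay balanced
  ps2 <- init_particles(theta0, m = 2, spread = 1e-12, seed = 4)
  up <- update_weights(ps2, obs, c(1, 1), 0.3)
  expect_equal(up$weights, c(0.5, 0.5), tolerance = 1e-12)
  # general set renormalizes
  ps <- init_particles(theta0, m = 50, spread = 0.5, seed = 6)
  up <- update_weights(ps, obs, c(2, 3), -0.4)
  expect_equal(sum(up$weights), 1, tolerance = 1e-12)
  # permuting particles permutes weights identically
  p <- sample(50)
  ps_p <- voltmapr:::new_particle_set(ps$theta[p, ], ps$weights[p],
                                      ps$base_spec)
  up_p <- update_weights(ps_p, obs, c(2, 3), -0.4)
  expect_equal(up_p$weights, up$weights[p], tolerance = 1e-12)
})

test_that("resample-move yields uniform weights and bounded jitter", {
  ps <- init_particles(theta0, m = 40, spread = 0.5, seed = 7)
  # all weight on one particle: outputs cluster around it
  w <- rep(0, 40); w[17] <- 1
  ps1 <- voltmapr:::new_particle_set(ps$theta, w, ps$base_spec)
  out <- resample_move(ps1, seed = 8)
  expect_equal(out$weights, rep(1 / 40, 40))
  # weighted covariance of a point mass is zero, so the jitter collapses
  expect_true(all(abs(sweep(out$theta, 2, ps$theta[17, ])) < 1e-4))
  # positivity in the linear domain survives the move
  psb <- init_particles(theta0, m = 200, spread = 0.9, seed = 9)
  up <- update_weights(psb, rand_obs(4, seed = 10), c(5, 5), 0.1)
  mv <- resample_move(up, seed = 11)
  expect_true(all(is.finite(exp(mv$theta))) && all(exp(mv$theta) > 0))
})

test_that("resample-move reproduces the weighted distribution convolved with the kernel", {
  m <- 1e5
  set.seed(12)
  # bimodal weight profile over a wide support
  theta <- cbind(runif(m, -1, 1), runif(m, -1, 1))
  w <- ifelse(theta[, 1] < 0, 3, 1) * ifelse(theta[, 2] > 0.5, 2, 1)
  ps <- voltmapr:::new_particle_set(theta, w / sum(w), theta0)
  out <- resample_move(ps, seed = 13)
  # oracle: independent index resampling + rejection-sampled Epanechnikov
  mu <- colSums(ps$theta * ps$weights)
  ctrd <- sweep(ps$theta, 2, mu)
  S <- crossprod(ctrd * sqrt(ps$weights))
  h <- (8 / pi * 6 * (2 * sqrt(pi))^2)^(1 / 6) * m^(-1 / 6)
  idx <- sample.int(m, m, replace = TRUE, prob = ps$weights)
  oracle <- ps$theta[idx, ] + h * epan2_reject(m) %*% chol(S)
  for (cmp in 1:2) {
    ks <- suppressWarnings(stats::ks.test(out$theta[, cmp], oracle[, cmp]))
    expect_lt(unname(ks$statistic), 0.02)
  }
})

test_that("effective sample size follows 1 / sum(w^2)", {
  ps <- init_particles(theta0, m = 100, spread = 0.5, seed = 14)
  expect_equal(effective_sample_size(ps), 100, tolerance = 1e-10)
  w1 <- rep(0, 100); w1[3] <- 1
  expect_equal(effective_sample_size(
    voltmapr:::new_particle_set(ps$theta, w1, ps$base_spec)), 1)
  ps3 <- init_particles(theta0, m = 3, spread = 0.5, seed = 15)
  ps3 <- voltmapr:::new_particle_set(ps3$theta, c(0.5, 0.25, 0.25),
                                     ps3$base_spec)
  expect_equal(effective_sample_size(ps3), 1 / 0.375, tolerance = 1e-10)
})

test_that("sequential updates track the generating length scale", {
  l_true <- 2
  wins <- 0L
  n_seeds <- 10
  for (s in seq_len(n_seeds)) {
    set.seed(1100 + s)
    X <- cbind(runif(60, 0, 10), runif(60, 0, 10))
    dom <- voltmapr:::new_sample_domain(X, "grid")
    y <- sample_gp_field(dom, kernel_spec("matern", l_true, 1, 0.01),
                         seed = 1150 + s) + rnorm(60, 0, 0.1)
    ps <- init_particles(theta0, 100, 0.5, seed = 1200 + s)
    ord <- sample(60)
    for (t in 2:25) {
      keep <- ord[seq_len(t - 1)]
      mu <- mean(y[keep])
      ps <- update_weights(ps, obs_set(X[keep, , drop = FALSE], y[keep] - mu),
                           X[ord[t], ], y[ord[t]] - mu)
      ps <- resample_move(ps)
    }
    post_l <- sum(ps$weights * ps$theta[, 1])
    if (abs(post_l - log(l_true)) < abs(0 - log(l_true))) wins <- wins + 1L
  }
  expect_gte(wins, 8)
})

test_that("particle snapshots write valid CSV", {
  ps <- init_particles(theta0, m = 10, spread = 0.5, seed = 16)
  f <- withr::local_tempfile(fileext = ".csv")
  write_particles_csv(ps, f)
  df <- read.csv(f)
  expect_identical(names(df), c("particle_id", "log_l", "log_sf2", "weight"))
  expect_equal(nrow(df), 10)
  expect_equal(sum(df$weight), 1, tolerance = 1e-12)
})
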